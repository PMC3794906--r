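# Identity-based element dynamics -----------------------------------------

#' Turnover, survival and addition primitives
#'
#' Identity-tracked set arithmetic on element id vectors:
#' * turnover rate over a period = (lost + gained) / (2 * initial count);
#' * survival fraction = fraction of the baseline ids still present;
#' * cumulative addition rate = elements created since baseline divided by
#'   the baseline count (elements deleted again still count as additions).
#'
#' @param ids_t0,ids_t1 Element id vectors at the start/end of the period.
#' @return `turnover_rate`: the rate, `NA` if the initial set is empty.
#' @export
turnover_rate <- function(ids_t0, ids_t1) {
  if (length(ids_t0) == 0) return(NA_real_)
  lost <- length(setdiff(ids_t0, ids_t1))
  gained <- length(setdiff(ids_t1, ids_t0))
  (lost + gained) / (2 * length(ids_t0))
}

#' @rdname turnover_rate
#' @param baseline_ids,current_ids Id vectors at lesion onset and at a later
#'   time.
#' @return `survival_fraction`: `|baseline intersect current| / |baseline|`,
#'   `NA` if the baseline is empty.
#' @export
survival_fraction <- function(baseline_ids, current_ids) {
  if (length(baseline_ids) == 0) return(NA_real_)
  length(intersect(baseline_ids, current_ids)) / length(baseline_ids)
}

#' @rdname turnover_rate
#' @param n_created Number of elements created since baseline.
#' @param n_baseline Element count at baseline.
#' @return `cumulative_addition_rate`: `n_created / n_baseline`, `NA` if the
#'   baseline is empty.
#' @export
cumulative_addition_rate <- function(n_created, n_baseline) {
  if (n_baseline == 0) return(NA_real_)
  n_created / n_baseline
}

# Indices (into the per-excitatory-neuron snapshot lists) of the excitatory
# neurons of one region.
region_exc_idx <- function(run, region) {
  net <- run$network
  exc <- which(net$sgn > 0)
  if (is.null(net$regions)) {
    if (region != "all") stop("run has no region map")
    return(seq_along(exc))
  }
  which(net$regions[exc] %in% region)
}

#' Dendritic element dynamics of a region
#'
#' Computes, from the snapshots of a run and for the excitatory neurons of
#' one region, the per-interval turnover rate, the survival fraction of the
#' elements present at lesion onset, the cumulative addition rate since
#' onset, and the mean element counts per neuron. All three rates are
#' computed from element identities (excitatory dendritic elements, i.e.
#' spines), the same bookkeeping the experimental imaging literature uses.
#'
#' @param run A [run_protocol()] result.
#' @param region Region label(s) (`"lpz_center"`, `"lpz_border"`,
#'   `"peri_lpz"`, `"outside"`), or `"all"` for a run without regions.
#' @return Data frame keyed by snapshot update with columns `update`, `day`
#'   (0 at onset), `turnover`, `survival`, `cumulative_addition`,
#'   `mean_dendritic`, `mean_axonal`.
#' @export
element_dynamics <- function(run, region) {
  idx <- region_exc_idx(run, region)
  exc <- which(run$network$sgn > 0)
  snaps <- run$snapshots
  ups <- vapply(snaps, `[[`, numeric(1), "update")
  base_i <- which(ups == run$onset)
  if (length(base_i) != 1)
    stop("no snapshot at the onset update; use a cadence dividing the onset")
  pool_ids <- function(s) unlist(s$dend_ids[idx], use.names = FALSE)
  base_ids <- pool_ids(snaps[[base_i]])
  base_created <- sum(snaps[[base_i]]$created_de[exc][idx])
  prev_ids <- NULL
  out <- lapply(seq_along(snaps), function(i) {
    s <- snaps[[i]]
    ids <- pool_ids(s)
    tr <- if (is.null(prev_ids)) NA_real_ else turnover_rate(prev_ids, ids)
    prev_ids <<- ids
    data.frame(
      update = s$update,
      day = update_to_day(s$update - run$onset),
      turnover = tr,
      survival = if (s$update >= run$onset)
        survival_fraction(base_ids, ids) else NA_real_,
      cumulative_addition = if (s$update >= run$onset)
        cumulative_addition_rate(
          sum(s$created_de[exc][idx]) - base_created,
          length(base_ids)) else NA_real_,
      mean_dendritic = mean(s$z_de[exc][idx]),
      mean_axonal = mean(s$z_ax[exc][idx]))
  })
  do.call(rbind, out)
}

#' Axonal overshoot profile
#'
#' Ratio of the mean axonal element count per excitatory neuron of a region
#' between a lesion run and its matched control, per snapshot, plus the
#' overshoot classification: the ratio must exceed `1 + theta`, peak in the
#' middle post-lesion phase, decline from its peak, and remain above 1 in
#' the late phase (elevated relative to control even after pruning).
#'
#' @param run,control Matched [run_protocol()] results (same seed, cadence
#'   and geometry; `control` without lesion).
#' @param region Region to profile (default `"peri_lpz"`, the source of the
#'   ingrowing axons).
#' @param theta Relative elevation required to call an overshoot.
#' @return List with `series` (data frame `update`, `day`, `ratio`) and
#'   logical `overshoot`.
#' @export
overshoot_profile <- function(run, control, region = "peri_lpz",
                              theta = 0.05) {
  ups <- vapply(run$snapshots, `[[`, numeric(1), "update")
  cups <- vapply(control$snapshots, `[[`, numeric(1), "update")
  if (!identical(ups, cups)) stop("run and control snapshot cadences differ")
  idx <- region_exc_idx(run, region)
  exc <- which(run$network$sgn > 0)
  mz <- function(r) vapply(r$snapshots,
                           function(s) mean(s$z_ax[exc][idx]), numeric(1))
  num <- mz(run); den <- mz(control)
  ratio <- ifelse(num == den, 1, num / den)  # covers the empty early network
  series <- data.frame(update = ups, day = update_to_day(ups - run$onset),
                       ratio = ratio)
  post <- which(ups > run$onset)
  ph <- run$phases
  in_phase <- function(w) post[ups[post] - run$onset >= w[1] &
                               ups[post] - run$onset <= w[2]]
  mid <- in_phase(ph$middle); late <- in_phase(ph$late)
  peak_i <- post[which.max(ratio[post])]
  overshoot <- length(mid) > 0 && length(late) > 0 &&
    max(ratio[post]) > 1 + theta &&
    (ups[peak_i] - run$onset) >= ph$early[2] &&
    (ups[peak_i] - run$onset) <= ph$late[1] &&
    mean(ratio[late]) < max(ratio[post]) &&
    mean(ratio[late]) > 1
  list(series = series, overshoot = overshoot,
       peak_update = ups[peak_i] - run$onset,
       late_ratio = mean(ratio[late]))
}

# Recovery times ------------------------------------------------------------

#' Per-neuron recovery times
#'
#' First post-onset snapshot at which a neuron's calcium reaches
#' `0.9 * eps` and stays there for `sustain` consecutive snapshots
#' ("sustained" recovery, to avoid classifying flicker); `Inf` for neurons
#' that never recover.
#'
#' @param run A [run_protocol()] result.
#' @param sustain Number of consecutive snapshots required.
#' @return Numeric vector of post-onset update indices (one per neuron).
#' @export
recovery_times <- function(run, sustain = 5) {
  eps <- run$scenario$curves$axonal$eps
  ups <- vapply(run$snapshots, `[[`, numeric(1), "update")
  post <- which(ups >= run$onset)
  ca <- vapply(run$snapshots[post], `[[`, numeric(run$network$n), "ca")
  ok <- ca >= 0.9 * eps  # neurons x snapshots
  ns <- ncol(ok)
  out <- rep(Inf, run$network$n)
  for (i in seq_len(nrow(ok))) {
    runs <- rle(ok[i, ])
    ends <- cumsum(runs$lengths)
    hit <- which(runs$values & runs$lengths >= sustain)
    if (length(hit)) {
      first <- ends[hit[1]] - runs$lengths[hit[1]] + sustain - 1
      out[i] <- ups[post[first]] - run$onset
    }
  }
  out
}

# Remapping assay ------------------------------------------------------------

#' Retinotopic remapping assay
#'
#' Frozen-connectivity mapping of spatial input representations: the plane
#' is divided into a 6x6 grid of non-overlapping rectangular areas; each
#' area in turn receives a noisy test current (scaled by each neuron's input
#' multiplier, so deafferented neurons receive none) for `t_test` ms while
#' all other neurons receive zero external input, and spikes are counted.
#' Each neuron's preferred area is the stimulus it responded to most
#' strongly (ties broken toward the lowest area index); neurons whose
#' maximum response is below `theta_resp` spikes are unresponsive. A neuron
#' is additionally flagged *selective* if its maximum response is at least
#' twice its median response across stimuli (plus one spike): a diffusely
#' ignited recurrent subnetwork that fires similarly whichever area is
#' stimulated is responsive but not selective, so its argmax carries no
#' retinotopic information.
#' Membrane state is reset to rest for every stimulus and the passed network
#' is not modified, so the assay cannot perturb the main trajectory.
#'
#' @param network A network object (its current connectivity is probed).
#' @param areas Grid of stimulation areas, columns x rows.
#' @param test_mean,test_sd Mean and SD of the noisy test current (defaults:
#'   twice the configured external mean, and the configured external SD).
#' @param t_test Stimulus duration in ms.
#' @param theta_resp Minimum spike count to call a neuron responsive.
#' @return Object of class `remap_report`: list with `map` (data frame: id,
#'   x, y, kind, region, own_area, preferred_area, max_response,
#'   responsive), `response` (neuron x area spike-count matrix) and the
#'   assay configuration.
#' @export
remapping_assay <- function(network, areas = c(6, 6),
                            test_mean = 2 * network$params$input$mu_ext,
                            test_sd = network$params$input$sigma_ext,
                            t_test = 1000, theta_resp = 5) {
  g <- network$geometry
  ext <- g$spacing * (g$exc_dims - 1)
  nx <- areas[1]; ny <- areas[2]
  ax_of <- function(pos) {
    cx <- pmin(nx - 1, pmax(0, floor(pos[, 1] / (ext[1] / nx))))
    cy <- pmin(ny - 1, pmax(0, floor(pos[, 2] / (ext[2] / ny))))
    as.integer(cy * nx + cx)  # area index 0..(nx*ny - 1)
  }
  own <- ax_of(network$pos)
  p <- network$params
  resp <- matrix(0L, network$n, nx * ny)
  v0 <- rep(p$membrane$c, network$n)
  u0 <- rep(p$membrane$b * p$membrane$c, network$n)
  for (a in seq_len(nx * ny) - 1L) {
    mult <- ifelse(own == a, network$input_multiplier, 0)
    out <- cpp_simulate_window(v0, u0, numeric(network$n), network$sgn,
                               network$omega, mult, numeric(network$n),
                               t_test, p$membrane$dt,
                               p$membrane$a, p$membrane$b, p$membrane$c,
                               p$membrane$d, p$membrane$v_spike,
                               test_mean, test_sd,
                               p$input$w_syn, p$input$tau_syn,
                               p$calcium$beta, p$calcium$tau_ca, 0)
    resp[, a + 1L] <- out$counts
  }
  pref <- max.col(resp, ties.method = "first") - 1L
  mx <- resp[cbind(seq_len(network$n), pref + 1L)]
  responsive <- mx >= theta_resp
  med <- apply(resp, 1, stats::median)
  selective <- mx >= 2 * (med + 1)
  map <- data.frame(
    id = seq_len(network$n), x = network$pos[, 1], y = network$pos[, 2],
    kind = network$kind,
    region = if (is.null(network$regions)) "outside" else network$regions,
    own_area = own,
    preferred_area = ifelse(responsive, pref, NA_integer_),
    max_response = mx, median_response = med,
    responsive = responsive, selective = selective)
  structure(list(map = map, response = resp, areas = areas,
                 test_mean = test_mean, test_sd = test_sd,
                 t_test = t_test, theta_resp = theta_resp),
            class = "remap_report")
}

#' @export
print.remap_report <- function(x, ...) {
  m <- x$map
  cat(sprintf(
    "remapping assay: %dx%d areas, %d/%d neurons responsive, retinotopy %.0f%%\n",
    x$areas[1], x$areas[2], sum(m$responsive), nrow(m),
    100 * mean(m$preferred_area[m$responsive] == m$own_area[m$responsive])))
  invisible(x)
}

# Which stimulation areas lie inside the lesion square (area center test).
areas_in_lpz <- function(network, areas = c(6, 6)) {
  g <- network$geometry
  ext <- g$spacing * (g$exc_dims - 1)
  nx <- areas[1]; ny <- areas[2]
  cx <- (seq_len(nx) - 0.5) * ext[1] / nx
  cy <- (seq_len(ny) - 0.5) * ext[2] / ny
  centers <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  which(in_rect(centers, network$lesion$square)) - 1L
}

# Synchrony ------------------------------------------------------------------

#' Population synchrony profile
#'
#' Histogram of the number of distinct firing neurons per time bin, its
#' coefficient of variation, and the dominant frequency of the binned
#' population rate (peak of the periodogram, DC excluded). Irregular
#' asynchronous activity gives a low CV; synchronized oscillatory activity
#' gives a high CV and a clear spectral peak.
#'
#' @param raster Data frame with `neuron_id`, `time_ms`.
#' @param bin_ms Bin width in ms.
#' @param t_range Optional `c(from, to)` ms; defaults to the raster's span.
#' @return List with `counts` (firing neurons per bin), `cv`,
#'   `peak_freq_hz`, `peak_power_ratio` (peak power over mean power) and
#'   `empty` flag.
#' @export
synchrony_profile <- function(raster, bin_ms = 5, t_range = NULL) {
  if (nrow(raster) == 0)
    return(list(counts = integer(0), cv = NA_real_, peak_freq_hz = NA_real_,
                peak_power_ratio = NA_real_, empty = TRUE))
  if (is.null(t_range)) t_range <- range(raster$time_ms)
  breaks <- seq(t_range[1] - bin_ms, t_range[2] + bin_ms, by = bin_ms)
  bin <- findInterval(raster$time_ms, breaks, rightmost.closed = TRUE)
  counts <- vapply(split(raster$neuron_id, factor(bin, seq_along(breaks))),
                   function(x) length(unique(x)), integer(1))
  cv <- stats::sd(counts) / mean(counts)
  x <- counts - mean(counts)
  peak_f <- NA_real_; ratio <- NA_real_
  if (length(x) >= 8 && any(x != 0)) {
    pw <- Mod(stats::fft(x))^2
    half <- 2:floor(length(x) / 2)
    pk <- half[which.max(pw[half])]
    peak_f <- (pk - 1) / (length(x) * bin_ms / 1000)
    ratio <- pw[pk] / mean(pw[half])
  }
  list(counts = counts, cv = cv, peak_freq_hz = peak_f,
       peak_power_ratio = ratio, empty = FALSE)
}

# Outcome classification ------------------------------------------------------

#' Classify the reorganization outcome of a scenario
#'
#' Operationalizes the scenario outcome matrix:
#' * `repair`: at least 90% of LPZ neurons show sustained recovery
#'   (calcium >= 0.9 * set-point for 5 consecutive snapshots) by the end of
#'   the standard-lesion run;
#' * `sequential`: the median recovery time of the LPZ border precedes that
#'   of the center by more than one snapshot interval;
#' * `large_lpz_repair`: the repair criterion on the large-lesion run;
#' * `remapping`: at the end of the standard run at least 50% of the LPZ's
#'   excitatory neurons are responsive *and selective* (see
#'   [remapping_assay()]) with a preferred input area outside the LPZ, and
#'   no single area accounts for 60% or more of those preferences. The
#'   diversity condition separates genuine retinotopic filling - adjacent
#'   representations enlarging into the LPZ from different sides, producing
#'   a gradient of preferences - from the collective ignition of a
#'   recurrently self-repaired cluster, in which one stimulus lights up the
#'   whole LPZ and every neuron inherits the same label.
#'
#' The cutoffs are this package's operationalization of the qualitative
#' Yes/No outcomes; they are deliberately coarse and robust to the assay
#' parameters.
#'
#' @param standard_run Standard-lesion [run_protocol()] result.
#' @param large_run Large-lesion run of the same growth-curve regime (or
#'   `NULL` to skip that cell).
#' @param assay Optionally a precomputed [remapping_assay()] of the
#'   standard run's final checkpoint.
#' @return Object of class `outcome_matrix`: logicals `repair`,
#'   `sequential`, `large_lpz_repair`, `remapping` plus the numeric
#'   evidence.
#' @export
classify_outcome <- function(standard_run, large_run = NULL, assay = NULL) {
  lpz <- c("lpz_center", "lpz_border")
  stopifnot(!is.null(standard_run$network$regions))
  in_lpz <- standard_run$network$regions %in% lpz
  rt <- recovery_times(standard_run)
  end <- standard_run$total_updates - standard_run$onset
  repaired_frac <- mean(is.finite(rt[in_lpz]) & rt[in_lpz] <= end)
  repair <- repaired_frac >= 0.9
  reg <- standard_run$network$regions
  med_border <- stats::median(rt[reg == "lpz_border"])
  med_center <- stats::median(rt[reg == "lpz_center"])
  cad <- standard_run$scenario$snapshot_every
  sequential <- repair && is.finite(med_center) && is.finite(med_border) &&
    (med_center - med_border) > cad
  large_repair <- NA
  if (!is.null(large_run)) {
    in_lpz_l <- large_run$network$regions %in% lpz
    rt_l <- recovery_times(large_run)
    large_repair <-
      mean(is.finite(rt_l[in_lpz_l]) &
             rt_l[in_lpz_l] <= large_run$total_updates - large_run$onset) >= 0.9
  }
  if (is.null(assay)) {
    final <- standard_run$checkpoints[[as.character(standard_run$total_updates)]]
    assay <- remapping_assay(final)
  }
  lpz_areas <- areas_in_lpz(standard_run$network, assay$areas)
  m <- assay$map
  sel <- m$region %in% lpz & m$kind == "exc"
  qual <- m$responsive[sel] & m$selective[sel] &
    !(m$preferred_area[sel] %in% lpz_areas)
  remap_frac <- mean(qual)
  pref <- m$preferred_area[sel][qual]
  modal_share <- if (length(pref)) max(table(pref)) / length(pref) else NA_real_
  remapping <- remap_frac >= 0.5 && is.finite(modal_share) &&
    modal_share < 0.6
  structure(list(repair = repair, sequential = sequential,
                 large_lpz_repair = large_repair, remapping = remapping,
                 evidence = list(repaired_frac = repaired_frac,
                                 median_recovery_border = med_border,
                                 median_recovery_center = med_center,
                                 remap_frac = remap_frac,
                                 remap_modal_share = modal_share)),
            class = "outcome_matrix")
}

#' @export
print.outcome_matrix <- function(x, ...) {
  yn <- function(v) if (is.na(v)) "-" else if (v) "Yes" else "No"
  cat(sprintf(
    "outcome: repair %s | sequential %s | large-LPZ repair %s | remapping %s\n",
    yn(x$repair), yn(x$sequential), yn(x$large_lpz_repair), yn(x$remapping)))
  cat(sprintf("  (%.0f%% of LPZ recovered; border median %s vs center %s; %.0f%% remapped)\n",
              100 * x$evidence$repaired_frac,
              format(x$evidence$median_recovery_border),
              format(x$evidence$median_recovery_center),
              100 * x$evidence$remap_frac))
  invisible(x)
}
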