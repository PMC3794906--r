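#' Growth-curve families for the named scenarios
#'
#' All element classes share the maximum growth speed `nu` and the
#' homeostatic set-point `eps`; the scenarios differ only in the minimum
#' activities `eta`. In the physiological regime dendritic elements start
#' forming at much lower activity than axonal elements
#' (`eta_D = 0.01 * eps`, `eta_A = 0.5 * eps`; `eta_D` must lie below the
#' residual activity of the deprived LPZ center, or its dendrites retract
#' and deprived neurons can never re-acquire input), which is the configuration
#' that yields sequential, wound-healing-like repair of the lesion
#' projection zone. `aberrant_dendritic_high_curves()` swaps the two (no
#' repair at all: deprived neurons cannot offer dendritic targets);
#' `aberrant_both_low_curves()` sets both thresholds low (repair through
#' massive recurrent wiring inside the LPZ, simultaneous rather than
#' sequential, no remapping).
#'
#' @param nu Maximum element growth rate, elements per ms.
#' @param eps Homeostatic calcium set-point.
#' @return Named list of [growth_curve()]s for `axonal`, `dendritic_exc`,
#'   `dendritic_inh`.
#' @export
physiological_curves <- function(nu = 3e-4, eps = 0.05) {
  list(axonal = growth_curve(nu, 0.5 * eps, eps),
       dendritic_exc = growth_curve(nu, 0.01 * eps, eps),
       dendritic_inh = growth_curve(nu, 0.01 * eps, eps))
}

#' @rdname physiological_curves
#' @export
aberrant_dendritic_high_curves <- function(nu = 3e-4, eps = 0.05) {
  list(axonal = growth_curve(nu, 0.01 * eps, eps),
       dendritic_exc = growth_curve(nu, 0.5 * eps, eps),
       dendritic_inh = growth_curve(nu, 0.5 * eps, eps))
}

#' @rdname physiological_curves
#' @export
aberrant_both_low_curves <- function(nu = 3e-4, eps = 0.05) {
  list(axonal = growth_curve(nu, 0.01 * eps, eps),
       dendritic_exc = growth_curve(nu, 0.01 * eps, eps),
       dendritic_inh = growth_curve(nu, 0.01 * eps, eps))
}

#' Build a scenario configuration
#'
#' Bundles everything one simulation run needs: geometry, growth curves,
#' lesion geometry and timing, peri-LPZ input manipulation, and snapshot /
#' checkpoint cadence. The named scenarios are:
#' `physiological` (standard lesion, repair with remapping),
#' `aberrant_dendritic_high` (high dendritic threshold, no repair),
#' `aberrant_both_low` (both thresholds low, recurrent self-repair),
#' `large_lpz` (physiological curves, lesion covering most of the plane),
#' `peri_reduction_20` / `peri_blockade` (physiological with the peri-LPZ
#' external input scaled to 0.8 / 0 at onset), `high_density` (4x neuron
#' density, same extent) and `control` (no lesion).
#'
#' @param name One of the named scenarios above.
#' @param geometry A [network_geometry()]; the default depends on the name.
#' @param pre_updates Connectivity updates before lesion onset (default
#'   8000, at which point the network is safely at equilibrium).
#' @param post_updates Updates after onset (default 5000; the standard
#'   protocol totals 13000 updates). The early/middle/late analysis phases
#'   are the printed windows 1-1000, 2000-3000 and 4000-5000 post-onset,
#'   scaled proportionally if `post_updates` differs from 5000.
#' @param snapshot_every Snapshot cadence in updates.
#' @param update_interval_ms Simulated activity per connectivity update.
#' @param ... Overrides for any of the fields of the returned object
#'   (`curves`, `lesion`, `peri_factor`, `membrane`, `input`, `calcium`,
#'   `kernel`, `vac`, `checkpoint_updates`, `raster_blocks`,
#'   `raster_block_len`).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name = "physiological",
                            geometry = NULL,
                            pre_updates = 8000, post_updates = 5000,
                            snapshot_every = 50,
                            update_interval_ms = 100, ...) {
  known <- c("physiological", "aberrant_dendritic_high", "aberrant_both_low",
             "large_lpz", "peri_reduction_20", "peri_blockade",
             "high_density", "control")
  name <- match.arg(name, known)
  if (is.null(geometry))
    geometry <- if (name == "high_density") high_density_geometry()
                else network_geometry()
  lesion <- if (name == "control") NULL
            else if (name == "large_lpz")
              large_lesion(geometry, pre_updates, post_updates)
            else standard_lesion(geometry, pre_updates, post_updates)
  cfg <- list(
    name = name, geometry = geometry,
    curves = switch(name,
      aberrant_dendritic_high = aberrant_dendritic_high_curves(),
      aberrant_both_low = aberrant_both_low_curves(),
      physiological_curves()),
    lesion = lesion,
    peri_factor = switch(name, peri_reduction_20 = 0.8, peri_blockade = 0, 1),
    membrane = membrane_params(), input = input_config(),
    calcium = calcium_params(),
    kernel = kernel_params(2 * geometry$spacing),
    vac = vacancy_decay_params(),
    pre_updates = as.integer(pre_updates),
    post_updates = as.integer(post_updates),
    snapshot_every = as.integer(snapshot_every),
    update_interval_ms = update_interval_ms,
    checkpoint_updates = NULL,  # defaults to onset and end of run
    raster_blocks = NULL,       # defaults to pre-end, early and late phase
    raster_block_len = 10L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown scenario fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_scenario(structure(cfg, class = "scenario_config"))
}

#' Scaled-down scenario for fast experimentation and testing
#'
#' A 100-neuron rendition of the named scenarios that preserves the
#' qualitative regimes of the full 400-neuron protocol while running an
#' order of magnitude faster. Relative to the defaults: a 10x8 excitatory
#' grid (80 excitatory + 20 inhibitory neurons), kernel width 1.25 grid
#' spacings and a lesion square of 5 grid spacings (about 25 excitatory
#' and 4 inhibitory neurons) so the lesion still spans about 4 kernel
#' widths and keeps a genuinely deprived center, and growth speed `nu`
#' raised to 3e-4 elements/ms so that the structural time covered by the
#' shortened protocol (2000 pre-lesion and 4500 post-lesion updates)
#' matches the full-length one. Analysis phases scale proportionally.
#'
#' @param name Scenario name, as in [scenario_config()].
#' @param seedless_overrides Additional overrides passed on to
#'   [scenario_config()].
#' @param pre_updates,post_updates Protocol length in connectivity updates.
#' @return A [scenario_config()].
#' @export
scaled_scenario <- function(name = "physiological", pre_updates = 2000,
                            post_updates = 4500,
                            seedless_overrides = list()) {
  g <- network_geometry(c(10, 8))
  nu <- 3e-4
  curves <- switch(name,
    aberrant_dendritic_high = aberrant_dendritic_high_curves(nu = nu),
    aberrant_both_low = aberrant_both_low_curves(nu = nu),
    physiological_curves(nu = nu))
  lesion <- if (name == "control") NULL
            else if (name == "large_lpz")
              large_lesion(g, pre_updates, post_updates)
            else standard_lesion(g, pre_updates, post_updates, side_frac = 0.5)
  args <- c(list(name = name, geometry = g,
                 pre_updates = pre_updates, post_updates = post_updates,
                 snapshot_every = 50, curves = curves, lesion = lesion,
                 input = input_config(w_syn = 3),
                 kernel = kernel_params(1.25 * g$spacing)),
            seedless_overrides)
  do.call(scenario_config, args)
}

#' Validate a scenario configuration
#'
#' Checks ordering constraints (`eta < eps` per curve, positive timings,
#' peri factor in \[0, 1\], lesion square inside the plane) and returns the
#' config invisibly augmented; stops with the offending field otherwise.
#'
#' @param cfg A `scenario_config`.
#' @return The validated config.
#' @export
validate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  for (cls in ELEMENT_CLASSES) {
    cv <- cfg$curves[[cls]]
    if (is.null(cv) || !(cv$eta < cv$eps) || cv$nu <= 0)
      stop("invalid growth curve for ", cls, ": need 0 <= eta < eps, nu > 0")
  }
  if (cfg$peri_factor < 0 || cfg$peri_factor > 1)
    stop("peri_factor must lie in [0, 1]")
  if (cfg$pre_updates < 0 || cfg$post_updates < 0 || cfg$snapshot_every < 1)
    stop("update counts must be non-negative and snapshot_every >= 1")
  cfg
}

#' Analysis phase windows
#'
#' Post-lesion update windows for the early, middle and late phases: the
#' printed 1-1000, 2000-3000 and 4000-5000 windows, scaled proportionally
#' when the protocol runs fewer (or more) than 5000 post-lesion updates.
#'
#' @param post_updates Number of post-lesion updates in the protocol.
#' @return Named list of `c(from, to)` post-onset update indices.
#' @export
phase_windows <- function(post_updates = 5000) {
  s <- post_updates / 5000
  lapply(list(early = c(1, 1000), middle = c(2000, 3000),
              late = c(4000, 5000)),
         function(w) pmax(1, round(w * s)))
}

#' Map connectivity updates to experiment days
#'
#' Linear conversion used for axis labelling only: 5000 post-lesion updates
#' correspond to 72 days of cortical reorganization, and update 0 to day 0.
#'
#' @param update Post-lesion update index (vectorized).
#' @return Day value(s).
#' @export
update_to_day <- function(update) update * 72 / 5000

# --- named RNG streams ----------------------------------------------------

# Four independent streams (placement, dynamics, rewiring, assay) derived
# from one master seed, so that e.g. running the remapping assay never
# perturbs the main trajectory. Stream states are full .Random.seed vectors
# swapped in and out of the global RNG.
rng_streams <- function(seed) {
  e <- new.env(parent = emptyenv())
  set.seed(seed)
  subs <- sample.int(.Machine$integer.max - 1, 4)
  names(subs) <- c("placement", "dynamics", "rewiring", "assay")
  e$seeds <- subs
  e$state <- lapply(subs, function(s) {
    set.seed(s)
    get(".Random.seed", envir = globalenv())
  })
  e
}

clone_streams <- function(streams) {
  e <- new.env(parent = emptyenv())
  e$seeds <- streams$seeds
  e$state <- streams$state
  e
}

with_stream <- function(streams, name, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  prev <- if (had) get(".Random.seed", envir = globalenv())
  assign(".Random.seed", streams$state[[name]], envir = globalenv())
  on.exit({
    streams$state[[name]] <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", prev, envir = globalenv())
  })
  code
}

# --- the protocol driver --------------------------------------------------

take_snapshot <- function(net, raster = NULL) {
  exc <- which(net$sgn > 0)
  list(update = net$update_index,
       ca = net$ca,
       z_ax = net$z_ax, z_de = net$z_de, z_di = net$z_di,
       created_de = net$created_de,
       dend_ids = net$ids_de[exc],
       synapses = sum(net$omega),
       raster = raster)
}

#' Run the full simulation protocol
#'
#' Alternates activity windows and connectivity updates: `pre_updates`
#' updates of self-organizing maturation, then (unless `control = TRUE` or
#' the scenario has no lesion) removal of external input from the lesion
#' square and any peri-LPZ input manipulation, then `post_updates` further
#' updates. Snapshots of calcium, element counts, dendritic element
#' identities and synapse totals are taken every `snapshot_every` updates;
#' full network states are stored at the checkpoint updates (by default at
#' onset, both before and after the lesion is applied, and at the end);
#' window rasters are stored for a few blocks of consecutive updates (by
#' default ending at onset, in the early phase, and at the end) for the
#' synchrony analysis.
#'
#' A control run with the same seed is identical to the lesion run up to the
#' onset update (all randomness flows through named streams: placement,
#' dynamics, rewiring, assay).
#'
#' @param scenario A [scenario_config()].
#' @param seed Integer master seed.
#' @param control Run the matched no-lesion control instead.
#' @param validate_every Run the full invariant scan every this many updates
#'   (`Inf` = never; used by the conservation tests).
#' @param progress Print a progress line every 1000 updates.
#' @return An object of class `plasticity_run`.
#' @export
run_protocol <- function(scenario, seed, control = FALSE,
                         validate_every = Inf, progress = FALSE) {
  variant <- if (control) "control" else "lesion"
  run_protocol_variants(scenario, seed, variants = variant,
                        validate_every = validate_every,
                        progress = progress)[[variant]]
}

#' Run several post-lesion variants from one equilibrated network
#'
#' Simulates the pre-lesion phase once and then branches the post-onset
#' phase into several variants that share the equilibrated network, the
#' placement and the post-onset random streams: `"lesion"` (the scenario as
#' configured), `"control"` (no lesion), `"blockade"` (lesion plus complete
#' blockade of peri-LPZ external input) and `"reduction"` (lesion plus a
#' 20% reduction of peri-LPZ input). All variants of one call are
#' bit-identical up to the onset update, which is what makes them matched
#' controls for turnover and overshoot comparisons.
#'
#' @inheritParams run_protocol
#' @param variants Character vector from `c("lesion", "control", "blockade",
#'   "reduction")`.
#' @return Named list of `plasticity_run` objects.
#' @export
run_protocol_variants <- function(scenario, seed,
                                  variants = c("lesion", "control"),
                                  validate_every = Inf, progress = FALSE) {
  scenario <- validate_scenario(scenario)
  stopifnot(all(variants %in% c("lesion", "control", "blockade",
                                "reduction")))
  streams <- rng_streams(seed)
  net <- with_stream(streams, "placement",
    build_network(scenario$geometry,
                  membrane = scenario$membrane, input = scenario$input,
                  calcium = scenario$calcium, kernel = scenario$kernel,
                  vac = scenario$vac, curves = scenario$curves,
                  update_interval_ms = scenario$update_interval_ms))
  if (!is.null(scenario$lesion)) net <- define_lesion(net, scenario$lesion)

  pre <- scenario$pre_updates
  post <- scenario$post_updates
  total <- pre + post
  onset <- pre
  cps <- scenario$checkpoint_updates
  if (is.null(cps)) cps <- c(onset, total)
  ph <- phase_windows(post)
  rb <- scenario$raster_blocks
  if (is.null(rb)) rb <- c(onset, onset + ph$early[2], total)
  blen <- scenario$raster_block_len
  raster_at <- unique(unlist(lapply(rb, function(e)
    seq(max(1, e - blen + 1), e))))

  acc <- list(snapshots = list(take_snapshot(net)), checkpoints = list(),
              logs = matrix(NA_real_, total, 4,
                            dimnames = list(NULL, c("update", "formed",
                                                    "deleted", "synapses"))),
              rasters = list())
  phase <- function(net, streams, acc, from, to) {
    for (k in from:to) {
      keep_raster <- k %in% raster_at
      sim <- with_stream(streams, "dynamics",
        simulate_window(net, scenario$update_interval_ms))
      net <- sim$network
      if (keep_raster) acc$rasters[[as.character(k)]] <- sim$raster
      net <- with_stream(streams, "rewiring",
        connectivity_update(net, validate = k %% validate_every == 0))
      acc$logs[k, ] <- attr(net, "update_log")
      attr(net, "update_log") <- NULL
      if (k %% scenario$snapshot_every == 0L)
        acc$snapshots[[length(acc$snapshots) + 1L]] <-
          take_snapshot(net, if (keep_raster) sim$raster)
      if (k %in% cps) acc$checkpoints[[as.character(k)]] <- net
      if (progress && k %% 1000L == 0L)
        message(sprintf("update %d/%d: %d synapses, mean ca %.4f",
                        k, total, sum(net$omega), mean(net$ca)))
    }
    list(net = net, acc = acc)
  }

  if (pre > 0) {
    up <- phase(net, streams, acc, 1L, pre)
    net <- up$net
    acc <- up$acc
  }
  acc$checkpoints[["pre_onset"]] <- net

  out <- list()
  for (v in variants) {
    vnet <- net
    vstreams <- clone_streams(streams)
    vacc <- acc
    lesioned <- v != "control" && !is.null(scenario$lesion)
    if (lesioned) {
      vnet <- apply_lesion(vnet)
      pf <- switch(v, blockade = 0, reduction = 0.8, scenario$peri_factor)
      if (pf != 1)
        vnet <- apply_input_manipulation(vnet, "peri_lpz", pf)
    }
    if (onset %in% cps) vacc$checkpoints[["onset"]] <- vnet
    if (post > 0) {
      up <- phase(vnet, vstreams, vacc, pre + 1L, total)
      vnet <- up$net
      vacc <- up$acc
    }
    out[[v]] <- structure(list(
      scenario = scenario, seed = seed, control = v == "control",
      variant = v, lesioned = lesioned,
      onset = onset, total_updates = total, phases = ph,
      snapshots = vacc$snapshots,
      checkpoints = vacc$checkpoints,
      log = as.data.frame(vacc$logs),
      rasters = vacc$rasters,
      network = vnet,
      stream_seeds = streams$seeds), class = "plasticity_run")
  }
  out
}

#' @export
print.plasticity_run <- function(x, ...) {
  cat(sprintf(
    "plasticity run: scenario '%s'%s, seed %d, %d updates (%d pre + %d post)\n",
    x$scenario$name, if (x$control) " [control]" else "", x$seed,
    x$total_updates, x$onset, x$total_updates - x$onset))
  cat(sprintf("  final: %d synapses, mean calcium %.4f (set-point %.3f)\n",
              sum(x$network$omega), mean(x$network$ca),
              x$scenario$curves$axonal$eps))
  invisible(x)
}

#' @export
summary.plasticity_run <- function(object, ...) {
  net <- object$network
  eps <- object$scenario$curves$axonal$eps
  regions <- if (is.null(net$regions)) rep("outside", net$n) else net$regions
  by_region <- data.frame(
    region = sort(unique(regions)),
    n = as.integer(table(regions)[sort(unique(regions))]),
    mean_ca = tapply(net$ca, regions, mean)[sort(unique(regions))],
    at_setpoint = tapply(abs(net$ca - eps) / eps < 0.1, regions,
                         mean)[sort(unique(regions))])
  rownames(by_region) <- NULL
  out <- list(run = object, by_region = by_region,
              synapses = sum(net$omega))
  class(out) <- "summary.plasticity_run"
  out
}

#' @export
print.summary.plasticity_run <- function(x, ...) {
  print(x$run)
  cat("  per-region state at end of run:\n")
  print(x$by_region, row.names = FALSE)
  invisible(x)
}

#' Fraction of neurons at the homeostatic set-point
#'
#' @param ca Calcium vector (or a network, from which it is taken).
#' @param eps Set-point.
#' @param tol Relative tolerance (default 10%).
#' @return Fraction of neurons with `|ca - eps| / eps < tol`.
#' @export
fraction_at_setpoint <- function(ca, eps, tol = 0.1) {
  if (is.list(ca)) ca <- ca$ca
  mean(abs(ca - eps) / eps < tol)
}
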