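#' Network geometry
#'
#' The cortical sheet: excitatory neurons sit on a rectangular grid with
#' spacing `spacing` micrometers; inhibitory neurons sit on a second grid
#' with twice the spacing, offset by half a spacing, so they are equally
#' distributed among the excitatory ones (one inhibitory per 2x2 block of
#' excitatory sites, 80/20 ratio). Every neuron's coordinates are jittered
#' around its grid point by an isotropic normal perturbation.
#'
#' @param exc_dims Columns x rows of the excitatory grid (default `c(20, 16)`
#'   = 320 neurons; the inhibitory grid is half the size in each dimension).
#' @param spacing Grid spacing Delta in micrometers.
#' @param jitter_sd SD in micrometers of the placement jitter.
#' @return An object of class `network_geometry`.
#' @export
network_geometry <- function(exc_dims = c(20, 16), spacing = 100,
                             jitter_sd = 0.25 * spacing) {
  stopifnot(length(exc_dims) == 2, all(exc_dims >= 2),
            all(exc_dims %% 2 == 0), spacing > 0, jitter_sd >= 0)
  structure(list(exc_dims = as.integer(exc_dims),
                 inh_dims = as.integer(exc_dims / 2),
                 spacing = spacing, jitter_sd = jitter_sd,
                 n_exc = as.integer(prod(exc_dims)),
                 n_inh = as.integer(prod(exc_dims) / 4)),
            class = "network_geometry")
}

#' High-density control geometry
#'
#' Four times as many neurons in the same physical extent as the reference
#' geometry: grid dimensions doubled, spacing halved (1280 excitatory and
#' 320 inhibitory neurons for the default network).
#'
#' @param geometry The reference [network_geometry()].
#' @return A `network_geometry` with quadrupled density.
#' @export
high_density_geometry <- function(geometry = network_geometry()) {
  network_geometry(exc_dims = 2L * geometry$exc_dims,
                   spacing = geometry$spacing / 2,
                   jitter_sd = geometry$jitter_sd / 2)
}

grid_sites <- function(dims, spacing, offset) {
  cbind(x = rep(offset + spacing * (seq_len(dims[1]) - 1), times = dims[2]),
        y = rep(offset + spacing * (seq_len(dims[2]) - 1), each = dims[1]))
}

#' Build a network
#'
#' Places neurons (kinds assigned by grid membership, excitatory neurons
#' first), with zero connectivity, zero synaptic elements, membrane state at
#' rest (`v = c`, `u = b*c`) and zero calcium: connectivity then develops in
#' a self-organizing way from activity alone.
#'
#' @param geometry A [network_geometry()].
#' @param membrane,input,calcium,kernel,vac Parameter objects (see
#'   [membrane_params()], [input_config()], [calcium_params()],
#'   [kernel_params()], [vacancy_decay_params()]).
#' @param curves Named list of [growth_curve()] objects for classes
#'   `axonal`, `dendritic_exc`, `dendritic_inh`.
#' @param update_interval_ms Activity-window length in ms between
#'   connectivity updates.
#' @return An object of class `plast_network`.
#' @export
build_network <- function(geometry = network_geometry(),
                          membrane = membrane_params(),
                          input = input_config(),
                          calcium = calcium_params(),
                          kernel = kernel_params(2 * geometry$spacing),
                          vac = vacancy_decay_params(),
                          curves = physiological_curves(),
                          update_interval_ms = 100) {
  stopifnot(setequal(names(curves), ELEMENT_CLASSES))
  exc <- grid_sites(geometry$exc_dims, geometry$spacing, 0)
  inh <- grid_sites(geometry$inh_dims, 2 * geometry$spacing,
                    geometry$spacing / 2)
  pos <- rbind(exc, inh)
  n <- nrow(pos)
  pos <- pos + matrix(stats::rnorm(2 * n, 0, geometry$jitter_sd), n, 2)
  kind <- rep(c("exc", "inh"), c(nrow(exc), nrow(inh)))
  net <- list(
    n = n, kind = kind, sgn = ifelse(kind == "exc", 1L, -1L), pos = pos,
    geometry = geometry,
    params = list(membrane = membrane, input = input, calcium = calcium,
                  kernel = kernel, vac = vac, curves = curves,
                  update_interval_ms = update_interval_ms),
    v = rep(membrane$c, n), u = rep(membrane$b * membrane$c, n),
    ca = numeric(n), isyn = numeric(n), input_multiplier = rep(1, n),
    omega = matrix(0, n, n), t_ms = 0, update_index = 0L, next_id = 1,
    lesion = NULL, regions = NULL)
  for (k in c("ax", "de", "di")) {
    net[[paste0("z_", k)]] <- numeric(n)
    net[[paste0("ids_", k)]] <- rep(list(numeric(0)), n)
    net[[paste0("prt_", k)]] <- rep(list(numeric(0)), n)
    net[[paste0("pn_", k)]] <- rep(list(integer(0)), n)
    net[[paste0("created_", k)]] <- numeric(n)
  }
  class(net) <- "plast_network"
  net
}

#' @export
print.plast_network <- function(x, ...) {
  cat(sprintf(
    "structural plasticity network: %d neurons (%d exc, %d inh), %d synapses, %d connectivity updates\n",
    x$n, sum(x$sgn > 0), sum(x$sgn < 0), sum(x$omega), x$update_index))
  if (!is.null(x$regions))
    cat("  regions:", paste(sprintf("%s=%d", names(table(x$regions)),
                                    table(x$regions)), collapse = ", "), "\n")
  invisible(x)
}

#' Standard lesion geometry
#'
#' The default focal lesion: a square of side `side_frac` of the excitatory
#' grid columns (7 grid spacings for the default 20x16 network), centered
#' between grid points as close to the network center as possible. For the
#' default network this square encloses on average about 49 excitatory and 9
#' inhibitory neurons. Neuron membership uses the half-open convention
#' `[x_lo, x_hi) x [y_lo, y_hi)`.
#'
#' @param geometry A [network_geometry()].
#' @param onset_update Connectivity update at which the lesion is applied.
#' @param post_updates Updates simulated after the lesion.
#' @param side_frac Square side as a fraction of the excitatory column count
#'   (rounded to whole grid spacings).
#' @return An object of class `lesion_spec` with the square bounds, the
#'   region ring widths (`border_width` inside, `peri_width` outside) and
#'   the protocol timing.
#' @export
standard_lesion <- function(geometry = network_geometry(),
                            onset_update = 8000, post_updates = 5000,
                            side_frac = 0.35) {
  d <- geometry$spacing
  side <- round(side_frac * geometry$exc_dims[1]) * d
  lo <- function(extent) {
    target <- (extent - side) / 2
    cand <- d * c(2 * floor((target / d - 1) / 2) + 1,
                  2 * ceiling((target / d - 1) / 2) + 1)
    cand[order(abs(cand - target), -cand)][1]
  }
  ex <- d * (geometry$exc_dims - 1)
  lesion_spec(square = c(lo(ex[1]), lo(ex[1]) + side,
                         lo(ex[2]), lo(ex[2]) + side),
              onset_update = onset_update, post_updates = post_updates,
              border_width = d, peri_width = 3 * d)
}

#' Large lesion geometry
#'
#' A lesion covering all of the plane except a half-spacing rim, used for
#' the large-LPZ regime in which the peri zone is much smaller than the LPZ.
#'
#' @inheritParams standard_lesion
#' @return A `lesion_spec`.
#' @export
large_lesion <- function(geometry = network_geometry(),
                         onset_update = 8000, post_updates = 5000) {
  d <- geometry$spacing
  ex <- d * (geometry$exc_dims - 1)
  lesion_spec(square = c(d / 2, ex[1] - d / 2, d / 2, ex[2] - d / 2),
              onset_update = onset_update, post_updates = post_updates,
              border_width = d, peri_width = 3 * d)
}

#' Lesion specification
#'
#' @param square Bounds `c(x_lo, x_hi, y_lo, y_hi)` in micrometers of the
#'   deafferented square (half-open membership).
#' @param onset_update Connectivity update index at which external input to
#'   the square is permanently set to zero.
#' @param post_updates Number of connectivity updates simulated post-lesion.
#' @param border_width Width in micrometers of the LPZ-border ring (inside
#'   the square); the remainder of the LPZ is the center.
#' @param peri_width Width in micrometers of the peri-LPZ ring outside the
#'   square.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(square, onset_update = 8000, post_updates = 5000,
                        border_width = 100, peri_width = 300) {
  stopifnot(length(square) == 4, square[1] < square[2], square[3] < square[4],
            onset_update > 0, post_updates >= 0,
            border_width > 0, peri_width > 0)
  structure(list(square = square, onset_update = as.integer(onset_update),
                 post_updates = as.integer(post_updates),
                 border_width = border_width, peri_width = peri_width),
            class = "lesion_spec")
}

in_rect <- function(pos, r) {
  pos[, 1] >= r[1] & pos[, 1] < r[2] & pos[, 2] >= r[3] & pos[, 2] < r[4]
}

#' Attach a lesion and label regions
#'
#' Classifies every neuron as `lpz_center`, `lpz_border` (within
#' `border_width` of the square's edge, inside), `peri_lpz` (outside the
#' square but within `peri_width` of it) or `outside`, and stores the lesion
#' on the network. External input is actually removed only when the protocol
#' reaches the onset update (see [apply_lesion()]).
#'
#' @param network A network object.
#' @param spec A [lesion_spec()].
#' @return The network with `$lesion` and `$regions` set.
#' @export
define_lesion <- function(network, spec) {
  sq <- spec$square
  inside <- in_rect(network$pos, sq)
  if (!any(inside)) stop("lesion square contains no neurons")
  edge_dist <- pmin(network$pos[, 1] - sq[1], sq[2] - network$pos[, 1],
                    network$pos[, 2] - sq[3], sq[4] - network$pos[, 2])
  w <- spec$peri_width
  peri <- !inside & in_rect(network$pos, sq + c(-w, w, -w, w))
  regions <- rep("outside", network$n)
  regions[peri] <- "peri_lpz"
  regions[inside & edge_dist < spec$border_width] <- "lpz_border"
  regions[inside & edge_dist >= spec$border_width] <- "lpz_center"
  network$lesion <- spec
  network$regions <- regions
  network
}

#' Remove external input from the lesioned square
#'
#' Permanently sets the input multiplier of every LPZ neuron to zero.
#'
#' @param network A network with a lesion defined.
#' @return The updated network.
#' @export
apply_lesion <- function(network) {
  if (is.null(network$regions)) stop("no lesion defined")
  network$input_multiplier[network$regions %in%
                             c("lpz_center", "lpz_border")] <- 0
  network
}

#' Manipulate external input to a region
#'
#' Scales the external input of all neurons in a region by a fixed factor,
#' e.g. a 20% reduction (`factor = 0.8`) or a complete blockade
#' (`factor = 0`) of the peri-LPZ.
#'
#' @param network A network with regions defined.
#' @param region Region label, typically `"peri_lpz"`.
#' @param factor Multiplier in \[0, 1\].
#' @return The updated network.
#' @export
apply_input_manipulation <- function(network, region = "peri_lpz", factor) {
  if (is.null(network$regions)) stop("no region map defined")
  if (factor < 0 || factor > 1) stop("factor must lie in [0, 1]")
  network$input_multiplier[network$regions == region] <- factor
  network
}
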