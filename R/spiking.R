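#' Advance Izhikevich membrane state by one step
#'
#' Forward-Euler step of the Izhikevich equations
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I` and `du/dt = a (b v - u)`, with the
#' membrane equation advanced in two `dt/2` half-steps. If the updated
#' potential reaches `v_spike` the neuron fires: `v` is reset to `c` and `u`
#' incremented by `d`.
#'
#' All arguments are vectorized over neurons.
#'
#' @param v,u Membrane potential (mV) and recovery variable.
#' @param I_total Total input current for this step.
#' @param params A [membrane_params()] object.
#' @return A list with updated `v`, `u` and a logical `spiked` vector.
#' @export
step_membrane <- function(v, u, I_total, params) {
  h <- params$dt / 2
  v <- v + h * (0.04 * v * v + 5 * v + 140 - u + I_total)
  v <- v + h * (0.04 * v * v + 5 * v + 140 - u + I_total)
  u <- u + params$dt * params$a * (params$b * v - u)
  bad <- !is.finite(v) | !is.finite(u)
  if (any(bad))
    stop("membrane integration diverged for neuron ",
         paste(which(bad), collapse = ", "))
  spiked <- v >= params$v_spike
  v[spiked] <- params$c
  u[spiked] <- u[spiked] + params$d
  list(v = v, u = u, spiked = spiked)
}

#' Update the calcium trace for one step
#'
#' The calcium concentration increases by `beta` when the neuron spiked in
#' this step and otherwise decays exponentially towards zero. The decay uses
#' the exact per-step factor `exp(-dt/tau_ca)` rather than its Euler
#' approximation, which keeps the analytic steady state `beta * r * tau_ca`
#' of a Poisson-driven trace tight.
#'
#' @param ca Calcium concentration (vectorized over neurons); must be >= 0.
#' @param spiked Logical vector: did the neuron fire in this step?
#' @param params A [calcium_params()] object.
#' @param dt Step length in ms.
#' @return Updated calcium vector.
#' @export
update_calcium <- function(ca, spiked, params, dt = 1) {
  out <- ca * exp(-dt / params$tau_ca)
  out[spiked] <- ca[spiked] + params$beta
  out
}

#' Sample the external (thalamic) input current
#'
#' One i.i.d. draw from `Normal(mu_ext, sigma_ext^2)` per neuron, scaled by
#' the neuron's input multiplier. A multiplier of exactly 0 (deafferented
#' neuron) yields exactly 0 regardless of the draw.
#'
#' @param cfg An [input_config()] object.
#' @param multiplier Per-neuron input multiplier in \[0, 1\].
#' @return Numeric vector of external currents, one per neuron.
#' @export
sample_external_input <- function(cfg, multiplier) {
  multiplier * stats::rnorm(length(multiplier), cfg$mu_ext, cfg$sigma_ext)
}

#' Synaptic input currents from a spike raster
#'
#' Closed-form evaluation of the exponentially filtered synaptic input at
#' time `t`: `I_syn(j) = sum_i sign(i) * w_syn * omega[i, j] * s_i(t)` where
#' `s_i(t) = sum over spikes of i at times ts <= t of exp(-(t - ts)/tau_syn)`.
#' A spike contributes at full strength at its own time. There is no
#' transmission delay.
#'
#' @param raster Data frame with columns `neuron_id` and `time_ms`.
#' @param omega Directed connectivity matrix of non-negative integer synapse
#'   counts; `omega[i, j]` is the number of synapses from neuron i to j.
#' @param cfg An [input_config()] object.
#' @param sgn Per-neuron sign vector (+1 excitatory, -1 inhibitory).
#' @param t Evaluation time in ms.
#' @return Numeric vector of synaptic currents, one per neuron.
#' @export
compute_synaptic_input <- function(raster, omega, cfg, sgn, t) {
  if (any(omega < 0)) stop("omega must have non-negative entries")
  n <- nrow(omega)
  s <- numeric(n)
  keep <- raster$time_ms <= t
  if (any(keep)) {
    contrib <- exp(-(t - raster$time_ms[keep]) / cfg$tau_syn)
    agg <- rowsum(contrib, raster$neuron_id[keep])
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  as.vector(crossprod(omega, sgn * cfg$w_syn * s))
}

#' Simulate electrical activity for one window
#'
#' Advances all neurons `duration` ms under frozen connectivity, using the
#' compiled integrator. Membrane state, calcium trace and the filtered
#' synaptic current are updated in place in the returned network; the spike
#' raster is returned as (neuron id, spike time) pairs. With the same RNG
#' state, configuration and inputs, rasters are reproduced bit for bit.
#'
#' @param network A network from [build_network()].
#' @param duration Window length in ms.
#' @param reference Use the pure-R per-neuron reference integrator instead of
#'   the compiled one (slow; used as an independent oracle in tests).
#' @return A list with elements `network` (updated), `raster` (data frame of
#'   `neuron_id`, `time_ms`) and `counts` (spikes per neuron in this window).
#' @export
simulate_window <- function(network, duration, reference = FALSE) {
  stopifnot(duration >= 0)
  p <- network$params
  if (duration == 0) {
    return(list(network = network,
                raster = data.frame(neuron_id = integer(0),
                                    time_ms = numeric(0)),
                counts = integer(network$n)))
  }
  fn <- if (reference) r_simulate_window else cpp_simulate_window
  out <- fn(network$v, network$u, network$ca, network$sgn, network$omega,
            network$input_multiplier, network$isyn,
            duration, p$membrane$dt,
            p$membrane$a, p$membrane$b, p$membrane$c, p$membrane$d,
            p$membrane$v_spike,
            p$input$mu_ext, p$input$sigma_ext, p$input$w_syn, p$input$tau_syn,
            p$calcium$beta, p$calcium$tau_ca, network$t_ms)
  network$v <- out$v
  network$u <- out$u
  network$ca <- out$ca
  network$isyn <- out$isyn
  network$t_ms <- network$t_ms + duration
  list(network = network,
       raster = data.frame(neuron_id = out$spike_id, time_ms = out$spike_t),
       counts = out$counts)
}

# Pure-R reference integrator. Mirrors cpp_simulate_window operation for
# operation (same RNG draw order, same floating-point evaluation order) so
# that rasters and final states are bit-identical; used as the independent
# oracle for the compiled engine.
r_simulate_window <- function(v, u, ca, sgn, omega, mult, isyn,
                              duration, dt, a, b, c, d, v_spike,
                              mu_ext, sigma_ext, w_syn, tau_syn,
                              beta, tau_ca, t0) {
  n <- length(v)
  nsteps <- round(duration / dt)
  h <- dt / 2
  dec_ca <- exp(-dt / tau_ca)
  dec_syn <- exp(-dt / tau_syn)
  counts <- integer(n)
  spike_id <- integer(0)
  spike_t <- numeric(0)
  for (s in seq_len(nsteps)) {
    I <- mult * stats::rnorm(n, mu_ext, sigma_ext) + isyn
    v <- v + h * (0.04 * v * v + 5 * v + 140 - u + I)
    v <- v + h * (0.04 * v * v + 5 * v + 140 - u + I)
    u <- u + dt * a * (b * v - u)
    if (any(!is.finite(v) | !is.finite(u)))
      stop("membrane integration diverged")
    fired <- which(v >= v_spike)
    ca_old <- ca
    ca <- ca_old * dec_ca
    if (length(fired)) {
      ca[fired] <- ca_old[fired] + beta
      v[fired] <- c
      u[fired] <- u[fired] + d
      counts[fired] <- counts[fired] + 1L
      spike_id <- c(spike_id, fired)
      spike_t <- c(spike_t, rep(t0 + s * dt, length(fired)))
    }
    isyn <- isyn * dec_syn
    for (i in fired) isyn <- isyn + (w_syn * sgn[i]) * omega[i, ]
  }
  list(v = v, u = u, ca = ca, isyn = isyn, counts = counts,
       spike_id = spike_id, spike_t = spike_t)
}
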