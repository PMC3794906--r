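#' Izhikevich membrane parameters
#'
#' Constants of the two-variable Izhikevich neuron used for every cell in the
#' network. Excitatory and inhibitory neurons share one parameter set and
#' differ only in the sign of the synaptic transmission they deliver, so a
#' single regular-spiking set (`a = 0.02`, `b = 0.2`, `c = -65`, `d = 8`,
#' spike threshold 30 mV) is the default for all neurons.
#'
#' @param a Recovery time-scale constant.
#' @param b Sensitivity of the recovery variable to the membrane potential.
#' @param c Reset potential in mV after a spike.
#' @param d Post-spike increment of the recovery variable.
#' @param v_spike Spike detection threshold in mV.
#' @param dt Integration step in ms (the membrane equation is advanced in two
#'   `dt/2` half-steps; the recovery variable in one full step).
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(a = 0.02, b = 0.2, c = -65, d = 8,
                            v_spike = 30, dt = 1) {
  stopifnot(dt > 0, v_spike > c)
  structure(list(a = a, b = b, c = c, d = d, v_spike = v_spike, dt = dt),
            class = "membrane_params")
}

#' External and synaptic input configuration
#'
#' The external drive (vertical input from the eye via the thalamus) is white
#' noise with mean `mu_ext` and SD `sigma_ext`, delivered every millisecond
#' and scaled per neuron by an input multiplier in \[0, 1\] (1 = intact,
#' 0 = deafferented). Synaptic (horizontal) input is the presynaptic spike
#' train low-pass filtered by an exponential with decay constant `tau_syn`;
#' every synapse has the same fixed strength `w_syn`, with the sign set by the
#' presynaptic neuron's class.
#'
#' @param mu_ext Mean external current (mV-equivalent per ms).
#' @param sigma_ext SD of the external current; must be non-negative.
#' @param w_syn Fixed synaptic strength. The default is a calibration
#'   constant chosen so the intact default network fires at roughly 5-10 Hz.
#' @param tau_syn Decay constant of the exponential synaptic filter in ms.
#' @return An object of class `input_config`.
#' @export
input_config <- function(mu_ext = 2.5, sigma_ext = 3, w_syn = 3,
                         tau_syn = 5) {
  stopifnot(sigma_ext >= 0, tau_syn > 0)
  structure(list(mu_ext = mu_ext, sigma_ext = sigma_ext, w_syn = w_syn,
                 tau_syn = tau_syn),
            class = "input_config")
}

#' Calcium trace parameters
#'
#' The intracellular calcium concentration is the neuron's slow activity
#' sensor: it increases by `beta` at every spike and otherwise decays
#' exponentially to zero with time constant `tau_ca`. At a steady firing rate
#' r (spikes/ms) the trace averages `beta * r * tau_ca`, so the defaults map
#' ~8.3 Hz to a calcium level of 0.05 (the default set-point). The per-spike
#' increment also sets the trace's intrinsic relative fluctuation at the
#' set-point, `sqrt(beta / (2 * eps))`; the default keeps it under 4% so
#' that "being at the set-point" is a well-defined network state.
#'
#' @param beta Per-spike calcium increment (dimensionless).
#' @param tau_ca Decay time constant in ms.
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(beta = 1.5e-4, tau_ca = 40000) {
  stopifnot(beta > 0, tau_ca > 0)
  structure(list(beta = beta, tau_ca = tau_ca), class = "calcium_params")
}

#' Gaussian homeostatic growth curve
#'
#' Defines the activity-dependent rate of change of one class of synaptic
#' elements as a Gaussian function of the calcium trace:
#' `nu * (2 * exp(-((ca - xi)/zeta)^2) - 1)`, which is zero at the minimum
#' activity `eta` and at the homeostatic set-point `eps`, reaches its maximum
#' `+nu` at the center `xi = (eta + eps)/2`, and is bounded below by `-nu`.
#' The width is `zeta = (eps - eta) / (2 * sqrt(log(2)))`, the unique choice
#' that places the x-axis intersections exactly at `eta` and `eps`.
#'
#' @param nu Maximum rate of element change, in elements per ms.
#' @param eta Low zero-crossing: minimum calcium level at which elements of
#'   this class start forming.
#' @param eps High zero-crossing: homeostatic set-point of the calcium trace.
#' @return An object of class `growth_curve` with fields `nu`, `eta`, `eps`
#'   and the derived `xi` (center) and `zeta` (width).
#' @export
growth_curve <- function(nu = 3e-4, eta = 0.025, eps = 0.05) {
  stopifnot(nu > 0, eta >= 0, eta < eps)
  structure(list(nu = nu, eta = eta, eps = eps,
                 xi = (eta + eps) / 2,
                 zeta = (eps - eta) / (2 * sqrt(log(2)))),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf(
    "growth curve: nu = %g /ms, zeros at eta = %g and eps = %g (xi = %g, zeta = %g)\n",
    x$nu, x$eta, x$eps, x$xi, x$zeta))
  invisible(x)
}

#' Distance kernel parameters
#'
#' @param sigma_k Width (SD) in micrometers of the two-dimensional Gaussian
#'   kernel governing the distance-dependent likelihood of synapse formation.
#'   The default is twice the excitatory grid spacing.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(sigma_k = 200) {
  stopifnot(sigma_k > 0)
  structure(list(sigma_k = sigma_k), class = "kernel_params")
}

#' Vacant-element decay parameters
#'
#' Synaptic elements not bound in a synapse decay with time constant
#' `tau_vac`, expressed in connectivity updates.
#'
#' @param tau_vac Decay time constant (connectivity updates); `Inf` disables
#'   decay.
#' @return An object of class `vacancy_decay_params`.
#' @export
vacancy_decay_params <- function(tau_vac = 20) {
  stopifnot(tau_vac > 0)
  structure(list(tau_vac = tau_vac), class = "vacancy_decay_params")
}
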