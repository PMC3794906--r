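#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Millisecond-scale integration of the whole network for one activity window.
//
// Izhikevich membrane dynamics (forward Euler, membrane equation advanced in
// two dt/2 half-steps, recovery variable in one full step), per-spike calcium
// increments with exact exponential decay, and an exponentially filtered
// synaptic current maintained incrementally: because every presynaptic trace
// decays at the same rate, I_syn can be kept as a single per-neuron state that
// is decayed once per step and bumped by w * sign(i) * omega[i, ] whenever
// neuron i fires. A spike at step t first reaches postsynaptic membranes at
// step t+1, at full (undecayed) strength.
//
// All randomness comes from R's RNG (one N(mu, sigma) draw per neuron per
// step, in neuron order) so that seeds set in R control the engine and the
// pure-R reference integrator can reproduce rasters bit for bit.
// [[Rcpp::export]]
List cpp_simulate_window(NumericVector v0, NumericVector u0, NumericVector ca0,
                         IntegerVector sgn, NumericMatrix omega,
                         NumericVector mult, NumericVector isyn0,
                         double duration, double dt,
                         double a, double b, double c, double d,
                         double v_spike,
                         double mu_ext, double sigma_ext,
                         double w_syn, double tau_syn,
                         double beta, double tau_ca,
                         double t0) {
  const int n = v0.size();
  NumericVector v = clone(v0), u = clone(u0), ca = clone(ca0),
                isyn = clone(isyn0);
  IntegerVector counts(n);
  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<int> fired;
  fired.reserve(n);

  const int nsteps = (int) std::lround(duration / dt);
  const double h = dt / 2.0;
  const double dec_ca = std::exp(-dt / tau_ca);
  const double dec_syn = std::exp(-dt / tau_syn);

  for (int s = 0; s < nsteps; ++s) {
    fired.clear();
    for (int i = 0; i < n; ++i) {
      double I = mult[i] * R::rnorm(mu_ext, sigma_ext) + isyn[i];
      double vi = v[i], ui = u[i];
      vi = vi + h * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      vi = vi + h * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      ui = ui + dt * a * (b * vi - ui);
      if (!std::isfinite(vi) || !std::isfinite(ui))
        stop("membrane integration diverged for neuron %d at step %d",
             i + 1, s + 1);
      if (vi >= v_spike) {
        vi = c;
        ui = ui + d;
        ca[i] = ca[i] + beta;
        counts[i] += 1;
        fired.push_back(i);
        spike_id.push_back(i + 1);
        spike_t.push_back(t0 + (s + 1) * dt);
      } else {
        ca[i] = ca[i] * dec_ca;
      }
      v[i] = vi;
      u[i] = ui;
    }
    for (int j = 0; j < n; ++j) isyn[j] = isyn[j] * dec_syn;
    for (size_t k = 0; k < fired.size(); ++k) {
      const int i = fired[k];
      const double scale = w_syn * (double) sgn[i];
      for (int j = 0; j < n; ++j) {
        double inc = scale * omega(i, j);
        isyn[j] = isyn[j] + inc;
      }
    }
  }

  return List::create(_["v"] = v, _["u"] = u, _["ca"] = ca,
                      _["isyn"] = isyn, _["counts"] = counts,
                      _["spike_id"] = wrap(spike_id),
                      _["spike_t"] = wrap(spike_t));
}
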