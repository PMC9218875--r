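#include <Rcpp.h>
using namespace Rcpp;

// Deterministic within-trial integration of the synaptic-plasticity TD
// circuit. All randomness (peak jitter, amplitudes, reward timing, probe,
// stimulation selection) is drawn in R and passed in; this routine only
// integrates value, RPE, eligibility and weights over the trial at step
// dt, so that a pure-R reference implementation can reproduce it exactly.
//
// Per step (t = t_start + k * dt):
//   f_i(t)   Gaussian-smoothed rate bumps (evaluated in closed form),
//            overridden by the stimulation constant for selected neurons
//            inside the stimulation window
//   V(t)     sum_i max(0, w_hat_i) f_i(t)
//   delta(t) r(t) + (gamma V(t) - V(t - Delta)) / Delta,
//            gamma = exp(-Delta / tau); V taken as 0 before the trial
//   E_i      exp(-dt / tau_e) E_i + f_i dt   (reset to 0 at trial start)
//   w_hat_i  += alpha delta E_i dt           (unclipped accumulator)
// [[Rcpp::export]]
List plasticity_trial_cpp(NumericVector mu, NumericVector amp,
                          double sd_eff, NumericVector w_hat_in,
                          IntegerVector stim_idx, double stim_value,
                          double stim_on, double stim_off,
                          double t_start, double t_end, double dt,
                          NumericVector r, double alpha, double tau,
                          double tau_e, double delta_lag,
                          bool floor_each_step) {
  const int n = mu.size();
  const int n_steps = r.size();
  const int m = (int) std::lround(delta_lag / dt);
  const double gamma = std::exp(-delta_lag / tau);
  const double e_decay = std::exp(-dt / tau_e);

  NumericVector w_hat = clone(w_hat_in);
  std::vector<double> E(n, 0.0), f(n, 0.0);
  std::vector<char> stim(n, 0);
  for (int j = 0; j < stim_idx.size(); ++j) stim[stim_idx[j] - 1] = 1;

  // Gaussian bumps on the uniform grid via the exact two-term recurrence
  // g_{k+1} = g_k * r_k, r_{k+1} = r_k * d  (d constant), avoiding an
  // exp() per neuron and step
  const double s2 = sd_eff * sd_eff;
  const double dfac = std::exp(-dt * dt / s2);
  std::vector<double> g(n), ratio(n);
  for (int i = 0; i < n; ++i) {
    const double z0 = (t_start - mu[i]) / sd_eff;
    g[i] = amp[i] * std::exp(-0.5 * z0 * z0);
    ratio[i] = std::exp(-(2.0 * (t_start - mu[i]) * dt + dt * dt) /
                        (2.0 * s2));
  }

  NumericVector v_trace(n_steps), d_trace(n_steps);

  for (int k = 0; k < n_steps; ++k) {
    const double t = t_start + k * dt;
    const bool stim_now = (t >= stim_on && t <= stim_off);
    double V = 0.0;
    for (int i = 0; i < n; ++i) {
      const double fi = (stim_now && stim[i]) ? stim_value : g[i];
      g[i] *= ratio[i];
      ratio[i] *= dfac;
      f[i] = fi;
      const double w = w_hat[i] > 0.0 ? w_hat[i] : 0.0;
      V += w * fi;
    }
    const double V_del = (k - m >= 0) ? v_trace[k - m] : 0.0;
    const double delta = r[k] + (gamma * V - V_del) / delta_lag;
    v_trace[k] = V;
    d_trace[k] = delta;
    const double lr = alpha * delta * dt;
    if (floor_each_step) {
      for (int i = 0; i < n; ++i) {
        E[i] = e_decay * E[i] + f[i] * dt;
        w_hat[i] += lr * E[i];
        if (w_hat[i] < 0.0) w_hat[i] = 0.0;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        E[i] = e_decay * E[i] + f[i] * dt;
        w_hat[i] += lr * E[i];
      }
    }
  }
  return List::create(_["w_hat"] = w_hat, _["value"] = v_trace,
                      _["rpe"] = d_trace);
}
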