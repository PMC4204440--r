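// Fixed-step integrators for the conductance-based circuit models.
//
// Neuron kinetics follow the standard Wang-Buzsaki single-compartment
// formulation (transient Na+, delayed-rectifier K+, leak) extended with a
// slow non-inactivating K+ current (I_ks) and a high-voltage-activated
// Ca++ current as neuromodulation targets. Synapses are single-exponential
// AMPA/GABA-A conductances plus a slow NMDA conductance with the standard
// voltage-dependent Mg++ block. Randomness (background Poisson drive) is
// drawn from R's RNG so a set.seed() on the R side makes runs reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

inline double safe_div(double num, double den) {
  // removable singularity of the alpha-rate expressions
  return std::fabs(den) < 1e-9 ? num / 1e-9 : num / den;
}

inline double alpha_m(double v) {
  double x = -(v + 35.0) / 10.0;
  return std::fabs(x) < 1e-7 ? 1.0 : 0.1 * (v + 35.0) / (1.0 - std::exp(x));
}
inline double beta_m(double v) { return 4.0 * std::exp(-(v + 60.0) / 18.0); }
inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 58.0) / 20.0); }
inline double beta_h(double v) { return 1.0 / (1.0 + std::exp(-(v + 28.0) / 10.0)); }
inline double alpha_n(double v) {
  double x = -(v + 34.0) / 10.0;
  return std::fabs(x) < 1e-7 ? 0.1 : 0.01 * (v + 34.0) / (1.0 - std::exp(x));
}
inline double beta_n(double v) { return 0.125 * std::exp(-(v + 44.0) / 80.0); }

inline double mg_block(double v) {
  // [Mg++] = 1 mM
  return 1.0 / (1.0 + 0.28 * std::exp(-0.062 * v));
}

} // namespace

// [[Rcpp::export(name = ".sim_ei_network_cpp")]]
List sim_ei_network_cpp(int n_exc, int n_inh, double dt, double duration,
                        NumericMatrix w_ampa, NumericMatrix w_nmda,
                        NumericMatrix w_gaba,
                        double stim_onset, double stim_duration,
                        double stim_amplitude, IntegerVector stim_targets,
                        IntegerVector distractor_targets,
                        double distractor_rate, double distractor_amp,
                        double noise_rate, double noise_amp,
                        double g_ks_exc, double g_hva_exc,
                        double i_dc_exc, double i_dc_inh,
                        double tau_ampa, double tau_nmda, double tau_gaba) {
  const int n = n_exc + n_inh;
  if (w_ampa.nrow() != n || w_ampa.ncol() != n ||
      w_nmda.nrow() != n || w_nmda.ncol() != n ||
      w_gaba.nrow() != n || w_gaba.ncol() != n)
    stop("weight matrices must be (n_exc+n_inh) square");

  const double c_m = 1.0, g_na = 35.0, e_na = 55.0, g_k = 9.0,
               e_k = -90.0, g_l = 0.1, e_l = -65.0, phi = 5.0,
               e_gaba = -75.0, e_ca = 120.0, tau_q = 100.0;
  const int n_steps = (int)std::round(duration / dt);

  std::vector<double> v(n, -64.0), h(n, 0.78), nn(n, 0.09), q(n, 0.0),
      xa(n, 0.0), xn(n, 0.0), xg(n, 0.0), xnoise(n, 0.0),
      last_spike(n, -1e9);
  // small deterministic heterogeneity in the initial voltage to break
  // symmetry even at zero noise
  for (int i = 0; i < n; ++i) v[i] += 0.5 * std::sin(1.0 + 3.7 * i);

  std::vector<bool> is_stim(n, false), is_distr(n, false);
  for (int k = 0; k < stim_targets.size(); ++k) {
    int i = stim_targets[k] - 1;
    if (i >= 0 && i < n_exc) is_stim[i] = true;
  }
  for (int k = 0; k < distractor_targets.size(); ++k) {
    int i = distractor_targets[k] - 1;
    if (i >= 0 && i < n_exc) is_distr[i] = true;
  }

  const double p_noise = noise_rate * dt / 1000.0;       // rate in Hz, dt in ms
  const double p_distr = distractor_rate * dt / 1000.0;

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  spike_t.reserve(4096);
  spike_id.reserve(4096);

  const double dec_a = std::exp(-dt / tau_ampa);
  const double dec_n = std::exp(-dt / tau_nmda);
  const double dec_g = std::exp(-dt / tau_gaba);

  // postsynaptic conductances are tracked incrementally: all gates of a
  // type share one decay factor, so the weighted sums decay by that same
  // factor and only spike events add the (column of) synaptic weights
  std::vector<double> ga(n, 0.0), gn(n, 0.0), gg(n, 0.0), v_new(n);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const bool stim_on = (t >= stim_onset) && (t < stim_onset + stim_duration);
    const bool distr_on = t >= stim_onset;

    for (int i = 0; i < n; ++i) {
      const double vi = v[i];
      const double minf = alpha_m(vi) / (alpha_m(vi) + beta_m(vi));
      const double i_na = g_na * minf * minf * minf * h[i] * (vi - e_na);
      const double i_k = g_k * std::pow(nn[i], 4) * (vi - e_k);
      const double i_l = g_l * (vi - e_l);
      double i_mod = 0.0;
      if (i < n_exc) {
        const double qinf = 1.0 / (1.0 + std::exp(-(vi + 34.0) / 6.5));
        q[i] += dt * (qinf - q[i]) / tau_q;
        i_mod += g_ks_exc * q[i] * (vi - e_k);
        const double mca = 1.0 / (1.0 + std::exp(-(vi + 20.0) / 9.0));
        i_mod += g_hva_exc * mca * mca * (vi - e_ca);
      }
      const double i_syn = ga[i] * vi + gn[i] * mg_block(vi) * vi +
                           gg[i] * (vi - e_gaba) + xnoise[i] * vi;
      double i_ext = (i < n_exc) ? i_dc_exc : i_dc_inh;
      if (stim_on && is_stim[i]) i_ext += stim_amplitude;

      const double dv = (-i_na - i_k - i_l - i_mod - i_syn + i_ext) / c_m;
      v_new[i] = vi + dt * dv;
      if (!std::isfinite(v_new[i]))
        stop("integration error at t = %f ms, neuron %d: non-finite "
             "membrane potential", t, i + 1);

      h[i] += dt * phi * (alpha_h(vi) * (1.0 - h[i]) - beta_h(vi) * h[i]);
      nn[i] += dt * phi * (alpha_n(vi) * (1.0 - nn[i]) - beta_n(vi) * nn[i]);
    }

    // spike detection (upward crossing of -20 mV, 2 ms refractory)
    for (int j = 0; j < n; ++j) {
      if (v[j] < -20.0 && v_new[j] >= -20.0 && t - last_spike[j] > 2.0) {
        last_spike[j] = t;
        spike_t.push_back(t);
        spike_id.push_back(j + 1);
        if (j < n_exc) {
          const double dxn = 0.5 * (1.0 - xn[j]);
          xa[j] += 1.0;
          xn[j] += dxn;
          for (int i = 0; i < n; ++i) {
            ga[i] += w_ampa(i, j);
            gn[i] += w_nmda(i, j) * dxn;
          }
        } else {
          xg[j] += 1.0;
          for (int i = 0; i < n; ++i) gg[i] += w_gaba(i, j);
        }
      }
      v[j] = v_new[j];
    }

    // gate decay and background events
    for (int i = 0; i < n; ++i) {
      xa[i] *= dec_a;
      xn[i] *= dec_n;
      xg[i] *= dec_g;
      ga[i] *= dec_a;
      gn[i] *= dec_n;
      gg[i] *= dec_g;
      xnoise[i] *= dec_a;
      if (p_noise > 0.0 && unif_rand() < p_noise) xnoise[i] += noise_amp;
      if (distr_on && is_distr[i] && p_distr > 0.0 &&
          unif_rand() < p_distr)
        xnoise[i] += distractor_amp;
    }
  }

  return List::create(_["spike_time"] = wrap(spike_t),
                      _["neuron"] = wrap(spike_id),
                      _["n_steps"] = n_steps);
}

// [[Rcpp::export(name = ".sim_msn_cpp")]]
List sim_msn_cpp(double dt, double duration, NumericVector drive,
                 NumericVector gate, double c_m, double g_na, double g_kdr,
                 double g_kir, double kir_u, double e_k, double v_h,
                 double v_c, double g_ka, double g_ksi, double g_cl,
                 double e_cl, double g_ca, double e_ca, double drive_gain,
                 double noise_rate, double noise_amp, int record_stride) {
  const int n_steps = (int)std::round(duration / dt);
  if (drive.size() < n_steps || gate.size() < n_steps)
    stop("drive and gate series must cover the full duration");

  const double e_na = 55.0, phi = 5.0, tau_q = 120.0, tau_a = 2.0,
               tau_b = 80.0, tau_noise = 2.0;
  double v = -80.0, h = 0.9, nn = 0.05, q = 0.0, a = 0.0, b = 1.0,
         xnoise = 0.0, last_spike = -1e9;
  const double p_noise = noise_rate * dt / 1000.0;
  const double dec_noise = std::exp(-dt / tau_noise);

  int n_rec = n_steps / record_stride + 1;
  NumericVector vtrace(n_rec), ttrace(n_rec);
  int rec = 0;
  std::vector<double> spikes;
  double depol_sum = 0.0;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    if (step % record_stride == 0 && rec < n_rec) {
      vtrace[rec] = v;
      ttrace[rec] = t;
      ++rec;
    }
    const double minf = alpha_m(v) / (alpha_m(v) + beta_m(v));
    const double i_na = g_na * minf * minf * minf * h * (v - e_na);
    const double i_kdr = g_kdr * std::pow(nn, 4) * (v - e_k);
    // inward rectifier: Boltzmann conductance with printed sign
    // convention (v_c = -11 mV makes it shut with depolarisation)
    const double g_kir_v = g_kir / (1.0 + std::exp(-(v - v_h) / v_c));
    const double i_kir = kir_u * g_kir_v * (v - e_k);
    const double ainf = 1.0 / (1.0 + std::exp(-(v + 45.0) / 12.0));
    const double binf = 1.0 / (1.0 + std::exp((v + 70.0) / 10.0));
    a += dt * (ainf - a) / tau_a;
    b += dt * (binf - b) / tau_b;
    const double i_ka = g_ka * a * b * (v - e_k);
    const double qinf = 1.0 / (1.0 + std::exp(-(v + 34.0) / 6.5));
    q += dt * (qinf - q) / tau_q;
    const double i_ksi = g_ksi * q * (v - e_k);
    const double i_cl = g_cl * (v - e_cl);
    const double mca = 1.0 / (1.0 + std::exp(-(v + 20.0) / 9.0));
    const double i_ca = g_ca * mca * mca * (v - e_ca);
    const double g_syn = drive_gain * drive[step] * gate[step] + xnoise;
    const double i_syn = g_syn * v;  // glutamatergic, E = 0 mV

    const double dv = (-i_na - i_kdr - i_kir - i_ka - i_ksi - i_cl -
                       i_ca - i_syn) / c_m;
    const double v_new = v + dt * dv;
    if (!std::isfinite(v_new))
      stop("integration error at t = %f ms: non-finite membrane potential",
           t);
    h += dt * phi * (alpha_h(v) * (1.0 - h) - beta_h(v) * h);
    nn += dt * phi * (alpha_n(v) * (1.0 - nn) - beta_n(v) * nn);
    if (v < -20.0 && v_new >= -20.0 && t - last_spike > 2.0) {
      last_spike = t;
      spikes.push_back(t);
    }
    v = v_new;
    depol_sum += v;
    xnoise *= dec_noise;
    if (p_noise > 0.0 && unif_rand() < p_noise) xnoise += noise_amp;
  }

  return List::create(
      _["spike_times"] = wrap(spikes),
      _["n_spikes"] = (int)spikes.size(),
      _["mean_v"] = depol_sum / n_steps,
      _["trace_time"] = ttrace[Range(0, rec - 1)],
      _["trace_v"] = vtrace[Range(0, rec - 1)]);
}
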