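#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Forward integration of the three-population conductance-based LIF
// network.  Synaptic conductances decay exponentially (exact update) and
// are incremented by the connection weight on each presynaptic spike;
// spikes take effect on the following integration step.  The membrane
// equation is integrated with forward Euler at step dt.  The two
// background conductances follow exact Ornstein-Uhlenbeck updates; their
// state is left free but negative excursions are clipped to zero where the
// conductance enters a current.  External Poisson spikes are drawn per
// step with probability 1 - exp(-lambda0 * dt) per neuron.
//
// All randomness is drawn from R's RNG, so a set.seed() call on the R side
// makes the trial fully reproducible.
//
// [[Rcpp::export]]
List simulate_lif_cpp(int n_exc, int n_inh, int n_ext,
                      IntegerVector ext_ptr, IntegerVector ext_idx, double a_ext,
                      IntegerVector exc_ptr, IntegerVector exc_idx, double a_rec,
                      IntegerVector inh_ptr, IntegerVector inh_idx, double a_inh,
                      double C_m, double g_L, double E_L, double E_e, double E_i,
                      double tau_exc, double tau_inh,
                      double theta_exc, double theta_inh,
                      double mu_be, double sigma_be,
                      double mu_bi, double sigma_bi,
                      bool background, bool clip_background,
                      double lambda0, double dt, int n_steps,
                      int record_start, double I_inj,
                      double na_frac, double E_Na,
                      bool record_spikes) {
  const int n_tot = n_exc + n_inh;
  std::vector<double> V(n_tot, E_L);
  std::vector<double> g_ext(n_tot, 0.0), g_exc(n_tot, 0.0), g_inh(n_tot, 0.0);
  std::vector<double> g_be(n_tot, background ? mu_be : 0.0);
  std::vector<double> g_bi(n_tot, background ? mu_bi : 0.0);
  std::vector<double> inc_ext(n_tot, 0.0), inc_exc(n_tot, 0.0), inc_inh(n_tot, 0.0);

  const double dec_e = std::exp(-dt / tau_exc);
  const double dec_i = std::exp(-dt / tau_inh);
  const double ou_e = std::exp(-dt / tau_exc);
  const double ou_i = std::exp(-dt / tau_inh);
  const double ou_e_s = sigma_be * std::sqrt(1.0 - ou_e * ou_e);
  const double ou_i_s = sigma_bi * std::sqrt(1.0 - ou_i * ou_i);
  const double p_spike = (lambda0 > 0.0) ? 1.0 - std::exp(-lambda0 * dt) : 0.0;

  std::vector<int> counts(n_tot, 0);
  std::vector<double> sum_INa(n_tot, 0.0), sum_Irec(n_tot, 0.0);
  double sum_gbe = 0.0, sum_gbi = 0.0;
  long ext_count = 0;
  long rec_steps = 0;

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  std::vector<int> ext_draw(n_ext, 0);
  std::vector<int> picked;

  for (int step = 0; step < n_steps; ++step) {
    const bool in_window = step >= record_start;

    // 1. synaptic conductance decay + pending increments from last step
    for (int i = 0; i < n_tot; ++i) {
      g_ext[i] = g_ext[i] * dec_e + inc_ext[i];
      g_exc[i] = g_exc[i] * dec_e + inc_exc[i];
      g_inh[i] = g_inh[i] * dec_i + inc_inh[i];
      inc_ext[i] = 0.0; inc_exc[i] = 0.0; inc_inh[i] = 0.0;
    }

    // 2. OU background, exact update
    if (background) {
      for (int i = 0; i < n_tot; ++i) {
        g_be[i] = mu_be + (g_be[i] - mu_be) * ou_e + ou_e_s * norm_rand();
        g_bi[i] = mu_bi + (g_bi[i] - mu_bi) * ou_i + ou_i_s * norm_rand();
      }
    }

    // 3. currents and Euler step for V; records use the pre-update V
    for (int i = 0; i < n_tot; ++i) {
      const double v = V[i];
      const double gbe = (clip_background && g_be[i] < 0.0) ? 0.0 : g_be[i];
      const double gbi = (clip_background && g_bi[i] < 0.0) ? 0.0 : g_bi[i];
      const double Ge = g_ext[i] + g_exc[i] + gbe;       // all E_e-reversal
      const double Gi = g_inh[i] + gbi;                  // all E_i-reversal
      const double I_rec = g_exc[i] * (E_e - v) + g_inh[i] * (E_i - v);
      const double I = g_L * (E_L - v) + Ge * (E_e - v) + Gi * (E_i - v) + I_inj;
      if (in_window) {
        sum_INa[i] += na_frac * Ge * (v - E_Na);         // pA
        sum_Irec[i] += I_rec;
        sum_gbe += g_be[i];
        sum_gbi += g_bi[i];
      }
      V[i] = v + dt / C_m * I;
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential (neuron %d, step %d)", i + 1, step);
    }
    if (in_window) ++rec_steps;

    // 4. threshold, reset, recurrent propagation (effective next step)
    for (int i = 0; i < n_tot; ++i) {
      const double theta = (i < n_exc) ? theta_exc : theta_inh;
      if (V[i] >= theta) {
        V[i] = E_L;
        if (in_window) ++counts[i];
        if (record_spikes) { spk_id.push_back(i); spk_t.push_back(step * dt); }
        if (i < n_exc) {
          if (a_rec > 0.0)
            for (int k = exc_ptr[i]; k < exc_ptr[i + 1]; ++k)
              inc_exc[exc_idx[k]] += a_rec;
        } else {
          if (a_inh > 0.0)
            for (int k = inh_ptr[i - n_exc]; k < inh_ptr[i - n_exc + 1]; ++k)
              inc_inh[inh_idx[k]] += a_inh;
        }
      }
    }

    // 5. external Poisson spikes for the next step
    if (p_spike > 0.0 && n_ext > 0) {
      int k = (int) R::rbinom((double) n_ext, p_spike);
      if (k > 0) {
        picked.clear();
        if (k < n_ext) {
          // sample k distinct neurons by rejection on a scratch array
          int found = 0;
          while (found < k) {
            int j = (int) (unif_rand() * n_ext);
            if (j >= n_ext) j = n_ext - 1;
            if (!ext_draw[j]) { ext_draw[j] = 1; picked.push_back(j); ++found; }
          }
          for (int j : picked) ext_draw[j] = 0;
        } else {
          for (int j = 0; j < n_ext; ++j) picked.push_back(j);
        }
        for (int j : picked)
          for (int m = ext_ptr[j]; m < ext_ptr[j + 1]; ++m)
            inc_ext[ext_idx[m]] += a_ext;
        if (in_window) ext_count += k;
      }
    }
  }

  NumericVector mean_INa(n_tot), mean_Irec(n_tot);
  for (int i = 0; i < n_tot; ++i) {
    mean_INa[i] = rec_steps > 0 ? sum_INa[i] / rec_steps : 0.0;
    mean_Irec[i] = rec_steps > 0 ? sum_Irec[i] / rec_steps : 0.0;
  }
  const double denom = rec_steps > 0 ? (double) rec_steps * n_tot : 1.0;

  return List::create(
    _["counts"] = IntegerVector(counts.begin(), counts.end()),
    _["mean_I_Na"] = mean_INa,
    _["mean_I_rec"] = mean_Irec,
    _["mean_g_bcg_exc"] = sum_gbe / denom,
    _["mean_g_bcg_inh"] = sum_gbi / denom,
    _["ext_spike_count"] = (double) ext_count,
    _["spike_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
    _["spike_time"] = NumericVector(spk_t.begin(), spk_t.end()),
    _["V_final"] = NumericVector(V.begin(), V.end()));
}
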