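#include <Rcpp.h>
using namespace Rcpp;

// Explicit-Euler steppers. Units: mV, ms, and current in pA-equivalents
// (unit input resistance for the QIF form). Spike time convention: the
// time at the end of the step on which v crossed v_peak.

// Adaptive substepping: the quadratic upswing is fast relative to dt, so
// each Euler substep is limited to a 2 mV membrane change (V_SUBSTEP_MAX);
// without it the spike time is systematically early at coarse dt.
#define V_SUBSTEP_MAX 2.0

static inline bool izh_step(double &v, double &u, const double *p,
                            double I, double dt) {
  // p: C, k, vr, vt, a, b, c, d, vpeak
  double rem = dt;
  bool spike = false;
  while (rem > 0) {
    double dv = (p[1] * (v - p[2]) * (v - p[3]) - u + I) / p[0];
    double h = rem;
    double adv = dv < 0 ? -dv : dv;
    if (adv * h > V_SUBSTEP_MAX) h = V_SUBSTEP_MAX / adv;
    double un = u + h * p[4] * (p[5] * (v - p[2]) - u);
    v += h * dv;
    u = un;
    rem -= h;
    if (v >= p[8]) {
      v = p[6];
      u += p[7];
      return true;  // step ends at the spike; v left at reset
    }
  }
  return spike;
}

static inline bool qif_step(double &v, const double *p, double I, double dt) {
  // p: tau, vr, vc, reset, vpeak
  double rem = dt;
  bool spike = false;
  while (rem > 0) {
    double dv = ((v - p[1]) * (v - p[2]) / (p[2] - p[1]) + I) / p[0];
    double h = rem;
    double adv = dv < 0 ? -dv : dv;
    if (adv * h > V_SUBSTEP_MAX) h = V_SUBSTEP_MAX / adv;
    v += h * dv;
    rem -= h;
    if (v >= p[4]) {
      v = p[3];
      return true;  // step ends at the spike; v left at reset
    }
  }
  return spike;
}

// [[Rcpp::export]]
List sim_izh_cpp(NumericVector par, NumericVector input, double dt,
                 int n_steps, double v0, double u0, double noise_sd) {
  std::vector<int> spikes;
  double v = v0, u = u0;
  const double *p = par.begin();
  const bool varying = input.size() > 1;
  const double nfac = noise_sd * std::sqrt(dt) / p[0];
  for (int t = 0; t < n_steps; ++t) {
    double I = varying ? input[t] : input[0];
    if (izh_step(v, u, p, I, dt)) spikes.push_back(t + 1);
    if (noise_sd > 0) v += nfac * norm_rand();
    if (!R_finite(v) || !R_finite(u))
      stop("Izhikevich integration diverged (non-finite state); reduce dt");
  }
  return List::create(_["spike_steps"] = wrap(spikes), _["v"] = v, _["u"] = u);
}

// [[Rcpp::export]]
List sim_qif_cpp(NumericVector par, double bias, NumericVector input,
                 double dt, int n_steps, double v0, double noise_sd) {
  std::vector<int> spikes;
  double v = v0;
  const double *p = par.begin();
  const bool varying = input.size() > 1;
  const double nfac = noise_sd * std::sqrt(dt) / p[0];
  for (int t = 0; t < n_steps; ++t) {
    double I = bias + (varying ? input[t] : input[0]);
    if (qif_step(v, p, I, dt)) spikes.push_back(t + 1);
    if (noise_sd > 0) v += nfac * norm_rand();
    if (!R_finite(v))
      stop("QIF integration diverged (non-finite state); reduce dt");
  }
  return List::create(_["spike_steps"] = wrap(spikes), _["v"] = v);
}

// Full circuit: vSub Poisson drive -> NAcc (Izhikevich MSN) -| VP (QIF)
// -| VTA DA (QIF pacemakers), with PPTN (+) and RMTN (-) Poisson drives
// onto the DA population. An aversive-responding DA subset receives the
// RMTN drive with flipped sign and extra gain.
// [[Rcpp::export]]
List sim_circuit_cpp(NumericVector msn_par, NumericVector vp_par,
                     NumericVector da_par, NumericVector vp_bias,
                     NumericVector da_bias, double msn_noise,
                     double vp_noise, double da_noise,
                     NumericMatrix W_vp_nacc, NumericMatrix W_da_vp,
                     IntegerVector aversive, double aversive_gain,
                     double vp_inh_max,
                     double ou_tau, double ou_sd,
                     NumericVector vsub_rate, NumericVector pptn_rate,
                     NumericVector rmtn_rate, NumericVector pptn_tonic_rate,
                     NumericVector rmtn_tonic_rate, double w_vsub,
                     double w_pptn, double w_rmtn, double w_pptn_tonic,
                     double w_rmtn_tonic, double tau_exc, double tau_inh,
                     double dt,
                     int n_steps, NumericVector v0_nacc, NumericVector u0_nacc,
                     NumericVector v0_vp, NumericVector v0_da) {
  const int n_nacc = v0_nacc.size(), n_vp = v0_vp.size(), n_da = v0_da.size();
  const double *pm = msn_par.begin(), *pv = vp_par.begin(),
               *pd = da_par.begin();

  std::vector<double> v_na(v0_nacc.begin(), v0_nacc.end());
  std::vector<double> u_na(u0_nacc.begin(), u0_nacc.end());
  std::vector<double> v_vp(v0_vp.begin(), v0_vp.end());
  std::vector<double> v_da(v0_da.begin(), v0_da.end());

  std::vector<double> s_na(n_nacc, 0.0);    // vSub -> NAcc excitation
  std::vector<double> s_vp(n_vp, 0.0);      // NAcc -> VP inhibition (>= 0)
  std::vector<double> s_da_in(n_da, 0.0);   // VP -> DA inhibition (>= 0)
  std::vector<double> s_pptn(n_da, 0.0);    // PPTN -> DA excitation
  std::vector<double> s_rmtn(n_da, 0.0);    // RMTN -> DA drive (sign per neuron)

  const double de = std::exp(-dt / tau_exc), di = std::exp(-dt / tau_inh);
  const double nf_na = msn_noise * std::sqrt(dt) / pm[0];
  const double nf_vp = vp_noise * std::sqrt(dt) / pv[0];
  const double nf_da = da_noise * std::sqrt(dt) / pd[0];

  std::vector<int> sp_na_id, sp_na_t, sp_vp_id, sp_vp_t, sp_da_id, sp_da_t;

  // slow log-normal Ornstein-Uhlenbeck modulation of the vSub drive rate
  // per MSN (correlated afferent fluctuations -> up/down states); the
  // multiplier exp(ou_sd * x - ou_sd^2/2) has mean 1 for standard OU x
  std::vector<double> ou(n_nacc, 0.0);
  const double ou_a = dt / ou_tau, ou_b = std::sqrt(2.0 * dt / ou_tau);
  const double ou_c = -0.5 * ou_sd * ou_sd;

  for (int t = 0; t < n_steps; ++t) {
    // drive events
    double lam0 = vsub_rate[t] * dt / 1000.0;
    for (int i = 0; i < n_nacc; ++i) {
      if (ou_sd > 0) ou[i] += -ou_a * ou[i] + ou_b * norm_rand();
      if (lam0 > 0) {
        double lam = lam0 * std::exp(ou_sd * ou[i] + ou_c);
        int k = (int)R::rpois(lam);
        if (k) s_na[i] += k * w_vsub;
      }
    }
    double lam = pptn_rate[t] * dt / 1000.0;
    if (lam > 0)
      for (int i = 0; i < n_da; ++i) {
        int k = (int)R::rpois(lam);
        if (k) s_pptn[i] += k * w_pptn;
      }
    lam = rmtn_rate[t] * dt / 1000.0;
    if (lam > 0)
      for (int i = 0; i < n_da; ++i) {
        int k = (int)R::rpois(lam);
        if (k) s_rmtn[i] += k * w_rmtn;
      }
    lam = pptn_tonic_rate[t] * dt / 1000.0;
    if (lam > 0)
      for (int i = 0; i < n_da; ++i) {
        int k = (int)R::rpois(lam);
        if (k) s_pptn[i] += k * w_pptn_tonic;
      }
    lam = rmtn_tonic_rate[t] * dt / 1000.0;
    if (lam > 0)
      for (int i = 0; i < n_da; ++i) {
        int k = (int)R::rpois(lam);
        if (k) s_rmtn[i] += k * w_rmtn_tonic;
      }

    // NAcc MSNs
    for (int i = 0; i < n_nacc; ++i) {
      if (izh_step(v_na[i], u_na[i], pm, s_na[i], dt)) {
        sp_na_id.push_back(i + 1);
        sp_na_t.push_back(t + 1);
        for (int j = 0; j < n_vp; ++j) s_vp[j] += W_vp_nacc(j, i);
      }
      if (msn_noise > 0) v_na[i] += nf_na * norm_rand();
    }
    // VP; NAcc inhibition saturates (GABA receptor saturation)
    for (int j = 0; j < n_vp; ++j) {
      double inh = s_vp[j] < vp_inh_max ? s_vp[j] : vp_inh_max;
      double I = vp_bias[j] - inh;
      if (qif_step(v_vp[j], pv, I, dt)) {
        sp_vp_id.push_back(j + 1);
        sp_vp_t.push_back(t + 1);
        for (int k = 0; k < n_da; ++k) s_da_in[k] += W_da_vp(k, j);
      }
      if (vp_noise > 0) v_vp[j] += nf_vp * norm_rand();
    }
    // VTA DA
    for (int k = 0; k < n_da; ++k) {
      double rm = aversive[k] ? aversive_gain * s_rmtn[k] : -s_rmtn[k];
      double I = da_bias[k] + s_pptn[k] - s_da_in[k] + rm;
      if (qif_step(v_da[k], pd, I, dt)) {
        sp_da_id.push_back(k + 1);
        sp_da_t.push_back(t + 1);
      }
      if (da_noise > 0) v_da[k] += nf_da * norm_rand();
    }

    for (int i = 0; i < n_nacc; ++i) s_na[i] *= de;
    for (int j = 0; j < n_vp; ++j) s_vp[j] *= di;
    for (int k = 0; k < n_da; ++k) {
      s_da_in[k] *= di;
      s_pptn[k] *= de;
      s_rmtn[k] *= di;
    }
    if (t % 2000 == 0 && (!R_finite(v_na[0]) || !R_finite(v_vp[0]) ||
                          !R_finite(v_da[0])))
      stop("circuit integration diverged (non-finite state); reduce dt");
  }

  return List::create(
      _["nacc_id"] = wrap(sp_na_id), _["nacc_step"] = wrap(sp_na_t),
      _["vp_id"] = wrap(sp_vp_id), _["vp_step"] = wrap(sp_vp_t),
      _["da_id"] = wrap(sp_da_id), _["da_step"] = wrap(sp_da_t));
}
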