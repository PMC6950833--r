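#include <Rcpp.h>
using namespace Rcpp;

// Guarded logistic 1/(1+exp(x)).
static inline double inv_logit_neg(double x) {
  if (x > 40.0) return 0.0;
  if (x < -40.0) return 1.0;
  return 1.0 / (1.0 + std::exp(x));
}

// Advance all gates of the channel model along a sampled membrane-voltage
// trace. Each sample interval uses the exact exponential update of the
// first-order gate ODE with the voltage held at the sample value, so on step
// protocols the integration is piecewise exact regardless of dt. The
// Ca2+-dependent gate is driven by the instantaneous inward current flowing
// during the preceding interval (exponential-Euler with frozen rates).
//
// State vector: m1 (fast activation pathway), m2 (slow-deactivation
// pathway), hf, hs (fast/slow VDI gates), hcdi (CDI gate, 1 = no CDI).
//
// Returned ionic current is in pA when g_max is in nS and voltages in mV.
// [[Rcpp::export]]
List sim_sweep_kernel(NumericVector v, double dt, List pars, bool ca_carrier,
                      double block, NumericVector state0, bool return_states) {
  const int n = v.size();
  const double g_max = pars["g_max"], v_rev = pars["v_rev"];
  const double vha = pars["v_half_act"], ka = pars["slope_act"];
  const double tau_act_min = pars["tau_act_min"], tau_act_max = pars["tau_act_max"];
  const double tau_act_v = pars["tau_act_v"], tau_act_k = pars["tau_act_k"];
  const double tsf = pars["tail_slow_frac"], tts = pars["tau_tail_slow"];
  const double ff = pars["frac_fast"], fs = pars["frac_slow"], fp = pars["frac_persistent"];
  const double tf0 = pars["tau_fast_0"], ts0 = pars["tau_slow_0"];
  const double tvd = pars["tau_v_dep"];
  const double vhi = pars["v_half_inact"], ki = pars["slope_inact"];
  const double coupling = pars["cdi_coupling"], tau_rec = pars["tau_cdi_recovery"];

  double m1 = state0[0], m2 = state0[1], hf = state0[2], hs = state0[3],
         hcdi = state0[4];

  NumericVector iion(n);
  NumericMatrix states;
  if (return_states) states = NumericMatrix(n, 5);

  const bool do_cdi = ca_carrier && coupling > 0.0;
  const double gscale = g_max * (1.0 - block);

  for (int i = 0; i < n; ++i) {
    const double vv = v[i];
    const double minf = inv_logit_neg(-(vv - vha) / ka);
    const double taum = tau_act_min + tau_act_max / std::cosh((vv - tau_act_v) / tau_act_k);
    m1 = minf + (m1 - minf) * std::exp(-dt / taum);
    const double tau2 = (m2 > minf) ? tts : taum;
    m2 = minf + (m2 - minf) * std::exp(-dt / tau2);

    const double hinf = inv_logit_neg((vv - vhi) / ki);
    // bell-shaped VDI time constants, slowest near the inactivation midpoint
    const double sech = 1.0 / std::cosh((vv - vhi) / tvd);
    const double tf = tf0 * sech, ts = ts0 * sech;
    hf = hinf + (hf - hinf) * std::exp(-dt / tf);
    hs = hinf + (hs - hinf) * std::exp(-dt / ts);

    const double hvdi = ff * hf + fs * hs + fp;
    const double m = (1.0 - tsf) * m1 + tsf * m2;
    const double icur = gscale * m * hvdi * hcdi * (vv - v_rev);
    iion[i] = icur;

    if (do_cdi) {
      const double inward = icur < 0.0 ? -icur : 0.0;
      const double lam = coupling * inward + 1.0 / tau_rec;
      const double hinfc = (1.0 / tau_rec) / lam;
      hcdi = hinfc + (hcdi - hinfc) * std::exp(-lam * dt);
    }

    if (return_states) {
      states(i, 0) = m1; states(i, 1) = m2; states(i, 2) = hf;
      states(i, 3) = hs; states(i, 4) = hcdi;
    }
  }

  NumericVector fin = NumericVector::create(m1, m2, hf, hs, hcdi);
  if (!R_finite(m1) || !R_finite(hf) || !R_finite(hs) || !R_finite(hcdi))
    stop("numerical failure: non-finite gating state (check tau and slope parameters)");

  if (return_states)
    return List::create(_["i_ion"] = iion, _["state"] = fin, _["states"] = states);
  return List::create(_["i_ion"] = iion, _["state"] = fin);
}
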