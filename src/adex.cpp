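#include <Rcpp.h>
using namespace Rcpp;

// Adaptive exponential integrate-and-fire membrane, fixed-step explicit
// Euler in physical units (mV, pA, nS, pF, ms).  The injected current is
// given per output sample, so the integration grid equals the sample grid.
// Ornstein-Uhlenbeck current noise uses R's RNG (exact discretization), so
// set.seed() in R makes traces bit-identical.
//
// A spike is registered when V crosses v_cut; V is clamped to the reset for
// t_ref ms while the adaptation current keeps evolving.  Spike shaping
// (pasting a stereotyped waveform) happens on the R side.
//
// [[Rcpp::export(name = ".adex_integrate")]]
List adex_integrate(NumericVector i_cmd,
                    double dt,
                    double C, double gL, double EL, double DeltaT,
                    double VT, double a, double tau_w, double Vr, double b,
                    double v_cut, double t_ref,
                    double noise_sd, double noise_tau,
                    double v0 = NA_REAL, double w0 = 0.0) {
  const int n = i_cmd.size();
  if (dt <= 0.0 || dt > 0.05)
    stop("integration step must be in (0, 0.05] ms");
  if (!R_finite(C) || !R_finite(gL) || !R_finite(EL) || !R_finite(DeltaT) ||
      !R_finite(VT) || !R_finite(a) || !R_finite(tau_w) || !R_finite(Vr) ||
      !R_finite(b) || C <= 0.0 || gL <= 0.0 || DeltaT <= 0.0 || tau_w <= 0.0)
    stop("non-finite or non-positive model parameter");

  NumericVector v(n);
  std::vector<int> spikes;
  double V = R_finite(v0) ? v0 : EL;
  double w = w0;
  double eta = 0.0;
  const bool noisy = noise_sd > 0.0;
  const double decay = noisy ? std::exp(-dt / noise_tau) : 0.0;
  const double drive = noisy ? noise_sd * std::sqrt(1.0 - decay * decay) : 0.0;
  int ref_left = 0;                       // samples left in refractory clamp
  const int ref_n = (int)std::ceil(t_ref / dt);

  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    if (noisy) eta = eta * decay + drive * R::rnorm(0.0, 1.0);
    if (ref_left > 0) {
      V = Vr;
      --ref_left;
    } else {
      double ex = (V - VT) / DeltaT;
      if (ex > 20.0) ex = 20.0;          // bounded drive; spike fires anyway
      double dV = (-gL * (V - EL) + gL * DeltaT * std::exp(ex) - w + i_cmd[i] + eta) / C;
      V += dt * dV;
    }
    w += dt * (a * (V - EL) - w) / tau_w;
    if (ref_left == 0 && V >= v_cut) {   // spike: record, reset, refractory
      spikes.push_back(i + 1);           // 1-based sample index
      V = Vr;
      w += b;
      ref_left = ref_n;
    }
    if (!R_finite(V) || V > 200.0 || V < -200.0)
      stop("numerical divergence: |V| exceeded 200 mV at sample %d", i + 1);
    v[i] = V;
  }
  return List::create(_["v"] = v,
                      _["spike_index"] = wrap(spikes),
                      _["w_end"] = w);
}
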