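#include <Rcpp.h>
using namespace Rcpp;

// Two-compartment Hodgkin-Huxley integrator.
//
// Kinetic matrix `kin`: one row per channel, columns
//   0 p (activation exponent), 1 q (inactivation exponent),
//   2 vhm, 3 km          activation Boltzmann midpoint / slope (mV)
//   4..8  taum: min (ms), amp (ms), v (mV), k1 (mV), k2 (mV)
//   9 vhh, 10 kh         inactivation Boltzmann midpoint / slope (mV)
//   11..15 tauh: min, amp, v, k1, k2
//   16 erev (mV), 17 q10, 18 tref (degC)
// Steady state: x_inf(v) = 1 / (1 + exp(-(v - vh)/k)); k < 0 encodes a gate
// that closes with depolarization (inactivation, HCN activation).
// Time constant: tau(v) = tmin + tamp / (exp((v - tv)/tk1) + exp(-(v - tv)/tk2)),
// scaled by q10^((tref - temperature)/10).
// Current: I = g * m^p * h^q * (v - erev), positive outward (pA with g in nS,
// v in mV).

static inline double xinf(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

static inline double taux(double v, const double* tp, double tscale) {
  // tp: min, amp, v, k1, k2
  double tau = tp[0] + tp[1] / (std::exp((v - tp[2]) / tp[3]) +
                                std::exp(-(v - tp[2]) / tp[4]));
  return tau * tscale;
}

static inline double gate_pow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

// [[Rcpp::export(name = ".hh2c_core")]]
List hh2c_core(NumericMatrix kin,
               NumericVector g_soma, NumericVector g_axon,
               double c_soma, double c_axon, double g_couple,
               double temperature, double dt,
               NumericVector i_soma,      // injected somatic current per step (pA)
               int mode,                  // 0 = current clamp, 1 = voltage clamp
               NumericVector v_cmd,       // somatic command per step (VC only)
               NumericVector state0,      // v_s, v_a, then m_s,h_s,m_a,h_a per channel
               bool record) {
  const int nc = kin.nrow();
  const int nstep = (mode == 0) ? i_soma.size() : (v_cmd.size() - 1);

  std::vector<double> ms(nc), hs(nc), ma(nc), ha(nc);
  double vs = state0[0], va = state0[1];
  for (int j = 0; j < nc; ++j) {
    ms[j] = state0[2 + j];
    hs[j] = state0[2 + nc + j];
    ma[j] = state0[2 + 2 * nc + j];
    ha[j] = state0[2 + 3 * nc + j];
  }

  // precompute per-channel temperature scale and integer exponents;
  // copy kinetics to a row-major buffer (NumericMatrix is column-major)
  std::vector<double> tscale(nc), K(nc * 19);
  std::vector<int> pp(nc), qq(nc);
  for (int j = 0; j < nc; ++j) {
    for (int c = 0; c < 19; ++c) K[j * 19 + c] = kin(j, c);
    tscale[j] = std::pow(kin(j, 17), (kin(j, 18) - temperature) / 10.0);
    pp[j] = (int)kin(j, 0);
    qq[j] = (int)kin(j, 1);
  }

  int nrec = record ? nstep + 1 : 1;
  NumericVector out_vs(nrec), out_va(nrec), out_ic(mode == 1 ? nrec : 1);

  if (mode == 1) vs = v_cmd[0];

  int bad_step = -1;

  // ionic current helper (lambda-free for speed): computed inline below
  for (int t = 0; t <= nstep; ++t) {
    // record state at time t
    double ion_s = 0.0, ion_a = 0.0;
    for (int j = 0; j < nc; ++j) {
      double open_s = gate_pow(ms[j], pp[j]) * gate_pow(hs[j], qq[j]);
      double open_a = gate_pow(ma[j], pp[j]) * gate_pow(ha[j], qq[j]);
      ion_s += g_soma[j] * open_s * (vs - K[j * 19 + 16]);
      ion_a += g_axon[j] * open_a * (va - K[j * 19 + 16]);
    }
    double icpl = g_couple * (vs - va); // soma -> axon positive

    if (record || t == nstep) {
      int idx = record ? t : 0;
      out_vs[idx] = vs;
      out_va[idx] = va;
      if (mode == 1) {
        // clamp current: capacitive + ionic + coupling balance at the soma
        double dvc = (t < nstep) ? (v_cmd[t + 1] - v_cmd[t]) / dt : 0.0;
        out_ic[idx] = c_soma * dvc + ion_s + icpl;
      }
    }
    if (t == nstep) break;

    // gate update (exponential Euler at v(t))
    for (int j = 0; j < nc; ++j) {
      if (pp[j] > 0) {
        double mi = xinf(vs, K[j * 19 + 2], K[j * 19 + 3]);
        double tm = taux(vs, &K[j * 19 + 4], tscale[j]);
        ms[j] = mi + (ms[j] - mi) * std::exp(-dt / tm);
        mi = xinf(va, K[j * 19 + 2], K[j * 19 + 3]);
        tm = taux(va, &K[j * 19 + 4], tscale[j]);
        ma[j] = mi + (ma[j] - mi) * std::exp(-dt / tm);
      }
      if (qq[j] > 0) {
        double hi = xinf(vs, K[j * 19 + 9], K[j * 19 + 10]);
        double th = taux(vs, &K[j * 19 + 11], tscale[j]);
        hs[j] = hi + (hs[j] - hi) * std::exp(-dt / th);
        hi = xinf(va, K[j * 19 + 9], K[j * 19 + 10]);
        th = taux(va, &K[j * 19 + 11], tscale[j]);
        ha[j] = hi + (ha[j] - hi) * std::exp(-dt / th);
      }
    }

    // membrane update with the refreshed gates at v(t)
    ion_s = 0.0; ion_a = 0.0;
    for (int j = 0; j < nc; ++j) {
      double open_s = gate_pow(ms[j], pp[j]) * gate_pow(hs[j], qq[j]);
      double open_a = gate_pow(ma[j], pp[j]) * gate_pow(ha[j], qq[j]);
      ion_s += g_soma[j] * open_s * (vs - K[j * 19 + 16]);
      ion_a += g_axon[j] * open_a * (va - K[j * 19 + 16]);
    }
    icpl = g_couple * (vs - va);

    if (mode == 0) {
      vs += dt * (i_soma[t] - ion_s - icpl) / c_soma;
    } else {
      vs = v_cmd[t + 1];
    }
    va += dt * (-ion_a + icpl) / c_axon;

    if (!std::isfinite(vs) || !std::isfinite(va)) {
      bad_step = t + 1;
      break;
    }
  }

  NumericVector sfin(2 + 4 * nc);
  sfin[0] = vs; sfin[1] = va;
  for (int j = 0; j < nc; ++j) {
    sfin[2 + j] = ms[j];
    sfin[2 + nc + j] = hs[j];
    sfin[2 + 2 * nc + j] = ma[j];
    sfin[2 + 3 * nc + j] = ha[j];
  }

  return List::create(_["v_soma"] = out_vs, _["v_axon"] = out_va,
                      _["i_clamp"] = out_ic, _["state"] = sfin,
                      _["bad_step"] = bad_step);
}
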