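// Ionic membrane kinetics: ten Tusscher-Panfilov 2006 human ventricular
// model (epicardial variant) and a two-variable threshold-and-recovery
// reduced model. Gating variables use Rush-Larsen updates; potentials,
// concentrations and the RyR variable use forward Euler. Intracellular
// calcium buffering uses the algebraic (quadratic) update of the original
// model code, which is stable at the 20 us step used here.
//
// State layout (column index) for "tt06", one row per node:
//  0 V (mV), 1 Ki, 2 Nai, 3 Cai, 4 CaSS, 5 CaSR (mM),
//  6 m, 7 h, 8 j, 9 xr1, 10 xr2, 11 xs, 12 r, 13 s,
//  14 d, 15 f, 16 f2, 17 fcass, 18 Rq
// For "ms": 0 V (mV), 1 h.
//
// External stimulus `iext` is positive-depolarizing in mV/ms (current per
// unit membrane capacitance with Cm = 1 uF/cm^2, i.e. uA/cm^2).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace tt06 {

const double Rgas = 8314.472, Temp = 310.0, Frdy = 96485.3415;
const double RTONF = Rgas * Temp / Frdy;          // 26.7137 mV
const double CAPACITANCE = 0.185;
const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
const double inverseVcF2 = 1.0 / (2.0 * Vc * Frdy);
const double inverseVcF = 1.0 / (Vc * Frdy);
const double inversevssF2 = 1.0 / (2.0 * Vss * Frdy);

const double Ko = 5.4, Cao = 2.0, Nao = 140.0;
const double Bufc = 0.2, Kbufc = 0.001;
const double Bufsr = 10.0, Kbufsr = 0.3;
const double Bufss = 0.4, Kbufss = 0.00025;
const double Vmaxup = 0.006375, Kup = 0.00025;
const double Vrel = 0.102, k1_ = 0.15, k2_ = 0.045, k3 = 0.060, k4 = 0.005;
const double EC = 1.5, maxsr = 2.5, minsr = 1.0;
const double Vleak = 0.00036, Vxfer = 0.0038;

const double Gkr = 0.153;
const double pKNa = 0.03;
const double Gks = 0.392;   // epicardial
const double GK1 = 5.405;
const double Gto = 0.294;   // epicardial
const double GNa = 14.838;
const double GbNa = 0.00029;
const double KmK = 1.0, KmNa = 40.0, knak = 2.724;
const double GCaL = 0.00003980;
const double GbCa = 0.000592;
const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1, nns = 0.35;
const double GpCa = 0.1238, KpCa = 0.0005;
const double GpK = 0.0146;

// One forward step for a single node; s points at the 19 state entries
// (strided by `str` between variables). iext positive-depolarizing, mV/ms.
inline void step_node(double* s, const int str, const double iext,
                      const double dt) {
  double V    = s[0];
  double Ki   = s[1 * str];
  double Nai  = s[2 * str];
  double Cai  = s[3 * str];
  double CaSS = s[4 * str];
  double CaSR = s[5 * str];
  double m = s[6 * str], h = s[7 * str], j = s[8 * str];
  double xr1 = s[9 * str], xr2 = s[10 * str], xs = s[11 * str];
  double r = s[12 * str], ss = s[13 * str];
  double d = s[14 * str], f = s[15 * str], f2 = s[16 * str];
  double fcass = s[17 * str], Rq = s[18 * str];

  const double Istim = -iext;   // model convention: negative = depolarizing

  const double Ek = RTONF * std::log(Ko / Ki);
  const double Ena = RTONF * std::log(Nao / Nai);
  const double Eks = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double Eca = 0.5 * RTONF * std::log(Cao / Cai);

  const double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
  const double Bk1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                      std::exp(0.1 * (V - Ek - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - Ek)));
  const double rec_iK1 = Ak1 / (Ak1 + Bk1);
  const double rec_iNaK =
      1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
             0.0353 * std::exp(-V / RTONF));
  const double rec_ipK = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));

  const double INa = GNa * m * m * m * h * j * (V - Ena);
  double Vm15 = V - 15.0;
  if (std::fabs(Vm15) < 1e-6) Vm15 = 1e-6;
  const double expf = std::exp(2.0 * Vm15 / RTONF);
  const double ICaL = GCaL * d * f * f2 * fcass * 4.0 * Vm15 *
                      (Frdy / RTONF) * (0.25 * expf * CaSS - Cao) /
                      (expf - 1.0);
  const double Ito = Gto * r * ss * (V - Ek);
  const double IKr = Gkr * std::sqrt(Ko / 5.4) * xr1 * xr2 * (V - Ek);
  const double IKs = Gks * xs * xs * (V - Eks);
  const double IK1 = GK1 * rec_iK1 * (V - Ek);
  const double INaCa =
      knaca * (1.0 / (KmNai * KmNai * KmNai + Nao * Nao * Nao)) *
      (1.0 / (KmCa + Cao)) *
      (1.0 / (1.0 + ksat * std::exp((nns - 1.0) * V / RTONF))) *
      (std::exp(nns * V / RTONF) * Nai * Nai * Nai * Cao -
       std::exp((nns - 1.0) * V / RTONF) * Nao * Nao * Nao * Cai * 2.5);
  const double INaK = knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) * rec_iNaK;
  const double IpCa = GpCa * Cai / (KpCa + Cai);
  const double IpK = GpK * rec_ipK * (V - Ek);
  const double IbNa = GbNa * (V - Ena);
  const double IbCa = GbCa * (V - Eca);

  const double sItot = IKr + IKs + IK1 + Ito + INa + IbNa + ICaL + IbCa +
                       INaK + INaCa + IpCa + IpK + Istim;

  // Calcium dynamics
  const double kCaSR =
      maxsr - ((maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR)));
  const double k1 = k1_ / kCaSR;
  const double k2 = k2_ * kCaSR;
  Rq += dt * (k4 * (1.0 - Rq) - k2 * CaSS * Rq);
  const double sOO = k1 * CaSS * CaSS * Rq / (k3 + k1 * CaSS * CaSS);
  const double Irel = Vrel * sOO * (CaSR - CaSS);
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  const double Ixfer = Vxfer * (CaSS - Cai);

  {
    const double CaCSQN = Bufsr * CaSR / (CaSR + Kbufsr);
    const double dCaSR = dt * (Iup - Irel - Ileak);
    const double bjsr = Bufsr - CaCSQN - dCaSR - CaSR + Kbufsr;
    const double cjsr = Kbufsr * (CaCSQN + dCaSR + CaSR);
    CaSR = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;
  }
  {
    const double CaSSBuf = Bufss * CaSS / (CaSS + Kbufss);
    const double dCaSS =
        dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) +
              (-ICaL * inversevssF2 * CAPACITANCE));
    const double bcss = Bufss - CaSSBuf - dCaSS - CaSS + Kbufss;
    const double ccss = Kbufss * (CaSSBuf + dCaSS + CaSS);
    CaSS = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;
  }
  {
    const double CaBuf = Bufc * Cai / (Cai + Kbufc);
    const double dCai =
        dt * ((-(IbCa + IpCa - 2.0 * INaCa) * inverseVcF2 * CAPACITANCE) -
              (Iup - Ileak) * (Vsr / Vc) + Ixfer);
    const double bc = Bufc - CaBuf - dCai - Cai + Kbufc;
    const double cc = Kbufc * (CaBuf + dCai + Cai);
    Cai = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;
  }
  Nai += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * inverseVcF *
               CAPACITANCE);
  Ki += dt * (-(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK + Istim) *
              inverseVcF * CAPACITANCE);

  // Gate rates (Rush-Larsen)
  const double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  const double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                    0.10 / (1.0 + std::exp((V - 50.0) / 200.0));
  const double taum = am * bm;
  const double minf =
      1.0 / ((1.0 + std::exp((-56.86 - V) / 9.03)) *
             (1.0 + std::exp((-56.86 - V) / 9.03)));
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    aj = (-2.5428e4 * std::exp(0.2444 * V) -
          6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  const double tauh = 1.0 / (ah + bh);
  const double hinf = 1.0 / ((1.0 + std::exp((V + 71.55) / 7.43)) *
                             (1.0 + std::exp((V + 71.55) / 7.43)));
  const double tauj = 1.0 / (aj + bj);
  const double jinf = hinf;

  const double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  const double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  const double tauxr1 = axr1 * bxr1;
  const double xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  const double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  const double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  const double tauxr2 = axr2 * bxr2;
  const double xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  const double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  const double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  const double tauxs = axs * bxs + 80.0;
  const double xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  const double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  const double taur =
      9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  // epicardial s gate
  const double sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
  const double taus = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
                      5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  const double dinf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  const double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  const double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  const double cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  const double taud = ad * bd + cd;
  const double finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  const double tauf = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                      200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                      180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  const double f2inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  const double tauf2 = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
                       31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                       80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  const double fcassinf = 0.6 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 0.4;
  const double taufcass = 80.0 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 2.0;

  m = minf - (minf - m) * std::exp(-dt / taum);
  h = hinf - (hinf - h) * std::exp(-dt / tauh);
  j = jinf - (jinf - j) * std::exp(-dt / tauj);
  xr1 = xr1inf - (xr1inf - xr1) * std::exp(-dt / tauxr1);
  xr2 = xr2inf - (xr2inf - xr2) * std::exp(-dt / tauxr2);
  xs = xsinf - (xsinf - xs) * std::exp(-dt / tauxs);
  r = rinf - (rinf - r) * std::exp(-dt / taur);
  ss = sinf - (sinf - ss) * std::exp(-dt / taus);
  d = dinf - (dinf - d) * std::exp(-dt / taud);
  f = finf - (finf - f) * std::exp(-dt / tauf);
  f2 = f2inf - (f2inf - f2) * std::exp(-dt / tauf2);
  fcass = fcassinf - (fcassinf - fcass) * std::exp(-dt / taufcass);

  V -= dt * sItot;

  s[0] = V;
  s[1 * str] = Ki;
  s[2 * str] = Nai;
  s[3 * str] = Cai;
  s[4 * str] = CaSS;
  s[5 * str] = CaSR;
  s[6 * str] = m; s[7 * str] = h; s[8 * str] = j;
  s[9 * str] = xr1; s[10 * str] = xr2; s[11 * str] = xs;
  s[12 * str] = r; s[13 * str] = ss;
  s[14 * str] = d; s[15 * str] = f; s[16 * str] = f2;
  s[17 * str] = fcass; s[18 * str] = Rq;
}

}  // namespace tt06

namespace msr {
// Mitchell-Schaeffer two-variable model, affinely mapped to mV:
// u = (V + 85)/100 so that rest is -85 mV and full excitation ~ +15 mV.
const double tau_in = 0.3, tau_out = 6.0;
const double tau_open = 120.0, tau_close = 120.0;
const double v_gate = 0.13;
const double v_rest = -85.0, v_amp = 100.0;

inline void step_node(double* s, const int str, const double iext,
                      const double dt) {
  double u = (s[0] - v_rest) / v_amp;
  double h = s[1 * str];
  const double du =
      h * u * u * (1.0 - u) / tau_in - u / tau_out + iext / v_amp;
  const double dh = (u < v_gate) ? (1.0 - h) / tau_open : -h / tau_close;
  u += dt * du;
  h += dt * dh;
  if (h < 0.0) h = 0.0;
  if (h > 1.0) h = 1.0;
  s[0] = v_rest + v_amp * u;
  s[1 * str] = h;
}
}  // namespace msr

static int model_id(const std::string& model) {
  if (model == "tt06") return 0;
  if (model == "ms") return 1;
  stop("unknown ionic model '%s'", model.c_str());
  return -1;
}

// [[Rcpp::export(name = ".ionic_published_state")]]
NumericVector ionic_published_state(std::string model) {
  if (model_id(model) == 0) {
    NumericVector s = NumericVector::create(
        _["V"] = -85.23, _["Ki"] = 136.89, _["Nai"] = 8.604,
        _["Cai"] = 0.000126, _["CaSS"] = 0.00036, _["CaSR"] = 3.64,
        _["m"] = 0.00172, _["h"] = 0.7444, _["j"] = 0.7045,
        _["xr1"] = 0.00621, _["xr2"] = 0.4712, _["xs"] = 0.0095,
        _["r"] = 2.42e-8, _["s"] = 0.999998, _["d"] = 3.373e-5,
        _["f"] = 0.7888, _["f2"] = 0.9755, _["fcass"] = 0.9953,
        _["Rq"] = 0.9073);
    return s;
  }
  return NumericVector::create(_["V"] = msr::v_rest, _["h"] = 1.0);
}

// Advance all rows of the state matrix by `nsteps` steps of size dt (ms),
// modifying `state` in place. `iext` is per node, recycled if scalar.
// [[Rcpp::export(name = ".ionic_step_inplace")]]
void ionic_step_inplace(NumericMatrix state, std::string model,
                        NumericVector iext, double dt, int nsteps) {
  const int id = model_id(model);
  const int n = state.nrow();
  const bool scalar = (iext.size() == 1);
  if (!scalar && iext.size() != n)
    stop("iext must have length 1 or nrow(state)");
  double* base = REAL(state);
  for (int it = 0; it < nsteps; ++it) {
    for (int i = 0; i < n; ++i) {
      const double ie = scalar ? iext[0] : iext[i];
      if (id == 0)
        tt06::step_node(base + i, n, ie, dt);
      else
        msr::step_node(base + i, n, ie, dt);
    }
  }
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(base[i]))
      stop("ionic model state became non-finite (node %d)", i + 1);
  }
}

// Single-cell run with a train of identical stimuli; the whole loop stays
// in C++. Returns the membrane potential sampled every `sample_dt` ms and
// the final state.
// [[Rcpp::export(name = ".cell_run")]]
List cell_run(std::string model, NumericVector state0,
              NumericVector stim_onsets, double stim_dur, double stim_amp,
              double duration, double dt, double sample_dt) {
  const int id = model_id(model);
  const int ns = state0.size();
  std::vector<double> s(state0.begin(), state0.end());
  const int nsteps = (int)std::llround(duration / dt);
  const int every = std::max(1, (int)std::llround(sample_dt / dt));
  std::vector<double> tout, vout;
  tout.reserve(nsteps / every + 2);
  vout.reserve(nsteps / every + 2);
  tout.push_back(0.0);
  vout.push_back(s[0]);
  for (int it = 0; it < nsteps; ++it) {
    const double t = it * dt;
    double ie = 0.0;
    for (int k = 0; k < stim_onsets.size(); ++k) {
      if (t >= stim_onsets[k] && t < stim_onsets[k] + stim_dur) {
        ie = stim_amp;
        break;
      }
    }
    if (id == 0)
      tt06::step_node(s.data(), 1, ie, dt);
    else
      msr::step_node(s.data(), 1, ie, dt);
    if ((it + 1) % every == 0) {
      tout.push_back((it + 1) * dt);
      vout.push_back(s[0]);
    }
  }
  NumericVector fin(s.begin(), s.end());
  fin.names() = state0.names();
  return List::create(_["time"] = wrap(tout), _["vm"] = wrap(vout),
                      _["state"] = fin);
}
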