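// 0D cellular electromechanics: integrate the Land-type active model and the
// three-element passive element under the stress-equilibrium constraint
//   Sa(Ca, lambda, dlambda/dt, t) + Sp(lambda, t) = 0,
// solving for the stretch trajectory lambda(t). Stabilised staggered scheme:
// the slow states (crossbridge fractions, troponin, tropomyosin, passive
// internal strain) advance by RK4 with the stretch and its rate frozen at
// the previous step, while the fast distortion states, which carry the
// velocity dependence of active stress, are advanced by implicit Euler AS
// FUNCTIONS OF THE NEW STRETCH inside the per-step equilibrium solve. The
// distortion kinetics then act as physical viscosity on the equilibrium,
// which keeps the massless force balance well posed where the tension
// crosses zero. Safeguarded Newton with bisection fallback; residual
// tolerance 1e-6 kPa. This compiled core exists because the cell-scale
// calibration and the sensitivity analysis evaluate it tens of thousands of
// times; an independent pure-R integrator cross-checks it in the tests.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct LandPar {
  double Tref, Ca50_ref, nTRPN, kTRPN, nTm, kUW, kWS, beta0, beta1,
      TRPN50, ku, rw, rs, TotA, gammaW, gammaS, phi;
  double kwu, ksu, Aw, As, cw, cs, kb;
  void derive() {
    kwu = kUW * (1.0 / rw - 1.0) - kWS;
    ksu = kWS * rw * (1.0 / rs - 1.0);
    Aw = TotA * rs / ((1.0 - rs) * rw + rs);
    As = Aw;
    cw = phi * kUW * ((1.0 - rs) * (1.0 - rw)) / ((1.0 - rs) * rw);
    cs = phi * kWS * ((1.0 - rs) * rw) / rs;
    kb = ku * std::pow(TRPN50, nTm) / (1.0 - rs - (1.0 - rs) * rw);
  }
};

struct PassPar { double a_p, b, k, eta_l, eta_s; };

// slow-state layout: 0 XS, 1 XW, 2 CaTRPN, 3 TmB, 4 Cd
static const int NSLOW = 5;

static inline double hfac(double lam, const LandPar &p) {
  double ls = lam < 1.2 ? lam : 1.2;
  double h = 1.0 + p.beta0 * (ls + (ls < 0.87 ? ls : 0.87) - 1.87);
  return h > 0.0 ? h : 0.0;
}

static inline double passive_stress(double cd, double lam,
                                    const PassPar &pp) {
  double C = lam - 1.0;
  return pp.a_p * (std::expm1(pp.b * C) + pp.k * (C - cd));
}

// RHS of the slow states at frozen lambda / distortions
static void rhs_slow(const double *s, double zs, double zw, double ca,
                     double lam, const LandPar &p, const PassPar &pp,
                     double *ds) {
  double ls = lam < 1.2 ? lam : 1.2;
  double ca50 = p.Ca50_ref * (1.0 + p.beta1 * (ls - 1.0));
  if (ca50 < 1e-6) ca50 = 1e-6;
  double XS = s[0], XW = s[1];
  double catrpn = s[2] > 1e-8 ? s[2] : 1e-8;
  double tmb = s[3];
  double XU = 1.0 - tmb - XS - XW;
  double gwu = p.gammaW * std::fabs(zw);
  double gsu = p.gammaS * (zs > 0.0 ? zs : (zs < -1.0 ? -zs - 1.0 : 0.0));
  ds[0] = p.kWS * XW - p.ksu * XS - gsu * XS;
  ds[1] = p.kUW * XU - p.kwu * XW - p.kWS * XW - gwu * XW;
  ds[2] = p.kTRPN * (std::pow(ca / ca50, p.nTRPN) * (1.0 - catrpn) - catrpn);
  double inv = std::pow(catrpn, -p.nTm / 2.0);
  if (inv > 100.0) inv = 100.0;
  ds[3] = p.kb * inv * XU - p.ku * std::pow(catrpn, p.nTm / 2.0) * tmb;
  double C = lam - 1.0;
  double eta = (C - s[4] < 0.0) ? pp.eta_l : pp.eta_s;
  ds[4] = pp.k * (C - s[4]) / eta;
}

struct CaInput {
  bool use_trace;
  double Ca_res, Ca_max, tauCR, tauCD, gpk_inv, tpk_equal;
  const double *tr; int ntr; double tr_dt, tr_t0;
  double eval(double ts) const {
    if (use_trace) {
      double u = (ts - tr_t0) / tr_dt;
      if (u <= 0.0) return tr[0];
      if (u >= ntr - 1) return tr[ntr - 1];
      int k = (int)u;
      double f = u - k;
      return tr[k] * (1.0 - f) + tr[k + 1] * f;
    }
    if (ts <= 0.0) return Ca_res;
    double g;
    if (tpk_equal > 0.0) {
      g = ts / tauCR * std::exp(1.0 - ts / tauCR);
    } else {
      g = std::fabs(std::exp(-ts / tauCD) - std::exp(-ts / tauCR)) * gpk_inv;
    }
    return Ca_res + (Ca_max - Ca_res) * g;
  }
};

static void rk4_slow(double *s, double zs, double zw, double t, double dt,
                     double lam, const CaInput &ca, const LandPar &p,
                     const PassPar &pp) {
  double k1[NSLOW], k2[NSLOW], k3[NSLOW], k4[NSLOW], tmp[NSLOW];
  double c0 = ca.eval(t), ch = ca.eval(t + 0.5 * dt), c1 = ca.eval(t + dt);
  rhs_slow(s, zs, zw, c0, lam, p, pp, k1);
  for (int i = 0; i < NSLOW; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  rhs_slow(tmp, zs, zw, ch, lam, p, pp, k2);
  for (int i = 0; i < NSLOW; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  rhs_slow(tmp, zs, zw, ch, lam, p, pp, k3);
  for (int i = 0; i < NSLOW; ++i) tmp[i] = s[i] + dt * k3[i];
  rhs_slow(tmp, zs, zw, c1, lam, p, pp, k4);
  for (int i = 0; i < NSLOW; ++i)
    s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// active stress with distortions implicit in the stretch increment
struct EqSolve {
  const double *s;         // slow states after RK4
  double zs0, zw0;         // distortions at step start
  double lam0;             // stretch at step start
  double dt;
  const LandPar *p;
  const PassPar *pp;
  double zs_of(double lam) const {
    return (zs0 + p->As * (lam - lam0)) / (1.0 + p->cs * dt);
  }
  double zw_of(double lam) const {
    return (zw0 + p->Aw * (lam - lam0)) / (1.0 + p->cw * dt);
  }
  double sa(double lam) const {
    return hfac(lam, *p) * p->Tref / p->rs *
        (s[0] * (zs_of(lam) + 1.0) + s[1] * zw_of(lam));
  }
  double f(double lam) const {
    return sa(lam) + passive_stress(s[4], lam, *pp);
  }
  double fprime(double lam) const {
    double dfp = pp->a_p * (pp->b * std::exp(pp->b * (lam - 1.0)) + pp->k);
    double h = hfac(lam, *p);
    double dvisc = h * p->Tref / p->rs *
        (s[0] * p->As / (1.0 + p->cs * dt) +
         s[1] * p->Aw / (1.0 + p->cw * dt));
    double dh = 0.0;
    if (lam < 1.2) {
      double ls = lam;
      double hraw = 1.0 + p->beta0 * (ls + (ls < 0.87 ? ls : 0.87) - 1.87);
      if (hraw > 0.0) dh = p->beta0 * (ls < 0.87 ? 2.0 : 1.0);
    }
    double bracket = p->Tref / p->rs *
        (s[0] * (zs_of(lam) + 1.0) + s[1] * zw_of(lam));
    return dfp + dvisc + dh * bracket;
  }
};

static bool solve_lambda(const EqSolve &eq, double lam_guess, double tol,
                         double &lam_out, double &res_out) {
  double lo = 0.3, hi = 1.8;
  double flo = eq.f(lo), fhi = eq.f(hi);
  if (!(flo <= 0.0 && fhi >= 0.0)) return false;
  double lam = lam_guess;
  if (lam < lo || lam > hi) lam = 0.5 * (lo + hi);
  for (int it = 0; it < 100; ++it) {
    double fv = eq.f(lam);
    if (std::fabs(fv) < tol) { lam_out = lam; res_out = std::fabs(fv); return true; }
    if (fv > 0.0) hi = lam; else lo = lam;
    double df = eq.fprime(lam);
    double cand = (df > 0.0) ? lam - fv / df : 0.5 * (lo + hi);
    if (!(cand > lo && cand < hi)) cand = 0.5 * (lo + hi);
    lam = cand;
  }
  double fv = eq.f(lam);
  lam_out = lam; res_out = std::fabs(fv);
  return std::fabs(fv) < 100.0 * tol;
}

// [[Rcpp::export(name = ".zerod_simulate_cpp")]]
List zerod_simulate_cpp(NumericVector land, NumericVector rice,
                        NumericVector passive, NumericVector state0,
                        double lam0, double cycle_ms, double dt,
                        int max_beats, double beat_tol, double newton_tol,
                        NumericVector ca_trace, double ca_dt, double ca_t0) {
  LandPar p;
  p.Tref = land["Tref"]; p.Ca50_ref = land["Ca50_ref"];
  p.nTRPN = land["nTRPN"]; p.kTRPN = land["kTRPN"]; p.nTm = land["nTm"];
  p.kUW = land["kUW"]; p.kWS = land["kWS"]; p.beta0 = land["beta0"];
  p.beta1 = land["beta1"]; p.TRPN50 = land["TRPN50"]; p.ku = land["ku"];
  p.rw = land["rw"]; p.rs = land["rs"]; p.TotA = land["TotA"];
  p.gammaW = land["gammaW"]; p.gammaS = land["gammaS"]; p.phi = land["phi"];
  p.derive();
  PassPar pp;
  pp.a_p = passive["a_p"]; pp.b = passive["b"]; pp.k = passive["k"];
  pp.eta_l = passive["eta_l"]; pp.eta_s = passive["eta_s"];

  CaInput ca;
  ca.use_trace = ca_trace.size() > 0;
  if (ca.use_trace) {
    ca.tr = ca_trace.begin(); ca.ntr = ca_trace.size();
    ca.tr_dt = ca_dt; ca.tr_t0 = ca_t0;
  } else {
    ca.Ca_res = rice["Ca_res"]; ca.Ca_max = rice["Ca_max"];
    ca.tauCR = rice["tauCR"]; ca.tauCD = rice["tauCD"];
    double t1 = ca.tauCD, t2 = ca.tauCR;
    if (std::fabs(t1 - t2) < 1e-9 * std::max(t1, t2)) {
      ca.tpk_equal = 1.0;
    } else {
      ca.tpk_equal = -1.0;
      double tpk = std::log(t1 / t2) * t1 * t2 / (t1 - t2);
      ca.gpk_inv = 1.0 /
          std::fabs(std::exp(-tpk / t1) - std::exp(-tpk / t2));
    }
  }

  int nstep = (int)std::lround(cycle_ms / dt);
  NumericVector lam_tr(nstep + 1), dlam_tr(nstep + 1), sa_tr(nstep + 1),
      ca_tr(nstep + 1);
  // state0 order: XS, XW, CaTRPN, TmB, ZetaS, ZetaW, Cd
  double s[NSLOW];
  s[0] = state0[0]; s[1] = state0[1]; s[2] = state0[2]; s[3] = state0[3];
  s[4] = state0[6];
  double zs = state0[4], zw = state0[5];
  double lam = lam0, dlam = 0.0;
  double residual_max = 0.0;
  int beats = 0;
  bool converged = false;

  for (int b = 0; b < max_beats; ++b) {
    double start[NSLOW + 3];
    for (int i = 0; i < NSLOW; ++i) start[i] = s[i];
    start[NSLOW] = zs; start[NSLOW + 1] = zw; start[NSLOW + 2] = lam;
    residual_max = 0.0;
    EqSolve eq0{s, zs, zw, lam, dt, &p, &pp};
    lam_tr[0] = lam; dlam_tr[0] = dlam;
    sa_tr[0] = eq0.sa(lam);
    ca_tr[0] = ca.eval(0.0);
    for (int k = 0; k < nstep; ++k) {
      double t = k * dt;
      rk4_slow(s, zs, zw, t, dt, lam, ca, p, pp);
      for (int i = 0; i < NSLOW; ++i)
        if (!std::isfinite(s[i])) stop("non-finite cell state at t = %f", t + dt);
      EqSolve eq{s, zs, zw, lam, dt, &p, &pp};
      double lam_new, res;
      if (!solve_lambda(eq, lam, newton_tol, lam_new, res))
        stop("stretch equilibrium solve failed at t = %f", t + dt);
      zs = eq.zs_of(lam_new);
      zw = eq.zw_of(lam_new);
      dlam = (lam_new - lam) / dt;
      lam = lam_new;
      if (res > residual_max) residual_max = res;
      lam_tr[k + 1] = lam; dlam_tr[k + 1] = dlam;
      sa_tr[k + 1] = eq.sa(lam);
      ca_tr[k + 1] = ca.eval(t + dt);
    }
    beats = b + 1;
    double diff = std::fabs(lam - start[NSLOW + 2]);
    double dz = std::fabs(zs - start[NSLOW]);
    if (dz > diff) diff = dz;
    dz = std::fabs(zw - start[NSLOW + 1]);
    if (dz > diff) diff = dz;
    for (int i = 0; i < NSLOW; ++i) {
      double d = std::fabs(s[i] - start[i]);
      if (d > diff) diff = d;
    }
    if (diff < beat_tol) { converged = true; break; }
  }

  NumericVector state_end = NumericVector::create(
      _["XS"] = s[0], _["XW"] = s[1], _["CaTRPN"] = s[2], _["TmB"] = s[3],
      _["ZetaS"] = zs, _["ZetaW"] = zw, _["Cd"] = s[4]);
  return List::create(_["lam"] = lam_tr, _["dlam_dt"] = dlam_tr,
                      _["sa"] = sa_tr, _["ca"] = ca_tr,
                      _["residual_max"] = residual_max,
                      _["n_beats"] = beats, _["converged"] = converged,
                      _["state_end"] = state_end);
}
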