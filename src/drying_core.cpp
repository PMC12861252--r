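// Finite-volume core for the multiphase mushroom drying model.
//
// Linearized backward-Euler (semi-implicit) flux-form integration of the
// coupled moisture / energy balances on a shrinking 1-D hemispherical grid
// (lamella region innermost), with the two-phase Flory-Huggins water
// activity, Maxwell viscoelastic state and the empirical shrinkage law
// evaluated per control volume.  The stiff modes (pore-vapor equilibration,
// dry-crust conduction, latent coupling) go through a 2x2 block-tridiagonal
// implicit solve; the update is applied in flux form from the linearized
// end-of-step state, so discrete conservation is exact to round-off.  Step
// size is governed by a local change-based error controller.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Phase {
  double v_dry;  // dry volume per kg total dry matter, m^3
  double S1;     // sum (1 - 1/N_i) v_i
  double S2;     // sum chi_i v_i
};

struct Pars {
  Phase p1, p2;
  double rho_water, v_w, elastic_sign;
  double G_a[2], G_b[2], tau_a[2], tau_b[2], Ea_tau, T_ref_ve, F_G[2], F_tau[2];
  double exp_a, exp_b, exp_c, lin_m, lin_k, X_star;
  bool blend;
  double rho_solid, rho_w_st;
  double F_w_diff, F_w_conv, emissivity, sigma_SB, M_v, Rgas;
  double c_p_s, c_p_w, c_p_v, c_p_air, rho_air, h_evap;
  double lambda_s, lambda_w, lambda_air, P_atm;
  double D_dil, Ea_D, T_ref_D, A_fv, B_fv, solute_ratio, M_dm;
  double safety, dt_max, dt_min, T0, tgt_dm, tgt_dT;
};

static Phase make_phase(const List& comps, int want_phase) {
  NumericVector mass = comps["mass_dm"], dens = comps["density"],
                Ninv = comps["N_inv"], chi = comps["chi"];
  IntegerVector ph = comps["phase"];
  Phase out{0, 0, 0};
  for (int i = 0; i < mass.size(); ++i) {
    if (ph[i] != want_phase) continue;
    double v = mass[i] / dens[i];
    out.v_dry += v;
    out.S1 += (1.0 - Ninv[i]) * v;
    out.S2 += chi[i] * v;
  }
  return out;
}

static Pars make_pars(const List& cfg) {
  Pars P;
  List comp = cfg["composition"], ve = cfg["viscoelastic"],
       st = cfg["structure"], tr = cfg["transport"], so = cfg["solver"];
  List comps = comp["components"];
  P.p1 = make_phase(comps, 1);
  P.p2 = make_phase(comps, 2);
  P.rho_water = as<double>(comp["rho_water"]);
  P.v_w = as<double>(comp["v_w"]);
  P.elastic_sign = as<double>(comp["elastic_sign"]);
  NumericVector Ga = ve["G_a"], Gb = ve["G_b"], ta = ve["tau_a"],
                tb = ve["tau_b"], FG = ve["F_G"], Ft = ve["F_tau"];
  for (int i = 0; i < 2; ++i) {
    P.G_a[i] = Ga[i]; P.G_b[i] = Gb[i];
    P.tau_a[i] = ta[i]; P.tau_b[i] = tb[i];
    P.F_G[i] = FG[i]; P.F_tau[i] = Ft[i];
  }
  P.Ea_tau = as<double>(ve["Ea_tau"]); P.T_ref_ve = as<double>(ve["T_ref"]);
  P.exp_a = as<double>(st["exp_a"]); P.exp_b = as<double>(st["exp_b"]);
  P.exp_c = as<double>(st["exp_c"]); P.lin_m = as<double>(st["lin_m"]);
  P.lin_k = as<double>(st["lin_k"]); P.X_star = as<double>(st["X_star"]);
  P.blend = as<bool>(st["blend"]);
  P.rho_solid = as<double>(st["rho_solid"]);
  P.rho_w_st = as<double>(st["rho_water"]);
  P.F_w_diff = as<double>(tr["F_w_diff"]); P.F_w_conv = as<double>(tr["F_w_conv"]);
  P.emissivity = as<double>(tr["emissivity"]); P.sigma_SB = as<double>(tr["sigma_SB"]);
  P.M_v = as<double>(tr["M_v"]); P.Rgas = as<double>(tr["R"]);
  P.c_p_s = as<double>(tr["c_p_s"]); P.c_p_w = as<double>(tr["c_p_w"]);
  P.c_p_v = as<double>(tr["c_p_v"]); P.c_p_air = as<double>(tr["c_p_air"]);
  P.rho_air = as<double>(tr["rho_air"]); P.h_evap = as<double>(tr["h_evap"]);
  P.lambda_s = as<double>(tr["lambda_s"]); P.lambda_w = as<double>(tr["lambda_w"]);
  P.lambda_air = as<double>(tr["lambda_air"]); P.P_atm = as<double>(tr["P_atm"]);
  List dp = tr["diffusivity"];
  P.D_dil = as<double>(dp["D_dil"]); P.Ea_D = as<double>(dp["Ea"]);
  P.T_ref_D = as<double>(dp["T_ref"]); P.A_fv = as<double>(dp["A_fv"]);
  P.B_fv = as<double>(dp["B_fv"]); P.solute_ratio = as<double>(dp["solute_ratio"]);
  P.M_dm = as<double>(dp["M_dm"]);
  P.safety = as<double>(so["safety"]); P.dt_max = as<double>(so["dt_max"]);
  P.dt_min = as<double>(so["dt_min"]); P.T0 = as<double>(so["T0"]);
  P.tgt_dm = as<double>(so["target_dm_rel"]); P.tgt_dT = as<double>(so["target_dT"]);
  return P;
}

static inline double psat(double T) {
  double TC = T - 273.15;
  return 133.322 * std::pow(10.0, 8.07131 - 1730.63 / (233.426 + TC));
}
static inline double dlnpsat_dT(double T) {
  double TC = T - 273.15, den = 233.426 + TC;
  return std::log(10.0) * 1730.63 / (den * den);
}
static inline double csat(const Pars& P, double T) {
  return P.M_v * psat(T) / (P.Rgas * T);
}

// ln a_w of one phase holding water mass w (per kg dry matter) and its
// derivative wrt w
static inline void ln_aw_phase(const Phase& ph, double w, double rho_w,
                               double& l, double& dldw) {
  double vw = w / rho_w, tot = ph.v_dry + vw, phiw = vw / tot;
  l = std::log(phiw) + ph.S1 / tot + ph.S2 * (1.0 - phiw) / tot;
  dldw = (1.0 / rho_w) * (ph.v_dry / (phiw * tot * tot)
                          - ph.S1 / (tot * tot)
                          - 2.0 * ph.S2 * ph.v_dry / (tot * tot * tot));
}

// equal-activity split: fraction of W assigned to phase 1, Newton with
// bisection fallback; vwp2RT = v_w * p2 / (R T) applied to phase 2
static double partition_f(const Pars& P, double W, double vwp2RT, double f0) {
  double f = (f0 > 1e-10 && f0 < 1 - 1e-10) ? f0 : 0.5;
  for (int it = 0; it < 40; ++it) {
    double l1, d1, l2, d2;
    ln_aw_phase(P.p1, f * W, P.rho_water, l1, d1);
    ln_aw_phase(P.p2, (1 - f) * W, P.rho_water, l2, d2);
    double g = l1 - l2 - vwp2RT;
    if (std::fabs(g) < 1e-12) return f;
    double dg = W * (d1 + d2);
    double fn = f - g / dg;
    if (!(fn > 1e-12 && fn < 1 - 1e-12) || !std::isfinite(fn)) break;
    f = fn;
  }
  double lo = 1e-12, hi = 1 - 1e-12;
  for (int it = 0; it < 90; ++it) {
    double mid = 0.5 * (lo + hi), l1, d1, l2, d2;
    ln_aw_phase(P.p1, mid * W, P.rho_water, l1, d1);
    ln_aw_phase(P.p2, (1 - mid) * W, P.rho_water, l2, d2);
    if (l1 - l2 - vwp2RT > 0) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}

static inline double phis2_of(const Pars& P, double w2) {
  return P.p2.v_dry / (P.p2.v_dry + w2 / P.rho_water);
}

// stress of the dual-mode Maxwell matrix; optionally also relaxation times
static double ve_stress(const Pars& P, double phis, const double* phiref,
                        double X, double T, double* tau_out) {
  double arr = std::exp(P.Ea_tau / 8.314 * (1.0 / T - 1.0 / P.T_ref_ve));
  double s = 0;
  for (int i = 0; i < 2; ++i) {
    double G = P.F_G[i] * std::pow(10.0, P.G_a[i] - P.G_b[i] * X);
    double pt = phis / phiref[i];
    s += G * (std::cbrt(pt) - pt);
    if (tau_out)
      tau_out[i] = P.F_tau[i] * std::pow(10.0, P.tau_a[i] - P.tau_b[i] * X) * arr;
  }
  return s;
}

// tissue water activity at fixed (lagged) phase-2 pressure term p2
static inline double aw_tissue(const Pars& P, double X, double T, double p2,
                               double& f) {
  double vwp = P.v_w * p2 / (P.Rgas * T);
  f = partition_f(P, X, vwp, f);
  double l1, d1;
  ln_aw_phase(P.p1, f * X, P.rho_water, l1, d1);
  return std::exp(l1);
}

// self-consistent tissue equilibrium (elastic loop); phiref == NULL means
// fully relaxed (no elastic term)
static double aw_equil(const Pars& P, double X, double T, const double* phiref,
                       double& f, double& phis, double& sig) {
  double p2 = 0, aw = 0;
  if (!phiref) {  // relaxed matrix: no elastic term, single solve
    aw = aw_tissue(P, X, T, 0.0, f);
    phis = phis2_of(P, (1 - f) * X);
    sig = 0.0;
    return aw;
  }
  // damped fixed point on the phase-2 pressure term; a shift of 1e2 Pa
  // moves ln a_w by ~1e-6, so the relative tolerance below is ample
  for (int it = 0; it < 60; ++it) {
    aw = aw_tissue(P, X, T, p2, f);
    phis = phis2_of(P, (1 - f) * X);
    sig = ve_stress(P, phis, phiref, X, T, nullptr);
    double p2n = P.elastic_sign * sig;
    if (std::fabs(p2n - p2) < 1e-4 * (1.0 + std::fabs(p2n))) {
      p2 = p2n;
      break;
    }
    p2 = 0.5 * p2 + 0.5 * p2n;
  }
  aw = aw_tissue(P, X, T, p2, f);
  phis = phis2_of(P, (1 - f) * X);
  sig = ve_stress(P, phis, phiref, X, T, nullptr);
  return aw;
}

static inline double gas_solid(const Pars& P, double X) {
  double lo = P.exp_a * std::exp(-P.exp_b * X) + P.exp_c;
  double hi = P.lin_m * X + P.lin_k;
  if (P.blend) {
    double w = std::min(1.0, std::max(0.0, (X - 0.90) / 0.10));
    return (1 - w) * lo + w * hi;
  }
  return X < P.X_star ? lo : hi;
}

static double Dw_mutual(const Pars& P, double X, double T, double Gamma) {
  double phidm = (1.0 / P.rho_solid) / (1.0 / P.rho_solid + X / P.rho_w_st);
  double Dw = P.D_dil * std::exp(-P.Ea_D / 8.314 * (1.0 / T - 1.0 / P.T_ref_D))
              * std::pow(10.0, -P.A_fv * phidm / (1.0 - P.B_fv * phidm));
  double Ds = P.solute_ratio * Dw;
  double nw = X / P.M_v, ns = 1.0 / P.M_dm, xw = nw / (nw + ns);
  return P.F_w_diff * (xw * Ds + (1 - xw) * Dw) * Gamma;
}

// d ln a_w / d ln phi_w on the relaxed isotherm (thermodynamic factor)
static double Gamma_relaxed(const Pars& P, double X, double T, double& fwarm) {
  double h = 1e-3 * X, f = fwarm;
  double dum_phis, dum_sig;
  double a1 = aw_equil(P, X - h, T, nullptr, f, dum_phis, dum_sig);
  double a2 = aw_equil(P, X + h, T, nullptr, f, dum_phis, dum_sig);
  fwarm = f;
  double vw = X / P.rho_w_st, vs = 1.0 / P.rho_solid;
  double dlnphiw_dX = (1.0 / X) * vs / (vw + vs);
  double G = (std::log(a2) - std::log(a1)) / (2.0 * h * dlnphiw_dX);
  return std::max(G, 1e-3);
}

// piecewise-linear interpolation of the ambient schedule
struct Ambient {
  std::vector<double> t, Tair, RH, u;
  void at(double tt, double& Ta, double& rh, double& uu) const {
    size_t n = t.size();
    if (tt <= t[0]) { Ta = Tair[0]; rh = RH[0]; uu = u[0]; return; }
    if (tt >= t[n - 1]) { Ta = Tair[n - 1]; rh = RH[n - 1]; uu = u[n - 1]; return; }
    size_t i = 1;
    while (i < n && t[i] < tt) ++i;
    double w = (tt - t[i - 1]) / (t[i] - t[i - 1]);
    Ta = Tair[i - 1] + w * (Tair[i] - Tair[i - 1]);
    rh = RH[i - 1] + w * (RH[i] - RH[i - 1]);
    uu = u[i - 1] + w * (u[i] - u[i - 1]);
  }
};

// [[Rcpp::export]]
List cpp_simulate(List cfg, List grid, List ambient, List control) {
  Pars P = make_pars(cfg);
  NumericVector ms_in = grid["m_s"];
  LogicalVector lam_in = grid["is_lamella"];
  double a_gap = as<double>(grid["a_gap"]);
  double phi_hyp = as<double>(grid["phi_hypha_lam"]);
  int N = ms_in.size();

  Ambient amb;
  {
    NumericVector t = ambient["t_s"], Ta = ambient["T_air_K"],
                  rh = ambient["RH"], u = ambient["u_air"];
    amb.t.assign(t.begin(), t.end());
    amb.Tair.assign(Ta.begin(), Ta.end());
    amb.RH.assign(rh.begin(), rh.end());
    amb.u.assign(u.begin(), u.end());
  }

  double t_end = as<double>(control["t_end_s"]);
  double save_dt = as<double>(control["save_dt_s"]);
  bool closed_box = as<bool>(control["closed_box"]);
  NumericVector prof_times = control["profile_times_s"];
  long max_steps = (long)as<double>(control["max_steps"]);

  std::vector<double> ms(ms_in.begin(), ms_in.end());
  std::vector<bool> lam(N);
  for (int i = 0; i < N; ++i) lam[i] = lam_in[i];

  // state
  std::vector<double> mw(N), H(N), pr1(N), pr2(N);
  // caches
  std::vector<double> Tc(N), mv(N, 0.0), fpart(N, 0.5), p2c(N, 0.0),
      Gam(N, 1.0), XlastG(N, -1.0), fG(N, 0.5);

  bool have_state0 = control.containsElementNamed("state0") &&
                     !Rf_isNull(control["state0"]);
  if (have_state0) {
    List s0 = control["state0"];
    NumericVector mw0 = s0["m_w"], H0 = s0["H"], p10 = s0["phi_ref1"],
                  p20 = s0["phi_ref2"], T0v = s0["T"], mv0 = s0["m_v"];
    for (int i = 0; i < N; ++i) {
      mw[i] = mw0[i]; H[i] = H0[i]; pr1[i] = p10[i]; pr2[i] = p20[i];
      Tc[i] = T0v[i]; mv[i] = mv0[i];
    }
  } else {
    double X0 = as<double>(control["X_m0"]);
    double T_init = as<double>(control["T_init_K"]);
    for (int i = 0; i < N; ++i) {
      mw[i] = X0 * ms[i];
      Tc[i] = T_init;
      // consistent vapor load and enthalpy at T_init
      double Vr = gas_solid(P, X0) + 1.0 + X0 * P.rho_solid / P.rho_w_st;
      double Vt = ms[i] / P.rho_solid * Vr;
      double phiair = gas_solid(P, X0) / Vr;
      double phis = 0.5, sig, aw0;
      for (int it = 0; it < 6; ++it) {
        double Xl = (mw[i] - mv[i]) / ms[i];
        aw0 = aw_equil(P, Xl, T_init, nullptr, fpart[i], phis, sig);
        mv[i] = std::min(aw0 * csat(P, T_init) * phiair * Vt, 0.5 * mw[i]);
      }
      pr1[i] = phis; pr2[i] = phis;  // fully relaxed initial matrix
      double mliq = mw[i] - mv[i];
      H[i] = (ms[i] * P.c_p_s + mliq * P.c_p_w) * (T_init - P.T0)
             + mv[i] * (P.c_p_v * (T_init - P.T0) + P.h_evap);
    }
  }

  // output buffers
  int n_save = (int)std::floor(t_end / save_dt + 1e-9) + 1;
  NumericMatrix series(n_save, 8);
  colnames(series) = CharacterVector::create(
      "t_s", "y_w", "X_m", "T_center_K", "T_surface_K",
      "aw_center", "aw_surface", "m_w_total");
  int n_prof = prof_times.size();
  NumericMatrix profiles(n_prof * N, 7);
  colnames(profiles) = CharacterVector::create(
      "t_s", "cv", "r_m", "X_m", "aw", "T_K", "phi_air");
  int prof_next = 0;

  int lam_n = 0;
  for (int i = 0; i < N; ++i) if (lam[i]) ++lam_n;
  int center_idx = lam_n + (N - lam_n) / 2;
  if (center_idx >= N) center_idx = N - 1;
  int surf_idx = N - 1;

  double ms_tot = 0;
  for (int i = 0; i < N; ++i) ms_tot += ms[i];

  // running balances
  double mw0_tot = 0, H0_tot = 0;
  for (int i = 0; i < N; ++i) { mw0_tot += mw[i]; H0_tot += H[i]; }
  double cum_m_out = 0, cum_E_out = 0;
  double max_mass_drift = 0, max_energy_drift = 0;  // per-step closure error

  // work arrays
  std::vector<double> Xm(N), Xl(N), Vt(N), Vreg(N), phiair(N), phiw(N),
      phis_t(N), cw(N), cv(N), aw(N), lam_eff(N), kw(N), kv(N), Dg(N),
      phis2(N), rc(N), rface(N + 1), Aface(N + 1), Aex(N, 0.0),
      dmw(N), dH(N);
  // face coefficients and linearization workspace
  std::vector<double> Gw(N + 1, 0.0), Gv(N + 1, 0.0), Gc(N + 1, 0.0),
      hwf(N + 1, 0.0), hvf(N + 1, 0.0),
      am(N), bm(N), cT(N), dvs(N), Bq(N), HA(N), hb(N),
      F_m(N), F_E(N);
  // 2x2 blocks (row-major: [mm, mH; Em, EH]) of the Jacobian of F
  std::vector<double> JD(4 * N), JL(4 * N), JU(4 * N),
      MD(4 * N), MU(4 * N), rr(2 * N), xx(2 * N);

  double t = 0, dt_ctrl = 1.0;
  long nsteps = 0;
  int isave = 0;
  bool aborted = false, saved0 = false;
  std::string abort_msg;

  auto record_series = [&](int row) {
    double mwt = 0;
    for (int i = 0; i < N; ++i) mwt += mw[i];
    series(row, 0) = t;
    series(row, 1) = mwt / (mwt + ms_tot);
    series(row, 2) = mwt / ms_tot;
    series(row, 3) = Tc[center_idx];
    series(row, 4) = Tc[surf_idx];
    series(row, 5) = aw[center_idx];
    series(row, 6) = aw[surf_idx];
    series(row, 7) = mwt;
  };

  while (t < t_end - 1e-9 && nsteps < max_steps) {
    double Tair, rh, u;
    amb.at(t, Tair, rh, u);
    double c_air = rh * csat(P, Tair);
    double h_rad = P.emissivity * 4.0 * P.sigma_SB * Tair * Tair * Tair;
    double h_conv = 6.0 + 10.0 * u;
    double h_ext = h_rad + h_conv;
    double beta = P.F_w_conv * h_conv / (P.rho_air * P.c_p_air);

    // --- state split & properties per CV ---
    double Vcum = 0;
    rface[0] = 0;
    for (int i = 0; i < N; ++i) {
      Xm[i] = mw[i] / ms[i];
      double gs = gas_solid(P, Xm[i]);
      double Vr = gs + 1.0 + Xm[i] * P.rho_solid / P.rho_w_st;
      Vt[i] = ms[i] / P.rho_solid * Vr;
      phiair[i] = gs / Vr;
      phis_t[i] = 1.0 / Vr;
      phiw[i] = 1.0 - phiair[i] - phis_t[i];
      Vreg[i] = lam[i] ? Vt[i] / phi_hyp : Vt[i];
      Aex[i] = lam[i] ? a_gap * Vreg[i] : 0.0;

      // split conserved (mw, H) into (T, m_liq, m_v) with lagged elastic p2
      double T = Tc[i], mvv = mv[i];
      for (int it = 0; it < 12; ++it) {
        double mliq = mw[i] - mvv;
        if (mliq <= 0) { mliq = 1e-12 * ms[i]; mvv = mw[i] - mliq; }
        double Xw = mliq / ms[i];
        double a = aw_tissue(P, Xw, T, p2c[i], fpart[i]);
        double cvv = a * csat(P, T);
        double mv_new = std::min(cvv * phiair[i] * Vt[i], 0.9 * mw[i]);
        double T_new = P.T0 + (H[i] - mv_new * P.h_evap)
                     / (ms[i] * P.c_p_s + (mw[i] - mv_new) * P.c_p_w
                        + mv_new * P.c_p_v);
        bool done = std::fabs(T_new - T) < 1e-10 &&
                    std::fabs(mv_new - mvv) < 1e-12 * (1.0 + mw[i]);
        T = T_new; mvv = mv_new;
        aw[i] = a; cv[i] = cvv;
        if (done) break;
      }
      if (!(T > 250 && T < 420) || !std::isfinite(T)) {
        aborted = true;
        abort_msg = "temperature out of physical bounds in CV " +
                    std::to_string(i + 1);
        break;
      }
      Tc[i] = T; mv[i] = mvv;
      Xl[i] = (mw[i] - mvv) / ms[i];
      cw[i] = (mw[i] - mvv) / ((1.0 - phiair[i]) * Vt[i]);

      // lazy thermodynamic factor / mutual diffusivity refresh
      if (XlastG[i] < 0 || std::fabs(Xl[i] / XlastG[i] - 1.0) > 1e-4) {
        Gam[i] = Gamma_relaxed(P, Xl[i], T, fG[i]);
        XlastG[i] = Xl[i];
      }
      kw[i] = (1.0 - phiair[i]) * Dw_mutual(P, Xl[i], T, Gam[i]);
      Dg[i] = 2.5e-5 * std::pow(T / 298.15, 1.75) * (101325.0 / P.P_atm);
      kv[i] = phiair[i] * Dg[i];
      lam_eff[i] = phis_t[i] * P.lambda_s + phiw[i] * P.lambda_w
                   + phiair[i] * P.lambda_air;
      phis2[i] = phis2_of(P, (1 - fpart[i]) * Xl[i]);

      Vcum += Vreg[i];
      rface[i + 1] = std::cbrt(3.0 * Vcum / (2.0 * M_PI));
    }
    if (aborted) break;
    for (int i = 0; i < N; ++i) {
      double Vmid = 0;
      for (int j = 0; j < i; ++j) Vmid += Vreg[j];
      Vmid += 0.5 * Vreg[i];
      rc[i] = std::cbrt(3.0 * Vmid / (2.0 * M_PI));
      Aface[i + 1] = 2.0 * M_PI * rface[i + 1] * rface[i + 1];
    }
    Aface[0] = 0;
    double A_out = Aface[N];
    if (!saved0) { record_series(0); saved0 = true; }

    // --- face transport coefficients (face k between CV k-1 and k) and
    //     explicit fluxes; harmonic-mean mobilities, upwinded enthalpy ---
    for (int k = 1; k < N; ++k) {
      int l = k - 1, r = k;
      // series (distance-weighted harmonic) conductances across the face
      double dl = rface[k] - rc[l], dr = rc[r] - rface[k];
      auto cond = [&](double kl, double kr) {
        if (kl <= 0 || kr <= 0) return 0.0;
        return Aface[k] / (dl / kl + dr / kr);
      };
      Gw[k] = cond(kw[l], kw[r]);
      Gv[k] = cond(kv[l], kv[r]);
      Gc[k] = cond(lam_eff[l], lam_eff[r]);
      double Jw0 = Gw[k] * (cw[l] - cw[r]);
      double Jv0 = Gv[k] * (cv[l] - cv[r]);
      double Tup_w = (Jw0 >= 0) ? Tc[l] : Tc[r];
      double Tup_v = (Jv0 >= 0) ? Tc[l] : Tc[r];
      hwf[k] = P.c_p_w * (Tup_w - P.T0);
      hvf[k] = P.h_evap + P.c_p_v * (Tup_v - P.T0);
    }
    Gw[0] = Gv[0] = Gc[0] = Gw[N] = Gv[N] = Gc[N] = 0;

    // --- per-CV sensitivities and boundary coefficients ---
    for (int i = 0; i < N; ++i) {
      double CapE = ms[i] * P.c_p_s + (mw[i] - mv[i]) * P.c_p_w
                    + mv[i] * P.c_p_v;
      am[i] = 1.0 / ((1.0 - phiair[i]) * Vt[i]);
      double vw_h = Xl[i] / P.rho_w_st, vs_h = 1.0 / P.rho_solid;
      double dlnphiw_dX = (1.0 / Xl[i]) * vs_h / (vw_h + vs_h);
      bm[i] = csat(P, Tc[i]) * aw[i] * Gam[i] * dlnphiw_dX / ms[i];
      cT[i] = 1.0 / CapE;
      dvs[i] = cv[i] * (dlnpsat_dT(Tc[i]) - 1.0 / Tc[i]) * cT[i];
      double Ab = closed_box ? 0.0
                             : ((i == surf_idx ? A_out : 0.0) + Aex[i]);
      Bq[i] = beta * Ab;
      HA[i] = h_ext * Ab;
      hb[i] = P.h_evap + P.c_p_v * (Tc[i] - P.T0);
      // explicit right-hand side (fluxes at the current state)
      double Jin_m = 0, Jin_E = 0;
      if (i > 0) {
        Jin_m += Gw[i] * (cw[i - 1] - cw[i]) + Gv[i] * (cv[i - 1] - cv[i]);
        Jin_E += hwf[i] * Gw[i] * (cw[i - 1] - cw[i])
                 + hvf[i] * Gv[i] * (cv[i - 1] - cv[i])
                 + Gc[i] * (Tc[i - 1] - Tc[i]);
      }
      if (i < N - 1) {
        int k = i + 1;
        Jin_m -= Gw[k] * (cw[i] - cw[i + 1]) + Gv[k] * (cv[i] - cv[i + 1]);
        Jin_E -= hwf[k] * Gw[k] * (cw[i] - cw[i + 1])
                 + hvf[k] * Gv[k] * (cv[i] - cv[i + 1])
                 + Gc[k] * (Tc[i] - Tc[i + 1]);
      }
      F_m[i] = Jin_m - Bq[i] * (cv[i] - c_air);
      F_E[i] = Jin_E + HA[i] * (Tair - Tc[i])
               - Bq[i] * (cv[i] - c_air) * hb[i];
    }

    // --- Jacobian of F (block tridiagonal) ---
    std::fill(JD.begin(), JD.end(), 0.0);
    std::fill(JL.begin(), JL.end(), 0.0);
    std::fill(JU.begin(), JU.end(), 0.0);
    for (int k = 1; k < N; ++k) {
      int l = k - 1, r = k;
      // flux J(k) wrt state of left/right CVs
      double dJm_dml = Gw[k] * am[l] + Gv[k] * bm[l];
      double dJm_dmr = -(Gw[k] * am[r] + Gv[k] * bm[r]);
      double dJm_dHl = Gv[k] * dvs[l];
      double dJm_dHr = -Gv[k] * dvs[r];
      double dJE_dml = hwf[k] * Gw[k] * am[l] + hvf[k] * Gv[k] * bm[l];
      double dJE_dmr = -(hwf[k] * Gw[k] * am[r] + hvf[k] * Gv[k] * bm[r]);
      double dJE_dHl = hvf[k] * Gv[k] * dvs[l] + Gc[k] * cT[l];
      double dJE_dHr = -(hvf[k] * Gv[k] * dvs[r] + Gc[k] * cT[r]);
      // CV l loses J(k): dF_l/dx -= dJ/dx
      JD[4 * l + 0] -= dJm_dml; JD[4 * l + 1] -= dJm_dHl;
      JD[4 * l + 2] -= dJE_dml; JD[4 * l + 3] -= dJE_dHl;
      JU[4 * l + 0] -= dJm_dmr; JU[4 * l + 1] -= dJm_dHr;
      JU[4 * l + 2] -= dJE_dmr; JU[4 * l + 3] -= dJE_dHr;
      // CV r gains J(k): dF_r/dx += dJ/dx
      JD[4 * r + 0] += dJm_dmr; JD[4 * r + 1] += dJm_dHr;
      JD[4 * r + 2] += dJE_dmr; JD[4 * r + 3] += dJE_dHr;
      JL[4 * r + 0] += dJm_dml; JL[4 * r + 1] += dJm_dHl;
      JL[4 * r + 2] += dJE_dml; JL[4 * r + 3] += dJE_dHl;
    }
    for (int i = 0; i < N; ++i) {
      // boundary: -Bq (cv_i - c_air); HA (Tair - T_i); latent carry hb
      JD[4 * i + 0] -= Bq[i] * bm[i];
      JD[4 * i + 1] -= Bq[i] * dvs[i];
      JD[4 * i + 2] -= Bq[i] * bm[i] * hb[i];
      JD[4 * i + 3] -= HA[i] * cT[i] + Bq[i] * dvs[i] * hb[i];
    }

    // --- choose dt, solve (I - dt J) x = dt F, retry on overshoot ---
    double dt = std::min(dt_ctrl, P.dt_max);
    double t_next_save = (isave + 1) * save_dt;
    if (t + dt > t_next_save) dt = t_next_save - t;
    if (t + dt > t_end) dt = t_end - t;
    if (prof_next < n_prof && t + dt > prof_times[prof_next] &&
        t < prof_times[prof_next])
      dt = prof_times[prof_next] - t;
    {  // next ambient breakpoint
      for (size_t q = 0; q < amb.t.size(); ++q)
        if (amb.t[q] > t + 1e-9 && t + dt > amb.t[q]) {
          dt = amb.t[q] - t;
          break;
        }
    }
    if (dt <= 0) dt = P.dt_min;

    bool solved = false;
    for (int tries = 0; tries < 30 && !solved; ++tries) {
      // M = I - dt*J
      for (int i = 0; i < N; ++i) {
        MD[4 * i + 0] = 1.0 - dt * JD[4 * i + 0];
        MD[4 * i + 1] = -dt * JD[4 * i + 1];
        MD[4 * i + 2] = -dt * JD[4 * i + 2];
        MD[4 * i + 3] = 1.0 - dt * JD[4 * i + 3];
        rr[2 * i] = dt * F_m[i];
        rr[2 * i + 1] = dt * F_E[i];
      }
      // block-Thomas forward sweep
      bool singular = false;
      std::vector<double> MUw(4 * N);
      for (int i = 0; i < N; ++i)
        for (int q = 0; q < 4; ++q) MUw[4 * i + q] = -dt * JU[4 * i + q];
      for (int i = 1; i < N; ++i) {
        double* Dm1 = &MD[4 * (i - 1)];
        double det = Dm1[0] * Dm1[3] - Dm1[1] * Dm1[2];
        if (std::fabs(det) < 1e-300) { singular = true; break; }
        double inv[4] = {Dm1[3] / det, -Dm1[1] / det,
                         -Dm1[2] / det, Dm1[0] / det};
        double L[4] = {-dt * JL[4 * i + 0], -dt * JL[4 * i + 1],
                       -dt * JL[4 * i + 2], -dt * JL[4 * i + 3]};
        double W[4] = {L[0] * inv[0] + L[1] * inv[2],
                       L[0] * inv[1] + L[1] * inv[3],
                       L[2] * inv[0] + L[3] * inv[2],
                       L[2] * inv[1] + L[3] * inv[3]};
        double* Um1 = &MUw[4 * (i - 1)];
        MD[4 * i + 0] -= W[0] * Um1[0] + W[1] * Um1[2];
        MD[4 * i + 1] -= W[0] * Um1[1] + W[1] * Um1[3];
        MD[4 * i + 2] -= W[2] * Um1[0] + W[3] * Um1[2];
        MD[4 * i + 3] -= W[2] * Um1[1] + W[3] * Um1[3];
        rr[2 * i] -= W[0] * rr[2 * (i - 1)] + W[1] * rr[2 * (i - 1) + 1];
        rr[2 * i + 1] -= W[2] * rr[2 * (i - 1)] + W[3] * rr[2 * (i - 1) + 1];
      }
      if (singular) { dt *= 0.5; continue; }
      // back substitution
      for (int i = N - 1; i >= 0; --i) {
        double bmv = rr[2 * i], bEv = rr[2 * i + 1];
        if (i < N - 1) {
          double* U = &MUw[4 * i];
          bmv -= U[0] * xx[2 * (i + 1)] + U[1] * xx[2 * (i + 1) + 1];
          bEv -= U[2] * xx[2 * (i + 1)] + U[3] * xx[2 * (i + 1) + 1];
        }
        double* D = &MD[4 * i];
        double det = D[0] * D[3] - D[1] * D[2];
        xx[2 * i] = (D[3] * bmv - D[1] * bEv) / det;
        xx[2 * i + 1] = (-D[2] * bmv + D[0] * bEv) / det;
      }
      // validity checks
      bool ok = true;
      for (int i = 0; i < N; ++i) {
        double dm = xx[2 * i], dh = xx[2 * i + 1];
        if (!std::isfinite(dm) || !std::isfinite(dh)) { ok = false; break; }
        if (mw[i] + dm < 1e-3 * ms[i]) { ok = false; break; }
        if (std::fabs(dm) > 0.5 * mw[i]) { ok = false; break; }
        if (std::fabs(cT[i] * dh) > 8.0) { ok = false; break; }
      }
      if (!ok && dt > P.dt_min) { dt *= 0.5; continue; }
      solved = true;
    }
    if (!solved) {
      aborted = true;
      abort_msg = "time step collapsed below dt_min";
      break;
    }

    // --- flux-form update from the linearized end-of-step state ---
    // (exactly telescoping interior fluxes => exact conservation)
    {
      double bm_tot = 0, bE_tot = 0;
      std::vector<double> chw(N), chv(N), chT(N);
      for (int i = 0; i < N; ++i) {
        chw[i] = cw[i] + am[i] * xx[2 * i];
        chv[i] = cv[i] + bm[i] * xx[2 * i] + dvs[i] * xx[2 * i + 1];
        chT[i] = Tc[i] + cT[i] * xx[2 * i + 1];
      }
      std::vector<double> Jm(N + 1, 0.0), JE(N + 1, 0.0);
      for (int k = 1; k < N; ++k) {
        int l = k - 1, r = k;
        double Jw = Gw[k] * (chw[l] - chw[r]);
        double Jv = Gv[k] * (chv[l] - chv[r]);
        Jm[k] = Jw + Jv;
        JE[k] = hwf[k] * Jw + hvf[k] * Jv + Gc[k] * (chT[l] - chT[r]);
      }
      for (int i = 0; i < N; ++i) {
        double Jbm = -Bq[i] * (chv[i] - c_air);
        double JbE = HA[i] * (Tair - chT[i])
                     - Bq[i] * (chv[i] - c_air) * hb[i];
        dmw[i] = dt * (Jm[i] - Jm[i + 1] + Jbm);
        dH[i] = dt * (JE[i] - JE[i + 1] + JbE);
        bm_tot += Jbm; bE_tot += JbE;
      }
      for (int i = 0; i < N; ++i) {
        mw[i] += dmw[i];
        H[i] += dH[i];
      }
      cum_m_out -= bm_tot * dt;
      cum_E_out -= bE_tot * dt;
    }

    // --- step-size controller (targets: 3% local moisture, 0.7 K) ---
    {
      double obs = 1e-8;
      for (int i = 0; i < N; ++i) {
        double em = std::fabs(dmw[i]) /
                    (P.tgt_dm * std::max(mw[i], 0.02 * ms[i]));
        double eT = std::fabs(cT[i] * dH[i]) / P.tgt_dT;
        if (em > obs) obs = em;
        if (eT > obs) obs = eT;
      }
      dt_ctrl = dt * std::min(1.6, std::max(0.3, 0.85 / obs));
      if (dt_ctrl < P.dt_min) dt_ctrl = P.dt_min;
      if (dt_ctrl > P.dt_max) dt_ctrl = P.dt_max;
    }

    // --- advance Maxwell states (exact exponential, frozen phi_s) ---
    for (int i = 0; i < N; ++i) {
      double tau[2];
      double prbuf[2] = {pr1[i], pr2[i]};
      double sig = ve_stress(P, phis2[i], prbuf, Xl[i], Tc[i], tau);
      p2c[i] = P.elastic_sign * sig;
      pr1[i] = phis2[i] + (pr1[i] - phis2[i]) * std::exp(-dt / tau[0]);
      pr2[i] = phis2[i] + (pr2[i] - phis2[i]) * std::exp(-dt / tau[1]);
    }

    t += dt;
    ++nsteps;

    // interior conservation bookkeeping (closure identity check)
    {
      double mwt = 0, Ht = 0;
      for (int i = 0; i < N; ++i) { mwt += mw[i]; Ht += H[i]; }
      double em = std::fabs((mwt + cum_m_out - mw0_tot) / mw0_tot);
      double eE = std::fabs((Ht + cum_E_out - H0_tot) /
                            std::max(std::fabs(H0_tot), 1.0));
      if (em > max_mass_drift) max_mass_drift = em;
      if (eE > max_energy_drift) max_energy_drift = eE;
    }

    if (prof_next < n_prof && t >= prof_times[prof_next] - 1e-9) {
      for (int i = 0; i < N; ++i) {
        int row = prof_next * N + i;
        profiles(row, 0) = prof_times[prof_next];
        profiles(row, 1) = i + 1;
        profiles(row, 2) = rc[i];
        profiles(row, 3) = Xm[i];
        profiles(row, 4) = aw[i];
        profiles(row, 5) = Tc[i];
        profiles(row, 6) = phiair[i];
      }
      ++prof_next;
    }
    if (t >= t_next_save - 1e-9 && isave + 1 < n_save) {
      ++isave;
      record_series(isave);
    }
  }
  if (!saved0) record_series(0);
  // simulation ended early (abort or max_steps): mark unreached rows
  for (int r = isave + 1; r < n_save; ++r)
    for (int c = 0; c < 8; ++c) series(r, c) = NA_REAL;

  double mw_end = 0, H_end = 0;
  for (int i = 0; i < N; ++i) { mw_end += mw[i]; H_end += H[i]; }

  return List::create(
      _["series"] = series,
      _["profiles"] = profiles,
      _["nsteps"] = (double)nsteps,
      _["t_final_s"] = t,
      _["aborted"] = aborted,
      _["abort_msg"] = abort_msg,
      _["balance"] = List::create(
          _["mass_closure_rel"] = max_mass_drift,
          _["energy_closure_rel"] = max_energy_drift,
          _["water_initial_kg"] = mw0_tot,
          _["water_final_kg"] = mw_end,
          _["water_out_kg"] = cum_m_out,
          _["energy_initial_J"] = H0_tot,
          _["energy_final_J"] = H_end,
          _["energy_out_J"] = cum_E_out),
      _["state"] = List::create(
          _["m_w"] = NumericVector(mw.begin(), mw.end()),
          _["H"] = NumericVector(H.begin(), H.end()),
          _["phi_ref1"] = NumericVector(pr1.begin(), pr1.end()),
          _["phi_ref2"] = NumericVector(pr2.begin(), pr2.end()),
          _["T"] = NumericVector(Tc.begin(), Tc.end()),
          _["m_v"] = NumericVector(mv.begin(), mv.end()),
          _["aw"] = NumericVector(aw.begin(), aw.end()),
          _["X_m"] = NumericVector(Xm.begin(), Xm.end()),
          _["r_m"] = NumericVector(rc.begin(), rc.end())));
}

// Tissue water activity curve for cross-checking the compiled path against
// the R implementation; phi_ref of length 0 means fully relaxed.
// [[Rcpp::export]]
NumericVector cpp_aw_curve(List cfg, NumericVector X_m, double T,
                           NumericVector phi_ref) {
  Pars P = make_pars(cfg);
  int n = X_m.size();
  NumericVector out(n);
  double f = 0.5, phis, sig;
  const double* pr = nullptr;
  double prbuf[2];
  if (phi_ref.size() == 2) {
    prbuf[0] = phi_ref[0]; prbuf[1] = phi_ref[1];
    pr = prbuf;
  }
  for (int i = 0; i < n; ++i)
    out[i] = aw_equil(P, X_m[i], T, pr, f, phis, sig);
  return out;
}

// Lumped stepped-RH dynamic vapor sorption simulator.  The powder sample
// has no internal gradients; moisture relaxes toward the ambient vapor
// concentration of each RH step through a lumped conductance k while the
// Maxwell matrix relaxes on its own clock (locally-linearized exponential
// moisture update, exact Maxwell update).
// [[Rcpp::export]]
List cpp_dvs(List cfg, NumericVector RH_steps, double dwell_s, double T,
             double k_cond, double X0, int n_sub) {
  Pars P = make_pars(cfg);
  double f = 0.5, phis, sig;
  double X = X0;
  // start fully relaxed at X0
  aw_equil(P, X, T, nullptr, f, phis, sig);
  double pr[2] = {phis, phis};
  int n_steps = RH_steps.size();
  NumericVector X_end(n_steps), aw_end(n_steps);
  int n_traj = n_steps * n_sub;
  NumericVector tt(n_traj), XX(n_traj), rr(n_traj);
  double cs = csat(P, T);
  double t = 0;
  int row = 0;
  double dt = dwell_s / n_sub;
  for (int s = 0; s < n_steps; ++s) {
    double c_amb = RH_steps[s] * cs;
    for (int q = 0; q < n_sub; ++q) {
      double a = aw_equil(P, X, T, pr, f, phis, sig);
      double c = a * cs;
      // local slope dc/dX by finite difference at the current state
      double h = std::max(1e-4 * X, 1e-7);
      double f2 = f, phis2v, sig2;
      double a2 = aw_equil(P, X + h, T, pr, f2, phis2v, sig2);
      double slope = (a2 - a) / h * cs;
      double Xn;
      if (slope > 1e-12) {
        double Xeq = X + (c_amb - c) / slope;
        Xn = Xeq + (X - Xeq) * std::exp(-dt * k_cond * slope);
      } else {
        Xn = X + dt * k_cond * (c_amb - c);
      }
      if (Xn < 1e-4) Xn = 1e-4;
      // Maxwell relaxation over the sub-step
      double tau[2];
      ve_stress(P, phis, pr, X, T, tau);
      pr[0] = phis + (pr[0] - phis) * std::exp(-dt / tau[0]);
      pr[1] = phis + (pr[1] - phis) * std::exp(-dt / tau[1]);
      X = Xn;
      t += dt;
      tt[row] = t; XX[row] = X; rr[row] = RH_steps[s];
      ++row;
    }
    double a = aw_equil(P, X, T, pr, f, phis, sig);
    X_end[s] = X;
    aw_end[s] = a;
  }
  return List::create(_["X_end"] = X_end, _["aw_end"] = aw_end,
                      _["t_s"] = tt, _["X_m"] = XX, _["RH"] = rr);
}

// Relaxed-isotherm inversion helper used to start DVS runs.
// [[Rcpp::export]]
double cpp_aw_to_Xm(List cfg, double a_w, double T) {
  Pars P = make_pars(cfg);
  double f = 0.5, phis, sig;
  double lo = 1e-8, hi = 1e3;
  for (int it = 0; it < 120; ++it) {
    double mid = std::sqrt(lo * hi);
    double a = aw_equil(P, mid, T, nullptr, f, phis, sig);
    if (a > a_w) hi = mid; else lo = mid;
  }
  return std::sqrt(lo * hi);
}
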