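// Compiled right-hand side of the neuro-musculoskeletal arm ODE and the
// four-element Hill-type muscle-tendon unit (CE + PEE in parallel, in series
// with SEE + SDE).  The contraction velocity solves the force balance
// CE + PEE = SEE + SDE in closed form: multiplying the balance by (b - v)
// (the Hill-hyperbola pole) makes it an exact quadratic in v.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// per-muscle parameter vector layout (must match R side, see muscle_parameters())
enum {P_FMAX, P_LOPT, P_W, P_NUFL, P_AREL, P_BREL, P_SECC, P_FECC,
      P_LPEE0, P_KPEE, P_NUPEE, P_LSEE0, P_DUNLL, P_DUL, P_DFSEE0,
      P_DSDE, P_RSDE, P_AMIN, P_MACT, P_NUACT, P_RHOC, P_CGAM,
      P_RSH, P_REL, P_LREF, P_PHIREF, P_PSIREF, NP_MUSC};

// arm/limit parameter vector layout
enum {A_L1, A_L2, A_M1, A_M2, A_C1, A_C2, A_I1, A_I2, A_G,
      A_PHILO, A_PHIHI, A_PSILO, A_PSIHI, A_KLIM, A_WLIM, NP_ARM};

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static double f_isom(double lce, const double* p) {
  double x = std::fabs(lce / p[P_LOPT] - 1.0) / p[P_W];
  return std::exp(-std::pow(x, p[P_NUFL]));
}

static double f_pee(double lce, const double* p) {
  double L0 = p[P_LPEE0] * p[P_LOPT];
  if (lce <= L0) return 0.0;
  double K = p[P_KPEE] * p[P_FMAX] /
    std::pow(p[P_LOPT] * (p[P_W] + 1.0 - p[P_LPEE0]), p[P_NUPEE]);
  return K * std::pow(lce - L0, p[P_NUPEE]);
}

static double f_see(double lsee, const double* p) {
  double l0 = p[P_LSEE0];
  if (lsee <= l0) return 0.0;
  double nu = p[P_DUNLL] / p[P_DUL];
  double lnll = (1.0 + p[P_DUNLL]) * l0;
  if (lsee < lnll) {
    double K = p[P_DFSEE0] / std::pow(p[P_DUNLL] * l0, nu);
    return K * std::pow(lsee - l0, nu);
  }
  double Kl = p[P_DFSEE0] / (p[P_DUL] * l0);
  return p[P_DFSEE0] + Kl * (lsee - lnll);
}

// Hatze-style length dependence of calcium sensitivity, increasing with length
static double rho_len(double lce, const double* p) {
  double lhat = clampd(lce / p[P_LOPT], 0.4, 1.9);
  double r = p[P_RHOC] * (p[P_CGAM] - 1.0 / lhat) / (p[P_CGAM] - 1.0);
  return r > 0.0 ? r : 0.0;
}

static double activity_of(double gam, double lce, const double* p) {
  double g = clampd(gam, 0.0, 1.0);
  double s = std::pow(rho_len(lce, p) * g, p[P_NUACT]);
  return (p[P_AMIN] + s) / (1.0 + s);
}

// hyperbola branch parameters: bb (pole), AA (asymptote factor), C0 = (Fi+AA)*bb
struct Branch { double bb, AA, C0; };

static Branch branch_con(double Fi, const double* p) {
  Branch br;
  br.bb = p[P_BREL] * p[P_LOPT];
  br.AA = p[P_AREL];
  br.C0 = (Fi + br.AA) * br.bb;
  return br;
}

static Branch branch_ecc(double Fi, const double* p) {
  Branch br;
  double b = p[P_BREL] * p[P_LOPT];
  br.AA = -p[P_FECC] * Fi;
  br.bb = b * Fi * (1.0 - p[P_FECC]) / (p[P_SECC] * (Fi + p[P_AREL]));
  br.C0 = (Fi + br.AA) * br.bb;
  return br;
}

// CE force along the hyperbola, clamped at zero: the fiber cannot push
// (concentric shortening faster than v_max, where the hyperbola crosses
// zero, produces no force)
static double fce_of(double v, const Branch& br, double Fmax) {
  double F = Fmax * (br.C0 / (br.bb - v) - br.AA);
  return F > 0.0 ? F : 0.0;
}

// shortening velocity at which the concentric CE force reaches zero
static double v_zero_force(const Branch& br) {
  // C0/(bb - v) = AA  =>  v = bb - C0/AA
  if (br.AA <= 0.0) return -1e30;
  return br.bb - br.C0 / br.AA;
}

// force balance residual CE + PEE - SEE - SDE at CE velocity v
static double balance_of(double v, const Branch& br, double Fpee, double Fsee,
                         double vmtu, double Dmax, double R, double Fmax) {
  double Fce = fce_of(v, br, Fmax);
  double D = Dmax * ((1.0 - R) * (Fce + Fpee) / Fmax + R);
  return Fce + Fpee - Fsee - D * (vmtu - v);
}

// solve balance(v) = 0 for the branch; balance*(bb - v) is quadratic in v
static double solve_branch(const Branch& br, double Fpee, double Fsee,
                           double vmtu, double Dmax, double R, double Fmax,
                           bool concentric, bool& ok) {
  double G = Dmax * (1.0 - R) / Fmax;
  double E = Fpee - Fmax * br.AA;
  double GS = G * E + Dmax * R;
  double A2 = -GS;
  double A1 = Fmax * br.AA - (Fpee - Fsee) + G * Fmax * br.C0 + GS * (vmtu + br.bb);
  double A0 = Fmax * (br.C0 - br.AA * br.bb) + (Fpee - Fsee) * br.bb
            - G * Fmax * br.C0 * vmtu - GS * vmtu * br.bb;
  double r1 = NA_REAL, r2 = NA_REAL;
  if (std::fabs(A2) < 1e-14 * (std::fabs(A1) + 1.0)) {
    if (A1 == 0.0) { ok = false; return 0.0; }
    r1 = -A0 / A1;
  } else {
    double disc = A1 * A1 - 4.0 * A2 * A0;
    if (disc < 0.0) { ok = false; return 0.0; }
    double sq = std::sqrt(disc);
    double q = -0.5 * (A1 + (A1 >= 0.0 ? sq : -sq));
    r1 = q / A2;
    if (q != 0.0) r2 = A0 / q;
  }
  // both roots can lie on the physical side of the pole (the damping term
  // makes the balance non-monotone far from zero); the physical solution is
  // the first crossing away from v = 0, i.e. the root nearest zero
  double tol = 1e-9, best = NA_REAL;
  for (double r : {r1, r2}) {
    if (!std::isfinite(r)) continue;
    bool side = concentric ? (r <= tol && r < br.bb) : (r >= -tol && r > br.bb);
    if (side && (!std::isfinite(best) || std::fabs(r) < std::fabs(best)))
      best = r;
  }
  if (std::isfinite(best)) { ok = true; return best; }
  ok = false;
  return 0.0;
}

// closed-form contraction velocity of the CE (m/s)
static double contraction_rate_impl(double lce, double lmtu, double vmtu,
                                    double a, const double* p) {
  double Fmax = p[P_FMAX];
  double Fi = a * f_isom(lce, p);
  double Fpee = f_pee(lce, p);
  double Fsee = f_see(lmtu - lce, p);
  double Dmax = p[P_DSDE] * Fmax * p[P_AREL] / (p[P_LOPT] * p[P_BREL]);
  double R = p[P_RSDE];
  Branch con = branch_con(Fi, p);
  double bal0 = balance_of(0.0, con, Fpee, Fsee, vmtu, Dmax, R, Fmax);
  bool ok = false;
  double v;
  if (bal0 > 0.0) {  // surplus CE force at v = 0: concentric shortening
    v = solve_branch(con, Fpee, Fsee, vmtu, Dmax, R, Fmax, true, ok);
    double vfz = v_zero_force(con);
    if (ok && v < vfz) {
      // beyond maximal shortening velocity the CE force is clamped at zero
      // and the balance is linear: PEE - SEE - D0 (vmtu - v) = 0
      double D0 = Dmax * ((1.0 - R) * Fpee / Fmax + R);
      v = vmtu - (Fpee - Fsee) / D0;
      if (v > vfz) v = vfz;
      ok = true;
    }
  } else {
    Branch ecc = branch_ecc(Fi, p);
    v = solve_branch(ecc, Fpee, Fsee, vmtu, Dmax, R, Fmax, false, ok);
  }
  if (!ok) {  // bisection fallback on the monotone (clamped) balance residual
    Branch ecc = branch_ecc(Fi, p);
    double lo = -10.0, hi = 10.0;
    for (int i = 0; i < 200; ++i) {
      double mid = 0.5 * (lo + hi);
      const Branch& br = mid <= 0.0 ? con : ecc;
      double Fce = fce_of(mid, br, Fmax);
      double D = Dmax * ((1.0 - R) * (Fce + Fpee) / Fmax + R);
      double b = Fce + Fpee - Fsee - D * (vmtu - mid);
      if (b > 0.0) hi = mid; else lo = mid;
    }
    v = 0.5 * (lo + hi);
  }
  return v;
}

// MTU force at a given CE velocity (serial side: SEE + SDE), clamped tensile
static double mtu_force_impl(double lce, double vce, double lmtu, double vmtu,
                             double a, const double* p) {
  double Fmax = p[P_FMAX];
  double Fi = a * f_isom(lce, p);
  Branch br = vce <= 0.0 ? branch_con(Fi, p) : branch_ecc(Fi, p);
  double Fce = fce_of(vce, br, Fmax);
  double Fpee = f_pee(lce, p);
  double Dmax = p[P_DSDE] * Fmax * p[P_AREL] / (p[P_LOPT] * p[P_BREL]);
  double D = Dmax * ((1.0 - p[P_RSDE]) * (Fce + Fpee) / Fmax + p[P_RSDE]);
  double F = f_see(lmtu - lce, p) + D * (vmtu - vce);
  return F > 0.0 ? F : 0.0;
}

static double limit_torque(double th, double lo, double hi, double k, double w) {
  if (k <= 0.0) return 0.0;
  return k * (std::exp((lo - th) / w) - std::exp((th - hi) / w));
}

// [[Rcpp::export(name = ".contraction_rate_cpp")]]
double contraction_rate_cpp(double lce, double lmtu, double vmtu, double a,
                            NumericVector p) {
  if (lce <= 0.0) stop("non-physical muscle state: l_CE <= 0");
  return contraction_rate_impl(lce, lmtu, vmtu, a, p.begin());
}

// [[Rcpp::export(name = ".mtu_force_cpp")]]
double mtu_force_cpp(double lce, double vce, double lmtu, double vmtu, double a,
                     NumericVector p) {
  if (lce <= 0.0) stop("non-physical muscle state: l_CE <= 0");
  return mtu_force_impl(lce, vce, lmtu, vmtu, a, p.begin());
}

// [[Rcpp::export(name = ".activity_cpp")]]
double activity_cpp(double gam, double lce, NumericVector p) {
  return activity_of(gam, lce, p.begin());
}

// [[Rcpp::export(name = ".muscle_curves_cpp")]]
NumericVector muscle_curves_cpp(double lce, double lsee, NumericVector p) {
  return NumericVector::create(_["f_isom"] = f_isom(lce, p.begin()),
                               _["f_pee"] = f_pee(lce, p.begin()),
                               _["f_see"] = f_see(lsee, p.begin()),
                               _["rho"] = rho_len(lce, p.begin()));
}

// state vector y = (phi, psi, phidot, psidot, lce[1..6], gamma[1..6])
// [[Rcpp::export(name = ".arm_rhs_cpp")]]
NumericVector arm_rhs_cpp(double t, NumericVector y, NumericVector arm,
                          NumericMatrix musc, NumericVector u) {
  const double* ap = arm.begin();
  int nm = musc.nrow();
  double phi = y[0], psi = y[1], dphi = y[2], dpsi = y[3];
  double tau_el = 0.0, tau_sh = 0.0;
  NumericVector dy(4 + 2 * nm);
  std::vector<double> prow(NP_MUSC);
  for (int i = 0; i < nm; ++i) {
    for (int j = 0; j < NP_MUSC; ++j) prow[j] = musc(i, j);
    const double* p = prow.data();
    double lce = y[4 + i], gam = y[4 + nm + i];
    if (lce <= 0.0) stop("non-physical muscle state: l_CE <= 0");
    double lmtu = p[P_LREF] - p[P_RSH] * (psi - p[P_PSIREF])
                            - p[P_REL] * (phi - p[P_PHIREF]);
    double vmtu = -p[P_RSH] * dpsi - p[P_REL] * dphi;
    double a = activity_of(gam, lce, p);
    double vce = contraction_rate_impl(lce, lmtu, vmtu, a, p);
    double F = mtu_force_impl(lce, vce, lmtu, vmtu, a, p);
    tau_el += p[P_REL] * F;
    tau_sh += p[P_RSH] * F;
    dy[4 + i] = vce;
    double ui = clampd(u[i], 0.0, 1.0);
    dy[4 + nm + i] = p[P_MACT] * (ui - gam);
  }
  tau_el += limit_torque(phi, ap[A_PHILO], ap[A_PHIHI], ap[A_KLIM], ap[A_WLIM]);
  tau_sh += limit_torque(psi, ap[A_PSILO], ap[A_PSIHI], ap[A_KLIM], ap[A_WLIM]);

  // skeleton in absolute angles q1 = psi, q2 = psi + phi (from downward vertical)
  double q1 = psi, q2 = psi + phi, dq1 = dpsi, dq2 = dpsi + dphi;
  double l1 = ap[A_L1], m1 = ap[A_M1], m2 = ap[A_M2];
  double c1 = ap[A_C1], c2 = ap[A_C2], g = ap[A_G];
  double M11 = ap[A_I1] + m1 * c1 * c1 + m2 * l1 * l1;
  double M12 = m2 * l1 * c2 * std::cos(q1 - q2);
  double M22 = ap[A_I2] + m2 * c2 * c2;
  double h = m2 * l1 * c2 * std::sin(q1 - q2);
  double C1v = h * dq2 * dq2;
  double C2v = -h * dq1 * dq1;
  double G1 = (m1 * c1 + m2 * l1) * g * std::sin(q1);
  double G2 = m2 * c2 * g * std::sin(q2);
  double Q1 = tau_sh - tau_el;  // generalized forces in (q1, q2)
  double Q2 = tau_el;
  double r1 = Q1 - C1v - G1, r2 = Q2 - C2v - G2;
  double det = M11 * M22 - M12 * M12;
  double ddq1 = (M22 * r1 - M12 * r2) / det;
  double ddq2 = (M11 * r2 - M12 * r1) / det;
  dy[0] = dphi;
  dy[1] = dpsi;
  dy[2] = ddq2 - ddq1;  // phiddot
  dy[3] = ddq1;         // psiddot
  return dy;
}

// per-sample muscle torques, forces and activities along a solved trajectory
// [[Rcpp::export(name = ".muscle_outputs_cpp")]]
List muscle_outputs_cpp(NumericMatrix Y, NumericMatrix musc, NumericVector u) {
  int n = Y.nrow(), nm = musc.nrow();
  NumericMatrix tau(n, 2), Fm(n, nm), am(n, nm);
  std::vector<double> prow(NP_MUSC);
  for (int k = 0; k < n; ++k) {
    double phi = Y(k, 0), psi = Y(k, 1), dphi = Y(k, 2), dpsi = Y(k, 3);
    double tel = 0.0, tsh = 0.0;
    for (int i = 0; i < nm; ++i) {
      for (int j = 0; j < NP_MUSC; ++j) prow[j] = musc(i, j);
      const double* p = prow.data();
      double lce = Y(k, 4 + i), gam = Y(k, 4 + nm + i);
      double lmtu = p[P_LREF] - p[P_RSH] * (psi - p[P_PSIREF])
                              - p[P_REL] * (phi - p[P_PHIREF]);
      double vmtu = -p[P_RSH] * dpsi - p[P_REL] * dphi;
      double a = activity_of(gam, lce, p);
      double vce = contraction_rate_impl(lce, lmtu, vmtu, a, p);
      double F = mtu_force_impl(lce, vce, lmtu, vmtu, a, p);
      tel += p[P_REL] * F;
      tsh += p[P_RSH] * F;
      Fm(k, i) = F;
      am(k, i) = a;
    }
    tau(k, 0) = tel;   // elbow
    tau(k, 1) = tsh;   // shoulder
  }
  return List::create(_["tau"] = tau, _["F"] = Fm, _["a"] = am);
}
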