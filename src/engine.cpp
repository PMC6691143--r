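// Model-system energies/gradients and the BAOAB Langevin integrator with
// optional dual-boost aMD bias.  Units: A, kcal/mol, ps, K, amu.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// kcal/mol/A per amu -> A/ps^2
static const double KFAC = 418.4;
static const double KBOLTZ = 0.0019872041; // kcal/mol/K

// ---------------------------------------------------------------------------
// System evaluation
// ---------------------------------------------------------------------------

struct SysEval {
  double V;   // total potential
  double VD;  // dihedral component
};

// Double well: V(x) = h*((x/w)^2 - 1)^2, 1 particle, 1-D.  V_D = 0.
static SysEval eval_dwell(double h, double w,
                          const std::vector<double>& x,
                          std::vector<double>& g,
                          std::vector<double>& gD) {
  double u = x[0] / w;
  double q = u * u - 1.0;
  SysEval e;
  e.V = h * q * q;
  e.VD = 0.0;
  g[0] = 4.0 * h * q * x[0] / (w * w);
  gD[0] = 0.0;
  return e;
}

// Harmonic: V(x) = 0.5*k*x^2 (1 particle, 1-D).  V_D = 0.
static SysEval eval_harm(double k,
                         const std::vector<double>& x,
                         std::vector<double>& g,
                         std::vector<double>& gD) {
  SysEval e;
  e.V = 0.5 * k * x[0] * x[0];
  e.VD = 0.0;
  g[0] = k * x[0];
  gD[0] = 0.0;
  return e;
}

struct HelixParams {
  int n;
  double bond_k, r0;
  double angle_k, theta0;
  double torsion_k, phi0;
  double eps;       // native-contact well depth
  double rep_eps, rep_sigma;
  std::vector<int> ci, cj;          // native contact pairs (0-based)
  std::vector<double> csig;         // native distances
  std::vector<int> ri, rj;          // repulsive (non-native, |i-j|>=2) pairs
};

static HelixParams parse_helix(const List& sys) {
  HelixParams p;
  p.n = as<int>(sys["n_particles"]);
  List par = sys["params"];
  p.bond_k = as<double>(par["bond_k"]);
  p.r0 = as<double>(par["r0"]);
  p.angle_k = as<double>(par["angle_k"]);
  p.theta0 = as<double>(par["theta0"]);
  p.torsion_k = as<double>(par["torsion_k"]);
  p.phi0 = as<double>(par["phi0"]);
  p.eps = as<double>(par["contact_eps"]);
  p.rep_eps = as<double>(par["repulsion_eps"]);
  p.rep_sigma = as<double>(par["repulsion_sigma"]);
  IntegerMatrix cp = par["contact_pairs"]; // 0-based, 2 cols
  NumericVector cs = par["contact_sigma"];
  for (int k = 0; k < cp.nrow(); ++k) {
    p.ci.push_back(cp(k, 0));
    p.cj.push_back(cp(k, 1));
    p.csig.push_back(cs[k]);
  }
  IntegerMatrix rp = par["repulsive_pairs"];
  for (int k = 0; k < rp.nrow(); ++k) {
    p.ri.push_back(rp(k, 0));
    p.rj.push_back(rp(k, 1));
  }
  return p;
}

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// CG helix energy; terms[0..4] = bond, angle, torsion, contact, repulsion.
static SysEval eval_helix(const HelixParams& p,
                          const std::vector<double>& x,
                          std::vector<double>& g,
                          std::vector<double>& gD,
                          double* terms) {
  const int n = p.n;
  std::fill(g.begin(), g.end(), 0.0);
  std::fill(gD.begin(), gD.end(), 0.0);
  double e_bond = 0, e_ang = 0, e_tor = 0, e_con = 0, e_rep = 0;

  // bonds: k*(r - r0)^2
  for (int i = 0; i + 1 < n; ++i) {
    double d[3];
    vsub(&x[3 * (i + 1)], &x[3 * i], d);
    double r = std::sqrt(vdot(d, d));
    double dr = r - p.r0;
    e_bond += p.bond_k * dr * dr;
    double c = 2.0 * p.bond_k * dr / r;
    for (int k = 0; k < 3; ++k) {
      g[3 * (i + 1) + k] += c * d[k];
      g[3 * i + k] -= c * d[k];
    }
  }

  // pseudo-angles: k*(theta - theta0)^2 on (i, i+1, i+2)
  for (int i = 0; i + 2 < n; ++i) {
    const double* a = &x[3 * i];
    const double* b = &x[3 * (i + 1)];
    const double* c3 = &x[3 * (i + 2)];
    double u[3], v[3];
    vsub(a, b, u);
    vsub(c3, b, v);
    double nu = std::sqrt(vdot(u, u)), nv = std::sqrt(vdot(v, v));
    double cs = vdot(u, v) / (nu * nv);
    if (cs > 1.0) cs = 1.0;
    if (cs < -1.0) cs = -1.0;
    double th = std::acos(cs);
    double dth = th - p.theta0;
    e_ang += p.angle_k * dth * dth;
    double sn = std::sqrt(1.0 - cs * cs);
    if (sn < 1e-8) sn = 1e-8;
    double pref = -2.0 * p.angle_k * dth / sn; // dE/dcos
    // d(cos)/da etc.
    for (int k = 0; k < 3; ++k) {
      double dca = (v[k] / (nu * nv)) - cs * u[k] / (nu * nu);
      double dcc = (u[k] / (nu * nv)) - cs * v[k] / (nv * nv);
      g[3 * i + k] += pref * dca;
      g[3 * (i + 2) + k] += pref * dcc;
      g[3 * (i + 1) + k] += -pref * (dca + dcc);
    }
  }

  // pseudo-dihedrals: k*(1 - cos(phi - phi0)) on (i..i+3) -- the V_D terms
  for (int i = 0; i + 3 < n; ++i) {
    const double* p1 = &x[3 * i];
    const double* p2 = &x[3 * (i + 1)];
    const double* p3 = &x[3 * (i + 2)];
    const double* p4 = &x[3 * (i + 3)];
    double b1[3], b2[3], b3[3];
    vsub(p2, p1, b1);
    vsub(p3, p2, b2);
    vsub(p4, p3, b3);
    double n1[3], n2[3];
    vcross(b1, b2, n1);
    vcross(b2, b3, n2);
    double nb2 = std::sqrt(vdot(b2, b2));
    double m1[3];
    vcross(n1, b2, m1);
    double xx = vdot(n1, n2);
    double yy = vdot(m1, n2) / nb2;
    double phi = std::atan2(yy, xx);
    double dphi = phi - p.phi0;
    e_tor += p.torsion_k * (1.0 - std::cos(dphi));
    double dEdphi = p.torsion_k * std::sin(dphi);
    // analytic dphi/dr for the atan2(y, x) convention above
    // (validated against central differences)
    double n1sq = vdot(n1, n1), n2sq = vdot(n2, n2);
    if (n1sq < 1e-12) n1sq = 1e-12;
    if (n2sq < 1e-12) n2sq = 1e-12;
    double dp1[3], dp4[3];
    for (int k = 0; k < 3; ++k) {
      dp1[k] = nb2 / n1sq * n1[k];
      dp4[k] = -nb2 / n2sq * n2[k];
    }
    double a12 = vdot(b1, b2) / (nb2 * nb2), a32 = vdot(b3, b2) / (nb2 * nb2);
    double dp2[3], dp3[3];
    for (int k = 0; k < 3; ++k) {
      dp2[k] = -(1.0 + a12) * dp1[k] + a32 * dp4[k];
      dp3[k] = a12 * dp1[k] - (1.0 + a32) * dp4[k];
    }
    for (int k = 0; k < 3; ++k) {
      double g1 = dEdphi * dp1[k], g2 = dEdphi * dp2[k];
      double g3 = dEdphi * dp3[k], g4 = dEdphi * dp4[k];
      g[3 * i + k] += g1;  gD[3 * i + k] += g1;
      g[3 * (i + 1) + k] += g2; gD[3 * (i + 1) + k] += g2;
      g[3 * (i + 2) + k] += g3; gD[3 * (i + 2) + k] += g3;
      g[3 * (i + 3) + k] += g4; gD[3 * (i + 3) + k] += g4;
    }
  }

  // native contacts: 12-10 Go well, min -eps at r = sigma_ij
  for (size_t m = 0; m < p.ci.size(); ++m) {
    const double* a = &x[3 * p.ci[m]];
    const double* b = &x[3 * p.cj[m]];
    double d[3];
    vsub(b, a, d);
    double r2 = vdot(d, d), r = std::sqrt(r2);
    double s = p.csig[m] / r;
    double s2 = s * s;
    double s10 = s2 * s2 * s2 * s2 * s2;
    double s12 = s10 * s2;
    e_con += p.eps * (5.0 * s12 - 6.0 * s10);
    // dE/dr = eps*(-60 s12 + 60 s10)/r
    double dEdr = 60.0 * p.eps * (s10 - s12) / r;
    double c = dEdr / r;
    for (int k = 0; k < 3; ++k) {
      g[3 * p.cj[m] + k] += c * d[k];
      g[3 * p.ci[m] + k] -= c * d[k];
    }
  }

  // excluded volume on non-native pairs: eps_rep*(sigma/r)^12
  for (size_t m = 0; m < p.ri.size(); ++m) {
    const double* a = &x[3 * p.ri[m]];
    const double* b = &x[3 * p.rj[m]];
    double d[3];
    vsub(b, a, d);
    double r2 = vdot(d, d), r = std::sqrt(r2);
    double s = p.rep_sigma / r;
    double s2 = s * s;
    double s12 = s2 * s2 * s2 * s2 * s2 * s2;
    e_rep += p.rep_eps * s12;
    double dEdr = -12.0 * p.rep_eps * s12 / r;
    double c = dEdr / r;
    for (int k = 0; k < 3; ++k) {
      g[3 * p.rj[m] + k] += c * d[k];
      g[3 * p.ri[m] + k] -= c * d[k];
    }
  }

  if (terms) {
    terms[0] = e_bond; terms[1] = e_ang; terms[2] = e_tor;
    terms[3] = e_con; terms[4] = e_rep;
  }
  SysEval e;
  e.V = e_bond + e_ang + e_tor + e_con + e_rep;
  e.VD = e_tor;
  return e;
}

// Dispatcher ----------------------------------------------------------------

class SystemEvaluator {
public:
  int kind; // 0 double_well, 1 harmonic, 2 cg_helix
  double h, w, kharm;
  HelixParams hp;
  int ncoord;

  explicit SystemEvaluator(const List& sys) {
    std::string k = as<std::string>(sys["kind"]);
    int n = as<int>(sys["n_particles"]);
    int dim = as<int>(sys["dim"]);
    ncoord = n * dim;
    if (k == "double_well") {
      kind = 0;
      List par = sys["params"];
      h = as<double>(par["barrier_height"]);
      w = as<double>(par["half_separation"]);
    } else if (k == "harmonic") {
      kind = 1;
      List par = sys["params"];
      kharm = as<double>(par["force_constant"]);
    } else if (k == "cg_helix") {
      kind = 2;
      hp = parse_helix(sys);
    } else {
      stop("unknown system kind: %s", k);
    }
  }

  SysEval eval(const std::vector<double>& x, std::vector<double>& g,
               std::vector<double>& gD, double* terms = nullptr) const {
    switch (kind) {
    case 0: {
      SysEval e = eval_dwell(h, w, x, g, gD);
      if (terms) terms[0] = e.V;
      return e;
    }
    case 1: {
      SysEval e = eval_harm(kharm, x, g, gD);
      if (terms) terms[0] = e.V;
      return e;
    }
    default:
      return eval_helix(hp, x, g, gD, terms);
    }
  }
};

// ---------------------------------------------------------------------------
// Boost bias
// ---------------------------------------------------------------------------

static inline double boost_e(double V, double E, double a) {
  if (V >= E) return 0.0;
  double u = E - V;
  return u * u / (a + u);
}
static inline double boost_s(double V, double E, double a) {
  if (V >= E) return 1.0;
  double u = E - V;
  return (a * a) / ((a + u) * (a + u));
}

struct BoostSpec {
  int mode;         // 0 none, 1 dihedral, 2 total, 3 dual
  int composition;  // 0 additive, 1 nested
  double EP, aP, ED, aD;
};

static BoostSpec parse_boost(const List& boost) {
  BoostSpec b;
  b.mode = as<int>(boost["mode_int"]);
  b.composition = as<int>(boost["composition_int"]);
  b.EP = b.aP = b.ED = b.aD = 0.0;
  if (b.mode == 2 || b.mode == 3) {
    b.EP = as<double>(boost["E_P"]);
    b.aP = as<double>(boost["alpha_P"]);
  }
  if (b.mode == 1 || b.mode == 3) {
    b.ED = as<double>(boost["E_D"]);
    b.aD = as<double>(boost["alpha_D"]);
  }
  return b;
}

// Applies the bias: returns deltaV and overwrites g with grad of V' = V + deltaV.
static double apply_boost(const BoostSpec& b, double V, double VD,
                          std::vector<double>& g,
                          const std::vector<double>& gD) {
  if (b.mode == 0) return 0.0;
  if (b.composition == 0) {
    // literal additive composition
    double dV = 0.0, sP = 1.0, sD = 1.0;
    if (b.mode == 2 || b.mode == 3) {
      dV += boost_e(V, b.EP, b.aP);
      sP = boost_s(V, b.EP, b.aP);
    }
    if (b.mode == 1 || b.mode == 3) {
      dV += boost_e(VD, b.ED, b.aD);
      sD = boost_s(VD, b.ED, b.aD);
    }
    for (size_t k = 0; k < g.size(); ++k)
      g[k] = sP * g[k] + (sD - 1.0) * gD[k];
    return dV;
  }
  // nested: dihedral boost first, its result fed to the total boost
  double bD = 0.0, sD = 1.0;
  if (b.mode == 1 || b.mode == 3) {
    bD = boost_e(VD, b.ED, b.aD);
    sD = boost_s(VD, b.ED, b.aD);
  }
  double Vstar = V + bD;
  double bP = 0.0, sP = 1.0;
  if (b.mode == 2 || b.mode == 3) {
    bP = boost_e(Vstar, b.EP, b.aP);
    sP = boost_s(Vstar, b.EP, b.aP);
  }
  for (size_t k = 0; k < g.size(); ++k)
    g[k] = sP * (g[k] + (sD - 1.0) * gD[k]);
  return bD + bP;
}

// ---------------------------------------------------------------------------
// Exposed evaluators
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_energy")]]
List cpp_energy(List sys, NumericVector coords) {
  SystemEvaluator ev(sys);
  std::vector<double> x(coords.begin(), coords.end());
  std::vector<double> g(ev.ncoord), gD(ev.ncoord);
  double terms[5] = {0, 0, 0, 0, 0};
  SysEval e = ev.eval(x, g, gD, terms);
  NumericVector tv;
  if (ev.kind == 2) {
    tv = NumericVector::create(_["bond"] = terms[0], _["angle"] = terms[1],
                               _["torsion"] = terms[2], _["contact"] = terms[3],
                               _["repulsion"] = terms[4]);
  } else {
    tv = NumericVector::create(_["well"] = terms[0]);
  }
  return List::create(_["V"] = e.V, _["V_D"] = e.VD, _["terms"] = tv,
                      _["gradient"] = NumericVector(g.begin(), g.end()),
                      _["gradient_D"] = NumericVector(gD.begin(), gD.end()));
}

// grad of V' = V + deltaV for a given boost; also returns deltaV
// [[Rcpp::export(name = ".cpp_boosted_gradient")]]
List cpp_boosted_gradient(List sys, NumericVector coords, List boost) {
  SystemEvaluator ev(sys);
  BoostSpec b = parse_boost(boost);
  std::vector<double> x(coords.begin(), coords.end());
  std::vector<double> g(ev.ncoord), gD(ev.ncoord);
  SysEval e = ev.eval(x, g, gD);
  double dV = apply_boost(b, e.V, e.VD, g, gD);
  return List::create(_["deltaV"] = dV,
                      _["gradient"] = NumericVector(g.begin(), g.end()),
                      _["V"] = e.V, _["V_D"] = e.VD);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_langevin_run")]]
List cpp_langevin_run(List sys, NumericVector x0, NumericVector v0,
                      NumericVector masses, double dt, int n_steps,
                      int save_interval, double gamma, double temperature,
                      int heat_ramp_steps, List boost, double energy_ceiling) {
  SystemEvaluator ev(sys);
  BoostSpec b = parse_boost(boost);
  const int nc = ev.ncoord;
  const int n_part = masses.size();
  const int dim = nc / n_part;

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> g(nc), gD(nc), f(nc);
  std::vector<double> minv(nc), msqrt(nc);
  for (int i = 0; i < n_part; ++i)
    for (int k = 0; k < dim; ++k) {
      minv[i * dim + k] = 1.0 / masses[i];
      msqrt[i * dim + k] = std::sqrt(KFAC * KBOLTZ / masses[i]);
    }

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const int ndof = nc;

  int n_save = n_steps / save_interval + 1; // includes the initial frame
  NumericMatrix out_x(n_save, nc);
  NumericVector out_t(n_save), out_V(n_save), out_VD(n_save), out_dV(n_save),
      out_T(n_save);
  int isave = 0;
  int status = 0; // 0 ok, 1 diverged
  int fail_step = -1;

  SysEval e = ev.eval(x, g, gD);
  double dV = apply_boost(b, e.V, e.VD, g, gD);

  auto record = [&](int step) {
    double ke = 0.0;
    for (int k = 0; k < nc; ++k) ke += masses[k / dim] * v[k] * v[k];
    ke /= (2.0 * KFAC);
    out_t[isave] = step * dt;
    for (int k = 0; k < nc; ++k) out_x(isave, k) = x[k];
    out_V[isave] = e.V;
    out_VD[isave] = e.VD;
    out_dV[isave] = dV;
    out_T[isave] = 2.0 * ke / (ndof * KBOLTZ);
    ++isave;
  };
  record(0);

  for (int step = 0; step < n_steps; ++step) {
    double Tt = temperature;
    if (heat_ramp_steps > 0 && step < heat_ramp_steps)
      Tt = temperature * (double)(step + 1) / (double)heat_ramp_steps;
    double sT = std::sqrt(Tt);

    for (int k = 0; k < nc; ++k) v[k] += 0.5 * dt * KFAC * (-g[k]) * minv[k];
    for (int k = 0; k < nc; ++k) x[k] += 0.5 * dt * v[k];
    if (gamma > 0.0) {
      for (int k = 0; k < nc; ++k)
        v[k] = c1 * v[k] + c2 * msqrt[k] * sT * R::norm_rand();
    }
    for (int k = 0; k < nc; ++k) x[k] += 0.5 * dt * v[k];
    e = ev.eval(x, g, gD);
    dV = apply_boost(b, e.V, e.VD, g, gD);
    if (!std::isfinite(e.V) || std::fabs(e.V) > energy_ceiling) {
      status = 1;
      fail_step = step;
      break;
    }
    for (int k = 0; k < nc; ++k) v[k] += 0.5 * dt * KFAC * (-g[k]) * minv[k];

    if ((step + 1) % save_interval == 0) record(step + 1);
  }

  if (isave < n_save) { // divergence: truncate
    out_x = out_x(Range(0, std::max(isave - 1, 0)), _);
    out_t = head(out_t, isave);
    out_V = head(out_V, isave);
    out_VD = head(out_VD, isave);
    out_dV = head(out_dV, isave);
    out_T = head(out_T, isave);
  }

  return List::create(
      _["coords"] = out_x, _["time_ps"] = out_t, _["V"] = out_V,
      _["V_D"] = out_VD, _["deltaV"] = out_dV, _["T_inst"] = out_T,
      _["final_x"] = NumericVector(x.begin(), x.end()),
      _["final_v"] = NumericVector(v.begin(), v.end()),
      _["status"] = status, _["fail_step"] = fail_step);
}

// First-passage stepper for 1-D systems: runs until coordinate >= target
// (or <= target when approaching from above), returns step count or -1.
// [[Rcpp::export(name = ".cpp_first_passage")]]
int cpp_first_passage(List sys, NumericVector x0, NumericVector v0,
                      NumericVector masses, double dt, int max_steps,
                      double gamma, double temperature, List boost,
                      double target, bool from_below) {
  SystemEvaluator ev(sys);
  BoostSpec b = parse_boost(boost);
  const int nc = ev.ncoord;
  if (nc != 1) stop("first-passage stepper supports 1-D single-particle systems only");
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> g(1), gD(1);
  const double minv = 1.0 / masses[0];
  const double msq = std::sqrt(KFAC * KBOLTZ * temperature / masses[0]);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);

  SysEval e = ev.eval(x, g, gD);
  apply_boost(b, e.V, e.VD, g, gD);
  for (int step = 0; step < max_steps; ++step) {
    v[0] += 0.5 * dt * KFAC * (-g[0]) * minv;
    x[0] += 0.5 * dt * v[0];
    if (gamma > 0.0) v[0] = c1 * v[0] + c2 * msq * R::norm_rand();
    x[0] += 0.5 * dt * v[0];
    e = ev.eval(x, g, gD);
    apply_boost(b, e.V, e.VD, g, gD);
    v[0] += 0.5 * dt * KFAC * (-g[0]) * minv;
    if (from_below ? (x[0] >= target) : (x[0] <= target)) return step + 1;
  }
  return -1;
}
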