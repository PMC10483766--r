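// Forward-dynamic engine for the planar 7-segment / 9-DOF walking model.
//
// The R layer compiles the YAML model configuration into flat numeric
// arrays (see compile_model() in R/model.R); this file implements the
// per-step physics: tree kinematics with analytic Jacobians, mass-matrix
// assembly, Hill-type muscle-tendon dynamics (equilibrium formulation with
// fiber damping), Hunt-Crossley sphere contact, knee-ligament and AFO
// torques, the gait-phase reflex controller, and the muscle energetics
// accumulator.  Scalar primitives (curves, torques, contact law,
// excitations) are exported individually so the R API wrappers and the
// engine share one implementation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DEG = 57.29577951308232; // degrees per radian

// ---------------------------------------------------------------------------
// Hill-type curve primitives
// ---------------------------------------------------------------------------

struct Curves {
  double fl_width, kpe, e0, eps_iso, kten, fvmax, af, beta;
};

static inline double fl_active(double l, const Curves& c) {
  double d = (l - 1.0) / c.fl_width;
  return std::exp(-d * d);
}

static inline double fl_passive(double l, const Curves& c) {
  if (l <= 1.0) return 0.0;
  return std::expm1(c.kpe * (l - 1.0) / c.e0) / std::expm1(c.kpe);
}

static inline double tendon_fl(double eps, const Curves& c) {
  if (eps <= 0.0) return 0.0;
  return std::expm1(c.kten * eps / c.eps_iso) / std::expm1(c.kten);
}

// force-velocity: v normalized to max shortening velocity, shortening < 0
static inline double fv(double v, const Curves& c) {
  if (v <= -1.0) return 0.0;
  if (v <= 0.0) return (1.0 + v) / (1.0 - v / c.af);
  // lengthening branch: slope at 0 twice the shortening slope, saturating
  double s0 = 2.0 * (1.0 + 1.0 / c.af);
  double c3 = (c.fvmax - 1.0) / s0;
  return c.fvmax - (c.fvmax - 1.0) * c3 / (c3 + v);
}

// [[Rcpp::export]]
NumericVector cpp_hill_curves(NumericVector x, std::string which,
                              NumericVector constants) {
  Curves c{constants[0], constants[1], constants[2], constants[3],
           constants[4], constants[5], constants[6], constants[7]};
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    if (which == "active_fl") out[i] = fl_active(x[i], c);
    else if (which == "passive_fl") out[i] = fl_passive(x[i], c);
    else if (which == "tendon_fl") out[i] = tendon_fl(x[i], c);
    else if (which == "fv") out[i] = fv(x[i], c);
    else stop("unknown curve '%s'", which.c_str());
  }
  return out;
}

// exact first-order activation update over one step
static inline double act_update(double u, double a, double dt,
                                double tact, double tdeact) {
  u = std::min(1.0, std::max(0.0, u));
  double tau = (u > a) ? tact : tdeact;
  double an = u + (a - u) * std::exp(-dt / tau);
  return std::min(1.0, std::max(0.0, an));
}

// [[Rcpp::export]]
double cpp_activation_update(double u, double a, double dt,
                             double tau_act, double tau_deact) {
  return act_update(u, a, dt, tau_act, tau_deact);
}

// ---------------------------------------------------------------------------
// Passive joint structures
// ---------------------------------------------------------------------------

// knee ligament: engages beyond flex_limit degrees of flexion or when the
// knee extends beyond ext_limit degrees of flexion; the spring resists the
// excursion and the damper acts only while the spring is engaged.  Angle in
// degrees flexion, velocity in deg/s; torque in Nm, positive toward flexion.
// [[Rcpp::export]]
double cpp_knee_ligament_torque(double angle_deg, double angvel_degs,
                                double k, double c, double flex_limit,
                                double ext_limit) {
  if (angle_deg < ext_limit)           // hyperextension side
    return k * (ext_limit - angle_deg) - c * angvel_degs;
  if (angle_deg > flex_limit)          // deep-flexion side
    return -k * (angle_deg - flex_limit) - c * angvel_degs;
  return 0.0;
}

// AFO torsional spring, neutral at 0 degrees; angle dorsiflexion-positive.
// [[Rcpp::export]]
double cpp_afo_torque(double ankle_angle_deg, double K_afo) {
  if (K_afo < 0) stop("AFO stiffness must be >= 0");
  return -K_afo * ankle_angle_deg;
}

// ---------------------------------------------------------------------------
// Hunt-Crossley contact
// ---------------------------------------------------------------------------

struct ContactPars { double k, n, c, mu, vreg; };

static inline void hc_force(double depth, double drate, double vt,
                            const ContactPars& p, double& fn, double& ft) {
  if (depth <= 0.0) { fn = 0.0; ft = 0.0; return; }
  fn = p.k * std::pow(depth, p.n) * (1.0 + p.c * drate);
  if (fn < 0.0) fn = 0.0;               // never adhesive
  ft = -p.mu * fn * std::tanh(vt / p.vreg);
}

// [[Rcpp::export]]
NumericVector cpp_contact_force(double depth, double depth_rate,
                                double tangential_vel, double stiffness,
                                double exponent, double dissipation,
                                double friction, double v_reg) {
  ContactPars p{stiffness, exponent, dissipation, friction, v_reg};
  double fn, ft;
  hc_force(depth, depth_rate, tangential_vel, p, fn, ft);
  return NumericVector::create(_["normal"] = fn, _["tangential"] = ft);
}

// ---------------------------------------------------------------------------
// Compiled model unpacking
// ---------------------------------------------------------------------------

struct Model {
  int nseg, nq, nm;
  arma::ivec parent;          // nseg, -1 for root
  arma::mat G;                // nseg x nq angle mapping (constant)
  arma::mat anchor, com;      // nseg x 2 (local)
  arma::vec mass, inertia;
  double grav, body_mass;
  // muscles
  arma::vec m_fmax, m_lopt, m_lslack, m_h, m_vmax, m_tact, m_tdeact,
      m_fpas, m_ften, m_delay;
  arma::ivec path_seg, path_ptr;  // concatenated path points
  arma::mat path_xy;
  Curves curves;
  // contact
  arma::ivec sph_seg;
  arma::mat sph_xy;
  arma::vec sph_r;
  ContactPars cpars;
  // passive joints
  double lig_k, lig_c, lig_flex, lig_ext;
  arma::ivec knee_q, ankle_q, hip_q;   // coordinate indices per leg (R,L)
  arma::ivec foot_seg;                 // per leg
  // metabolics
  double met_basal, met_act, met_maint, met_short, met_sigma, met_rho;
  // controller wiring
  arma::ivec r_target, r_type, r_source, r_mask, r_gain, r_l0;
  arma::ivec pd_muscle, pd_gain, pd_sign;
  int pd_theta0, pd_kdr, pd_mask;
  arma::ivec th_idx;                   // load_on, load_off, d_ls, d_la
  arma::ivec pose_idx;                 // pitch + 6 joints
  int vx_idx, npar;
  arma::ivec pf_local;                 // plantarflexor indices within a leg
  int head_seg; arma::vec head_xy;
};

static arma::ivec as_ivec(SEXP x) {
  IntegerVector v(x);
  arma::ivec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i];
  return out;
}

static Model unpack(const List& cm) {
  Model m;
  m.parent = as_ivec(cm["parent"]);
  m.nseg = m.parent.n_elem;
  m.G = as<arma::mat>(cm["G"]);
  m.nq = m.G.n_cols;
  m.anchor = as<arma::mat>(cm["anchor"]);
  m.com = as<arma::mat>(cm["com"]);
  m.mass = as<arma::vec>(cm["mass"]);
  m.inertia = as<arma::vec>(cm["inertia"]);
  m.grav = as<double>(cm["gravity"]);
  m.body_mass = as<double>(cm["body_mass"]);
  m.m_fmax = as<arma::vec>(cm["m_fmax"]);
  m.nm = m.m_fmax.n_elem;
  m.m_lopt = as<arma::vec>(cm["m_lopt"]);
  m.m_lslack = as<arma::vec>(cm["m_lslack"]);
  m.m_h = as<arma::vec>(cm["m_h"]);
  m.m_vmax = as<arma::vec>(cm["m_vmax"]);
  m.m_tact = as<arma::vec>(cm["m_tact"]);
  m.m_tdeact = as<arma::vec>(cm["m_tdeact"]);
  m.m_fpas = as<arma::vec>(cm["m_fpas"]);
  m.m_ften = as<arma::vec>(cm["m_ften"]);
  m.m_delay = as<arma::vec>(cm["m_delay"]);
  m.path_seg = as_ivec(cm["path_seg"]);
  m.path_ptr = as_ivec(cm["path_ptr"]);
  m.path_xy = as<arma::mat>(cm["path_xy"]);
  NumericVector cc(cm["curves"]);
  m.curves = Curves{cc[0], cc[1], cc[2], cc[3], cc[4], cc[5], cc[6], cc[7]};
  m.sph_seg = as_ivec(cm["sph_seg"]);
  m.sph_xy = as<arma::mat>(cm["sph_xy"]);
  m.sph_r = as<arma::vec>(cm["sph_r"]);
  NumericVector cp(cm["contact"]);
  m.cpars = ContactPars{cp[0], cp[1], cp[2], cp[3], cp[4]};
  NumericVector lg(cm["ligament"]);
  m.lig_k = lg[0]; m.lig_c = lg[1]; m.lig_flex = lg[2]; m.lig_ext = lg[3];
  m.knee_q = as_ivec(cm["knee_q"]);
  m.ankle_q = as_ivec(cm["ankle_q"]);
  m.hip_q = as_ivec(cm["hip_q"]);
  m.foot_seg = as_ivec(cm["foot_seg"]);
  NumericVector mt(cm["metab"]);
  m.met_basal = mt[0]; m.met_act = mt[1]; m.met_maint = mt[2];
  m.met_short = mt[3]; m.met_sigma = mt[4]; m.met_rho = mt[5];
  m.r_target = as_ivec(cm["r_target"]);
  m.r_type = as_ivec(cm["r_type"]);
  m.r_source = as_ivec(cm["r_source"]);
  m.r_mask = as_ivec(cm["r_mask"]);
  m.r_gain = as_ivec(cm["r_gain"]);
  m.r_l0 = as_ivec(cm["r_l0"]);
  m.pd_muscle = as_ivec(cm["pd_muscle"]);
  m.pd_gain = as_ivec(cm["pd_gain"]);
  m.pd_sign = as_ivec(cm["pd_sign"]);
  m.pd_theta0 = as<int>(cm["pd_theta0"]);
  m.pd_kdr = as<int>(cm["pd_kdr"]);
  m.pd_mask = as<int>(cm["pd_mask"]);
  m.th_idx = as_ivec(cm["th_idx"]);
  m.pose_idx = as_ivec(cm["pose_idx"]);
  m.vx_idx = as<int>(cm["vx_idx"]);
  m.npar = as<int>(cm["npar"]);
  m.pf_local = as_ivec(cm["pf_local"]);
  m.head_seg = as<int>(cm["head_seg"]);
  m.head_xy = as<arma::vec>(cm["head_xy"]);
  return m;
}

// ---------------------------------------------------------------------------
// Kinematics
// ---------------------------------------------------------------------------

struct Kin {
  arma::vec theta, thetad;            // nseg
  arma::mat O, vO, aO;                // nseg x 2 origins, velocities, bias acc
  std::vector<arma::mat> JO;          // per segment 2 x nq origin Jacobian
};

static inline arma::vec rot(double th, const arma::vec& v) {
  double c = std::cos(th), s = std::sin(th);
  return arma::vec{c * v[0] - s * v[1], s * v[0] + c * v[1]};
}
static inline arma::vec drot(double th, const arma::vec& v) {
  double c = std::cos(th), s = std::sin(th);
  return arma::vec{-s * v[0] - c * v[1], c * v[0] - s * v[1]};
}

static void kin_pass(const Model& m, const arma::vec& q, const arma::vec& qd,
                     Kin& K) {
  int ns = m.nseg, nq = m.nq;
  K.theta = m.G * q;
  K.thetad = m.G * qd;
  K.O.set_size(ns, 2); K.vO.set_size(ns, 2); K.aO.set_size(ns, 2);
  K.JO.assign(ns, arma::mat(2, nq, arma::fill::zeros));
  for (int s = 0; s < ns; ++s) {
    int p = m.parent[s];
    if (p < 0) {
      K.O.row(s) = arma::rowvec{q[0], q[1]};
      K.vO.row(s) = arma::rowvec{qd[0], qd[1]};
      K.aO.row(s).zeros();
      K.JO[s](0, 0) = 1.0; K.JO[s](1, 1) = 1.0;
    } else {
      arma::vec a = m.anchor.row(s).t();
      arma::vec Ra = rot(K.theta[p], a), dRa = drot(K.theta[p], a);
      K.O.row(s) = K.O.row(p) + Ra.t();
      K.vO.row(s) = K.vO.row(p) + (K.thetad[p] * dRa).t();
      K.aO.row(s) = K.aO.row(p) -
        (K.thetad[p] * K.thetad[p] * Ra).t();
      K.JO[s] = K.JO[p];
      for (int j = 0; j < nq; ++j)
        if (m.G(p, j) != 0.0) K.JO[s].col(j) += m.G(p, j) * dRa;
    }
  }
}

// world point on a segment plus its Jacobian / velocity / bias acceleration
struct PointK { arma::vec p, v, a; arma::mat J; };

static PointK point_kin(const Model& m, const Kin& K, int s,
                        const arma::vec& loc) {
  PointK pk;
  arma::vec Rl = rot(K.theta[s], loc), dRl = drot(K.theta[s], loc);
  pk.p = K.O.row(s).t() + Rl;
  pk.v = K.vO.row(s).t() + K.thetad[s] * dRl;
  pk.a = K.aO.row(s).t() - K.thetad[s] * K.thetad[s] * Rl;
  pk.J = K.JO[s];
  for (int j = 0; j < m.nq; ++j)
    if (m.G(s, j) != 0.0) pk.J.col(j) += m.G(s, j) * dRl;
  return pk;
}

// [[Rcpp::export]]
List cpp_kinematics(List cm, NumericVector q_, NumericVector qd_) {
  Model m = unpack(cm);
  arma::vec q = as<arma::vec>(q_), qd = as<arma::vec>(qd_);
  Kin K; kin_pass(m, q, qd, K);
  arma::mat comw(m.nseg, 2), comv(m.nseg, 2);
  for (int s = 0; s < m.nseg; ++s) {
    PointK pk = point_kin(m, K, s, m.com.row(s).t());
    comw.row(s) = pk.p.t(); comv.row(s) = pk.v.t();
  }
  return List::create(
      _["theta"] = NumericVector(K.theta.begin(), K.theta.end()),
      _["thetad"] = NumericVector(K.thetad.begin(), K.thetad.end()),
      _["origin"] = K.O, _["com"] = comw, _["com_vel"] = comv);
}

// [[Rcpp::export]]
NumericVector cpp_muscle_lengths(List cm, NumericVector q_) {
  Model m = unpack(cm);
  arma::vec q = as<arma::vec>(q_), qd(m.nq, arma::fill::zeros);
  Kin K; kin_pass(m, q, qd, K);
  NumericVector out(m.nm);
  for (int i = 0; i < m.nm; ++i) {
    double L = 0.0;
    for (int k = m.path_ptr[i]; k < m.path_ptr[i + 1] - 1; ++k) {
      PointK a = point_kin(m, K, m.path_seg[k], m.path_xy.row(k).t());
      PointK b = point_kin(m, K, m.path_seg[k + 1],
                           m.path_xy.row(k + 1).t());
      L += arma::norm(b.p - a.p);
    }
    out[i] = L;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Dynamics: mass matrix and generalized forces
// ---------------------------------------------------------------------------

static void mass_and_bias(const Model& m, const Kin& K, arma::mat& M,
                          arma::vec& Q) {
  int nq = m.nq;
  M.zeros(nq, nq); Q.zeros(nq);
  for (int s = 0; s < m.nseg; ++s) {
    PointK pc = point_kin(m, K, s, m.com.row(s).t());
    M += m.mass[s] * (pc.J.t() * pc.J);
    arma::rowvec g = m.G.row(s);
    M += m.inertia[s] * (g.t() * g);
    // gravity and velocity-product forces
    arma::vec fg{0.0, -m.mass[s] * m.grav};
    Q += pc.J.t() * fg;
    Q -= m.mass[s] * (pc.J.t() * pc.a);
  }
}

// [[Rcpp::export]]
List cpp_dynamics(List cm, NumericVector q_, NumericVector qd_,
                  NumericVector tau_, Nullable<NumericMatrix> extF_ = R_NilValue) {
  Model m = unpack(cm);
  arma::vec q = as<arma::vec>(q_), qd = as<arma::vec>(qd_);
  arma::vec tau = as<arma::vec>(tau_);
  Kin K; kin_pass(m, q, qd, K);
  arma::mat M; arma::vec Q;
  mass_and_bias(m, K, M, Q);
  Q += tau;
  if (extF_.isNotNull()) {
    NumericMatrix E(extF_);
    for (int r = 0; r < E.nrow(); ++r) {
      int s = (int)E(r, 0);
      arma::vec loc{E(r, 1), E(r, 2)}, F{E(r, 3), E(r, 4)};
      PointK pk = point_kin(m, K, s, loc);
      Q += pk.J.t() * F;
    }
  }
  arma::vec qdd = arma::solve(M, Q, arma::solve_opts::likely_sympd);
  return List::create(
      _["qdd"] = NumericVector(qdd.begin(), qdd.end()), _["M"] = M,
      _["rhs"] = NumericVector(Q.begin(), Q.end()));
}

// ---------------------------------------------------------------------------
// Controller
// ---------------------------------------------------------------------------

// gait phases: 0 early stance, 1 late stance, 2 liftoff, 3 swing, 4 landing
static int phase_next(int phase, double load, double contra_load, double dx,
                      double load_on, double load_off, double d_ls,
                      double d_la) {
  switch (phase) {
  case 0: if (dx < d_ls) return 1; break;
  case 1: if (contra_load > load_on) return 2; break;
  case 2: if (load < load_off) return 3; break;
  // landing triggers on forward swing distance or on early foot contact,
  // so a prematurely loaded leg can never sit in a swing phase
  case 3: if (dx > d_la || load > load_on) return 4; break;
  case 4: if (load > load_on) return 0; break;
  }
  return phase;
}

// [[Rcpp::export]]
int cpp_phase_next(int phase, double load, double contra_load, double dx,
                   double load_on, double load_off, double d_ls,
                   double d_la) {
  return phase_next(phase, load, contra_load, dx, load_on, load_off, d_ls,
                    d_la);
}

// muscle excitations from delayed force/length signals; the wiring is
// defined for one leg and applied to both with the leg's own phase.
static void excitations(const Model& m, const arma::vec& par, int phase_r,
                        int phase_l, const arma::vec& Fdel,
                        const arma::vec& Ldel, double pitch, double pitchd,
                        arma::vec& u) {
  u.zeros(m.nm);
  int nhalf = m.nm / 2;
  for (int leg = 0; leg < 2; ++leg) {
    int off = leg * nhalf;
    int ph = leg == 0 ? phase_r : phase_l;
    int bit = 1 << ph;
    for (arma::uword e = 0; e < m.r_target.n_elem; ++e) {
      if (!(m.r_mask[e] & bit)) continue;
      int tgt = m.r_target[e] + off;
      double g = par[m.r_gain[e]];
      switch (m.r_type[e]) {
      case 0: u[tgt] += g; break;                                // constant
      case 1: u[tgt] += g * Fdel[m.r_source[e] + off]; break;    // force
      case 2: {                                                  // length
        double l0 = par[m.r_l0[e]];
        double s = Ldel[m.r_source[e] + off] - l0;
        if (s > 0) u[tgt] += g * s;
        break; }
      }
    }
    if (m.pd_mask & bit) {
      double th0 = par[m.pd_theta0], kdr = par[m.pd_kdr];
      double s = (pitch - th0) + kdr * pitchd;
      for (arma::uword e = 0; e < m.pd_muscle.n_elem; ++e)
        u[m.pd_muscle[e] + off] += m.pd_sign[e] * par[m.pd_gain[e]] * s;
    }
  }
  for (int i = 0; i < m.nm; ++i) u[i] = std::min(1.0, std::max(0.0, u[i]));
}

// [[Rcpp::export]]
NumericVector cpp_excitations(List cm, NumericVector par_, int phase_r,
                              int phase_l, NumericVector Fdel_,
                              NumericVector Ldel_, double pitch,
                              double pitchd) {
  Model m = unpack(cm);
  arma::vec par = as<arma::vec>(par_), Fdel = as<arma::vec>(Fdel_),
            Ldel = as<arma::vec>(Ldel_), u;
  excitations(m, par, phase_r, phase_l, Fdel, Ldel, pitch, pitchd, u);
  return wrap(u);
}

// ---------------------------------------------------------------------------
// Muscle fiber dynamics
// ---------------------------------------------------------------------------

// solve the damped equilibrium a*fl*fv(v) + fpas + beta*v = Ft/cos(phi)
// for the normalized fiber velocity v (monotone in v); bisection.
static double solve_fiber_vel(double a, double flv, double fpas,
                              double rhs, const Curves& c) {
  double lo = -1.0, hi = 1.5;
  auto h = [&](double v) { return a * flv * fv(v, c) + fpas + c.beta * v - rhs; };
  if (h(lo) >= 0.0) return lo;
  while (h(hi) < 0.0) { hi *= 2.0; if (hi > 64.0) return 64.0; }
  for (int it = 0; it < 48; ++it) {
    double mid = 0.5 * (lo + hi);
    if (h(mid) < 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

static inline double cos_penn(double lnorm, double h) {
  if (h <= 0.0) return 1.0;
  double s = h / std::max(lnorm, h + 1e-6);
  return std::sqrt(std::max(1.0 - s * s, 1e-6));
}

// [[Rcpp::export]]
double cpp_solve_fiber_vel(double a, double flv, double fpas, double rhs,
                           NumericVector constants) {
  Curves c{constants[0], constants[1], constants[2], constants[3],
           constants[4], constants[5], constants[6], constants[7]};
  return solve_fiber_vel(a, flv, fpas, rhs, c);
}

// static equilibrium: find normalized fiber length such that the tendon
// force balances the (isometric) fiber force for a given MTU length
static double static_fiber_length(const Model& m, int i, double lmt,
                                  double a) {
  const Curves& c = m.curves;
  double lopt = m.m_lopt[i], lsl = m.m_lslack[i], h = m.m_h[i] / lopt;
  double lo = 0.2, hi = 1.9;
  auto bal = [&](double ln) {
    double cp = cos_penn(ln, h);
    double lt = lmt - ln * lopt * cp;
    double ft = m.m_ften[i] * tendon_fl(lt / lsl - 1.0, c);
    double ff = (a * fl_active(ln, c) + m.m_fpas[i] * fl_passive(ln, c)) * cp;
    return ff - ft;   // increasing in ln
  };
  if (bal(lo) > 0.0) return lo;
  if (bal(hi) < 0.0) return hi;
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    if (bal(mid) < 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// ---------------------------------------------------------------------------
// Main simulation loop
// ---------------------------------------------------------------------------
//
// The loop below re-implements the generic kinematics above with
// preallocated flat arrays (no per-step heap allocation): one forward pass
// per step computing segment frames, then cached position/velocity/Jacobian
// blocks for every muscle path point and contact sphere.

namespace {

constexpr int NQ = 9;

struct FastKin {
  double th[8], thd[8];
  double O[8][2], vO[8][2], aO[8][2];
  double JO[8][2 * NQ];
};

struct SegDeps {            // nonzero entries of one row of G
  int n;
  int idx[6];
  double val[6];
};

inline void kin_fast(const Model& m, const std::vector<SegDeps>& deps,
                     const double* q, const double* qd, FastKin& K) {
  int ns = m.nseg;
  for (int s = 0; s < ns; ++s) {
    double th = 0, thd = 0;
    for (int k = 0; k < deps[s].n; ++k) {
      th += deps[s].val[k] * q[deps[s].idx[k]];
      thd += deps[s].val[k] * qd[deps[s].idx[k]];
    }
    K.th[s] = th; K.thd[s] = thd;
    int p = m.parent[s];
    if (p < 0) {
      K.O[s][0] = q[0]; K.O[s][1] = q[1];
      K.vO[s][0] = qd[0]; K.vO[s][1] = qd[1];
      K.aO[s][0] = K.aO[s][1] = 0.0;
      std::fill(K.JO[s], K.JO[s] + 2 * NQ, 0.0);
      K.JO[s][0] = 1.0; K.JO[s][NQ + 1] = 1.0;
    } else {
      double ax = m.anchor(s, 0), ay = m.anchor(s, 1);
      double c = std::cos(K.th[p]), sn = std::sin(K.th[p]);
      double Rx = c * ax - sn * ay, Ry = sn * ax + c * ay;
      double dRx = -sn * ax - c * ay, dRy = c * ax - sn * ay;
      K.O[s][0] = K.O[p][0] + Rx;  K.O[s][1] = K.O[p][1] + Ry;
      K.vO[s][0] = K.vO[p][0] + K.thd[p] * dRx;
      K.vO[s][1] = K.vO[p][1] + K.thd[p] * dRy;
      double w2 = K.thd[p] * K.thd[p];
      K.aO[s][0] = K.aO[p][0] - w2 * Rx;
      K.aO[s][1] = K.aO[p][1] - w2 * Ry;
      std::copy(K.JO[p], K.JO[p] + 2 * NQ, K.JO[s]);
      for (int k = 0; k < deps[p].n; ++k) {
        int j = deps[p].idx[k]; double g = deps[p].val[k];
        K.JO[s][j] += g * dRx;
        K.JO[s][NQ + j] += g * dRy;
      }
    }
  }
}

// point on segment s at local (lx, ly): position, velocity, bias
// acceleration and (optionally) Jacobian
inline void pt_fast(const FastKin& K, const SegDeps& dep, int s, double lx,
                    double ly, double* p, double* v, double* a, double* J) {
  double c = std::cos(K.th[s]), sn = std::sin(K.th[s]);
  double Rx = c * lx - sn * ly, Ry = sn * lx + c * ly;
  double dRx = -sn * lx - c * ly, dRy = c * lx - sn * ly;
  p[0] = K.O[s][0] + Rx;  p[1] = K.O[s][1] + Ry;
  if (v) {
    v[0] = K.vO[s][0] + K.thd[s] * dRx;
    v[1] = K.vO[s][1] + K.thd[s] * dRy;
  }
  if (a) {
    double w2 = K.thd[s] * K.thd[s];
    a[0] = K.aO[s][0] - w2 * Rx;
    a[1] = K.aO[s][1] - w2 * Ry;
  }
  if (J) {
    std::copy(K.JO[s], K.JO[s] + 2 * NQ, J);
    for (int k = 0; k < dep.n; ++k) {
      int j = dep.idx[k]; double g = dep.val[k];
      J[j] += g * dRx;
      J[NQ + j] += g * dRy;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate(List cm, NumericVector par_, List opt) {
  Model m = unpack(cm);
  arma::vec par = as<arma::vec>(par_);
  const Curves& cv = m.curves;

  double duration = as<double>(opt["duration"]);
  double dt = as<double>(opt["dt"]);
  double record_dt = as<double>(opt["record_dt"]);
  double K_afo = as<double>(opt["K_afo"]);
  double transient = as<double>(opt["transient"]);
  double fall_frac = as<double>(opt["fall_frac"]);
  bool use_muscles = as<bool>(opt["use_muscles"]);
  bool use_contact = as<bool>(opt["use_contact"]);
  bool use_controller = as<bool>(opt["use_controller"]);
  bool use_gravity = opt.containsElementNamed("use_gravity") ?
    as<bool>(opt["use_gravity"]) : true;
  double act_thresh = as<double>(opt["act_threshold"]);
  arma::ivec lock;
  if (opt.containsElementNamed("lock") && !Rf_isNull(opt["lock"]))
    lock = as_ivec(opt["lock"]);
  double saved_grav = m.grav;
  if (!use_gravity) m.grav = 0.0;

  const int nq = NQ, nm = m.nm, ns = m.nseg, nhalf = nm / 2;

  std::vector<SegDeps> deps(ns);
  for (int s = 0; s < ns; ++s) {
    deps[s].n = 0;
    for (int j = 0; j < nq; ++j)
      if (m.G(s, j) != 0.0) {
        deps[s].idx[deps[s].n] = j;
        deps[s].val[deps[s].n] = m.G(s, j);
        ++deps[s].n;
      }
  }

  // initial state
  double q[NQ] = {0}, qd[NQ] = {0};
  if (opt.containsElementNamed("init_q") && !Rf_isNull(opt["init_q"])) {
    NumericVector iq(opt["init_q"]);
    for (int j = 0; j < nq; ++j) q[j] = iq[j];
    if (opt.containsElementNamed("init_qd") && !Rf_isNull(opt["init_qd"])) {
      NumericVector iqd(opt["init_qd"]);
      for (int j = 0; j < nq; ++j) qd[j] = iqd[j];
    }
  } else {
    q[2] = par[m.pose_idx[0]];
    for (int j = 0; j < 6; ++j) q[3 + j] = par[m.pose_idx[1 + j]];
    qd[0] = par[m.vx_idx];
  }
  FastKin K;
  bool settle = opt.containsElementNamed("settle_y") ?
    as<bool>(opt["settle_y"]) : true;
  if (settle) {
    kin_fast(m, deps, q, qd, K);
    double low = 1e9, p[2];
    for (arma::uword s = 0; s < m.sph_seg.n_elem; ++s) {
      pt_fast(K, deps[m.sph_seg[s]], m.sph_seg[s], m.sph_xy(s, 0),
              m.sph_xy(s, 1), p, nullptr, nullptr, nullptr);
      low = std::min(low, p[1] - m.sph_r[s]);
    }
    q[1] -= low;
  }
  const double y0 = q[1];

  // muscle state and cached path-point buffers
  const int npts = m.path_ptr[nm];
  std::vector<double> ppos(2 * npts), pvel(2 * npts), pJ(2 * NQ * npts);
  arma::vec act(nm, arma::fill::zeros), lm(nm, arma::fill::ones);
  arma::vec Fmt(nm, arma::fill::zeros), vmv(nm, arma::fill::zeros);
  arma::vec lmt(nm, arma::fill::zeros);
  double a_init = opt.containsElementNamed("init_act") ?
    as<double>(opt["init_act"]) : 0.02;

  auto path_points = [&](bool withJ) {
    for (int k = 0; k < npts; ++k) {
      int s = m.path_seg[k];
      pt_fast(K, deps[s], s, m.path_xy(k, 0), m.path_xy(k, 1),
              &ppos[2 * k], &pvel[2 * k], nullptr,
              withJ ? &pJ[2 * NQ * k] : nullptr);
    }
  };
  auto mtu_from_points = [&]() {
    for (int i = 0; i < nm; ++i) {
      double s = 0.0;
      for (int k = m.path_ptr[i]; k < m.path_ptr[i + 1] - 1; ++k) {
        double dx = ppos[2 * (k + 1)] - ppos[2 * k];
        double dy = ppos[2 * (k + 1) + 1] - ppos[2 * k + 1];
        s += std::sqrt(dx * dx + dy * dy);
      }
      lmt[i] = s;
    }
  };
  if (use_muscles) {
    kin_fast(m, deps, q, qd, K);
    path_points(false);
    mtu_from_points();
    for (int i = 0; i < nm; ++i) {
      act[i] = a_init;
      lm[i] = static_fiber_length(m, i, lmt[i], a_init);
    }
  }

  // neural delay ring buffers
  int maxdel = 1;
  arma::ivec dsteps(nm);
  for (int i = 0; i < nm; ++i) {
    dsteps[i] = std::max(1, (int)std::lround(m.m_delay[i] / dt));
    maxdel = std::max(maxdel, dsteps[i] + 1);
  }
  arma::mat bufF(maxdel, nm, arma::fill::zeros),
            bufL(maxdel, nm, arma::fill::ones);
  int bufpos = 0;

  // controller state
  int phase_r = 0, phase_l = 2;
  double load_on = par[m.th_idx[0]], load_off = par[m.th_idx[1]];
  double d_ls = par[m.th_idx[2]], d_la = par[m.th_idx[3]];

  // free coordinates (box for locked-joint audits)
  std::vector<int> freeq;
  for (int j = 0; j < nq; ++j) {
    bool locked = false;
    for (arma::uword l = 0; l < lock.n_elem; ++l)
      if (lock[l] == j) locked = true;
    if (!locked) freeq.push_back(j);
  }
  const int nf = (int)freeq.size();

  // recording
  int nstep = (int)std::ceil(duration / dt);
  int rec_every = std::max(1, (int)std::lround(record_dt / dt));
  int nrec = nstep / rec_every + 2;
  arma::mat R_q(nrec, nq), R_qd(nrec, nq), R_act(nrec, nm), R_F(nrec, nm),
      R_lm(nrec, nm), R_grf(nrec, 6), R_u(nrec, nm);
  arma::vec R_t(nrec);
  arma::ivec R_ph(2 * nrec);
  int irec = 0;

  bool fell = false;
  double E_met = 0.0, head_acc_sum = 0.0, head_n = 0.0;
  double joint_viol = 0.0, act_excess = 0.0, afo_work = 0.0;
  double x_w0 = NA_REAL, t_w0 = NA_REAL;
  double grfR[3] = {0, 0, 0}, grfL[3] = {0, 0, 0};
  double t = 0.0, t_end = 0.0;
  arma::vec u(nm, arma::fill::zeros), Fdel(nm), Ldel(nm);

  double M9[NQ * NQ], Q9[NQ], Jbuf[2 * NQ], pbuf[2], vbuf[2], abuf[2];
  arma::vec qdd_v(nq);

  for (int step = 0; step <= nstep; ++step) {
    t = step * dt;
    kin_fast(m, deps, q, qd, K);

    std::fill(Q9, Q9 + nq, 0.0);

    // ---- contact ----
    double newR[3] = {0, 0, 0}, newL[3] = {0, 0, 0};
    double copR = 0.0, copL = 0.0;
    if (use_contact) {
      for (arma::uword s = 0; s < m.sph_seg.n_elem; ++s) {
        int seg = m.sph_seg[s];
        double c = std::cos(K.th[seg]), sn = std::sin(K.th[seg]);
        double r = m.sph_r[s];
        // centre height decides contact; force acts at the lowest point
        double lx = m.sph_xy(s, 0), ly = m.sph_xy(s, 1);
        double cy = K.O[seg][1] + sn * lx + c * ly;
        double depth = r - cy;
        if (depth <= 0.0) continue;
        double lx2 = lx - r * sn, ly2 = ly - r * c;   // lowest point, local
        pt_fast(K, deps[seg], seg, lx2, ly2, pbuf, vbuf, nullptr, Jbuf);
        double fn, ft;
        hc_force(depth, -vbuf[1], vbuf[0], m.cpars, fn, ft);
        for (int j = 0; j < nq; ++j)
          Q9[j] += Jbuf[j] * ft + Jbuf[NQ + j] * fn;
        bool rightFoot = (seg == m.foot_seg[0]);
        double* acc = rightFoot ? newR : newL;
        acc[0] += ft; acc[1] += fn;
        if (rightFoot) copR += fn * pbuf[0]; else copL += fn * pbuf[0];
      }
      if (newR[1] > 0) newR[2] = copR / newR[1];
      if (newL[1] > 0) newL[2] = copL / newL[1];
    }
    std::copy(newR, newR + 3, grfR);
    std::copy(newL, newL + 3, grfL);

    // ---- knee ligament and AFO ----
    for (int leg = 0; leg < 2; ++leg) {
      int kq = m.knee_q[leg], aq = m.ankle_q[leg];
      double kang = q[kq] * DEG, kvel = qd[kq] * DEG;
      double lig = 0.0;
      if (kang < m.lig_ext) lig = m.lig_k * (m.lig_ext - kang) - m.lig_c * kvel;
      else if (kang > m.lig_flex)
        lig = -m.lig_k * (kang - m.lig_flex) - m.lig_c * kvel;
      Q9[kq] += lig;
      double tafo = -K_afo * (q[aq] * DEG);
      Q9[aq] += tafo;
      afo_work += tafo * qd[aq] * dt;
    }

    // ---- muscles ----
    if (use_muscles) {
      path_points(true);
      mtu_from_points();
      if (use_controller) {
        double loadR = grfR[1] / (m.body_mass * saved_grav);
        double loadL = grfL[1] / (m.body_mass * saved_grav);
        double dxR = K.O[m.foot_seg[0]][0] - q[0];
        double dxL = K.O[m.foot_seg[1]][0] - q[0];
        phase_r = phase_next(phase_r, loadR, loadL, dxR, load_on, load_off,
                             d_ls, d_la);
        phase_l = phase_next(phase_l, loadL, loadR, dxL, load_on, load_off,
                             d_ls, d_la);
        for (int i = 0; i < nm; ++i) {
          int idx = (bufpos - dsteps[i] + 8 * maxdel) % maxdel;
          Fdel[i] = bufF(idx, i); Ldel[i] = bufL(idx, i);
        }
        excitations(m, par, phase_r, phase_l, Fdel, Ldel, q[2], qd[2], u);
      }
      for (int i = 0; i < nm; ++i) {
        act[i] = act_update(u[i], act[i], dt, m.m_tact[i], m.m_tdeact[i]);
        double lopt = m.m_lopt[i], hn = m.m_h[i] / lopt;
        double cp = cos_penn(lm[i], hn);
        double lt = lmt[i] - lm[i] * lopt * cp;
        double ftn = m.m_ften[i] * tendon_fl(lt / m.m_lslack[i] - 1.0, cv);
        double flv = fl_active(lm[i], cv);
        double fpas = m.m_fpas[i] * fl_passive(lm[i], cv);
        double v = solve_fiber_vel(act[i], flv, fpas, ftn / cp, cv);
        vmv[i] = v;
        Fmt[i] = m.m_fmax[i] * ftn;
        double F = Fmt[i];
        for (int k = m.path_ptr[i]; k < m.path_ptr[i + 1]; ++k) {
          double fx = 0.0, fy = 0.0;
          if (k > m.path_ptr[i]) {
            double dx = ppos[2 * (k - 1)] - ppos[2 * k];
            double dy = ppos[2 * (k - 1) + 1] - ppos[2 * k + 1];
            double nn = std::sqrt(dx * dx + dy * dy);
            if (nn > 1e-9) { fx += F * dx / nn; fy += F * dy / nn; }
          }
          if (k < m.path_ptr[i + 1] - 1) {
            double dx = ppos[2 * (k + 1)] - ppos[2 * k];
            double dy = ppos[2 * (k + 1) + 1] - ppos[2 * k + 1];
            double nn = std::sqrt(dx * dx + dy * dy);
            if (nn > 1e-9) { fx += F * dx / nn; fy += F * dy / nn; }
          }
          const double* J = &pJ[2 * NQ * k];
          for (int j = 0; j < nq; ++j)
            Q9[j] += J[j] * fx + J[NQ + j] * fy;
        }
        lm[i] += dt * v * m.m_vmax[i];
        if (lm[i] < 0.2) lm[i] = 0.2;
        if (lm[i] > 1.9) lm[i] = 1.9;
        bufF(bufpos, i) = ftn;
        bufL(bufpos, i) = lm[i];
      }
      bufpos = (bufpos + 1) % maxdel;

      // ---- metabolics over the steady-state window (gross) ----
      if (t >= transient) {
        double rate = m.met_basal * m.body_mass;
        for (int i = 0; i < nm; ++i) {
          double mm = m.m_fmax[i] * m.m_lopt[i] * m.met_rho / m.met_sigma;
          double h_am = mm * act[i] *
            (m.met_act + m.met_maint * fl_active(lm[i], cv));
          double vfib = vmv[i] * m.m_vmax[i] * m.m_lopt[i];
          double cp = cos_penn(lm[i], m.m_h[i] / m.m_lopt[i]);
          double Ffib = Fmt[i] / std::max(cp, 0.2);
          double h_sl = vfib < 0 ? m.met_short * Ffib * (-vfib) : 0.0;
          double w = -Ffib * vfib;
          double ri = h_am + h_sl + w;
          if (ri < 0.0) ri = 0.0;
          rate += ri;
        }
        E_met += rate * dt;
        for (int leg = 0; leg < 2; ++leg)
          for (arma::uword pi = 0; pi < m.pf_local.n_elem; ++pi) {
            double a = act[m.pf_local[pi] + leg * nhalf];
            if (a > act_thresh) act_excess += (a - act_thresh) * dt;
          }
      }
    }

    // ---- mass matrix, gravity, velocity-product forces ----
    std::fill(M9, M9 + nq * nq, 0.0);
    for (int s = 0; s < ns; ++s) {
      pt_fast(K, deps[s], s, m.com(s, 0), m.com(s, 1), pbuf, nullptr, abuf,
              Jbuf);
      double ms = m.mass[s];
      for (int j = 0; j < nq; ++j) {
        double j0 = Jbuf[j], j1 = Jbuf[NQ + j];
        if (j0 == 0.0 && j1 == 0.0) continue;
        for (int k = j; k < nq; ++k)
          M9[j * nq + k] += ms * (j0 * Jbuf[k] + j1 * Jbuf[NQ + k]);
        Q9[j] += -ms * m.grav * j1 - ms * (j0 * abuf[0] + j1 * abuf[1]);
      }
      for (int a1 = 0; a1 < deps[s].n; ++a1)
        for (int a2 = 0; a2 < deps[s].n; ++a2) {
          int j = deps[s].idx[a1], k = deps[s].idx[a2];
          if (k >= j)
            M9[j * nq + k] += m.inertia[s] * deps[s].val[a1] * deps[s].val[a2];
        }
    }
    for (int j = 0; j < nq; ++j)
      for (int k = 0; k < j; ++k) M9[j * nq + k] = M9[k * nq + j];

    // ---- solve for accelerations ----
    qdd_v.zeros();
    if (nf == nq) {
      arma::mat Mm(M9, nq, nq, false, true);
      arma::vec Qv(Q9, nq, false, true);
      qdd_v = arma::solve(Mm, Qv, arma::solve_opts::likely_sympd);
    } else {
      arma::mat Mf(nf, nf); arma::vec Qf(nf);
      for (int a1 = 0; a1 < nf; ++a1) {
        Qf[a1] = Q9[freeq[a1]];
        for (int a2 = 0; a2 < nf; ++a2)
          Mf(a1, a2) = M9[freeq[a1] * nq + freeq[a2]];
      }
      arma::vec qf = arma::solve(Mf, Qf, arma::solve_opts::likely_sympd);
      for (int a1 = 0; a1 < nf; ++a1) qdd_v[freeq[a1]] = qf[a1];
    }

    // ---- head acceleration and joint-range penalty over the window ----
    if (t >= transient) {
      pt_fast(K, deps[m.head_seg], m.head_seg, m.head_xy[0], m.head_xy[1],
              pbuf, nullptr, abuf, Jbuf);
      double ax = abuf[0], ay = abuf[1];
      for (int j = 0; j < nq; ++j) {
        ax += Jbuf[j] * qdd_v[j];
        ay += Jbuf[NQ + j] * qdd_v[j];
      }
      head_acc_sum += std::sqrt(ax * ax + ay * ay) * dt;
      head_n += dt;
      for (int leg = 0; leg < 2; ++leg) {
        double kang = q[m.knee_q[leg]] * DEG;
        double aang = q[m.ankle_q[leg]] * DEG;
        if (kang < 0.0) joint_viol += (-kang) * dt;
        if (std::fabs(aang) > 60.0) joint_viol += (std::fabs(aang) - 60.0) * dt;
      }
      if (!std::isfinite(x_w0)) { x_w0 = q[0]; t_w0 = t; }
    }

    // ---- record ----
    if (step % rec_every == 0 && irec < nrec) {
      R_t[irec] = t;
      for (int j = 0; j < nq; ++j) {
        R_q(irec, j) = q[j]; R_qd(irec, j) = qd[j];
      }
      R_act.row(irec) = act.t(); R_F.row(irec) = Fmt.t();
      R_lm.row(irec) = lm.t(); R_u.row(irec) = u.t();
      R_grf(irec, 0) = grfR[0]; R_grf(irec, 1) = grfR[1];
      R_grf(irec, 2) = grfR[2]; R_grf(irec, 3) = grfL[0];
      R_grf(irec, 4) = grfL[1]; R_grf(irec, 5) = grfL[2];
      R_ph[2 * irec] = phase_r; R_ph[2 * irec + 1] = phase_l;
      ++irec;
    }

    // ---- semi-implicit Euler ----
    bool finite = true;
    for (int j = 0; j < nq; ++j)
      if (!std::isfinite(qdd_v[j])) finite = false;
    if (finite)
      for (int j = 0; j < nq; ++j) qd[j] += dt * qdd_v[j];
    else fell = true;
    for (arma::uword l = 0; l < lock.n_elem; ++l) qd[lock[l]] = 0.0;
    for (int j = 0; j < nq; ++j) q[j] += dt * qd[j];
    t_end = t;
    for (int j = 0; j < nq; ++j)
      if (!std::isfinite(q[j]) || !std::isfinite(qd[j])) fell = true;
    if (use_contact && q[1] < fall_frac * y0) fell = true;
    if (fell) break;
  }

  m.grav = saved_grav;

  double distance = NA_REAL, mean_speed = NA_REAL, cot = NA_REAL,
         head_acc = NA_REAL;
  if (std::isfinite(x_w0) && t_end > t_w0) {
    distance = q[0] - x_w0;
    mean_speed = distance / (t_end - t_w0);
  }
  if (head_n > 0) head_acc = head_acc_sum / head_n;
  if (use_muscles && std::isfinite(distance) && distance > 1e-3)
    cot = E_met / (m.body_mass * distance);

  NumericVector summary = NumericVector::create(
      _["t_end"] = t_end, _["fell"] = fell ? 1.0 : 0.0,
      _["distance"] = distance, _["mean_speed"] = mean_speed,
      _["cot"] = cot, _["E_metab"] = E_met, _["head_acc"] = head_acc,
      _["joint_viol"] = joint_viol, _["act_excess"] = act_excess,
      _["afo_work"] = afo_work, _["y0"] = y0, _["x_end"] = q[0]);

  int n = irec;
  List traj = List::create(
      _["time"] = NumericVector(R_t.begin(), R_t.begin() + n),
      _["q"] = wrap(arma::mat(R_q.head_rows(n))),
      _["qd"] = wrap(arma::mat(R_qd.head_rows(n))),
      _["act"] = wrap(arma::mat(R_act.head_rows(n))),
      _["Fmt"] = wrap(arma::mat(R_F.head_rows(n))),
      _["lm"] = wrap(arma::mat(R_lm.head_rows(n))),
      _["u"] = wrap(arma::mat(R_u.head_rows(n))),
      _["grf"] = wrap(arma::mat(R_grf.head_rows(n))),
      _["phase"] = IntegerVector(R_ph.begin(), R_ph.begin() + 2 * n));
  return List::create(_["summary"] = summary, _["traj"] = traj);
}
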