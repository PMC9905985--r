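// Compiled core of the planar reaching simulator: rigid-body dynamics of the
// 3-link arm, Hill-type muscle mechanics with the exponential passive element,
// third-order activation dynamics, the predictive PD + inverse-dynamics
// controller, and the fixed-step RK4 reach integrator.  All user-facing R
// functions are thin wrappers around the entry points exported here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NJ = 3;  // joints: shoulder, elbow, wrist
static const int NM = 6;  // muscles: flexor/extensor per joint
static const int NS = 6 + 3 * NM;  // state: q, qdot, 3 activation states/muscle

struct Model {
  arma::vec L, m, d, In, qmin, qmax, qinit;   // geometry (3)
  double klim, clim;                          // joint-limit penalty
  arma::vec fmax, l0, r;                      // muscles (6)
  arma::ivec msign, mjoint;                   // +1 flexor / -1 extensor; joint 0..2
  double fl_w, vmax, fv_k, fv_flen, fv_c;    // active force-length-velocity
  arma::vec tau_act;                          // activation chain time constants (3)
  double sp, rp, lp;                          // passive curve of the scenario
};

static Model parse_model(const List& geom, const List& mus,
                         const NumericVector& scen) {
  Model M;
  M.L = as<arma::vec>(geom["segment_lengths"]);
  M.m = as<arma::vec>(geom["segment_masses"]);
  M.d = as<arma::vec>(geom["segment_com_offsets"]);
  M.In = as<arma::vec>(geom["segment_inertias"]);
  M.qmin = as<arma::vec>(geom["joint_min"]);
  M.qmax = as<arma::vec>(geom["joint_max"]);
  M.qinit = as<arma::vec>(geom["initial_joint_angles"]);
  M.klim = as<double>(geom["limit_stiffness"]);
  M.clim = as<double>(geom["limit_damping"]);
  M.fmax = as<arma::vec>(mus["fmax"]);
  M.l0 = as<arma::vec>(mus["l0"]);
  M.r = as<arma::vec>(mus["moment_arm"]);
  M.msign = as<arma::ivec>(mus["sign"]);
  M.mjoint = as<arma::ivec>(mus["joint"]);  // 1-based from R
  M.fl_w = as<double>(mus["fl_width"]);
  M.vmax = as<double>(mus["v_max"]);
  M.fv_k = as<double>(mus["fv_curvature"]);
  M.fv_flen = as<double>(mus["fv_flen"]);
  // slope-continuous eccentric branch: f'(0) matches the concentric branch
  M.fv_c = (M.fv_flen - 1.0) * M.vmax / (1.0 + 1.0 / M.fv_k);
  M.tau_act = as<arma::vec>(mus["act_tau"]);
  M.sp = scen[0];
  M.rp = scen[1];
  M.lp = scen[2];
  return M;
}

// ---------------------------------------------------------------- kinematics

static void seg_angles(const arma::vec& q, double* th) {
  th[0] = q[0];
  th[1] = q[0] + q[1];
  th[2] = q[0] + q[1] + q[2];
}

// endpoint and joint positions
static arma::vec2 fk_point(const Model& M, const arma::vec& q) {
  double th[3];
  seg_angles(q, th);
  arma::vec2 p = {0.0, 0.0};
  for (int i = 0; i < NJ; ++i) {
    p[0] += M.L[i] * std::cos(th[i]);
    p[1] += M.L[i] * std::sin(th[i]);
  }
  return p;
}

static arma::mat fk_jacobian(const Model& M, const arma::vec& q) {
  double th[3];
  seg_angles(q, th);
  arma::mat J(2, NJ, arma::fill::zeros);
  for (int k = 0; k < NJ; ++k)
    for (int j = k; j < NJ; ++j) {
      J(0, k) += -M.L[j] * std::sin(th[j]);
      J(1, k) += M.L[j] * std::cos(th[j]);
    }
  return J;
}

// --------------------------------------------------------------- rigid body
// Inverse dynamics by d'Alembert virtual work on segment centres of mass.
// c(i,j): distance coefficient of e(theta_j) in COM i position.
static double cij(const Model& M, int i, int j) {
  if (j < i) return M.L[j];
  if (j == i) return M.d[i];
  return 0.0;
}

static arma::vec id_tau(const Model& M, const arma::vec& q, const arma::vec& qd,
                        const arma::vec& qdd) {
  double th[3];
  seg_angles(q, th);
  double w[3], al[3];  // segment angular velocity / acceleration
  w[0] = qd[0]; w[1] = w[0] + qd[1]; w[2] = w[1] + qd[2];
  al[0] = qdd[0]; al[1] = al[0] + qdd[1]; al[2] = al[1] + qdd[2];
  double ct[3], st[3];
  for (int j = 0; j < 3; ++j) { ct[j] = std::cos(th[j]); st[j] = std::sin(th[j]); }
  arma::vec tau(NJ, arma::fill::zeros);
  for (int i = 0; i < NJ; ++i) {
    // COM acceleration of segment i
    double ax = 0.0, ay = 0.0;
    for (int j = 0; j <= i; ++j) {
      double c = cij(M, i, j);
      ax += c * (-st[j] * al[j] - ct[j] * w[j] * w[j]);
      ay += c * (ct[j] * al[j] - st[j] * w[j] * w[j]);
    }
    for (int k = 0; k < NJ; ++k) {
      // d p_i / d q_k
      double gx = 0.0, gy = 0.0;
      for (int j = k; j <= i; ++j) {
        double c = cij(M, i, j);
        gx += -c * st[j];
        gy += c * ct[j];
      }
      tau[k] += M.m[i] * (ax * gx + ay * gy);
      if (k <= i) tau[k] += M.In[i] * al[i];
    }
  }
  return tau;
}

static arma::mat mass_matrix(const Model& M, const arma::vec& q) {
  arma::mat Mm(NJ, NJ);
  arma::vec zero(NJ, arma::fill::zeros);
  for (int j = 0; j < NJ; ++j) {
    arma::vec e(NJ, arma::fill::zeros);
    e[j] = 1.0;
    Mm.col(j) = id_tau(M, q, zero, e);
  }
  return Mm;
}

static arma::vec limit_torque(const Model& M, const arma::vec& q,
                              const arma::vec& qd) {
  arma::vec tl(NJ, arma::fill::zeros);
  for (int j = 0; j < NJ; ++j) {
    if (q[j] > M.qmax[j]) tl[j] = -M.klim * (q[j] - M.qmax[j]) - M.clim * qd[j];
    else if (q[j] < M.qmin[j]) tl[j] = -M.klim * (q[j] - M.qmin[j]) - M.clim * qd[j];
  }
  return tl;
}

static arma::vec fwd_dyn(const Model& M, const arma::vec& q, const arma::vec& qd,
                         const arma::vec& tau, bool limits) {
  arma::vec rhs = tau - id_tau(M, q, qd, arma::vec(NJ, arma::fill::zeros));
  if (limits) rhs += limit_torque(M, q, qd);
  arma::vec qdd;
  if (!arma::solve(qdd, mass_matrix(M, q), rhs,
                   arma::solve_opts::likely_sympd + arma::solve_opts::no_approx)) {
    qdd.zeros(NJ);  // only reachable from a non-finite state; frozen upstream
  }
  return qdd;
}

// ------------------------------------------------------------------ muscles

static double passive_f(const Model& M, double lbar) {
  return lbar > M.lp ? M.sp * (std::exp(M.rp * (lbar - M.lp)) - 1.0) : 0.0;
}

static double active_fl(const Model& M, double lbar) {
  double z = (lbar - 1.0) / M.fl_w;
  return std::exp(-z * z);
}

static double active_fv(const Model& M, double u) {  // u = ldot/l0 (1/s)
  if (u <= 0.0) {
    if (u <= -M.vmax) return 0.0;
    return (M.vmax + u) / (M.vmax - u / M.fv_k);
  }
  return (M.fv_flen * u + M.fv_c) / (u + M.fv_c);
}

// length, normalized length, velocity for muscle i at (q, qd)
static void muscle_kin(const Model& M, int i, const arma::vec& q,
                       const arma::vec& qd, double& l, double& lbar,
                       double& ldot) {
  int j = M.mjoint[i] - 1;
  double s = (double)M.msign[i];
  l = M.l0[i] - s * M.r[i] * (q[j] - M.qinit[j]);
  lbar = l / M.l0[i];
  ldot = -s * M.r[i] * qd[j];
}

// total muscle torque on the three joints, plus per-muscle force
static arma::vec muscle_torques(const Model& M, const arma::vec& q,
                                const arma::vec& qd, const double* a,
                                double* fout) {
  arma::vec tau(NJ, arma::fill::zeros);
  for (int i = 0; i < NM; ++i) {
    double l, lbar, ldot;
    muscle_kin(M, i, q, qd, l, lbar, ldot);
    double fa = active_fl(M, lbar) * active_fv(M, ldot / M.l0[i]);
    double f = M.fmax[i] * (fa * a[i] + passive_f(M, lbar));
    if (f < 0.0) f = 0.0;
    if (fout) fout[i] = f;
    tau[M.mjoint[i] - 1] += f * (double)M.msign[i] * M.r[i];
  }
  return tau;
}

// ------------------------------------------------------------- full system

static void rhs(const Model& M, const arma::vec& y, const arma::vec& u,
                arma::vec& dy) {
  // violent (diverging) trajectories are frozen rather than propagated: a
  // non-finite or absurd state yields zero derivatives and the caller flags
  // the reach unstable
  if (!y.is_finite() || arma::abs(y.subvec(0, 5)).max() > 1e6) {
    dy.zeros(NS);
    return;
  }
  arma::vec q = y.subvec(0, 2), qd = y.subvec(3, 5);
  double a[NM];
  for (int i = 0; i < NM; ++i) a[i] = y[6 + 3 * i + 2];
  arma::vec tau = muscle_torques(M, q, qd, a, nullptr);
  arma::vec qdd = fwd_dyn(M, q, qd, tau, true);
  dy.set_size(NS);
  dy.subvec(0, 2) = qd;
  dy.subvec(3, 5) = qdd;
  for (int i = 0; i < NM; ++i) {
    double s1 = y[6 + 3 * i], s2 = y[6 + 3 * i + 1], s3 = y[6 + 3 * i + 2];
    dy[6 + 3 * i] = (u[i] - s1) / M.tau_act[0];
    dy[6 + 3 * i + 1] = (s1 - s2) / M.tau_act[1];
    dy[6 + 3 * i + 2] = (s2 - s3) / M.tau_act[2];
  }
}

static void rk4_step(const Model& M, arma::vec& y, const arma::vec& u, double h) {
  arma::vec k1, k2, k3, k4, yt;
  rhs(M, y, u, k1);
  yt = y + 0.5 * h * k1; rhs(M, yt, u, k2);
  yt = y + 0.5 * h * k2; rhs(M, yt, u, k3);
  yt = y + h * k3;       rhs(M, yt, u, k4);
  y += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  // activation states are mathematically confined to [0,1]; project off
  // round-off excursions so downstream force terms stay admissible
  for (int i = 6; i < NS; ++i) {
    if (y[i] < 0.0) y[i] = 0.0;
    else if (y[i] > 1.0) y[i] = 1.0;
  }
}

// excitations realizing tau_des at state y under the no-co-excitation rule
static arma::vec excitations(const Model& M, const arma::vec& y,
                             const arma::vec& tau_des, double t_pred,
                             int* sat_flag) {
  arma::vec u(NM, arma::fill::zeros);
  if (!y.is_finite() || !tau_des.is_finite()) return u;
  arma::vec q = y.subvec(0, 2), qd = y.subvec(3, 5);
  double tau_eff = arma::sum(M.tau_act);
  // first-order lead compensation of the activation lag over the prediction
  // horizon; the factor is capped because the uncapped gain (1/(1-e^{-T/tau}))
  // amplifies step-to-step excitation noise into a limit cycle at short
  // prediction times
  double lead = 1.0;
  if (t_pred > 0.0) lead = std::min(1.0 / (1.0 - std::exp(-t_pred / tau_eff)), 2.0);
  const double eps = 1e-6;
  for (int j = 0; j < NJ; ++j) {
    int fi = 2 * j, ei = 2 * j + 1;  // flexor, extensor of joint j
    double lf, lbf, ldf, le, lbe, lde;
    muscle_kin(M, fi, q, qd, lf, lbf, ldf);
    muscle_kin(M, ei, q, qd, le, lbe, lde);
    double faf = active_fl(M, lbf) * active_fv(M, ldf / M.l0[fi]);
    double fae = active_fl(M, lbe) * active_fv(M, lde / M.l0[ei]);
    double af = y[6 + 3 * fi + 2], ae = y[6 + 3 * ei + 2];
    // the inversion knows only the active muscle apparatus: passive forces
    // are an unmodeled disturbance the feedback gains must overcome, which
    // is what lets passive stiffening degrade performance at all (and what
    // pushes tuned gains up with scenario severity)
    double tau_res = tau_des[j];
    // the agonist is the muscle whose pull has the sign of the residual
    // torque; the antagonist is left unexcited and its decaying activation
    // is corrected by the feedback loop, not double-counted here (feeding
    // the antagonist's activation back into the demand makes the discrete
    // excitation loop ratchet unstably)
    double a_des;
    int agonist;
    if (tau_res >= 0.0) {
      agonist = fi;
      a_des = tau_res / (M.r[fi] * M.fmax[fi] * std::max(faf, eps));
    } else {
      agonist = ei;
      a_des = -tau_res / (M.r[ei] * M.fmax[ei] * std::max(fae, eps));
    }
    (void)af; (void)ae;
    if (a_des > 1.0 && sat_flag) *sat_flag = 1;
    double a_cur = y[6 + 3 * agonist + 2];
    double ui = a_des + (lead - 1.0) * (a_des - a_cur);
    if (ui < 0.0) ui = 0.0;
    if (ui > 1.0) ui = 1.0;
    u[agonist] = ui;
  }
  return u;
}

// ------------------------------------------------------------ R interfaces

// [[Rcpp::export]]
arma::vec cpp_forward_kinematics(List geom, List mus, NumericVector scen,
                                 arma::vec q) {
  Model M = parse_model(geom, mus, scen);
  return fk_point(M, q);
}

// [[Rcpp::export]]
arma::mat cpp_joint_positions(List geom, List mus, NumericVector scen,
                              arma::vec q) {
  Model M = parse_model(geom, mus, scen);
  double th[3];
  seg_angles(q, th);
  arma::mat P(4, 2, arma::fill::zeros);  // shoulder, elbow, wrist, endpoint
  for (int i = 0; i < NJ; ++i) {
    P(i + 1, 0) = P(i, 0) + M.L[i] * std::cos(th[i]);
    P(i + 1, 1) = P(i, 1) + M.L[i] * std::sin(th[i]);
  }
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_jacobian(List geom, List mus, NumericVector scen, arma::vec q) {
  Model M = parse_model(geom, mus, scen);
  return fk_jacobian(M, q);
}

// [[Rcpp::export]]
arma::vec cpp_inverse_dynamics(List geom, List mus, NumericVector scen,
                               arma::vec q, arma::vec qd, arma::vec qdd) {
  Model M = parse_model(geom, mus, scen);
  return id_tau(M, q, qd, qdd);
}

// [[Rcpp::export]]
arma::mat cpp_mass_matrix(List geom, List mus, NumericVector scen, arma::vec q) {
  Model M = parse_model(geom, mus, scen);
  return mass_matrix(M, q);
}

// [[Rcpp::export]]
arma::vec cpp_forward_dynamics(List geom, List mus, NumericVector scen,
                               arma::vec q, arma::vec qd, arma::vec tau,
                               bool limits) {
  Model M = parse_model(geom, mus, scen);
  return fwd_dyn(M, q, qd, tau, limits);
}

// [[Rcpp::export]]
double cpp_kinetic_energy(List geom, List mus, NumericVector scen, arma::vec q,
                          arma::vec qd) {
  Model M = parse_model(geom, mus, scen);
  double th[3];
  seg_angles(q, th);
  double w[3];
  w[0] = qd[0]; w[1] = w[0] + qd[1]; w[2] = w[1] + qd[2];
  double ke = 0.0;
  for (int i = 0; i < NJ; ++i) {
    double vx = 0.0, vy = 0.0;
    for (int j = 0; j <= i; ++j) {
      double c = cij(M, i, j);
      vx += -c * std::sin(th[j]) * w[j];
      vy += c * std::cos(th[j]) * w[j];
    }
    ke += 0.5 * M.m[i] * (vx * vx + vy * vy) + 0.5 * M.In[i] * w[i] * w[i];
  }
  return ke;
}

// free (muscle-less) integration of the rigid arm, for energy checks
// [[Rcpp::export]]
List cpp_integrate_arm(List geom, List mus, NumericVector scen, arma::vec q0,
                       arma::vec qd0, arma::vec tau, double t_end, double h,
                       bool limits) {
  Model M = parse_model(geom, mus, scen);
  int n = (int)std::round(t_end / h);
  arma::mat Q(n + 1, NJ), QD(n + 1, NJ);
  arma::vec KE(n + 1);
  arma::vec q = q0, qd = qd0;
  for (int k = 0; k <= n; ++k) {
    Q.row(k) = q.t(); QD.row(k) = qd.t();
    KE[k] = cpp_kinetic_energy(geom, mus, scen, q, qd);
    if (k == n) break;
    // RK4 on the 6-dim rigid-body state only
    arma::vec y(6);
    y.subvec(0, 2) = q; y.subvec(3, 5) = qd;
    auto f = [&](const arma::vec& yy) {
      arma::vec dy(6);
      dy.subvec(0, 2) = yy.subvec(3, 5);
      dy.subvec(3, 5) = fwd_dyn(M, yy.subvec(0, 2), yy.subvec(3, 5), tau, limits);
      return dy;
    };
    arma::vec k1 = f(y), k2 = f(y + 0.5 * h * k1), k3 = f(y + 0.5 * h * k2),
              k4 = f(y + h * k3);
    y += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    q = y.subvec(0, 2); qd = y.subvec(3, 5);
  }
  return List::create(_["q"] = Q, _["qdot"] = QD, _["kinetic_energy"] = KE);
}

// [[Rcpp::export]]
List cpp_muscle_kinematics(List geom, List mus, NumericVector scen, arma::vec q,
                           arma::vec qd) {
  Model M = parse_model(geom, mus, scen);
  arma::vec l(NM), lbar(NM), ldot(NM), arm(NM);
  for (int i = 0; i < NM; ++i) {
    muscle_kin(M, i, q, qd, l[i], lbar[i], ldot[i]);
    arm[i] = (double)M.msign[i] * M.r[i];
  }
  return List::create(_["l"] = l, _["lbar"] = lbar, _["ldot"] = ldot,
                      _["moment_arm"] = arm);
}

// [[Rcpp::export]]
List cpp_muscle_torques(List geom, List mus, NumericVector scen, arma::vec q,
                        arma::vec qd, arma::vec a) {
  Model M = parse_model(geom, mus, scen);
  double f[NM];
  arma::vec tau = muscle_torques(M, q, qd, a.memptr(), f);
  return List::create(_["tau"] = tau,
                      _["force"] = NumericVector(f, f + NM));
}

// [[Rcpp::export]]
double cpp_active_fa(List geom, List mus, NumericVector scen, double lbar,
                     double u_norm) {
  Model M = parse_model(geom, mus, scen);
  return active_fl(M, lbar) * active_fv(M, u_norm);
}

// dense sweep of all joint combinations for the normalized-length extremum
// [[Rcpp::export]]
double cpp_max_lbar(List geom, List mus, NumericVector scen, int n_grid) {
  Model M = parse_model(geom, mus, scen);
  double best = 0.0;
  arma::vec q(NJ), qd(NJ, arma::fill::zeros);
  for (int i1 = 0; i1 < n_grid; ++i1) {
    q[0] = M.qmin[0] + (M.qmax[0] - M.qmin[0]) * i1 / (n_grid - 1.0);
    for (int i2 = 0; i2 < n_grid; ++i2) {
      q[1] = M.qmin[1] + (M.qmax[1] - M.qmin[1]) * i2 / (n_grid - 1.0);
      for (int i3 = 0; i3 < n_grid; ++i3) {
        q[2] = M.qmin[2] + (M.qmax[2] - M.qmin[2]) * i3 / (n_grid - 1.0);
        for (int i = 0; i < NM; ++i) {
          double l, lb, ld;
          muscle_kin(M, i, q, qd, l, lb, ld);
          if (lb > best) best = lb;
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
arma::vec cpp_excitations(List geom, List mus, NumericVector scen, arma::vec y,
                          arma::vec tau_des, double t_pred) {
  Model M = parse_model(geom, mus, scen);
  int sat = 0;
  return excitations(M, y, tau_des, t_pred, &sat);
}

// forward-simulate the model's own dynamics over t_pred holding excitations
// [[Rcpp::export]]
arma::vec cpp_predict_state(List geom, List mus, NumericVector scen,
                            arma::vec y, arma::vec u, double t_pred, double h) {
  Model M = parse_model(geom, mus, scen);
  int n = (int)std::round(t_pred / h);
  arma::vec ys = y;
  for (int k = 0; k < n; ++k) rk4_step(M, ys, u, h);
  return ys;
}

// closed-loop damped-least-squares IK along a sampled endpoint reference,
// with null-space attraction to mid-range joint angles
// [[Rcpp::export]]
List cpp_plan_ik(List geom, List mus, NumericVector scen, arma::mat p_ref,
                 arma::mat v_ref, double dt, int m_sub, double k_ik,
                 double lambda, double k_ns) {
  Model M = parse_model(geom, mus, scen);
  int n = p_ref.n_rows;
  arma::mat refq(n, NJ), refqd(n, NJ);
  arma::vec q = M.qinit, qmid = 0.5 * (M.qmin + M.qmax);
  arma::vec qd(NJ, arma::fill::zeros);
  double h = dt / m_sub;
  double lam2 = lambda * lambda;
  for (int k = 0; k < n; ++k) {
    for (int s = 0; s < m_sub; ++s) {
      arma::mat J = fk_jacobian(M, q);
      arma::vec2 ep = fk_point(M, q);
      arma::vec2 v = {v_ref(k, 0) + k_ik * (p_ref(k, 0) - ep[0]),
                      v_ref(k, 1) + k_ik * (p_ref(k, 1) - ep[1])};
      arma::mat JJt = J * J.t() + lam2 * arma::eye(2, 2);
      qd = J.t() * arma::solve(JJt, v);
      arma::vec ns = k_ns * (qmid - q);
      qd += ns - J.t() * arma::solve(JJt, J * ns);
      q += h * qd;
      for (int j = 0; j < NJ; ++j) {
        if (q[j] < M.qmin[j]) q[j] = M.qmin[j];
        else if (q[j] > M.qmax[j]) q[j] = M.qmax[j];
      }
    }
    refq.row(k) = q.t();
    refqd.row(k) = qd.t();
  }
  // endpoint error of the joint-space reference against the planned path
  double err = 0.0;
  for (int k = 0; k < n; ++k) {
    arma::vec2 ep = fk_point(M, refq.row(k).t());
    double e = std::hypot(ep[0] - p_ref(k, 0), ep[1] - p_ref(k, 1));
    if (e > err) err = e;
  }
  return List::create(_["refq"] = refq, _["refqd"] = refqd,
                      _["ik_endpoint_error"] = err);
}

// [[Rcpp::export]]
List cpp_simulate_reach(List geom, List mus, NumericVector scen,
                        NumericVector kp, NumericVector kd, double t_pred,
                        arma::mat refq, arma::mat refqd, arma::mat refqdd,
                        arma::mat refp, double dt, int n_sub) {
  Model M = parse_model(geom, mus, scen);
  int N = refq.n_rows;
  int n_pred = (int)std::round(t_pred / dt);
  arma::vec y(NS, arma::fill::zeros);
  y.subvec(0, 2) = M.qinit;
  arma::vec u(NM, arma::fill::zeros);
  arma::mat Q(N, NJ), QD(N, NJ), EP(N, 2), A(N, NM), F(N, NM), U(N, NM), TD(N, NJ);
  int saturated = 0, unstable = 0;
  double h = dt / n_sub;
  arma::vec tau_prev(NJ, arma::fill::zeros);
  bool have_prev = false;
  for (int k = 0; k < N; ++k) {
    arma::vec q = y.subvec(0, 2), qd = y.subvec(3, 5);
    // predict the state t_pred ahead under the currently held excitations;
    // the internal forward model integrates at a coarser step (<= 5 ms),
    // which RK4 resolves easily given the ~15 ms activation time constants
    arma::vec yp = y;
    if (n_pred > 0) {
      double horizon = n_pred * dt;
      int nip = (int)std::ceil(horizon / 0.005);
      double hp = horizon / nip;
      for (int s = 0; s < nip; ++s) rk4_step(M, yp, u, hp);
      if (!yp.is_finite()) yp = y;  // fall back to the current state
    }
    int idx = std::min(k + n_pred, N - 1);
    arma::vec tau_des =
        id_tau(M, refq.row(idx).t(), refqd.row(idx).t(), refqdd.row(idx).t());
    for (int j = 0; j < NJ; ++j) {
      tau_des[j] += kp[j] * (refq(idx, j) - yp[j]) +
                    kd[j] * (refqd(idx, j) - yp[3 + j]);
    }
    // two-tap average of the torque demand: the held-excitation prediction
    // makes the discrete loop's period-2 (Nyquist) mode marginally unstable,
    // and the averaging zeroes that mode at a cost of half a control step
    // of delay
    arma::vec tau_use = have_prev ? arma::vec(0.5 * (tau_des + tau_prev))
                                  : tau_des;
    tau_prev = tau_des;
    have_prev = true;
    u = excitations(M, yp, tau_use, t_pred, &saturated);
    TD.row(k) = tau_use.t();
    // record state and the control chosen at t_k
    double a[NM], f[NM];
    for (int i = 0; i < NM; ++i) a[i] = y[6 + 3 * i + 2];
    muscle_torques(M, q, qd, a, f);
    Q.row(k) = q.t(); QD.row(k) = qd.t();
    EP.row(k) = fk_point(M, q).t();
    for (int i = 0; i < NM; ++i) { A(k, i) = a[i]; F(k, i) = f[i]; U(k, i) = u[i]; }
    if (k == N - 1) break;
    bool blown = false;
    for (int s = 0; s < n_sub; ++s) {
      rk4_step(M, y, u, h);
      if (!y.is_finite() || arma::abs(y.subvec(0, 5)).max() > 1e4) {
        blown = true;
        break;
      }
    }
    if (blown || arma::abs(y.subvec(0, 2)).max() > 50.0) {
      unstable = 1;
      // freeze the trajectory at the last finite state; metrics then report
      // the (large) terminal error instead of propagating NaNs
      arma::vec qf = Q.row(k).t();
      for (int kk = k + 1; kk < N; ++kk) {
        Q.row(kk) = Q.row(k); QD.row(kk).zeros();
        EP.row(kk) = EP.row(k);
        for (int i = 0; i < NM; ++i) { A(kk, i) = A(k, i); F(kk, i) = F(k, i); U(kk, i) = 0.0; }
      }
      break;
    }
  }
  return List::create(_["q"] = Q, _["qdot"] = QD, _["endpoint"] = EP,
                      _["activation"] = A, _["force"] = F, _["excitation"] = U,
                      _["tau_des"] = TD,
                      _["saturated"] = saturated, _["unstable"] = unstable);
}
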