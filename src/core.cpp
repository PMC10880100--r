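// Compiled numerical core: Hill-type muscle curves, smoothed Hunt-Crossley
// contact, planar recursive Newton-Euler inverse dynamics, and the fused
// per-mesh-point path-constraint evaluator used by the collocation solver.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Muscle curve primitives (dimensionless, Gaussian active force-length,
// log-type force-velocity, exponential passive and tendon curves).
// Active and force-velocity curves are normalised so f_act(1) = f_v(0) = 1.
// ---------------------------------------------------------------------------

struct Curves {
  // active force-length: 3 gaussians, rows (b1,b2,b3,b4)
  double b1[3], b2[3], b3[3], b4[3];
  double act_norm;
  // force-velocity
  double d1, d2, d3, d4, fv_norm;
  // passive
  double kpe, e0;
  // tendon
  double c1, c3, kT; // c2 tied so that f_T(1) = 0
  double beta;       // fibre damping
  double c2() const { return 1.0 - std::log(c3 / c1) / kT; }
};

static Curves parse_curves(const List& cl) {
  Curves c;
  NumericMatrix act = cl["active"];
  for (int i = 0; i < 3; ++i) {
    c.b1[i] = act(i, 0); c.b2[i] = act(i, 1); c.b3[i] = act(i, 2); c.b4[i] = act(i, 3);
  }
  c.act_norm = as<double>(cl["act_norm"]);
  NumericVector fv = cl["fv"];
  c.d1 = fv[0]; c.d2 = fv[1]; c.d3 = fv[2]; c.d4 = fv[3];
  c.fv_norm = as<double>(cl["fv_norm"]);
  c.kpe = as<double>(cl["kpe"]); c.e0 = as<double>(cl["e0"]);
  c.c1 = as<double>(cl["c1"]); c.c3 = as<double>(cl["c3"]); c.kT = as<double>(cl["kT"]);
  c.beta = as<double>(cl["beta"]);
  return c;
}

static inline double f_act_raw(const Curves& c, double l) {
  double s = 0.0;
  for (int i = 0; i < 3; ++i) {
    double den = c.b3[i] + c.b4[i] * l;
    double z = (l - c.b2[i]) / den;
    s += c.b1[i] * std::exp(-0.5 * z * z);
  }
  return s;
}
static inline double f_act(const Curves& c, double l) { return f_act_raw(c, l) / c.act_norm; }
static inline double f_v_raw(const Curves& c, double v) {
  double z = c.d2 * v + c.d3;
  return c.d1 * std::log(z + std::sqrt(z * z + 1.0)) + c.d4;
}
static inline double f_v(const Curves& c, double v) { return f_v_raw(c, v) / c.fv_norm; }
static inline double f_pas(const Curves& c, double l) {
  return (std::exp(c.kpe * (l - 1.0) / c.e0) - 1.0) / (std::exp(c.kpe) - 1.0);
}
static inline double f_ten(const Curves& c, double ltn) {
  return c.c1 * std::exp(c.kT * (ltn - c.c2())) - c.c3;
}

// [[Rcpp::export]]
List cpp_muscle_curves(NumericVector lm_norm, NumericVector vm_norm,
                       NumericVector tendon_strain, List curves) {
  Curves c = parse_curves(curves);
  int n = lm_norm.size();
  NumericVector fa(n), fv(n), fp(n), ft(n);
  for (int i = 0; i < n; ++i) {
    fa[i] = f_act(c, lm_norm[i]);
    fv[i] = f_v(c, vm_norm[i]);
    fp[i] = f_pas(c, lm_norm[i]);
    ft[i] = f_ten(c, 1.0 + tendon_strain[i]);
  }
  return List::create(_["f_act_fl"] = fa, _["f_v"] = fv,
                      _["f_pas"] = fp, _["f_tendon"] = ft);
}

// ---------------------------------------------------------------------------
// Smoothed Hunt-Crossley contact (C^2; smooth positive parts throughout).
// ---------------------------------------------------------------------------

struct ContactPars { double mu, v0, eps_d, eps_f; };

static inline double smooth_pos(double x, double eps) {
  return 0.5 * (x + std::sqrt(x * x + eps * eps));
}

static inline void hc_force(double d, double ddot, double vx,
                            double k, double cdamp, const ContactPars& cp,
                            double& fn, double& ftan) {
  double dp = smooth_pos(d, cp.eps_d);
  double f1 = k * dp * std::sqrt(dp) * (1.0 + 1.5 * cdamp * ddot);
  fn = smooth_pos(f1, cp.eps_f);
  ftan = -cp.mu * fn * std::tanh(vx / cp.v0);
}

// [[Rcpp::export]]
List cpp_contact_force(NumericVector penetration, NumericVector penetration_velocity,
                       NumericVector slip_velocity, double stiffness, double damping,
                       double mu, double v0, double eps_d, double eps_f) {
  ContactPars cp{mu, v0, eps_d, eps_f};
  int n = penetration.size();
  NumericVector fn(n), ft(n);
  for (int i = 0; i < n; ++i) {
    double a, b;
    hc_force(penetration[i], penetration_velocity[i], slip_velocity[i],
             stiffness, damping, cp, a, b);
    fn[i] = a; ft[i] = b;
  }
  return List::create(_["normal"] = fn, _["tangential"] = ft);
}

// ---------------------------------------------------------------------------
// Planar tree kinematics + recursive Newton-Euler inverse dynamics.
// Model blob fields (all 0-based already converted in R where needed):
//   nseg, nq, parent (1-based, 0 = world), jloc (2 x nseg), mass, com (2 x nseg),
//   izz, coord (1-based coordinate index of segment joint; root uses coords 1:3),
//   grav
// Coordinate order: 1 pelvis_tx, 2 pelvis_ty, 3 pelvis_tilt, then one rotational
// coordinate per non-root segment in segment order.
// ---------------------------------------------------------------------------

struct Body {
  int parent;        // 0-based, -1 for root
  double jx, jy;     // joint location in parent frame
  double m, cx, cy, I;
  int coord;         // 0-based coordinate index (root: -1)
};

struct Skel {
  int nseg, nq;
  std::vector<Body> b;
  double grav;
};

static Skel parse_skel(const List& blob) {
  Skel s;
  s.nseg = as<int>(blob["nseg"]);
  s.nq = as<int>(blob["nq"]);
  s.grav = as<double>(blob["grav"]);
  IntegerVector parent = blob["parent"];
  NumericMatrix jloc = blob["jloc"];
  NumericVector mass = blob["mass"];
  NumericMatrix com = blob["com"];
  NumericVector izz = blob["izz"];
  IntegerVector coord = blob["coord"];
  s.b.resize(s.nseg);
  for (int i = 0; i < s.nseg; ++i) {
    s.b[i].parent = parent[i] - 1;
    s.b[i].jx = jloc(0, i); s.b[i].jy = jloc(1, i);
    s.b[i].m = mass[i]; s.b[i].cx = com(0, i); s.b[i].cy = com(1, i);
    s.b[i].I = izz[i];
    s.b[i].coord = coord[i] - 1;
  }
  return s;
}

// per-instant kinematic state of every segment
struct SegKin {
  std::vector<double> th, w, al;        // angle, ang vel, ang acc
  std::vector<double> px, py, vx, vy, ax, ay;           // joint origin
  std::vector<double> cxw, cyw, cvx, cvy, cax, cay;     // com (world)
  SegKin(int n) : th(n), w(n), al(n), px(n), py(n), vx(n), vy(n), ax(n), ay(n),
                  cxw(n), cyw(n), cvx(n), cvy(n), cax(n), cay(n) {}
};

static void fk_instant(const Skel& s, const double* q, const double* qd,
                       const double* qdd, SegKin& K) {
  for (int i = 0; i < s.nseg; ++i) {
    const Body& bi = s.b[i];
    if (bi.parent < 0) {
      K.th[i] = q[2]; K.w[i] = qd[2]; K.al[i] = qdd[2];
      K.px[i] = q[0]; K.py[i] = q[1];
      K.vx[i] = qd[0]; K.vy[i] = qd[1];
      K.ax[i] = qdd[0]; K.ay[i] = qdd[1];
    } else {
      int p = bi.parent;
      K.th[i] = K.th[p] + q[bi.coord];
      K.w[i] = K.w[p] + qd[bi.coord];
      K.al[i] = K.al[p] + qdd[bi.coord];
      double ct = std::cos(K.th[p]), st = std::sin(K.th[p]);
      double rx = ct * bi.jx - st * bi.jy;
      double ry = st * bi.jx + ct * bi.jy;
      K.px[i] = K.px[p] + rx; K.py[i] = K.py[p] + ry;
      K.vx[i] = K.vx[p] - K.w[p] * ry; K.vy[i] = K.vy[p] + K.w[p] * rx;
      K.ax[i] = K.ax[p] - K.al[p] * ry - K.w[p] * K.w[p] * rx;
      K.ay[i] = K.ay[p] + K.al[p] * rx - K.w[p] * K.w[p] * ry;
    }
    double ct = std::cos(K.th[i]), st = std::sin(K.th[i]);
    const Body& bi2 = s.b[i];
    double rx = ct * bi2.cx - st * bi2.cy;
    double ry = st * bi2.cx + ct * bi2.cy;
    K.cxw[i] = K.px[i] + rx; K.cyw[i] = K.py[i] + ry;
    K.cvx[i] = K.vx[i] - K.w[i] * ry; K.cvy[i] = K.vy[i] + K.w[i] * rx;
    K.cax[i] = K.ax[i] - K.al[i] * ry - K.w[i] * K.w[i] * rx;
    K.cay[i] = K.ay[i] + K.al[i] * rx - K.w[i] * K.w[i] * ry;
  }
}

// external point forces at one instant
struct ExtF {
  std::vector<int> seg;                  // 0-based segment
  std::vector<double> px, py, fx, fy, tz; // world application point, force, couple
};

// inverse dynamics at one instant; tau has length nq, root rows are residuals
static void rnea_instant(const Skel& s, const SegKin& K, const ExtF& E,
                         double* tau) {
  int n = s.nseg;
  std::vector<double> fx(n, 0.0), fy(n, 0.0), nz(n, 0.0);
  // children lists are implicit: iterate segments in reverse order (parents
  // always precede children by construction)
  for (int i = n - 1; i >= 0; --i) {
    const Body& bi = s.b[i];
    double Fx = bi.m * K.cax[i];
    double Fy = bi.m * (K.cay[i] + s.grav);
    double Nz = bi.I * K.al[i]
      + (K.cxw[i] - K.px[i]) * bi.m * (K.cay[i] + s.grav)
      - (K.cyw[i] - K.py[i]) * bi.m * K.cax[i];
    // external forces on this segment
    for (size_t e = 0; e < E.seg.size(); ++e) {
      if (E.seg[e] != i) continue;
      Fx -= E.fx[e]; Fy -= E.fy[e];
      Nz -= (E.px[e] - K.px[i]) * E.fy[e] - (E.py[e] - K.py[i]) * E.fx[e];
      Nz -= E.tz[e];
    }
    fx[i] += Fx; fy[i] += Fy; nz[i] += Nz;
    if (bi.parent >= 0) {
      int p = bi.parent;
      fx[p] += fx[i]; fy[p] += fy[i];
      nz[p] += nz[i] + (K.px[i] - K.px[p]) * fy[i] - (K.py[i] - K.py[p]) * fx[i];
    }
  }
  for (int i = 0; i < n; ++i) {
    const Body& bi = s.b[i];
    if (bi.parent < 0) {
      tau[0] = fx[i]; tau[1] = fy[i]; tau[2] = nz[i];
    } else {
      tau[bi.coord] = nz[i];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_inverse_dynamics(List blob, NumericMatrix Q, NumericMatrix QD,
                                   NumericMatrix QDD, IntegerVector ext_seg,
                                   List ext_pt, List ext_force, List ext_torque) {
  Skel s = parse_skel(blob);
  int nt = Q.nrow();
  NumericMatrix TAU(nt, s.nq);
  SegKin K(s.nseg);
  int ne = ext_seg.size();
  std::vector<NumericMatrix> pts, frc;
  std::vector<NumericVector> trq;
  for (int e = 0; e < ne; ++e) {
    pts.push_back(as<NumericMatrix>(ext_pt[e]));
    frc.push_back(as<NumericMatrix>(ext_force[e]));
    trq.push_back(as<NumericVector>(ext_torque[e]));
  }
  std::vector<double> q(s.nq), qd(s.nq), qdd(s.nq), tau(s.nq);
  for (int t = 0; t < nt; ++t) {
    for (int j = 0; j < s.nq; ++j) { q[j] = Q(t, j); qd[j] = QD(t, j); qdd[j] = QDD(t, j); }
    fk_instant(s, q.data(), qd.data(), qdd.data(), K);
    ExtF E;
    for (int e = 0; e < ne; ++e) {
      E.seg.push_back(ext_seg[e] - 1);
      E.px.push_back(pts[e](t, 0)); E.py.push_back(pts[e](t, 1));
      E.fx.push_back(frc[e](t, 0)); E.fy.push_back(frc[e](t, 1));
      E.tz.push_back(trq[e][t]);
    }
    rnea_instant(s, K, E, tau.data());
    for (int j = 0; j < s.nq; ++j) TAU(t, j) = tau[j];
  }
  return TAU;
}

// [[Rcpp::export]]
List cpp_forward_kinematics(List blob, NumericMatrix Q, NumericMatrix QD,
                            NumericMatrix QDD) {
  Skel s = parse_skel(blob);
  int nt = Q.nrow(), n = s.nseg;
  NumericMatrix th(nt, n), w(nt, n), al(nt, n), px(nt, n), py(nt, n),
    vx(nt, n), vy(nt, n), ax(nt, n), ay(nt, n), cx(nt, n), cy(nt, n),
    cvx(nt, n), cvy(nt, n), cax(nt, n), cay(nt, n);
  SegKin K(n);
  std::vector<double> q(s.nq), qd(s.nq), qdd(s.nq);
  for (int t = 0; t < nt; ++t) {
    for (int j = 0; j < s.nq; ++j) { q[j] = Q(t, j); qd[j] = QD(t, j); qdd[j] = QDD(t, j); }
    fk_instant(s, q.data(), qd.data(), qdd.data(), K);
    for (int i = 0; i < n; ++i) {
      th(t, i) = K.th[i]; w(t, i) = K.w[i]; al(t, i) = K.al[i];
      px(t, i) = K.px[i]; py(t, i) = K.py[i];
      vx(t, i) = K.vx[i]; vy(t, i) = K.vy[i]; ax(t, i) = K.ax[i]; ay(t, i) = K.ay[i];
      cx(t, i) = K.cxw[i]; cy(t, i) = K.cyw[i];
      cvx(t, i) = K.cvx[i]; cvy(t, i) = K.cvy[i];
      cax(t, i) = K.cax[i]; cay(t, i) = K.cay[i];
    }
  }
  return List::create(_["theta"] = th, _["omega"] = w, _["alpha"] = al,
                      _["ox"] = px, _["oy"] = py, _["ovx"] = vx, _["ovy"] = vy,
                      _["oax"] = ax, _["oay"] = ay,
                      _["cx"] = cx, _["cy"] = cy, _["cvx"] = cvx, _["cvy"] = cvy,
                      _["cax"] = cax, _["cay"] = cay);
}

// ---------------------------------------------------------------------------
// MTU polynomial geometry: length, lengthening velocity and moment arms from
// fitted monomial coefficients (moment arm about q_k is -dL/dq_k).
// ---------------------------------------------------------------------------

struct MusPoly {
  std::vector<int> coords;     // 0-based coordinate indices
  std::vector<double> coef;
  std::vector<std::vector<int> > expo; // term x coordinate exponents
};

struct Muscles {
  int nm;
  std::vector<double> fmax, lopt, lslack, vmax, h, pv;
  std::vector<MusPoly> poly;
};

static Muscles parse_muscles(const List& blob) {
  Muscles M;
  NumericVector fmax = blob["mus_fmax"], lopt = blob["mus_lopt"],
    lsl = blob["mus_lslack"], vmax = blob["mus_vmax"], h = blob["mus_h"],
    pv = blob["mus_pv"];
  M.nm = fmax.size();
  for (int j = 0; j < M.nm; ++j) {
    M.fmax.push_back(fmax[j]); M.lopt.push_back(lopt[j]);
    M.lslack.push_back(lsl[j]); M.vmax.push_back(vmax[j]);
    M.h.push_back(h[j]); M.pv.push_back(pv[j]);
  }
  List plist = blob["poly"];
  for (int j = 0; j < M.nm; ++j) {
    List pj = plist[j];
    MusPoly mp;
    IntegerVector cc = pj["coords"];
    for (int k = 0; k < cc.size(); ++k) mp.coords.push_back(cc[k] - 1);
    NumericVector cf = pj["coef"];
    IntegerMatrix ex = pj["expo"];
    for (int tI = 0; tI < cf.size(); ++tI) {
      mp.coef.push_back(cf[tI]);
      std::vector<int> row;
      for (int k = 0; k < ex.ncol(); ++k) row.push_back(ex(tI, k));
      mp.expo.push_back(row);
    }
    M.poly.push_back(mp);
  }
  return M;
}

// length and dL/dq_k for one muscle at one pose; power tables keep the
// evaluation linear in the number of terms
static void poly_eval(const MusPoly& mp, const double* q, double& L, double* dL) {
  int ns = mp.coords.size();
  double pw[4][8];
  for (int k = 0; k < ns; ++k) {
    double x = q[mp.coords[k]];
    pw[k][0] = 1.0;
    for (int e = 1; e < 8; ++e) pw[k][e] = pw[k][e - 1] * x;
  }
  L = 0.0;
  for (int k = 0; k < ns; ++k) dL[k] = 0.0;
  for (size_t tI = 0; tI < mp.coef.size(); ++tI) {
    const std::vector<int>& ex = mp.expo[tI];
    double term = mp.coef[tI];
    for (int k = 0; k < ns; ++k) term *= pw[k][ex[k]];
    L += term;
    for (int k = 0; k < ns; ++k) {
      int e = ex[k];
      if (e == 0) continue;
      double dterm = mp.coef[tI] * e * pw[k][e - 1];
      for (int kk = 0; kk < ns; ++kk) {
        if (kk != k) dterm *= pw[kk][ex[kk]];
      }
      dL[k] += dterm;
    }
  }
}

// [[Rcpp::export]]
List cpp_eval_mtu(List blob, NumericMatrix Q, NumericMatrix QD) {
  Muscles M = parse_muscles(blob);
  int nq = as<int>(blob["nq"]);
  int nt = Q.nrow();
  NumericMatrix L(nt, M.nm), V(nt, M.nm);
  List arms(M.nm);
  std::vector<NumericMatrix> R;
  for (int j = 0; j < M.nm; ++j)
    R.push_back(NumericMatrix(nt, (int)M.poly[j].coords.size()));
  std::vector<double> q(nq), dL(nq);
  for (int t = 0; t < nt; ++t) {
    for (int k = 0; k < nq; ++k) q[k] = Q(t, k);
    for (int j = 0; j < M.nm; ++j) {
      double Lj;
      poly_eval(M.poly[j], q.data(), Lj, dL.data());
      L(t, j) = Lj;
      double v = 0.0;
      for (size_t k = 0; k < M.poly[j].coords.size(); ++k) {
        v += dL[k] * QD(t, M.poly[j].coords[k]);
        R[j](t, k) = -dL[k];
      }
      V(t, j) = v;
    }
  }
  for (int j = 0; j < M.nm; ++j) arms[j] = R[j];
  return List::create(_["length"] = L, _["velocity"] = V, _["moment_arms"] = arms);
}

// ---------------------------------------------------------------------------
// Fused path-constraint evaluator. At each time row computes
//   rows 1..nm          : Hill equilibrium residuals (dimensionless)
//   rows nm+1..nm+nq    : inverse-dynamics consistency
//                         (root residual forces/moment; torque-actuator
//                          coordinate: tau_ID - a_tau*tau_max; muscle-driven:
//                          tau_ID - (muscle moments + tau_res))
//   rows +1, +2         : u_GRF - contact-model force (x, y)
// plus outputs tau_ID at the muscle-driven coordinates.
// Parameter vector par = (stiffness, damping, s1x, s1y, s2x, s2y, ...).
// ---------------------------------------------------------------------------

struct FusedModel {
  Skel s;
  Muscles M;
  Curves C;
  ContactPars cp;
  int nsph, sph_seg;              // 0-based segment of spheres
  double radius;
  int act_coord;                  // 0-based; -1 if none
  double act_taumax;
  std::vector<int> mus_coords;    // 0-based muscle-driven coordinates
  double bwss;                    // vertical support force (N)
  double pelvis_cx, pelvis_cy;    // pelvis com in pelvis frame
};

static FusedModel parse_fused(const List& blob, double bwss) {
  FusedModel F;
  F.s = parse_skel(blob);
  F.M = parse_muscles(blob);
  F.C = parse_curves(blob["curves"]);
  F.cp.mu = as<double>(blob["mu"]);
  F.cp.v0 = as<double>(blob["v0"]);
  F.cp.eps_d = as<double>(blob["eps_d"]);
  F.cp.eps_f = as<double>(blob["eps_f"]);
  F.nsph = as<int>(blob["nsph"]);
  F.sph_seg = as<int>(blob["sph_seg"]) - 1;
  F.radius = as<double>(blob["radius"]);
  F.act_coord = as<int>(blob["act_coord"]) - 1;
  F.act_taumax = as<double>(blob["act_taumax"]);
  IntegerVector mc = blob["mus_coord_idx"];
  for (int k = 0; k < mc.size(); ++k) F.mus_coords.push_back(mc[k] - 1);
  F.bwss = bwss;
  NumericMatrix com = blob["com"];
  F.pelvis_cx = com(0, 0); F.pelvis_cy = com(1, 0);
  return F;
}

// hill residual for one muscle given local values
static double hill_residual_one(const FusedModel& F, int j, double a, double ft,
                                double dft, double lmt, double vmt) {
  const Curves& C = F.C;
  double c2 = C.c2();
  double ltn = c2 + std::log((ft + C.c3) / C.c1) / C.kT;
  double lt = ltn * F.M.lslack[j];
  double lmp = lmt - lt;
  double h = F.M.h[j];
  double lm = std::sqrt(lmp * lmp + h * h);
  double cosp = lmp / lm;
  double lmn = lm / F.M.lopt[j];
  double dftdlt = C.kT * (ft + C.c3) / F.M.lslack[j]; // dF~t/dlt
  double vt = dft / dftdlt;
  double vmp = vmt - vt;
  double vm = vmp * cosp;
  double vmn = vm / F.M.vmax[j];
  double fm = a * f_act(C, lmn) * f_v(C, vmn) + f_pas(C, lmn) + C.beta * vmn;
  return ft - cosp * fm;
}

// evaluates all rows for all time points given flat input matrices
static void fused_eval_core(const FusedModel& F,
                            const NumericMatrix& Q, const NumericMatrix& QD,
                            const NumericMatrix& QDD, const NumericMatrix& AM,
                            const NumericMatrix& FT, const NumericMatrix& DFT,
                            const NumericMatrix& ATAU, const NumericMatrix& UGRF,
                            const NumericMatrix& TRES, const NumericVector& par,
                            NumericMatrix& OUT) {
  const Skel& s = F.s;
  int nt = Q.nrow(), nm = F.M.nm, nq = s.nq;
  int nmusdof = F.mus_coords.size();
  SegKin K(s.nseg);
  std::vector<double> q(nq), qd(nq), qdd(nq), tau(nq), dL(nq);
  double kstiff = par[0], cdamp = par[1];
  ExtF E;
  int next = F.nsph + 1;
  E.seg.resize(next); E.px.resize(next); E.py.resize(next);
  E.fx.resize(next); E.fy.resize(next); E.tz.resize(next);
  for (int t = 0; t < nt; ++t) {
    for (int j = 0; j < nq; ++j) { q[j] = Q(t, j); qd[j] = QD(t, j); qdd[j] = QDD(t, j); }
    fk_instant(s, q.data(), qd.data(), qdd.data(), K);
    // contact forces
    int fs = F.sph_seg;
    double ctf = std::cos(K.th[fs]), stf = std::sin(K.th[fs]);
    double fgx = 0.0, fgy = 0.0;
    for (int sp = 0; sp < F.nsph; ++sp) {
      double sx = par[2 + 2 * sp], sy = par[3 + 2 * sp];
      double rx = ctf * sx - stf * sy, ry = stf * sx + ctf * sy;
      double cxw = K.px[fs] + rx, cyw = K.py[fs] + ry;
      double cvxw = K.vx[fs] - K.w[fs] * ry, cvyw = K.vy[fs] + K.w[fs] * rx;
      double d = F.radius - cyw;
      double ddot = -cvyw;
      double fn, ftan;
      hc_force(d, ddot, cvxw, kstiff, cdamp, F.cp, fn, ftan);
      E.seg[sp] = fs; E.px[sp] = cxw; E.py[sp] = cyw;
      E.fx[sp] = ftan; E.fy[sp] = fn; E.tz[sp] = 0.0;
      fgx += ftan; fgy += fn;
    }
    // body-weight support at pelvis com
    double ct0 = std::cos(K.th[0]), st0 = std::sin(K.th[0]);
    E.seg[F.nsph] = 0;
    E.px[F.nsph] = K.px[0] + ct0 * F.pelvis_cx - st0 * F.pelvis_cy;
    E.py[F.nsph] = K.py[0] + st0 * F.pelvis_cx + ct0 * F.pelvis_cy;
    E.fx[F.nsph] = 0.0; E.fy[F.nsph] = F.bwss; E.tz[F.nsph] = 0.0;
    rnea_instant(s, K, E, tau.data());
    // muscle lengths / arms / forces
    int col = 0;
    std::vector<double> mus_mom(nq, 0.0);
    for (int j = 0; j < nm; ++j) {
      double L;
      poly_eval(F.M.poly[j], q.data(), L, dL.data());
      double vmt = 0.0;
      for (size_t k = 0; k < F.M.poly[j].coords.size(); ++k)
        vmt += dL[k] * qd[F.M.poly[j].coords[k]];
      double res = hill_residual_one(F, j, AM(t, j), FT(t, j), DFT(t, j), L, vmt);
      OUT(t, col + j) = res;
      double Ften = FT(t, j) * F.M.fmax[j];
      for (size_t k = 0; k < F.M.poly[j].coords.size(); ++k)
        mus_mom[F.M.poly[j].coords[k]] += -dL[k] * Ften;
    }
    col += nm;
    // inverse-dynamics consistency rows, coordinate order
    int mdof = 0;
    for (int j = 0; j < nq; ++j) {
      double r;
      if (j < 3) {
        r = tau[j]; // pelvis residuals must vanish
      } else if (j == F.act_coord) {
        r = tau[j] - ATAU(t, 0) * F.act_taumax;
      } else {
        r = tau[j] - (mus_mom[j] + TRES(t, mdof));
        ++mdof;
      }
      OUT(t, col + j) = r;
    }
    col += nq;
    OUT(t, col) = UGRF(t, 0) - fgx;
    OUT(t, col + 1) = UGRF(t, 1) - fgy;
    col += 2;
    // net joint moment outputs at muscle-driven coordinates
    for (int k = 0; k < nmusdof; ++k) OUT(t, col + k) = tau[F.mus_coords[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_path_eval(List blob, double bwss, NumericMatrix Q, NumericMatrix QD,
                            NumericMatrix QDD, NumericMatrix AM, NumericMatrix FT,
                            NumericMatrix DFT, NumericMatrix ATAU, NumericMatrix UGRF,
                            NumericMatrix TRES, NumericVector par) {
  FusedModel F = parse_fused(blob, bwss);
  int nt = Q.nrow();
  int nrow_out = F.M.nm + F.s.nq + 2 + (int)F.mus_coords.size();
  NumericMatrix OUT(nt, nrow_out);
  fused_eval_core(F, Q, QD, QDD, AM, FT, DFT, ATAU, UGRF, TRES, par, OUT);
  return OUT;
}

// Jacobian by central differences over the local column layout
// [q, qd, qdd, am, ft, dft, atau, ugrf, tres, par]; returns array
// (nt) x (nrow) x (ncol_local). Perturbations are applied to all time rows at
// once (rows are independent across time).
// [[Rcpp::export]]
NumericVector cpp_path_jacobian(List blob, double bwss, NumericMatrix Q, NumericMatrix QD,
                                NumericMatrix QDD, NumericMatrix AM, NumericMatrix FT,
                                NumericMatrix DFT, NumericMatrix ATAU, NumericMatrix UGRF,
                                NumericMatrix TRES, NumericVector par,
                                NumericVector steps) {
  FusedModel F = parse_fused(blob, bwss);
  int nt = Q.nrow();
  int nm = F.M.nm, nq = F.s.nq;
  int nmusdof = F.mus_coords.size();
  int nrow_out = nm + nq + 2 + nmusdof;
  int ncol = 3 * nq + 3 * nm + 1 + 2 + nmusdof + par.size();
  NumericVector J(Dimension(nt, nrow_out, ncol));
  NumericMatrix OP(nt, nrow_out), O0(nt, nrow_out);
  // copies we can perturb
  NumericMatrix q2(clone(Q)), qd2(clone(QD)), qdd2(clone(QDD)), am2(clone(AM)),
    ft2(clone(FT)), dft2(clone(DFT)), atau2(clone(ATAU)), ugrf2(clone(UGRF)),
    tres2(clone(TRES));
  NumericVector par2(clone(par));
  int col = 0;
  // forward differences against a single baseline evaluation
  fused_eval_core(F, q2, qd2, qdd2, am2, ft2, dft2, atau2, ugrf2, tres2, par2, O0);
  NumericMatrix* mats[9] = { &q2, &qd2, &qdd2, &am2, &ft2, &dft2, &atau2, &ugrf2, &tres2 };
  int widths[9] = { nq, nq, nq, nm, nm, nm, 1, 2, nmusdof };
  for (int b = 0; b < 9; ++b) {
    for (int c = 0; c < widths[b]; ++c) {
      double hstep = steps[col];
      NumericMatrix& Mv = *mats[b];
      for (int t = 0; t < nt; ++t) Mv(t, c) += hstep;
      fused_eval_core(F, q2, qd2, qdd2, am2, ft2, dft2, atau2, ugrf2, tres2, par2, OP);
      for (int t = 0; t < nt; ++t) Mv(t, c) -= hstep;
      for (int r = 0; r < nrow_out; ++r)
        for (int t = 0; t < nt; ++t)
          J[t + nt * (r + nrow_out * col)] = (OP(t, r) - O0(t, r)) / hstep;
      ++col;
    }
  }
  for (int p = 0; p < par.size(); ++p) {
    double hstep = steps[col];
    par2[p] += hstep;
    fused_eval_core(F, q2, qd2, qdd2, am2, ft2, dft2, atau2, ugrf2, tres2, par2, OP);
    par2[p] -= hstep;
    for (int r = 0; r < nrow_out; ++r)
      for (int t = 0; t < nt; ++t)
        J[t + nt * (r + nrow_out * col)] = (OP(t, r) - O0(t, r)) / hstep;
    ++col;
  }
  return J;
}

// [[Rcpp::export]]
List cpp_sphere_kinematics(List blob, NumericMatrix Q, NumericMatrix QD,
                           NumericMatrix spos) {
  // spos: nsph x 2 sphere positions in foot frame
  Skel s = parse_skel(blob);
  int fs = as<int>(blob["sph_seg"]) - 1;
  double radius = as<double>(blob["radius"]);
  int nt = Q.nrow(), nsph = spos.nrow();
  NumericMatrix QDD(nt, s.nq); // zeros
  SegKin K(s.nseg);
  std::vector<double> q(s.nq), qd(s.nq), qdd(s.nq, 0.0);
  NumericMatrix pen(nt, nsph), pvel(nt, nsph), slip(nt, nsph), cx(nt, nsph), cy(nt, nsph);
  for (int t = 0; t < nt; ++t) {
    for (int j = 0; j < s.nq; ++j) { q[j] = Q(t, j); qd[j] = QD(t, j); }
    fk_instant(s, q.data(), qd.data(), qdd.data(), K);
    double ct = std::cos(K.th[fs]), st = std::sin(K.th[fs]);
    for (int sp = 0; sp < nsph; ++sp) {
      double rx = ct * spos(sp, 0) - st * spos(sp, 1);
      double ry = st * spos(sp, 0) + ct * spos(sp, 1);
      double cxw = K.px[fs] + rx, cyw = K.py[fs] + ry;
      double cvx = K.vx[fs] - K.w[fs] * ry, cvy = K.vy[fs] + K.w[fs] * rx;
      pen(t, sp) = radius - cyw;
      pvel(t, sp) = -cvy;
      slip(t, sp) = cvx;
      cx(t, sp) = cxw; cy(t, sp) = cyw;
    }
  }
  return List::create(_["penetration"] = pen, _["penetration_velocity"] = pvel,
                      _["slip_velocity"] = slip, _["cx"] = cx, _["cy"] = cy);
}
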