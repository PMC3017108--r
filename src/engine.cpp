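// Simulation core: contact detection, generalized forces, overdamped motion
// with pairwise friction, stochastic growth, division, removal and the
// Wnt/Notch fate update.  Units: um, h, nN, nN*um.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "shape.h"
#include "mech.h"

using namespace Rcpp;

enum State { UNDIFF = 0, PANETH_PRIMED = 1, PANETH = 2,
             ENT_PROG = 3, GOB_PROG = 4, ENTEROCYTE = 5, GOBLET = 6 };

static inline bool is_terminal(int s) {
  return s == PANETH || s == ENTEROCYTE || s == GOBLET;
}
static inline bool is_paneth_family(int s) {
  return s == PANETH || s == PANETH_PRIMED;
}
static inline double lp_of(int s, double lp_pan, double lp_gob) {
  if (s == PANETH || s == PANETH_PRIMED) return lp_pan;
  if (s == GOBLET || s == GOB_PROG) return lp_gob;
  return 0.0;
}

struct Pars {
  Shape S;
  double E, nu, eps_c, K;
  double eta_c, eta_bm, eta_vo;
  double F_A_paneth, F_A_other;
  double R0, V0, tau;
  int n_growth_steps;
  double V_p_ratio, omega, eps_knot_paneth, eps_knot_other;
  int vp_abs;
  double z_p, z_d, lp_paneth, lp_goblet, tp_notch, td_notch, t_paneth, dt_max;
  double wnt_scale, z_flat, tp_wnt, td_wnt;
  int wnt_mode, notch_mode;  // 0 normal, 1 up, 2 down
};

static Pars read_pars(const List& pl) {
  Pars P;
  P.S = make_shape(as<double>(pl["z0"]), as<double>(pl["r0"]),
                   as<double>(pl["lambda1"]), as<double>(pl["lambda2"]));
  P.E = pl["E"]; P.nu = pl["nu"]; P.eps_c = pl["eps_c"]; P.K = pl["K"];
  P.eta_c = pl["eta_c"]; P.eta_bm = pl["eta_bm"]; P.eta_vo = pl["eta_vo"];
  P.F_A_paneth = pl["F_A_paneth"]; P.F_A_other = pl["F_A_other"];
  P.R0 = pl["R0"]; P.V0 = pl["V0"]; P.tau = pl["tau"];
  P.n_growth_steps = pl["n_growth_steps"];
  P.V_p_ratio = pl["V_p_ratio"]; P.vp_abs = pl["vp_abs"];
  P.omega = pl["omega"];
  P.eps_knot_paneth = pl["eps_knot_paneth"];
  P.eps_knot_other = pl["eps_knot_other"];
  P.z_p = pl["z_p"]; P.z_d = pl["z_d"];
  P.lp_paneth = pl["lp_paneth"]; P.lp_goblet = pl["lp_goblet"];
  P.tp_notch = pl["tp_notch"]; P.td_notch = pl["td_notch"];
  P.t_paneth = pl["t_paneth"]; P.dt_max = pl["dt_max"];
  P.wnt_scale = pl["wnt_scale"]; P.z_flat = pl["z_flat"];
  P.tp_wnt = pl["tp_wnt"]; P.td_wnt = pl["td_wnt"];
  P.wnt_mode = pl["wnt_mode"]; P.notch_mode = pl["notch_mode"];
  return P;
}

// ---------------------------------------------------------------- knot grid
struct KnotGrid {
  double x0, y0, z0, h;
  int nx, ny, nz;
  std::vector<std::vector<int>> bucket;
  std::vector<double> kx, ky, kz;
  int nk;

  void build(const NumericMatrix& knots, double cell) {
    nk = knots.nrow();
    kx.resize(nk); ky.resize(nk); kz.resize(nk);
    for (int i = 0; i < nk; ++i) {
      kx[i] = knots(i, 0); ky[i] = knots(i, 1); kz[i] = knots(i, 2);
    }
    h = cell;
    double xmin = 1e300, ymin = 1e300, zmin = 1e300;
    double xmax = -1e300, ymax = -1e300, zmax = -1e300;
    for (int i = 0; i < nk; ++i) {
      xmin = std::min(xmin, kx[i]); xmax = std::max(xmax, kx[i]);
      ymin = std::min(ymin, ky[i]); ymax = std::max(ymax, ky[i]);
      zmin = std::min(zmin, kz[i]); zmax = std::max(zmax, kz[i]);
    }
    x0 = xmin - 1e-6; y0 = ymin - 1e-6; z0 = zmin - 1e-6;
    nx = std::max(1, (int)std::floor((xmax - x0) / h) + 1);
    ny = std::max(1, (int)std::floor((ymax - y0) / h) + 1);
    nz = std::max(1, (int)std::floor((zmax - z0) / h) + 1);
    bucket.assign((size_t)nx * ny * nz, {});
    for (int i = 0; i < nk; ++i) {
      int ix = (int)((kx[i] - x0) / h), iy = (int)((ky[i] - y0) / h),
          iz = (int)((kz[i] - z0) / h);
      bucket[(size_t)(ix * ny + iy) * nz + iz].push_back(i);
    }
  }

  void query(double cx, double cy, double cz, double R,
             std::vector<int>& out, std::vector<double>& dist) const {
    out.clear(); dist.clear();
    int ix0 = std::max(0, (int)((cx - R - x0) / h));
    int ix1 = std::min(nx - 1, (int)((cx + R - x0) / h));
    int iy0 = std::max(0, (int)((cy - R - y0) / h));
    int iy1 = std::min(ny - 1, (int)((cy + R - y0) / h));
    int iz0 = std::max(0, (int)((cz - R - z0) / h));
    int iz1 = std::min(nz - 1, (int)((cz + R - z0) / h));
    double R2 = R * R;
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int iz = iz0; iz <= iz1; ++iz)
          for (int k : bucket[(size_t)(ix * ny + iy) * nz + iz]) {
            double dx = cx - kx[k], dy = cy - ky[k], dz = cz - kz[k];
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < R2) { out.push_back(k); dist.push_back(std::sqrt(d2)); }
          }
  }
};

// ------------------------------------------------------------------- cells
struct Cells {
  std::vector<double> x, y, z, R, Vt, Va, clock_, wait, birth, psince, prsince, zeta;
  std::vector<int> state, gsteps, clone, id, nK;
  std::vector<char> brdu;
  long next_id = 0;

  int n() const { return (int)x.size(); }

  void from_list(const List& L) {
    x = as<std::vector<double>>(L["x"]);
    y = as<std::vector<double>>(L["y"]);
    z = as<std::vector<double>>(L["z"]);
    R = as<std::vector<double>>(L["radius"]);
    Vt = as<std::vector<double>>(L["target_volume"]);
    state = as<std::vector<int>>(L["state"]);
    gsteps = as<std::vector<int>>(L["growth_steps"]);
    clock_ = as<std::vector<double>>(L["growth_clock"]);
    wait = as<std::vector<double>>(L["next_wait"]);
    clone = as<std::vector<int>>(L["clone"]);
    brdu.clear();
    for (int b : as<std::vector<int>>(L["brdu"])) brdu.push_back((char)b);
    birth = as<std::vector<double>>(L["birth_time"]);
    psince = as<std::vector<double>>(L["paneth_since"]);
    prsince = as<std::vector<double>>(L["primed_since"]);
    id = as<std::vector<int>>(L["id"]);
    int nn = n();
    Va.assign(nn, 0.0); nK.assign(nn, 0);
    if (L.containsElementNamed("bm_zeta")) {
      zeta = as<std::vector<double>>(L["bm_zeta"]);
      if ((int)zeta.size() != nn) zeta.assign(nn, 0.0);
    } else zeta.assign(nn, 0.0);
    for (int i = 0; i < nn; ++i) {
      if (!L.containsElementNamed("bm_zeta")) zeta[i] = z[i];
      next_id = std::max(next_id, (long)id[i] + 1);
    }
  }

  List to_list() const {
    std::vector<int> brdu_i(brdu.begin(), brdu.end());
    return List::create(
      _["x"] = x, _["y"] = y, _["z"] = z, _["radius"] = R,
      _["target_volume"] = Vt, _["state"] = state,
      _["growth_steps"] = gsteps, _["growth_clock"] = clock_,
      _["next_wait"] = wait, _["clone"] = clone, _["brdu"] = brdu_i,
      _["birth_time"] = birth, _["paneth_since"] = psince,
      _["primed_since"] = prsince, _["id"] = id,
      _["va"] = Va, _["n_knots"] = nK, _["bm_zeta"] = zeta);
  }

  void erase_sorted(const std::vector<int>& idx) {
    if (idx.empty()) return;
    int nn = n(), w = 0, k = 0;
    for (int i = 0; i < nn; ++i) {
      if (k < (int)idx.size() && idx[k] == i) { ++k; continue; }
      x[w] = x[i]; y[w] = y[i]; z[w] = z[i]; R[w] = R[i]; Vt[w] = Vt[i];
      Va[w] = Va[i]; clock_[w] = clock_[i]; wait[w] = wait[i];
      birth[w] = birth[i]; psince[w] = psince[i]; prsince[w] = prsince[i];
      zeta[w] = zeta[i];
      state[w] = state[i]; gsteps[w] = gsteps[i]; clone[w] = clone[i];
      id[w] = id[i]; nK[w] = nK[i]; brdu[w] = brdu[i];
      ++w;
    }
    x.resize(w); y.resize(w); z.resize(w); R.resize(w); Vt.resize(w);
    Va.resize(w); clock_.resize(w); wait.resize(w); birth.resize(w);
    psince.resize(w); prsince.resize(w); zeta.resize(w); state.resize(w);
    gsteps.resize(w);
    clone.resize(w); id.resize(w); nK.resize(w); brdu.resize(w);
  }
};

struct Events {
  std::vector<double> t;
  std::vector<int> type, id, a1, a2, a3;
  // type 0: division (id mother, a1 d1, a2 d2, a3 mother state)
  // type 1: removal  (id, a1 cause: 0 junction 1 anoikis 2 paneth_lifespan,
  //                   a2 state)
  // type 2: fate     (id, a1 from, a2 to)
  void div(double tt, int m, int d1, int d2, int st) {
    t.push_back(tt); type.push_back(0); id.push_back(m);
    a1.push_back(d1); a2.push_back(d2); a3.push_back(st);
  }
  void rem(double tt, int i, int cause, int st) {
    t.push_back(tt); type.push_back(1); id.push_back(i);
    a1.push_back(cause); a2.push_back(st); a3.push_back(0);
  }
  void fate(double tt, int i, int from, int to) {
    t.push_back(tt); type.push_back(2); id.push_back(i);
    a1.push_back(from); a2.push_back(to); a3.push_back(0);
  }
  DataFrame to_df() const {
    return DataFrame::create(
      _["time"] = t, _["type"] = type, _["id"] = id,
      _["a1"] = a1, _["a2"] = a2, _["a3"] = a3);
  }
};

struct Pair { int i, j; double d, area; };

struct Scratch {
  std::vector<Pair> pairs;
  std::vector<double> fx, fy, fz, fR, vx, vy, vz, vR;
  std::vector<double> press, dist_bm;
  // per-cell Gauss-Newton stiffness of the cell-BM potential (symmetric 3x3,
  // packed xx,xy,xz,yy,yz,zz) and its radius-equation analogue, for the
  // semi-implicit treatment of the stiff modes
  std::vector<double> kbm6, kbmR;
  std::vector<std::vector<int>> kn_idx;
  std::vector<std::vector<double>> kn_dist;
  // CG work
  std::vector<double> diag, cg_r, cg_p, cg_ap, cg_x, cg_b;
  int clamp_warn = 0, radius_warn = 0;
};

static void find_pairs(const Cells& C, std::vector<Pair>& pairs) {
  pairs.clear();
  int n = C.n();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = C.x[i] - C.x[j], dy = C.y[i] - C.y[j], dz = C.z[i] - C.z[j];
      double rr = C.R[i] + C.R[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < rr * rr) {
        Pair p; p.i = i; p.j = j; p.d = std::sqrt(d2);
        if (p.d < 1e-9) p.d = 1e-9;
        p.area = hertz_area(C.R[i], C.R[j], p.d);
        pairs.push_back(p);
      }
    }
}

// knot contacts and nearest-surface distance for every cell
static void bm_contacts(Cells& C, const KnotGrid* G, const Pars& P,
                        Scratch& W) {
  int n = C.n();
  W.kn_idx.resize(n); W.kn_dist.resize(n);
  W.dist_bm.assign(n, 1e300);
  for (int i = 0; i < n; ++i) {
    if (!G) { W.kn_idx[i].clear(); W.kn_dist[i].clear(); C.nK[i] = 0; continue; }
    G->query(C.x[i], C.y[i], C.z[i], C.R[i], W.kn_idx[i], W.kn_dist[i]);
    C.nK[i] = (int)W.kn_idx[i].size();
    double rho = std::sqrt(C.x[i] * C.x[i] + C.y[i] * C.y[i]);
    double lo = std::max(-P.S.z0, C.zeta[i] - 5.0);
    double hi = std::min(0.0, C.zeta[i] + 5.0);
    double d2;
    double zb = nearest_meridian(P.S, rho, C.z[i], lo, hi, d2);
    if ((zb <= lo + 1e-7 && lo > -P.S.z0 + 1e-7) ||
        (zb >= hi - 1e-7 && hi < -1e-7))
      zb = nearest_surface(P.S, rho, C.z[i], d2);
    C.zeta[i] = zb;
    W.dist_bm[i] = std::sqrt(d2);
  }
}

static void actual_volumes(Cells& C, Scratch& W, const Pars& P, bool has_bm) {
  int n = C.n();
  for (int i = 0; i < n; ++i)
    C.Va[i] = (4.0 / 3.0) * M_PI * C.R[i] * C.R[i] * C.R[i];
  for (const Pair& p : W.pairs) {
    double hi, hj;
    pair_cap_heights(C.R[p.i], C.R[p.j], p.d, hi, hj);
    C.Va[p.i] -= cap_volume(C.R[p.i], hi);
    C.Va[p.j] -= cap_volume(C.R[p.j], hj);
  }
  // V_a counts cell-cell overlaps only; the BM enters through the knot
  // potential, not the volume budget
  double floor_ = 0.05 * P.V0;
  for (int i = 0; i < n; ++i)
    if (C.Va[i] < floor_) { C.Va[i] = floor_; ++W.clamp_warn; }
}

// meridian up-tangent (unit, 3D) and outward normal at a cell's surface foot
static void surface_frame(const Pars& P, double cx, double cy, double zeta,
                          double tvec[3], double nvec[3]) {
  double rho = std::sqrt(cx * cx + cy * cy);
  double cphi = rho > 1e-9 ? cx / rho : 1.0;
  double sphi = rho > 1e-9 ? cy / rho : 0.0;
  double rp = shape_rp(P.S, zeta);
  double q = std::sqrt(1.0 + rp * rp);
  if (!std::isfinite(rp) || rp > 1e6) {  // at the pole the tangent is radial
    tvec[0] = cphi; tvec[1] = sphi; tvec[2] = 0.0;
    nvec[0] = 0.0; nvec[1] = 0.0; nvec[2] = -1.0;
    return;
  }
  tvec[0] = cphi * rp / q; tvec[1] = sphi * rp / q; tvec[2] = 1.0 / q;
  nvec[0] = cphi / q; nvec[1] = sphi / q; nvec[2] = -rp / q;
}

// generalized forces; pairs, knot contacts and Va must be current
static void forces(Cells& C, const Pars& P, Scratch& W, const KnotGrid* G,
                   bool migration) {
  int n = C.n();
  W.fx.assign(n, 0.0); W.fy.assign(n, 0.0); W.fz.assign(n, 0.0);
  W.fR.assign(n, 0.0);
  W.kbm6.assign(6 * n, 0.0);
  W.kbmR.assign(n, 0.0);
  W.press.assign(n, 0.0);
  for (int i = 0; i < n; ++i)
    W.press[i] = compression_pressure(C.Vt[i], C.Va[i], P.K);

  // bare-sphere part of the compression radius force: press * dVa/dR
  for (int i = 0; i < n; ++i)
    W.fR[i] += W.press[i] * 4.0 * M_PI * C.R[i] * C.R[i];

  for (const Pair& p : W.pairs) {
    int i = p.i, j = p.j;
    double Ri = C.R[i], Rj = C.R[j], d = p.d;
    double dA_dd, dA_dRi, dA_dRj;
    hertz_area_derivs(Ri, Rj, d, dA_dd, dA_dRi, dA_dRj);
    double dW_dd = -P.eps_c * dA_dd;
    double dW_dRi = -P.eps_c * dA_dRi;
    double dW_dRj = -P.eps_c * dA_dRj;
    double hz_dd, hz_dRi, hz_dRj;
    hertz_derivs(Ri, Rj, d, P.E, P.nu, hz_dd, hz_dRi, hz_dRj);
    dW_dd += hz_dd; dW_dRi += hz_dRi; dW_dRj += hz_dRj;

    // compression, coupled through the overlap caps
    double xi = contact_plane_xi(Ri, Rj, d), xj = d - xi;
    double hi, hj;
    pair_cap_heights(Ri, Rj, d, hi, hj);
    double dVi_dh = cap_dV_dh(Ri, hi), dVj_dh = cap_dV_dh(Rj, hj);
    // dVa_i/dd = -dVcap_i/dh * dh_i/dd, dh_i/dd = -xj/d
    double dVa_i_dd = dVi_dh * (xj / d);
    double dVa_j_dd = dVj_dh * (xi / d);
    dW_dd += -W.press[i] * dVa_i_dd - W.press[j] * dVa_j_dd;
    double dVa_i_dRi = -(cap_dV_dR(Ri, hi) + dVi_dh * (1.0 - Ri / d));
    double dVa_j_dRi = -(dVj_dh * (Ri / d));
    double dVa_j_dRj = -(cap_dV_dR(Rj, hj) + dVj_dh * (1.0 - Rj / d));
    double dVa_i_dRj = -(dVi_dh * (Rj / d));
    dW_dRi += -W.press[i] * dVa_i_dRi - W.press[j] * dVa_j_dRi;
    dW_dRj += -W.press[j] * dVa_j_dRj - W.press[i] * dVa_i_dRj;

    double nxv = (C.x[i] - C.x[j]) / d, nyv = (C.y[i] - C.y[j]) / d,
           nzv = (C.z[i] - C.z[j]) / d;
    W.fx[i] -= dW_dd * nxv; W.fy[i] -= dW_dd * nyv; W.fz[i] -= dW_dd * nzv;
    W.fx[j] += dW_dd * nxv; W.fy[j] += dW_dd * nyv; W.fz[j] += dW_dd * nzv;
    W.fR[i] -= dW_dRi; W.fR[j] -= dW_dRj;
  }

  if (G) {
    for (int i = 0; i < n; ++i) {
      double eps = is_paneth_family(C.state[i]) ? P.eps_knot_paneth
                                                : P.eps_knot_other;
      double* K6 = &W.kbm6[6 * i];
      int m = (int)W.kn_idx[i].size();
      if (m > 0) {
        // knot-based repulsive barrier, scaled by the interacting-knot count
        double eps_s = eps / m;
        for (int k = 0; k < m; ++k) {
          double d = std::max(W.kn_dist[i][k], 1e-9);
          double dW_dd, dW_dR;
          knot_rep_derivs(C.R[i], d, eps_s, P.omega, dW_dd, dW_dR);
          if (dW_dd == 0.0 && dW_dR == 0.0) continue;
          int kk = W.kn_idx[i][k];
          double nxk = (C.x[i] - G->kx[kk]) / d;
          double nyk = (C.y[i] - G->ky[kk]) / d;
          double nzk = (C.z[i] - G->kz[kk]) / d;
          W.fx[i] -= dW_dd * nxk; W.fy[i] -= dW_dd * nyk; W.fz[i] -= dW_dd * nzk;
          W.fR[i] -= dW_dR;
          double kc = knot_rep_curvature(C.R[i], d, eps_s, P.omega);
          K6[0] += kc * nxk * nxk; K6[1] += kc * nxk * nyk;
          K6[2] += kc * nxk * nzk; K6[3] += kc * nyk * nyk;
          K6[4] += kc * nyk * nzk; K6[5] += kc * nzk * nzk;
          W.kbmR[i] += kc * (d / C.R[i]) * (d / C.R[i]);
        }
      }
      // adhesive skin: continuum limit over the smooth surface
      double dist = W.dist_bm[i];
      if (dist < C.R[i] && dist < 1e290) {
        double dW_dd, dW_dR;
        bm_adhesion_derivs(C.R[i], dist, eps, P.omega, dW_dd, dW_dR);
        double rho = std::sqrt(C.x[i] * C.x[i] + C.y[i] * C.y[i]);
        double rft = shape_r(P.S, C.zeta[i]);
        double sx = rft * (rho > 1e-9 ? C.x[i] / rho : 1.0);
        double sy = rft * (rho > 1e-9 ? C.y[i] / rho : 0.0);
        double ux = C.x[i] - sx, uy = C.y[i] - sy, uz = C.z[i] - C.zeta[i];
        double un = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (un > 1e-9) {
          ux /= un; uy /= un; uz /= un;
          W.fx[i] -= dW_dd * ux; W.fy[i] -= dW_dd * uy; W.fz[i] -= dW_dd * uz;
          W.fR[i] -= dW_dR;
          double kc = bm_adhesion_curvature(C.R[i], dist, eps, P.omega);
          K6[0] += kc * ux * ux; K6[1] += kc * ux * uy;
          K6[2] += kc * ux * uz; K6[3] += kc * uy * uy;
          K6[4] += kc * uy * uz; K6[5] += kc * uz * uz;
          W.kbmR[i] += kc * (dist / C.R[i]) * (dist / C.R[i]);
        }
      }
      // migration force along the meridian tangent, on BM-attached cells:
      // Paneth-lineage cells crawl down, primed and differentiated cells
      // move up, undifferentiated cells move only passively
      if (migration && W.dist_bm[i] <= C.R[i] && C.state[i] != UNDIFF) {
        double tv[3], nv[3];
        surface_frame(P, C.x[i], C.y[i], C.zeta[i], tv, nv);
        double f = is_paneth_family(C.state[i]) ? -P.F_A_paneth : P.F_A_other;
        W.fx[i] += f * tv[0]; W.fy[i] += f * tv[1]; W.fz[i] += f * tv[2];
      }
    }
  }
}

// Solve the overdamped friction system (eta_bm + sum gamma) v_i -
// sum gamma v_j = F_i, gamma = eta_c * contact area, by conjugate gradients
// (same SPD matrix for the three components).  Radius motion is independent:
// eta_vo dR/dt = F_R.
// The stiff cell-BM normal mode is treated semi-implicitly: the friction
// operator gains a rank-one term dt_imp * k_i (u_i u_i^T) per cell (backward
// Euler on the linearised knot potential).  Equilibria and tangential
// mobilities are unaffected; the attachment transient is over-damped.
static void solve_motion(const Cells& C, const Pars& P, Scratch& W,
                         double dt_imp) {
  int n = C.n();
  W.diag.assign(n, P.eta_bm);
  for (const Pair& p : W.pairs) {
    double g = P.eta_c * p.area;
    W.diag[p.i] += g; W.diag[p.j] += g;
  }
  int N3 = 3 * n;
  auto mul = [&](const std::vector<double>& in, std::vector<double>& out) {
    for (int i = 0; i < n; ++i) {
      double vx = in[i], vy = in[n + i], vz = in[2 * n + i];
      const double* K6 = &W.kbm6[6 * i];
      out[i] = W.diag[i] * vx +
               dt_imp * (K6[0] * vx + K6[1] * vy + K6[2] * vz);
      out[n + i] = W.diag[i] * vy +
               dt_imp * (K6[1] * vx + K6[3] * vy + K6[4] * vz);
      out[2 * n + i] = W.diag[i] * vz +
               dt_imp * (K6[2] * vx + K6[4] * vy + K6[5] * vz);
    }
    for (const Pair& p : W.pairs) {
      double g = P.eta_c * p.area;
      for (int c = 0; c < 3; ++c) {
        out[c * n + p.i] -= g * in[c * n + p.j];
        out[c * n + p.j] -= g * in[c * n + p.i];
      }
    }
  };
  std::vector<double>& b = W.cg_b; b.assign(N3, 0.0);
  for (int i = 0; i < n; ++i) {
    b[i] = W.fx[i]; b[n + i] = W.fy[i]; b[2 * n + i] = W.fz[i];
  }
  std::vector<double>& xv = W.cg_x; xv.assign(N3, 0.0);
  std::vector<double>& r = W.cg_r; std::vector<double>& pd = W.cg_p;
  std::vector<double>& ap = W.cg_ap;
  r.assign(N3, 0.0); pd.assign(N3, 0.0); ap.assign(N3, 0.0);
  // Jacobi start (diagonal of the full operator)
  for (int i = 0; i < n; ++i) {
    const double* K6 = &W.kbm6[6 * i];
    xv[i] = b[i] / (W.diag[i] + dt_imp * K6[0]);
    xv[n + i] = b[n + i] / (W.diag[i] + dt_imp * K6[3]);
    xv[2 * n + i] = b[2 * n + i] / (W.diag[i] + dt_imp * K6[5]);
  }
  mul(xv, ap);
  double b2 = 0.0, rs = 0.0;
  for (int i = 0; i < N3; ++i) {
    r[i] = b[i] - ap[i]; b2 += b[i] * b[i]; rs += r[i] * r[i];
  }
  if (b2 > 1e-300) {
    pd = r;
    for (int it = 0; it < 400 && rs > 1e-18 * b2; ++it) {
      mul(pd, ap);
      double pap = 0.0;
      for (int i = 0; i < N3; ++i) pap += pd[i] * ap[i];
      if (pap <= 0.0) break;
      double alpha = rs / pap;
      double rs2 = 0.0;
      for (int i = 0; i < N3; ++i) {
        xv[i] += alpha * pd[i];
        r[i] -= alpha * ap[i];
        rs2 += r[i] * r[i];
      }
      double beta = rs2 / rs;
      rs = rs2;
      for (int i = 0; i < N3; ++i) pd[i] = r[i] + beta * pd[i];
    }
  }
  W.vx.assign(n, 0.0); W.vy.assign(n, 0.0); W.vz.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    W.vx[i] = xv[i]; W.vy[i] = xv[n + i]; W.vz[i] = xv[2 * n + i];
  }
  W.vR.assign(n, 0.0);
  for (int i = 0; i < n; ++i)
    W.vR[i] = W.fR[i] / (P.eta_vo + dt_imp * W.kbmR[i]);
}

// Wnt activity with perturbation overrides
static inline double wnt_of(const Pars& P, double z) {
  double f = wnt_link(P.S, z, P.z_flat, P.wnt_scale);
  if (P.wnt_mode == 1) return std::max(f, P.tp_wnt);
  if (P.wnt_mode == 2) return std::min(f, 0.5 * (P.tp_wnt + P.td_wnt));
  return f;
}

static inline double notch_of(const Pars& P, double raw) {
  if (P.notch_mode == 1) return std::max(raw, std::max(P.tp_notch, P.td_notch));
  if (P.notch_mode == 2) return 0.0;
  return raw;
}

// fate truth table (never returns a terminal Paneth; that transition is
// tied to cell-cycle completion)
static int classify(double Iw, double In, const Pars& P) {
  if (Iw >= P.tp_wnt) return (In >= P.tp_notch) ? UNDIFF : PANETH_PRIMED;
  if (Iw >= P.td_wnt) return (In >= P.tp_notch) ? ENT_PROG : GOB_PROG;
  return (In >= P.td_notch) ? ENTEROCYTE : GOBLET;
}

// [[Rcpp::export]]
int cpp_classify_fate(double i_wnt, double i_notch, List pars) {
  Pars P = read_pars(pars);
  return classify(i_wnt, i_notch, P);
}

// one full simulation; returns updated cells, trajectory and events
// [[Rcpp::export]]
List cpp_simulate(List cells_list, Nullable<NumericMatrix> knots_,
                  List pars, double t0, double duration, double obs_dt,
                  bool migration = true, bool biology = true,
                  bool interactions = true) {
  Pars P = read_pars(pars);
  Cells C; C.from_list(cells_list);
  KnotGrid grid;
  const KnotGrid* G = nullptr;
  if (interactions && knots_.isNotNull()) {
    NumericMatrix km(knots_);
    if (km.nrow() > 0) { grid.build(km, 2.0 * P.R0); G = &grid; }
  }
  Scratch W;
  Events E;

  double t = t0, t_end = t0 + duration;
  double next_obs = t0 + obs_dt;
  long cum_div = 0, cum_junction = 0, cum_anoikis = 0, cum_paneth = 0,
       cum_dediff = 0;
  std::vector<double> tr_t;
  std::vector<long> tr_n, tr_cnt[7], tr_div, tr_jun, tr_ano, tr_pan, tr_ded;
  auto record = [&](double tt) {
    tr_t.push_back(tt);
    long cnt[7] = {0, 0, 0, 0, 0, 0, 0};
    for (int s : C.state) ++cnt[s];
    long tot = 0;
    for (int s = 0; s < 7; ++s) { tr_cnt[s].push_back(cnt[s]); tot += cnt[s]; }
    tr_n.push_back(tot);
    tr_div.push_back(cum_div); tr_jun.push_back(cum_junction);
    tr_ano.push_back(cum_anoikis); tr_pan.push_back(cum_paneth);
    tr_ded.push_back(cum_dediff);
  };

  int guard = 0;
  const int guard_max = 50000000;
  while (t < t_end - 1e-7 && C.n() > 0) {
    if (++guard > guard_max) stop("step limit exceeded");
    // flush observer boundaries reached up to float slivers, so the
    // time-step caps below never collapse to rounding residue
    while (next_obs <= t + 1e-7 && next_obs <= t_end + 1e-7) {
      record(next_obs);
      next_obs += obs_dt;
    }
    int n = C.n();
    double dt = P.dt_max;
    if (interactions) {
      // (1) contacts
      find_pairs(C, W.pairs);
      bm_contacts(C, G, P, W);
      actual_volumes(C, W, P, G != nullptr);
      // (2) forces
      forces(C, P, W, G, migration);
      // (3) motion: adaptive dt with interpenetration rejection
      solve_motion(C, P, W, P.dt_max);
      double vmax = 0.0;
      for (int i = 0; i < n; ++i) {
        double v = std::sqrt(W.vx[i] * W.vx[i] + W.vy[i] * W.vy[i] +
                             W.vz[i] * W.vz[i]) + std::fabs(W.vR[i]);
        vmax = std::max(vmax, v);
      }
      if (vmax > 0.0) dt = std::min(dt, 0.1 * P.R0 / vmax);
      dt = std::min(dt, t_end - t);
      if (next_obs < t_end + 1e-12) dt = std::min(dt, next_obs - t);
      std::vector<double> nxp(n), nyp(n), nzp(n), nRp(n);
      for (;;) {
        if (dt < 1e-6) stop("time step underflow (dt < 1e-6 h) at t = %f", t);
        for (int i = 0; i < n; ++i) {
          nxp[i] = C.x[i] + W.vx[i] * dt;
          nyp[i] = C.y[i] + W.vy[i] * dt;
          nzp[i] = C.z[i] + W.vz[i] * dt;
          nRp[i] = C.R[i] + W.vR[i] * dt;
        }
        bool ok = true;
        for (int i = 0; i < n && ok; ++i)
          for (int j = i + 1; j < n; ++j) {
            double dx = nxp[i] - nxp[j], dy = nyp[i] - nyp[j],
                   dz = nzp[i] - nzp[j];
            double lim = 0.2 * (nRp[i] + nRp[j]);
            double d2n = dx * dx + dy * dy + dz * dz;
            if (d2n < lim * lim) {
              // tolerate a pre-existing violation (e.g. a fresh daughter
              // wedged against a neighbour) as long as the step relieves it
              double ox = C.x[i] - C.x[j], oy = C.y[i] - C.y[j],
                     oz = C.z[i] - C.z[j];
              double d2o = ox * ox + oy * oy + oz * oz;
              if (d2n < d2o) { ok = false; break; }
            }
          }
        if (ok) break;
        dt *= 0.5;
      }
      for (int i = 0; i < n; ++i) {
        C.x[i] = nxp[i]; C.y[i] = nyp[i]; C.z[i] = nzp[i];
        double Rn = nRp[i];
        double Rlo = 0.4 * P.R0, Rhi = 1.6 * P.R0;
        if (Rn < Rlo) { Rn = Rlo; ++W.radius_warn; }
        if (Rn > Rhi) { Rn = Rhi; ++W.radius_warn; }
        C.R[i] = Rn;
      }
    } else {
      // isolated-cell mode: no mechanics; cells stay put and uncompressed
      W.pairs.clear();
      for (int i = 0; i < n; ++i) { C.nK[i] = 0; C.Va[i] = C.Vt[i]; }
      dt = std::min(dt, t_end - t);
      if (next_obs < t_end + 1e-12) dt = std::min(dt, next_obs - t);
    }
    t += dt;
    // land exactly on observer boundaries so that checkpoint replays align
    if (std::fabs(next_obs - t) < 1e-9) t = next_obs;

    if (biology) {
      // (4) growth: exponential waiting times on an active-growth clock,
      // suppressed under contact inhibition
      for (int i = 0; i < n; ++i) {
        int st = C.state[i];
        bool can = (st == UNDIFF || st == ENT_PROG) ||
                   (C.gsteps[i] > 0 && (st == PANETH_PRIMED || st == GOB_PROG));
        if (!can) continue;
        double vref = P.vp_abs ? P.V0 : C.Vt[i];
        if (C.Va[i] < P.V_p_ratio * vref) continue;  // contact inhibited
        C.clock_[i] += dt;
        if (C.wait[i] < 0.0)
          C.wait[i] = R::rexp(P.tau / P.n_growth_steps);
        while (C.clock_[i] >= C.wait[i] && C.Vt[i] < 2.0 * P.V0 - 1e-9) {
          C.clock_[i] -= C.wait[i];
          C.wait[i] = R::rexp(P.tau / P.n_growth_steps);
          C.gsteps[i] += 1;
          C.Vt[i] += P.V0 / P.n_growth_steps;
        }
      }
      // (5) divisions
      int n_before = n;
      for (int i = 0; i < n_before; ++i) {
        if (C.Vt[i] < 2.0 * P.V0 - 1e-9) continue;
        double tv[3], nv[3];
        surface_frame(P, C.x[i], C.y[i], C.zeta[i], tv, nv);
        // random direction in the local tangent plane
        double phi_az = std::atan2(C.y[i], C.x[i]);
        double ex = -std::sin(phi_az), ey = std::cos(phi_az), ez = 0.0;
        double th = R::runif(0.0, 2.0 * M_PI);
        double ux = std::cos(th) * tv[0] + std::sin(th) * ex;
        double uy = std::cos(th) * tv[1] + std::sin(th) * ey;
        double uz = std::cos(th) * tv[2] + std::sin(th) * ez;
        double un = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= un; uy /= un; uz /= un;
        double off = 0.5 * P.R0;
        int id1 = (int)C.next_id++, id2 = (int)C.next_id++;
        int mid = C.id[i], mst = C.state[i];
        // daughter 1 replaces the mother in place
        double mx = C.x[i], my = C.y[i], mz = C.z[i];
        double d1x = mx + off * ux, d1y = my + off * uy, d1z = mz + off * uz;
        double d2x = mx - off * ux, d2y = my - off * uy, d2z = mz - off * uz;
        if (G) {
          // snap each daughter to its own equilibrium height above the BM
          // (the mother, being larger, sits farther out than a fresh cell
          // can reach)
          auto snap = [&](double& px, double& py, double& pz) {
            double rho = std::sqrt(px * px + py * py);
            double dd2;
            double zb = nearest_meridian(P.S, rho, pz,
                                         std::max(-P.S.z0, C.zeta[i] - 8.0),
                                         std::min(0.0, C.zeta[i] + 8.0), dd2);
            double rft = shape_r(P.S, zb);
            double cph = rho > 1e-9 ? px / rho : 1.0;
            double sph = rho > 1e-9 ? py / rho : 0.0;
            double fx = rft * cph, fy = rft * sph, fz = zb;
            double vx2 = px - fx, vy2 = py - fy, vz2 = pz - fz;
            double vn = std::sqrt(vx2 * vx2 + vy2 * vy2 + vz2 * vz2);
            double h = P.omega * P.R0;
            if (vn > 1e-9) {
              px = fx + vx2 / vn * h; py = fy + vy2 / vn * h;
              pz = fz + vz2 / vn * h;
            }
          };
          snap(d1x, d1y, d1z);
          snap(d2x, d2y, d2z);
        }
        C.x[i] = d1x; C.y[i] = d1y; C.z[i] = d1z;
        C.R[i] = P.R0; C.Vt[i] = P.V0; C.Va[i] = P.V0;
        C.gsteps[i] = 0; C.clock_[i] = 0.0; C.wait[i] = -1.0;
        C.birth[i] = t; C.id[i] = id1;
        // daughter 2 appended
        C.x.push_back(d2x); C.y.push_back(d2y); C.z.push_back(d2z);
        C.R.push_back(P.R0); C.Vt.push_back(P.V0); C.Va.push_back(P.V0);
        C.clock_.push_back(0.0); C.wait.push_back(-1.0);
        C.birth.push_back(t); C.psince.push_back(C.psince[i]);
        C.prsince.push_back(C.prsince[i]);
        C.zeta.push_back(C.zeta[i]);
        C.state.push_back(mst); C.gsteps.push_back(0);
        C.clone.push_back(C.clone[i]); C.id.push_back(id2);
        C.nK.push_back(C.nK[i]); C.brdu.push_back(C.brdu[i]);
        E.div(t, mid, id1, id2, mst);
        ++cum_div;
        if (mst == PANETH_PRIMED && C.prsince[i] >= 0.0 &&
            t - C.prsince[i] >= P.tau) {
          // terminal Paneth differentiation at cell-cycle completion, for
          // mothers committed (continuously primed) for at least tau
          C.state[i] = PANETH; C.psince[i] = t;
          C.state.back() = PANETH; C.psince.back() = t;
          E.fate(t, id1, PANETH_PRIMED, PANETH);
          E.fate(t, id2, PANETH_PRIMED, PANETH);
        }
      }
      n = C.n();
      // (6) removals; recompute BM contacts after motion and division
      if (interactions) bm_contacts(C, G, P, W);
      std::vector<int> kill;
      for (int i = 0; i < n; ++i) {
        if (C.z[i] > 0.0) {
          E.rem(t, C.id[i], 0, C.state[i]); ++cum_junction;
          kill.push_back(i);
        } else if (G && W.dist_bm[i] > C.R[i]) {
          E.rem(t, C.id[i], 1, C.state[i]); ++cum_anoikis;
          E.a3.back() = (int)std::lround(C.z[i]);
          kill.push_back(i);
        } else if (C.state[i] == PANETH &&
                   t - C.psince[i] > P.t_paneth) {
          E.rem(t, C.id[i], 2, C.state[i]); ++cum_paneth;
          kill.push_back(i);
        }
      }
      C.erase_sorted(kill);
      n = C.n();
      // (7) state-vector update and fate reclassification.  Cells are
      // visited in a random sequential order and each sees the already
      // updated states of its neighbours: a synchronous update lets the
      // lateral-inhibition rule flip whole contact clusters in lockstep
      // (a period-2 artefact); the asynchronous sweep settles into the
      // stable checkerboard patterns instead.
      if (interactions) find_pairs(C, W.pairs); else W.pairs.clear();
      static std::vector<std::vector<int>> nb;
      nb.resize(n);
      for (int i = 0; i < n; ++i) nb[i].clear();
      for (const Pair& p : W.pairs) {
        nb[p.i].push_back(p.j);
        nb[p.j].push_back(p.i);
      }
      std::vector<int> order(n);
      for (int i = 0; i < n; ++i) order[i] = i;
      if (interactions)  // without contacts the update order is immaterial
        for (int i = n - 1; i > 0; --i) {
          int j = (int)std::floor(R::runif(0.0, 1.0) * (i + 1));
          if (j > i) j = i;
          std::swap(order[i], order[j]);
        }
      for (int oi = 0; oi < n; ++oi) {
        int i = order[oi];
        int st = C.state[i];
        if (is_terminal(st)) continue;
        double Iw = wnt_of(P, C.z[i]);
        double raw = 0.0;
        for (int j : nb[i])
          raw += lp_of(C.state[j], P.lp_paneth, P.lp_goblet);
        double In = notch_of(P, raw);
        int tgt = classify(Iw, In, P);
        bool in_cycle = C.gsteps[i] > 0;
        if ((tgt == ENTEROCYTE || tgt == GOBLET) && in_cycle)
          continue;  // finish the running cycle before terminal differentiation
        if (tgt != st) {
          E.fate(t, C.id[i], st, tgt);
          if (st == ENT_PROG && tgt == UNDIFF) ++cum_dediff;
          C.state[i] = tgt;
          C.prsince[i] = (tgt == PANETH_PRIMED) ? t : -1.0;
        }
      }
    }

    Rcpp::checkUserInterrupt();
  }
  if (t > t_end - 1e-7) t = t_end;
  while (next_obs <= t + 1e-7 && next_obs <= t_end + 1e-7) {
    record(next_obs);
    next_obs += obs_dt;
  }

  List traj = List::create(
    _["time"] = tr_t, _["n"] = tr_n,
    _["n_undifferentiated"] = tr_cnt[0], _["n_paneth_primed"] = tr_cnt[1],
    _["n_paneth"] = tr_cnt[2], _["n_enterocyte_progenitor"] = tr_cnt[3],
    _["n_goblet_progenitor"] = tr_cnt[4], _["n_enterocyte"] = tr_cnt[5],
    _["n_goblet"] = tr_cnt[6],
    _["cum_divisions"] = tr_div, _["cum_junction_exits"] = tr_jun,
    _["cum_anoikis"] = tr_ano, _["cum_paneth_deaths"] = tr_pan,
    _["cum_dedifferentiation"] = tr_ded);

  return List::create(
    _["cells"] = C.to_list(), _["time"] = t, _["trajectory"] = traj,
    _["events"] = E.to_df(),
    _["clamp_warnings"] = W.clamp_warn, _["radius_warnings"] = W.radius_warn);
}

// mechanical relaxation (no growth, no fate, optional migration)
// [[Rcpp::export]]
List cpp_relax(List cells_list, Nullable<NumericMatrix> knots_, List pars,
               double tol = 0.01, int max_steps = 2000,
               bool migration = false) {
  Pars P = read_pars(pars);
  Cells C; C.from_list(cells_list);
  KnotGrid grid;
  const KnotGrid* G = nullptr;
  if (knots_.isNotNull()) {
    NumericMatrix km(knots_);
    if (km.nrow() > 0) { grid.build(km, 2.0 * P.R0); G = &grid; }
  }
  Scratch W;
  double maxdisp = 1e300;
  int steps = 0;
  int n = C.n();
  std::vector<double> nxp, nyp, nzp, nRp;
  while (steps < max_steps && maxdisp > tol) {
    find_pairs(C, W.pairs);
    bm_contacts(C, G, P, W);
    actual_volumes(C, W, P, G != nullptr);
    forces(C, P, W, G, migration);
    solve_motion(C, P, W, P.dt_max);
    n = C.n();
    double vmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = std::sqrt(W.vx[i] * W.vx[i] + W.vy[i] * W.vy[i] +
                           W.vz[i] * W.vz[i]) + std::fabs(W.vR[i]);
      vmax = std::max(vmax, v);
    }
    double dt = P.dt_max;
    if (vmax > 0.0) dt = std::min(dt, 0.1 * P.R0 / vmax);
    nxp.assign(n, 0.0); nyp.assign(n, 0.0); nzp.assign(n, 0.0);
    nRp.assign(n, 0.0);
    for (;;) {
      if (dt < 1e-9) break;
      for (int i = 0; i < n; ++i) {
        nxp[i] = C.x[i] + W.vx[i] * dt;
        nyp[i] = C.y[i] + W.vy[i] * dt;
        nzp[i] = C.z[i] + W.vz[i] * dt;
        nRp[i] = C.R[i] + W.vR[i] * dt;
      }
      bool ok = true;
      for (int i = 0; i < n && ok; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = nxp[i] - nxp[j], dy = nyp[i] - nyp[j],
                 dz = nzp[i] - nzp[j];
          double lim = 0.2 * (nRp[i] + nRp[j]);
          double d2n = dx * dx + dy * dy + dz * dz;
          if (d2n < lim * lim) {
            double ox = C.x[i] - C.x[j], oy = C.y[i] - C.y[j],
                   oz = C.z[i] - C.z[j];
            double d2o = ox * ox + oy * oy + oz * oz;
            if (d2n < d2o) { ok = false; break; }
          }
        }
      if (ok) break;
      dt *= 0.5;
    }
    maxdisp = 0.0;
    for (int i = 0; i < n; ++i) {
      maxdisp = std::max(maxdisp, std::sqrt(
        (nxp[i] - C.x[i]) * (nxp[i] - C.x[i]) +
        (nyp[i] - C.y[i]) * (nyp[i] - C.y[i]) +
        (nzp[i] - C.z[i]) * (nzp[i] - C.z[i])));
      C.x[i] = nxp[i]; C.y[i] = nyp[i]; C.z[i] = nzp[i];
      C.R[i] = std::min(std::max(nRp[i], 0.4 * P.R0), 1.6 * P.R0);
    }
    ++steps;
  }
  // leave Va / nK fresh for the caller
  find_pairs(C, W.pairs);
  bm_contacts(C, G, P, W);
  actual_volumes(C, W, P, G != nullptr);
  return List::create(_["cells"] = C.to_list(), _["steps"] = steps,
                      _["max_displacement"] = maxdisp);
}

// forces and derived per-cell quantities for a static configuration
// [[Rcpp::export]]
List cpp_net_forces(List cells_list, Nullable<NumericMatrix> knots_,
                    List pars, bool migration = true) {
  Pars P = read_pars(pars);
  Cells C; C.from_list(cells_list);
  KnotGrid grid;
  const KnotGrid* G = nullptr;
  if (knots_.isNotNull()) {
    NumericMatrix km(knots_);
    if (km.nrow() > 0) { grid.build(km, 2.0 * P.R0); G = &grid; }
  }
  Scratch W;
  find_pairs(C, W.pairs);
  bm_contacts(C, G, P, W);
  actual_volumes(C, W, P, G != nullptr);
  forces(C, P, W, G, migration);
  int n = C.n();
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = W.fx[i]; F(i, 1) = W.fy[i]; F(i, 2) = W.fz[i];
  }
  NumericVector FR(n), Va(n), dbm(n);
  IntegerVector nk(n);
  for (int i = 0; i < n; ++i) {
    FR[i] = W.fR[i]; Va[i] = C.Va[i]; nk[i] = C.nK[i];
    dbm[i] = W.dist_bm[i] < 1e290 ? W.dist_bm[i] : NA_REAL;
  }
  return List::create(_["force"] = F, _["force_radius"] = FR,
                      _["actual_volume"] = Va, _["n_knots"] = nk,
                      _["dist_bm"] = dbm);
}

// total mechanical energy of a configuration (for relaxation tests)
// [[Rcpp::export]]
double cpp_total_energy(List cells_list, Nullable<NumericMatrix> knots_,
                        List pars) {
  Pars P = read_pars(pars);
  Cells C; C.from_list(cells_list);
  KnotGrid grid;
  const KnotGrid* G = nullptr;
  if (knots_.isNotNull()) {
    NumericMatrix km(knots_);
    if (km.nrow() > 0) { grid.build(km, 2.0 * P.R0); G = &grid; }
  }
  Scratch W;
  find_pairs(C, W.pairs);
  bm_contacts(C, G, P, W);
  actual_volumes(C, W, P, G != nullptr);
  double Wtot = 0.0;
  for (const Pair& p : W.pairs) {
    Wtot += -P.eps_c * p.area;
    Wtot += hertz_energy(C.R[p.i], C.R[p.j], p.d, P.E, P.nu);
  }
  int n = C.n();
  for (int i = 0; i < n; ++i) {
    Wtot += compression_energy(C.Vt[i], C.Va[i], P.K);
    if (G) {
      double eps = is_paneth_family(C.state[i]) ? P.eps_knot_paneth
                                                : P.eps_knot_other;
      int m = (int)W.kn_idx[i].size();
      for (int k = 0; k < m; ++k)
        Wtot += knot_rep_energy(C.R[i], W.kn_dist[i][k], eps / m, P.omega);
      if (W.dist_bm[i] < C.R[i] && W.dist_bm[i] < 1e290)
        Wtot += bm_adhesion_energy(C.R[i], W.dist_bm[i], eps, P.omega);
    }
  }
  return Wtot;
}

// knots within interaction range of a point, via the spatial grid
// [[Rcpp::export]]
IntegerVector cpp_knots_in_range(NumericMatrix knots, NumericVector centre,
                                 double radius) {
  KnotGrid grid;
  grid.build(knots, std::max(radius, 1.0));
  std::vector<int> idx;
  std::vector<double> dist;
  grid.query(centre[0], centre[1], centre[2], radius, idx, dist);
  std::sort(idx.begin(), idx.end());
  IntegerVector out(idx.size());
  for (int i = 0; i < (int)idx.size(); ++i) out[i] = idx[i] + 1;
  return out;
}

// per-cell Wnt and Notch activities for a configuration (post-contact)
// [[Rcpp::export]]
List cpp_activities(List cells_list, List pars) {
  Pars P = read_pars(pars);
  Cells C; C.from_list(cells_list);
  Scratch W;
  find_pairs(C, W.pairs);
  int n = C.n();
  NumericVector Iw(n), In(n);
  std::vector<double> notch(n, 0.0);
  for (const Pair& p : W.pairs) {
    notch[p.i] += lp_of(C.state[p.j], P.lp_paneth, P.lp_goblet);
    notch[p.j] += lp_of(C.state[p.i], P.lp_paneth, P.lp_goblet);
  }
  for (int i = 0; i < n; ++i) {
    Iw[i] = wnt_of(P, C.z[i]);
    In[i] = notch_of(P, notch[i]);
  }
  return List::create(_["i_wnt"] = Iw, _["i_notch"] = In);
}

// random division direction in the local BM tangent plane (RNG-consuming,
// used by the R-level divide() and for directional statistics tests)
// [[Rcpp::export]]
NumericVector cpp_division_direction(NumericVector centre, List pars) {
  Pars P = read_pars(pars);
  double rho = std::sqrt(centre[0] * centre[0] + centre[1] * centre[1]);
  double d2;
  double zeta = nearest_surface(P.S, rho, centre[2], d2);
  double tv[3], nv[3];
  surface_frame(P, centre[0], centre[1], zeta, tv, nv);
  double phi_az = std::atan2(centre[1], centre[0]);
  double ex = -std::sin(phi_az), ey = std::cos(phi_az), ez = 0.0;
  double th = R::runif(0.0, 2.0 * M_PI);
  double ux = std::cos(th) * tv[0] + std::sin(th) * ex;
  double uy = std::cos(th) * tv[1] + std::sin(th) * ey;
  double uz = std::cos(th) * tv[2] + std::sin(th) * ez;
  double un = std::sqrt(ux * ux + uy * uy + uz * uz);
  return NumericVector::create(ux / un, uy / un, uz / un);
}
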