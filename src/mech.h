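#ifndef CRYPTSIM_MECH_H
#define CRYPTSIM_MECH_H

#include <cmath>
#include <algorithm>

// Pairwise cell-cell interaction pieces for adhering elastic spheres.
// Units: um, h, nN, nN*um; moduli nN/um^2 (= kPa).

// Area of the sphere-sphere intersection disc (flattened contact facet).
// xi is the distance from centre i to the contact plane along the axis.
inline double contact_plane_xi(double Ri, double Rj, double d) {
  return (d * d + Ri * Ri - Rj * Rj) / (2.0 * d);
}

inline double contact_area(double Ri, double Rj, double d) {
  if (d >= Ri + Rj) return 0.0;
  double dmin = std::fabs(Ri - Rj);
  double rmin = std::min(Ri, Rj);
  if (d <= dmin) return M_PI * rmin * rmin;  // engulfed: great disc
  double xi = contact_plane_xi(Ri, Rj, d);
  double a2 = Ri * Ri - xi * xi;
  return a2 > 0.0 ? M_PI * a2 : 0.0;
}

// dA/dd and dA/dRi (dA/dRj by symmetry with xj = d - xi)
inline void contact_area_derivs(double Ri, double Rj, double d,
                                double& dA_dd, double& dA_dRi, double& dA_dRj) {
  dA_dd = dA_dRi = dA_dRj = 0.0;
  if (d >= Ri + Rj) return;
  double dmin = std::fabs(Ri - Rj);
  if (d <= dmin) {
    if (Ri < Rj) dA_dRi = 2.0 * M_PI * Ri; else dA_dRj = 2.0 * M_PI * Rj;
    return;
  }
  double xi = contact_plane_xi(Ri, Rj, d);
  double xj = d - xi;
  dA_dd = -2.0 * M_PI * xi * xj / d;
  dA_dRi = 2.0 * M_PI * Ri * xj / d;
  dA_dRj = 2.0 * M_PI * Rj * xi / d;
}

// Hertz contact facet: the flattened contact circle of Hertz theory,
// radius a with a^2 = R* delta.  This is the area entering the adhesion
// energy (A1) and the contact friction; the geometric intersection disc
// overestimates the facet at the overlaps adhesion produces.
// The facet factor interpolates between the bare Hertz circle (1) and the
// geometric intersection disc (~2); 1.5 reproduces the stated relation
// between the 14 h growth time and the ~24 h effective cell cycle.
static const double CONTACT_FACET_FACTOR = 1.5;

inline double hertz_area(double Ri, double Rj, double d) {
  double delta = Ri + Rj - d;
  if (delta <= 0.0) return 0.0;
  double Rs = Ri * Rj / (Ri + Rj);
  return CONTACT_FACET_FACTOR * M_PI * Rs * delta;
}

inline void hertz_area_derivs(double Ri, double Rj, double d,
                              double& dA_dd, double& dA_dRi, double& dA_dRj) {
  dA_dd = dA_dRi = dA_dRj = 0.0;
  double delta = Ri + Rj - d;
  if (delta <= 0.0) return;
  double sum = Ri + Rj;
  double Rs = Ri * Rj / sum;
  double f = CONTACT_FACET_FACTOR;
  dA_dd = -f * M_PI * Rs;
  dA_dRi = f * M_PI * (Rj * Rj / (sum * sum) * delta + Rs);
  dA_dRj = f * M_PI * (Ri * Ri / (sum * sum) * delta + Rs);
}

// Hertz deformation energy of the sphere-sphere contact.
// W = (8/15) E* sqrt(R*) delta^(5/2), F = dW/ddelta = (4/3) E* sqrt(R*) delta^(3/2)
inline double hertz_estar(double E, double nu) {
  return E / (2.0 * (1.0 - nu * nu));
}

inline double hertz_energy(double Ri, double Rj, double d, double E, double nu) {
  double delta = Ri + Rj - d;
  if (delta <= 0.0) return 0.0;
  double Rs = Ri * Rj / (Ri + Rj);
  return (8.0 / 15.0) * hertz_estar(E, nu) * std::sqrt(Rs) * std::pow(delta, 2.5);
}

inline void hertz_derivs(double Ri, double Rj, double d, double E, double nu,
                         double& dW_dd, double& dW_dRi, double& dW_dRj) {
  dW_dd = dW_dRi = dW_dRj = 0.0;
  double delta = Ri + Rj - d;
  if (delta <= 0.0) return;
  double Es = hertz_estar(E, nu);
  double sum = Ri + Rj;
  double Rs = Ri * Rj / sum;
  double sq = std::sqrt(Rs);
  double d32 = std::pow(delta, 1.5);
  double dWddelta = (4.0 / 3.0) * Es * sq * d32;          // > 0
  dW_dd = -dWddelta;
  // d sqrt(R*)/dRi = Rj^2 / (2 sqrt(R*) sum^2)
  double pref = (8.0 / 15.0) * Es * d32 * delta / (2.0 * sq * sum * sum);
  dW_dRi = pref * Rj * Rj + dWddelta;
  dW_dRj = pref * Ri * Ri + dWddelta;
}

// Spherical cap volume of height h cut from a sphere of radius R.
inline double cap_volume(double R, double h) {
  if (h <= 0.0) return 0.0;
  if (h >= 2.0 * R) return (4.0 / 3.0) * M_PI * R * R * R;
  return M_PI * h * h * (3.0 * R - h) / 3.0;
}
inline double cap_dV_dh(double R, double h) {
  if (h <= 0.0 || h >= 2.0 * R) return 0.0;
  return M_PI * h * (2.0 * R - h);
}
inline double cap_dV_dR(double R, double h) {  // at fixed h
  if (h <= 0.0) return 0.0;
  if (h >= 2.0 * R) return 4.0 * M_PI * R * R;
  return M_PI * h * h;
}

// Cap heights of the two spheres cut by their contact plane.
inline void pair_cap_heights(double Ri, double Rj, double d,
                             double& hi, double& hj) {
  double xi = contact_plane_xi(Ri, Rj, d);
  double xj = d - xi;
  hi = std::min(std::max(Ri - xi, 0.0), 2.0 * Ri);
  hj = std::min(std::max(Rj - xj, 0.0), 2.0 * Rj);
}

// Energy of uniform compression/inflation against the target volume.
inline double compression_energy(double Vt, double Va, double K) {
  double dV = Vt - Va;
  return 0.5 * K * dV * dV / Vt;
}

// "pressure" conjugate: P = -dW/dVa = K (Vt - Va) / Vt (> 0 when compressed)
inline double compression_pressure(double Vt, double Va, double K) {
  return K * (Vt - Va) / Vt;
}

// Cell-knot potential.  Cells interact with knots closer than their radius R.
// eps is the maximum interaction energy per knot: the height of the repulsive
// barrier that makes the fibre network impenetrable.  In the adhesive shell
// omega R < d < R the energy is a weak smooth well of depth KNOT_ADH_FRAC*eps
// (minimum, i.e. zero force, at the threshold distance d = omega R); below
// omega R the energy rises as a convex cubic to +eps at d = 0 ("strongly
// repulsive"), with zero slope at omega R so the two branches join C1.
// W depends on (d, R) only through x = d/R, hence dW/dR = -(d/R) dW/dd.
static const double KNOT_ADH_FRAC = 0.005;

inline double knot_energy(double R, double d, double eps, double omega) {
  if (d >= R) return 0.0;
  double x = d / R;
  double a = KNOT_ADH_FRAC;
  if (x >= omega) {
    double u = (1.0 - x) / (1.0 - omega);       // 0 at boundary, 1 at well
    return -a * eps * (3.0 * u * u - 2.0 * u * u * u);
  }
  double v = (omega - x) / omega;               // 0 at well, 1 at d = 0
  return eps * (-a + (1.0 + a) * v * v * v);
}

// dW/dx (x = d/R), used for both derivatives
inline double knot_dWdx(double R, double d, double eps, double omega) {
  double x = d / R;
  double a = KNOT_ADH_FRAC;
  if (x >= omega) {
    double u = (1.0 - x) / (1.0 - omega);
    return a * eps * 6.0 * u * (1.0 - u) / (1.0 - omega);
  }
  double v = (omega - x) / omega;
  return -eps * (1.0 + a) * 3.0 * v * v / omega;
}

inline void knot_derivs(double R, double d, double eps, double omega,
                        double& dW_dd, double& dW_dR) {
  dW_dd = dW_dR = 0.0;
  if (d >= R) return;
  double g = knot_dWdx(R, d, eps, omega);
  dW_dd = g / R;
  dW_dR = -g * d / (R * R);
}

// |d2W/dd2|, the stiffness estimate for the semi-implicit normal mode
inline double knot_curvature(double R, double d, double eps, double omega) {
  if (d >= R) return 0.0;
  double x = d / R;
  double a = KNOT_ADH_FRAC;
  if (x >= omega) {
    double u = (1.0 - x) / (1.0 - omega);
    double w = (1.0 - omega) * R;
    return std::fabs(6.0 * a * eps * (1.0 - 2.0 * u)) / (w * w);
  }
  double v = (omega - x) / omega;
  double w = omega * R;
  return 6.0 * eps * (1.0 + a) * v / (w * w);
}

// --- engine-side split of the cell-BM interaction -------------------------
// The repulsive barrier is summed over knots (scaled by 1/n_K); the weak
// adhesive skin is evaluated in its continuum limit as a function of the
// distance to the smooth surface, which removes the lattice corrugation of
// the discrete knot sum (the two agree in total energy on a fine mesh).

inline double knot_rep_energy(double R, double d, double eps, double omega) {
  double x = d / R;
  if (x >= omega) return 0.0;
  double v = (omega - x) / omega;
  return eps * (1.0 + KNOT_ADH_FRAC) * v * v * v;
}

inline void knot_rep_derivs(double R, double d, double eps, double omega,
                            double& dW_dd, double& dW_dR) {
  dW_dd = dW_dR = 0.0;
  double x = d / R;
  if (x >= omega) return;
  double v = (omega - x) / omega;
  double g = -eps * (1.0 + KNOT_ADH_FRAC) * 3.0 * v * v / omega;  // dW/dx
  dW_dd = g / R;
  dW_dR = -g * d / (R * R);
}

inline double knot_rep_curvature(double R, double d, double eps,
                                 double omega) {
  double x = d / R;
  if (x >= omega) return 0.0;
  double v = (omega - x) / omega;
  double w = omega * R;
  return 6.0 * eps * (1.0 + KNOT_ADH_FRAC) * v / (w * w);
}

inline double bm_adhesion_energy(double R, double dist, double eps,
                                 double omega) {
  double x = dist / R;
  double a = KNOT_ADH_FRAC;
  if (x >= 1.0) return 0.0;
  if (x <= omega) return -a * eps;
  double u = (1.0 - x) / (1.0 - omega);
  return -a * eps * (3.0 * u * u - 2.0 * u * u * u);
}

inline void bm_adhesion_derivs(double R, double dist, double eps, double omega,
                               double& dW_dd, double& dW_dR) {
  dW_dd = dW_dR = 0.0;
  double x = dist / R;
  if (x >= 1.0 || x <= omega) return;
  double a = KNOT_ADH_FRAC;
  double u = (1.0 - x) / (1.0 - omega);
  double g = a * eps * 6.0 * u * (1.0 - u) / (1.0 - omega);  // dW/dx
  dW_dd = g / R;
  dW_dR = -g * dist / (R * R);
}

inline double bm_adhesion_curvature(double R, double dist, double eps,
                                    double omega) {
  double x = dist / R;
  if (x >= 1.0 || x <= omega) return 0.0;
  double a = KNOT_ADH_FRAC;
  double u = (1.0 - x) / (1.0 - omega);
  double w = (1.0 - omega) * R;
  return std::fabs(6.0 * a * eps * (1.0 - 2.0 * u)) / (w * w);
}

#endif
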