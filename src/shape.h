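#ifndef CRYPTSIM_SHAPE_H
#define CRYPTSIM_SHAPE_H

#include <cmath>
#include <algorithm>

// Parametric crypt surface of revolution.
// Axis: z, junction at z = 0, base (pole) at z = -z0.  s = z + z0 >= 0.
// r(s) = rb*sqrt(1 - exp(-2 s / rb)) + a*(1 - exp(-s / L1))
//        + b*(exp(-(z0 - s)/L2) - exp(-z0/L2))
// rb = lambda1 * r0 (bottom-cap radius; the first term interpolates a
// spherical cap of radius rb into a cylinder), a = r0/4 (mid-crypt widening,
// scale L1 = 0.15 z0), flare scale L2 = 2 lambda2 z0, b fixed by r(0) = r0;
// the flare is anchored so that the profile closes exactly at the pole.
struct Shape {
  double z0, r0, l1, l2;
  double rb, a, L1, L2, b, f0;
};

inline Shape make_shape(double z0, double r0, double l1, double l2) {
  Shape S;
  S.z0 = z0; S.r0 = r0; S.l1 = l1; S.l2 = l2;
  S.rb = l1 * r0;
  S.a  = 0.25 * r0;
  S.L1 = 0.15 * z0;
  S.L2 = 2.0 * l2 * z0;
  S.f0 = std::exp(-z0 / S.L2);
  double cap1 = (S.rb > 0.0) ? S.rb * std::sqrt(1.0 - std::exp(-2.0 * z0 / S.rb)) : 0.0;
  S.b = (r0 - cap1 - S.a * (1.0 - std::exp(-z0 / S.L1))) / (1.0 - S.f0);
  return S;
}

inline double shape_r(const Shape& S, double z) {
  double s = z + S.z0;
  if (s <= 0.0) return 0.0;
  double cap = 0.0;
  if (S.rb > 0.0) {
    double u = std::exp(-2.0 * s / S.rb);
    cap = S.rb * std::sqrt(std::max(1.0 - u, 0.0));
  }
  return cap + S.a * (1.0 - std::exp(-s / S.L1))
             + S.b * (std::exp(-(S.z0 - s) / S.L2) - S.f0);
}

// dr/dz
inline double shape_rp(const Shape& S, double z) {
  double s = z + S.z0;
  if (s <= 0.0) s = 1e-12;
  double cap = 0.0;
  if (S.rb > 0.0) {
    double u = std::exp(-2.0 * s / S.rb);
    double om = std::max(1.0 - u, 1e-300);
    cap = u / std::sqrt(om);
  }
  return cap + S.a / S.L1 * std::exp(-s / S.L1)
             + S.b / S.L2 * std::exp(-(S.z0 - s) / S.L2);
}

// d2r/dz2
inline double shape_rpp(const Shape& S, double z) {
  double s = z + S.z0;
  if (s <= 0.0) s = 1e-12;
  double cap = 0.0;
  if (S.rb > 0.0) {
    double u = std::exp(-2.0 * s / S.rb);
    double om = std::max(1.0 - u, 1e-300);
    cap = (-2.0 * u / S.rb) / std::sqrt(om)
          - (u * u / S.rb) / (om * std::sqrt(om));
  }
  return cap - S.a / (S.L1 * S.L1) * std::exp(-s / S.L1)
             + S.b / (S.L2 * S.L2) * std::exp(-(S.z0 - s) / S.L2);
}

// Gaussian and mean curvature of a surface of revolution with profile r(z),
// with the normal oriented into the lumen (a sphere of radius R has K = 1/R^2
// and H = 1/R; a cylinder has K = 0, H = 1/(2 r)).
inline void profile_curvatures(double r, double rp, double rpp,
                               double& gauss, double& mean) {
  double q = 1.0 + rp * rp;
  double km = -rpp / (q * std::sqrt(q));     // meridian
  double kc = 1.0 / (r * std::sqrt(q));      // circumferential
  gauss = km * kc;
  mean = 0.5 * (km + kc);
}

// Curvature evaluation clamped slightly above the pole where the profile
// parametrisation degenerates (r -> 0, r' -> inf).
inline double shape_gauss(const Shape& S, double z) {
  double smin = 0.05;
  if (z + S.z0 < smin) z = smin - S.z0;
  double g, m;
  profile_curvatures(shape_r(S, z), shape_rp(S, z), shape_rpp(S, z), g, m);
  return g;
}

// Monotone Wnt link: normalised Gaussian curvature, clamped to its running
// minimum above z_flat (the argmin of K; above it the flare lets K creep back
// towards zero, which would break monotonicity of the activity profile).
inline double wnt_link(const Shape& S, double z, double z_flat, double scale) {
  if (z > z_flat) z = z_flat;
  return shape_gauss(S, z) / scale;
}

// Nearest point on the meridian profile to a point at (rho, z) in the
// (radial, axial) plane.  Golden-section search on a local bracket, robust to
// the pole.  Returns zeta in [-z0, 0]; dist2 receives the squared distance.
inline double nearest_meridian(const Shape& S, double rho, double z,
                               double lo, double hi, double& dist2) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  auto f = [&](double zeta) {
    double dr = rho - shape_r(S, zeta);
    double dz = z - zeta;
    return dr * dr + dz * dz;
  };
  double fc = f(c), fd = f(d);
  for (int it = 0; it < 60 && (b - a) > 1e-10; ++it) {
    if (fc < fd) { b = d; d = c; fd = fc; c = b - gr * (b - a); fc = f(c); }
    else         { a = c; c = d; fc = fd; d = a + gr * (b - a); fd = f(d); }
  }
  double zeta = 0.5 * (a + b);
  dist2 = f(zeta);
  return zeta;
}

// Full-domain nearest point: coarse scan then local refinement.
inline double nearest_surface(const Shape& S, double rho, double z,
                              double& dist2) {
  double lo = -S.z0, hi = 0.0;
  // coarse scan
  int n = 60;
  double best = lo, fbest = 1e300;
  for (int i = 0; i <= n; ++i) {
    double zeta = lo + (hi - lo) * i / n;
    double dr = rho - shape_r(S, zeta);
    double dz = z - zeta;
    double v = dr * dr + dz * dz;
    if (v < fbest) { fbest = v; best = zeta; }
  }
  double w = (hi - lo) / n;
  double a = std::max(lo, best - w), b = std::min(hi, best + w);
  return nearest_meridian(S, rho, z, a, b, dist2);
}

#endif
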