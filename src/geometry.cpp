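// Analytic crypt-surface geometry: radius profile, curvatures, Wnt link,
// nearest-surface projection.

#include <Rcpp.h>
#include "shape.h"
#include "mech.h"

using namespace Rcpp;

static Shape shape_from(const List& s) {
  return make_shape(as<double>(s["z0"]), as<double>(s["r0"]),
                    as<double>(s["lambda1"]), as<double>(s["lambda2"]));
}

// [[Rcpp::export]]
NumericVector cpp_crypt_radius(NumericVector z, List shape) {
  Shape S = shape_from(shape);
  NumericVector out(z.size());
  for (int i = 0; i < z.size(); ++i) out[i] = shape_r(S, z[i]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_crypt_radius_derivs(NumericVector z, List shape) {
  Shape S = shape_from(shape);
  NumericMatrix out(z.size(), 2);
  for (int i = 0; i < z.size(); ++i) {
    out(i, 0) = shape_rp(S, z[i]);
    out(i, 1) = shape_rpp(S, z[i]);
  }
  colnames(out) = CharacterVector::create("rp", "rpp");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_surface_curvatures(NumericVector z, List shape) {
  Shape S = shape_from(shape);
  NumericMatrix out(z.size(), 2);
  for (int i = 0; i < z.size(); ++i) {
    double zz = z[i];
    double smin = 0.05;
    if (zz + S.z0 < smin) zz = smin - S.z0;
    double g, m;
    profile_curvatures(shape_r(S, zz), shape_rp(S, zz), shape_rpp(S, zz),
                       g, m);
    out(i, 0) = g; out(i, 1) = m;
  }
  colnames(out) = CharacterVector::create("gaussian", "mean");
  return out;
}

// generic surface-of-revolution curvatures from profile values (used to
// check the closed forms for cylinders and spheres)
// [[Rcpp::export]]
NumericMatrix cpp_profile_curvatures(NumericVector r, NumericVector rp,
                                     NumericVector rpp) {
  NumericMatrix out(r.size(), 2);
  for (int i = 0; i < r.size(); ++i) {
    double g, m;
    profile_curvatures(r[i], rp[i], rpp[i], g, m);
    out(i, 0) = g; out(i, 1) = m;
  }
  colnames(out) = CharacterVector::create("gaussian", "mean");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_wnt_link(NumericVector z, List shape, double z_flat,
                           double scale) {
  Shape S = shape_from(shape);
  NumericVector out(z.size());
  for (int i = 0; i < z.size(); ++i)
    out[i] = wnt_link(S, z[i], z_flat, scale);
  return out;
}

// nearest surface point for each row of pts (x, y, z); returns the meridian
// coordinate zeta, the distance and the surface foot point
// [[Rcpp::export]]
List cpp_nearest_surface(NumericMatrix pts, List shape) {
  Shape S = shape_from(shape);
  int n = pts.nrow();
  NumericVector zeta(n), dist(n);
  NumericMatrix foot(n, 3);
  for (int i = 0; i < n; ++i) {
    double rho = std::sqrt(pts(i, 0) * pts(i, 0) + pts(i, 1) * pts(i, 1));
    double d2;
    double zb = nearest_surface(S, rho, pts(i, 2), d2);
    zeta[i] = zb;
    dist[i] = std::sqrt(d2);
    double r = shape_r(S, zb);
    double c = rho > 1e-12 ? pts(i, 0) / rho : 1.0;
    double s = rho > 1e-12 ? pts(i, 1) / rho : 0.0;
    foot(i, 0) = r * c; foot(i, 1) = r * s; foot(i, 2) = zb;
  }
  return List::create(_["zeta"] = zeta, _["dist"] = dist, _["foot"] = foot);
}
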