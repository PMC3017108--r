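// Scalar/vectorised exports of the pairwise interaction model, used by the
// R-level mechanics operations and their tests.

#include <Rcpp.h>
#include "mech.h"

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_contact_area(NumericVector Ri, NumericVector Rj,
                               NumericVector d) {
  int n = Ri.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = contact_area(Ri[i], Rj[i], d[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hertz_energy(NumericVector Ri, NumericVector Rj,
                               NumericVector d, double E, double nu) {
  int n = Ri.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = hertz_energy(Ri[i], Rj[i], d[i], E, nu);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hertz_force(NumericVector Ri, NumericVector Rj,
                              NumericVector d, double E, double nu) {
  int n = Ri.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double dd, dri, drj;
    hertz_derivs(Ri[i], Rj[i], d[i], E, nu, dd, dri, drj);
    out[i] = -dd;  // force along increasing d
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_compression_energy(NumericVector Vt, NumericVector Va,
                                     double K) {
  int n = Vt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = compression_energy(Vt[i], Va[i], K);
  return out;
}

// energy and radial force (-dW/dd) of a single cell-knot interaction
// [[Rcpp::export]]
NumericMatrix cpp_knot_interaction(NumericVector R, NumericVector d,
                                   double eps, double omega) {
  int n = R.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = knot_energy(R[i], d[i], eps, omega);
    double dd, dR;
    knot_derivs(R[i], d[i], eps, omega, dd, dR);
    out(i, 1) = -dd;
  }
  colnames(out) = CharacterVector::create("energy", "force");
  return out;
}

// actual volume: sphere minus pairwise lens caps minus an optional BM
// half-space cap (bm_dist = distance of the centre to the BM plane)
// [[Rcpp::export]]
double cpp_actual_volume(double R, NumericVector neigh_R, NumericVector neigh_d,
                         double bm_dist) {
  double V = (4.0 / 3.0) * M_PI * R * R * R;
  for (int j = 0; j < neigh_R.size(); ++j) {
    if (neigh_d[j] >= R + neigh_R[j]) continue;
    double hi, hj;
    pair_cap_heights(R, neigh_R[j], neigh_d[j], hi, hj);
    V -= cap_volume(R, hi);
  }
  if (std::isfinite(bm_dist) && bm_dist < R) V -= cap_volume(R, R - bm_dist);
  return std::max(V, 0.0);
}
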