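#' Local crypt radius
#'
#' Radius of the parametric crypt surface of revolution at axial position z.
#' The profile is a rounded bottom cap of radius `lambda1 * r0` blended into a
#' gently widening mid-crypt tube and an exponential flare that reaches `r0`
#' at the crypt-villus junction.
#'
#' @param z Axial coordinate(s), um; must lie in `[-z0, 0]`.
#' @param shape A [crypt_shape()].
#' @return Radius r(z) in um.
#' @export
crypt_radius <- function(z, shape = crypt_shape()) {
  stopifnot(inherits(shape, "crypt_shape"))
  if (any(z < -shape$z0 - 1e-9) || any(z > 1e-9))
    stop("z outside the crypt domain [-z0, 0]")
  cpp_crypt_radius(as.numeric(z), unclass(shape))
}

#' Analytic surface curvatures of the crypt
#'
#' Gaussian (1/um^2) and mean (1/um) curvature of the crypt surface of
#' revolution, with the normal oriented into the lumen: a spherical cap of
#' radius R has Gaussian curvature 1/R^2 and mean curvature 1/R, a cylinder 0
#' and 1/(2 r). On the reference shape the Gaussian curvature is maximal at
#' the crypt bottom, stays positive through the lower crypt and crosses zero
#' in the flare below the junction.
#'
#' @inheritParams crypt_radius
#' @return A two-column matrix with columns `gaussian` and `mean`.
#' @export
surface_curvatures <- function(z, shape = crypt_shape()) {
  stopifnot(inherits(shape, "crypt_shape"))
  if (any(z < -shape$z0 - 1e-9) || any(z > 1e-9))
    stop("z outside the crypt domain [-z0, 0]")
  r <- cpp_crypt_radius(as.numeric(z), unclass(shape))
  if (any(r <= 0))
    stop("degenerate surface: r(z) = 0 at the requested position")
  cpp_surface_curvatures(as.numeric(z), unclass(shape))
}

# curvatures of an arbitrary profile of revolution (closed-form checks)
profile_curvatures <- function(r, rp, rpp) {
  cpp_profile_curvatures(as.numeric(r), as.numeric(rp), as.numeric(rpp))
}

# normalisation scale of the Wnt link: Gaussian curvature a short way
# (0.05 z0) above the base, where the cap parametrisation is already stable
wnt_link_scale <- function(shape) {
  z_ref <- -shape$z0 + 0.05 * shape$z0
  cpp_surface_curvatures(z_ref, unclass(shape))[1, "gaussian"]
}

# axial position of the Gaussian-curvature minimum; above it the Wnt link is
# clamped flat so that the activity profile is monotone non-increasing
wnt_link_flat_point <- function(shape) {
  zg <- seq(-shape$z0 * 0.98, -1e-3, length.out = 600)
  K <- cpp_surface_curvatures(zg, unclass(shape))[, "gaussian"]
  i <- which.min(K)
  lo <- zg[max(1, i - 2)]; hi <- zg[min(length(zg), i + 2)]
  opt <- stats::optimize(function(zz)
    cpp_surface_curvatures(zz, unclass(shape))[1, "gaussian"],
    interval = c(lo, hi))
  opt$minimum
}

#' Wnt activity along the crypt axis
#'
#' The Wnt activity of a cell is a monotone function of the local curvature of
#' the basal membrane, which itself is a function of the axial position:
#' `I_wnt = f(z)`, where f is the analytic Gaussian curvature of the crypt
#' surface normalised by its near-base value, clamped to its running minimum
#' above the curvature minimum so that f is non-increasing from base to
#' junction. The fate thresholds are `TP_wnt = f(z_p)` and `TD_wnt = f(z_d)`.
#'
#' @inheritParams crypt_radius
#' @return Dimensionless Wnt activities, decreasing from ~1 near the base.
#' @export
wnt_activity <- function(z, shape = crypt_shape()) {
  stopifnot(inherits(shape, "crypt_shape"))
  cpp_wnt_link(as.numeric(z), unclass(shape),
               wnt_link_flat_point(shape), wnt_link_scale(shape))
}

#' Project points onto the crypt surface
#'
#' Nearest point on the crypt surface for each row of a point matrix.
#'
#' @param pts Numeric matrix with columns x, y, z (um).
#' @inheritParams crypt_radius
#' @return A list with `zeta` (meridian coordinate of the foot point), `dist`
#'   (Euclidean distance to the surface) and `foot` (n x 3 foot points).
#' @export
nearest_surface_point <- function(pts, shape = crypt_shape()) {
  stopifnot(inherits(shape, "crypt_shape"))
  pts <- rbind(pts)
  storage.mode(pts) <- "double"
  cpp_nearest_surface(pts, unclass(shape))
}

#' Total surface area of the crypt
#'
#' Area of the surface of revolution, by quadrature of
#' `2 pi r(z) sqrt(1 + r'(z)^2)`.
#'
#' @inheritParams crypt_radius
#' @return Area in um^2.
#' @export
crypt_surface_area <- function(shape = crypt_shape()) {
  f <- function(z) {
    rp <- cpp_crypt_radius_derivs(z, unclass(shape))[, "rp"]
    2 * pi * cpp_crypt_radius(z, unclass(shape)) * sqrt(1 + rp^2)
  }
  stats::integrate(f, -shape$z0 + 1e-6, 0, subdivisions = 2000L,
                   rel.tol = 1e-8)$value
}
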