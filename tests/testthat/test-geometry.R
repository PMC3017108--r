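# Parametric crypt surface: radius profile, curvatures, Wnt link.

ref_shape <- crypt_shape()

test_that("crypt radius honours its boundary values and domain", {
  expect_equal(crypt_radius(0, ref_shape), 60)
  # profile closes at the pole
  expect_lt(crypt_radius(-150 + 1e-6, ref_shape), 1e-2)
  # regression anchor for the reference profile at mid-depth
  expect_equal(crypt_radius(-75, ref_shape), 31.74174, tolerance = 1e-6)
  expect_error(crypt_radius(-151, ref_shape), "domain")
  expect_error(crypt_radius(1, ref_shape), "domain")
  # continuity
  z <- seq(-149.9, 0, by = 0.05)
  r <- crypt_radius(z, ref_shape)
  expect_true(all(abs(diff(r)) < 0.5))  # steep only at the sqrt-like cap
  # the simple shape family (lambda1 = 0) is well defined
  s0 <- crypt_shape(lambda1 = 0)
  expect_true(all(is.finite(crypt_radius(z, s0))))
  expect_equal(crypt_radius(0, s0), 60)
})

test_that("curvatures of cylinders and spheres match the closed forms", {
  # cylinder of radius r: K = 0, H = 1/(2 r)
  r <- 7.5
  cc <- cryptsim:::profile_curvatures(r, 0, 0)
  expect_equal(unname(cc[1, "gaussian"]), 0, tolerance = 1e-9)
  expect_equal(unname(cc[1, "mean"]), 1 / (2 * r), tolerance = 1e-9)
  # sphere of radius R at several latitudes: K = 1/R^2, H = 1/R
  R <- 12
  for (z in c(-8, -3, 0, 5)) {
    rr <- sqrt(R^2 - z^2)
    rp <- -z / rr
    rpp <- -R^2 / rr^3
    cc <- cryptsim:::profile_curvatures(rr, rp, rpp)
    expect_equal(unname(cc[1, "gaussian"]), 1 / R^2, tolerance = 1e-9)
    expect_equal(unname(cc[1, "mean"]), 1 / R, tolerance = 1e-9)
  }
})

test_that("reference Gaussian curvature peaks at the base and crosses zero below the junction", {
  z <- seq(-149.5, -0.5, by = 0.1)
  K <- surface_curvatures(z, ref_shape)[, "gaussian"]
  expect_equal(which.max(K), 1L)
  sgn <- which(diff(sign(K)) != 0)
  expect_length(sgn, 1L)
  z_cross <- z[sgn]
  expect_gt(z_cross, -87.5)   # between z_d and the junction
  expect_lt(z_cross, 0)
  expect_error(surface_curvatures(-150, ref_shape), "degenerate")
})

test_that("Wnt activity is a monotone link with the threshold ordering", {
  p <- model_params()
  iw <- wnt_activity(c(-149, -100, -50), ref_shape)
  expect_gte(iw[1], p$tp_wnt)                       # deep in the niche
  expect_true(iw[2] < p$tp_wnt && iw[2] >= p$td_wnt)  # progenitor zone
  expect_lt(iw[3], p$td_wnt)                        # differentiation zone
  z <- seq(-149, -0.5, by = 0.25)
  expect_true(all(diff(wnt_activity(z, ref_shape)) <= 1e-12))
})

test_that("nearest-surface projection recovers points constructed on the surface", {
  set.seed(4)
  z <- runif(40, -140, -5)
  r <- crypt_radius(z, ref_shape)
  phi <- runif(40, 0, 2 * pi)
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  np <- nearest_surface_point(pts, ref_shape)
  expect_lt(max(np$dist), 1e-4)
  expect_equal(np$zeta, z, tolerance = 1e-3)
})
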