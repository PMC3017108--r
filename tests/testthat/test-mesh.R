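# Triangulated basal-membrane network.

mini_shape <- crypt_shape(z0 = 75, r0 = 30)

test_that("mesh respects the inradius bound and scales with the mesh size", {
  net1 <- triangulate_crypt(mini_shape, 2.5)
  net2 <- triangulate_crypt(mini_shape, 5)
  expect_lte(max(mesh_inradii(net1)), 2.5)
  expect_lte(max(mesh_inradii(net2)), 5)
  # knot count scales like 1 / lambda_max^2
  ratio <- nrow(net1$knots) / nrow(net2$knots)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5.5)
})

test_that("knot layout is uniform and lies on the surface", {
  net <- triangulate_crypt(mini_shape, 2.5)
  co <- mesh_coordination(net)
  expect_lt(stats::sd(co) / mean(co), 0.25)
  rho <- sqrt(net$knots[, 1]^2 + net$knots[, 2]^2)
  r_expect <- crypt_radius(net$knot_z, mini_shape)
  expect_lt(max(abs(rho[-1] - r_expect[-1])), 1e-6)  # pole knot has rho = 0
  # outward normals are unit length
  expect_equal(rowSums(net$knot_normal^2), rep(1, nrow(net$knots)),
               tolerance = 1e-9)
})

test_that("the network is watertight for cell-sized probes", {
  net <- triangulate_crypt(mini_shape, 2.5)
  # every edge is shared by exactly two triangles, except the top rim
  T_ <- net$triangles
  e <- rbind(T_[, c(1, 2)], T_[, c(2, 3)], T_[, c(1, 3)])
  e <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(table(e))
  rim <- sum(table(e) == 1)
  m_top <- sum(net$knot_z > max(net$knot_z) - 1e-6)
  expect_equal(rim, m_top)               # boundary edges = top ring only
  expect_true(all(names(tab) %in% c("1", "2")))
  # ray sampling: rays from the axis always cross the membrane
  set.seed(9)
  for (k in 1:40) {
    z0p <- runif(1, -70, -15)
    dir <- c(rnorm(2), 0)  # radial rays; the crypt mouth at z = 0 is open
    expect_gte(ray_crossings(net, c(0, 0, z0p), dir), 1)
  }
  # the mesh is far finer than any cell: no gap admits a 5 um sphere
  expect_lt(max(mesh_inradii(net)), 5)
})

test_that("discrete angle-deficit curvature converges to the analytic value", {
  kdeficit <- function(net) {
    K <- net$knots; T_ <- net$triangles
    nk <- nrow(K)
    ang <- numeric(nk); area <- numeric(nk)
    for (c1 in 1:3) {
      a <- T_[, c1]; b <- T_[, c1 %% 3 + 1]; c_ <- T_[, (c1 + 1) %% 3 + 1]
      u <- K[b, ] - K[a, ]; v <- K[c_, ] - K[a, ]
      cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
      th <- acos(pmin(pmax(cosang, -1), 1))
      ang <- ang + tabulate(a, nk) * 0  # keep length
      ang[sort(unique(a))] <- ang[sort(unique(a))] +
        tapply(th, a, sum)[as.character(sort(unique(a)))]
      cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                  u[, 3] * v[, 1] - u[, 1] * v[, 3],
                  u[, 1] * v[, 2] - u[, 2] * v[, 1])
      tri_area <- 0.5 * sqrt(rowSums(cr^2))
      area[sort(unique(a))] <- area[sort(unique(a))] +
        tapply(tri_area / 3, a, sum)[as.character(sort(unique(a)))]
    }
    (2 * pi - ang) / area
  }
  err_at <- function(lmax) {
    net <- triangulate_crypt(mini_shape, lmax)
    kd <- kdeficit(net)
    band <- which(net$knot_z > -60 & net$knot_z < -20)
    ka <- surface_curvatures(net$knot_z[band], mini_shape)[, "gaussian"]
    stats::median(abs(kd[band] - ka))
  }
  e_coarse <- err_at(5)
  e_fine <- err_at(2.5)
  expect_lt(e_fine, e_coarse)
})

test_that("interacting knots match a brute-force distance scan", {
  net <- triangulate_crypt(mini_shape, 5)   # a few hundred knots
  set.seed(3)
  for (k in 1:10) {
    z <- runif(1, -60, -10)
    centre <- c(crypt_radius(z, mini_shape) - 4, 0, z)
    R <- runif(1, 4, 7)
    got <- interacting_knots(centre, R, net)
    d <- sqrt(colSums((t(net$knots) - centre)^2))
    expect_equal(got, which(d < R))
  }
  # a cell far from all knots interacts with none
  expect_length(interacting_knots(c(0, 0, -30), 5, net), 0)
})

test_that("cell-BM energy is stable under mesh refinement", {
  p <- model_params(shape = mini_shape, lambda_max = 2.5,
                    z_p = -50, z_d = -35)
  cells <- cryptsim:::new_cells_df(1)
  cells$id <- 0L; cells$radius <- 5
  cells$target_volume <- cells$actual_volume <- p$V0
  cells$state <- "ENTEROCYTE_PROGENITOR"; cells$next_wait <- -1
  z <- -40
  cells$x <- crypt_radius(z, mini_shape) - 0.93 * 5; cells$y <- 0; cells$z <- z
  pe <- cryptsim:::params_for_engine(p)
  ce <- cryptsim:::cells_to_engine(cells)
  e1 <- cryptsim:::cpp_total_energy(ce, triangulate_crypt(mini_shape, 2.5)$knots, pe)
  e2 <- cryptsim:::cpp_total_energy(ce, triangulate_crypt(mini_shape, 1.25)$knots, pe)
  expect_lt(abs(e1 - e2) / abs(e2), 0.1)
})

test_that("OFF and PLY exports round-trip their counts", {
  net <- triangulate_crypt(mini_shape, 5)
  off <- tempfile(fileext = ".off"); ply <- tempfile(fileext = ".ply")
  write_off(net, off); write_ply(net, ply)
  l1 <- readLines(off)
  expect_identical(l1[1], "OFF")
  counts <- as.integer(strsplit(l1[2], " ")[[1]])
  expect_identical(counts[1:2], c(nrow(net$knots), nrow(net$triangles)))
  expect_identical(length(l1), 2L + nrow(net$knots) + nrow(net$triangles))
  l2 <- readLines(ply)
  expect_identical(l2[1], "ply")
  expect_true(any(grepl("property float gauss_curvature", l2)))
  nv <- as.integer(sub("element vertex ", "",
                       grep("element vertex", l2, value = TRUE)))
  expect_identical(nv, nrow(net$knots))
})
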