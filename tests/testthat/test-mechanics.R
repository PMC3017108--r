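# Cell-cell and cell-BM interaction model.

test_that("contact area follows the sphere-sphere intersection geometry", {
  expect_equal(contact_area(5, 6, 11), 0)
  expect_equal(contact_area(5, 6, 12), 0)
  # equal spheres R at distance d = R: intersection disc pi (R^2 - (d/2)^2)
  R <- 5
  expect_equal(contact_area(R, R, R), pi * (R^2 - (R / 2)^2))
  # symmetry in the two cells
  expect_equal(contact_area(4, 6.3, 8.1), contact_area(6.3, 4, 8.1))
  expect_error(contact_area(5, 5, 0), "degenerate")
  # continuity through tangency
  d <- seq(9.9, 10.1, by = 0.001)
  a <- contact_area(5, 5, d)
  expect_true(all(diff(a) <= 0))
  expect_lt(a[which(d == 10) - 1], 0.5)
})

test_that("adhesion energy is linear in area and carries the right units", {
  expect_equal(adhesion_energy(0, 0.2), 0)
  expect_equal(adhesion_energy(20, 0.2), 2 * adhesion_energy(10, 0.2))
  # 200 uN/m over a 10 um^2 facet: |W| = 2 nN*um = 2e-15 N*m
  w <- adhesion_energy(10, 0.2)
  expect_lt(w, 0)  # adhesion lowers the energy
  expect_equal(abs(w) * 1e-15, 2e-15)
})

test_that("Hertz energy vanishes at tangency, grows with overlap, scales with E", {
  expect_equal(hertz_energy(5, 6, 11), 0)
  d <- seq(10.5, 8, by = -0.1)
  w <- hertz_energy(5, 6, d)
  expect_true(all(diff(w) > 0))
  expect_equal(hertz_energy(5, 5, 9, E = 2), 2 * hertz_energy(5, 5, 9, E = 1))
  expect_equal(hertz_energy(4, 6, 9), hertz_energy(6, 4, 9))
  # force is the negative distance-derivative of the energy
  eps <- 1e-6
  for (dd in c(9.5, 8.7, 8)) {
    fd <- -(hertz_energy(5, 5, dd + eps) - hertz_energy(5, 5, dd - eps)) /
      (2 * eps)
    expect_equal(hertz_force(5, 5, dd), fd, tolerance = 1e-6)
  }
})

test_that("compression energy is symmetric and monotone in the volume deviation", {
  V0 <- 4 / 3 * pi * 125
  expect_equal(compression_energy(V0, V0), 0)
  expect_equal(compression_energy(V0, 0.9 * V0),
               compression_energy(V0, 1.1 * V0))
  dev <- seq(0, 0.3, by = 0.05)
  w <- compression_energy(V0, V0 * (1 - dev))
  expect_true(all(diff(w) > 0))
  expect_error(compression_energy(V0, -1), "positive")
})

test_that("cell-knot interaction has the stated boundary structure", {
  R <- 5; eps <- 100; omega <- 0.95
  ck <- cell_knot_interaction(R, c(R, omega * R, 0), eps, omega)
  expect_equal(ck[1, "energy"], 0, ignore_attr = TRUE)   # boundary
  expect_equal(ck[2, "force"], 0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ck[3, "energy"], eps, ignore_attr = TRUE) # barrier maximum
  # adhesive above the threshold, repulsive below it
  d_ad <- cell_knot_interaction(R, 0.975 * R, eps, omega)
  d_rep <- cell_knot_interaction(R, 0.8 * R, eps, omega)
  expect_lt(d_ad[1, "energy"], 0)
  expect_lt(d_ad[1, "force"], 0)
  expect_gt(d_rep[1, "force"], 0)
  # force matches the finite-difference derivative of the energy
  hh <- 1e-6
  for (dd in c(0.97 * R, 0.9 * R, 0.5 * R)) {
    wp <- cell_knot_interaction(R, dd + hh, eps, omega)[1, "energy"]
    wm <- cell_knot_interaction(R, dd - hh, eps, omega)[1, "energy"]
    expect_equal(cell_knot_interaction(R, dd, eps, omega)[1, "force"],
                 -(wp - wm) / (2 * hh), tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("actual volume matches geometry and a Monte-Carlo oracle", {
  R <- 5
  expect_equal(actual_volume(R), 4 / 3 * pi * R^3)
  expect_equal(actual_volume(R, list(radius = 5, distance = 10)),
               4 / 3 * pi * R^3)
  # two symmetric neighbours
  nb <- list(radius = c(5, 5), distance = c(8, 8))
  set.seed(10)
  vmc <- mc_actual_volume(R, nb$radius, nb$distance,
                          rbind(c(1, 0, 0), c(-1, 0, 0)), n = 2e6)
  expect_equal(actual_volume(R, nb), vmc, tolerance = 0.005)
})

test_that("net generalized forces are exact energy gradients with action-reaction", {
  st2 <- make_fixture("two_cell", seed = 1)
  nf <- net_generalized_forces(st2, migration = FALSE)
  expect_equal(nf$force[1, ], -nf$force[2, ], tolerance = 1e-12)
  st5 <- make_fixture("five_cell", seed = 2)
  expect_lt(fd_force_check(st5), 1e-5)
  # an isolated relaxed cell feels nothing
  iso <- make_fixture("two_cell", seed = 1)
  iso$cells <- iso$cells[1, ]
  iso$cells$radius <- (iso$cells$target_volume / (4 / 3 * pi))^(1 / 3)
  nf1 <- net_generalized_forces(iso, migration = FALSE)
  expect_lt(max(abs(nf1$force)), 1e-9)
  expect_lt(abs(nf1$force_radius), 1e-6)
})

test_that("migration forces have the stated magnitudes and directions", {
  p <- model_params()
  z <- -60
  pos <- c(crypt_radius(z, p$shape) - 4.5, 0, z)
  f_pan <- migration_force(pos, "PANETH", p)
  f_ent <- migration_force(pos, "ENTEROCYTE_PROGENITOR", p)
  f_und <- migration_force(pos, "UNDIFFERENTIATED", p)
  expect_equal(sqrt(sum(f_pan^2)), 7.5, tolerance = 1e-6)
  expect_equal(sqrt(sum(f_ent^2)), 4.5, tolerance = 1e-6)
  expect_lt(f_pan[3], 0)   # Paneth cells crawl down
  expect_gt(f_ent[3], 0)   # all other primed cells move up
  expect_equal(f_und, c(0, 0, 0))
  expect_equal(migration_force(pos, "ENTEROCYTE", p, attached = FALSE),
               c(0, 0, 0))
})

test_that("overdamped motion matches the scalar limit and an ODE oracle", {
  skip_if_not_installed("deSolve")
  # single cell under migration on the membrane: v = F / eta_BM
  p <- model_params()
  net <- triangulate_crypt(p$shape, p$lambda_max)
  cells <- cryptsim:::new_cells_df(1)
  cells$id <- 0L; cells$radius <- 5
  cells$target_volume <- cells$actual_volume <- p$V0
  cells$state <- "ENTEROCYTE_PROGENITOR"; cells$next_wait <- -1
  z <- -50
  cells$x <- crypt_radius(z, p$shape) - 4.6; cells$y <- 0; cells$z <- z
  st <- new_sim_state(cells, net, p)
  st <- relax_state(st, tol = 1e-4, max_steps = 500)
  res <- simulate_crypt(st, 2, obs_dt = 2, biology = FALSE, migration = TRUE)
  disp <- sqrt(sum((res$state$cells[1, c("x", "y", "z")] -
                      st$cells[1, c("x", "y", "z")])^2))
  expect_equal(disp, 4.5 / p$eta_bm * 2, tolerance = 0.01)

  # two overlapping cells relax monotonically toward the pair equilibrium,
  # following dense-output ODE integration of the same two-body system:
  # d' = 2 F(d) / (eta_BM + 2 eta_c A(d))
  st2 <- make_fixture("two_cell", seed = 1)
  st2$cells$radius <- c(5, 5)
  st2$cells$target_volume <- st2$cells$actual_volume <- p$V0
  pe <- cryptsim:::params_for_engine(st2$params)
  pair_force <- function(d) {
    ce <- cryptsim:::cells_to_engine(st2$cells)
    ce$x <- c(0, d); ce$y <- c(0, 0); ce$z <- c(-100, -100)
    nf <- cryptsim:::cpp_net_forces(ce, NULL, pe, FALSE)
    nf$force[2, 1]
  }
  facet <- function(d) 1.5 * pi * 2.5 * pmax(10 - d, 0)
  ode <- deSolve::ode(
    y = c(d = 9), times = seq(0, 10, 0.25),
    func = function(t, y, ...) {
      list(2 * pair_force(y[1]) /
             (st2$params$eta_bm + 2 * st2$params$eta_c * facet(y[1])))
    })
  st2$cells$x <- c(0, 9); st2$cells$y <- 0; st2$cells$z <- -100
  traj_d <- numeric(0)
  s <- st2
  for (k in 1:40) {
    s <- simulate_crypt(s, 0.25, obs_dt = 0.25, biology = FALSE,
                        migration = FALSE)$state
    traj_d <- c(traj_d, abs(s$cells$x[2] - s$cells$x[1]))
  }
  # monotone approach to the equilibrium distance (no oscillation)
  expect_true(all(diff(traj_d) <= 1e-9) || all(diff(traj_d) >= -1e-9))
  expect_equal(traj_d[40], unname(ode[41, "d"]), tolerance = 0.02)
  # centre of mass is preserved by internal forces
  expect_equal(mean(s$cells$x), 4.5, tolerance = 1e-6)
})
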