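# Simulation loop: initialisation, determinism, stepping, checkpointing.

test_that("initialisation is deterministic and produces an attached monolayer", {
  a <- make_fixture("mini_crypt", seed = 5)
  b <- make_fixture("mini_crypt", seed = 5)
  expect_identical(a$cells, b$cells)
  expect_identical(a$network$knots, b$network$knots)
  nf <- net_generalized_forces(a, migration = FALSE)
  expect_true(all(nf$dist_bm < a$cells$radius))   # every cell touches the BM
  expect_true(all(nf$n_knots >= 1))
  # relaxation brought the per-step displacement below the tolerance
  expect_lt(attr(a, "relax")$max_displacement, 0.05 + 1e-9)
})

test_that("same seed gives identical trajectories and event logs", {
  st <- make_fixture("mini_crypt", seed = 6)
  r1 <- simulate_crypt(st, 24, obs_dt = 6, seed = 99)
  r2 <- simulate_crypt(st, 24, obs_dt = 6, seed = 99)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$state$cells, r2$state$cells)
})

test_that("a zero-duration run returns the state unchanged", {
  st <- make_fixture("mini_crypt", seed = 6)
  r <- simulate_crypt(st, 0)
  expect_identical(r$state$cells, st$cells)
  expect_equal(nrow(r$events), 0)
  expect_equal(nrow(r$trajectory), 1)
})

test_that("observer cadence is respected", {
  st <- make_fixture("mini_crypt", seed = 6)
  r <- simulate_crypt(st, 12, obs_dt = 3, seed = 1)
  expect_equal(r$trajectory$time, c(0, 3, 6, 9, 12))
})

test_that("cell-count bookkeeping matches the event log", {
  st <- warmed_mini()
  r <- simulate_crypt(st, 48, obs_dt = 48, seed = 13)
  ev <- r$events
  dn <- nrow(r$state$cells) - nrow(st$cells)
  expect_equal(dn, sum(ev$type == "division") - sum(ev$type == "removal"))
  # unique ids, never reused
  expect_false(any(duplicated(r$state$cells$id)))
  expect_gt(min(setdiff(r$state$cells$id, st$cells$id)), max(st$cells$id))
})

test_that("no step leaves cells interpenetrating beyond the rejection bound", {
  st <- warmed_mini()
  r <- simulate_crypt(st, 24, obs_dt = 24, seed = 17)
  cc <- r$state$cells
  pos <- as.matrix(cc[, c("x", "y", "z")])
  D <- as.matrix(dist(pos)); diag(D) <- Inf
  lim <- 0.2 * outer(cc$radius, cc$radius, "+")
  expect_true(all(D >= lim))
})

test_that("resuming from a checkpoint replays the uninterrupted run", {
  st <- make_fixture("mini_crypt", seed = 8)
  full <- simulate_crypt(st, 6, obs_dt = 3, seed = 77)
  set.seed(77)
  half1 <- simulate_crypt(st, 3, obs_dt = 3)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(half1$state, path)
  resumed <- load_checkpoint(path)
  half2 <- simulate_crypt(resumed, 3, obs_dt = 3)
  expect_equal(half2$state$cells, full$state$cells, tolerance = 1e-12)
  expect_equal(half2$state$time, full$state$time)
})

test_that("the junction boundary keeps the crypt mouth decompressed", {
  st <- warmed_mini()
  cc <- st$cells
  comp <- 1 - cc$actual_volume / cc$target_volume
  top <- cc$z > -10
  midband <- cc$z > -55 & cc$z < -35
  if (sum(top) >= 3 && sum(midband) >= 3)
    expect_lt(mean(comp[top]), mean(comp[midband]) + 0.02)
})

test_that("relaxation decreases the total mechanical energy", {
  st <- make_fixture("five_cell", seed = 9)
  pe <- cryptsim:::params_for_engine(st$params)
  e0 <- cryptsim:::cpp_total_energy(cryptsim:::cells_to_engine(st$cells),
                                    NULL, pe)
  st2 <- relax_state(st, tol = 1e-5, max_steps = 400)
  e1 <- cryptsim:::cpp_total_energy(cryptsim:::cells_to_engine(st2$cells),
                                    NULL, pe)
  expect_lt(e1, e0 + 1e-9)
})
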