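# Wnt/Notch activities, the lineage state machine, growth and division.

p_ref <- model_params()

test_that("Notch activity sums the ligand weights of contacting neighbours", {
  expect_equal(notch_activity(character(0), p_ref), 0)
  expect_equal(notch_activity("ENTEROCYTE_PROGENITOR", p_ref), 0)
  expect_equal(notch_activity("GOBLET", p_ref), 1.00)
  expect_equal(notch_activity(c("PANETH", "PANETH"), p_ref), 0.70)
  expect_equal(notch_activity(c("PANETH", "GOBLET_PROGENITOR",
                                "UNDIFFERENTIATED"), p_ref), 1.35)
})

test_that("the fate truth table matches a hand-coded oracle over all quadrants", {
  oracle <- function(iw, in_, p) {
    if (iw >= p$tp_wnt) {
      if (in_ >= p$tp_notch) "UNDIFFERENTIATED" else "PANETH_PRIMED"
    } else if (iw >= p$td_wnt) {
      if (in_ >= p$tp_notch) "ENTEROCYTE_PROGENITOR" else "GOBLET_PROGENITOR"
    } else {
      if (in_ >= p$td_notch) "ENTEROCYTE" else "GOBLET"
    }
  }
  iw_grid <- c(p_ref$tp_wnt + 0.1, p_ref$tp_wnt,
               (p_ref$tp_wnt + p_ref$td_wnt) / 2, p_ref$td_wnt,
               p_ref$td_wnt - 0.05)
  in_grid <- c(0, 0.7, 1, 1.05, 2)
  nonterm <- setdiff(LINEAGE_STATES, TERMINAL_STATES)
  for (iw in iw_grid) for (inn in in_grid) for (cur in nonterm)
    expect_identical(classify_fate(iw, inn, cur, p_ref),
                     oracle(iw, inn, p_ref))
  # activities exactly at a threshold count as high: one Goblet contact is
  # enough to keep an undifferentiated cell undifferentiated
  expect_identical(classify_fate(p_ref$tp_wnt, 1, "UNDIFFERENTIATED", p_ref),
                   "UNDIFFERENTIATED")
  # de-differentiation: a progenitor back in the niche reverts
  expect_identical(classify_fate(p_ref$tp_wnt + 0.1, 1.05,
                                 "ENTEROCYTE_PROGENITOR", p_ref),
                   "UNDIFFERENTIATED")
  expect_error(classify_fate(1, 1, "PANETH", p_ref), "terminal")
})

test_that("contact inhibition compares the actual volume to the threshold", {
  V0 <- p_ref$V0
  expect_false(contact_inhibited(V0, V0, p_ref))           # isolated
  expect_true(contact_inhibited(0.80 * V0, V0, p_ref))     # compressed
  expect_false(contact_inhibited(0.90 * V0, V0, p_ref))
  p_rel <- model_params(vp_reference = "Vt")
  expect_true(contact_inhibited(0.80 * 2 * V0, 2 * V0, p_rel))
  expect_false(contact_inhibited(0.90 * 2 * V0, 2 * V0, p_rel))
})

test_that("doubling times are Gamma distributed with the configured mean", {
  dt <- growth_doubling_times(10000, p_ref, seed = 7, horizon = 40)
  expect_gt(length(dt), 9500)
  expect_equal(mean(dt), p_ref$tau, tolerance = 0.02)
  ks <- suppressWarnings(
    stats::ks.test(dt, stats::pgamma, shape = p_ref$n_growth_steps,
                   scale = p_ref$tau / p_ref$n_growth_steps))
  expect_gt(ks$p.value, 0.01)
})

test_that("division conserves volume, inherits labels and needs a ready mother", {
  st <- make_fixture("two_cell", seed = 3)
  st$cells$target_volume[1] <- 2 * st$params$V0
  st$cells$brdu[1] <- TRUE
  st$cells$clone[1] <- 77L
  expect_error(divide_cell(st, 2), "not division-ready")
  st2 <- divide_cell(st, 1)
  expect_equal(nrow(st2$cells), 3)
  kids <- st2$cells[st2$cells$clone == 77L, ]
  expect_equal(nrow(kids), 2)
  expect_equal(sum(kids$target_volume), 2 * st$params$V0)
  expect_true(all(kids$brdu))
  expect_true(all(kids$id > max(st$cells$id)))
  # centre separation equals the daughter radius
  sep <- sqrt(sum((kids[1, c("x", "y", "z")] - kids[2, c("x", "y", "z")])^2))
  expect_equal(sep, st$params$R0, tolerance = 1e-9)
})

test_that("division directions are uniform in the local tangent plane", {
  set.seed(21)
  pe <- cryptsim:::params_for_engine(p_ref)
  z <- -60
  centre <- c(crypt_radius(z, p_ref$shape) - 4.5, 0, z)
  n <- 4000
  dirs <- t(vapply(seq_len(n),
                   function(i) cryptsim:::cpp_division_direction(centre, pe),
                   numeric(3)))
  # all unit and tangent to the surface (no normal component)
  expect_equal(rowSums(dirs^2), rep(1, n), tolerance = 1e-9)
  np <- nearest_surface_point(matrix(centre, 1), p_ref$shape)
  u <- (centre - np$foot[1, ]) / np$dist
  expect_lt(max(abs(dirs %*% u)), 1e-6)
  # Rayleigh test for uniformity of the in-plane angle
  ez <- c(0, 0, 1); t1 <- ez - sum(ez * u) * u; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  ang <- atan2(dirs %*% t2, dirs %*% t1)
  rbar2 <- mean(cos(ang))^2 + mean(sin(ang))^2
  p_rayleigh <- exp(-n * rbar2)
  expect_gt(p_rayleigh, 0.01)
})

test_that("removal verdicts follow the junction, anoikis and life-span rules", {
  st <- warmed_mini()
  v <- removal_verdicts(st)
  expect_true(all(v == "keep"))
  st2 <- st
  st2$cells$z[1] <- 1          # beyond the crypt-villus junction
  st2$cells$x[2] <- 0; st2$cells$y[2] <- 0; st2$cells$z[2] <- -30  # lumen
  i_pan <- setdiff(which(st2$cells$state == "PANETH"), 1:2)[1]
  if (!is.na(i_pan)) st2$cells$paneth_since[i_pan] <- st2$time - 58 * 24
  v2 <- removal_verdicts(st2)
  expect_identical(v2[1], "junction_exit")
  expect_identical(v2[2], "anoikis")
  if (!is.na(i_pan)) expect_identical(v2[i_pan], "paneth_lifespan")
})

test_that("terminal states are never left in simulated trajectories", {
  st <- warmed_mini()
  res <- simulate_crypt(st, 48, obs_dt = 12, seed = 31)
  f <- res$events[res$events$type == "fate", ]
  expect_false(any(f$from %in% TERMINAL_STATES &
                     f$to != f$from))
  # and the only route into PANETH is from PANETH_PRIMED
  expect_true(all(f$from[f$to == "PANETH"] == "PANETH_PRIMED"))
})

test_that("secretory-primed cells do not start new growth cycles", {
  st <- warmed_mini()
  res <- simulate_crypt(st, 72, obs_dt = 12, seed = 41)
  div <- res$events[res$events$type == "division", ]
  # divisions of secretory-primed mothers only complete already-running
  # cycles; their daughters (fresh cycles) never divide while still primed
  prim_daughters <- c(div$daughter1[div$mother_state == "PANETH_PRIMED"],
                      div$daughter2[div$mother_state == "PANETH_PRIMED"])
  expect_false(any(div$id %in% prim_daughters &
                     div$mother_state == "PANETH_PRIMED"))
})
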