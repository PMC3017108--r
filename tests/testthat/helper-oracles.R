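# Shared oracles and cached fixtures for the suite.

# finite-difference gradient of the total energy of a membrane-free state
fd_force_check <- function(state, eps = 1e-5) {
  pe <- cryptsim:::params_for_engine(state$params)
  ce <- cryptsim:::cells_to_engine(state$cells)
  kn <- cryptsim:::state_knots(state)
  nf <- cryptsim:::cpp_net_forces(ce, kn, pe, FALSE)
  en <- function(cc) cryptsim:::cpp_total_energy(cc, kn, pe)
  worst <- 0
  for (i in seq_len(nrow(state$cells))) {
    for (k in c("x", "y", "z", "radius")) {
      cp <- ce; cm <- ce
      cp[[k]][i] <- cp[[k]][i] + eps
      cm[[k]][i] <- cm[[k]][i] - eps
      fd <- -(en(cp) - en(cm)) / (2 * eps)
      an <- switch(k, x = nf$force[i, 1], y = nf$force[i, 2],
                   z = nf$force[i, 3], radius = nf$force_radius[i])
      worst <- max(worst, abs(fd - an) / max(abs(an), 1e-6))
    }
  }
  worst
}

# Monte-Carlo actual-volume oracle: sphere minus the caps cut off by the
# contact planes with neighbours sitting along given unit directions
mc_actual_volume <- function(R, neigh_R, neigh_d, dirs, n = 1e6) {
  pts <- matrix(stats::runif(3 * n, -R, R), ncol = 3)
  inside <- rowSums(pts^2) < R^2
  for (j in seq_along(neigh_R)) {
    d <- neigh_d[j]; Rj <- neigh_R[j]
    xi <- (d^2 + R^2 - Rj^2) / (2 * d)
    proj <- pts %*% dirs[j, ]
    inside <- inside & (proj < xi)
  }
  mean(inside) * (2 * R)^3
}

# memoised expensive fixtures (built once per test session)
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

warmed_mini <- function() cached("warmed_mini", {
  st <- make_fixture("mini_crypt", seed = 2)
  simulate_crypt(st, 240, obs_dt = 24, seed = 12)$state
})

# reference-crypt steady state: 10-day warm-up, then a 10-day measurement
# window (shared by several acceptance checks)
acceptance_ref <- function() cached("acceptance_ref", {
  p <- model_params()
  st <- initialize_crypt(p, seed = 101)
  wu <- simulate_crypt(st, 240, obs_dt = 240, seed = 101)
  res <- simulate_crypt(wu$state, 240, obs_dt = 12)
  list(warm = wu$state, res = res,
       metrics = steady_state_metrics(res$trajectory, res$events, res$state))
})
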