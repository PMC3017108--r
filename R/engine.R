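# Simulation state container and the main driver functions.

empty_events <- function() {
  data.frame(time = numeric(0), type = character(0), id = integer(0),
             daughter1 = integer(0), daughter2 = integer(0),
             mother_state = character(0), cause = character(0),
             state = character(0), from = character(0), to = character(0),
             stringsAsFactors = FALSE)
}

new_cells_df <- function(n = 0) {
  data.frame(id = integer(n), x = numeric(n), y = numeric(n), z = numeric(n),
             radius = numeric(n), target_volume = numeric(n),
             actual_volume = numeric(n), state = character(n),
             growth_steps = integer(n), growth_clock = numeric(n),
             next_wait = numeric(n), clone = integer(n), brdu = logical(n),
             birth_time = numeric(n), paneth_since = numeric(n) - 1,
             primed_since = numeric(n) - 1,
             n_knots = integer(n), bm_zeta = numeric(n),
             stringsAsFactors = FALSE)
}

cells_to_engine <- function(cells) {
  list(x = cells$x, y = cells$y, z = cells$z, radius = cells$radius,
       target_volume = cells$target_volume,
       state = state_code(cells$state),
       growth_steps = as.integer(cells$growth_steps),
       growth_clock = cells$growth_clock,
       next_wait = cells$next_wait,
       clone = as.integer(cells$clone),
       brdu = as.integer(cells$brdu),
       birth_time = cells$birth_time,
       paneth_since = cells$paneth_since,
       primed_since = cells$primed_since,
       id = as.integer(cells$id),
       bm_zeta = if ("bm_zeta" %in% names(cells)) cells$bm_zeta else cells$z)
}

engine_to_cells <- function(L) {
  data.frame(id = L$id, x = L$x, y = L$y, z = L$z, radius = L$radius,
             target_volume = L$target_volume, actual_volume = L$va,
             state = state_name(L$state),
             growth_steps = L$growth_steps, growth_clock = L$growth_clock,
             next_wait = L$next_wait, clone = L$clone,
             brdu = as.logical(L$brdu), birth_time = L$birth_time,
             paneth_since = L$paneth_since, primed_since = L$primed_since,
             n_knots = L$n_knots, bm_zeta = L$bm_zeta,
             stringsAsFactors = FALSE)
}

engine_events_to_df <- function(E) {
  n <- length(E$time)
  out <- empty_events()
  if (n == 0) return(out)
  causes <- c("junction_exit", "anoikis", "paneth_lifespan")
  out <- data.frame(
    time = E$time,
    type = c("division", "removal", "fate")[E$type + 1L],
    id = E$id,
    daughter1 = ifelse(E$type == 0L, E$a1, NA_integer_),
    daughter2 = ifelse(E$type == 0L, E$a2, NA_integer_),
    mother_state = ifelse(E$type == 0L, state_name(pmax(E$a3, 0L)), NA),
    cause = ifelse(E$type == 1L, causes[pmin(E$a1, 2L) + 1L], NA),
    state = ifelse(E$type == 1L, state_name(pmax(E$a2, 0L)), NA),
    from = ifelse(E$type == 2L, state_name(pmax(E$a1, 0L)), NA),
    to = ifelse(E$type == 2L, state_name(pmax(E$a2, 0L)), NA),
    stringsAsFactors = FALSE)
  out
}

state_knots <- function(state) {
  if (is.null(state$network)) NULL else state$network$knots
}

#' Construct a simulation state
#'
#' @param cells A cell data frame (see [initialize_crypt()] for the columns).
#' @param network A `bm_network` or `NULL` for membrane-free fixtures.
#' @param params A [model_params()].
#' @param time Simulation clock (h).
#' @return An object of class `sim_state`.
#' @export
new_sim_state <- function(cells, network, params, time = 0) {
  stopifnot(inherits(params, "model_params"),
            is.null(network) || inherits(network, "bm_network"))
  structure(list(time = time, cells = cells, network = network,
                 params = params, events = empty_events()),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: t = %.2f h, %d cells", x$time, nrow(x$cells)))
  if (!is.null(x$network))
    cat(sprintf(", BM network with %d knots", nrow(x$network$knots)))
  cat("\n")
  if (nrow(x$cells) > 0) print(table(x$cells$state))
  invisible(x)
}

#' Initialise a crypt in a mechanically relaxed monolayer
#'
#' Builds the BM network for the configured shape, places cells in a single
#' layer on the membrane from the base upwards at near-close packing, assigns
#' initial lineage states by axial position (a mixed Paneth/undifferentiated
#' bottom compartment below `z_p`, mostly enterocyte progenitors between
#' `z_p` and `z_d`, mostly terminal enterocytes above), staggers cell-cycle
#' progress and Paneth ages, and relaxes the packing mechanically (no growth,
#' no migration) until the maximum displacement per step falls below `tol`.
#'
#' @param params A [model_params()].
#' @param seed Integer seed for the initial-state randomness.
#' @param tol Relaxation displacement tolerance (um per step).
#' @param max_relax_steps Cap on relaxation steps.
#' @return A `sim_state` at time 0.
#' @export
initialize_crypt <- function(params = model_params(), seed = 1L,
                             tol = 0.05, max_relax_steps = 1000L) {
  set.seed(seed)
  shape <- params$shape
  net <- triangulate_crypt(shape, params$lambda_max)

  # cell placement rings along the meridian arc, centres pulled inside
  R0 <- params$R0
  spacing <- 1.95 * R0
  u <- seq(0, 1, length.out = 2000L)
  zg <- -shape$z0 + u^2 * shape$z0
  rg <- cpp_crypt_radius(zg, unclass(shape))
  arc <- c(0, cumsum(sqrt(diff(zg)^2 + diff(rg)^2)))
  Ltot <- arc[length(arc)]
  v <- spacing * sqrt(3) / 2
  nrow_ <- max(3L, round((Ltot - spacing) / v))
  ell <- spacing * 0.8 + seq_len(nrow_) * ((Ltot - spacing * 0.8) / nrow_)
  zr <- stats::approx(arc, zg, xout = pmin(ell, Ltot))$y
  zr[length(zr)] <- -0.5  # keep the top ring just inside the crypt
  rr <- cpp_crypt_radius(zr, unclass(shape))
  dv <- cpp_crypt_radius_derivs(zr, unclass(shape))
  q <- sqrt(1 + dv[, "rp"]^2)

  xs <- ys <- zs <- numeric(0)
  inward <- 0.9 * R0
  for (k in seq_along(zr)) {
    m <- max(3L, round(2 * pi * rr[k] / spacing))
    phi <- (k %% 2) * pi / m + 2 * pi * (seq_len(m) - 1) / m
    # offset the centre inwards along the local surface normal
    rc <- rr[k] - inward / q[k]
    zc <- zr[k] + inward * dv[k, "rp"] / q[k]
    xs <- c(xs, rc * cos(phi)); ys <- c(ys, rc * sin(phi))
    zs <- c(zs, rep(zc, m))
  }
  # one cell over the pole
  xs <- c(0, xs); ys <- c(0, ys); zs <- c(-shape$z0 + inward, zs)
  n <- length(xs)

  st <- character(n)
  low <- zs < params$z_p
  mid <- zs >= params$z_p & zs < params$z_d
  hi <- zs >= params$z_d
  # niche: undifferentiated cells interspersed singly between Paneth cells
  # (two of three niche cells are Paneth), so every stem cell starts with
  # enough Notch-ligand contacts to stay undifferentiated
  st[low] <- ifelse(seq_len(sum(low)) %% 2 == 0, "UNDIFFERENTIATED", "PANETH")
  st[mid] <- ifelse(stats::runif(sum(mid)) < 0.85, "ENTEROCYTE_PROGENITOR",
                    "GOBLET_PROGENITOR")
  # upper crypt: a mix of terminal cells and progenitors still finishing
  # their cycle (they terminally differentiate at cycle completion)
  uu <- stats::runif(sum(hi))
  st[hi] <- ifelse(uu < 0.55, "ENTEROCYTE_PROGENITOR",
                   ifelse(uu < 0.65, "GOBLET_PROGENITOR",
                          ifelse(uu < 0.9, "ENTEROCYTE", "GOBLET")))

  cycling <- st %in% c(PROLIFERATIVE_STATES, "GOBLET_PROGENITOR") &
    (zs < params$z_d | st %in% c("ENTEROCYTE_PROGENITOR", "GOBLET_PROGENITOR"))
  gs <- integer(n)
  # every initial cycling cell is mid-cycle (>= 1 growth step done)
  gs[cycling] <- 1L + as.integer(floor(stats::runif(sum(cycling)) *
                                         (params$n_growth_steps - 1L)))
  Vt <- params$V0 * (1 + gs / params$n_growth_steps)
  psince <- rep(-1, n)
  pan <- st == "PANETH"
  # Paneth ages uniform over the life span, so replacement demand is steady
  # from the start
  psince[pan] <- -stats::runif(sum(pan), 0, params$t_paneth)

  cells <- data.frame(
    id = seq_len(n) - 1L, x = xs, y = ys, z = zs,
    radius = R0 * (Vt / params$V0)^(1 / 3),
    target_volume = Vt, actual_volume = Vt, state = st,
    growth_steps = gs, growth_clock = 0, next_wait = -1,
    clone = seq_len(n) - 1L, brdu = FALSE, birth_time = 0,
    paneth_since = psince, primed_since = -1, n_knots = 0L,
    stringsAsFactors = FALSE)

  state <- new_sim_state(cells, net, params)
  relax_state(state, tol = tol, max_steps = max_relax_steps)
}

#' Mechanically relax a state
#'
#' Advances the overdamped mechanics (no growth, division, removal or fate
#' changes; migration off by default) until the maximum displacement per step
#' drops below `tol` or `max_steps` is reached.
#'
#' @param state A `sim_state`.
#' @param tol Displacement tolerance (um per step).
#' @param max_steps Step cap.
#' @param migration Include active migration forces?
#' @return The relaxed `sim_state` (with an attribute `relax` holding the
#'   step count and final displacement).
#' @export
relax_state <- function(state, tol = 0.01, max_steps = 1000L,
                        migration = FALSE) {
  stopifnot(inherits(state, "sim_state"))
  res <- cpp_relax(cells_to_engine(state$cells), state_knots(state),
                   params_for_engine(state$params), tol,
                   as.integer(max_steps), migration)
  state$cells <- engine_to_cells(res$cells)
  attr(state, "relax") <- list(steps = res$steps,
                               max_displacement = res$max_displacement)
  state
}

#' Run the simulation
#'
#' Advances a state by `duration` hours with the full update loop: contact
#' detection, generalized forces, the parallel overdamped update of positions
#' and radii under an adaptive time step with interpenetration rejection,
#' stochastic growth, divisions, removals (junction exit, anoikis, Paneth
#' life span) and finally the Wnt/Notch state-vector update with fate
#' reclassification.
#'
#' @param state A `sim_state`.
#' @param duration Simulated time to advance (h).
#' @param obs_dt Observer cadence (h) for the trajectory table.
#' @param migration Apply active migration forces?
#' @param biology Run growth/division/removal/fate (otherwise pure
#'   mechanics)?
#' @param interactions Compute cell-cell and cell-BM interactions? Switching
#'   this off simulates isolated, motionless cells and is used for growth
#'   calibration runs.
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @return A list of class `sim_result` with elements `state` (the advanced
#'   `sim_state`), `trajectory` (data frame of counts per observer time) and
#'   `events` (data frame of division/removal/fate events).
#' @export
simulate_crypt <- function(state, duration, obs_dt = 1, migration = TRUE,
                           biology = TRUE, interactions = TRUE, seed = NULL) {
  stopifnot(inherits(state, "sim_state"), duration >= 0)
  if (!is.null(seed)) set.seed(seed)
  t0 <- state$time
  if (duration == 0) {
    res <- list(state = state,
                trajectory = trajectory_row(state),
                events = empty_events())
    class(res) <- "sim_result"
    return(res)
  }
  row0 <- trajectory_row(state, t0)
  out <- cpp_simulate(cells_to_engine(state$cells), state_knots(state),
                      params_for_engine(state$params), t0, duration, obs_dt,
                      migration, biology, interactions)
  state$cells <- engine_to_cells(out$cells)
  state$time <- out$time
  ev <- engine_events_to_df(out$events)
  state$events <- rbind(state$events, ev)
  traj <- as.data.frame(out$trajectory)
  traj <- rbind(row0, traj)
  res <- list(state = state, trajectory = traj, events = ev,
              clamp_warnings = out$clamp_warnings,
              radius_warnings = out$radius_warnings)
  class(res) <- "sim_result"
  res
}

# a single trajectory row from a static state (used for the t0 row)
trajectory_row <- function(state, time = state$time) {
  cnt <- table(factor(state$cells$state, levels = LINEAGE_STATES))
  data.frame(time = time, n = nrow(state$cells),
             n_undifferentiated = as.integer(cnt["UNDIFFERENTIATED"]),
             n_paneth_primed = as.integer(cnt["PANETH_PRIMED"]),
             n_paneth = as.integer(cnt["PANETH"]),
             n_enterocyte_progenitor = as.integer(cnt["ENTEROCYTE_PROGENITOR"]),
             n_goblet_progenitor = as.integer(cnt["GOBLET_PROGENITOR"]),
             n_enterocyte = as.integer(cnt["ENTEROCYTE"]),
             n_goblet = as.integer(cnt["GOBLET"]),
             cum_divisions = 0, cum_junction_exits = 0, cum_anoikis = 0,
             cum_paneth_deaths = 0, cum_dedifferentiation = 0)
}

#' Removal verdicts for all cells of a state
#'
#' Applies the removal rules to every cell: `junction_exit` for cells beyond
#' the crypt-villus junction (z > 0), `anoikis` for cells that lost contact
#' with the basal membrane (empty interacting-knot set), `paneth_lifespan`
#' for terminal Paneth cells older than `t_paneth`, otherwise `keep`.
#'
#' @param state A `sim_state` (with a BM network).
#' @return Character vector of verdicts, one per cell.
#' @export
removal_verdicts <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  cells <- state$cells
  nf <- net_generalized_forces(state, migration = FALSE)
  verdict <- rep("keep", nrow(cells))
  age_paneth <- state$time - cells$paneth_since
  verdict[cells$state == "PANETH" &
            age_paneth > state$params$t_paneth] <- "paneth_lifespan"
  if (!is.null(state$network))
    verdict[nf$dist_bm > cells$radius] <- "anoikis"
  verdict[cells$z > 0] <- "junction_exit"
  verdict
}

#' Save / load a simulation checkpoint
#'
#' Checkpoints are written as RDS containers holding the full `sim_state`
#' (cells, network, parameters, clock and event log) with a schema version.
#'
#' @param state A `sim_state`.
#' @param path File path.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the restored `sim_state`.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "sim_state"))
  saveRDS(list(schema = 1L, state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, 1L)) stop("unknown checkpoint schema")
  stopifnot(inherits(obj$state, "sim_state"))
  obj$state
}

#' Write a trajectory table
#'
#' Writes observer samples as a comma-separated table with a header row.
#'
#' @param trajectory A trajectory data frame from [simulate_crypt()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
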