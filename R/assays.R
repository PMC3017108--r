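# Virtual experiments: sectioning, BrdU pulse-chase, clonal conversion,
# signalling perturbations, ablation and steady-state statistics.

#' Virtual half-crypt section
#'
#' Cuts a planar slab of given thickness through the crypt axis at a given
#' azimuth and splits it into the two half-crypts, mimicking the scoring of
#' histological sections. Cells whose centres lie in the slab are assigned to
#' a half by the sign of their in-plane coordinate and ordered by axial
#' position from the crypt base; the positional index counts 1, 2, ... from
#' the basal-most cell of each half.
#'
#' @param state A `sim_state`.
#' @param thickness Slab thickness (um); defaults to the configured section
#'   thickness.
#' @param azimuth Azimuth of the section plane (radians).
#' @return A data frame with the sectioned cells, their `half` (1 or 2) and
#'   `position` (1 = crypt base), ordered by half and position. Empty
#'   sections give a zero-row data frame.
#' @export
virtual_section <- function(state, thickness = state$params$t_section,
                            azimuth = 0) {
  stopifnot(inherits(state, "sim_state"), thickness > 0)
  cells <- state$cells
  if (nrow(cells) == 0) return(cbind(cells, half = integer(0),
                                     position = integer(0)))
  nx <- -sin(azimuth); ny <- cos(azimuth)
  off <- cells$x * nx + cells$y * ny
  inplane <- cells$x * cos(azimuth) + cells$y * sin(azimuth)
  keep <- abs(off) < thickness / 2
  sec <- cells[keep, , drop = FALSE]
  if (nrow(sec) == 0) return(cbind(sec, half = integer(0),
                                   position = integer(0)))
  sec$half <- ifelse(inplane[keep] >= 0, 1L, 2L)
  sec <- sec[order(sec$half, sec$z), , drop = FALSE]
  sec$position <- stats::ave(sec$z, sec$half, FUN = seq_along)
  rownames(sec) <- NULL
  sec
}

#' Positional profile over many half-crypt sections
#'
#' Scores a cell property on a positional basis over `n_halfcrypts` random
#' half-crypt sections.
#'
#' @param state A `sim_state`.
#' @param indicator A function mapping the section data frame to a logical
#'   vector (one entry per cell), e.g. BrdU positivity.
#' @param n_halfcrypts Number of half-crypts scored.
#' @param thickness Section thickness (um).
#' @return Data frame with `position`, `fraction` (of positive cells) and
#'   `n` (half-crypts contributing at that position).
#' @export
positional_profile <- function(state, indicator, n_halfcrypts = 50,
                               thickness = state$params$t_section) {
  az <- stats::runif(ceiling(n_halfcrypts / 2), 0, pi)
  pos <- integer(0); hit <- integer(0)
  cnt <- integer(0)
  tally <- list()
  for (a in az) {
    sec <- virtual_section(state, thickness, a)
    if (nrow(sec) == 0) next
    lab <- indicator(sec)
    for (h in unique(sec$half)) {
      sel <- sec$half == h
      tally[[length(tally) + 1]] <- data.frame(position = sec$position[sel],
                                               positive = lab[sel])
    }
  }
  if (length(tally) == 0)
    return(data.frame(position = integer(0), fraction = numeric(0),
                      n = integer(0)))
  all <- do.call(rbind, tally)
  agg <- stats::aggregate(positive ~ position, all,
                          FUN = function(v) c(mean(v), length(v)))
  data.frame(position = agg$position,
             fraction = agg$positive[, 1],
             n = as.integer(agg$positive[, 2]))
}

#' Virtual BrdU pulse-chase assay
#'
#' At time zero every proliferating cell (undifferentiated cells and
#' enterocyte progenitors, plus secretory-primed cells still completing a
#' cycle) is labelled independently with probability `label_fraction`; labels
#' are inherited by the entire progeny. The simulation is then advanced and
#' the positional label index is scored over half-crypt sections at each
#' sample time.
#'
#' @param state A `sim_state` (steady state).
#' @param sample_times Chase times (h) at which profiles are taken.
#' @param label_fraction Labelling probability of a proliferating cell.
#' @param n_halfcrypts Half-crypts scored per sample time.
#' @param seed Integer seed.
#' @return A list with `profiles` (one positional profile per sample time,
#'   named by the time) and `state` (the final state).
#' @export
brdu_assay <- function(state, sample_times = c(2, 24),
                       label_fraction = state$params$brdu_label_fraction,
                       n_halfcrypts = 50, seed = 1L) {
  stopifnot(inherits(state, "sim_state"), all(sample_times >= 0))
  set.seed(seed)
  cells <- state$cells
  prolif <- cells$state %in% PROLIFERATIVE_STATES |
    (cells$growth_steps > 0 &
       cells$state %in% c("PANETH_PRIMED", "GOBLET_PROGENITOR"))
  cells$brdu <- prolif & stats::runif(nrow(cells)) < label_fraction
  state$cells <- cells
  sample_times <- sort(sample_times)
  profiles <- list()
  now <- 0
  for (tt in sample_times) {
    if (tt > now) {
      res <- simulate_crypt(state, tt - now, obs_dt = max(tt - now, 1))
      state <- res$state
      now <- tt
    }
    profiles[[as.character(tt)]] <-
      positional_profile(state, function(sec) sec$brdu, n_halfcrypts)
  }
  list(profiles = profiles, state = state)
}

# label-weighted centre of mass of a positional profile
profile_centre <- function(profile) {
  if (nrow(profile) == 0 || sum(profile$fraction) == 0) return(NA_real_)
  sum(profile$position * profile$fraction) / sum(profile$fraction)
}

#' Double-exponential decay fit
#'
#' Least-squares fit of `N(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2)` with
#' `tau1 <= tau2`, used for clone-count decay curves.
#'
#' @param t Time points.
#' @param N Counts.
#' @return List with `tau1`, `tau2`, `A1`, `A2`, `fitted`, and `converged`.
#' @export
fit_biexponential <- function(t, N) {
  stopifnot(length(t) == length(N), length(t) >= 5)
  span <- max(t) - min(t)
  start <- list(A1 = max(N) * 0.7, l1 = 10 / span,
                A2 = max(N) * 0.3, l2 = 1 / span)
  fit <- try(minpack.lm::nlsLM(
    N ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t),
    start = start,
    lower = c(0, 1e-8, 0, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(tau1 = NA_real_, tau2 = NA_real_, A1 = NA_real_,
                A2 = NA_real_, fitted = rep(NA_real_, length(t)),
                converged = FALSE))
  cf <- stats::coef(fit)
  taus <- sort(1 / c(cf[["l1"]], cf[["l2"]]))
  amps <- c(cf[["A1"]], cf[["A2"]])[order(1 / c(cf[["l1"]], cf[["l2"]]))]
  list(tau1 = taus[1], tau2 = taus[2], A1 = amps[1], A2 = amps[2],
       fitted = stats::fitted(fit), converged = TRUE)
}

#' Clonal labelling and monoclonal conversion
#'
#' Labels every cell with a unique clonal marker, inherited by all offspring,
#' and follows the number of coexisting clones over time. The clone-count
#' decay is fitted with a double exponential; per-founder survival records
#' are returned.
#'
#' @param state A `sim_state` (steady state).
#' @param duration Simulated time to follow (h).
#' @param obs_dt Sampling cadence for clone counts (h).
#' @param seed Integer seed.
#' @return A list: `counts` (data frame time, n_clones, n_cells), `records`
#'   (per-clone founder z, founder state, extinction time or NA), `fit`
#'   (double-exponential fit of the clone counts) and `state`.
#' @export
clonal_conversion <- function(state, duration = 21 * 24, obs_dt = 24,
                              seed = 1L) {
  stopifnot(inherits(state, "sim_state"), duration > 0)
  set.seed(seed)
  cells <- state$cells
  cells$clone <- seq_len(nrow(cells)) - 1L
  state$cells <- cells
  founders <- data.frame(clone = cells$clone, founder_z = cells$z,
                         founder_state = cells$state,
                         stringsAsFactors = FALSE)
  times <- seq(0, duration, by = obs_dt)
  counts <- data.frame(time = 0, n_clones = nrow(cells),
                       n_cells = nrow(cells))
  extinct <- rep(NA_real_, nrow(founders))
  alive_prev <- founders$clone
  t0 <- state$time
  for (k in seq_along(times)[-1]) {
    res <- simulate_crypt(state, times[k] - times[k - 1], obs_dt = obs_dt)
    state <- res$state
    alive <- unique(state$cells$clone)
    gone <- setdiff(alive_prev, alive)
    extinct[match(gone, founders$clone)] <- t0 + times[k]
    alive_prev <- alive
    counts <- rbind(counts, data.frame(time = times[k],
                                       n_clones = length(alive),
                                       n_cells = nrow(state$cells)))
  }
  founders$extinction_time <- extinct
  founders$survived <- is.na(extinct) & founders$clone %in% alive_prev
  fit <- if (nrow(counts) >= 5)
    fit_biexponential(counts$time, counts$n_clones)
  else list(converged = FALSE)
  list(counts = counts, records = founders, fit = fit, state = state)
}

#' Wnt/Notch gain- and loss-of-function perturbation
#'
#' Installs a constitutive signalling perturbation in the model rules:
#' `WNT_UP` holds the Wnt activity of every cell at or above the priming
#' threshold, `WNT_DOWN` below it, `NOTCH_UP` holds the Notch activity above
#' threshold everywhere and `NOTCH_DOWN` blocks Notch signalling completely.
#' Fate rules are otherwise unchanged.
#'
#' @param state A `sim_state`.
#' @param kind One of `"WNT_UP"`, `"WNT_DOWN"`, `"NOTCH_UP"`, `"NOTCH_DOWN"`.
#' @return The state with the perturbed rule set.
#' @export
apply_perturbation <- function(state, kind = c("WNT_UP", "WNT_DOWN",
                                               "NOTCH_UP", "NOTCH_DOWN")) {
  stopifnot(inherits(state, "sim_state"))
  kind <- match.arg(kind)
  p <- state$params
  if (kind == "WNT_UP") p$wnt_mode <- "up"
  if (kind == "WNT_DOWN") p$wnt_mode <- "down"
  if (kind == "NOTCH_UP") p$notch_mode <- "up"
  if (kind == "NOTCH_DOWN") p$notch_mode <- "down"
  state$params <- p
  state
}

#' Ablate a set of lineages
#'
#' Removes all cells of the targeted lineage states instantaneously.
#' Ablating every proliferative state is flagged: without undifferentiated
#' cells and progenitors the crypt loses its regenerative action and dies
#' out.
#'
#' @param state A `sim_state`.
#' @param lineages Character vector of [LINEAGE_STATES] to remove (may be
#'   empty, in which case the state is returned unchanged).
#' @return The ablated `sim_state`, with attribute `ablation` recording the
#'   removed count and whether crypt death is expected.
#' @export
ablate <- function(state, lineages = character(0)) {
  stopifnot(inherits(state, "sim_state"),
            all(lineages %in% LINEAGE_STATES))
  keep <- !(state$cells$state %in% lineages)
  removed <- sum(!keep)
  prolif_left <- any(state$cells$state[keep] %in%
                       c(PROLIFERATIVE_STATES, "PANETH_PRIMED",
                         "GOBLET_PROGENITOR"))
  state$cells <- state$cells[keep, , drop = FALSE]
  rownames(state$cells) <- NULL
  attr(state, "ablation") <- list(removed = removed,
                                  lineages = lineages,
                                  expected_crypt_death = !prolif_left)
  state
}

#' Recovery time of a lineage count after a perturbation
#'
#' First time at which a trajectory column re-enters the band
#' `(1 +/- band) * reference` and stays inside it for at least `hold` hours.
#'
#' @param trajectory A trajectory data frame.
#' @param column Column name (e.g. `"n_undifferentiated"`).
#' @param reference Pre-perturbation steady-state mean of that count.
#' @param band Relative half-width of the recovery band.
#' @param hold Time (h) the count must remain in the band.
#' @param smooth Width (h) of the running-mean window applied to the count
#'   before band detection (0 disables smoothing).
#' @return Recovery time in hours since the start of the trajectory, or `NA`
#'   if the count never stabilises in the band.
#' @export
recovery_time <- function(trajectory, column, reference, band = 0.2,
                          hold = 24, smooth = 24) {
  tt <- trajectory$time - trajectory$time[1]
  v <- trajectory[[column]]
  if (smooth > 0 && length(tt) > 2) {
    # running mean over the smoothing window: small pools fluctuate by
    # whole cells, which would otherwise keep them out of a 20% band forever
    v <- vapply(seq_along(tt), function(i) {
      w <- tt >= tt[i] - smooth / 2 & tt <= tt[i] + smooth / 2
      mean(trajectory[[column]][w])
    }, numeric(1))
  }
  inside <- abs(v - reference) <= band * max(reference, 1e-9)
  for (i in seq_along(tt)) {
    if (!inside[i]) next
    j <- which(tt >= tt[i] + hold)
    horizon <- if (length(j)) seq(i, j[1]) else seq(i, length(tt))
    if (all(inside[horizon]) && (length(j) > 0 || tt[length(tt)] - tt[i] >= hold))
      return(tt[i])
  }
  NA_real_
}

#' Steady-state statistics of a crypt trajectory
#'
#' Summarises a steady-state run: mean counts per lineage, the Paneth
#' compartment size (undifferentiated plus Paneth-committed cells), the
#' turnover time (mean cell number divided by the mean removal rate), the
#' spontaneous apoptosis (anoikis) rate as percent of crypt cells per day,
#' undifferentiated-cell division-interval statistics and the
#' de-differentiation rate per enterocyte-progenitor-day.
#'
#' @param trajectory A trajectory data frame spanning the measurement window.
#' @param events Optional events data frame (needed for division-interval
#'   statistics).
#' @param state Optional final `sim_state` (used to censor division
#'   intervals of still-alive cells).
#' @return A list of named statistics.
#' @export
steady_state_metrics <- function(trajectory, events = NULL, state = NULL) {
  tr <- trajectory
  span_h <- max(tr$time) - min(tr$time)
  if (span_h < 48) stop("measurement window shorter than 2 days")
  span_d <- span_h / 24
  mean_n <- mean(tr$n)
  counts <- vapply(c("n_undifferentiated", "n_paneth_primed", "n_paneth",
                     "n_enterocyte_progenitor", "n_goblet_progenitor",
                     "n_enterocyte", "n_goblet"),
                   function(cn) mean(tr[[cn]]), numeric(1))
  d_jun <- tail(tr$cum_junction_exits, 1) - tr$cum_junction_exits[1]
  d_ano <- tail(tr$cum_anoikis, 1) - tr$cum_anoikis[1]
  d_pan <- tail(tr$cum_paneth_deaths, 1) - tr$cum_paneth_deaths[1]
  d_div <- tail(tr$cum_divisions, 1) - tr$cum_divisions[1]
  efflux_day <- (d_jun + d_ano) / span_d
  out <- list(
    mean_n = mean_n,
    mean_counts = counts,
    paneth_compartment = unname(counts["n_undifferentiated"] +
                                  counts["n_paneth_primed"] +
                                  counts["n_paneth"]),
    divisions_per_day = d_div / span_d,
    efflux_per_day = efflux_day,
    turnover_days = if (efflux_day > 0) mean_n / efflux_day else Inf,
    paneth_deaths_per_day = d_pan / span_d,
    anoikis_pct_per_day = 100 * (d_ano / span_d) / mean_n,
    dediff_per_progenitor_day =
      dediff_episode_count(events, min(tr$time), max(tr$time)) / span_d /
        max(counts["n_enterocyte_progenitor"], 1e-9))
  if (!is.null(events) && nrow(events) > 0) {
    div <- events[events$type == "division", , drop = FALSE]
    if (nrow(div) > 0) {
      # birth times known for cells born in this window (as daughters)
      birth <- c(stats::setNames(div$time, div$daughter1),
                 stats::setNames(div$time, div$daughter2))
      mother_birth <- birth[as.character(div$id)]
      known <- !is.na(mother_birth)
      iv <- div$time[known] - mother_birth[known]
      st <- div$mother_state[known]
      ivu <- iv[st == "UNDIFFERENTIATED"]
      cens <- numeric(0)
      if (!is.null(state)) {
        cc <- state$cells
        alive_u <- cc$state == "UNDIFFERENTIATED" &
          cc$birth_time > min(tr$time)
        cens <- state$time - cc$birth_time[alive_u]
      }
      out$division_intervals_undiff <- ivu
      out$censored_ages_undiff <- cens
      n48 <- sum(ivu < 48) + 0
      denom <- length(ivu) + sum(cens >= 48)
      out$frac_divide_within_48h <- if (denom > 0) {
        # cells observed to divide within 48 h over all cells whose fate at
        # 48 h is known (divided, or still undivided past 48 h)
        n48 / denom
      } else NA_real_
      week <- 7 * 24
      denom_w <- length(ivu) + sum(cens >= week)
      out$frac_quiescent_over_week <-
        if (denom_w > 0) (sum(ivu > week) + sum(cens >= week)) / denom_w
        else NA_real_
    }
  }
  out
}

# de-differentiation episodes: EP -> UNDIFFERENTIATED transitions whose
# preceding enterocyte-progenitor dwell exceeded one hour (a cell hovering on
# the z_p boundary flips once per step and would otherwise be counted each
# crossing)
dediff_episode_count <- function(events, t_from, t_to, min_dwell = 1) {
  if (is.null(events) || nrow(events) == 0) return(0)
  f <- events[events$type == "fate", , drop = FALSE]
  if (nrow(f) == 0) return(0)
  f <- f[order(f$time), , drop = FALSE]
  n <- 0
  ids <- unique(f$id[f$from == "ENTEROCYTE_PROGENITOR" &
                       f$to == "UNDIFFERENTIATED"])
  for (id in ids) {
    fi <- f[f$id == id, , drop = FALSE]
    entered <- -Inf
    for (k in seq_len(nrow(fi))) {
      if (fi$to[k] == "ENTEROCYTE_PROGENITOR") entered <- fi$time[k]
      if (fi$from[k] == "ENTEROCYTE_PROGENITOR" &&
          fi$to[k] == "UNDIFFERENTIATED") {
        if (fi$time[k] >= t_from && fi$time[k] <= t_to &&
            fi$time[k] - entered >= min_dwell)
          n <- n + 1
        entered <- -Inf
      }
    }
  }
  n
}

#' Parameter sweep runner
#'
#' Runs replicate simulations over a grid of values of one model parameter
#' and summarises each run with [steady_state_metrics()].
#'
#' @param param Name of a [model_params()] argument (e.g. `"lp_paneth"`,
#'   `"z_p"`, `"F_A_paneth"`).
#' @param values Numeric vector of parameter values.
#' @param base Named list of further [model_params()] overrides applied to
#'   every run (the study conditions).
#' @param replicates Replicate runs per value.
#' @param warmup,window Warm-up and measurement durations (h).
#' @param seed Integer seed; replicate r of value v uses
#'   `seed + 1000 * match(v) + r`.
#' @return Data frame with one row per (value, replicate) and the summary
#'   statistics as columns.
#' @export
parameter_sweep <- function(param, values, base = list(), replicates = 1,
                            warmup = 120, window = 120, seed = 1L) {
  rows <- list()
  for (vi in seq_along(values)) {
    for (r in seq_len(replicates)) {
      args <- base
      args[[param]] <- values[vi]
      params <- do.call(model_params, args)
      s <- seed + 1000L * vi + r
      st <- initialize_crypt(params, seed = s)
      wu <- simulate_crypt(st, warmup, obs_dt = max(warmup, 1), seed = s)
      res <- simulate_crypt(wu$state, window, obs_dt = 12)
      m <- steady_state_metrics(res$trajectory, res$events, res$state)
      rows[[length(rows) + 1]] <- data.frame(
        param = param, value = values[vi], replicate = r,
        mean_n = m$mean_n,
        n_undifferentiated = m$mean_counts[["n_undifferentiated"]],
        n_paneth = m$mean_counts[["n_paneth"]],
        paneth_compartment = m$paneth_compartment,
        turnover_days = m$turnover_days,
        divisions_per_day = m$divisions_per_day,
        anoikis_pct_per_day = m$anoikis_pct_per_day)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an assay table
#'
#' Writes any of the assay outputs as a comma-separated table with a header
#' row.
#'
#' @param table A data frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_assay_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
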