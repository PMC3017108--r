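# Lineage specification: Notch activity, the fate truth table, growth and
# division rules exposed at the R level.  (Wnt activity lives in geometry.R,
# next to the curvature link it is built on.)

#' Notch activity from cell contacts
#'
#' Lateral-inhibition input of a cell: the sum of the Notch-activation
#' weights `LP` presented by every neighbour in direct contact
#' (`R_i + R_j > d_ij`). Paneth and Paneth-primed neighbours contribute
#' `lp_paneth`, Goblet and Goblet-progenitor neighbours `lp_goblet`, all
#' other states contribute nothing.
#'
#' @param contact_states Character vector of lineage states of the
#'   neighbours in direct contact.
#' @param params A [model_params()].
#' @return Dimensionless Notch activity.
#' @export
notch_activity <- function(contact_states, params = model_params()) {
  if (length(contact_states) == 0) return(0)
  code <- state_code(contact_states)
  lp <- numeric(length(code))
  lp[code %in% c(1L, 2L)] <- params$lp_paneth
  lp[code %in% c(4L, 6L)] <- params$lp_goblet
  sum(lp)
}

#' Fate classification truth table
#'
#' Reclassifies a non-terminal cell from its Wnt and Notch activities.
#' High Wnt (`I_wnt >= TP_wnt`) with high Notch keeps a cell
#' undifferentiated; high Wnt with low Notch primes the Paneth fate;
#' intermediate Wnt (`TD_wnt <= I_wnt < TP_wnt`) primes the enterocyte
#' (high Notch) or Goblet (low Notch) fate; and below `TD_wnt` the cell
#' differentiates terminally into an enterocyte or Goblet according to the
#' same Notch branch. Activities exactly at a threshold count as high.
#' All transitions among non-terminal states are permitted, so priming is
#' reversible. The transition of a Paneth-primed cell into the terminal
#' Paneth state is not part of this table: it happens when the cell
#' completes its running cell cycle (handled by the simulation engine).
#'
#' @param i_wnt,i_notch Wnt and Notch activity.
#' @param current Current lineage state (must not be terminal).
#' @param params A [model_params()].
#' @return The new lineage state name.
#' @export
classify_fate <- function(i_wnt, i_notch, current = "UNDIFFERENTIATED",
                          params = model_params()) {
  if (current %in% TERMINAL_STATES)
    stop("terminal states are never reclassified")
  state_name(cpp_classify_fate(i_wnt, i_notch, params_for_engine(params)))
}

#' Fate truth table as a data frame
#'
#' Enumerates the fate rule over the Wnt bands (above `TP_wnt`, between the
#' thresholds, below `TD_wnt`) and Notch branches, as a delimited-text-ready
#' table.
#'
#' @param params A [model_params()].
#' @return Data frame with columns `wnt_band`, `notch_band`, `state`.
#' @export
fate_truth_table <- function(params = model_params()) {
  wnt_mid <- (params$tp_wnt + params$td_wnt) / 2
  grid <- expand.grid(
    wnt_band = c("high", "intermediate", "low"),
    notch_band = c("high", "low"), stringsAsFactors = FALSE)
  iw <- c(high = params$tp_wnt + 1, intermediate = wnt_mid,
          low = params$td_wnt - 1)[grid$wnt_band]
  in_ <- c(high = max(params$tp_notch, params$td_notch),
           low = 0)[grid$notch_band]
  grid$state <- vapply(seq_len(nrow(grid)), function(i)
    classify_fate(iw[i], in_[i], params = params), character(1))
  grid
}

#' Contact inhibition of growth
#'
#' A cell stops volume growth while it is compressed below the threshold
#' volume `V_p`: inhibited iff `V_a < V_p_ratio * V0` (default) or, with
#' `vp_reference = "Vt"`, iff `V_a < V_p_ratio * V_t`.
#'
#' @param V_a Actual volume (um^3).
#' @param V_t Target volume (um^3).
#' @param params A [model_params()].
#' @return Logical.
#' @export
contact_inhibited <- function(V_a, V_t, params = model_params()) {
  ref <- if (params$vp_reference == "V0") params$V0 else V_t
  V_a < params$V_p_ratio * ref
}

#' Divide a cell of a state
#'
#' Splits a division-ready cell (target volume at twice the minimal volume)
#' into two daughters of equal target volume `V0`, placed symmetrically
#' about the mother centre along a random direction in the local BM tangent
#' plane with centre separation equal to the daughter radius. Clone and BrdU
#' labels are inherited by both daughters.
#'
#' @param state A `sim_state`.
#' @param index Row index of the mother cell in `state$cells`.
#' @return The state with the mother replaced by two daughters.
#' @export
divide_cell <- function(state, index) {
  stopifnot(inherits(state, "sim_state"))
  cells <- state$cells
  m <- cells[index, ]
  if (m$target_volume < 2 * state$params$V0 - 1e-9)
    stop("cell is not division-ready (target volume below 2 V0)")
  u <- cpp_division_direction(c(m$x, m$y, m$z),
                              params_for_engine(state$params))
  R0 <- state$params$R0
  off <- 0.5 * R0
  next_id <- max(cells$id) + 1L
  d1 <- m; d2 <- m
  d1$x <- m$x + off * u[1]; d1$y <- m$y + off * u[2]; d1$z <- m$z + off * u[3]
  d2$x <- m$x - off * u[1]; d2$y <- m$y - off * u[2]; d2$z <- m$z - off * u[3]
  d1$id <- next_id; d2$id <- next_id + 1L
  d1$radius <- d2$radius <- R0
  d1$target_volume <- d2$target_volume <- state$params$V0
  d1$actual_volume <- d2$actual_volume <- state$params$V0
  d1$growth_steps <- d2$growth_steps <- 0L
  d1$growth_clock <- d2$growth_clock <- 0
  d1$next_wait <- d2$next_wait <- -1
  d1$birth_time <- d2$birth_time <- state$time
  state$cells <- rbind(cells[-index, ], d1, d2)
  rownames(state$cells) <- NULL
  state
}

#' Doubling times of unconstrained cells
#'
#' Simulates `n` isolated, uncompressed, Notch-saturated undifferentiated
#' cells through the engine's stochastic growth process (exponential waiting
#' times between `n_growth_steps` volume increments) and returns the time
#' each initial cell takes to complete its first division. Their
#' distribution is Gamma(`n_growth_steps`, `tau / n_growth_steps`), with
#' mean `tau`.
#'
#' @param n Number of cells.
#' @param params A [model_params()].
#' @param seed Integer seed.
#' @param horizon Simulated time cap (h).
#' @return Numeric vector of doubling times (h), one per initial cell that
#'   divided within the horizon.
#' @export
growth_doubling_times <- function(n, params = model_params(), seed = 1L,
                                  horizon = 40) {
  set.seed(seed)
  params$notch_mode <- "up"  # keep cells undifferentiated without neighbours
  params$dt_max <- min(params$dt_max, 0.01)  # resolve the waiting times finely
  cells <- new_cells_df(n)
  cells$id <- seq_len(n) - 1L
  cells$x <- stats::runif(n, -1, 1) * 1e4
  cells$y <- stats::runif(n, -1, 1) * 1e4
  cells$z <- rep(-params$shape$z0 + 1, n)
  cells$radius <- params$R0
  cells$target_volume <- params$V0
  cells$actual_volume <- params$V0
  cells$state <- "UNDIFFERENTIATED"
  cells$next_wait <- -1
  cells$paneth_since <- -1
  st <- new_sim_state(cells, NULL, params)
  res <- simulate_crypt(st, horizon, obs_dt = horizon, migration = FALSE,
                        interactions = FALSE)
  ev <- res$events
  div <- ev[ev$type == "division" & ev$id < n, ]
  div$time[order(div$id)]
}
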