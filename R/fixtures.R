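#' Test fixtures
#'
#' Small deterministic states used in tests and examples:
#' `two_cell` and `five_cell` are membrane-free mechanics fixtures
#' (overlapping elastic spheres, no BM network); `mini_crypt` is a fully
#' initialised reduced crypt (z0 = 75 um, r0 = 30 um, lambda_max = 2.5 um)
#' that keeps simulation runs fast.
#'
#' @param kind One of `"two_cell"`, `"five_cell"`, `"mini_crypt"`.
#' @param seed Integer seed.
#' @param ... Passed to [model_params()] (mini crypt only).
#' @return A `sim_state`.
#' @export
make_fixture <- function(kind = c("two_cell", "five_cell", "mini_crypt"),
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "mini_crypt") {
    # reduced crypt: migration forces scaled with the length so the transit
    # time relative to the cell cycle matches the full-size crypt, and the
    # fate thresholds placed to keep a viable (~18-cell) stem/Paneth niche
    # rather than exactly scaling the reference geometry
    args <- list(shape = crypt_shape(z0 = 75, r0 = 30), lambda_max = 2.5,
                 z_p = -50, z_d = -35,
                 F_A_paneth = 7.5 / 2, F_A_other = 4.5 / 2)
    extra <- list(...)
    args[names(extra)] <- extra
    params <- do.call(model_params, args)
    return(initialize_crypt(params, seed = seed))
  }
  params <- model_params()
  n <- if (kind == "two_cell") 2L else 5L
  pos <- switch(kind,
    two_cell = rbind(c(0, 0, -100), c(9, 0, -100)),
    five_cell = rbind(c(0, 0, -100), c(9, 0, -100), c(4.5, 8, -100),
                      c(4.5, 2.5, -92.5), c(-4, 6, -98)))
  cells <- new_cells_df(n)
  cells$id <- seq_len(n) - 1L
  cells$x <- pos[, 1]; cells$y <- pos[, 2]; cells$z <- pos[, 3]
  cells$radius <- params$R0 * stats::runif(n, 1, 1.2)
  cells$target_volume <- 4 / 3 * pi * cells$radius^3
  cells$actual_volume <- cells$target_volume
  cells$state <- "ENTEROCYTE_PROGENITOR"
  cells$next_wait <- -1
  cells$paneth_since <- -1
  cells$clone <- cells$id
  new_sim_state(cells, NULL, params)
}
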