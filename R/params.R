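#' Lineage states of the crypt model
#'
#' The seven lineage states of the model. `UNDIFFERENTIATED`, `PANETH_PRIMED`,
#' `ENTEROCYTE_PROGENITOR` and `GOBLET_PROGENITOR` are reversible
#' (any transition among them is permitted); `PANETH`, `ENTEROCYTE` and
#' `GOBLET` are terminal and never left again.
#'
#' @format A character vector of state names, in the internal coding order.
#' @export
LINEAGE_STATES <- c(
  "UNDIFFERENTIATED", "PANETH_PRIMED", "PANETH",
  "ENTEROCYTE_PROGENITOR", "GOBLET_PROGENITOR",
  "ENTEROCYTE", "GOBLET"
)

#' @rdname LINEAGE_STATES
#' @export
TERMINAL_STATES <- c("PANETH", "ENTEROCYTE", "GOBLET")

#' @rdname LINEAGE_STATES
#' @export
PROLIFERATIVE_STATES <- c("UNDIFFERENTIATED", "ENTEROCYTE_PROGENITOR")

# internal 0-based codes used by the compiled engine
state_code <- function(state) {
  i <- match(state, LINEAGE_STATES)
  if (anyNA(i)) stop("unknown lineage state: ",
                     paste(state[is.na(i)], collapse = ", "))
  i - 1L
}

state_name <- function(code) LINEAGE_STATES[code + 1L]

#' Crypt shape parameters
#'
#' Parameters of the parametric crypt surface of revolution. The crypt axis is
#' z, the crypt-villus junction sits at z = 0 and the crypt base at z = -z0;
#' all lengths are in micrometres.
#'
#' @param z0 Crypt length (um).
#' @param r0 Crypt radius at the crypt-villus junction, z = 0 (um).
#' @param lambda1 Dimensionless shape parameter; controls the radius of the
#'   rounded bottom cap (`lambda1 * r0`). `lambda1 = 0` gives the simple
#'   (conical-capped) shape family used in shape sweeps.
#' @param lambda2 Dimensionless shape parameter; controls the length scale of
#'   the flare towards the junction.
#' @return An object of class `crypt_shape`.
#' @export
crypt_shape <- function(z0 = 150, r0 = 60, lambda1 = 0.25, lambda2 = 0.1) {
  stopifnot(z0 > 0, r0 > 0, lambda1 >= 0, lambda1 < 1, lambda2 > 0)
  structure(list(z0 = z0, r0 = r0, lambda1 = lambda1, lambda2 = lambda2),
            class = "crypt_shape")
}

#' @export
print.crypt_shape <- function(x, ...) {
  cat(sprintf("crypt shape: z0 = %g um, r0 = %g um, lambda1 = %g, lambda2 = %g\n",
              x$z0, x$r0, x$lambda1, x$lambda2))
  invisible(x)
}

#' Full model parameter set
#'
#' Builds the complete parameter set of the crypt model. All defaults are the
#' reference values of the fitted model. Units: lengths um, time h, forces nN,
#' energies nN*um (= 1e-15 N*m), moduli nN/um^2 (= kPa).
#'
#' @param shape A [crypt_shape()].
#' @param E Young modulus of a cell (kPa).
#' @param nu Poisson ratio (dimensionless, < 0.5).
#' @param eps_c Adhesion energy per unit contact area (nN/um, = mN/m * 1e-3;
#'   the default 0.2 nN/um equals 200 uN/m).
#' @param K Bulk modulus (kPa). Defaults to the isotropic relation
#'   E / (3 (1 - 2 nu)).
#' @param eta_c Cell-cell friction constant per unit contact area
#'   (nN*h/um^3; the default corresponds to 5e10 N*s/m^3).
#' @param eta_bm Cell-BM friction coefficient (nN*h/um; default = 3.2 N*s/m).
#' @param eta_vo Volume-change friction coefficient (nN*h/um; 400 N*s/m).
#' @param F_A_paneth Migration force magnitude of Paneth(-primed) cells,
#'   directed down the crypt axis (nN).
#' @param F_A_other Migration force magnitude of all other cells, directed up
#'   the crypt axis (nN).
#' @param R0 Radius of an isolated minimal cell (um); the minimal volume V0 is
#'   (4/3) pi R0^3.
#' @param tau Mean unconstrained volume-doubling (growth) time (h).
#' @param n_growth_steps Number of stochastic growth increments per doubling;
#'   doubling times are Gamma(n_growth_steps, tau / n_growth_steps).
#' @param V_p_ratio Contact-inhibition threshold ratio: growth is suppressed
#'   while the actual volume falls below `V_p_ratio * V0` (with
#'   `vp_reference = "V0"`, the default) or `V_p_ratio * V_t`
#'   (`vp_reference = "Vt"`).
#' @param vp_reference Volume the contact-inhibition threshold refers to:
#'   the minimal volume `"V0"` or the current target volume `"Vt"`.
#' @param lambda_max Basal-membrane mesh size (um): target knot spacing and
#'   upper bound on the triangle inradius.
#' @param omega Threshold ratio of the cell-knot potential: the energy minimum
#'   sits at distance `omega * R` from a knot.
#' @param eps_knot_paneth,eps_knot_other Maximum cell-knot interaction energy
#'   for Paneth(-primed) cells and all other cells (nN*um; defaults equal
#'   35e-12 and 5.5e-12 N*m).
#' @param z_p Axial position of the Wnt priming threshold TP_Wnt (um).
#' @param z_d Axial position of the Wnt differentiation threshold TD_Wnt (um).
#' @param lp_paneth,lp_goblet Notch-activation weight presented by
#'   Paneth(-primed) and Goblet(-progenitor) cells.
#' @param tp_notch,td_notch Notch thresholds for priming and differentiation.
#'   A single threshold value of 1 is used for both by default.
#' @param t_paneth Life span of a terminal Paneth cell (h; default 57 days).
#' @param brdu_label_fraction Probability that a proliferating cell is labelled
#'   in the virtual BrdU pulse.
#' @param t_section Thickness of a virtual section (um).
#' @param dt_max Maximum integration time step (h).
#' @param wnt_mode,notch_mode Signalling perturbation switches:
#'   `"normal"`, `"up"` (constitutive activation) or `"down"` (block).
#' @return An object of class `model_params`: a named list with all model
#'   parameters plus derived quantities (`V0`, `tp_wnt`, `td_wnt`,
#'   `wnt_scale`, `z_flat`).
#' @export
model_params <- function(shape = crypt_shape(),
                         E = 1, nu = 1 / 3, eps_c = 0.2, K = NULL,
                         eta_c = 0.0138889, eta_bm = 0.888889,
                         eta_vo = 111.1111,
                         F_A_paneth = 7.5, F_A_other = 4.5,
                         R0 = 5, tau = 14, n_growth_steps = 50,
                         V_p_ratio = 0.88, vp_reference = c("V0", "Vt"),
                         lambda_max = 1.25, omega = 0.95,
                         eps_knot_paneth = 35000, eps_knot_other = 5500,
                         z_p = -125, z_d = -87.5,
                         lp_paneth = 0.35, lp_goblet = 1.0,
                         tp_notch = 1, td_notch = 1,
                         t_paneth = 57 * 24,
                         brdu_label_fraction = 0.7, t_section = 4.5,
                         dt_max = 0.05,
                         wnt_mode = "normal", notch_mode = "normal") {
  stopifnot(inherits(shape, "crypt_shape"),
            E > 0, nu > 0, nu < 0.5, eps_c > 0,
            eta_c > 0, eta_bm > 0, eta_vo > 0,
            F_A_paneth >= 0, F_A_other >= 0,
            R0 > 0, tau > 0, n_growth_steps >= 1,
            V_p_ratio > 0, V_p_ratio < 1,
            lambda_max > 0, omega > 0, omega < 1,
            eps_knot_paneth > 0, eps_knot_other > 0,
            z_p < z_d, z_d <= 0, -shape$z0 < z_p,
            lp_paneth > 0, lp_goblet >= lp_paneth,
            tp_notch > 0, td_notch > 0, t_paneth > 0,
            brdu_label_fraction >= 0, brdu_label_fraction <= 1,
            t_section > 0, dt_max > 0)
  vp_reference <- match.arg(vp_reference)
  wnt_mode <- match.arg(wnt_mode, c("normal", "up", "down"))
  notch_mode <- match.arg(notch_mode, c("normal", "up", "down"))
  if (is.null(K)) K <- E / (3 * (1 - 2 * nu))
  p <- list(shape = shape, E = E, nu = nu, eps_c = eps_c, K = K,
            eta_c = eta_c, eta_bm = eta_bm, eta_vo = eta_vo,
            F_A_paneth = F_A_paneth, F_A_other = F_A_other,
            R0 = R0, V0 = 4 / 3 * pi * R0^3,
            tau = tau, n_growth_steps = as.integer(n_growth_steps),
            V_p_ratio = V_p_ratio, vp_reference = vp_reference,
            lambda_max = lambda_max, omega = omega,
            eps_knot_paneth = eps_knot_paneth,
            eps_knot_other = eps_knot_other,
            z_p = z_p, z_d = z_d,
            lp_paneth = lp_paneth, lp_goblet = lp_goblet,
            tp_notch = tp_notch, td_notch = td_notch,
            t_paneth = t_paneth,
            brdu_label_fraction = brdu_label_fraction,
            t_section = t_section, dt_max = dt_max,
            wnt_mode = wnt_mode, notch_mode = notch_mode)
  # derived Wnt-link quantities: normalisation scale and monotone clamp point
  p$wnt_scale <- wnt_link_scale(shape)
  p$z_flat <- wnt_link_flat_point(shape)
  p$tp_wnt <- wnt_activity(z_p, shape)
  p$td_wnt <- wnt_activity(z_d, shape)
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("crypt model parameters\n")
  print(x$shape)
  cat(sprintf("  mechanics: E = %g kPa, nu = %g, eps_c = %g nN/um, K = %g kPa\n",
              x$E, x$nu, x$eps_c, x$K))
  cat(sprintf("  friction:  eta_c = %g, eta_bm = %g, eta_vo = %g (nN*h/um units)\n",
              x$eta_c, x$eta_bm, x$eta_vo))
  cat(sprintf("  migration: F_A_paneth = %g nN (down), F_A_other = %g nN (up)\n",
              x$F_A_paneth, x$F_A_other))
  cat(sprintf("  growth:    tau = %g h in %d steps, V_p = %g Vt, R0 = %g um\n",
              x$tau, x$n_growth_steps, x$V_p_ratio, x$R0))
  cat(sprintf("  BM:        lambda_max = %g um, omega = %g, eps_knot = %g/%g nN*um\n",
              x$lambda_max, x$omega, x$eps_knot_paneth, x$eps_knot_other))
  cat(sprintf("  fate:      z_p = %g, z_d = %g um; LP = %g/%g; T_notch = %g/%g; t_P = %g h\n",
              x$z_p, x$z_d, x$lp_paneth, x$lp_goblet, x$tp_notch, x$td_notch,
              x$t_paneth))
  if (x$wnt_mode != "normal" || x$notch_mode != "normal")
    cat(sprintf("  perturbed: wnt_mode = %s, notch_mode = %s\n",
                x$wnt_mode, x$notch_mode))
  invisible(x)
}

# flat list of numeric parameters handed to the compiled engine
params_for_engine <- function(p) {
  list(z0 = p$shape$z0, r0 = p$shape$r0,
       lambda1 = p$shape$lambda1, lambda2 = p$shape$lambda2,
       E = p$E, nu = p$nu, eps_c = p$eps_c, K = p$K,
       eta_c = p$eta_c, eta_bm = p$eta_bm, eta_vo = p$eta_vo,
       F_A_paneth = p$F_A_paneth, F_A_other = p$F_A_other,
       R0 = p$R0, V0 = p$V0, tau = p$tau,
       n_growth_steps = p$n_growth_steps, V_p_ratio = p$V_p_ratio,
       vp_abs = as.integer(p$vp_reference == "V0"),
       omega = p$omega,
       eps_knot_paneth = p$eps_knot_paneth,
       eps_knot_other = p$eps_knot_other,
       z_p = p$z_p, z_d = p$z_d,
       lp_paneth = p$lp_paneth, lp_goblet = p$lp_goblet,
       tp_notch = p$tp_notch, td_notch = p$td_notch,
       t_paneth = p$t_paneth, dt_max = p$dt_max,
       wnt_scale = p$wnt_scale, z_flat = p$z_flat,
       tp_wnt = p$tp_wnt, td_wnt = p$td_wnt,
       wnt_mode = match(p$wnt_mode, c("normal", "up", "down")) - 1L,
       notch_mode = match(p$notch_mode, c("normal", "up", "down")) - 1L)
}
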