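#' Cell-cell contact area
#'
#' Area of the flattened contact facet between two adhering elastic spheres:
#' the disc in which the spheres of radii `R_i`, `R_j` at centre distance `d`
#' intersect. Zero at and beyond tangency, symmetric in the two cells.
#'
#' @param R_i,R_j Cell radii (um).
#' @param d Centre-centre distance (um), > 0.
#' @return Contact area (um^2).
#' @export
contact_area <- function(R_i, R_j, d) {
  stopifnot(R_i > 0, R_j > 0)
  if (any(d <= 0)) stop("degenerate contact: d must be positive")
  cpp_contact_area(rep_len(as.numeric(R_i), length(d)),
                   rep_len(as.numeric(R_j), length(d)), as.numeric(d))
}

#' Adhesion energy of a contact
#'
#' Adhesive interaction energy `W = -eps_c * A`: proportional to the contact
#' area, negative so that adhesion lowers the total energy.
#'
#' @param area Contact area (um^2).
#' @param eps_c Adhesion energy per unit contact area (nN/um).
#' @return Energy (nN*um = 1e-15 N*m).
#' @export
adhesion_energy <- function(area, eps_c) {
  stopifnot(area >= 0, eps_c > 0)
  -eps_c * area
}

#' Hertz deformation energy of a contact
#'
#' Energy of the elastic deformation of two isotropic homogeneous spheres in
#' contact, `W = (8/15) E* sqrt(R*) delta^(5/2)` with overlap
#' `delta = R_i + R_j - d`, effective modulus
#' `1/E* = (1 - nu^2)/E + (1 - nu^2)/E` and reduced radius
#' `1/R* = 1/R_i + 1/R_j`. Zero without overlap.
#'
#' @inheritParams contact_area
#' @param E Young modulus (kPa = nN/um^2).
#' @param nu Poisson ratio.
#' @return Energy (nN*um).
#' @export
hertz_energy <- function(R_i, R_j, d, E = 1, nu = 1 / 3) {
  cpp_hertz_energy(rep_len(as.numeric(R_i), length(d)),
                   rep_len(as.numeric(R_j), length(d)), as.numeric(d), E, nu)
}

#' @rdname hertz_energy
#' @return `hertz_force`: the repulsive force `-dW/dd` (nN) along the
#'   centre-centre axis.
#' @export
hertz_force <- function(R_i, R_j, d, E = 1, nu = 1 / 3) {
  cpp_hertz_force(rep_len(as.numeric(R_i), length(d)),
                  rep_len(as.numeric(R_j), length(d)), as.numeric(d), E, nu)
}

#' Volume compression energy
#'
#' Energy of uniform compression or inflation of a cell against its target
#' volume, `W = K/2 (V_t - V_a)^2 / V_t`; symmetric in the sign of the volume
#' change and zero at `V_a = V_t`.
#'
#' @param V_t Target volume (um^3): the volume an isolated cell would adopt.
#' @param V_a Actual volume (um^3).
#' @param K Bulk modulus (kPa).
#' @return Energy (nN*um).
#' @export
compression_energy <- function(V_t, V_a, K = 1) {
  stopifnot(V_t > 0)
  if (any(V_a <= 0)) stop("actual volume must be positive")
  cpp_compression_energy(rep_len(as.numeric(V_t), length(V_a)),
                         as.numeric(V_a), K)
}

#' Cell-knot interaction
#'
#' Interaction of a cell with a single knot of the basal-membrane network.
#' Cells interact with knots closer than their radius `R`; the energy is a
#' smooth well of depth `eps_knot` at the threshold distance `omega * R`,
#' weakly adhesive above it, strongly repulsive below it and zero (with zero
#' force) at the interaction boundary `d = R`.
#'
#' @param cell_radius Cell radius R (um).
#' @param distance Cell-knot distance (um), >= 0. Distances >= R return zero
#'   interaction.
#' @param eps_knot Maximum interaction energy per knot (nN*um).
#' @param omega Threshold ratio in (0, 1).
#' @return A two-column matrix `energy` (nN*um) and `force` (nN, the radial
#'   force `-dW/dd`; positive = repulsive, negative = adhesive).
#' @export
cell_knot_interaction <- function(cell_radius, distance, eps_knot,
                                  omega = 0.95) {
  stopifnot(cell_radius > 0, eps_knot > 0, omega > 0, omega < 1,
            all(distance >= 0))
  cpp_knot_interaction(rep_len(as.numeric(cell_radius), length(distance)),
                       as.numeric(distance), eps_knot, omega)
}

#' Actual cell volume under overlaps
#'
#' Volume of a cell of radius `R`: the sphere volume minus the spherical-cap
#' volumes cut off by the contact planes with each neighbour and, optionally,
#' by the local tangent plane of the basal membrane.
#'
#' @param R Cell radius (um).
#' @param neighbours Optional data frame or list with elements `radius` and
#'   `distance` for each neighbour in contact.
#' @param bm_dist Distance from the cell centre to the basal membrane
#'   (um), or `NA` for a cell without BM contact.
#' @return Volume (um^3), never negative.
#' @export
actual_volume <- function(R, neighbours = NULL, bm_dist = NA_real_) {
  stopifnot(R > 0)
  if (is.null(neighbours)) {
    nr <- numeric(0); nd <- numeric(0)
  } else {
    nr <- as.numeric(neighbours$radius)
    nd <- as.numeric(neighbours$distance)
    stopifnot(length(nr) == length(nd), all(nd > 0))
  }
  cpp_actual_volume(R, nr, nd, if (is.na(bm_dist)) Inf else bm_dist)
}

#' Net generalized forces on all cells
#'
#' Total generalized forces of a configuration: the negative gradients of the
#' cell-cell adhesion, Hertz deformation, compression and cell-knot energies
#' with respect to the cell positions and radii, plus the active migration
#' forces. Newton's third law holds pairwise for the position forces.
#'
#' @param state A `sim_state` (see [initialize_crypt()], [make_fixture()]).
#' @param migration Include the active migration forces?
#' @return A list: `force` (n x 3 matrix, nN), `force_radius` (nN),
#'   `actual_volume` (um^3), `n_knots` (interacting-knot counts) and
#'   `dist_bm` (distance to the BM surface, um).
#' @export
net_generalized_forces <- function(state, migration = TRUE) {
  stopifnot(inherits(state, "sim_state"))
  cpp_net_forces(cells_to_engine(state$cells),
                 state_knots(state), params_for_engine(state$params),
                 migration)
}

#' Migration force of a cell
#'
#' Active migration force: Paneth and Paneth-primed cells are pulled down the
#' crypt along the local meridian tangent with magnitude `F_A_paneth`; primed
#' and terminally differentiated cells of the other lineages are pushed up
#' with magnitude `F_A_other`; undifferentiated cells move only passively.
#' Cells without basal membrane contact experience no migration force.
#'
#' @param position Length-3 cell centre (um).
#' @param lineage_state A value of [LINEAGE_STATES].
#' @param params A [model_params()].
#' @param attached Does the cell touch the BM (>= 1 interacting knot)?
#' @return Length-3 force vector (nN).
#' @export
migration_force <- function(position, lineage_state, params = model_params(),
                            attached = TRUE) {
  stopifnot(length(position) == 3)
  code <- state_code(lineage_state)
  if (!attached) return(c(0, 0, 0))
  np <- nearest_surface_point(matrix(position, 1), params$shape)
  rp <- cpp_crypt_radius_derivs(np$zeta, unclass(params$shape))[1, "rp"]
  rho <- sqrt(position[1]^2 + position[2]^2)
  cphi <- if (rho > 1e-9) position[1] / rho else 1
  sphi <- if (rho > 1e-9) position[2] / rho else 0
  q <- sqrt(1 + rp^2)
  tv <- if (!is.finite(rp) || rp > 1e6) c(cphi, sphi, 0)
        else c(cphi * rp / q, sphi * rp / q, 1 / q)
  if (code == 0L) return(c(0, 0, 0))  # undifferentiated: passive only
  f <- if (code %in% c(1L, 2L)) -params$F_A_paneth else params$F_A_other
  f * tv
}
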