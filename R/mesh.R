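#' Triangulated basal-membrane network
#'
#' Builds the triangulated fibre network representing the basal membrane on
#' the crypt surface. Knots are laid out in rings along the meridian arc
#' length with spacing `lambda_max` (rows of near-equilateral triangles, row
#' spacing `sqrt(3)/2 * lambda_max`, per-ring knot count proportional to the
#' local circumference), consecutive rings are stitched by a zig-zag walk and
#' the bottom cap is closed by a fan around the pole knot. The construction is
#' deterministic; the maximum triangle inradius is bounded by
#' `lambda_max / (2 sqrt(3))` times a shape factor and always kept below
#' `lambda_max` itself, narrow enough that no cell can cross the network.
#'
#' @param shape A [crypt_shape()].
#' @param lambda_max Mesh size (um): target knot spacing and upper bound on
#'   the triangle inradius.
#' @param seed Ignored (the construction is deterministic); accepted so that
#'   callers can treat mesh generation like the other seeded generators.
#' @return An object of class `bm_network`: list with `knots` (n x 3 matrix,
#'   um), `triangles` (m x 3 integer matrix, 1-based), `lambda_max`,
#'   `knot_z`, `knot_normal` (outward unit normals) and `shape`.
#' @export
triangulate_crypt <- function(shape = crypt_shape(), lambda_max = 1.25,
                              seed = NULL) {
  stopifnot(inherits(shape, "crypt_shape"), lambda_max > 0)
  z0 <- shape$z0
  # cumulative meridian arc length from the pole on a grid graded toward it
  u <- seq(0, 1, length.out = 4000L)
  zg <- -z0 + u^2 * z0
  rg <- cpp_crypt_radius(zg, unclass(shape))
  arc <- c(0, cumsum(sqrt(diff(zg)^2 + diff(rg)^2)))
  Ltot <- arc[length(arc)]
  v <- lambda_max * sqrt(3) / 2
  nrow_ <- round(Ltot / v)
  if (nrow_ < 3)
    stop("refinement failure: lambda_max too large for this crypt shape")
  ell <- seq_len(nrow_) * (Ltot / nrow_)
  zr <- stats::approx(arc, zg, xout = ell, rule = 2)$y
  zr[length(zr)] <- 0
  rr <- cpp_crypt_radius(zr, unclass(shape))

  m <- pmax(3L, as.integer(round(2 * pi * rr / lambda_max)))
  off <- (seq_along(m) %% 2) * pi / m

  # knots: pole first, then the rings
  nk <- 1L + sum(m)
  knots <- matrix(0, nk, 3)
  knot_z <- numeric(nk)
  knots[1, ] <- c(0, 0, -z0)
  knot_z[1] <- -z0
  start <- integer(length(m))  # first knot index of each ring
  at <- 2L
  for (k in seq_along(m)) {
    start[k] <- at
    phi <- off[k] + 2 * pi * (seq_len(m[k]) - 1) / m[k]
    idx <- at:(at + m[k] - 1L)
    knots[idx, 1] <- rr[k] * cos(phi)
    knots[idx, 2] <- rr[k] * sin(phi)
    knots[idx, 3] <- zr[k]
    knot_z[idx] <- zr[k]
    at <- at + m[k]
  }

  tris <- vector("list", length(m))
  # bottom fan
  i1 <- start[1] + seq_len(m[1]) - 1L
  tris[[1]] <- cbind(1L, i1, i1[c(2:m[1], 1L)])
  # stitch consecutive rings by merging the two angular sequences
  for (k in seq_len(length(m) - 1L)) {
    m1 <- m[k]; m2 <- m[k + 1L]
    a1 <- off[k] + 2 * pi * (seq_len(m1) - 1) / m1
    a2 <- off[k + 1L] + 2 * pi * (seq_len(m2) - 1) / m2
    t_local <- matrix(0L, m1 + m2, 3)
    i <- 0L; j <- 0L; nt <- 0L
    while (i < m1 || j < m2) {
      # advance on the ring whose next boundary angle is smaller
      nxt1 <- if (i < m1) a1[i + 1L] + (if (i + 1L > m1) 2 * pi else 0) else Inf
      nxt2 <- if (j < m2) a2[j + 1L] + (if (j + 1L > m2) 2 * pi else 0) else Inf
      c1 <- start[k] + (i %% m1)
      c2 <- start[k + 1L] + (j %% m2)
      nt <- nt + 1L
      if (nxt1 <= nxt2) {
        n1 <- start[k] + ((i + 1L) %% m1)
        t_local[nt, ] <- c(c1, n1, c2)
        i <- i + 1L
      } else {
        n2 <- start[k + 1L] + ((j + 1L) %% m2)
        t_local[nt, ] <- c(c1, n2, c2)
        j <- j + 1L
      }
    }
    tris[[k + 1L]] <- t_local[seq_len(nt), , drop = FALSE]
  }
  triangles <- do.call(rbind, tris)
  storage.mode(triangles) <- "integer"

  # outward unit normals from the analytic profile
  dv <- cpp_crypt_radius_derivs(knot_z, unclass(shape))
  rp <- dv[, "rp"]
  q <- sqrt(1 + rp^2)
  rho <- sqrt(knots[, 1]^2 + knots[, 2]^2)
  cphi <- ifelse(rho > 1e-9, knots[, 1] / rho, 1)
  sphi <- ifelse(rho > 1e-9, knots[, 2] / rho, 0)
  nrm <- cbind(cphi / q, sphi / q, -rp / q)
  pole <- !is.finite(rp) | rp > 1e6
  nrm[pole, ] <- rep(c(0, 0, -1), each = sum(pole))

  structure(list(knots = knots, triangles = triangles,
                 lambda_max = lambda_max, knot_z = knot_z,
                 knot_normal = nrm, shape = shape),
            class = "bm_network")
}

#' @export
print.bm_network <- function(x, ...) {
  cat(sprintf("basal-membrane network: %d knots, %d triangles, lambda_max = %g um\n",
              nrow(x$knots), nrow(x$triangles), x$lambda_max))
  invisible(x)
}

#' Triangle inradii of a BM network
#'
#' @param network A `bm_network`.
#' @return Numeric vector of triangle inradii (area / semi-perimeter), um.
#' @export
mesh_inradii <- function(network) {
  K <- network$knots; T_ <- network$triangles
  A <- K[T_[, 1], , drop = FALSE]
  B <- K[T_[, 2], , drop = FALSE]
  C <- K[T_[, 3], , drop = FALSE]
  ab <- B - A; ac <- C - A; bc <- C - B
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  s <- 0.5 * (sqrt(rowSums(ab^2)) + sqrt(rowSums(ac^2)) + sqrt(rowSums(bc^2)))
  area / s
}

#' Knot coordination numbers
#'
#' Number of distinct mesh neighbours of every knot.
#'
#' @param network A `bm_network`.
#' @return Integer vector, one entry per knot.
#' @export
mesh_coordination <- function(network) {
  T_ <- network$triangles
  e <- rbind(T_[, c(1, 2)], T_[, c(2, 3)], T_[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  tabulate(c(e[, 1], e[, 2]), nbins = nrow(network$knots))
}

#' Knots interacting with a cell
#'
#' Indices of the BM knots within the interaction range of a cell, i.e. at a
#' distance smaller than the cell radius, found through a uniform spatial
#' grid. The per-knot interaction energy is scaled by the size of this set so
#' that the total cell-BM interaction is insensitive to the mesh density.
#'
#' @param centre Cell centre, length-3 numeric (um).
#' @param radius Cell radius (um).
#' @param network A `bm_network`.
#' @return Sorted integer vector of knot indices (possibly empty).
#' @export
interacting_knots <- function(centre, radius, network) {
  stopifnot(length(centre) == 3, radius > 0)
  cpp_knots_in_range(network$knots, as.numeric(centre), radius)
}

#' Export a BM network as OFF
#'
#' @param network A `bm_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_off <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(network$knots), nrow(network$triangles)),
             con)
  utils::write.table(format(network$knots, digits = 9, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  tri0 <- cbind(3L, network$triangles - 1L)
  utils::write.table(tri0, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a BM network as ASCII PLY with per-knot scalar fields
#'
#' Writes the mesh with the axial coordinate and the analytic Gaussian
#' curvature as vertex attributes.
#'
#' @param network A `bm_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ply <- function(network, path) {
  K <- network$knots
  gauss <- cpp_surface_curvatures(network$knot_z,
                                  unclass(network$shape))[, "gaussian"]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(K)),
               "property float x", "property float y", "property float z",
               "property float axial_z", "property float gauss_curvature",
               sprintf("element face %d", nrow(network$triangles)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vt <- cbind(K, network$knot_z, gauss)
  utils::write.table(format(vt, digits = 9, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  tri0 <- cbind(3L, network$triangles - 1L)
  utils::write.table(tri0, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# count ray-triangle crossings (Moller-Trumbore, vectorised over triangles);
# used to verify that the network is watertight for cell-sized probes
ray_crossings <- function(network, origin, dir) {
  K <- network$knots; T_ <- network$triangles
  A <- K[T_[, 1], , drop = FALSE]
  e1 <- K[T_[, 2], , drop = FALSE] - A
  e2 <- K[T_[, 3], , drop = FALSE] - A
  d <- dir / sqrt(sum(dir^2))
  pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
              d[3] * e2[, 1] - d[1] * e2[, 3],
              d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  tv <- matrix(origin, nrow(A), 3, byrow = TRUE) - A  # origin - A
  u <- rowSums(tv * pv) / det
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  vv <- rowSums(matrix(rep(d, each = nrow(A)), ncol = 3) * qv) / det
  tt <- rowSums(e2 * qv) / det
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & tt > 1e-9
  sum(hit)
}
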