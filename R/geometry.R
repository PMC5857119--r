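# Local coordinate frames anchored on residue geometry centers.
#
# Every residue gets a right-handed orthonormal frame: origin at the
# unweighted mean of its heavy atoms, x toward the backbone nitrogen,
# y the Gram-Schmidt-orthogonalized direction toward the carboxyl carbon,
# z their cross product. Ion positions expressed in this frame are
# invariant under rigid motion of the residue.

# tolerance below which the orthogonalized y direction is treated as
# degenerate (N and C directions collinear)
FRAME_DEGENERACY_TOL <- 1e-6

#' Geometry center of a set of atoms
#'
#' The unweighted mean position of the heavy atoms, used as the origin of
#' the residue local frame and as the anchor of the pairing cutoff.
#'
#' @param atoms A data frame with numeric columns `x`, `y`, `z` (one row
#'   per heavy atom), or a numeric matrix with three columns.
#' @return A numeric 3-vector.
#' @export
#' @examples
#' geometry_center(data.frame(x = c(0, 2), y = 0, z = 0))
geometry_center <- function(atoms) {
  m <- atom_xyz(atoms)
  if (nrow(m) == 0L) abort("geometry_center(): no atoms supplied")
  colMeans(m)
}

atom_xyz <- function(atoms) {
  if (is.matrix(atoms)) {
    stopifnot(ncol(atoms) == 3L)
    return(atoms)
  }
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

#' Build the local coordinate frame of a residue
#'
#' @param residue A data frame of the residue's heavy atoms with columns
#'   `elety` (PDB atom name), `x`, `y`, `z`. Must contain the backbone
#'   nitrogen `N` and carboxyl carbon `C`.
#' @return An object of class `local_frame`: a list with `origin` (3-vector)
#'   and `axes` (3x3 matrix whose columns are the x, y, z unit vectors).
#' @details Errors with class `frame_undefined` when `N` or `C` is missing
#'   or coincides with the geometry center, and `frame_degenerate` when the
#'   N and C directions are collinear (orthogonalized y shorter than 1e-6).
#' @export
build_frame <- function(residue) {
  origin <- geometry_center(residue)
  n_row <- which(residue$elety == "N")
  c_row <- which(residue$elety == "C")
  if (length(n_row) != 1L || length(c_row) != 1L) {
    abort("build_frame(): residue lacks a unique backbone N or C atom",
          class = "frame_undefined")
  }
  vx <- c(residue$x[n_row], residue$y[n_row], residue$z[n_row]) - origin
  nx <- sqrt(sum(vx^2))
  if (nx < FRAME_DEGENERACY_TOL) {
    abort("build_frame(): backbone N coincides with the geometry center",
          class = "frame_undefined")
  }
  x_hat <- vx / nx
  yp <- c(residue$x[c_row], residue$y[c_row], residue$z[c_row]) - origin
  y <- yp - sum(x_hat * yp) * x_hat
  ny <- sqrt(sum(y^2))
  if (ny < FRAME_DEGENERACY_TOL) {
    abort("build_frame(): N and C directions are collinear",
          class = "frame_degenerate")
  }
  y_hat <- y / ny
  z_hat <- c(x_hat[2] * y_hat[3] - x_hat[3] * y_hat[2],
             x_hat[3] * y_hat[1] - x_hat[1] * y_hat[3],
             x_hat[1] * y_hat[2] - x_hat[2] * y_hat[1])
  structure(list(origin = unname(origin),
                 axes = unname(cbind(x_hat, y_hat, z_hat))),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat("<local_frame> origin:", sprintf("%.3f", x$origin), "\n")
  print(round(x$axes, 4))
  invisible(x)
}

#' Map points into a residue local frame
#'
#' Projects one or more points onto a frame's axes and converts to polar
#' coordinates and octant indices.
#'
#' @param frame A `local_frame` from [build_frame()].
#' @param points A numeric 3-vector or an n x 3 matrix of positions in the
#'   structure coordinate system.
#' @return A tibble with one row per point: local Cartesian `x`, `y`, `z`,
#'   polar `r`, `theta` (inclination, 0..pi), `phi` (azimuth, two-argument
#'   arctangent convention, -pi..pi], and `octant` (0-7).
#' @details At zero radius the angles are set to 0 by convention. `phi` uses
#'   `atan2`, not the quadrant-ambiguous single-argument arctangent, so the
#'   octant assignment always agrees with the Cartesian signs.
#' @export
to_local <- function(frame, points) {
  stopifnot(inherits(frame, "local_frame"))
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  loc <- sweep(p, 2L, frame$origin) %*% frame$axes
  r <- sqrt(rowSums(loc^2))
  theta <- ifelse(r > 0, acos(pmin(pmax(loc[, 3] / ifelse(r > 0, r, 1), -1), 1)), 0)
  phi <- ifelse(r > 0, atan2(loc[, 2], loc[, 1]), 0)
  tibble(x = loc[, 1], y = loc[, 2], z = loc[, 3],
         r = r, theta = theta, phi = phi,
         octant = octant_index(loc))
}

#' Octant of a local Cartesian position
#'
#' The sphere around a residue is split into eight sectors by the signs of
#' the local Cartesian coordinates; index = 4*(x<0) + 2*(y<0) + (z<0), with
#' zero counting as non-negative.
#'
#' @param cart A numeric 3-vector or an n x 3 matrix.
#' @return Integer vector of octant indices in 0..7.
#' @export
#' @examples
#' octant_index(c(1, 1, 1))   # 0
#' octant_index(c(-1, 1, -1)) # 5
octant_index <- function(cart) {
  m <- if (is.matrix(cart)) cart else matrix(cart, ncol = 3L)
  as.integer(4L * (m[, 1] < 0) + 2L * (m[, 2] < 0) + (m[, 3] < 0))
}

#' Place a point at given polar coordinates in a local frame
#'
#' The inverse of [to_local()]: converts (r, theta, phi) to local Cartesian
#' coordinates and maps them back into the structure coordinate system.
#' Used by the fixture generator to plant ions at known frame positions.
#'
#' @param frame A `local_frame`.
#' @param r,theta,phi Polar coordinates (Angstroms / radians); vectors are
#'   recycled to a common length.
#' @return An n x 3 matrix of structure-coordinate positions.
#' @export
place_ion <- function(frame, r, theta, phi) {
  stopifnot(inherits(frame, "local_frame"), all(r >= 0))
  n <- max(length(r), length(theta), length(phi))
  r <- rep_len(r, n); theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  cart <- cbind(r * sin(theta) * cos(phi),
                r * sin(theta) * sin(phi),
                r * cos(theta))
  sweep(cart %*% t(frame$axes), 2L, frame$origin, `+`)
}

#' Random proper rotation matrices
#'
#' Uniform (Haar) random rotations via quaternions, drawing from the
#' session RNG; set a seed beforehand for reproducibility.
#'
#' @param n Number of rotations.
#' @return A list of n 3x3 rotation matrices with determinant +1.
#' @export
random_rotation <- function(n = 1L) {
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3L, byrow = TRUE)
  })
}
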