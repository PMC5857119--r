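# Clustering amino acids by the 3-D density of ions around them.
# Similarity between two amino acids = the maximum Pearson correlation
# between their binned local-frame densities over a discrete rotation
# grid; distances (1 - similarity) feed complete-linkage hierarchical
# clustering.

#' Binned 3-D ion density around an amino acid
#'
#' Pools the local-frame Cartesian positions of all pairs involving `aa`
#' (optionally restricted to some ion types) into a cubic histogram over
#' the ball of radius `cutoff`, normalized to unit sum.
#'
#' @param stats An `ion_stats` with pair records.
#' @param aa Three-letter code.
#' @param bins Number of bins per axis (even, so bin centers are symmetric
#'   about the origin and the 24 cube rotations permute them exactly).
#' @param ions Optional subset of ion labels to pool; default all.
#' @return An object of class `density_map`: `aa`, `values` (array of
#'   dimension `bins^3`, sums to 1 when any pair fell inside), `n` (points
#'   binned), `bins`, `cutoff`, and `empty` flag.
#' @export
density_map <- function(stats, aa, bins = 12L, ions = NULL) {
  stopifnot(inherits(stats, "ion_stats"), bins %% 2L == 0L)
  p <- stats$pairs
  p <- p[p$aa == aa, , drop = FALSE]
  if (!is.null(ions)) p <- p[p$ion %in% ions, , drop = FALSE]
  new_density_map(as.matrix(p[, c("x", "y", "z")]), aa = aa, bins = bins,
                  cutoff = stats$cutoff)
}

# bin a point matrix into a normalized cubic histogram
new_density_map <- function(xyz, aa = NA_character_, bins = 12L,
                            cutoff = 6.0) {
  arr <- array(0, dim = rep(bins, 3L))
  n_in <- 0L
  if (nrow(xyz) > 0) {
    w <- 2 * cutoff / bins
    idx <- floor(sweep(xyz, 2L, -cutoff) / w) + 1L
    ok <- rowSums(idx >= 1L & idx <= bins) == 3L
    idx <- idx[ok, , drop = FALSE]
    n_in <- nrow(idx)
    if (n_in > 0) {
      flat <- (idx[, 3] - 1L) * bins^2 + (idx[, 2] - 1L) * bins + idx[, 1]
      tab <- tabulate(flat, nbins = bins^3)
      arr <- array(tab / sum(tab), dim = rep(bins, 3L))
    }
  }
  structure(list(aa = aa, values = arr, n = n_in, bins = bins,
                 cutoff = cutoff, empty = n_in == 0L),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s: %d points in %d^3 bins (cutoff %.1f A)%s\n",
              x$aa, x$n, x$bins, x$cutoff, if (x$empty) " [empty]" else ""))
  invisible(x)
}

# centers of the cubic bins, as a bins^3 x 3 matrix (column-major order
# matching the flattened density array)
map_bin_centers <- function(bins, cutoff) {
  w <- 2 * cutoff / bins
  ax <- -cutoff + w * (seq_len(bins) - 0.5)
  as.matrix(expand.grid(x = ax, y = ax, z = ax))
}

#' Discrete rotation grids
#'
#' `rotation_grid()` enumerates proper rotations from a z-y-z Euler-angle
#' lattice at the given step and removes duplicates; `cube_rotations()`
#' returns the 24-element rotation group of the cube, whose elements
#' permute the bins of a symmetric cubic histogram exactly.
#'
#' @param step_deg Euler-angle step in degrees (divisor of 90 recommended
#'   so the cube group is included).
#' @return A list of 3x3 rotation matrices.
#' @export
rotation_grid <- function(step_deg = 15) {
  s <- step_deg * pi / 180
  alphas <- seq(0, 2 * pi - s / 2, by = s)
  betas <- seq(0, pi, by = s)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3L, byrow = TRUE)
  ry <- function(b) matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)),
                           3L, byrow = TRUE)
  grid <- expand.grid(a = alphas, b = betas, g = alphas)
  rots <- lapply(seq_len(nrow(grid)), function(i)
    rz(grid$a[i]) %*% ry(grid$b[i]) %*% rz(grid$g[i]))
  keys <- vapply(rots, function(m) paste(round(m, 9), collapse = ","),
                 character(1))
  rots[!duplicated(keys)]
}

#' @rdname rotation_grid
#' @export
cube_rotations <- function() {
  rots <- list()
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) for (s1 in c(1, -1)) for (s2 in c(1, -1))
    for (s3 in c(1, -1)) {
      m <- matrix(0, 3L, 3L)
      m[1, p[1]] <- s1; m[2, p[2]] <- s2; m[3, p[3]] <- s3
      if (abs(det(m) - 1) < 1e-12) rots[[length(rots) + 1L]] <- m
    }
  rots
}

#' Rotation-maximized correlation between two density maps
#'
#' The maximum, over a discrete rotation set, of the Pearson correlation
#' between map `a` and map `b` resampled under the rotation (each bin's
#' mass moved to the bin containing its rotated center; mass rotated
#' outside the cube is dropped). For rotations in the cube group the
#' resampling is an exact bin permutation.
#'
#' @param a,b `density_map` objects with identical bin geometry.
#' @param rotations A list of 3x3 rotation matrices; default
#'   [rotation_grid()] at 15 degree steps.
#' @return The maximum correlation, in \[-1, 1\]. A constant (or empty) map
#'   has no variance; the correlation is then defined as 0, with a warning.
#' @export
rotation_correlation <- function(a, b, rotations = rotation_grid(15)) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (a$bins != b$bins || abs(a$cutoff - b$cutoff) > 1e-12)
    abort("rotation_correlation(): maps have different bin geometry")
  va <- as.numeric(a$values)
  vb <- as.numeric(b$values)
  if (sd(va) == 0 || sd(vb) == 0) {
    warn("rotation_correlation(): constant map, correlation defined as 0")
    return(0)
  }
  bins <- a$bins
  w <- 2 * a$cutoff / bins
  centers <- map_bin_centers(bins, a$cutoff)
  best <- -1
  for (R in rotations) {
    rc <- centers %*% t(R)
    idx <- floor(sweep(rc, 2L, -a$cutoff) / w) + 1L
    ok <- rowSums(idx >= 1L & idx <= bins) == 3L
    out <- numeric(bins^3)
    flat <- (idx[ok, 3] - 1L) * bins^2 + (idx[ok, 2] - 1L) * bins + idx[ok, 1]
    mass <- rowsum(vb[ok], flat)
    out[as.integer(rownames(mass))] <- mass
    if (sd(out) > 0) best <- max(best, cor(va, out))
  }
  best
}

#' Similarity matrix between amino-acid ion distributions
#'
#' Pairwise rotation-maximized correlations between the pooled ion density
#' maps of the amino acids, with unit diagonal. Amino acids with no pairs
#' (empty maps) get similarity 0 to everything.
#'
#' @param stats An `ion_stats` with pair records.
#' @param aas Amino acids to include; default all 20.
#' @param bins Bins per axis of the density maps.
#' @param ions Optional ion subset pooled into the maps.
#' @param rotations Rotation set (see [rotation_correlation()]).
#' @return A symmetric matrix with `aas` as dimnames.
#' @export
similarity_matrix <- function(stats, aas = AA3, bins = 12L, ions = NULL,
                              rotations = rotation_grid(15)) {
  maps <- lapply(aas, density_map, stats = stats, bins = bins, ions = ions)
  n <- length(aas)
  sim <- diag(1, n)
  dimnames(sim) <- list(aas, aas)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    v <- if (maps[[i]]$empty || maps[[j]]$empty) 0
         else suppressWarnings(rotation_correlation(maps[[i]], maps[[j]],
                                                    rotations = rotations))
    sim[i, j] <- v
    sim[j, i] <- v
  }
  sim
}

#' Cluster amino acids from a similarity matrix
#'
#' Converts similarities to distances (1 - similarity) and applies
#' complete-linkage hierarchical clustering: the distance between two
#' clusters is the maximum pairwise distance between their members, so
#' merge heights are non-decreasing.
#'
#' @param sim Symmetric similarity matrix with unit diagonal and dimnames.
#' @return An `hclust` object (19 merges for 20 amino acids).
#' @export
cluster_amino_acids <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim) ||
      max(abs(sim - t(sim))) > 1e-8)
    abort("cluster_amino_acids(): similarity matrix must be symmetric")
  if (max(abs(diag(sim) - 1)) > 1e-8)
    abort("cluster_amino_acids(): diagonal must be 1")
  d <- as.dist(1 - sim)
  hclust(d, method = "complete")
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` from [cluster_amino_acids()].
#' @param path Optional output path.
#' @return The Newick string, invisibly when written to `path`.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
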