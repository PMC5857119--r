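# 'Ion-amino acid' pair extraction at the geometry-center cutoff, and the
# side-chain preference ratio R.

#' Extract ion-amino acid pairs from a structure
#'
#' An ion and a residue form a pair when the ion lies within `cutoff` of
#' the residue's geometry center. Each pair carries the ion's position in
#' the residue local frame (Cartesian, polar, octant). Ions pair with
#' residues of any chain.
#'
#' @param struct An `ion_structure` from [read_structure()] or
#'   [make_structure()].
#' @param cutoff Pairing distance in Angstroms (default 6, chosen so that
#'   only directly interacting ions are captured).
#' @return A tibble with one row per pair: `source_id`, `aa`, `chain`,
#'   `resno`, `ion`, `ion_chain`, `ion_resno`, local `x`, `y`, `z`, `r`,
#'   `theta`, `phi`, `octant`. `r` equals the geometry-center distance.
#'   Residues whose frame cannot be built (missing backbone N/C, collinear
#'   geometry) are skipped with a warning, never silently.
#' @export
find_pairs <- function(struct, cutoff = 6.0) {
  stopifnot(inherits(struct, "ion_structure"), cutoff > 0)
  empty <- tibble(source_id = character(), aa = character(),
                  chain = character(), resno = integer(),
                  ion = character(), ion_chain = character(),
                  ion_resno = integer(),
                  x = numeric(), y = numeric(), z = numeric(),
                  r = numeric(), theta = numeric(), phi = numeric(),
                  octant = integer())
  if (nrow(struct$ions) == 0L || nrow(struct$atoms) == 0L) return(empty)

  res_list <- structure_residues(struct)
  gc <- t(vapply(res_list, geometry_center, numeric(3)))
  ion_xyz <- as.matrix(struct$ions[, c("x", "y", "z")])
  # squared distance matrix residues x ions
  d2 <- outer(rowSums(gc^2), rowSums(ion_xyz^2), `+`) -
    2 * gc %*% t(ion_xyz)
  within <- d2 <= cutoff^2 + 1e-12
  hit_res <- which(rowSums(within) > 0)

  out <- vector("list", length(hit_res))
  skipped <- character()
  for (k in seq_along(hit_res)) {
    i <- hit_res[k]
    res <- res_list[[i]]
    frame <- tryCatch(build_frame(res), error = function(e) e)
    if (inherits(frame, "error")) {
      skipped <- c(skipped, paste0(res$chain[1], "/", res$resno[1], " ",
                                   res$aa[1]))
      next
    }
    js <- which(within[i, ])
    loc <- to_local(frame, ion_xyz[js, , drop = FALSE])
    out[[k]] <- tibble(source_id = struct$source_id, aa = res$aa[1],
                       chain = res$chain[1], resno = res$resno[1],
                       ion = struct$ions$ion[js],
                       ion_chain = struct$ions$chain[js],
                       ion_resno = struct$ions$resno[js],
                       x = loc$x, y = loc$y, z = loc$z, r = loc$r,
                       theta = loc$theta, phi = loc$phi,
                       octant = loc$octant)
  }
  if (length(skipped) > 0) {
    warn(paste0("find_pairs(): skipped ", length(skipped),
                " residue(s) with no buildable frame: ",
                paste(head(skipped, 5), collapse = "; ")))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) empty else res
}

#' Side-chain preference of the ions around one residue
#'
#' Splits the residue into backbone (N, CA, C, O, OXT) and side-chain atom
#' groups, and counts ions within the shrunken radius
#' `r_a = cutoff - max(r_c, r_s)` of each group's center, where `r_c` and
#' `r_s` are the distances from the backbone and side-chain centers to the
#' residue geometry center. The preference ratio is
#' `R = N_s / (N_s + N_c)`; an ion within `r_a` of both centers counts in
#' both groups. Undefined for glycine (no heavy side-chain atom).
#'
#' @param residue Tibble of one residue's heavy atoms (columns `elety`,
#'   `x`, `y`, `z`, plus `aa` if available).
#' @param ions Ion positions: a tibble with `x`, `y`, `z` or an n x 3
#'   matrix, in structure coordinates.
#' @param cutoff Pairing cutoff in Angstroms.
#' @return One-row tibble: `aa`, `r_c`, `r_s`, `r_a`, `n_backbone`,
#'   `n_sidechain`, `R`. For glycine all split fields are `NA`; with zero
#'   ions in range `R` is `NA` but the counts are 0.
#' @export
side_chain_preference <- function(residue, ions, cutoff = 6.0) {
  aa <- if (!is.null(residue$aa)) residue$aa[1] else NA_character_
  bb <- residue[residue$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  sc <- residue[!residue$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  if (nrow(sc) == 0L) {
    return(tibble(aa = aa, r_c = NA_real_, r_s = NA_real_, r_a = NA_real_,
                  n_backbone = NA_integer_, n_sidechain = NA_integer_,
                  R = NA_real_))
  }
  g <- geometry_center(residue)
  cb <- geometry_center(bb)
  cs <- geometry_center(sc)
  r_c <- sqrt(sum((cb - g)^2))
  r_s <- sqrt(sum((cs - g)^2))
  r_a <- cutoff - max(r_c, r_s)
  m <- atom_xyz(ions)
  if (nrow(m) > 0) {
    d_b <- sqrt(rowSums(sweep(m, 2L, cb)^2))
    d_s <- sqrt(rowSums(sweep(m, 2L, cs)^2))
    n_c <- sum(d_b <= r_a)
    n_s <- sum(d_s <= r_a)
  } else {
    n_c <- 0L; n_s <- 0L
  }
  tibble(aa = aa, r_c = r_c, r_s = r_s, r_a = r_a,
         n_backbone = as.integer(n_c), n_sidechain = as.integer(n_s),
         R = if (n_c + n_s > 0) n_s / (n_s + n_c) else NA_real_)
}

#' Side-chain preference summary over structures
#'
#' Applies [side_chain_preference()] to every residue of every structure
#' and aggregates per amino-acid type: the pooled percentage of in-range
#' ions that sit within `r_a` of the side-chain center.
#'
#' @param structs An `ion_structure` or a list of them.
#' @param cutoff Pairing cutoff in Angstroms.
#' @return Tibble with `aa`, `n_backbone`, `n_sidechain`, and
#'   `pct_sidechain` (= 100 * sum N_s / sum(N_s + N_c)); glycine appears
#'   with `NA`.
#' @export
side_chain_summary <- function(structs, cutoff = 6.0) {
  if (inherits(structs, "ion_structure")) structs <- list(structs)
  per_res <- bind_rows(lapply(structs, function(s) {
    if (nrow(s$ions) == 0L) return(NULL)
    bind_rows(lapply(structure_residues(s), side_chain_preference,
                     ions = s$ions, cutoff = cutoff))
  }))
  base <- tibble(aa = AA3)
  if (nrow(per_res) == 0L) {
    return(mutate(base, n_backbone = 0L, n_sidechain = 0L,
                  pct_sidechain = NA_real_))
  }
  agg <- summarise(group_by(per_res, .data$aa),
                   n_backbone = sum(.data$n_backbone, na.rm = TRUE),
                   n_sidechain = sum(.data$n_sidechain, na.rm = TRUE),
                   .groups = "drop")
  out <- left_join(base, agg, by = "aa")
  out$n_backbone[is.na(out$n_backbone)] <- 0L
  out$n_sidechain[is.na(out$n_sidechain)] <- 0L
  out$n_backbone[out$aa == "GLY"] <- NA_integer_
  out$n_sidechain[out$aa == "GLY"] <- NA_integer_
  mutate(out, pct_sidechain = ifelse(
    !is.na(.data$n_backbone) & (.data$n_backbone + .data$n_sidechain) > 0,
    100 * .data$n_sidechain / (.data$n_backbone + .data$n_sidechain),
    NA_real_))
}
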