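# Synthetic PDB fixtures with known ground truth: idealized residues
# placed under arbitrary rigid transforms and ions planted at chosen
# (r, theta, phi) positions in a residue's local frame. The frame depends
# only on the geometry center and the backbone N and C atoms, so template
# side chains need internally consistent geometry, not real rotamers.

SIDECHAIN_ATOMS <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.template_cache <- new.env(parent = emptyenv())

#' Idealized heavy-atom template for an amino acid
#'
#' One fixed template per amino acid: a standard backbone (N, CA, C, O)
#' plus the residue's heavy side-chain atoms laid out along a deterministic
#' helical path from CB, giving uniform ~1.5 A steps between consecutive
#' atoms. Side-chain placement is geometric, not chemical: the local frame
#' and the pair statistics only depend on atom identities and the geometry
#' center, N, and C.
#'
#' @param aa Three-letter amino-acid code.
#' @return Tibble with columns `elety`, `element`, `x`, `y`, `z`.
#' @export
aa_residue_template <- function(aa) {
  aa <- toupper(aa)
  if (!aa %in% AA3) abort(paste0("unknown amino-acid type: ", aa))
  if (!is.null(.template_cache[[aa]])) return(.template_cache[[aa]])
  # backbone: CA at origin, N along +x, C in the xy-plane, O off C
  bb <- rbind(
    N  = c(1.458, 0.000, 0.000),
    CA = c(0.000, 0.000, 0.000),
    C  = c(-0.546, 1.424, 0.000),
    O  = c(-1.770, 1.580, 0.120)
  )
  sc_names <- SIDECHAIN_ATOMS[[aa]]
  coords <- bb
  if (length(sc_names) > 0) {
    # helical growth from CB: axis away from the backbone, 1.2 A rise and
    # 0.9 A radius per step -> consecutive atoms ~1.5 A apart, no overlaps
    u <- c(-0.35, -0.55, -0.76); u <- u / sqrt(sum(u^2))
    v <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u; v <- v / sqrt(sum(v^2))
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    sc <- t(vapply(seq_along(sc_names) - 1L, function(k) {
      1.53 * u + k * 1.2 * u + 0.9 * (k > 0) * (cos(2.2 * k) * v +
                                                sin(2.2 * k) * w)
    }, numeric(3)))
    rownames(sc) <- sc_names
    coords <- rbind(bb, sc)
  }
  out <- tibble(elety = rownames(coords),
                element = substr(rownames(coords), 1L, 1L),
                x = unname(coords[, 1]), y = unname(coords[, 2]),
                z = unname(coords[, 3]))
  .template_cache[[aa]] <- out
  out
}

#' Construct a residue from its template under a rigid transform
#'
#' @param aa Three-letter code.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Numeric 3-vector.
#' @param chain,resno Identity carried into the atom table.
#' @return Tibble of heavy atoms with columns `chain`, `resno`, `insert`,
#'   `aa`, `elety`, `element`, `x`, `y`, `z`, `occupancy`.
#' @export
make_residue <- function(aa, rotation = diag(3), translation = c(0, 0, 0),
                         chain = "A", resno = 1L) {
  stopifnot(abs(det(rotation) - 1) < 1e-8)
  tpl <- aa_residue_template(aa)
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, `+`)
  tibble(chain = chain, resno = as.integer(resno), insert = "",
         aa = toupper(aa), elety = tpl$elety, element = tpl$element,
         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1)
}

#' Assemble an in-memory structure from residues and ions
#'
#' Builds an `ion_structure` directly (no PDB round trip), for fast
#' simulation; [make_pdb_fixture()] serializes the same content to PDB.
#'
#' @param residues A list of residue atom tibbles from [make_residue()].
#' @param ions A tibble with columns `ion` (canonical label) and `x`, `y`,
#'   `z` (structure coordinates); may be `NULL`.
#' @param source_id Structure identifier.
#' @return An `ion_structure`.
#' @export
make_structure <- function(residues, ions = NULL, source_id = "SYN1") {
  atoms <- bind_rows(residues)
  if (is.null(ions) || nrow(ions) == 0L) {
    ions <- tibble(ion = character(), element = character(),
                   chain = character(), resno = integer(),
                   x = numeric(), y = numeric(), z = numeric())
  } else {
    code <- ion_label_to_code(ions$ion)
    ions <- tibble(ion = ions$ion, element = ion_code_element(code),
                   chain = ions[["chain"]] %||% rep("A", nrow(ions)),
                   resno = ions[["resno"]] %||% (1000L + seq_len(nrow(ions))),
                   x = ions$x, y = ions$y, z = ions$z)
  }
  structure(list(source_id = source_id, atoms = atoms, ions = ions,
                 log = tibble(event = character(), detail = character())),
            class = "ion_structure")
}

#' Generate a PDB fixture with planted residues and ions
#'
#' Serializes a fixture specification to PDB text: residues built from
#' templates under the given rigid transforms, and ions placed either at
#' absolute coordinates or at (r, theta, phi) in the local frame of an
#' anchor residue. Output is deterministic given the specification.
#'
#' @param spec A list with elements
#'   \describe{
#'     \item{residues}{tibble with columns `aa` and optionally `chain`,
#'       `resno`, plus either a `rotation` list-column of 3x3 matrices
#'       and/or `tx`, `ty`, `tz` translation columns}
#'     \item{ions}{tibble with column `ion` plus either `x`, `y`, `z`
#'       (absolute) or `anchor` (row index into `residues`), `r`, `theta`,
#'       `phi` (local polar placement)}
#'     \item{source_id}{optional identifier}
#'   }
#' @param path Optional output path for the PDB text.
#' @return List with `text` (PDB lines), `structure` (the in-memory
#'   `ion_structure`), and `planted` (tibble of the planted local
#'   coordinates, when anchored placement was used).
#' @details Atom pairs closer than 0.5 A trigger a warning but are still
#'   written.
#' @export
make_pdb_fixture <- function(spec, path = NULL) {
  rs <- as_tibble(spec$residues)
  n_res <- nrow(rs)
  if (is.null(rs[["chain"]])) rs$chain <- "A"
  if (is.null(rs[["resno"]])) rs$resno <- seq_len(n_res)
  residues <- lapply(seq_len(n_res), function(i) {
    rot <- if (!is.null(rs[["rotation"]])) rs[["rotation"]][[i]] else diag(3)
    tr <- if (!is.null(rs[["tx"]])) c(rs$tx[i], rs$ty[i], rs$tz[i]) else c(0, 0, 0)
    make_residue(rs$aa[i], rot, tr, chain = rs$chain[i], resno = rs$resno[i])
  })
  frames <- lapply(residues, build_frame)

  planted <- NULL
  ions <- NULL
  if (!is.null(spec$ions) && nrow(spec$ions) > 0) {
    is_ <- as_tibble(spec$ions)
    if (!is.null(is_[["anchor"]])) {
      pos <- t(vapply(seq_len(nrow(is_)), function(j) {
        place_ion(frames[[is_$anchor[j]]], is_$r[j], is_$theta[j],
                  is_$phi[j])[1, ]
      }, numeric(3)))
      planted <- tibble(ion = is_$ion, anchor = is_$anchor,
                        r = is_$r, theta = is_$theta, phi = is_$phi,
                        octant = octant_index(
                          cbind(is_$r * sin(is_$theta) * cos(is_$phi),
                                is_$r * sin(is_$theta) * sin(is_$phi),
                                is_$r * cos(is_$theta))))
      ions <- tibble(ion = is_$ion, x = pos[, 1], y = pos[, 2], z = pos[, 3])
    } else {
      ions <- tibble(ion = is_$ion, x = is_$x, y = is_$y, z = is_$z)
    }
  }
  struct <- make_structure(residues, ions,
                           source_id = spec$source_id %||% "SYN1")

  all_xyz <- rbind(as.matrix(struct$atoms[, c("x", "y", "z")]),
                   as.matrix(struct$ions[, c("x", "y", "z")]))
  if (nrow(all_xyz) > 1L) {
    d <- as.matrix(stats::dist(all_xyz))
    diag(d) <- Inf
    if (min(d) < 0.5)
      warn(sprintf("fixture contains atoms %.2f A apart (< 0.5 A)", min(d)))
  }

  text <- serialize_structure_pdb(struct)
  if (!is.null(path)) writeLines(text, path)
  list(text = text, structure = struct, planted = planted)
}

# write an ion_structure as PDB lines via bio3d
serialize_structure_pdb <- function(struct) {
  a <- struct$atoms
  i <- struct$ions
  n <- nrow(a) + nrow(i)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  ion_code <- if (nrow(i)) ion_label_to_code(i$ion) else character()
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(rbind(as.matrix(a[, c("x", "y", "z")]),
                                            as.matrix(i[, c("x", "y", "z")])))),
                   type = c(rep("ATOM", nrow(a)), rep("HETATM", nrow(i))),
                   resno = c(a$resno, i$resno),
                   resid = c(a$aa, ion_code),
                   eleno = seq_len(n),
                   elety = c(a$elety, ion_code),
                   chain = c(a$chain, i$chain),
                   o = rep(1, n),
                   b = rep(0, n),
                   elesy = c(a$element, i$element),
                   end = TRUE, verbose = FALSE)
  readLines(tmp)
}
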