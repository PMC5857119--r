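# Reading PDB structures into the package's tabular representation and
# writing the point-cloud export dialect. Record-level parsing is delegated
# to bio3d; residue curation (altLoc resolution, hydrogen removal, ion
# table lookup, water/polyatomic exclusion) happens here.

# Curated monoatomic ion chemical-component codes -> canonical labels.
# FE and FE2 are pooled into one iron label, matching how ferric/ferrous
# sites are usually reported together; Cu(I) and Cu(II) stay distinct.
ION_TABLE <- c(
  LI = "Li+", NA. = "Na+", K = "K+", RB = "Rb+", CS = "Cs+",
  MG = "Mg2+", CA = "Ca2+", SR = "Sr2+", BA = "Ba2+",
  MN = "Mn2+", FE = "Fe2+/3+", FE2 = "Fe2+/3+", CO = "Co2+",
  NI = "Ni2+", CU = "Cu2+", CU1 = "Cu+", ZN = "Zn2+", CD = "Cd2+",
  HG = "Hg2+", F = "F-", CL = "Cl-", BR = "Br-", IOD = "I-"
)

ion_code_table <- function() {
  codes <- names(ION_TABLE)
  codes[codes == "NA."] <- "NA"
  setNames(unname(ION_TABLE), codes)
}

# element symbol of a curated ion component code
ion_code_element <- function(code) {
  el <- gsub("[0-9]", "", code)
  el[el == "IOD"] <- "I"
  el
}

# preferred PDB component code for each ion label (for fixture writing)
ion_label_to_code <- function(label) {
  tab <- ion_code_table()
  code <- names(tab)[match(label, tab)]
  if (anyNA(code)) abort(paste0("unknown ion label(s): ",
                                paste(label[is.na(code)], collapse = ", ")))
  code
}

#' The candidate ion set used for type prediction
#'
#' The eleven monoatomic ions most commonly resolved in protein crystal
#' structures; the default candidate set for [score_ions()] and
#' [evaluate_sites()].
#'
#' @return Character vector of canonical ion labels.
#' @export
default_ion_candidates <- function() {
  c("Br-", "Ca2+", "Cl-", "Cu2+", "Fe2+/3+", "K+", "Mg2+", "Mn2+",
    "Na+", "Ni2+", "Zn2+")
}

#' Read a PDB-format structure
#'
#' Parses a PDB file (or raw PDB text) into an `ion_structure`: a tibble of
#' heavy atoms belonging to the 20 proteinogenic amino acids plus a tibble
#' of curated monoatomic ion sites.
#'
#' @param file Path to a PDB file, or a character vector of PDB record
#'   lines (anything containing a newline or more than one element is
#'   treated as text).
#' @param source_id Structure identifier stored with every atom and ion;
#'   defaults to the file name without extension.
#' @return An object of class `ion_structure` with elements
#'   \describe{
#'     \item{source_id}{identifier string}
#'     \item{atoms}{tibble of residue heavy atoms: `chain`, `resno`,
#'       `insert`, `aa`, `elety`, `element`, `x`, `y`, `z`, `occupancy`}
#'     \item{ions}{tibble of ion sites: `ion`, `element`, `chain`, `resno`,
#'       `x`, `y`, `z`}
#'     \item{log}{tibble of curation events (skipped residues, excluded
#'       hetero species, altLoc resolutions)}
#'   }
#' @details Curation rules: hydrogens and deuteriums are dropped; within
#'   each (residue, atom name) group only the highest-occupancy alternate
#'   location survives (ties broken by altLoc letter); only model 1 of a
#'   multi-model file is read; waters and polyatomic hetero-groups are never
#'   ions; monoatomic hetero species outside the curated ion table are
#'   logged and excluded; residues with non-canonical names (MSE etc.) are
#'   logged and excluded.
#' @export
read_structure <- function(file, source_id = NULL) {
  is_text <- length(file) > 1L || grepl("\n", file[1]) ||
    grepl("^(ATOM|HETATM|MODEL|REMARK|HEADER)", file[1])
  if (is_text) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(file, "\n")), path)
    if (is.null(source_id)) source_id <- "TEXT"
  } else {
    path <- file
    if (is.null(source_id))
      source_id <- toupper(sub("\\.(pdb|ent)$", "", basename(file),
                               ignore.case = TRUE))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- as_tibble(pdb$atom)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    substr(trimws(at$elety[is.na(at$elesy) | at$elesy == ""]), 1L, 1L)
  at$elesy <- toupper(trimws(at$elesy))

  log <- list()
  n_h <- sum(at$elesy %in% c("H", "D"))
  if (n_h > 0) log <- c(log, list(tibble(event = "hydrogens_dropped",
                                         detail = as.character(n_h))))
  at <- at[!at$elesy %in% c("H", "D"), , drop = FALSE]

  # altLoc resolution: keep highest occupancy per (chain, resno, insert,
  # resid, elety); ties by altLoc letter
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    keep <- !duplicated(key[ord])
    n_alt <- sum(!keep)
    at <- at[keep, , drop = FALSE]
    log <- c(log, list(tibble(event = "altloc_resolved",
                              detail = as.character(n_alt))))
  }

  het <- at[at$type == "HETATM", , drop = FALSE]
  res <- at[at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% AA3),
            , drop = FALSE]
  # some depositions mark modified/ligand residues as ATOM; keep canonical only
  bad_aa <- !res$resid %in% AA3
  if (any(bad_aa)) {
    skipped <- unique(res$resid[bad_aa])
    log <- c(log, list(tibble(event = "noncanonical_residue_excluded",
                              detail = skipped)))
    res <- res[!bad_aa, , drop = FALSE]
  }
  het <- het[!het$resid %in% AA3, , drop = FALSE]

  ions <- tibble(ion = character(), element = character(),
                 chain = character(), resno = integer(),
                 x = numeric(), y = numeric(), z = numeric())
  if (nrow(het) > 0) {
    hkey <- paste(het$chain, het$resno, het$insert, het$resid, sep = "\r")
    grp_size <- table(hkey)
    het$n_in_group <- as.integer(grp_size[hkey])
    tab <- ion_code_table()
    is_ion <- het$n_in_group == 1L & het$resid %in% names(tab)
    mono_unknown <- het$n_in_group == 1L & !het$resid %in% names(tab) &
      het$resid != "HOH"
    if (any(mono_unknown)) {
      log <- c(log, list(tibble(event = "unknown_monoatomic_excluded",
                                detail = unique(het$resid[mono_unknown]))))
    }
    if (any(is_ion)) {
      hi <- het[is_ion, , drop = FALSE]
      ions <- tibble(ion = unname(tab[hi$resid]), element = hi$elesy,
                     chain = as.character(hi$chain), resno = hi$resno,
                     x = hi$x, y = hi$y, z = hi$z)
    }
  }

  atoms <- tibble(chain = as.character(res$chain), resno = res$resno,
                  insert = res$insert, aa = res$resid,
                  elety = trimws(res$elety), element = res$elesy,
                  x = res$x, y = res$y, z = res$z, occupancy = res$o)
  structure(list(source_id = source_id, atoms = atoms, ions = ions,
                 log = if (length(log)) bind_rows(log)
                       else tibble(event = character(), detail = character())),
            class = "ion_structure")
}

#' @export
print.ion_structure <- function(x, ...) {
  n_res <- nrow(distinct(x$atoms, .data$chain, .data$resno, .data$insert))
  cat(sprintf("<ion_structure> %s: %d residues (%d heavy atoms), %d ions\n",
              x$source_id, n_res, nrow(x$atoms), nrow(x$ions)))
  if (nrow(x$ions)) {
    tab <- table(x$ions$ion)
    cat("  ions:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# split the atom table into a named list of per-residue tibbles
structure_residues <- function(struct) {
  a <- struct$atoms
  if (nrow(a) == 0L) return(list())
  key <- paste(a$chain, a$resno, a$insert, sep = "_")
  split(a, factor(key, levels = unique(key)))
}

#' Write an ion point cloud in the PDB provenance dialect
#'
#' Exports the local-frame positions of one (amino acid, ion) pair set as a
#' PDB file: one HETATM record per ion with coordinates in the residue
#' local frame, the distance to the residue geometry center in the B-factor
#' column, the source chain in the chain column, and the source structure
#' ID in the atom-name and segment fields. The file parses back through
#' [read_structure()] as a point set.
#'
#' @param pairs A pair tibble from [find_pairs()] (or the `pairs` element
#'   of an `ion_stats` object) restricted to a single `aa`/`ion`
#'   combination.
#' @param path Output path; if `NULL` the PDB text is returned invisibly
#'   without touching disk.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_point_cloud <- function(pairs, path = NULL) {
  if (nrow(pairs) > 0) {
    combos <- distinct(pairs, .data$aa, .data$ion)
    if (nrow(combos) > 1L) {
      abort(paste0("write_point_cloud(): pairs mix combinations: ",
                   paste(paste(combos$aa, combos$ion, sep = "/"),
                         collapse = ", ")))
    }
  }
  hdr <- c(sprintf("REMARK   6 ION POINT CLOUD%s",
                   if (nrow(pairs)) sprintf(" %s AROUND %s",
                                            pairs$ion[1], pairs$aa[1]) else ""),
           sprintf("REMARK   6 N_POINTS %d", nrow(pairs)))
  if (nrow(pairs) == 0L) {
    out <- c(hdr, "END")
  } else {
    code <- ion_label_to_code(pairs$ion[1])
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    bio3d::write.pdb(file = tmp,
                     xyz = as.numeric(t(cbind(pairs$x, pairs$y, pairs$z))),
                     type = rep("HETATM", nrow(pairs)),
                     resno = seq_len(nrow(pairs)),
                     resid = rep(code, nrow(pairs)),
                     eleno = seq_len(nrow(pairs)),
                     elety = substr(pairs$source_id, 1L, 4L),
                     chain = substr(pairs$chain, 1L, 1L),
                     o = rep(1, nrow(pairs)),
                     b = round(pairs$r, 2),
                     segid = substr(pairs$source_id, 1L, 4L),
                     elesy = rep("", nrow(pairs)),
                     print.segid = TRUE, end = TRUE, verbose = FALSE)
    out <- c(hdr, readLines(tmp))
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
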