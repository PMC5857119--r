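# Independent reference implementations used as oracles; deliberately
# naive and separate from the package's code paths.

# brute-force all-pairs (residue, ion) scan on an ion_structure
oracle_pair_scan <- function(struct, cutoff = 6.0) {
  a <- struct$atoms
  keys <- unique(paste(a$chain, a$resno, a$insert, sep = "_"))
  out <- list()
  for (k in keys) {
    sel <- paste(a$chain, a$resno, a$insert, sep = "_") == k
    res <- a[sel, ]
    gc <- c(mean(res$x), mean(res$y), mean(res$z))
    for (j in seq_len(nrow(struct$ions))) {
      d <- sqrt(sum((c(struct$ions$x[j], struct$ions$y[j],
                       struct$ions$z[j]) - gc)^2))
      if (d <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          aa = res$aa[1], chain = res$chain[1], resno = res$resno[1],
          ion = struct$ions$ion[j], ion_resno = struct$ions$resno[j],
          dist = d)
      }
    }
  }
  do.call(rbind, c(out, list(data.frame(aa = character(),
                                        chain = character(),
                                        resno = integer(),
                                        ion = character(),
                                        ion_resno = integer(),
                                        dist = numeric()))))
}

# naive O(n^3) complete-linkage agglomeration; returns sorted merge heights
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# apply a rigid transform to a residue atom tibble
transform_residue <- function(res, rot, trans) {
  xyz <- as.matrix(res[, c("x", "y", "z")]) %*% t(rot)
  res$x <- xyz[, 1] + trans[1]
  res$y <- xyz[, 2] + trans[2]
  res$z <- xyz[, 3] + trans[3]
  res
}

# minimal hand-written PDB text (independent of the package's writer)
pdb_line <- function(type, serial, name, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, element = substr(name, 1, 1),
                     altloc = " ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, altloc, resname, chain, resno, x, y, z,
          occ, b, element)
}

ala_zn_pdb <- function() {
  c(pdb_line("ATOM", 1, "N", "ALA", "A", 1, 1.458, 0, 0),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 3, "C", "ALA", "A", 1, -0.546, 1.424, 0),
    pdb_line("ATOM", 4, "O", "ALA", "A", 1, -1.770, 1.580, 0.120),
    pdb_line("ATOM", 5, "CB", "ALA", "A", 1, -0.532, -0.774, -1.203),
    pdb_line("HETATM", 6, "ZN", "ZN", "A", 101, 2, 2, 2, element = "ZN"),
    "END")
}
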