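planted_pair_structure <- function(aa, ion, r, theta, phi, resno = 1L,
                                   shift = c(0, 0, 0)) {
  res <- make_residue(aa, translation = shift, resno = resno)
  f <- build_frame(res)
  pos <- place_ion(f, r, theta, phi)[1, ]
  make_structure(list(res),
                 dplyr::tibble(ion = ion, x = pos[1], y = pos[2],
                               z = pos[3]))
}

test_that("a single planted pair lands in the right count cells", {
  st <- planted_pair_structure("ALA", "Zn2+", 3, 0.3, 0.2)  # octant 0
  s <- ion_stats(st)
  expect_equal(s$n_pair$n[s$n_pair$aa == "ALA" & s$n_pair$ion == "Zn2+"], 1L)
  oct0 <- s$n_pair_octant[s$n_pair_octant$octant == 0L, ]
  expect_equal(oct0$n, 1L)
  expect_equal(s$n_aa$n[s$n_aa$aa == "ALA"], 1L)
  expect_equal(s$n_ion$n[s$n_ion$ion == "Zn2+"], 1L)
  # n_aa counts unpaired residues too
  far <- make_residue("TRP", translation = c(100, 0, 0), resno = 2L)
  s2 <- ion_stats(make_structure(list(make_residue("ALA"), far),
                                 st$ions))
  expect_equal(s2$n_aa$n[s2$n_aa$aa == "TRP"], 1L)
})

test_that("merging stats equals accumulating the concatenated input", {
  st1 <- planted_pair_structure("ALA", "Zn2+", 3, 0.3, 0.2)
  st2 <- planted_pair_structure("CYS", "Ca2+", 4, 2.0, -1.2)
  st3 <- planted_pair_structure("CYS", "Zn2+", 2, 1.0, 2.8)
  merged <- merge_stats(ion_stats(st1), ion_stats(list(st2, st3)))
  joint <- ion_stats(list(st1, st2, st3))
  for (f in c("n_aa", "n_ion", "n_pair", "n_pair_octant")) {
    m <- dplyr::arrange_all(merged[[f]])
    j <- dplyr::arrange_all(joint[[f]])
    expect_equal(as.data.frame(m), as.data.frame(j), ignore_attr = TRUE)
  }
  expect_equal(merged$n_structures, joint$n_structures)
})

test_that("marginals match an independent tally on seeded random pairs", {
  set.seed(71)
  n <- 200
  aa_pick <- sample(c("ALA", "CYS", "HIS", "ASP"), n, replace = TRUE)
  ion_pick <- sample(c("Zn2+", "Ca2+", "Na+"), n, replace = TRUE)
  structs <- lapply(seq_len(n), function(i)
    planted_pair_structure(aa_pick[i], ion_pick[i],
                           runif(1, 1, 5.5), runif(1, 0, pi),
                           runif(1, -pi, pi)))
  s <- ion_stats(structs)
  want <- table(aa_pick, ion_pick)
  for (aa in rownames(want)) for (io in colnames(want)) {
    got <- s$n_pair$n[s$n_pair$aa == aa & s$n_pair$ion == io]
    expect_equal(if (length(got)) got else 0L, unname(want[aa, io]))
  }
  # octant table sums to the pair table
  oct_sum <- dplyr::summarise(dplyr::group_by(s$n_pair_octant, aa, ion),
                              n = sum(n), .groups = "drop")
  expect_equal(as.data.frame(dplyr::arrange(oct_sum, aa, ion)),
               as.data.frame(dplyr::arrange(s$n_pair, aa, ion)),
               ignore_attr = TRUE)
  expect_equal(sum(s$n_pair$n), n)
})

test_that("histograms tally pairs and sum to the pair count", {
  structs <- lapply(1:4, function(i)
    planted_pair_structure("ALA", "Zn2+", 2.05, 0.4, 0.3, resno = i))
  s <- ion_stats(structs)
  h <- pair_histogram(s, "ALA", "Zn2+", kind = "radial", radial_bin = 0.1)
  expect_equal(h$count[h$r_lo == 2.0], 4L)
  expect_equal(sum(h$count), 4L)
  expect_true(all(h$count[h$r_lo != 2.0] == 0L))

  set.seed(81)
  structs2 <- lapply(1:30, function(i)
    planted_pair_structure("CYS", "Ca2+", runif(1, 1, 5.5),
                           runif(1, 0.01, pi - 0.01), runif(1, -pi, pi),
                           resno = i))
  s2 <- ion_stats(structs2)
  for (kind in c("radial", "angular", "octant")) {
    expect_equal(sum(pair_histogram(s2, "CYS", "Ca2+", kind = kind)$count),
                 30L)
  }
  # absent combination -> all-zero histogram, not an error
  h0 <- pair_histogram(s2, "TRP", "K+", kind = "octant")
  expect_equal(sum(h0$count), 0L)

  # octant histogram of a +/+/+ distribution concentrates in octant 0
  h1 <- pair_histogram(s, "ALA", "Zn2+", kind = "octant")
  expect_equal(h1$count[h1$octant == 0], 4L)
})

test_that("group means reproduce the grouped-table averages", {
  pos <- data.frame(aa = c("ARG", "HIS", "LYS"), n = c(2478, 12547, 3854))
  out <- group_summary(pos)
  expect_equal(out$mean[out$group == "positive"], 6293)

  neg_pct <- data.frame(aa = c("ASP", "GLU"), pct = c(81.7, 92.1))
  expect_equal(group_summary(neg_pct)$mean, 86.9)

  one <- data.frame(aa = "TRP", n = 514)
  expect_equal(group_summary(one)$mean, 514)

  # NA values (glycine in the side-chain summary) drop from their group
  pol <- data.frame(aa = c("ASN", "GLY"), v = c(67.1, NA))
  out_pol <- group_summary(pol)
  expect_equal(out_pol$mean, 67.1)
  expect_equal(out_pol$n, 1L)
})

test_that("stats survive a JSON round trip", {
  st <- planted_pair_structure("HIS", "Zn2+", 3.3, 1.1, 0.4)
  s <- ion_stats(st)
  path <- withr::local_tempfile(fileext = ".json")
  write_stats_json(s, path)
  back <- read_stats_json(path)
  expect_equal(as.data.frame(back$n_pair), as.data.frame(s$n_pair))
  expect_equal(as.data.frame(back$n_pair_octant),
               as.data.frame(s$n_pair_octant))
  expect_equal(back$cutoff, s$cutoff)
  # probabilities from the reloaded object are identical
  p1 <- ion_probabilities(s, ions = default_ion_candidates())
  p2 <- ion_probabilities(back, ions = default_ion_candidates())
  expect_equal(p1$p_pair$p, p2$p_pair$p)
})

test_that("smoothed probabilities normalize and cover every cell", {
  st <- planted_pair_structure("ALA", "Zn2+", 3, 0.3, 0.2)
  probs <- ion_probabilities(ion_stats(st), alpha = 1,
                             ions = default_ion_candidates())
  expect_equal(sum(probs$p_pair$p), 1, tolerance = 1e-12)
  expect_equal(sum(probs$p_octant$p), 1, tolerance = 1e-12)
  expect_equal(sum(probs$p_aa), 1, tolerance = 1e-12)
  expect_equal(sum(probs$p_ion), 1, tolerance = 1e-12)
  expect_true(all(probs$p_pair$p > 0))
  expect_equal(nrow(probs$p_pair), 20 * 11)
  expect_equal(nrow(probs$p_octant), 20 * 11 * 8)
})
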