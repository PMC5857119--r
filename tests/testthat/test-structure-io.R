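test_that("a minimal ALA + Zn file parses into one residue and one ion", {
  st <- read_structure(ala_zn_pdb(), "TST1")
  expect_s3_class(st, "ion_structure")
  expect_equal(nrow(st$atoms), 5L)
  expect_equal(unique(st$atoms$aa), "ALA")
  expect_equal(nrow(st$ions), 1L)
  expect_equal(st$ions$ion, "Zn2+")
  expect_equal(st$ions$x, 2)
})

test_that("waters and polyatomic hetero-groups are never ions", {
  lines <- c(ala_zn_pdb()[1:6],
             pdb_line("HETATM", 7, "O", "HOH", "A", 201, 5, 5, 5),
             pdb_line("HETATM", 8, "O", "HOH", "A", 202, 6, 6, 6),
             pdb_line("HETATM", 9, "O", "HOH", "A", 203, 7, 7, 7),
             # a two-atom hetero group: monoatomic rule must exclude it
             pdb_line("HETATM", 10, "C1", "LIG", "A", 301, 8, 8, 8),
             pdb_line("HETATM", 11, "O1", "LIG", "A", 301, 9, 9, 9),
             "END")
  st <- read_structure(lines, "TST2")
  expect_equal(nrow(st$ions), 1L)
  expect_equal(st$ions$ion, "Zn2+")
})

test_that("hydrogens/deuteriums are dropped and logged", {
  lines <- c(ala_zn_pdb()[1:5],
             pdb_line("ATOM", 6, "HA", "ALA", "A", 1, 0.5, 0.5, 0.5,
                      element = "H"),
             "END")
  st <- read_structure(lines, "TSTH")
  expect_false(any(st$atoms$element %in% c("H", "D")))
  expect_true("hydrogens_dropped" %in% st$log$event)
})

test_that("altLoc resolution keeps the max-occupancy conformer (oracle check)", {
  # CB in three conformers; an independent scan over altLoc groups picks
  # the winner by (occupancy desc, altLoc asc)
  confs <- data.frame(alt = c("A", "B", "C"), occ = c(0.3, 0.5, 0.2),
                      x = c(-0.5, -0.6, -0.7))
  lines <- c(ala_zn_pdb()[1:4],
             vapply(seq_len(3), function(i)
               pdb_line("ATOM", 4 + i, "CB", "ALA", "A", 1,
                        confs$x[i], -0.774, -1.203, occ = confs$occ[i],
                        altloc = confs$alt[i]), character(1)),
             "END")
  ord <- order(-confs$occ, confs$alt)
  expected_x <- confs$x[ord[1]]
  st <- read_structure(lines, "TALT")
  cb <- st$atoms[st$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, expected_x)

  # tie in occupancy -> lexicographically first altLoc
  lines2 <- c(ala_zn_pdb()[1:4],
              pdb_line("ATOM", 5, "CB", "ALA", "A", 1, -0.9, -0.774, -1.203,
                       occ = 0.5, altloc = "B"),
              pdb_line("ATOM", 6, "CB", "ALA", "A", 1, -0.1, -0.774, -1.203,
                       occ = 0.5, altloc = "A"),
              "END")
  st2 <- read_structure(lines2, "TALT2")
  expect_equal(st2$atoms$x[st2$atoms$elety == "CB"], -0.1)
})

test_that("multi-model files contribute model 1 only", {
  lines <- c("MODEL        1", ala_zn_pdb()[1:6], "ENDMDL",
             "MODEL        2",
             pdb_line("ATOM", 1, "N", "ALA", "A", 1, 9, 9, 9),
             pdb_line("HETATM", 2, "ZN", "ZN", "A", 102, 12, 12, 12,
                      element = "ZN"),
             "ENDMDL", "END")
  st <- read_structure(lines, "TMDL")
  expect_equal(nrow(st$ions), 1L)
  expect_equal(st$ions$x, 2)
  expect_equal(nrow(st$atoms), 5L)
})

test_that("non-canonical residues and unknown monoatomic species are excluded and logged", {
  lines <- c(ala_zn_pdb()[1:6],
             pdb_line("HETATM", 7, "SE", "MSE", "B", 2, 4, 4, 4,
                      element = "SE"),
             pdb_line("HETATM", 8, "XE", "XE", "A", 301, 5, 5, 5,
                      element = "XE"),
             "END")
  st <- read_structure(lines, "TEXC")
  expect_equal(unique(st$atoms$aa), "ALA")
  expect_equal(nrow(st$ions), 1L)
  expect_true("unknown_monoatomic_excluded" %in% st$log$event)
})

test_that("iron components FE and FE2 pool into one label", {
  lines <- c(ala_zn_pdb()[1:5],
             pdb_line("HETATM", 6, "FE", "FE", "A", 101, 2, 2, 2,
                      element = "FE"),
             pdb_line("HETATM", 7, "FE", "FE2", "A", 102, 3, 3, 3,
                      element = "FE"),
             "END")
  st <- read_structure(lines, "TFE")
  expect_equal(st$ions$ion, c("Fe2+/3+", "Fe2+/3+"))
})

test_that("point-cloud export writes provenance and round-trips coordinates", {
  # empty pair set -> header-only file
  empty <- find_pairs(read_structure(ala_zn_pdb()[1:5], "TPC0"))
  txt0 <- write_point_cloud(empty)
  expect_false(any(grepl("^HETATM", txt0)))
  expect_true(any(grepl("^REMARK", txt0)))

  # single pair at local (1, 2, 2) -> B-factor 3.00
  st <- read_structure(ala_zn_pdb(), "TPC1")
  p <- find_pairs(st)
  p$x <- 1; p$y <- 2; p$z <- 2; p$r <- 3
  txt1 <- write_point_cloud(p)
  rec <- grep("^HETATM", txt1, value = TRUE)
  expect_match(rec, "3\\.00")

  # 50 generated pairs round-trip through the parser within PDB precision
  set.seed(42)
  n <- 50
  pairs <- dplyr::tibble(
    source_id = "SYNA", aa = "ALA", chain = "A", resno = seq_len(n),
    ion = "Zn2+", ion_chain = "A", ion_resno = 100L + seq_len(n),
    x = runif(n, -5, 5), y = runif(n, -5, 5), z = runif(n, -5, 5))
  pairs$r <- sqrt(pairs$x^2 + pairs$y^2 + pairs$z^2)
  pairs$theta <- acos(pairs$z / pairs$r)
  pairs$phi <- atan2(pairs$y, pairs$x)
  pairs$octant <- octant_index(cbind(pairs$x, pairs$y, pairs$z))
  txt <- write_point_cloud(pairs)
  back <- read_structure(txt, "RT")
  expect_equal(nrow(back$ions), n)
  got <- as.matrix(back$ions[order(back$ions$resno), c("x", "y", "z")])
  expect_equal(unname(got), unname(cbind(pairs$x, pairs$y, pairs$z)),
               tolerance = 2e-3)
})

test_that("mixed (aa, ion) combinations are rejected with the offender named", {
  p1 <- dplyr::tibble(source_id = "S", aa = c("ALA", "CYS"),
                      chain = "A", resno = 1:2, ion = "Zn2+",
                      ion_chain = "A", ion_resno = 101:102,
                      x = 1, y = 1, z = 1, r = sqrt(3),
                      theta = acos(1 / sqrt(3)), phi = pi / 4, octant = 0L)
  expect_error(write_point_cloud(p1), "CYS")
})
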