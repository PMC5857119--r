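test_that("neighbor context equals a brute-force distance scan", {
  res1 <- make_residue("ALA", resno = 1L)
  g1 <- geometry_center(res1)
  ctx <- neighbor_context(make_structure(list(res1)), g1)
  expect_equal(nrow(ctx), 1L)
  expect_equal(ctx$r, 0)

  far <- neighbor_context(make_structure(list(res1)), g1 + c(7, 0, 0))
  expect_equal(nrow(far), 0L)

  set.seed(141)
  residues <- lapply(1:8, function(i)
    make_residue(sample(AA3, 1), rotation = random_rotation(1)[[1]],
                 translation = runif(3, -9, 9), resno = i))
  st <- make_structure(residues)
  q <- runif(3, -4, 4)
  ctx2 <- neighbor_context(st, q)
  gcs <- t(vapply(residues, geometry_center, numeric(3)))
  want <- which(sqrt(rowSums(sweep(gcs, 2, q)^2)) <= 6)
  expect_setequal(ctx2$resno, want)
})

test_that("scores reduce to zero under independence and flat with no context", {
  probs <- new_ion_probs(
    p_pair = dplyr::tibble(aa = rep(c("ALA", "CYS"), each = 2),
                           ion = rep(c("Zn2+", "Ca2+"), 2),
                           p = c(0.2, 0.3, 0.2, 0.3)),
    p_aa = c(ALA = 0.5, CYS = 0.5),
    p_ion = c(`Zn2+` = 0.4, `Ca2+` = 0.6))
  ctx <- dplyr::tibble(aa = "ALA", chain = "A", resno = 1L, x = 1, y = 1,
                       z = 1, r = sqrt(3), theta = acos(1 / sqrt(3)),
                       phi = pi / 4, octant = 0L)
  sc <- score_ions(probs, ctx, mode = "pair")
  # p(ALA, Zn) = p(ALA) p(Zn) -> log-score 0 (score ratio 1)
  expect_equal(sc$log_score[sc$ion == "Zn2+"], 0, tolerance = 1e-12)

  empty_ctx <- ctx[0, ]
  sc0 <- score_ions(probs, empty_ctx)
  expect_true(all(sc0$log_score == 0))

  expect_error(score_ions(probs, ctx, ions = c("Zn2+", "U4+")), "U4\\+")
})

test_that("pair and octant scores equal a direct product oracle", {
  set.seed(151)
  ions <- c("Zn2+", "Ca2+")
  grid <- expand.grid(aa = c("ALA", "CYS", "HIS"), ion = ions,
                      stringsAsFactors = FALSE)
  grid$p <- runif(nrow(grid))
  grid$p <- grid$p / sum(grid$p)
  ogrid <- expand.grid(aa = c("ALA", "CYS", "HIS"), ion = ions,
                       octant = 0:7, stringsAsFactors = FALSE)
  ogrid$p <- runif(nrow(ogrid))
  ogrid$p <- ogrid$p / sum(ogrid$p)
  probs <- new_ion_probs(grid, p_octant = ogrid)
  ctx <- dplyr::tibble(aa = c("ALA", "CYS", "HIS"), chain = "A",
                       resno = 1:3, x = c(1, -1, 1), y = c(1, 1, -1),
                       z = c(1, -1, -1), r = sqrt(3),
                       theta = acos(c(1, -1, -1) / sqrt(3)),
                       phi = atan2(c(1, 1, -1), c(1, -1, 1)),
                       octant = octant_index(cbind(c(1, -1, 1),
                                                   c(1, 1, -1),
                                                   c(1, -1, -1))))
  p_aa <- probs$p_aa; p_ion <- probs$p_ion
  for (io in ions) {
    want_pair <- prod(vapply(ctx$aa, function(a)
      grid$p[grid$aa == a & grid$ion == io] / (p_aa[[a]] * p_ion[[io]]),
      numeric(1)))
    got_pair <- score_ions(probs, ctx, mode = "pair")
    expect_equal(got_pair$log_score[got_pair$ion == io], log(want_pair),
                 tolerance = 1e-12)
    want_oct <- prod(vapply(seq_len(nrow(ctx)), function(i)
      ogrid$p[ogrid$aa == ctx$aa[i] & ogrid$ion == io &
                ogrid$octant == ctx$octant[i]] /
        (p_aa[[ctx$aa[i]]] * p_ion[[io]]), numeric(1)))
    got_oct <- score_ions(probs, ctx, mode = "octant")
    expect_equal(got_oct$log_score[got_oct$ion == io], log(want_oct),
                 tolerance = 1e-12)
  }
  # permutation invariance in neighbor order
  perm <- ctx[c(3, 1, 2), ]
  expect_equal(dplyr::arrange(score_ions(probs, ctx), ion)$log_score,
               dplyr::arrange(score_ions(probs, perm), ion)$log_score,
               tolerance = 1e-12)
})

test_that("a neighbor with above-independence pairing raises the score", {
  base <- dplyr::tibble(aa = rep(c("ALA", "CYS"), each = 2),
                        ion = rep(c("Zn2+", "Ca2+"), 2),
                        p = c(0.35, 0.15, 0.15, 0.35))
  probs <- new_ion_probs(base)
  ctx1 <- dplyr::tibble(aa = "ALA", chain = "A", resno = 1L, x = 1, y = 1,
                        z = 1, r = sqrt(3), theta = 0.9, phi = 0.7,
                        octant = 0L)
  ctx2 <- dplyr::bind_rows(ctx1, dplyr::mutate(ctx1, resno = 2L))
  s1 <- score_ions(probs, ctx1, mode = "pair")
  s2 <- score_ions(probs, ctx2, mode = "pair")
  # ALA pairs with Zn above independence in this table
  expect_gt(s2$log_score[s2$ion == "Zn2+"], s1$log_score[s1$ion == "Zn2+"])
})

test_that("ranking averages ties and matches a sort-based oracle", {
  pred <- rank_ions(dplyr::tibble(ion = c("Zn2+", "Ca2+"),
                                  log_score = c(3, 1)), true_ion = "Zn2+")
  expect_equal(pred$rank_of_truth, 1)

  flat <- rank_ions(dplyr::tibble(ion = default_ion_candidates(),
                                  log_score = 0))
  expect_equal(unique(flat$ranking$rank), 6)

  set.seed(161)
  for (i in 1:20) {
    sc <- dplyr::tibble(ion = paste0("I", 1:7),
                        log_score = sample(c(-1, 0, 1, 2), 7,
                                           replace = TRUE))
    got <- rank_ions(sc)$ranking
    want <- rank(-sc$log_score, ties.method = "average")
    expect_equal(got$rank[match(sc$ion, got$ion)], unname(want))
  }
  expect_error(rank_ions(dplyr::tibble(ion = "A", log_score = 1),
                         true_ion = "B"), "not among")
})

test_that("uniform random scores give mean rank near the analytic baseline", {
  set.seed(171)
  k <- 11
  n <- 4000
  ranks <- vapply(seq_len(n), function(i) {
    sc <- dplyr::tibble(ion = paste0("I", seq_len(k)), log_score = runif(k))
    rank_ions(sc, true_ion = "I1")$rank_of_truth
  }, numeric(1))
  expect_equal(mean(ranks), (k + 1) / 2, tolerance = 0.05 * (k + 1) / 2)
})

test_that("evaluation summarizes per-ion ranks and a proper CDF", {
  set.seed(181)
  model <- planted_model(ions = c("Zn2+", "Ca2+", "Cl-", "K+"))
  train <- simulate_training(model, n_per_ion = 120L)
  stats <- ion_stats(train)
  sites <- simulate_sites(model, n_sites = 40L)
  ev <- evaluate_sites(stats, sites, ions = model$ions, mode = "octant")
  expect_s3_class(ev, "ion_evaluation")
  expect_equal(sum(ev$summary$n), 40L)
  expect_true(all(ev$summary$mean_rank >= 1 &
                    ev$summary$mean_rank <= length(model$ions)))
  cdf_end <- dplyr::filter(ev$cdf, rank == length(model$ions))
  expect_true(all(abs(cdf_end$cum_prob - 1) < 1e-12))
  by_ion <- split(ev$cdf, ev$cdf$ion)
  expect_true(all(vapply(by_ion, function(d)
    all(diff(d$cum_prob[order(d$rank)]) >= -1e-12), logical(1))))
  # the planted generator is recoverable: strong model, low mean rank
  expect_lt(mean(ev$per_site$rank), 2.5)
})
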