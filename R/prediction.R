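# Naive-Bayes style ranking of candidate ion types at a query position.
# Each neighboring residue contributes the pointwise-mutual-information
# term log p(aa, ion) - log p(aa) - log p(ion); the octant-resolved mode
# replaces the pair term with the (aa, ion, octant) probability at the
# query's octant in that residue's frame.

#' Smoothed probability tables for ion-type scoring
#'
#' Converts the count tables of an `ion_stats` into probabilities over the
#' full (amino acid) x (candidate ion) grid with add-alpha smoothing, so a
#' single unseen combination never annihilates the score product. The
#' amino-acid and ion marginals are taken over the smoothed pair table.
#'
#' @param stats An `ion_stats`.
#' @param alpha Smoothing pseudo-count added to every cell (default 1).
#' @param ions Candidate ion labels; defaults to the ions present in the
#'   pair table.
#' @return An object of class `ion_probs`: tibbles `p_pair` (aa, ion, p),
#'   `p_octant` (aa, ion, octant, p), and named vectors `p_aa`, `p_ion`.
#' @export
ion_probabilities <- function(stats, alpha = 1, ions = NULL) {
  stopifnot(inherits(stats, "ion_stats"), alpha >= 0)
  ions <- ions %||% sort(unique(stats$n_pair$ion))
  if (length(ions) == 0L) abort("ion_probabilities(): no candidate ions")
  grid <- tidyr::crossing(aa = AA3, ion = ions)
  grid <- left_join(grid, stats$n_pair, by = c("aa", "ion"))
  grid$n[is.na(grid$n)] <- 0
  grid$n <- grid$n + alpha
  tot <- sum(grid$n)
  if (tot <= 0) abort("ion_probabilities(): empty counts and alpha = 0")
  p_pair <- mutate(grid, p = .data$n / tot, n = NULL)
  p_aa <- with(summarise(group_by(p_pair, .data$aa), p = sum(.data$p),
                         .groups = "drop"), setNames(p, aa))
  p_ion <- with(summarise(group_by(p_pair, .data$ion), p = sum(.data$p),
                          .groups = "drop"), setNames(p, ion))
  ogrid <- tidyr::crossing(aa = AA3, ion = ions, octant = 0:7)
  ogrid <- left_join(ogrid, stats$n_pair_octant,
                     by = c("aa", "ion", "octant"))
  ogrid$n[is.na(ogrid$n)] <- 0
  ogrid$n <- ogrid$n + alpha
  p_octant <- mutate(ogrid, p = .data$n / sum(.data$n), n = NULL)
  new_ion_probs(p_pair, p_octant, p_aa, p_ion)
}

#' Assemble probability tables directly
#'
#' Low-level constructor for hand-built probability scenarios (e.g. exact
#' textbook cases); [ion_probabilities()] is the estimator from counts.
#'
#' @param p_pair Tibble `aa`, `ion`, `p`.
#' @param p_octant Tibble `aa`, `ion`, `octant`, `p`; when `NULL`, the pair
#'   probabilities are spread uniformly over octants.
#' @param p_aa,p_ion Named probability vectors; default to the marginals of
#'   `p_pair`.
#' @return An `ion_probs`.
#' @export
new_ion_probs <- function(p_pair, p_octant = NULL, p_aa = NULL,
                          p_ion = NULL) {
  p_pair <- as_tibble(p_pair)
  if (is.null(p_octant)) {
    p_octant <- tidyr::crossing(p_pair, octant = 0:7)
    p_octant$p <- p_octant$p / 8
    p_octant <- select(p_octant, "aa", "ion", "octant", "p")
  }
  if (is.null(p_aa))
    p_aa <- with(summarise(group_by(p_pair, .data$aa), p = sum(.data$p),
                           .groups = "drop"), setNames(p, aa))
  if (is.null(p_ion))
    p_ion <- with(summarise(group_by(p_pair, .data$ion), p = sum(.data$p),
                            .groups = "drop"), setNames(p, ion))
  structure(list(p_pair = p_pair, p_octant = as_tibble(p_octant),
                 p_aa = p_aa, p_ion = p_ion, ions = sort(unique(p_pair$ion))),
            class = "ion_probs")
}

#' Neighboring residues of a query position
#'
#' Residues whose geometry center lies within `cutoff` of the query, each
#' paired with the query's coordinates in that residue's local frame.
#' Residues without a buildable frame are skipped with a warning.
#'
#' @param struct An `ion_structure`.
#' @param position Numeric 3-vector in structure coordinates.
#' @param cutoff Neighborhood radius in Angstroms.
#' @return Tibble: `aa`, `chain`, `resno`, local `x`, `y`, `z`, `r`,
#'   `theta`, `phi`, `octant`. Zero rows when no residue is in range (the
#'   prediction then degenerates to a flat score).
#' @export
neighbor_context <- function(struct, position, cutoff = 6.0) {
  stopifnot(inherits(struct, "ion_structure"),
            length(position) == 3L, all(is.finite(position)))
  res_list <- structure_residues(struct)
  empty <- tibble(aa = character(), chain = character(), resno = integer(),
                  x = numeric(), y = numeric(), z = numeric(), r = numeric(),
                  theta = numeric(), phi = numeric(), octant = integer())
  if (length(res_list) == 0L) return(empty)
  gc <- t(vapply(res_list, geometry_center, numeric(3)))
  d <- sqrt(colSums((t(gc) - position)^2))
  hits <- which(d <= cutoff + 1e-12)
  out <- vector("list", length(hits))
  skipped <- 0L
  for (k in seq_along(hits)) {
    res <- res_list[[hits[k]]]
    frame <- tryCatch(build_frame(res), error = function(e) e)
    if (inherits(frame, "error")) { skipped <- skipped + 1L; next }
    loc <- to_local(frame, position)
    out[[k]] <- tibble(aa = res$aa[1], chain = res$chain[1],
                       resno = res$resno[1], x = loc$x, y = loc$y, z = loc$z,
                       r = loc$r, theta = loc$theta, phi = loc$phi,
                       octant = loc$octant)
  }
  if (skipped > 0)
    warn(sprintf("neighbor_context(): %d residue(s) without a buildable frame skipped",
                 skipped))
  res <- bind_rows(out)
  if (nrow(res) == 0L) empty else res
}

#' Log-scores of candidate ions given a neighborhood
#'
#' For each candidate ion, sums over the neighboring residues the log
#' ratio of the joint (aa, ion) probability — or, in octant mode, the
#' (aa, ion, octant) probability at the query's octant in that residue's
#' frame — to the product of the marginals. Scores live in the log domain;
#' the product form underflows for large neighborhoods.
#'
#' @param x An `ion_stats` (converted with `alpha` smoothing) or an
#'   `ion_probs`.
#' @param context A neighbor tibble from [neighbor_context()].
#' @param ions Candidate set; defaults to the candidates of `x` when it is
#'   an `ion_probs`, else to [default_ion_candidates()] intersected with
#'   availability, else all ions of `x`.
#' @param mode `"pair"` (aa-level joint) or `"octant"` (octant-resolved).
#' @param alpha Smoothing used when `x` is an `ion_stats`.
#' @return Tibble `ion`, `log_score`, sorted by descending score. An empty
#'   context yields 0 for every ion.
#' @export
score_ions <- function(x, context, ions = NULL,
                       mode = c("pair", "octant"), alpha = 1) {
  mode <- match.arg(mode)
  probs <- as_ion_probs(x, alpha = alpha, ions = ions)
  ions <- ions %||% probs$ions
  missing <- setdiff(ions, probs$ions)
  if (length(missing) > 0)
    abort(paste0("score_ions(): unknown ion(s) ",
                 paste(missing, collapse = ", "), "; candidates are: ",
                 paste(probs$ions, collapse = ", ")))
  if (nrow(context) == 0L)
    return(tibble(ion = ions, log_score = 0))
  lp_aa <- log(probs$p_aa[context$aa])
  scores <- vapply(ions, function(io) {
    if (mode == "pair") {
      tab <- probs$p_pair[probs$p_pair$ion == io, , drop = FALSE]
      lp_joint <- log(tab$p[match(context$aa, tab$aa)])
    } else {
      tab <- probs$p_octant[probs$p_octant$ion == io, , drop = FALSE]
      key <- paste(tab$aa, tab$octant)
      lp_joint <- log(tab$p[match(paste(context$aa, context$octant), key)])
    }
    sum(lp_joint - lp_aa - log(probs$p_ion[[io]]))
  }, numeric(1))
  arrange(tibble(ion = ions, log_score = unname(scores)),
          dplyr::desc(.data$log_score))
}

as_ion_probs <- function(x, alpha = 1, ions = NULL) {
  if (inherits(x, "ion_probs")) return(x)
  if (inherits(x, "ion_stats")) {
    cand <- ions %||% {
      present <- sort(unique(x$n_pair$ion))
      if (length(present) == 0L) default_ion_candidates() else present
    }
    return(ion_probabilities(x, alpha = alpha, ions = cand))
  }
  abort("expected an ion_stats or ion_probs object")
}

#' Rank candidate ions from their scores
#'
#' Orders ions by descending log-score; tied scores share the average of
#' the ranks they cover, so the best attainable rank is 1 and a flat score
#' vector over k candidates gives every ion rank (k + 1) / 2.
#'
#' @param scores Tibble `ion`, `log_score` from [score_ions()].
#' @param true_ion Optional known ion type; its rank is recorded.
#' @return An object of class `ion_prediction`; `tidy()` returns the
#'   ranked table.
#' @export
rank_ions <- function(scores, true_ion = NULL) {
  stopifnot(nrow(scores) >= 1L)
  rk <- rank(-scores$log_score, ties.method = "average")
  out <- arrange(mutate(scores, rank = rk), .data$rank)
  rank_of_truth <- if (!is.null(true_ion)) {
    if (!true_ion %in% out$ion)
      abort(paste0("rank_ions(): true ion ", true_ion,
                   " not among candidates"))
    out$rank[out$ion == true_ion]
  } else NA_real_
  structure(list(ranking = out, rank_of_truth = rank_of_truth,
                 true_ion = true_ion %||% NA_character_),
            class = "ion_prediction")
}

#' @export
print.ion_prediction <- function(x, ...) {
  cat("<ion_prediction>\n")
  print(x$ranking, n = 5)
  if (!is.na(x$rank_of_truth))
    cat(sprintf("  true ion %s at rank %.1f\n", x$true_ion,
                x$rank_of_truth))
  invisible(x)
}

#' @rdname rank_ions
#' @param x An `ion_prediction`.
#' @param ... Unused.
#' @export
tidy.ion_prediction <- function(x, ...) x$ranking

#' Predict the ion type at a position in a structure
#'
#' Convenience wrapper: builds the neighbor context at the query position
#' and ranks the candidate ions by their statistics-derived log-scores.
#'
#' @inheritParams score_ions
#' @param struct An `ion_structure`.
#' @param position Query position (3-vector, structure coordinates).
#' @param cutoff Neighborhood radius in Angstroms.
#' @param true_ion Optional known type to evaluate.
#' @return An `ion_prediction`.
#' @export
predict_ion_type <- function(x, struct, position, cutoff = 6.0,
                             ions = NULL, mode = c("pair", "octant"),
                             alpha = 1, true_ion = NULL) {
  ctx <- neighbor_context(struct, position, cutoff = cutoff)
  rank_ions(score_ions(x, ctx, ions = ions, mode = mode, alpha = alpha),
            true_ion = true_ion)
}

#' Evaluate ion-type prediction on labelled sites
#'
#' For each labelled site the true ion is masked (its record removed from
#' the structure's ion table), the remaining structure defines the
#' neighborhood of the true ion's coordinates, and the rank of the true
#' type among the candidates is recorded. Summaries are the per-ion mean
#' rank, its standard deviation, and the cumulative rank distribution.
#'
#' @inheritParams score_ions
#' @param sites A tibble with a list-column `structure` of `ion_structure`
#'   objects and columns `x`, `y`, `z`, `true_ion`; or a list of lists with
#'   those fields.
#' @param cutoff Neighborhood radius.
#' @return An object of class `ion_evaluation`: `per_site` (site index,
#'   true ion, rank, number of neighbors), `summary` (per-ion n, mean
#'   rank, sd), `cdf` (per-ion cumulative rank distribution). `tidy()`
#'   returns the summary, `glance()` the overall mean rank.
#' @export
evaluate_sites <- function(x, sites, ions = NULL,
                           mode = c("pair", "octant"), cutoff = 6.0,
                           alpha = 1) {
  mode <- match.arg(mode)
  if (!is.data.frame(sites)) {
    sites <- tibble(structure = lapply(sites, `[[`, "structure"),
                    x = vapply(sites, `[[`, numeric(1), "x"),
                    y = vapply(sites, `[[`, numeric(1), "y"),
                    z = vapply(sites, `[[`, numeric(1), "z"),
                    true_ion = vapply(sites, `[[`, character(1), "true_ion"))
  }
  probs <- as_ion_probs(x, alpha = alpha,
                        ions = ions %||% default_ion_candidates())
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    st <- sites$structure[[i]]
    pos <- c(sites$x[i], sites$y[i], sites$z[i])
    # mask the evaluated ion: drop any ion record at (essentially) the query
    keep <- sqrt((st$ions$x - pos[1])^2 + (st$ions$y - pos[2])^2 +
                   (st$ions$z - pos[3])^2) > 1e-6
    st$ions <- st$ions[keep, , drop = FALSE]
    ctx <- neighbor_context(st, pos, cutoff = cutoff)
    pred <- rank_ions(score_ions(probs, ctx, mode = mode),
                      true_ion = sites$true_ion[i])
    tibble(site = i, true_ion = sites$true_ion[i],
           rank = pred$rank_of_truth, n_neighbors = nrow(ctx))
  })
  per_site <- bind_rows(rows)
  summary <- summarise(group_by(per_site, ion = .data$true_ion),
                       n = dplyr::n(), mean_rank = mean(.data$rank),
                       sd_rank = sd(.data$rank), .groups = "drop")
  k <- length(probs$ions)
  cdf <- bind_rows(lapply(split(per_site, per_site$true_ion), function(d) {
    tibble(ion = d$true_ion[1], rank = seq_len(k),
           cum_prob = vapply(seq_len(k),
                             function(r) mean(d$rank <= r + 1e-9),
                             numeric(1)))
  }))
  structure(list(per_site = per_site, summary = summary, cdf = cdf,
                 mode = mode, candidates = probs$ions),
            class = "ion_evaluation")
}

#' @export
print.ion_evaluation <- function(x, ...) {
  cat(sprintf("<ion_evaluation> %d sites, mode '%s', %d candidates\n",
              nrow(x$per_site), x$mode, length(x$candidates)))
  print(x$summary)
  invisible(x)
}

#' @rdname evaluate_sites
#' @param ... Unused.
#' @export
tidy.ion_evaluation <- function(x, ...) x$summary

#' @rdname evaluate_sites
#' @export
glance.ion_evaluation <- function(x, ...) {
  tibble(n_sites = nrow(x$per_site), mean_rank = mean(x$per_site$rank),
         mode = x$mode, n_candidates = length(x$candidates))
}
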