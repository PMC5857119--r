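# The aggregated statistics database: counts of residues, ions, pairs and
# octant-resolved pairs, plus the raw pair records for histograms and
# density maps. This is the trained artifact consumed by prediction and
# clustering.

#' Accumulate pair statistics over structures
#'
#' Runs [find_pairs()] over one or more structures and aggregates the
#' count tables: residues per amino-acid type (all parsed residues, not
#' only paired ones), accepted ions per type, pairs per (aa, ion), pairs
#' per (aa, ion, octant), plus the side-chain preference tallies and the
#' full pair record table.
#'
#' @param structs An `ion_structure` or a list of them.
#' @param cutoff Pairing cutoff in Angstroms.
#' @param label Free-text dataset label stored in the metadata.
#' @return An object of class `ion_stats`.
#' @export
ion_stats <- function(structs, cutoff = 6.0, label = "") {
  if (inherits(structs, "ion_structure")) structs <- list(structs)
  pairs <- bind_rows(lapply(structs, find_pairs, cutoff = cutoff))
  n_aa_tab <- bind_rows(lapply(structs, function(s)
    distinct(s$atoms, .data$chain, .data$resno, .data$insert, .data$aa)))
  n_aa <- complete_counts(count(n_aa_tab, .data$aa), "aa", AA3)
  ion_levels <- sort(unique(unlist(lapply(structs, function(s) s$ions$ion))))
  n_ion <- bind_rows(lapply(structs, function(s) count(s$ions, .data$ion)))
  n_ion <- if (nrow(n_ion)) summarise(group_by(n_ion, .data$ion),
                                      n = sum(.data$n), .groups = "drop")
           else tibble(ion = character(), n = integer())
  scp <- side_chain_summary(structs, cutoff = cutoff)
  new_ion_stats(cutoff = cutoff, n_structures = length(structs),
                n_aa = n_aa, n_ion = n_ion,
                n_pair = count_pairs(pairs),
                n_pair_octant = count_pairs_octant(pairs),
                scp = scp, pairs = pairs,
                meta = list(label = label, built = format(Sys.time())))
}

new_ion_stats <- function(cutoff, n_structures, n_aa, n_ion, n_pair,
                          n_pair_octant, scp, pairs, meta) {
  structure(list(cutoff = cutoff, n_structures = n_structures,
                 n_aa = n_aa, n_ion = n_ion, n_pair = n_pair,
                 n_pair_octant = n_pair_octant, scp = scp, pairs = pairs,
                 meta = meta),
            class = "ion_stats")
}

complete_counts <- function(cnt, key, levels) {
  base <- as_tibble(setNames(list(levels), key))
  out <- left_join(base, cnt, by = key)
  out$n[is.na(out$n)] <- 0L
  out
}

count_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(tibble(aa = character(), ion = character(),
                                       n = integer()))
  count(pairs, .data$aa, .data$ion)
}

count_pairs_octant <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(tibble(aa = character(), ion = character(), octant = integer(),
                  n = integer()))
  count(pairs, .data$aa, .data$ion, .data$octant)
}

#' Build an `ion_stats` object from pre-tabulated counts
#'
#' Constructs the statistics database directly from count tables, without
#' pair records — e.g. from published pair-count tables or hand-built
#' probability scenarios.
#'
#' @param n_pair Tibble with `aa`, `ion`, `n`.
#' @param n_pair_octant Optional tibble with `aa`, `ion`, `octant`, `n`;
#'   when omitted, pair counts are spread uniformly over the 8 octants.
#' @param n_aa,n_ion Optional marginal count tables; defaults to the
#'   marginals of `n_pair`.
#' @param cutoff Cutoff recorded in the object.
#' @param label Metadata label.
#' @return An `ion_stats` with an empty pair-record table.
#' @export
ion_stats_from_counts <- function(n_pair, n_pair_octant = NULL,
                                  n_aa = NULL, n_ion = NULL,
                                  cutoff = 6.0, label = "from-counts") {
  n_pair <- as_tibble(n_pair)
  if (is.null(n_pair_octant)) {
    n_pair_octant <- tidyr::crossing(n_pair, octant = 0:7)
    n_pair_octant$n <- n_pair_octant$n / 8
    n_pair_octant <- select(n_pair_octant, "aa", "ion", "octant", "n")
  }
  if (is.null(n_aa))
    n_aa <- summarise(group_by(n_pair, .data$aa), n = sum(.data$n),
                      .groups = "drop")
  if (is.null(n_ion))
    n_ion <- summarise(group_by(n_pair, .data$ion), n = sum(.data$n),
                       .groups = "drop")
  new_ion_stats(cutoff = cutoff, n_structures = 0L, n_aa = n_aa,
                n_ion = n_ion, n_pair = n_pair,
                n_pair_octant = as_tibble(n_pair_octant), scp = NULL,
                pairs = tibble(),
                meta = list(label = label, built = format(Sys.time())))
}

#' Merge statistics databases
#'
#' Count tables are additive, so merging two databases equals accumulating
#' the concatenated structure sets.
#'
#' @param ... `ion_stats` objects with a common cutoff.
#' @return The merged `ion_stats`.
#' @export
merge_stats <- function(...) {
  xs <- list(...)
  stopifnot(all(vapply(xs, inherits, logical(1), "ion_stats")))
  cutoffs <- unique(vapply(xs, `[[`, numeric(1), "cutoff"))
  if (length(cutoffs) != 1L) abort("merge_stats(): differing cutoffs")
  sum_by <- function(field, keys) {
    tab <- bind_rows(lapply(xs, `[[`, field))
    if (nrow(tab) == 0L) return(tab)
    summarise(group_by(tab, across(dplyr::all_of(keys))),
              n = sum(.data$n), .groups = "drop")
  }
  scp <- bind_rows(lapply(xs, `[[`, "scp"))
  scp <- if (nrow(scp)) {
    agg <- summarise(group_by(scp, .data$aa),
                     n_backbone = sum(.data$n_backbone),
                     n_sidechain = sum(.data$n_sidechain), .groups = "drop")
    mutate(agg, pct_sidechain = ifelse(
      !is.na(.data$n_backbone) & (.data$n_backbone + .data$n_sidechain) > 0,
      100 * .data$n_sidechain / (.data$n_backbone + .data$n_sidechain),
      NA_real_))
  } else NULL
  new_ion_stats(cutoff = cutoffs,
                n_structures = sum(vapply(xs, `[[`, numeric(1),
                                          "n_structures")),
                n_aa = sum_by("n_aa", "aa"), n_ion = sum_by("n_ion", "ion"),
                n_pair = sum_by("n_pair", c("aa", "ion")),
                n_pair_octant = sum_by("n_pair_octant",
                                       c("aa", "ion", "octant")),
                scp = scp,
                pairs = bind_rows(lapply(xs, `[[`, "pairs")),
                meta = list(label = "merged", built = format(Sys.time())))
}

#' @export
print.ion_stats <- function(x, ...) {
  cat(sprintf("<ion_stats> %d structure(s), cutoff %.1f A\n",
              x$n_structures, x$cutoff))
  cat(sprintf("  %d pairs over %d (aa, ion) combinations; %d ion type(s)\n",
              sum(x$n_pair$n), nrow(x$n_pair), nrow(x$n_ion)))
  invisible(x)
}

#' @rdname ion_stats
#' @param x An `ion_stats` object.
#' @param ... Unused.
#' @export
tidy.ion_stats <- function(x, ...) {
  arrange(x$n_pair, dplyr::desc(.data$n))
}

#' @rdname ion_stats
#' @export
glance.ion_stats <- function(x, ...) {
  tibble(n_structures = x$n_structures, cutoff = x$cutoff,
         n_pairs = sum(x$n_pair$n), n_aa_types = sum(x$n_aa$n > 0),
         n_ion_types = nrow(x$n_ion))
}

#' Group means of a per-amino-acid quantity
#'
#' Aggregates any per-amino-acid column (pair counts, side-chain
#' percentages, ...) by side-chain property group and reports the
#' arithmetic mean per group, i.e. the "Average" row of the grouped
#' summary tables. Amino acids whose value is `NA` (glycine in the
#' side-chain preference summary) are dropped from their group mean.
#'
#' @param values A data frame with a column `aa` and one numeric column
#'   (or a column named by `value`).
#' @param grouping Named character vector mapping the 20 three-letter codes
#'   to group labels; defaults to [aa_side_chain_groups()].
#' @param value Name of the value column; defaults to the first numeric
#'   column.
#' @return Tibble with `group`, `n` (members contributing) and `mean`.
#' @export
#' @examples
#' pos <- data.frame(aa = c("ARG", "HIS", "LYS"), n = c(2478, 12547, 3854))
#' group_summary(pos)  # mean 6293
group_summary <- function(values, grouping = aa_side_chain_groups(),
                          value = NULL) {
  values <- as_tibble(values)
  if (is.null(value)) {
    num <- names(values)[vapply(values, is.numeric, logical(1))]
    if (length(num) == 0L) abort("group_summary(): no numeric column")
    value <- num[1]
  }
  if (!all(values$aa %in% names(grouping)))
    abort("group_summary(): grouping does not cover all amino acids present")
  df <- tibble(aa = values$aa, value = values[[value]],
               group = unname(grouping[values$aa]))
  df <- filter(df, !is.na(.data$value))
  summarise(group_by(df, .data$group), n = dplyr::n(),
            mean = mean(.data$value), .groups = "drop")
}

#' Distribution histograms for one (amino acid, ion) combination
#'
#' @param stats An `ion_stats` built from structures (pair records
#'   required for `radial` and `angular`).
#' @param aa,ion Combination to summarize.
#' @param kind `"radial"` (counts over distance bins on 0..cutoff),
#'   `"angular"` (2-D counts over theta x phi bins), or `"octant"`
#'   (counts per octant 0..7).
#' @param radial_bin Radial bin width in Angstroms.
#' @param theta_bins,phi_bins Angular bin counts.
#' @return A tibble of bins and counts; bin sums equal the pair count for
#'   the combination. An absent combination yields an all-zero histogram.
#' @export
pair_histogram <- function(stats, aa, ion,
                           kind = c("radial", "angular", "octant"),
                           radial_bin = 0.1, theta_bins = 18L,
                           phi_bins = 36L) {
  kind <- match.arg(kind)
  p <- stats$pairs
  p <- p[p$aa == aa & p$ion == ion, , drop = FALSE]
  if (kind == "radial") {
    breaks <- seq(0, stats$cutoff, by = radial_bin)
    if (breaks[length(breaks)] < stats$cutoff)
      breaks <- c(breaks, stats$cutoff)
    idx <- pmin(findInterval(p$r, breaks, rightmost.closed = TRUE),
                length(breaks) - 1L)
    tibble(r_lo = breaks[-length(breaks)], r_hi = breaks[-1],
           count = as.integer(tabulate(idx, nbins = length(breaks) - 1L)))
  } else if (kind == "angular") {
    tb <- seq(0, pi, length.out = theta_bins + 1L)
    pb <- seq(-pi, pi, length.out = phi_bins + 1L)
    ti <- pmin(pmax(findInterval(p$theta, tb, rightmost.closed = TRUE), 1L),
               theta_bins)
    pi_ <- pmin(pmax(findInterval(p$phi, pb, rightmost.closed = TRUE), 1L),
                phi_bins)
    grid <- tidyr::crossing(theta_bin = seq_len(theta_bins),
                            phi_bin = seq_len(phi_bins))
    cnt <- count(tibble(theta_bin = ti, phi_bin = pi_),
                 .data$theta_bin, .data$phi_bin)
    out <- left_join(grid, cnt, by = c("theta_bin", "phi_bin"))
    out$n[is.na(out$n)] <- 0L
    mutate(out,
           theta_lo = tb[.data$theta_bin], theta_hi = tb[.data$theta_bin + 1L],
           phi_lo = pb[.data$phi_bin], phi_hi = pb[.data$phi_bin + 1L],
           count = as.integer(.data$n), n = NULL)
  } else {
    tibble(octant = 0:7,
           count = as.integer(tabulate(p$octant + 1L, nbins = 8L)))
  }
}

#' Serialize an `ion_stats` database to JSON
#'
#' Writes all count tables and metadata (not the raw pair records) as one
#' JSON document readable by [read_stats_json()].
#'
#' @param stats An `ion_stats`.
#' @param path Output path.
#' @export
write_stats_json <- function(stats, path) {
  doc <- list(cutoff = stats$cutoff, n_structures = stats$n_structures,
              n_aa = stats$n_aa, n_ion = stats$n_ion,
              n_pair = stats$n_pair, n_pair_octant = stats$n_pair_octant,
              scp = stats$scp, meta = stats$meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_stats_json
#' @return `read_stats_json()` returns the `ion_stats` (with an empty
#'   pair-record table, so histograms and density maps need the original
#'   structures).
#' @export
read_stats_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_ion_stats(cutoff = doc$cutoff, n_structures = doc$n_structures,
                n_aa = as_tibble(doc$n_aa), n_ion = as_tibble(doc$n_ion),
                n_pair = as_tibble(doc$n_pair),
                n_pair_octant = as_tibble(doc$n_pair_octant),
                scp = if (!is.null(doc$scp)) as_tibble(doc$scp) else NULL,
                pairs = tibble(), meta = doc$meta)
}
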