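# ggplot2 views of the distribution statistics and evaluation results.

#' Radial distribution plot for one (amino acid, ion) combination
#'
#' @inheritParams pair_histogram
#' @return A ggplot object: counts per radial bin from the residue
#'   geometry center out to the cutoff.
#' @export
plot_radial_distribution <- function(stats, aa, ion, radial_bin = 0.1) {
  h <- pair_histogram(stats, aa, ion, kind = "radial",
                      radial_bin = radial_bin)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$r_lo + .data$r_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = radial_bin, fill = "steelblue") +
    ggplot2::labs(x = "distance to geometry center (Å)", y = "count",
                  title = sprintf("%s around %s: radial distribution",
                                  ion, aa)) +
    ggplot2::theme_minimal()
}

#' Angular distribution plot for one (amino acid, ion) combination
#'
#' @inheritParams pair_histogram
#' @return A ggplot object: 2-D (theta, phi) histogram of ion directions
#'   in the residue local frame.
#' @export
plot_angular_distribution <- function(stats, aa, ion, theta_bins = 18L,
                                      phi_bins = 36L) {
  h <- pair_histogram(stats, aa, ion, kind = "angular",
                      theta_bins = theta_bins, phi_bins = phi_bins)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$phi_lo + .data$phi_hi) / 2,
                                  y = (.data$theta_lo + .data$theta_hi) / 2,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(phi), y = expression(theta),
                  title = sprintf("%s around %s: angular distribution",
                                  ion, aa)) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_sites Cumulative rank distribution per ion type.
#' @param object An `ion_evaluation`.
#' @export
autoplot.ion_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(x = .data$rank, y = .data$cum_prob,
                               colour = .data$ion)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "rank", y = "cumulative probability",
                  colour = "true ion") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
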