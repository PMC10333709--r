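# Diagnostic plots: mixture fits, positivity histograms, concordance
# separation and abundance effects.

#' Plot a hashtag mixture fit over its log-count histogram
#'
#' @param object A `hashtag_gmm` from [fit_hashtag_gmm()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot: density histogram of the fitted log-counts with the two
#'   weighted component densities and their sum overlaid.
#' @method autoplot hashtag_gmm
#' @export
autoplot.hashtag_gmm <- function(object, bins = 60, ...) {
  grid <- seq(min(object$x), max(object$x), length.out = 400)
  dens <- tibble(
    x = rep(grid, 3),
    density = c(
      (1 - object$pi_hi) * dnorm(grid, object$mu_lo, object$sigma_lo),
      object$pi_hi * dnorm(grid, object$mu_hi, object$sigma_hi),
      (1 - object$pi_hi) * dnorm(grid, object$mu_lo, object$sigma_lo) +
        object$pi_hi * dnorm(grid, object$mu_hi, object$sigma_hi)
    ),
    component = rep(c("noise", "signal", "mixture"), each = length(grid))
  )
  ggplot2::ggplot(tibble(x = object$x), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "log10(count + 1)", y = "density",
                  colour = NULL, title = "Hashtag log-count mixture") +
    ggplot2::theme_minimal()
}

#' Bar plot of positive-hashtag counts per cell
#'
#' @param calls Tibble from [assign_by_hashtag()].
#' @return A ggplot of the number of cells by number of positive hashtags
#'   (0 = negative, 1 = singlet, 2+ = multiplet).
#' @export
plot_hashtag_positivity <- function(calls) {
  summarize_hashtag_positivity(calls) %>%
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$n_positive),
                                 y = .data$n_cells)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "positive hashtags per cell", y = "cells") +
    ggplot2::theme_minimal()
}

#' Concordance separation plot
#'
#' Strip plot of all-pairs genotype concordance, split by whether the pair is
#' expected to be the same donor; complete separation of the two strips
#' validates the sample-to-donor linking.
#'
#' @param pairs Tibble from [pairwise_concordance()] with
#'   `same_donor_expected`.
#' @return A ggplot.
#' @export
plot_concordance <- function(pairs) {
  check_columns(pairs, c("concordance", "same_donor_expected"), "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$same_donor_expected,
                                      y = .data$concordance)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "same donor expected", y = "genotype concordance") +
    ggplot2::theme_minimal()
}

#' Challenge-effect plot for cluster abundance results
#'
#' @param results Tibble from [test_cluster_abundance()].
#' @return A ggplot of the per-cluster challenge log-odds effects with
#'   95% Wald intervals, faceted by group; significant clusters highlighted.
#' @export
plot_abundance_effects <- function(results) {
  check_columns(results, c("cluster_id", "beta1", "se", "significant"),
                "results")
  ggplot2::ggplot(results, ggplot2::aes(x = .data$cluster_id, y = .data$beta1,
                                        colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$beta1 - 1.96 * .data$se,
      ymax = .data$beta1 + 1.96 * .data$se
    )) +
    {if ("group" %in% names(results)) ggplot2::facet_wrap(~group)} +
    ggplot2::labs(x = NULL, y = "challenge effect (log-odds)",
                  colour = "BH significant") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
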