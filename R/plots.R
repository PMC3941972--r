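#' Plot per-family log fold enrichment
#'
#' Bar chart of log10 fold ratio per family (the cross-strain abundance
#' screen figure). Families with undefined ratios are dropped.
#'
#' @param enrichment An [enrichment_report()] tibble (or `te_screen`).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  if (inherits(enrichment, "te_screen")) enrichment <- enrichment$enrichment
  d <- enrichment[!is.na(enrichment$fold) & is.finite(enrichment$fold), ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$family_id, -.data$fold),
    y = log10(.data$fold)
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "repeat family",
                  y = "log10 fold ratio (strain a : strain b)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot per-site coverage and major-variant frequency
#'
#' Two-panel profile along the consensus, one facet row per statistic and
#' one color per strain: homogeneous recently active copy populations show
#' flat major-variant frequency near 1, degraded populations scatter lower.
#'
#' @param profiles A long [site_profile()] tibble (or `te_screen`).
#' @param family Optional single family to plot (required when profiles
#'   contain several).
#' @return A ggplot object.
#' @export
plot_site_profile <- function(profiles, family = NULL) {
  if (inherits(profiles, "te_screen")) profiles <- profiles$profiles
  if (!is.null(family)) profiles <- profiles[profiles$family_id == family, ]
  stopifnot(nrow(profiles) > 0, length(unique(profiles$family_id)) == 1)
  long <- profiles |>
    dplyr::select("strain", "pos", "coverage_per_million", "major_fraction") |>
    tidyr::pivot_longer(c("coverage_per_million", "major_fraction"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$pos, .data$value,
                                     color = .data$strain)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5, na.rm = TRUE) +
    ggplot2::facet_grid(statistic ~ strain, scales = "free_y") +
    ggplot2::labs(x = "consensus position (bp)", y = NULL,
                  title = unique(profiles$family_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the fragment age (branch length) distribution
#'
#' Histogram of terminal branch lengths; a recent burst piles near zero
#' while ancient cohorts center at their divergence.
#'
#' @param x A `te_age_result`, `te_age_distribution`, or numeric vector of
#'   branch lengths.
#' @param bins Number of bins when `x` is raw values.
#' @return A ggplot object.
#' @export
plot_age_distribution <- function(x, bins = 20L) {
  if (inherits(x, "te_age_result")) x <- x$summary
  if (!inherits(x, "te_age_distribution")) x <- age_distribution(x, bins)
  ggplot2::ggplot(x$histogram, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(width = diff(x$histogram$lower[1:2]) * 0.95) +
    ggplot2::labs(x = "terminal branch length (substitutions/bp)",
                  y = "fragments") +
    ggplot2::theme_minimal()
}

#' Plot group mean expression with technical-replicate error bars
#'
#' @param report A `te_expression_report` with `group_means` (i.e. built
#'   with the raw observations), or the `group_means` tibble itself.
#' @return A ggplot object.
#' @export
plot_expression <- function(report) {
  gm <- if (inherits(report, "te_expression_report")) report$group_means else report
  stopifnot(!is.null(gm))
  ggplot2::ggplot(gm, ggplot2::aes(.data$age_class, .data$mean_rpm,
                                   fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rpm - .data$se_rpm,
                   ymax = .data$mean_rpm + .data$se_rpm),
      position = ggplot2::position_dodge(0.9), width = 0.2
    ) +
    ggplot2::facet_wrap(~te, scales = "free_y") +
    ggplot2::labs(x = "F1 female age", y = "RNA-seq reads per million mapped") +
    ggplot2::theme_minimal()
}
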