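# ggplot2 views of the result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.strat_mc <- function(object, ...) {
  df <- dplyr::filter(object, .data$rr == min(.data$rr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                   y = .data$rejection_rate)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$band_low),
                        linetype = "dashed") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$band_high),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(object, "alpha") %||% 0.05) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "Rejection rate",
                  title = sprintf("Scenario %d, RR = %g",
                                  df$scenario[1], df$rr[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.strat_power_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rr,
                                       y = .data$rejection_rate,
                                       colour = .data$method)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$band_high),
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Relative risk", y = "Power (rejection rate)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.strat_sweep_r <- function(object, ...) {
  df <- dplyr::filter(object, .data$cohort == "full")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$rejection_rate,
                                   colour = .data$method,
                                   linetype = factor(.data$rr))) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$band_high),
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Proportion of cases in population 1",
                  y = "Rejection rate", colour = NULL, linetype = "RR") +
    ggplot2::theme_minimal()
}

#' Plot a cohort on its first two principal components
#'
#' The usual visual check of the simulated population structure: individuals
#' on PC1/PC2 of the null-marker matrix, colored by true subpopulation.
#'
#' @param cohort A `strat_cohort` with null SNPs.
#' @param basis Optional precomputed [pca_genotypes()] basis.
#' @return A ggplot object.
#' @export
plot_cohort_pca <- function(cohort, basis = NULL) {
  basis <- basis %||% pca_genotypes(cohort$genotypes, k = 2)
  df <- tibble::tibble(PC1 = basis$axes[, 1], PC2 = basis$axes[, 2],
                       label = cohort$labels,
                       phenotype = factor(cohort$phenotype,
                                          labels = c("control", "case")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$label,
                                   shape = .data$phenotype)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "Subpopulation", shape = NULL) +
    ggplot2::theme_minimal()
}
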