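# broom-style views of the package's objects.

#' Tidy a simulated cohort into a per-individual tibble
#'
#' @param x A `strat_cohort`.
#' @param ... Unused.
#' @return A tibble with one row per individual: `id`, `phenotype`,
#'   `label`, `dsl` dosage and one `ancestry_*` column per subpopulation.
#' @method tidy strat_cohort
#' @export
tidy.strat_cohort <- function(x, ...) {
  anc <- tibble::as_tibble(x$ancestry, .name_repair = "minimal")
  names(anc) <- paste0("ancestry_", colnames(x$ancestry))
  dplyr::bind_cols(
    tibble::tibble(id = seq_along(x$phenotype),
                   phenotype = as.integer(x$phenotype),
                   label = x$labels, dsl = as.integer(x$dsl)),
    anc)
}

#' One-row summary of a simulated cohort
#'
#' @param x A `strat_cohort`.
#' @param ... Unused.
#' @return A one-row tibble: scenario, sizes, case count, DSL frequency
#'   range across subpopulations.
#' @method glance strat_cohort
#' @export
glance.strat_cohort <- function(x, ...) {
  tibble::tibble(
    scenario = x$config$scenario,
    n = length(x$phenotype),
    n_cases = sum(x$phenotype == 1L),
    n_controls = sum(x$phenotype == 0L),
    n_null_snps = ncol(x$genotypes),
    n_subpops = nlevels(x$labels),
    dsl_maf_min = min(x$dsl_freqs),
    dsl_maf_max = max(x$dsl_freqs),
    admixed = isTRUE(x$admixed))
}

#' Tidy association-test results
#'
#' @param x A `strat_assoc` table from [run_association_tests()].
#' @param ... Unused.
#' @return The underlying tibble (method, statistic, df, p_value, lambda,
#'   k_pcs, note).
#' @method tidy strat_assoc
#' @export
tidy.strat_assoc <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a Monte-Carlo result table
#'
#' @param x A `strat_mc` from [run_monte_carlo()] or [power_curve()].
#' @param ... Unused.
#' @return The underlying tibble, one row per (method, rr).
#' @method tidy strat_mc
#' @export
tidy.strat_mc <- function(x, ...) {
  tibble::as_tibble(x[setdiff(names(x), character(0))])
}

#' One-row summary of a Monte-Carlo run
#'
#' @param x A `strat_mc`.
#' @param ... Unused.
#' @return A one-row tibble: scenario, replicate count, number of methods,
#'   how many methods fall inside the null reference band, mean lambda.
#' @method glance strat_mc
#' @export
glance.strat_mc <- function(x, ...) {
  null_rows <- dplyr::filter(x, .data$rr == min(.data$rr))
  tibble::tibble(
    scenario = null_rows$scenario[1],
    B = null_rows$B[1],
    alpha = attr(x, "alpha") %||% 0.05,
    n_methods = dplyr::n_distinct(x$method),
    n_in_band = sum(null_rows$rejection_rate >= null_rows$band_low &
                      null_rows$rejection_rate <= null_rows$band_high),
    mean_lambda = null_rows$mean_lambda[1])
}
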