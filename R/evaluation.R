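#' Configure a Monte-Carlo evaluation
#'
#' @param alpha Significance level of every test (default 0.05).
#' @param B Number of simulated replicate datasets (default 2,000; reduce
#'   for desk-scale runs — the confidence intervals make the precision of
#'   any B explicit).
#' @param rr_grid Relative risks for power curves; must include 1 (the null,
#'   where power and false positive rate coincide).
#' @param methods Association strategies to evaluate (see
#'   [run_association_tests()]).
#' @param k_pcs Principal components used by PC-based methods.
#' @param gc_estimator Lambda estimator for Genomic Control.
#' @param seed Master seed; per-replicate seeds are derived from it by a
#'   counter scheme so each replicate is independently re-runnable.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(alpha = 0.05, B = 2000,
                        rr_grid = c(1, 1.5, 2, 2.5),
                        methods = c("trend", "gc", "eigenstrat", "reg_pcs",
                                    "reg_real", "reg_est", "meta_fisher"),
                        k_pcs = 5L, gc_estimator = "median", seed = 1L) {
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  B <- check_count(B, "B", min = 1L)
  structure(
    list(alpha = alpha, B = B, rr_grid = sort(unique(rr_grid)),
         methods = methods, k_pcs = as.integer(k_pcs),
         gc_estimator = gc_estimator, seed = as.integer(seed)),
    class = "eval_config"
  )
}

#' @export
print.eval_config <- function(x, ...) {
  cat(sprintf("<eval_config> alpha = %g, B = %d, seed = %d\n",
              x$alpha, x$B, x$seed))
  cat("  methods:", paste(x$methods, collapse = ", "), "\n")
  cat("  rr grid:", paste(x$rr_grid, collapse = ", "), "\n")
  invisible(x)
}

#' Rejection rate with binomial confidence interval
#'
#' The Monte-Carlo estimate `#\{p <= alpha\} / B_effective`, its 95% binomial
#' confidence interval, and the null reference band
#' `alpha +/- 1.96 sqrt(alpha (1 - alpha) / B)` that a calibrated test should
#' fall into under the null. `NA` p-values (e.g. separation) are excluded
#' from the denominator and counted.
#'
#' @param p_values Vector of p-values in `[0, 1]`, possibly with `NA`s.
#' @param alpha Significance level.
#' @return A one-row tibble with `rejection_rate`, `ci_low`, `ci_high`,
#'   `band_low`, `band_high`, `B`, `B_effective`, `n_na`.
#' @export
estimate_rejection_rate <- function(p_values, alpha = 0.05) {
  B <- length(p_values)
  ok <- !is.na(p_values)
  if (!any(ok)) abort("All p-values are NA.")
  b_eff <- sum(ok)
  rate <- sum(p_values[ok] <= alpha) / b_eff
  se <- sqrt(rate * (1 - rate) / b_eff)
  band <- 1.96 * sqrt(alpha * (1 - alpha) / B)
  tibble::tibble(
    rejection_rate = rate,
    ci_low = max(0, rate - 1.96 * se), ci_high = min(1, rate + 1.96 * se),
    band_low = alpha - band, band_high = alpha + band,
    B = B, B_effective = b_eff, n_na = B - b_eff
  )
}

# Build one replicate cohort for a scenario at a given relative risk,
# skipping null-SNP generation when no requested method needs it.
replicate_cohort <- function(config, rr, methods, seed,
                             force_nulls = FALSE) {
  cfg <- config
  if (!is.null(rr)) cfg$disease <- set_rr(cfg$disease, rr)
  needs_nulls <- force_nulls ||
    any(methods %in% c(NEEDS_LAMBDA, NEEDS_PCA))
  if (!needs_nulls) cfg$n_snps <- 0L
  build_cohort(cfg, seed = seed)
}

mc_aggregate <- function(p_mat, lambdas, config, eval, rr) {
  rows <- lapply(colnames(p_mat), function(m) {
    dplyr::mutate(estimate_rejection_rate(p_mat[, m], eval$alpha),
                  method = m, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    scenario = config$scenario, rr = rr,
    mean_lambda = if (length(lambdas)) mean(lambdas, na.rm = TRUE)
                  else NA_real_,
    .before = 1L)
  attr(out, "p_values") <- p_mat
  attr(out, "lambdas") <- lambdas
  attr(out, "alpha") <- eval$alpha
  class(out) <- c("strat_mc", class(out))
  out
}

#' Monte-Carlo false positive rate / power estimation
#'
#' Simulates `B` fresh replicate cohorts of the scenario (replicate-specific
#' seeds derived from the master seed), applies every requested strategy to
#' the DSL of each, and estimates the per-method rejection proportion at
#' level `alpha`. With `rr = 1` (no association) the result is the false
#' positive rate; with `rr > 1` it is power — the two coincide at `rr = 1`
#' by construction. The Genomic Control lambda is re-estimated per replicate
#' from that replicate's null markers and reported as the across-replicate
#' mean.
#'
#' @param scenario A [scenario_config()].
#' @param eval An [eval_config()].
#' @param rr Relative risk of the replicates (default 1, the null).
#' @return A tibble of class `strat_mc`, one row per method, with the
#'   rejection rate, its 95% CI, the null reference band, `mean_lambda`, and
#'   replicate counts. Per-replicate p-values are attached as
#'   `attr(, "p_values")`.
#' @export
run_monte_carlo <- function(scenario, eval = eval_config(), rr = 1) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(eval, "eval_config"))
  methods <- eval$methods
  p_mat <- matrix(NA_real_, eval$B, length(methods),
                  dimnames = list(NULL, methods))
  lambdas <- rep(NA_real_, eval$B)
  want_lambda <- "gc" %in% methods
  for (b in seq_len(eval$B)) {
    seed_b <- derive_seed(eval$seed, b)
    res <- withCallingHandlers(
      {
        cohort <- replicate_cohort(scenario, rr, methods, seed_b)
        run_association_tests(cohort, methods = methods, k_pcs = eval$k_pcs,
                              gc_estimator = eval$gc_estimator)
      },
      stratsim_warning = function(w) invokeRestart("muffleWarning"),
      error = function(e) {
        abort(sprintf("Replicate %d (seed %d) failed: %s", b, seed_b,
                      conditionMessage(e)), parent = e)
      })
    p_mat[b, ] <- res$p_value[match(methods, res$method)]
    if (want_lambda) lambdas[b] <- res$lambda[match("gc", res$method)]
  }
  mc_aggregate(p_mat, if (want_lambda) lambdas else numeric(0),
               scenario, eval, rr)
}

#' Power curve over a relative-risk grid
#'
#' Runs [run_monte_carlo()] at each relative risk of the evaluation grid.
#' The `rr = 1` entry equals the false positive rate — it is literally the
#' same computation.
#'
#' @param scenario A [scenario_config()].
#' @param eval An [eval_config()] whose `rr_grid` includes 1.
#' @return A tibble of class `strat_power_curve` stacking the per-rr
#'   `strat_mc` tables; a per-method monotonicity diagnostic (is the curve
#'   non-decreasing within twice the Monte-Carlo standard error?) is
#'   attached as `attr(, "monotonicity")`.
#' @export
power_curve <- function(scenario, eval = eval_config()) {
  if (!1 %in% eval$rr_grid) abort("`rr_grid` must include 1 (the null).")
  parts <- lapply(eval$rr_grid, function(rr)
    run_monte_carlo(scenario, eval, rr = rr))
  out <- dplyr::bind_rows(parts)
  mono <- out |>
    dplyr::group_by(.data$method) |>
    dplyr::arrange(.data$rr, .by_group = TRUE) |>
    dplyr::summarise(non_decreasing = all(
      diff(.data$rejection_rate) >=
        -2 * sqrt(max(.data$rejection_rate * (1 - .data$rejection_rate)) /
                    .data$B[1L])),
      .groups = "drop")
  attr(out, "monotonicity") <- mono
  class(out) <- c("strat_power_curve", "strat_mc", class(out))
  out
}

#' Case-split sweep (scenario 6)
#'
#' Evaluates the methods while the proportion `r` of cases sampled in the
#' first subpopulation varies, controls staying balanced. At the extreme
#' designs r = 0 and r = 1 (all cases in one population) it additionally
#' runs the exclusion comparison: the same replicate cohorts reduced to the
#' subpopulation that contains both cases and controls, for the methods able
#' to correct the bias.
#'
#' @param scenario A scenario-6 [scenario_config()].
#' @param r_grid Case-split proportions to sweep.
#' @param eval An [eval_config()].
#' @param rr_power Relative risk at which power is evaluated.
#' @param rrs Relative risks evaluated at every `r` (default: the null and
#'   `rr_power`).
#' @param exclusion_methods Methods evaluated on the reduced cohort.
#' @return A tibble of class `strat_sweep_r`: columns `r`, `cohort`
#'   (`"full"`/`"reduced"`), and the `strat_mc` columns.
#' @export
sweep_case_ratio <- function(scenario, r_grid = c(0, 0.25, 0.5, 0.75, 1),
                             eval = eval_config(), rr_power = 2,
                             rrs = unique(c(1, rr_power)),
                             exclusion_methods = c("eigenstrat", "reg_pcs")) {
  if (scenario$scenario != 6L) {
    abort("`sweep_case_ratio()` needs a scenario-6 configuration.")
  }
  if (any(r_grid < 0 | r_grid > 1)) abort("Field `r`: values must be in [0, 1].")
  parts <- list()
  for (r in r_grid) {
    cfg <- scenario; cfg$r <- r
    for (rr in rrs) {
      mc <- run_monte_carlo(cfg, eval, rr = rr)
      parts[[length(parts) + 1L]] <- dplyr::mutate(mc, r = r,
                                                   cohort = "full",
                                                   .before = 1L)
    }
    if (r %in% c(0, 1) && length(exclusion_methods)) {
      counts <- resolve_counts(cfg)
      both <- which(counts$cases > 0 & counts$controls > 0)
      keep_pop <- cfg$subpops[both]
      red_eval <- eval; red_eval$methods <- exclusion_methods
      p_mat <- matrix(NA_real_, eval$B, length(exclusion_methods),
                      dimnames = list(NULL, exclusion_methods))
      for (b in seq_len(eval$B)) {
        seed_b <- derive_seed(eval$seed, b)
        res <- withCallingHandlers({
          cohort <- replicate_cohort(cfg, rr_power, exclusion_methods, seed_b)
          reduced <- cohort_subset(cohort, keep_pop)
          run_association_tests(reduced, methods = exclusion_methods,
                                k_pcs = eval$k_pcs,
                                gc_estimator = eval$gc_estimator)
        }, stratsim_warning = function(w) invokeRestart("muffleWarning"))
        p_mat[b, ] <- res$p_value[match(exclusion_methods, res$method)]
      }
      mc_red <- mc_aggregate(p_mat, numeric(0), cfg, red_eval, rr_power)
      parts[[length(parts) + 1L]] <- dplyr::mutate(mc_red, r = r,
                                                   cohort = "reduced",
                                                   .before = 1L)
    }
  }
  out <- dplyr::bind_rows(parts)
  class(out) <- c("strat_sweep_r", "strat_mc", class(out))
  out
}

#' Sweep of the number of principal components
#'
#' False positive rate and power of the PC-based methods (Eigenstrat and the
#' PC-adjusted logistic regression) as the number of components included in
#' the models varies. One PCA per replicate is computed at the largest k and
#' truncated for the smaller ones.
#'
#' @param scenario A [scenario_config()].
#' @param k_grid Numbers of components to compare.
#' @param eval An [eval_config()].
#' @param rr_power Relative risk at which power is evaluated.
#' @return A tibble of class `strat_sweep_k` with columns `k_pcs`, `method`,
#'   `rr` and the rejection-rate columns.
#' @export
sweep_num_components <- function(scenario, k_grid = c(1, 2, 5, 10, 20, 50),
                                 eval = eval_config(), rr_power = 2) {
  n_total <- sum(resolve_counts(scenario)$cases) +
    sum(resolve_counts(scenario)$controls)
  if (max(k_grid) >= n_total - 2L) {
    abort("`k_grid` maximum must be below the cohort size minus 2.")
  }
  k_max <- as.integer(max(k_grid))
  parts <- list()
  for (rr in unique(c(1, rr_power))) {
    p_arr <- array(NA_real_,
                   dim = c(eval$B, length(k_grid), 2L),
                   dimnames = list(NULL, paste0("k", k_grid),
                                   c("eigenstrat", "reg_pcs")))
    for (b in seq_len(eval$B)) {
      seed_b <- derive_seed(eval$seed, b)
      withCallingHandlers({
        cohort <- replicate_cohort(scenario, rr, "reg_pcs", seed_b,
                                   force_nulls = TRUE)
        basis <- pca_genotypes(cohort$genotypes, k = k_max)
        for (ki in seq_along(k_grid)) {
          k <- k_grid[ki]
          eig <- eigenstrat_test(cohort$dsl, cohort$phenotype, basis, k = k)
          reg <- adjusted_logistic_test(cohort$dsl, cohort$phenotype, "pcs",
                                        cohort, basis, k = k)
          p_arr[b, ki, "eigenstrat"] <- eig$p_value
          p_arr[b, ki, "reg_pcs"] <- reg$p_value
        }
      }, stratsim_warning = function(w) invokeRestart("muffleWarning"))
    }
    for (ki in seq_along(k_grid)) {
      for (m in c("eigenstrat", "reg_pcs")) {
        frag <- estimate_rejection_rate(p_arr[, ki, m], eval$alpha)
        parts[[length(parts) + 1L]] <- dplyr::mutate(
          frag, scenario = scenario$scenario, method = m, rr = rr,
          k_pcs = k_grid[ki], .before = 1L)
      }
    }
  }
  out <- dplyr::bind_rows(parts)
  class(out) <- c("strat_sweep_k", class(out))
  out
}

#' Evaluation at a rare disease susceptibility locus
#'
#' Repeats the scenario evaluation with the DSL minor allele frequency set
#' to a low value (default 0.01) and attaches the comparison against the
#' common-MAF run: all methods are expected to keep their calibration
#' behavior but lose power.
#'
#' @param scenario A [scenario_config()] (typically scenario 4 or 5).
#' @param eval An [eval_config()].
#' @param low_maf Rare-variant DSL MAF.
#' @param rr_power Relative risk at which power is compared.
#' @return A tibble of class `strat_lowmaf` with a `dsl_maf` column
#'   distinguishing the two runs.
#' @export
low_maf_eval <- function(scenario, eval = eval_config(), low_maf = 0.01,
                         rr_power = 2) {
  run_at <- function(maf) {
    cfg <- scenario
    cfg$disease <- disease_model(
      maf = maf, prevalence = cfg$disease$prevalence, rr = cfg$disease$rr,
      mode = cfg$disease$mode, F = cfg$disease$F,
      prevalence_by_pop = cfg$disease$prevalence_by_pop)
    dplyr::bind_rows(
      dplyr::mutate(run_monte_carlo(cfg, eval, rr = 1), dsl_maf = maf,
                    .before = 1L),
      dplyr::mutate(run_monte_carlo(cfg, eval, rr = rr_power), dsl_maf = maf,
                    .before = 1L))
  }
  out <- dplyr::bind_rows(run_at(low_maf), run_at(scenario$disease$maf))
  class(out) <- c("strat_lowmaf", "strat_mc", class(out))
  out
}
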