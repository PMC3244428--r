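# Association strategies compared on simulated cohorts: trend test, Genomic
# Control, PCA/Eigenstrat, adjusted logistic and linear regressions,
# population-label estimation, and Fisher/Stouffer meta-analyses.

test_outcome <- function(method, statistic, df, p_value, lambda = NA_real_,
                         k_pcs = NA_integer_, note = NA_character_) {
  tibble::tibble(method = method, statistic = as.numeric(statistic),
                 df = as.numeric(df), p_value = as.numeric(p_value),
                 lambda = lambda, k_pcs = as.integer(k_pcs), note = note)
}

#' Armitage trend test
#'
#' With dosage scores (0, 1, 2) the trend statistic is `T = N * rho^2`, where
#' `rho` is the Pearson correlation between dosage and the binary phenotype;
#' under the null of no association `T` follows a chi-square distribution
#' with 1 df.
#'
#' @param dosages Dosage vector (0/1/2).
#' @param phenotype Binary vector (1 = case).
#' @return A one-row tibble with `method`, `statistic`, `df`, `p_value`.
#' @export
armitage_trend_test <- function(dosages, phenotype) {
  n <- length(dosages)
  if (n < 2L) abort("Need at least 2 individuals.")
  if (length(unique(phenotype)) < 2L) {
    abort("Undefined test: both phenotype classes must be present.")
  }
  if (stats::var(dosages) == 0) {
    abort("Undefined test: dosage is constant.")
  }
  rho <- cor(dosages, phenotype)
  t_stat <- n * rho^2
  test_outcome("trend", t_stat, 1, pchisq(t_stat, 1, lower.tail = FALSE))
}

#' Trend statistics for every SNP of a matrix
#'
#' Vectorized `N * cor^2` trend statistics, used to estimate the Genomic
#' Control inflation factor from the null markers. Constant SNPs give `NA`.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param phenotype Binary vector.
#' @return Numeric vector of chi-square(1) statistics.
#' @export
trend_statistics <- function(genotypes, phenotype) {
  cpp_trend_statistics(genotypes, as.integer(phenotype))
}

#' Genomic Control inflation factor
#'
#' `lambda = median(statistics) / 0.4549364` (the chi-square(1) median) for
#' the median estimator, or `mean(statistics) / 1` for the mean estimator.
#' No clipping at 1 is applied: an underestimated lambda is informative (it
#' is exactly how Genomic Control turns anti-conservative under weak
#' structure), though `clip = TRUE` is available for comparison.
#'
#' @param statistics Chi-square(1) trend statistics of null markers.
#' @param estimator `"median"` (default) or `"mean"`.
#' @param clip If `TRUE`, lambda is floored at 1.
#' @return A list of class `gc_estimate` with `lambda`, `estimator`, `n`.
#' @export
gc_lambda <- function(statistics, estimator = c("median", "mean"),
                      clip = FALSE) {
  estimator <- match.arg(estimator)
  statistics <- statistics[!is.na(statistics)]
  if (!length(statistics)) abort("No statistics supplied to `gc_lambda()`.")
  if (length(statistics) < 100L) {
    warn(sprintf(
      "Genomic Control lambda estimated from only %d statistics; >= 100 recommended.",
      length(statistics)), class = "stratsim_warning")
  }
  lambda <- switch(estimator,
                   median = median(statistics) / CHISQ1_MEDIAN,
                   mean = mean(statistics))
  if (clip) lambda <- max(lambda, 1)
  structure(list(lambda = lambda, estimator = estimator,
                 n = length(statistics)),
            class = "gc_estimate")
}

#' @export
print.gc_estimate <- function(x, ...) {
  cat(sprintf("<gc_estimate> lambda = %.4f (%s of %d statistics)\n",
              x$lambda, x$estimator, x$n))
  invisible(x)
}

#' Genomic Control corrected test
#'
#' Divides the trend statistic by the inflation factor and refers the result
#' to the chi-square(1) distribution.
#'
#' @param trend_outcome A row from [armitage_trend_test()] (or any outcome
#'   with a chi-square(1) `statistic`).
#' @param gc A [gc_lambda()] estimate (or a bare positive number).
#' @return A one-row outcome tibble, with the lambda used attached.
#' @export
genomic_control_test <- function(trend_outcome, gc) {
  lambda <- if (inherits(gc, "gc_estimate")) gc$lambda else as.numeric(gc)
  if (!is.finite(lambda) || lambda <= 0) abort("`lambda` must be > 0.")
  stat <- trend_outcome$statistic / lambda
  test_outcome("gc", stat, 1, pchisq(stat, 1, lower.tail = FALSE),
               lambda = lambda)
}

#' Genotype principal components
#'
#' Each SNP column is mean-centered and divided by
#' `sqrt(g/2 * (1 - g/2))` with `g` the column mean dosage (the binomial
#' standard deviation at the estimated allele frequency), then the top `k`
#' left singular vectors of the normalized matrix are extracted from its
#' individual-by-individual cross-product. For small cohorts the full
#' eigendecomposition is used; for larger ones a randomized subspace
#' iteration (block power method with Rayleigh-Ritz extraction, the
#' standard approach of large-scale genotype PCA) computes the leading
#' eigenpairs. Constant columns are dropped with a warning. The DSL is
#' never part of this matrix: structure is always estimated from the null
#' markers only.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param k Number of axes to retain (`k >= 1`, less than the matrix rank).
#' @param n_extra Number of additional leading eigenpairs kept beyond `k`
#'   (used by the Tracy-Widom axis test).
#' @param exact Force the full eigendecomposition.
#' @return An object of class `pca_basis`: `axes` (individuals x k, unit
#'   norm), `eigenvalues` (top k), `top_eigenvalues` (all leading
#'   eigenvalues computed), `spectrum_sum` (trace of the cross-product,
#'   i.e. the sum of all eigenvalues), `n_nonzero` (rank), `n_snps_used`,
#'   `column_stats`.
#' @export
pca_genotypes <- function(genotypes, k = 5, n_extra = 10L, exact = NULL) {
  k <- check_count(k, "k", min = 1L)
  norm <- cpp_normalize_genotypes(genotypes)
  if (!all(norm$keep)) {
    warn(sprintf("Dropping %d constant SNP column(s) before PCA.",
                 sum(!norm$keep)), class = "stratsim_warning")
  }
  x <- norm$x[, norm$keep, drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  if (k >= min(n, p)) {
    abort(sprintf("`k` = %d must be smaller than the matrix rank (<= %d).",
                  k, min(n, p) - 1L))
  }
  cp <- tcrossprod(x) / p
  rank <- min(n - 1L, p)
  q <- min(k + n_extra, rank)
  exact <- exact %||% (n <= 400L || q > n / 3)
  if (exact) {
    ev <- eigen(cp, symmetric = TRUE)
    vals <- pmax(ev$values, 0)
    top_vals <- vals[seq_len(q)]
    vectors <- ev$vectors[, seq_len(q), drop = FALSE]
    n_nonzero <- sum(vals > 1e-12)
  } else {
    re <- randomized_eigen(cp, q)
    top_vals <- pmax(re$values, 0)
    vectors <- re$vectors
    n_nonzero <- rank
  }
  axes <- vectors[, seq_len(k), drop = FALSE]
  colnames(axes) <- paste0("PC", seq_len(k))
  structure(
    list(axes = axes, eigenvalues = top_vals[seq_len(k)],
         top_eigenvalues = top_vals,
         spectrum_sum = sum(diag(cp)), n_nonzero = n_nonzero,
         k = k, n_snps_used = p,
         column_stats = list(mean = norm$mean, scale = norm$scale,
                             keep = norm$keep)),
    class = "pca_basis"
  )
}

# Block power iteration with Rayleigh-Ritz extraction for the leading
# eigenpairs of a dense symmetric PSD matrix. Enough iterations for the
# well-separated structure eigenvalues; bulk (noise) directions need no
# precision here.
randomized_eigen <- function(cp, q, iters = 8L) {
  n <- nrow(cp)
  qmat <- qr.Q(qr(matrix(stats::rnorm(n * q), n, q)))
  for (i in seq_len(iters)) qmat <- qr.Q(qr(cp %*% qmat))
  small <- crossprod(qmat, cp %*% qmat)
  eb <- eigen((small + t(small)) / 2, symmetric = TRUE)
  list(values = eb$values, vectors = qmat %*% eb$vectors)
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> %d axes over %d individuals (%d SNPs used)\n",
              x$k, nrow(x$axes), x$n_snps_used))
  cat("  leading eigenvalues:",
      paste(sprintf("%.3f", head(x$eigenvalues, 5)), collapse = ", "), "\n")
  invisible(x)
}

# Residualize a vector on the basis axes (plus intercept) by least squares.
residualize <- function(y, axes) {
  if (is.null(axes) || ncol(axes) == 0L) return(y - mean(y))
  qr_a <- qr(cbind(1, axes))
  qr.resid(qr_a, y)
}

#' Eigenstrat association test
#'
#' Residualizes both the candidate dosage and the phenotype on the top `k`
#' principal components (ordinary least squares), then refers
#' `(N - k - 1) * rho^2` of the residual correlation to chi-square(1).
#' With `k = 0` this reduces to `(N - 1)/N` times the trend statistic.
#'
#' @param dosages Dosage vector at the candidate locus.
#' @param phenotype Binary phenotype.
#' @param basis A [pca_genotypes()] basis computed on the same individuals
#'   (or `NULL` for `k = 0`).
#' @param k Number of axes to use (defaults to all axes in the basis).
#' @return A one-row outcome tibble.
#' @export
eigenstrat_test <- function(dosages, phenotype, basis = NULL, k = NULL) {
  axes <- if (is.null(basis)) NULL else basis$axes
  if (!is.null(k) && !is.null(axes)) {
    if (k > ncol(axes)) abort("`k` exceeds the number of axes in the basis.")
    axes <- axes[, seq_len(k), drop = FALSE]
  }
  k_used <- if (is.null(axes)) 0L else ncol(axes)
  n <- length(dosages)
  if (n - k_used - 1L < 1L) abort("Too few individuals for this many axes.")
  rg <- residualize(as.numeric(dosages), axes)
  ry <- residualize(as.numeric(phenotype), axes)
  tol_g <- 1e-8 * (stats::sd(dosages) + 1e-300)
  tol_y <- 1e-8 * (stats::sd(phenotype) + 1e-300)
  if (stats::sd(rg) <= tol_g || stats::sd(ry) <= tol_y) {
    return(test_outcome("eigenstrat", 0, 1, 1, k_pcs = k_used,
                        note = "degenerate residual"))
  }
  rho <- cor(rg, ry)
  stat <- (n - k_used - 1L) * rho^2
  test_outcome("eigenstrat", stat, 1, pchisq(stat, 1, lower.tail = FALSE),
               k_pcs = k_used)
}

# Tracy-Widom (GOE) critical values for the axis-significance test.
TW_CRITICAL <- c("0.05" = 0.9793, "0.01" = 2.0234, "0.001" = 3.2724)

# Count statistically significant leading axes: the largest remaining
# eigenvalue, normalized by the remaining spectrum mass, is referred to the
# Tracy-Widom (GOE) edge distribution with half-integer finite-size
# centering; the top eigenvalue is then removed and the test repeated.
# The marker count is known exactly here (unlinked SNPs by construction).
count_significant_axes <- function(top_values, spectrum_sum, n_nonzero,
                                   n_snps, level = 0.05) {
  key <- as.character(level)
  if (!key %in% names(TW_CRITICAL)) {
    abort("Tracy-Widom level must be one of 0.05, 0.01, 0.001.")
  }
  crit <- TW_CRITICAL[[key]]
  vals <- top_values[top_values > 1e-12]
  n <- n_snps
  s1 <- spectrum_sum
  m <- n_nonzero
  n_sig <- 0L
  for (i in seq_along(vals)) {
    if (m < 3L || s1 <= 0) break
    l <- m * vals[i] / s1
    a <- sqrt(n - 0.5) + sqrt(m - 0.5)
    mu <- a^2 / n
    sig <- (a / n) * (1 / sqrt(n - 0.5) + 1 / sqrt(m - 0.5))^(1 / 3)
    tw <- (l - mu) / sig
    if (is.na(tw) || tw < crit) break
    n_sig <- n_sig + 1L
    s1 <- s1 - vals[i]
    m <- m - 1L
  }
  n_sig
}

#' Estimate population labels from the principal components
#'
#' The number of clusters is the number of Tracy-Widom-significant axes plus
#' one; k-means (multiple restarts) on the significant axes assigns hard
#' labels, and soft membership probabilities are the normalized inverse
#' squared distances to the cluster centroids. When no axis is significant a
#' single cluster is returned (a homogeneous cohort).
#'
#' @param basis A [pca_genotypes()] basis.
#' @param level Tracy-Widom significance level (0.05, 0.01 or 0.001).
#' @param max_clusters Safety cap on the number of clusters.
#' @return An object of class `label_estimate`: `labels` (factor),
#'   `probabilities` (individuals x clusters, rows sum to 1), `n_clusters`,
#'   `n_significant_axes`.
#' @export
estimate_population_labels <- function(basis, level = 0.05,
                                       max_clusters = 10L) {
  stopifnot(inherits(basis, "pca_basis"))
  n <- nrow(basis$axes)
  n_sig <- count_significant_axes(basis$top_eigenvalues, basis$spectrum_sum,
                                  basis$n_nonzero, basis$n_snps_used, level)
  n_sig <- min(n_sig, ncol(basis$axes), max_clusters - 1L)
  if (n_sig == 0L) {
    return(structure(
      list(labels = factor(rep("cluster1", n)),
           probabilities = matrix(1, n, 1,
                                  dimnames = list(NULL, "cluster1")),
           n_clusters = 1L, n_significant_axes = 0L),
      class = "label_estimate"))
  }
  axes <- basis$axes[, seq_len(n_sig), drop = FALSE]
  km <- kmeans(axes, centers = n_sig + 1L, nstart = 20L, iter.max = 100L)
  d2 <- vapply(seq_len(nrow(km$centers)), function(c_i) {
    rowSums((axes - matrix(km$centers[c_i, ], n, n_sig, byrow = TRUE))^2)
  }, numeric(n))
  inv <- 1 / pmax(d2, 1e-12)
  probs <- inv / rowSums(inv)
  colnames(probs) <- paste0("cluster", seq_len(ncol(probs)))
  labels <- factor(colnames(probs)[max.col(probs)], levels = colnames(probs))
  structure(
    list(labels = labels, probabilities = probs,
         n_clusters = ncol(probs), n_significant_axes = n_sig),
    class = "label_estimate"
  )
}

#' @export
print.label_estimate <- function(x, ...) {
  cat(sprintf("<label_estimate> %d cluster(s) from %d significant axis/axes\n",
              x$n_clusters, x$n_significant_axes))
  print(table(x$labels))
  invisible(x)
}

# Build the covariate matrix for an adjusted regression. Discrete labels are
# one-hot encoded dropping a reference level; constant covariates vanish.
covariates_for <- function(source, cohort, basis = NULL, labels_est = NULL,
                           k = 5L) {
  pc_block <- function() {
    if (is.null(basis)) abort("Covariate source needs a PCA basis.")
    kk <- min(k, ncol(basis$axes))
    basis$axes[, seq_len(kk), drop = FALSE]
  }
  label_block <- function(lab) {
    lab <- droplevels(as.factor(lab))
    if (nlevels(lab) < 2L) return(NULL)
    stats::model.matrix(~lab)[, -1L, drop = FALSE]
  }
  real_block <- function() {
    if (isTRUE(cohort$admixed)) {
      # For admixed cohorts the true labels are continuous ancestry
      # proportions; drop the last column (rows sum to 1).
      a <- cohort$ancestry
      a[, -ncol(a), drop = FALSE]
    } else {
      label_block(cohort$labels)
    }
  }
  est_block <- function() {
    if (is.null(labels_est)) abort("Covariate source needs estimated labels.")
    label_block(labels_est$labels)
  }
  out <- switch(source,
    pcs = pc_block(),
    real_labels = real_block(),
    estimated_labels = est_block(),
    probabilities = {
      if (is.null(labels_est)) abort("Covariate source needs estimated labels.")
      p <- labels_est$probabilities
      if (ncol(p) < 2L) NULL else p[, -ncol(p), drop = FALSE]
    },
    labels_plus_pcs = {
      lb <- est_block()
      if (is.null(lb)) pc_block() else cbind(lb, pc_block())
    },
    none = NULL,
    abort(sprintf("Unknown covariate source '%s'.", source))
  )
  if (!is.null(out)) {
    keep <- apply(out, 2L, function(v) stats::sd(v) > 0)
    out <- out[, keep, drop = FALSE]
    if (ncol(out) == 0L) out <- NULL
  }
  out
}

# Shared engine for the adjusted logistic/linear tests. The dosage enters
# as the last model term so that aliasing with a confounded covariate is
# detected on the dosage coefficient itself.
adjusted_test <- function(dosages, phenotype, covariates, family,
                          method_label, k_pcs = NA_integer_) {
  df <- if (is.null(covariates)) {
    data.frame(row.names = seq_along(dosages))
  } else {
    as.data.frame(covariates)
  }
  names(df) <- make.names(names(df), unique = TRUE)
  cov_names <- names(df)
  df$.g <- as.numeric(dosages)
  df$.y <- as.numeric(phenotype)
  f1 <- stats::as.formula(paste(".y ~", paste(c(cov_names, ".g"),
                                              collapse = " + ")))
  f0 <- stats::as.formula(paste(".y ~", if (length(cov_names))
    paste(cov_names, collapse = " + ") else "1"))
  if (family == "binomial") {
    separation <- FALSE
    fit1 <- withCallingHandlers(
      glm(f1, family = binomial(), data = df),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (is.na(coef(fit1)[".g"])) {
      abort("Rank deficiency: a covariate is confounded 1:1 with the dosage.")
    }
    # glm can drift to a separated solution without warning: flag fits whose
    # linear predictor has escaped to the boundary
    if (!fit1$converged || max(abs(stats::predict(fit1))) > 15) {
      separation <- TRUE
    }
    if (separation) {
      return(test_outcome(method_label, NA_real_, 1, NA_real_, k_pcs = k_pcs,
                          note = "separation"))
    }
    fit0 <- glm(f0, family = binomial(), data = df)
    stat <- fit0$deviance - fit1$deviance
    test_outcome(method_label, stat, 1,
                 pchisq(stat, 1, lower.tail = FALSE), k_pcs = k_pcs)
  } else {
    fit <- lm(f1, data = df)
    if (is.na(coef(fit)[".g"])) {
      abort("Rank deficiency: a covariate is confounded 1:1 with the dosage.")
    }
    sm <- summary(fit)$coefficients
    tval <- sm[".g", "t value"]
    pval <- sm[".g", "Pr(>|t|)"]
    test_outcome(method_label, tval^2, 1, pval, k_pcs = k_pcs)
  }
}

#' Adjusted logistic regression test
#'
#' Logistic model `phenotype ~ dosage + covariates`, with the dosage
#' coefficient tested by a 1-df likelihood-ratio test. Covariates come from
#' one of five sources: the top principal components, the true population
#' labels (ancestry proportions for admixed cohorts), estimated population
#' labels, estimated membership probabilities, or estimated labels combined
#' with the principal components.
#'
#' @param dosages Dosage vector at the candidate locus.
#' @param phenotype Binary phenotype.
#' @param covariate_source One of `"pcs"`, `"real_labels"`,
#'   `"estimated_labels"`, `"probabilities"`, `"labels_plus_pcs"`, `"none"`.
#' @param cohort The `strat_cohort` providing labels/ancestry context.
#' @param basis Optional [pca_genotypes()] basis (required by PC sources).
#' @param labels_est Optional [estimate_population_labels()] result
#'   (required by estimated-label sources).
#' @param k Number of principal components used by PC sources.
#' @return A one-row outcome tibble; perfect separation gives `p_value = NA`
#'   with `note = "separation"`.
#' @export
adjusted_logistic_test <- function(dosages, phenotype,
                                   covariate_source = "pcs", cohort = NULL,
                                   basis = NULL, labels_est = NULL, k = 5L) {
  covs <- covariates_for(covariate_source, cohort, basis, labels_est, k)
  k_pcs <- if (covariate_source %in% c("pcs", "labels_plus_pcs"))
    min(k, if (is.null(basis)) k else ncol(basis$axes)) else NA_integer_
  adjusted_test(dosages, phenotype, covs, "binomial",
                paste0("reg_", switch(covariate_source,
                                      pcs = "pcs", real_labels = "real",
                                      estimated_labels = "est",
                                      probabilities = "prob",
                                      labels_plus_pcs = "est_pcs",
                                      none = "none")),
                k_pcs = k_pcs)
}

#' Adjusted linear regression test
#'
#' Ordinary least squares of the binary phenotype on dosage + covariates,
#' with a t-test on the dosage coefficient; the computationally cheap
#' alternative to the logistic model.
#'
#' @inheritParams adjusted_logistic_test
#' @return A one-row outcome tibble.
#' @export
adjusted_linear_test <- function(dosages, phenotype, covariate_source = "pcs",
                                 cohort = NULL, basis = NULL,
                                 labels_est = NULL, k = 5L) {
  covs <- covariates_for(covariate_source, cohort, basis, labels_est, k)
  k_pcs <- if (covariate_source %in% c("pcs", "labels_plus_pcs"))
    min(k, if (is.null(basis)) k else ncol(basis$axes)) else NA_integer_
  adjusted_test(dosages, phenotype, covs, "gaussian",
                paste0("linear_", switch(covariate_source,
                                         pcs = "pcs", real_labels = "real",
                                         estimated_labels = "est",
                                         probabilities = "prob",
                                         labels_plus_pcs = "est_pcs",
                                         none = "none")),
                k_pcs = k_pcs)
}

# Per-stratum trend tests used by both meta-analyses. Strata with a single
# phenotype class or constant dosage are dropped with a warning.
stratum_trend_tests <- function(dosages, phenotype, strata) {
  strata <- droplevels(as.factor(strata))
  out <- list()
  for (s in levels(strata)) {
    i <- strata == s
    if (length(unique(phenotype[i])) < 2L || stats::var(dosages[i]) == 0) {
      warn(sprintf("Dropping stratum '%s' (single phenotype class or constant dosage).", s),
           class = "stratsim_warning")
      next
    }
    n <- sum(i)
    rho <- cor(dosages[i], phenotype[i])
    out[[s]] <- list(n = n, rho = rho, stat = n * rho^2,
                     p = pchisq(n * rho^2, 1, lower.tail = FALSE))
  }
  if (!length(out)) abort("No usable stratum for the meta-analysis.")
  out
}

#' Fisher meta-analysis across strata
#'
#' Trend tests within each stratum, combined as `X = -2 sum(log p_k)`,
#' referred to chi-square with `2 x (number of strata)` df. Exact zero
#' p-values are clamped at `p_floor` with a warning.
#'
#' @param dosages,phenotype Candidate dosage and binary phenotype.
#' @param strata Stratum labels (real or estimated population labels).
#' @param p_floor Clamp for zero p-values.
#' @return A one-row outcome tibble.
#' @export
fisher_meta <- function(dosages, phenotype, strata, p_floor = 1e-300) {
  tests <- stratum_trend_tests(dosages, phenotype, strata)
  p <- vapply(tests, `[[`, numeric(1), "p")
  if (any(p < p_floor)) {
    warn("Clamping zero p-value(s) at the configured floor.", class = "stratsim_warning")
    p <- pmax(p, p_floor)
  }
  x <- -2 * sum(log(p))
  df <- 2 * length(p)
  test_outcome("meta_fisher", x, df, pchisq(x, df, lower.tail = FALSE))
}

#' Stouffer Z meta-analysis across strata
#'
#' Signed per-stratum z-scores (sign = direction of the allele effect)
#' combined with square-root-of-size weights:
#' `Z = sum(w_k z_k) / sqrt(sum(w_k^2))`, two-sided normal p-value.
#'
#' @inheritParams fisher_meta
#' @return A one-row outcome tibble.
#' @export
stouffer_meta <- function(dosages, phenotype, strata) {
  tests <- stratum_trend_tests(dosages, phenotype, strata)
  z <- vapply(tests, function(t) {
    sign(t$rho) * qnorm(t$p / 2, lower.tail = FALSE)
  }, numeric(1))
  w <- sqrt(vapply(tests, `[[`, numeric(1), "n"))
  if (sum(w^2) == 0) abort("Zero total weight in Stouffer combination.")
  zc <- sum(w * z) / sqrt(sum(w^2))
  test_outcome("meta_stouffer", zc, 1, 2 * pnorm(-abs(zc)))
}

# Which methods need the null-SNP matrix (lambda and/or PCA)?
NEEDS_LAMBDA <- "gc"
NEEDS_PCA <- c("eigenstrat", "reg_pcs", "reg_est", "reg_prob", "reg_est_pcs",
               "linear_pcs")

#' All association strategies on one cohort
#'
#' Applies the selected strategies to the cohort's DSL, sharing the expensive
#' intermediates (per-SNP trend statistics for the Genomic Control lambda,
#' one PCA of the null markers, one label estimation) across methods.
#'
#' Available methods: `trend`, `gc`, `eigenstrat`, `reg_pcs`, `reg_real`,
#' `reg_est`, `reg_prob`, `reg_est_pcs`, `linear_pcs`, `meta_fisher`,
#' `meta_stouffer`. The default set is the panel of strategies compared in
#' the package's evaluation.
#'
#' @param cohort A `strat_cohort`.
#' @param methods Character vector of method labels.
#' @param k_pcs Number of principal components for PC-based methods.
#' @param gc_estimator `"median"` or `"mean"` lambda estimator.
#' @param tw_level Tracy-Widom level for the label estimation.
#' @param meta_strata `"auto"` (true labels when available, estimated
#'   otherwise), `"real"`, or `"estimated"`.
#' @return A tibble of class `strat_assoc`, one row per method, with columns
#'   `method`, `statistic`, `df`, `p_value`, `lambda`, `k_pcs`, `note`.
#' @export
run_association_tests <- function(cohort,
                                  methods = c("trend", "gc", "eigenstrat",
                                              "reg_pcs", "reg_real",
                                              "reg_est", "meta_fisher"),
                                  k_pcs = 5L, gc_estimator = "median",
                                  tw_level = 0.05, meta_strata = "auto") {
  stopifnot(inherits(cohort, "strat_cohort"))
  y <- cohort$phenotype
  g <- cohort$dsl
  needs_nulls <- any(methods %in% c(NEEDS_LAMBDA, NEEDS_PCA)) ||
    (meta_strata == "estimated")
  if (needs_nulls && ncol(cohort$genotypes) == 0L) {
    abort("This method set needs null-SNP genotypes, but the cohort has none.")
  }
  trend <- armitage_trend_test(g, y)
  gc_est <- NULL
  if (any(methods %in% NEEDS_LAMBDA)) {
    stats_null <- trend_statistics(cohort$genotypes, y)
    gc_est <- gc_lambda(stats_null, estimator = gc_estimator)
  }
  basis <- NULL
  labels_est <- NULL
  if (any(methods %in% NEEDS_PCA) || meta_strata == "estimated") {
    basis <- pca_genotypes(cohort$genotypes, k = k_pcs)
    if (any(methods %in% c("reg_est", "reg_prob", "reg_est_pcs")) ||
        meta_strata %in% c("estimated")) {
      labels_est <- estimate_population_labels(basis, level = tw_level)
    }
  }
  strata <- switch(meta_strata,
                   auto = cohort$labels,
                   real = cohort$labels,
                   estimated = labels_est$labels,
                   abort("`meta_strata` must be auto, real or estimated."))
  rows <- lapply(methods, function(m) {
    switch(m,
      trend = trend,
      gc = genomic_control_test(trend, gc_est),
      eigenstrat = eigenstrat_test(g, y, basis),
      reg_pcs = adjusted_logistic_test(g, y, "pcs", cohort, basis, k = k_pcs),
      reg_real = adjusted_logistic_test(g, y, "real_labels", cohort),
      reg_est = adjusted_logistic_test(g, y, "estimated_labels", cohort,
                                       basis, labels_est),
      reg_prob = adjusted_logistic_test(g, y, "probabilities", cohort,
                                        basis, labels_est),
      reg_est_pcs = adjusted_logistic_test(g, y, "labels_plus_pcs", cohort,
                                           basis, labels_est, k = k_pcs),
      linear_pcs = adjusted_linear_test(g, y, "pcs", cohort, basis,
                                        k = k_pcs),
      meta_fisher = fisher_meta(g, y, strata),
      meta_stouffer = stouffer_meta(g, y, strata),
      abort(sprintf("Unknown method '%s'.", m))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$method <- methods
  class(out) <- c("strat_assoc", class(out))
  out
}
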