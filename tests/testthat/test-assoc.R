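test_that("trend test matches the textbook 2x3 contingency formula", {
  cases <- c(10, 20, 10); controls <- c(20, 15, 5)
  v <- counts_to_vectors(cases, controls)
  res <- armitage_trend_test(v$dosage, v$phenotype)
  expect_equal(res$statistic, trend_oracle_2x3(cases, controls),
               tolerance = 1e-9)

  set.seed(1)
  for (i in 1:20) {
    cases <- rmultinom(1, 40, c(0.3, 0.5, 0.2))[, 1]
    controls <- rmultinom(1, 40, c(0.5, 0.4, 0.1))[, 1]
    v <- counts_to_vectors(cases, controls)
    if (stats::var(v$dosage) == 0) next
    expect_equal(armitage_trend_test(v$dosage, v$phenotype)$statistic,
                 trend_oracle_2x3(cases, controls), tolerance = 1e-9)
  }
})

test_that("trend test boundary cases behave", {
  # identical genotype distributions: zero statistic
  v <- counts_to_vectors(c(10, 20, 10), c(10, 20, 10))
  res <- armitage_trend_test(v$dosage, v$phenotype)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # perfect correlation: T = N
  v2 <- list(dosage = c(rep(2, 10), rep(0, 10)),
             phenotype = rep(c(1L, 0L), each = 10))
  expect_equal(armitage_trend_test(v2$dosage, v2$phenotype)$statistic, 20)

  expect_error(armitage_trend_test(rep(1, 10), rep(c(0, 1), 5)), "constant")
  expect_error(armitage_trend_test(0:9, rep(1L, 10)), "phenotype")
})

test_that("genomic control lambda estimators behave as defined", {
  expect_equal(gc_lambda(rep(0.4549364, 200))$lambda, 1.0)
  stats <- rchisq(500, 1)
  expect_equal(gc_lambda(stats * 3)$lambda, 3 * gc_lambda(stats)$lambda)
  set.seed(2)
  draws <- rchisq(5500, 1)
  expect_lt(abs(gc_lambda(draws)$lambda - 1), 0.05)
  expect_lt(abs(gc_lambda(draws, estimator = "mean")$lambda - 1), 0.05)
  expect_warning(gc_lambda(rchisq(50, 1)), "recommended")
  expect_error(gc_lambda(numeric(0)), "No statistics")
})

test_that("genomic control correction rescales the chi-square", {
  trend <- tibble::tibble(statistic = 3.8415)
  expect_equal(genomic_control_test(trend, 1)$p_value, 0.05,
               tolerance = 1e-4)
  corrected <- genomic_control_test(trend, 2)
  expect_equal(corrected$statistic, 1.92075)
  expect_equal(corrected$p_value, pchisq(1.92075, 1, lower.tail = FALSE))
  # lambda < 1 is anti-conservative: statistic grows
  expect_gt(genomic_control_test(trend, 0.8)$statistic, 3.8415)
  # lambda = 1 is a no-op
  expect_identical(genomic_control_test(trend, 1)$statistic, 3.8415)
})

test_that("PCA normalization centers columns and separates populations", {
  fm <- founder_model(n_snps = 1500, fst = c(0.1, 0.1), subpops = c("a", "b"))
  ff <- simulate_founder_frequencies(fm, seed = 3)
  g <- rbind(sample_founder_genotypes(ff$freqs[, 1], 120, seed = 4),
             sample_founder_genotypes(ff$freqs[, 2], 120, seed = 5))
  norm <- cpp_normalize_genotypes(g)
  expect_lt(max(abs(colMeans(norm$x))), 1e-10)
  basis <- pca_genotypes(g, k = 3)
  grp <- rep(c(0, 1), each = 120)
  expect_gt(abs(cor(basis$axes[, 1], grp)), 0.9)
  # axes are orthogonal
  gram <- crossprod(basis$axes)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
})

test_that("PCA rejects k at or above the rank and drops constant columns", {
  g <- sample_founder_genotypes(runif(30, 0.2, 0.8), 20, seed = 6)
  expect_error(pca_genotypes(g, k = 20), "rank")
  g2 <- cbind(g, 0L)
  expect_warning(pca_genotypes(g2, k = 2), "constant")
})

test_that("eigenstrat with an empty basis reduces to the trend test", {
  set.seed(7)
  g <- rbinom(200, 2, 0.3)
  y <- rbinom(200, 1, 0.5)
  trend <- armitage_trend_test(g, y)
  eig <- eigenstrat_test(g, y, basis = NULL)
  expect_equal(eig$statistic, (199 / 200) * trend$statistic,
               tolerance = 1e-9)
})

test_that("eigenstrat removes phenotype structure aligned with an axis", {
  fm <- founder_model(n_snps = 800, fst = c(0.15, 0.15), subpops = c("a", "b"))
  ff <- simulate_founder_frequencies(fm, seed = 8)
  g <- rbind(sample_founder_genotypes(ff$freqs[, 1], 100, seed = 9),
             sample_founder_genotypes(ff$freqs[, 2], 100, seed = 10))
  basis <- pca_genotypes(g, k = 2)
  # phenotype exactly linear in axis 1: residual phenotype ~ 0
  y <- basis$axes[, 1]
  eig <- eigenstrat_test(g[, 1], y, basis)
  expect_lt(eig$statistic, 1e-10)
})

test_that("label estimation finds one cluster in homogeneous data and two under structure", {
  g0 <- sample_founder_genotypes(runif(800, 0.1, 0.5), 150, seed = 11)
  basis0 <- pca_genotypes(g0, k = 5)
  est0 <- estimate_population_labels(basis0)
  expect_equal(est0$n_clusters, 1L)

  fm <- founder_model(n_snps = 5500, fst = c(0.1, 0.1), subpops = c("a", "b"))
  ff <- simulate_founder_frequencies(fm, seed = 12)
  g <- rbind(sample_founder_genotypes(ff$freqs[, 1], 200, seed = 13),
             sample_founder_genotypes(ff$freqs[, 2], 200, seed = 14))
  basis <- pca_genotypes(g, k = 5)
  set.seed(15)
  est <- estimate_population_labels(basis)
  truth <- rep(c("a", "b"), each = 200)
  agreement <- max(table(est$labels, truth)[1, ]) +
    max(table(est$labels, truth)[2, ])
  expect_gte(agreement / 400, 0.99)
  expect_equal(rowSums(est$probabilities), rep(1, 400))
  hard <- colnames(est$probabilities)[max.col(est$probabilities)]
  expect_equal(as.character(est$labels), hard)
})

test_that("unadjusted logistic test agrees asymptotically with the trend test", {
  set.seed(16)
  g <- rbinom(3000, 2, 0.3)
  risk <- plogis(-1 + 0.12 * g)
  y <- rbinom(3000, 1, risk)
  trend <- armitage_trend_test(g, y)
  logit <- adjusted_logistic_test(g, y, "none")
  expect_lt(abs(logit$p_value - trend$p_value) /
              max(trend$p_value, 1e-12), 0.1)
})

test_that("label adjustment degenerates gracefully in one population", {
  cfg <- tiny_scenario(1, cases = 80, controls = 80, n_snps = 50)
  co <- build_cohort(cfg, seed = 17)
  with_lab <- adjusted_logistic_test(co$dsl, co$phenotype, "real_labels", co)
  without <- adjusted_logistic_test(co$dsl, co$phenotype, "none", co)
  expect_equal(with_lab$statistic, without$statistic)
})

test_that("real-label adjustment is calibrated on a discrete two-population null", {
  cfg <- tiny_scenario(4, cases = c(90, 60), controls = c(60, 90),
                       n_snps = 0, n_founders = 100)
  B <- 300
  p <- vapply(seq_len(B), function(b) {
    co <- build_cohort(cfg, seed = 1000 + b)
    adjusted_logistic_test(co$dsl, co$phenotype, "real_labels", co)$p_value
  }, numeric(1))
  rate <- mean(p <= 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / B)
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
})

test_that("perfect separation is reported, confounded dosage errors", {
  y <- rep(c(1L, 0L), each = 20)
  g <- c(rep(2L, 20), rep(0L, 20))
  res <- adjusted_logistic_test(g, y, "none")
  expect_true(is.na(res$p_value))
  expect_equal(res$note, "separation")

  co <- list(labels = factor(rep(c("a", "b"), each = 20)),
             admixed = FALSE)
  class(co) <- "strat_cohort"
  g2 <- c(rep(1L, 20), rep(0L, 20)) + 0  # dosage identical to the label
  y2 <- rep(c(0L, 1L), 20)
  expect_error(adjusted_logistic_test(g2, y2, "real_labels", co),
               "Rank deficiency")
})

test_that("linear and logistic adjusted tests agree on balanced nulls", {
  set.seed(18)
  B <- 300
  p_lin <- numeric(B)
  for (b in 1:B) {
    g <- rbinom(120, 2, 0.4)
    y <- rep(c(1L, 0L), 60)
    if (stats::var(g) == 0) { p_lin[b] <- NA; next }
    p_lin[b] <- adjusted_linear_test(g, y, "none")$p_value
  }
  p_lin <- p_lin[!is.na(p_lin)]
  # uniform p-values by KS
  expect_gt(suppressWarnings(ks.test(p_lin, "punif"))$p.value, 0.01)
})

test_that("fisher meta on one stratum is the identity on p-values", {
  set.seed(19)
  g <- rbinom(300, 2, 0.3)
  y <- rbinom(300, 1, 0.5)
  single <- fisher_meta(g, y, rep("s1", 300))
  expect_equal(single$p_value, armitage_trend_test(g, y)$p_value,
               tolerance = 1e-12)
})

test_that("fisher meta combines strata through the chi-square convolution", {
  v1 <- counts_to_vectors(c(10, 20, 10), c(14, 18, 8))
  v2 <- counts_to_vectors(c(8, 22, 10), c(12, 20, 8))
  g <- c(v1$dosage, v2$dosage)
  y <- c(v1$phenotype, v2$phenotype)
  strata <- rep(c("s1", "s2"), c(length(v1$dosage), length(v2$dosage)))
  p1 <- armitage_trend_test(v1$dosage, v1$phenotype)$p_value
  p2 <- armitage_trend_test(v2$dosage, v2$phenotype)$p_value
  combined <- fisher_meta(g, y, strata)
  x_oracle <- -2 * (log(p1) + log(p2))
  expect_equal(combined$statistic, x_oracle, tolerance = 1e-12)
  expect_equal(combined$df, 4)
  expect_equal(combined$p_value, pchisq(x_oracle, 4, lower.tail = FALSE))
  # the spec'd arithmetic: p = (0.5, 0.5) combines to X = 2.77259
  expect_equal(-2 * (log(0.5) + log(0.5)), 2.77259, tolerance = 1e-5)
})

test_that("strata without both phenotype classes are dropped with a warning", {
  v <- counts_to_vectors(c(10, 20, 10), c(14, 18, 8))
  g <- c(v$dosage, rbinom(30, 2, 0.3))
  y <- c(v$phenotype, rep(1L, 30))
  strata <- rep(c("ok", "cases_only"), c(length(v$dosage), 30))
  expect_warning(res <- fisher_meta(g, y, strata), "Dropping stratum")
  expect_equal(res$df, 2)
})

test_that("stouffer combination cancels opposite effects and matches the normal oracle", {
  # mirrored strata: same |z|, opposite direction, equal sizes
  v1 <- counts_to_vectors(c(10, 20, 30), c(30, 20, 10))
  v2 <- counts_to_vectors(c(30, 20, 10), c(10, 20, 30))
  g <- c(v1$dosage, v2$dosage)
  y <- c(v1$phenotype, v2$phenotype)
  strata <- rep(c("s1", "s2"), each = length(v1$dosage))
  res <- stouffer_meta(g, y, strata)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  # same-direction strata: Z = sqrt(2) * z, p from the normal tail
  res2 <- stouffer_meta(c(v1$dosage, v1$dosage), c(y[1:120], v1$phenotype),
                        strata)
  z1 <- qnorm(armitage_trend_test(v1$dosage, v1$phenotype)$p_value / 2,
              lower.tail = FALSE)
  expect_equal(res2$statistic, sqrt(2) * z1 * sign(res2$statistic),
               tolerance = 1e-9)
  expect_equal(res2$p_value, 2 * pnorm(-abs(res2$statistic)))
})

test_that("run_association_tests shares intermediates coherently", {
  cfg <- tiny_scenario(4, n_snps = 400, n_founders = 80)
  co <- build_cohort(cfg, seed = 20)
  res <- suppressWarnings(
    run_association_tests(co, methods = c("trend", "gc", "eigenstrat",
                                          "reg_pcs", "reg_real",
                                          "meta_fisher", "meta_stouffer"),
                          k_pcs = 3))
  expect_equal(nrow(res), 7L)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  expect_true(is.finite(res$lambda[res$method == "gc"]))
  expect_equal(res$k_pcs[res$method == "eigenstrat"], 3L)
  expect_error(
    run_association_tests(build_cohort(tiny_scenario(1, n_snps = 0), seed = 1),
                          methods = "gc"),
    "needs null-SNP")
})
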