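test_that("scenario configs validate their fields", {
  expect_error(scenario_config(7), "scenario")
  expect_error(scenario_config(6, r = 1.5), "`r`")
  expect_error(scenario_config(1, r = 0.5), "`r`")
  expect_error(scenario_config(3, cases = c(-1, 10)), "cases")
})

test_that("scenario 1 cohort bookkeeping is exact", {
  cfg <- tiny_scenario(1, cases = 50, controls = 50, n_snps = 120)
  co <- build_cohort(cfg, seed = 1)
  expect_s3_class(co, "strat_cohort")
  expect_equal(length(co$phenotype), 100L)
  expect_equal(sum(co$phenotype), 50L)
  expect_equal(ncol(co$genotypes), 120L)
  expect_equal(nlevels(co$labels), 1L)
  expect_true(all(co$genotypes %in% 0:2))
  expect_true(all(co$dsl %in% 0:2))
  expect_equal(rowSums(co$ancestry), rep(1, 100))
})

test_that("per-subpopulation counts are honored exactly", {
  cfg <- tiny_scenario(4)
  co <- build_cohort(cfg, seed = 2)
  tab <- table(co$labels, co$phenotype)
  expect_equal(unname(tab["pop1", "1"]), 36)
  expect_equal(unname(tab["pop1", "0"]), 24)
  expect_equal(unname(tab["pop2", "1"]), 24)
  expect_equal(unname(tab["pop2", "0"]), 36)
})

test_that("scenario 6 splits cases (r, 1 - r) with balanced controls", {
  cfg0 <- tiny_scenario(6, r = 0)
  co0 <- build_cohort(cfg0, seed = 3)
  tab0 <- table(co0$labels, co0$phenotype)
  # r = 0: all cases carry the second subpopulation's label
  expect_equal(unname(tab0["pop1", "1"]), 0)
  expect_equal(unname(tab0["pop2", "1"]), 60)
  expect_equal(unname(tab0[, "0"]), c(30, 30))

  cfg75 <- tiny_scenario(6, r = 0.75)
  co75 <- build_cohort(cfg75, seed = 4)
  tab75 <- table(co75$labels, co75$phenotype)
  expect_equal(unname(tab75["pop1", "1"]), 45)
  expect_equal(unname(tab75["pop2", "1"]), 15)
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- tiny_scenario(3)
  a <- build_cohort(cfg, seed = 7)
  b <- build_cohort(cfg, seed = 7)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$dsl, b$dsl)
  expect_identical(a$phenotype, b$phenotype)
})

test_that("admixed cohorts carry continuous ancestry", {
  cfg <- tiny_scenario(2, n_founders = 80)
  co <- build_cohort(cfg, seed = 5)
  expect_true(co$admixed)
  expect_true(all(co$ancestry >= 0 & co$ancestry <= 1))
  expect_equal(rowSums(co$ancestry), rep(1, length(co$phenotype)))
  # two generations of admixture spread ancestry off the pure extremes
  expect_gt(mean(co$ancestry[, 1] > 0 & co$ancestry[, 1] < 1), 0.5)
})

test_that("null SNPs carry no phenotype dependence under rr = 1", {
  cfg <- tiny_scenario(1, cases = 100, controls = 100, n_snps = 400)
  co <- build_cohort(cfg, seed = 6)
  stats <- trend_statistics(co$genotypes, co$phenotype)
  # mean trend statistic ~ chi-square(1) mean of 1
  expect_lt(abs(mean(stats, na.rm = TRUE) - 1), 0.25)
})

test_that("scenario 5 produces five differentiated subpopulations", {
  cfg <- tiny_scenario(5, n_snps = 400, n_founders = 40)
  co <- build_cohort(cfg, seed = 8)
  expect_equal(nlevels(co$labels), 5L)
  expect_equal(length(co$dsl_freqs), 5L)
  # continental differentiation far exceeds within-continent differentiation
  fst_between <- wc_fst(co$genotypes,
                        ifelse(co$labels %in% c("pop1", "pop2"), "afr",
                               ifelse(co$labels %in% c("pop3", "pop4"),
                                      "asia", "eur")))
  expect_gt(fst_between, 0.05)
})

test_that("cohort subsetting keeps rows consistent", {
  cfg <- tiny_scenario(4)
  co <- build_cohort(cfg, seed = 9)
  sub <- cohort_subset(co, "pop1")
  expect_equal(nlevels(sub$labels), 1L)
  expect_equal(length(sub$dsl), nrow(sub$genotypes))
  expect_equal(length(sub$phenotype), 60L)
  expect_error(cohort_subset(co, "nope"), "No individuals")
})

test_that("cohort export writes matching sidecar files", {
  cfg <- tiny_scenario(1, cases = 10, controls = 10, n_snps = 15)
  co <- build_cohort(cfg, seed = 10)
  prefix <- file.path(withr::local_tempdir(), "cohort")
  paths <- export_cohort(co, prefix)
  g <- load_genotype_matrix(paths[["genotypes"]], format = "dosage",
                            maf_min = 0)
  expect_identical(unname(g$genotypes), unname(co$genotypes))
  side <- read.delim(paths[["samples"]])
  expect_equal(side$phenotype, co$phenotype)
  expect_equal(side$dsl, co$dsl)
})

test_that("tidy and glance views agree with the cohort", {
  cfg <- tiny_scenario(3, n_snps = 60)
  co <- build_cohort(cfg, seed = 11)
  td <- tidy(co)
  expect_equal(nrow(td), length(co$phenotype))
  expect_true(all(c("id", "phenotype", "label", "dsl",
                    "ancestry_pop1") %in% names(td)))
  gl <- glance(co)
  expect_equal(gl$n_cases, sum(co$phenotype))
  expect_equal(gl$n_null_snps, 60L)
})
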