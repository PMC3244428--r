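test_that("founder model validates its inputs", {
  expect_error(founder_model(n_snps = 0), "n_snps")
  expect_error(founder_model(maf_range = c(0, 0.5)), "maf_range")
  expect_error(founder_model(maf_range = c(0.6, 0.7)), "maf_range")
  expect_error(founder_model(fst = 1), "FST = 1")
  expect_error(founder_model(fst = -0.1), "fst")
})

test_that("FST = 0 reproduces the ancestral frequencies exactly", {
  fm <- founder_model(n_snps = 50, fst = c(0, 0), subpops = c("a", "b"))
  ff <- simulate_founder_frequencies(fm, seed = 1)
  expect_equal(ff$freqs[, "a"], ff$ancestral)
  expect_equal(ff$freqs[, "b"], ff$ancestral)
})

test_that("ancestral frequencies respect the MAF range", {
  fm <- founder_model(n_snps = 500, maf_range = c(0.05, 0.5), fst = 0.1)
  ff <- simulate_founder_frequencies(fm, seed = 2)
  expect_true(all(ff$ancestral >= 0.05 & ff$ancestral <= 0.5))
  expect_true(all(ff$freqs > 0 & ff$freqs < 1))
})

test_that("Weir-Cockerham FST on sampled genotypes recovers the parameter", {
  fm <- founder_model(n_snps = 5500, fst = c(0.1, 0.1),
                      subpops = c("a", "b"))
  ff <- simulate_founder_frequencies(fm, seed = 3)
  ga <- sample_founder_genotypes(ff$freqs[, "a"], 100, seed = 4)
  gb <- sample_founder_genotypes(ff$freqs[, "b"], 100, seed = 5)
  est <- wc_fst(rbind(ga, gb), rep(c("a", "b"), each = 100))
  expect_true(abs(est - 0.1) < 0.02)
})

test_that("higher FST increases between-subpopulation frequency variance", {
  fm_at <- function(fst) founder_model(n_snps = 2000, fst = rep(fst, 2),
                                       subpops = c("a", "b"))
  spread <- vapply(c(0.002, 0.02, 0.2), function(fst) {
    ff <- simulate_founder_frequencies(fm_at(fst), seed = 11)
    mean((ff$freqs[, 1] - ff$freqs[, 2])^2)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("founder genotypes are HWE binomial draws of the right shape", {
  g <- sample_founder_genotypes(rep(0.5, 3), 5, seed = 6)
  expect_equal(dim(g), c(5L, 3L))
  expect_true(all(g %in% 0:2))

  g2 <- sample_founder_genotypes(0.5, 10000, seed = 7)
  expect_true(abs(mean(g2) - 1.0) < 0.03)

  # genotype frequencies converge to HWE proportions
  f <- 0.3
  g3 <- sample_founder_genotypes(f, 20000, seed = 8)
  props <- tabulate(g3 + 1L, 3L) / length(g3)
  expect_equal(props, c((1 - f)^2, 2 * f * (1 - f), f^2), tolerance = 0.02)
})

test_that("pooled FST = 0 subpopulations look like one homogeneous population", {
  fm <- founder_model(n_snps = 1000, fst = c(0, 0), subpops = c("a", "b"))
  ff <- simulate_founder_frequencies(fm, seed = 9)
  g <- rbind(sample_founder_genotypes(ff$freqs[, 1], 100, seed = 10),
             sample_founder_genotypes(ff$freqs[, 2], 100, seed = 11))
  basis <- pca_genotypes(g, k = 2)
  # leading eigenvalue stays within the Marchenko-Pastur bulk (spectrum
  # rescaled to unit mean: dosage columns have variance 2 after the
  # sqrt(p(1-p)) normalization)
  mean_val <- basis$spectrum_sum / basis$n_nonzero
  mp_edge <- (1 + sqrt(nrow(g) / basis$n_snps_used))^2
  expect_lt(basis$top_eigenvalues[1] / mean_val, mp_edge * 1.1)
  expect_equal(count_significant_axes(basis$top_eigenvalues,
                                      basis$spectrum_sum, basis$n_nonzero,
                                      basis$n_snps_used), 0L,
               ignore_attr = TRUE)
})

test_that("dosage TSV round-trips bit-exactly", {
  fm <- founder_model(n_snps = 25, fst = 0.3)
  ff <- simulate_founder_frequencies(fm, seed = 12)
  g <- sample_founder_genotypes(ff$freqs[, 1], 10, seed = 13)
  colnames(g) <- paste0("snp", 1:25)
  fp <- founder_population("test", g, allele_freqs = ff$freqs[, 1])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(fp, path)
  reloaded <- load_genotype_matrix(path, format = "dosage", maf_min = 0)
  expect_identical(unname(reloaded$genotypes), unname(g))
  expect_identical(colnames(reloaded$genotypes), colnames(g))
})

test_that("dosage reader drops SNPs under the MAF threshold and counts them", {
  g <- cbind(snpA = c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 0L, 1L),
             snpB = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))  # MAF 0.05
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(g, path)
  suppressMessages(fp <- load_genotype_matrix(path, format = "dosage",
                                              maf_min = 0.06))
  expect_equal(colnames(fp$genotypes), "snpA")
  expect_equal(attr(fp, "n_dropped"), 1L)
})

test_that("VCF reader transcribes GT fields into minor-allele dosages", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path)
  fp <- load_genotype_matrix(path, format = "vcf", maf_min = 0)
  expect_equal(dim(fp$genotypes), c(3L, 2L))
  expect_equal(unname(fp$genotypes[, "rs1"]), c(0L, 1L, 2L))
  expect_equal(fp$allele_freqs[1], 0.5)
})

test_that("VCF reader skips multi-allelic sites with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path,
                 extra_site = "1\t300\trs3\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t1/2\t0/0")
  expect_warning(fp <- load_genotype_matrix(path, format = "vcf", maf_min = 0),
                 "multi-allelic")
  expect_equal(ncol(fp$genotypes), 2L)
})

test_that("malformed dosage files raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp1\tsnp2", "0\t1", "2"), path)
  expect_error(load_genotype_matrix(path, format = "dosage"), "line 3")
})
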