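# Independent oracles and small fixtures used across the test files.

# Classical 2x3 contingency-table form of the Cochran-Armitage trend
# statistic with scores (0, 1, 2): an independent check of the N * cor^2
# implementation.
trend_oracle_2x3 <- function(case_counts, control_counts) {
  s <- c(0, 1, 2)
  n_i <- case_counts + control_counts
  R <- sum(case_counts)
  N <- sum(n_i)
  num <- N * sum(case_counts * s) - R * sum(n_i * s)
  den <- R * (N - R) * (N * sum(n_i * s^2) - sum(n_i * s)^2)
  N * num^2 / den
}

# Expand genotype count triples into dosage/phenotype vectors.
counts_to_vectors <- function(case_counts, control_counts) {
  list(
    dosage = c(rep(0:2, case_counts), rep(0:2, control_counts)),
    phenotype = c(rep(1L, sum(case_counts)), rep(0L, sum(control_counts)))
  )
}

# A small scenario configuration for fast structural tests.
tiny_scenario <- function(scenario = 1, n_snps = 200, ...) {
  defaults <- switch(scenario,
    list(cases = 60, controls = 60),
    list(cases = 60, controls = 60),
    list(cases = c(36, 24), controls = c(24, 36)),
    list(cases = c(36, 24), controls = c(24, 36)),
    list(cases = c(21, 18, 12, 6, 3), controls = c(3, 6, 12, 18, 21)),
    list(cases = 60, controls = c(30, 30)))
  args <- modifyList(c(list(scenario = scenario, n_snps = n_snps,
                            n_founders = 60), defaults), list(...))
  do.call(scenario_config, args)
}

# Minimal VCF text fixture written at test time.
write_test_vcf <- function(path, extra_site = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0",
    extra_site)
  writeLines(lines[!is.na(lines)], path)
  path
}
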