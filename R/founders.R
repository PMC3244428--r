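#' Describe a set of synthetic founder populations
#'
#' A founder model emulates the per-SNP allele-frequency pools that a panel of
#' reference populations (such as the HapMap collections) would provide: a
#' common ancestral frequency per SNP, and per-subpopulation frequencies
#' differentiated from it under the Balding-Nichols model, with the amount of
#' differentiation controlled by an FST parameter per branch.
#'
#' Two layouts are supported. A flat layout gives one FST value (or one per
#' subpopulation) for branches radiating from the common ancestor. A
#' hierarchical layout (`tree`) groups the leaves into continents: continental
#' frequencies are drawn from the ancestral frequency with `fst_between`, and
#' each leaf from its continental frequency with `fst_within`.
#'
#' @param n_snps Number of unlinked SNPs to simulate.
#' @param maf_range Length-2 vector; ancestral minor-allele frequencies are
#'   drawn uniformly in this range. Must satisfy 0 < low <= high <= 0.5.
#' @param fst FST value(s) in `[0, 1)`: a scalar shared by all subpopulations
#'   or a vector with one value per subpopulation. Ignored when `tree` is
#'   given.
#' @param subpops Character vector of subpopulation names. Defaults to
#'   `"pop1"`, ... as needed.
#' @param tree Optional hierarchical layout:
#'   `list(groups = list(<name> = c(leaves...), ...), fst_between =, fst_within =)`.
#' @return An object of class `founder_model`.
#' @export
founder_model <- function(n_snps = 5500, maf_range = c(0.05, 0.5), fst = 0,
                          subpops = NULL, tree = NULL) {
  n_snps <- check_count(n_snps, "n_snps", min = 1L)
  if (length(maf_range) != 2L || any(is.na(maf_range))) {
    abort("`maf_range` must be two frequencies (low, high).")
  }
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] &&
        maf_range[2] <= 0.5)) {
    abort("`maf_range` must satisfy 0 < low <= high <= 0.5.")
  }
  if (!is.null(tree)) {
    if (!is.list(tree$groups) || length(tree$groups) < 1L) {
      abort("`tree$groups` must be a non-empty list of leaf-name vectors.")
    }
    check_number(tree$fst_between, "tree$fst_between", 0, 1, open_upper = TRUE)
    check_number(tree$fst_within, "tree$fst_within", 0, 1, open_upper = TRUE)
    subpops <- unlist(tree$groups, use.names = FALSE)
    fst <- NULL
  } else {
    if (any(fst < 0 | fst >= 1)) {
      abort("All `fst` values must lie in [0, 1); FST = 1 is degenerate.")
    }
    if (is.null(subpops)) subpops <- paste0("pop", seq_len(max(1L, length(fst))))
    if (length(fst) == 1L) fst <- rep(fst, length(subpops))
    if (length(fst) != length(subpops)) {
      abort("`fst` must have one value per subpopulation.")
    }
    fst <- setNames(fst, subpops)
  }
  structure(
    list(n_snps = n_snps, maf_range = as.numeric(maf_range), fst = fst,
         subpops = subpops, tree = tree),
    class = "founder_model"
  )
}

#' @export
print.founder_model <- function(x, ...) {
  cat("<founder_model> ", length(x$subpops), " subpopulation(s), ",
      x$n_snps, " SNPs, ancestral MAF in [", x$maf_range[1], ", ",
      x$maf_range[2], "]\n", sep = "")
  if (is.null(x$tree)) {
    cat("  FST:", paste(sprintf("%s=%g", x$subpops, x$fst), collapse = ", "),
        "\n")
  } else {
    cat("  tree: between =", x$tree$fst_between, ", within =",
        x$tree$fst_within, "\n")
  }
  invisible(x)
}

# Balding-Nichols draw: Beta with mean p and variance fst * p * (1 - p).
# fst = 0 is the zero-variance limit and returns p exactly.
bn_draw <- function(p, fst) {
  if (fst == 0) return(p)
  shape <- (1 - fst) / fst
  q <- stats::rbeta(length(p), p * shape, (1 - p) * shape)
  pmin(pmax(q, FREQ_EPS), 1 - FREQ_EPS)
}

#' Simulate per-subpopulation allele frequencies
#'
#' Draws one ancestral frequency per SNP uniformly in the model's MAF range,
#' then differentiates it into each subpopulation with the Balding-Nichols
#' Beta model (mean `p`, variance `fst * p * (1 - p)`). Frequencies are
#' clipped to `[1e-4, 1 - 1e-4]` so that no column is monomorphic in
#' expectation.
#'
#' @param model A [founder_model()].
#' @param seed Optional integer seed.
#' @return A list of class `founder_freqs` with elements `ancestral` (length
#'   `n_snps`) and `freqs` (`n_snps` x n-subpopulations matrix).
#' @export
simulate_founder_frequencies <- function(model, seed = NULL) {
  stopifnot(inherits(model, "founder_model"))
  with_seed(seed, {
    p <- runif(model$n_snps, model$maf_range[1], model$maf_range[2])
    if (is.null(model$tree)) {
      freqs <- vapply(model$subpops, function(s) bn_draw(p, model$fst[[s]]),
                      numeric(model$n_snps))
    } else {
      cols <- list()
      for (g in names(model$tree$groups)) {
        pg <- bn_draw(p, model$tree$fst_between)
        for (leaf in model$tree$groups[[g]]) {
          cols[[leaf]] <- bn_draw(pg, model$tree$fst_within)
        }
      }
      freqs <- do.call(cbind, cols[model$subpops])
    }
    freqs <- matrix(freqs, nrow = model$n_snps,
                    dimnames = list(NULL, model$subpops))
    structure(list(ancestral = p, freqs = freqs, model = model),
              class = "founder_freqs")
  })
}

#' Sample founder genotypes under Hardy-Weinberg proportions
#'
#' Each genotype is an independent Binomial(2, freq) dosage draw, i.e. the
#' founders of every subpopulation are at Hardy-Weinberg equilibrium at their
#' own allele frequencies.
#'
#' @param freqs Allele-frequency vector (one entry per SNP), all in (0, 1).
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return An `n` x `length(freqs)` integer dosage matrix with entries 0/1/2.
#' @export
sample_founder_genotypes <- function(freqs, n, seed = NULL) {
  n <- check_count(n, "n", min = 1L)
  if (any(freqs <= 0 | freqs >= 1)) {
    abort("All `freqs` must lie strictly in (0, 1).")
  }
  with_seed(seed, cpp_sample_genotypes(as.numeric(freqs), n))
}

#' Bundle genotypes and allele frequencies for one source population
#'
#' @param name Population identifier.
#' @param genotypes Individuals x SNPs dosage matrix with entries 0/1/2.
#' @param allele_freqs Per-SNP frequency of the coded allele; computed from
#'   the genotypes when omitted.
#' @return An object of class `founder_population`.
#' @export
founder_population <- function(name, genotypes, allele_freqs = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% 0:2)) {
    abort("`genotypes` entries must be dosages in {0, 1, 2}.")
  }
  if (is.null(allele_freqs)) allele_freqs <- colMeans(genotypes) / 2
  if (length(allele_freqs) != ncol(genotypes)) {
    abort("`allele_freqs` must have one entry per genotype column.")
  }
  if (any(allele_freqs <= 0 | allele_freqs >= 1)) {
    abort("All `allele_freqs` must lie strictly in (0, 1).")
  }
  structure(
    list(name = as.character(name), allele_freqs = as.numeric(allele_freqs),
         genotypes = genotypes),
    class = "founder_population"
  )
}

#' @export
print.founder_population <- function(x, ...) {
  cat("<founder_population> '", x$name, "': ", nrow(x$genotypes),
      " individuals x ", ncol(x$genotypes), " SNPs\n", sep = "")
  invisible(x)
}

#' Weir-Cockerham FST estimator
#'
#' Multi-locus ratio-of-averages estimator of FST from dosage genotypes and
#' subpopulation labels; used as a diagnostic that the Balding-Nichols
#' generator realizes the differentiation it was asked for.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param labels Subpopulation assignment, one per row.
#' @return A single FST estimate.
#' @export
wc_fst <- function(genotypes, labels) {
  labels <- as.factor(labels)
  r <- nlevels(labels)
  if (r < 2L) abort("`wc_fst()` needs at least two subpopulations.")
  idx <- split(seq_along(labels), labels)
  ni <- vapply(idx, length, integer(1))
  pmat <- vapply(idx, function(i) colMeans(genotypes[i, , drop = FALSE]) / 2,
                 numeric(ncol(genotypes)))
  hmat <- vapply(idx, function(i) colMeans(genotypes[i, , drop = FALSE] == 1L),
                 numeric(ncol(genotypes)))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- as.vector(pmat %*% ni) / (r * nbar)
  s2 <- as.vector((pmat - pbar)^2 %*% ni) / ((r - 1) * nbar)
  hbar <- as.vector(hmat %*% ni) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

#' Write a dosage matrix as tab-separated text
#'
#' Dialect: a header row of SNP identifiers, then one row of tab-separated
#' integer dosages per individual, LF line endings.
#'
#' @param x A `founder_population` or a dosage matrix.
#' @param path Output file.
#' @param snp_ids SNP identifiers; defaults to column names or `snp1`, ...
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(x, path, snp_ids = NULL) {
  g <- if (inherits(x, "founder_population")) x$genotypes else as.matrix(x)
  if (is.null(snp_ids)) {
    snp_ids <- colnames(g) %||% paste0("snp", seq_len(ncol(g)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(snp_ids, collapse = "\t"), con, sep = "\n")
  body <- apply(g, 1L, paste, collapse = "\t")
  writeLines(body, con, sep = "\n")
  invisible(path)
}

read_dosage_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) {
    abort(sprintf("Malformed dosage TSV '%s': need a header and >= 1 row.",
                  path))
  }
  ids <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(ids))
  if (length(bad)) {
    abort(sprintf("Malformed dosage TSV '%s': line %d has %d fields, expected %d.",
                  path, bad[1L] + 1L, lengths(rows)[bad[1L]], length(ids)))
  }
  g <- matrix(suppressWarnings(as.integer(unlist(rows))),
              nrow = length(rows), byrow = TRUE,
              dimnames = list(NULL, ids))
  if (anyNA(g) || !all(g %in% 0:2)) {
    abort(sprintf("Malformed dosage TSV '%s': entries must be integers 0/1/2.",
                  path))
  }
  g
}

vcf_to_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) abort(sprintf("VCF '%s' contains no variants.", path))
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warn(sprintf("Skipping %d multi-allelic site(s) in '%s'.", sum(!bi), path))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  ids[is.na(ids) | ids == "."] <- paste0("site", which(is.na(ids) | ids == "."))
  count_alt <- function(s) {
    ifelse(is.na(s) | s %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(s, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  d <- apply(gt, 2L, count_alt)
  d <- matrix(as.integer(d), nrow = nrow(gt),
              dimnames = list(ids, colnames(gt)))
  g <- t(d)  # individuals x SNPs
  all_na <- colSums(!is.na(g)) == 0L
  if (any(all_na)) {
    warn(sprintf("Dropping %d all-missing SNP(s) in '%s'.", sum(all_na), path))
    g <- g[, !all_na, drop = FALSE]
  }
  # Impute sporadic missing genotypes with the rounded column mean dosage.
  for (j in which(colSums(is.na(g)) > 0L)) {
    g[is.na(g[, j]), j] <- as.integer(round(mean(g[, j], na.rm = TRUE)))
  }
  # Recode to minor-allele dosage.
  f_alt <- colMeans(g) / 2
  flip <- f_alt > 0.5
  g[, flip] <- 2L - g[, flip, drop = FALSE]
  g
}

#' Load a genotype matrix from VCF or dosage TSV
#'
#' Reads real (or exported) genotypes as an alternative founder source.
#' VCF sites are recoded to minor-allele dosage; multi-allelic sites are
#' skipped with a warning, all-missing sites dropped, sporadic missing
#' genotypes imputed with the rounded column mean. SNPs with minor allele
#' frequency below `maf_min` are removed and the drop count reported.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage"`.
#' @param maf_min MAF threshold below which SNPs are dropped (default 0.05).
#' @param name Population name for the returned object.
#' @return A [founder_population()]; the number of SNPs dropped by the MAF
#'   filter is available as `attr(, "n_dropped")`.
#' @export
load_genotype_matrix <- function(path, format = c("auto", "vcf", "dosage"),
                                 maf_min = 0.05, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "dosage"
  }
  g <- switch(format, vcf = vcf_to_dosage(path), dosage = read_dosage_tsv(path))
  freqs <- colMeans(g) / 2
  maf <- pmin(freqs, 1 - freqs)
  drop <- maf < maf_min
  if (any(drop)) {
    inform(sprintf("Dropped %d SNP(s) with MAF < %g.", sum(drop), maf_min))
    g <- g[, !drop, drop = FALSE]
    freqs <- freqs[!drop]
  }
  # Guard degenerate frequencies surviving a zero threshold.
  freqs <- pmin(pmax(freqs, FREQ_EPS), 1 - FREQ_EPS)
  out <- founder_population(name %||% basename(path), g, freqs)
  attr(out, "n_dropped") <- sum(drop)
  out
}
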