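#' Configure a stratification scenario
#'
#' Six scenario families cover the main types of population structure studied
#' in stratified case-control GWAS:
#'
#' 1. one homogeneous population;
#' 2. admixture of two genetically close sources (FST 0.002);
#' 3. two fairly close discrete populations (FST 0.005);
#' 4. two distant discrete populations (FST 0.11);
#' 5. hierarchical structure: five populations in three continental groups
#'    (FST 0.15 between groups, 0.01 within), with within-continent
#'    admixture by default;
#' 6. the scenario-4 structure with the case split between the two
#'    populations varied as a (r, 1 - r) ratio while controls stay balanced.
#'
#' Sampling proportions of cases and controls differ between subpopulations
#' (defaults below), which together with the allele-frequency differentiation
#' induces the stratification bias. All defaults are overridable.
#'
#' @param scenario Integer 1-6.
#' @param n_snps Number of unlinked null SNPs (default 5,500).
#' @param maf_range Ancestral MAF range for the null SNPs.
#' @param n_founders Founder-pool size per subpopulation.
#' @param cases,controls Per-subpopulation case/control counts. Scenario
#'   defaults: 500/500 (scenarios 1, 2), 300+200 cases vs 200+300 controls
#'   (scenarios 3, 4), 175/150/100/50/25 cases with mirrored controls
#'   (scenario 5), 500 total cases split by `r` with 250+250 controls
#'   (scenario 6).
#' @param r Scenario 6 only: proportion of cases sampled in the first
#'   subpopulation (cases split `(r, 1 - r)`).
#' @param disease A [disease_model()]. Scenario 2 defaults to per-source
#'   prevalences (0.05, 0.15); scenario 6 defaults to per-population DSL
#'   MAFs (0.4, 0.2) so that the first population is the more affected one.
#' @param fst Override the scenario's FST preset (flat layouts).
#' @param tree Override the hierarchical layout (scenario 5).
#' @param admix Admixture settings for scenario 2:
#'   `list(q = 0.5, generations = 2)`.
#' @param admix_within Scenario 5: admix populations within a continental
#'   group (migrant fraction `migrant`) before mating. Set `FALSE` for a
#'   purely discrete hierarchy.
#' @param migrant Scenario 5 within-group migrant fraction.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = 1, n_snps = 5500,
                            maf_range = c(0.05, 0.5), n_founders = 200,
                            cases = NULL, controls = NULL, r = NULL,
                            disease = NULL, fst = NULL, tree = NULL,
                            admix = list(q = 0.5, generations = 2),
                            admix_within = TRUE, migrant = 0.2) {
  scenario <- check_count(scenario, "scenario", min = 1L)
  if (scenario > 6L) abort("`scenario` must be 1..6.")
  n_snps <- check_count(n_snps, "n_snps", min = 0L)
  n_founders <- check_count(n_founders, "n_founders", min = 2L)

  def <- switch(scenario,
    list(subpops = "pop1", fst = 0, cases = 500, controls = 500),
    list(subpops = c("src1", "src2"), fst = c(0.002, 0.002),
         cases = 500, controls = 500),
    list(subpops = c("pop1", "pop2"), fst = c(0.005, 0.005),
         cases = c(300, 200), controls = c(200, 300)),
    list(subpops = c("pop1", "pop2"), fst = c(0.11, 0.11),
         cases = c(300, 200), controls = c(200, 300)),
    list(tree = list(groups = list(africa = c("pop1", "pop2"),
                                   asia = c("pop3", "pop4"),
                                   europe = "pop5"),
                     fst_between = 0.15, fst_within = 0.01),
         cases = c(175, 150, 100, 50, 25),
         controls = c(25, 50, 100, 150, 175)),
    list(subpops = c("pop1", "pop2"), fst = c(0.11, 0.11),
         cases = 500, controls = c(250, 250), r = 0.5)
  )
  if (scenario == 5L) {
    tree <- tree %||% def$tree
    subpops <- unlist(tree$groups, use.names = FALSE)
    fst <- NULL
  } else {
    fst <- fst %||% def$fst
    subpops <- def$subpops
    tree <- NULL
  }
  cases <- cases %||% def$cases
  controls <- controls %||% def$controls
  if (any(cases < 0) || any(controls < 0)) {
    abort("Field `cases`/`controls`: counts must be >= 0.")
  }
  if (scenario == 6L) {
    r <- r %||% def$r
    check_number(r, "r", 0, 1)
    if (length(cases) != 1L) {
      abort("Field `cases`: scenario 6 takes a single total case count, split by `r`.")
    }
  } else if (!is.null(r)) {
    abort("Field `r` only applies to scenario 6.")
  }
  if (is.null(disease)) {
    disease <- switch(scenario,
      disease_model(),
      disease_model(prevalence_by_pop = c(src1 = 0.05, src2 = 0.15)),
      disease_model(), disease_model(), disease_model(),
      disease_model(maf_by_pop = c(pop1 = 0.4, pop2 = 0.2)))
  }
  stopifnot(inherits(disease, "disease_model"))
  n_pops <- length(subpops)
  expand <- function(x, name) {
    if (length(x) == 1L) rep(as.integer(x), n_pops)
    else if (length(x) == n_pops) as.integer(x)
    else abort(sprintf("Field `%s` must have 1 or %d entries.", name, n_pops))
  }
  # Scenario 2 pools are admixed into a single cohort; scenario 6 resolves
  # its case split at build time.
  if (scenario != 6L && scenario != 2L) {
    cases <- expand(cases, "cases")
    controls <- expand(controls, "controls")
  }
  if (scenario == 2L) {
    cases <- sum(cases); controls <- sum(controls)
  }
  structure(
    list(scenario = scenario, n_snps = n_snps,
         maf_range = as.numeric(maf_range), n_founders = n_founders,
         subpops = subpops, fst = fst, tree = tree, cases = cases,
         controls = controls, r = r, disease = disease, admix = admix,
         admix_within = isTRUE(admix_within), migrant = migrant),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> scenario %d: %d subpopulation(s), %d SNPs\n",
              x$scenario, length(x$subpops), x$n_snps))
  cat("  cases:", paste(x$cases, collapse = "/"),
      " controls:", paste(x$controls, collapse = "/"), "\n")
  if (!is.null(x$r)) cat("  case split r =", x$r, "\n")
  print(x$disease)
  invisible(x)
}

# Per-subpopulation DSL frequencies: fixed override if provided, otherwise
# differentiated from the ancestral DSL MAF with the scenario's own
# Balding-Nichols structure (the DSL is "one locus per subpopulation",
# excluded from mating, so only its frequencies are needed).
dsl_pop_freqs <- function(config) {
  d <- config$disease
  pops <- config$subpops
  if (!is.null(d$maf_by_pop)) {
    m <- d$maf_by_pop
    if (is.null(names(m))) m <- setNames(rep_len(m, length(pops)), pops)
    return(m[pops])
  }
  if (is.null(config$tree)) {
    m <- vapply(pops, function(s) bn_draw(d$maf, config$fst[[match(s, pops)]]),
                numeric(1))
  } else {
    m <- c()
    for (g in names(config$tree$groups)) {
      pg <- bn_draw(d$maf, config$tree$fst_between)
      for (leaf in config$tree$groups[[g]]) {
        m[leaf] <- bn_draw(pg, config$tree$fst_within)
      }
    }
    m <- m[pops]
  }
  m
}

#' Sample DSL genotypes conditional on phenotype and ancestry
#'
#' Each individual's DSL genotype is drawn from the case or control genotype
#' triple of its subpopulation; admixed individuals draw from the
#' ancestry-weighted mixture of the subpopulation triples.
#'
#' @param ccdists Named list (one per subpopulation) of
#'   [case_control_genotype_frequencies()] results.
#' @param phenotype Binary vector (1 = case).
#' @param ancestry Individuals x subpopulations ancestry-proportion matrix
#'   (rows sum to 1); a plain label vector is also accepted.
#' @param seed Optional integer seed.
#' @return Integer dosage vector.
#' @export
sample_dsl_genotypes <- function(ccdists, phenotype, ancestry, seed = NULL) {
  pops <- names(ccdists)
  if (is.null(pops)) abort("`ccdists` must be a named list per subpopulation.")
  if (!is.matrix(ancestry)) {
    lab <- as.character(ancestry)
    if (!all(lab %in% pops)) {
      abort("Missing subpopulation distribution for some labels.")
    }
    ancestry <- outer(lab, pops, `==`) * 1
    colnames(ancestry) <- pops
  }
  if (!all(pops %in% colnames(ancestry))) {
    abort("`ancestry` columns must cover all subpopulations in `ccdists`.")
  }
  A <- ancestry[, pops, drop = FALSE]
  Tcase <- do.call(rbind, lapply(ccdists, `[[`, "case"))
  Tctrl <- do.call(rbind, lapply(ccdists, `[[`, "control"))
  with_seed(seed, {
    P <- matrix(NA_real_, nrow(A), 3L)
    is_case <- phenotype == 1L
    if (any(is_case)) P[is_case, ] <- A[is_case, , drop = FALSE] %*% Tcase
    if (any(!is_case)) P[!is_case, ] <- A[!is_case, , drop = FALSE] %*% Tctrl
    u <- runif(nrow(A))
    as.integer((u > P[, 1L]) + (u > P[, 1L] + P[, 2L]))
  })
}

#' Build a simulated case-control cohort
#'
#' Runs the full generative pipeline for a scenario: founder allele
#' frequencies (Balding-Nichols), founder genotypes at Hardy-Weinberg
#' proportions, random mating / admixture to realize the population
#' structure, phenotype assignment honoring the configured per-subpopulation
#' case and control counts, and finally the disease susceptibility locus
#' drawn conditional on phenotype and ancestry from the Bayes-inverted
#' penetrance model. The DSL is excluded from the mating process, so its
#' relative risks are conserved whatever structure is simulated; the null
#' SNPs carry no phenotype dependence.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed (one seed fully determines the cohort).
#' @return An object of class `strat_cohort`: list with `genotypes`
#'   (null-SNP dosage matrix), `dsl` (dosage vector), `phenotype` (0/1),
#'   `labels` (factor), `ancestry` (individuals x subpopulations matrix),
#'   `dsl_freqs`, `admixed`, `config`, `seed`.
#' @export
build_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  fm <- founder_model(n_snps = max(config$n_snps, 1L),
                      maf_range = config$maf_range,
                      fst = config$fst, subpops = config$subpops,
                      tree = config$tree)
  ff <- simulate_founder_frequencies(fm)
  freqs <- ff$freqs
  if (config$n_snps == 0L) freqs <- freqs[0L, , drop = FALSE]
  m_pop <- dsl_pop_freqs(config)
  pops <- config$subpops
  d <- config$disease
  K_pop <- d$prevalence_by_pop
  if (!is.null(K_pop) && is.null(names(K_pop))) {
    K_pop <- setNames(rep_len(K_pop, length(pops)), pops)
  }

  if (config$scenario == 2L) {
    fa <- cpp_sample_genotypes(freqs[, 1L], config$n_founders)
    fb <- cpp_sample_genotypes(freqs[, 2L], config$n_founders)
    n_total <- config$cases + config$controls
    adm <- admix_populations(fa, fb, q = config$admix$q %||% 0.5,
                             generations = config$admix$generations %||% 2,
                             n_offspring = n_total)
    genotypes <- adm$genotypes
    ancestry <- cbind(adm$ancestry, 1 - adm$ancestry)
    colnames(ancestry) <- pops
    # Baseline risk differs between the sources: individuals are sampled as
    # cases with probability proportional to their ancestry-weighted risk.
    Ki <- as.vector(ancestry %*% (K_pop %||% setNames(rep(d$prevalence, 2), pops))[pops])
    phenotype <- integer(n_total)
    phenotype[sample.int(n_total, config$cases, prob = Ki)] <- 1L
    labels <- factor(paste0("anc", round(adm$ancestry * 4) / 4))
    admixed <- TRUE
  } else {
    counts <- resolve_counts(config)
    blocks <- vector("list", length(pops))
    anc_blocks <- vector("list", length(pops))
    for (s in seq_along(pops)) {
      pool <- cpp_sample_genotypes(freqs[, s], config$n_founders)
      anc0 <- matrix(0, config$n_founders, length(pops))
      anc0[, s] <- 1
      if (!is.null(config$tree) && config$admix_within && config$migrant > 0) {
        sibs <- setdiff(unlist(config$tree$groups[
          vapply(config$tree$groups, function(g) pops[s] %in% g, logical(1))]),
          pops[s])
        if (length(sibs)) {
          n_mig <- round(config$migrant * config$n_founders)
          if (n_mig > 0) {
            sib_idx <- match(sibs[1L], pops)
            mig <- cpp_sample_genotypes(freqs[, sib_idx], n_mig)
            anc_mig <- matrix(0, n_mig, length(pops))
            anc_mig[, sib_idx] <- 1
            pool <- rbind(pool, mig)
            anc0 <- rbind(anc0, anc_mig)
          }
        }
      }
      n_s <- counts$cases[s] + counts$controls[s]
      if (n_s == 0L) {
        blocks[[s]] <- pool[0L, , drop = FALSE]
        anc_blocks[[s]] <- anc0[0L, , drop = FALSE]
        next
      }
      res <- mate_once(pool, n_s, anc0)
      blocks[[s]] <- res$genotypes
      anc_blocks[[s]] <- res$ancestry
    }
    genotypes <- do.call(rbind, blocks)
    ancestry <- do.call(rbind, anc_blocks)
    colnames(ancestry) <- pops
    phenotype <- unlist(lapply(seq_along(pops), function(s) {
      c(rep(1L, counts$cases[s]), rep(0L, counts$controls[s]))
    }))
    labels <- factor(rep(pops, counts$cases + counts$controls), levels = pops)
    admixed <- FALSE
  }

  ccdists <- lapply(setNames(pops, pops), function(s) {
    ccdist_for_pop(d, m_pop[[s]], if (!is.null(K_pop)) K_pop[[s]])
  })
  dsl <- sample_dsl_genotypes(ccdists, phenotype, ancestry)

  structure(
    list(genotypes = genotypes, dsl = dsl, phenotype = phenotype,
         labels = labels, ancestry = ancestry, dsl_freqs = m_pop,
         admixed = admixed, config = config, seed = seed),
    class = "strat_cohort"
  )
}

# Per-subpopulation case/control counts, resolving scenario 6's (r, 1 - r)
# case split at build time.
resolve_counts <- function(config) {
  if (config$scenario == 6L) {
    total <- sum(config$cases)
    c1 <- as.integer(round(config$r * total))
    list(cases = c(c1, total - c1), controls = config$controls)
  } else {
    list(cases = config$cases, controls = config$controls)
  }
}

#' @export
print.strat_cohort <- function(x, ...) {
  cat(sprintf(
    "<strat_cohort> scenario %d: %d individuals (%d cases / %d controls), %d null SNPs + 1 DSL\n",
    x$config$scenario, length(x$phenotype), sum(x$phenotype == 1L),
    sum(x$phenotype == 0L), ncol(x$genotypes)))
  cat("  subpopulations:", paste(levels(x$labels), collapse = ", "), "\n")
  cat("  DSL freqs:", paste(sprintf("%.3f", x$dsl_freqs), collapse = ", "),
      "\n")
  invisible(x)
}

#' Restrict a cohort to a subset of subpopulations
#'
#' Used for the scenario-6 exclusion comparison: keeping only the
#' subpopulation that contains both cases and controls.
#'
#' @param cohort A `strat_cohort`.
#' @param pops Subpopulation labels to keep.
#' @return A `strat_cohort` with the selected rows.
#' @export
cohort_subset <- function(cohort, pops) {
  keep <- cohort$labels %in% pops
  if (!any(keep)) abort("No individuals left after subsetting.")
  out <- cohort
  out$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  out$dsl <- cohort$dsl[keep]
  out$phenotype <- cohort$phenotype[keep]
  out$labels <- droplevels(cohort$labels[keep])
  out$ancestry <- cohort$ancestry[keep, , drop = FALSE]
  out
}

#' Export a cohort as plain-text files
#'
#' Writes the null-SNP dosage matrix as a dosage TSV and a sidecar TSV with
#' phenotype, subpopulation label, ancestry proportions and DSL dosage.
#'
#' @param cohort A `strat_cohort`.
#' @param prefix Output path prefix; writes `<prefix>_genotypes.tsv` and
#'   `<prefix>_samples.tsv`.
#' @return Character vector of the two paths, invisibly.
#' @export
export_cohort <- function(cohort, prefix) {
  gpath <- paste0(prefix, "_genotypes.tsv")
  spath <- paste0(prefix, "_samples.tsv")
  write_dosage_tsv(cohort$genotypes, gpath)
  anc <- cohort$ancestry
  colnames(anc) <- paste0("ancestry_", colnames(anc))
  side <- cbind(
    data.frame(id = seq_along(cohort$phenotype),
               phenotype = cohort$phenotype,
               label = as.character(cohort$labels),
               dsl = cohort$dsl, stringsAsFactors = FALSE),
    as.data.frame(round(anc, 6)))
  con <- file(spath, open = "wb")
  writeLines(paste(colnames(side), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(side, sep = "\t")), con, sep = "\n")
  close(con)
  invisible(c(genotypes = gpath, samples = spath))
}
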