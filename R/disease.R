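#' Specify the disease susceptibility locus (DSL) model
#'
#' The DSL is a biallelic locus with susceptibility allele A at minor allele
#' frequency `maf`. Genotype population frequencies follow Wright's model
#' with consanguinity coefficient `F` (0 by default, i.e. Hardy-Weinberg
#' proportions). Disease risk is parameterized by the prevalence `K` and the
#' genotype relative risks `RR1 = f1/f0`, `RR2 = f2/f0`, from which the
#' penetrances are recovered so that the population prevalence is exactly `K`.
#'
#' A mode of inheritance maps a single headline relative risk `rr` to the
#' pair (RR1, RR2): additive `RR2 = 2 RR1 - 1`, dominant `RR2 = RR1`,
#' recessive `RR1 = 1`, multiplicative `RR2 = RR1^2`; `mode = "general"`
#' takes `rr1` and `rr2` explicitly.
#'
#' @param maf DSL minor-allele frequency in (0, 1).
#' @param prevalence Disease prevalence `K` in (0, 1).
#' @param rr Headline relative risk (the heterozygote relative risk except in
#'   the recessive mode, where it is the homozygote relative risk).
#' @param mode Mode of inheritance.
#' @param rr1,rr2 Explicit relative risks for `mode = "general"`.
#' @param F Consanguinity coefficient in `[0, 1]`.
#' @param maf_by_pop Optional named per-subpopulation MAF override; when
#'   absent, per-subpopulation DSL frequencies are differentiated with the
#'   scenario's Balding-Nichols model.
#' @param prevalence_by_pop Optional named per-subpopulation prevalence
#'   override (differing baseline risks across subpopulations).
#' @return An object of class `disease_model` with fields `rr1`, `rr2`
#'   resolved from the mode.
#' @export
disease_model <- function(maf = 0.3, prevalence = 0.1, rr = 1,
                          mode = c("additive", "dominant", "recessive",
                                   "multiplicative", "general"),
                          rr1 = NULL, rr2 = NULL, F = 0,
                          maf_by_pop = NULL, prevalence_by_pop = NULL) {
  mode <- match.arg(mode)
  check_number(maf, "maf", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(prevalence, "prevalence", 0, 1, open_lower = TRUE,
               open_upper = TRUE)
  check_number(F, "F", 0, 1)
  if (mode == "general") {
    if (is.null(rr1) || is.null(rr2)) {
      abort("`mode = \"general\"` needs explicit `rr1` and `rr2`.")
    }
  } else {
    check_number(rr, "rr", 0)
    rr1 <- switch(mode, recessive = 1, rr)
    rr2 <- switch(mode,
                  additive = 2 * rr - 1,
                  dominant = rr,
                  recessive = rr,
                  multiplicative = rr^2)
    if (mode == "additive" && rr < 0.5) {
      abort("Additive mode needs `rr` >= 0.5 so that RR2 = 2 rr - 1 >= 0.")
    }
  }
  if (rr1 < 0 || rr2 < 0) abort("Relative risks must be >= 0.")
  structure(
    list(maf = maf, prevalence = prevalence, rr = if (mode == "general") NA
         else rr, rr1 = rr1, rr2 = rr2, mode = mode, F = F,
         maf_by_pop = maf_by_pop, prevalence_by_pop = prevalence_by_pop),
    class = "disease_model"
  )
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf(
    "<disease_model> %s: MAF %g, K %g, RR1 %g, RR2 %g, F %g\n",
    x$mode, x$maf, x$prevalence, x$rr1, x$rr2, x$F))
  invisible(x)
}

# Re-resolve the (rr1, rr2) pair for a new headline rr, keeping the mode.
set_rr <- function(model, rr) {
  if (model$mode == "general") {
    abort("Cannot sweep `rr` for a general-mode disease model.")
  }
  disease_model(maf = model$maf, prevalence = model$prevalence, rr = rr,
                mode = model$mode, F = model$F, maf_by_pop = model$maf_by_pop,
                prevalence_by_pop = model$prevalence_by_pop)
}

#' Genotype frequencies under Wright's model
#'
#' For susceptibility-allele frequency `m` and consanguinity coefficient `F`,
#' the genotypes aa, aA, AA have frequencies
#' `(1-m)^2 + F m (1-m)`, `2 m (1-m) (1-F)`, `m^2 + F m (1-m)`.
#' `F = 0` gives Hardy-Weinberg proportions.
#'
#' @param m Susceptibility-allele frequency in (0, 1).
#' @param F Consanguinity coefficient in `[0, 1]`.
#' @return Named numeric vector `c(p0, p1, p2)` summing to 1.
#' @export
wright_genotype_frequencies <- function(m, F = 0) {
  check_number(m, "m", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(F, "F", 0, 1)
  c(p0 = (1 - m)^2 + F * m * (1 - m),
    p1 = 2 * m * (1 - m) * (1 - F),
    p2 = m^2 + F * m * (1 - m))
}

#' Penetrances from prevalence and relative risks
#'
#' Solves `f0 = K / (p0 + RR1 p1 + RR2 p2)`, `f1 = RR1 f0`, `f2 = RR2 f0`,
#' so that the population prevalence `sum(fi * pi)` equals `K` exactly.
#'
#' @param model A [disease_model()] (supplies K, RR1, RR2).
#' @param dist Genotype frequency triple, e.g. from
#'   [wright_genotype_frequencies()].
#' @param prevalence Optional prevalence overriding the model's `K` (used for
#'   per-subpopulation baseline risks).
#' @return Named numeric vector `c(f0, f1, f2)` of penetrances.
#' @export
penetrances_from_rr <- function(model, dist, prevalence = NULL) {
  K <- prevalence %||% model$prevalence
  f0 <- K / (dist[[1]] + model$rr1 * dist[[2]] + model$rr2 * dist[[3]])
  f <- c(f0 = f0, f1 = model$rr1 * f0, f2 = model$rr2 * f0)
  bad <- which(f < 0 | f > 1)
  if (length(bad)) {
    abort(sprintf(
      "Infeasible disease model: penetrance %s = %.4g outside [0, 1] (K = %g, RR1 = %g, RR2 = %g).",
      names(f)[bad[1]], f[bad[1]], K, model$rr1, model$rr2))
  }
  f
}

#' Case and control genotype frequencies at the DSL
#'
#' Bayes inversion of the penetrance model: given genotype frequencies `p_i`
#' and penetrances `f_i` with prevalence `K = sum(f_i p_i)`,
#' `P(genotype i | case) = f_i p_i / K` and
#' `P(genotype i | control) = (1 - f_i) p_i / (1 - K)`.
#'
#' @param model A [disease_model()].
#' @param dist Genotype frequency triple.
#' @param pens Penetrance triple from [penetrances_from_rr()].
#' @param prevalence Optional prevalence overriding the model's `K`.
#' @return List with numeric triples `case` and `control`, each summing to 1.
#' @export
case_control_genotype_frequencies <- function(model, dist,
                                              pens = penetrances_from_rr(model, dist, prevalence),
                                              prevalence = NULL) {
  K <- prevalence %||% model$prevalence
  check_number(K, "prevalence", 0, 1, open_lower = TRUE, open_upper = TRUE)
  dist <- as.numeric(dist)
  pens <- as.numeric(pens)
  case <- pens * dist / K
  control <- (1 - pens) * dist / (1 - K)
  list(case = setNames(case, c("p0", "p1", "p2")),
       control = setNames(control, c("p0", "p1", "p2")))
}

# Case/control triples for one subpopulation: Wright genotype frequencies at
# that subpopulation's DSL frequency, penetrances re-solved under its
# baseline prevalence, then the Bayes inversion.
ccdist_for_pop <- function(model, m_pop, K_pop = NULL) {
  dist <- wright_genotype_frequencies(m_pop, model$F)
  K <- K_pop %||% model$prevalence
  pens <- penetrances_from_rr(model, dist, prevalence = K)
  case_control_genotype_frequencies(model, dist, pens, prevalence = K)
}
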