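---
title: "Comparing corrections for population stratification in case-control GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing corrections for population stratification in case-control GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratsim)
```

## The problem

In a case-control genome-wide association study, population stratification
arises when the cohort mixes subgroups of different ancestry *and* the
proportion of cases differs between those subgroups. Allele frequencies then
differ systematically between cases and controls at every differentiated
marker, whether or not it has anything to do with the disease, inflating the
Armitage trend test and producing spurious associations (or masking real
ones). stratsim simulates this situation under controllable population
structures and estimates, by Monte Carlo, the false positive rate and power
of the correction strategies in common use: Genomic Control, the Eigenstrat
test, adjusted logistic (and linear) regressions with several covariate
sources, and within-stratum meta-analyses.

## The generative model

**Founders.** Each subpopulation is summarized by per-SNP allele
frequencies. An ancestral frequency $p$ is drawn uniformly in the
configured MAF range (default $[0.05, 0.5]$, matching the common-variant
panels used in GWAS) and each subpopulation's frequency is drawn from the
Balding-Nichols Beta distribution with mean $p$ and variance
$F_{ST}\,p(1-p)$. Frequencies are clipped to $[10^{-4}, 1-10^{-4}]$ so no
column is monomorphic in expectation; SNPs are simulated unlinked because a
genome-scattered panel of a few thousand markers carries negligible LD
between markers. Founder genotypes are Binomial(2, freq) draws, i.e.
Hardy-Weinberg proportions within each source.

**Structure.** Cohorts are built by one generation of random mating within
each subpopulation (two distinct parents per offspring, one transmitted
allele each), by cross-population mating for admixed designs, and by a
two-level $F_{ST}$ tree (between- and within-continent branches) for the
hierarchical design. Six scenario presets cover: (1) one homogeneous
population; (2) admixture of two close sources ($F_{ST} = 0.002$, one
generation of intermating at $q = 0.5$ plus one within-pool generation);
(3) two close discrete populations ($F_{ST} = 0.005$); (4) two distant
discrete populations ($F_{ST} = 0.11$); (5) five populations on a
hierarchical tree ($F_{ST}$ 0.15 between continental groups, 0.01 within),
with a 20% within-continent migrant fraction in each mating pool by
default — the hierarchical structure is treated as containing admixture,
with a purely discrete variant available via `admix_within = FALSE`; (6)
the scenario-4 structure with the case split between the two populations
swept as a $(r, 1-r)$ ratio while controls stay balanced. The pairwise
$F_{ST}$ presets follow published magnitudes for pairs of East-Asian,
European and cross-continental reference populations; all are
config-overridable.

**Disease locus.** The DSL is a single biallelic locus, never part of the
mating or of the null-marker panel, so its properties survive any amount of
structure. Genotype frequencies follow Wright's model with consanguinity
$F$ (default 0, i.e. HWE): $(1-m)^2 + Fm(1-m)$, $2m(1-m)(1-F)$,
$m^2 + Fm(1-m)$. Risk is parameterized by prevalence $K$ (default 0.1) and
genotype relative risks $RR_i = f_i / f_0$; penetrances are recovered as
$f_0 = K / (p_0 + RR_1 p_1 + RR_2 p_2)$ so that $\sum_i f_i p_i = K$
exactly, and an infeasible combination (any $f_i \notin [0,1]$) is
rejected with an error naming the offending penetrance. Case and control
genotype distributions follow by Bayes inversion:
$P(g_i \mid \text{case}) = f_i p_i / K$ and
$P(g_i \mid \text{control}) = (1-f_i) p_i / (1-K)$. A mode of inheritance
maps one headline relative risk to the pair $(RR_1, RR_2)$; the additive
mapping $RR_2 = 2RR_1 - 1$ is the default, and the swept value is read as
the heterozygote relative risk.

Each subpopulation carries its own DSL. By default the per-subpopulation
DSL frequencies are drawn from the same Balding-Nichols model as the null
SNPs, so the DSL is differentiated exactly like a typical marker of the
panel — this differentiation is what makes the trend test anti-conservative
under structure even at $RR = 1$. Scenario 6 instead fixes the two DSL
frequencies at (0.4, 0.2) so that the first population is deterministically
the more affected one, which is what gives the case-split sweep its
asymmetry. For the admixed scenario the two sources additionally differ in
baseline prevalence (defaults 0.05 and 0.15): in a single admixed cohort
there is no per-subpopulation sampling design, so individuals are sampled
as cases with probability proportional to their ancestry-weighted risk,
and without a baseline-risk difference the phenotype would be independent
of ancestry and no bias would exist to correct. Admixed individuals draw
their DSL genotype from the ancestry-weighted mixture of the source
conditional distributions.

**Sampling design.** Discrete scenarios fix the per-subpopulation case and
control counts. Defaults: 500 cases + 500 controls in one population
(scenario 1); 300/200 cases vs 200/300 controls in the two-population
scenarios; 175/150/100/50/25 cases with mirrored controls across the five
hierarchical populations; scenario 6 splits 500 cases as
$(r \cdot 500, (1-r) \cdot 500)$ over balanced 250 + 250 controls. Founder
pools default to 200 individuals per subpopulation. These sizes are the
package's own defaults for a realistic single-study cohort of ~1,000
genotyped subjects; every one of them is a config field.

## The association strategies

All strategies test the DSL; the 5,500 null SNPs serve only to estimate
structure. Genotypes are coded as minor-allele dosage 0/1/2 throughout.

* **Trend** — Armitage trend test, $T = N\rho^2$ with $\rho$ the Pearson
  correlation of dosage and phenotype, $\chi^2_1$ under the null. The
  uncorrected reference.
* **GC** — Genomic Control: $\lambda$ = median of the null-SNP trend
  statistics divided by 0.4549364 (the $\chi^2_1$ median); the DSL
  statistic is divided by $\lambda$. A mean-based estimator is available.
  $\lambda$ is deliberately *not* clipped at 1: an underestimated
  $\lambda$ is exactly how GC turns anti-conservative under weak
  structure, and clipping would hide it (a `clip` option exists).
* **Eigenstrat** — dosage and phenotype are residualized on the top $k$
  principal components of the column-standardized null-marker matrix
  (centering by the column mean, scaling by $\sqrt{\hat g/2\,(1-\hat
  g/2)}$), and $(N - k - 1)\rho^2_{\text{resid}}$ is referred to
  $\chi^2_1$. Default $k = 5$, sweepable.
* **Adjusted regressions** — logistic `phenotype ~ dosage + covariates`
  with a 1-df likelihood-ratio test on the dosage term. Covariate sources:
  top $k$ PCs; true population labels (continuous ancestry proportions in
  admixed cohorts); estimated labels; estimated membership probabilities;
  estimated labels plus PCs. A linear-regression variant (t-test on the
  dosage coefficient) mirrors the computationally cheap alternative.
  The LRT was chosen over the Wald test for its better small-sample
  calibration.
* **Label estimation** — number of clusters = number of Tracy-Widom
  significant axes + 1, k-means on the significant axes, soft memberships
  as normalized inverse squared distances to the centroids. Because the
  simulated SNPs are unlinked, the Tracy-Widom reference uses the known
  marker count directly (with half-integer finite-size centering) instead
  of a moment-based effective marker count; the interface isolates the
  estimator so another clustering scheme can be dropped in.
* **Meta-analyses** — per-stratum trend tests (strata = true labels when
  available, estimated otherwise; strata with one phenotype class are
  dropped with a warning) combined by Fisher ($-2\sum\log p_k$ on
  $\chi^2_{2K}$) or by Stouffer (direction-signed z-scores with
  $\sqrt{n_k}$ weights).

## Monte-Carlo evaluation

For each replicate a fresh cohort is generated from a counter-derived seed,
every method is applied to the DSL, and the rejection proportion at
$\alpha = 0.05$ is estimated as $\#\{p \le \alpha\}/B$. At $RR = 1$ this is
the false positive rate; at $RR > 1$, power — the two are the same
computation and coincide bit-exactly for the same seed. Every table
carries the 95% binomial CI of the estimate and the null reference band
$\alpha \pm 1.96\sqrt{\alpha(1-\alpha)/B}$ that a calibrated test should
fall into; $\lambda$ is re-estimated per replicate and reported as the
across-replicate mean. `NA` p-values (logistic separation, which the
package flags explicitly including silent boundary drift of the linear
predictor) are excluded from the denominator and counted. The default
$B$ is 2,000; the package's own test suite runs desk-scale sizes
(B = 500 for homogeneous-null calibration and the strong-discrete pattern
at ~1,000 individuals and 5,500 SNPs; B = 250 for the hierarchical
pattern; B = 300 for the case-split sweep and B = 60 with paired cohorts
for its exclusion comparison), with the bands
always recomputed for the B in use.

Sweeps reproduce the secondary analyses: the case-split ratio $r$ (with
the exclusion comparison at $r \in \{0, 1\}$ — the same replicate cohorts
evaluated in full and reduced to the subpopulation containing both cases
and controls), the number of principal components
$k \in \{1, 2, 5, 10, 20, 50\}$ (one PCA per replicate, truncated per
$k$), and a rare DSL (MAF 0.01) against the common-MAF run.

## What the generator does and does not emulate

The synthetic founders reproduce the frequency differentiation of real
reference panels at the chosen $F_{ST}$, Hardy-Weinberg genotypes, and
unlinked markers. They do not reproduce linkage disequilibrium, haplotype
sharing, cryptic relatedness, genotyping error or missingness — all absent
from real-data panels' idealization here. Consequences worth knowing:

* Inflation factors under strong structure are reproduced in *direction*
  but not in printed value: $\lambda$ under distant discrete or
  hierarchical structure depends on the empirical differentiation profile
  of the real source populations, which a single-$F_{ST}$ Beta model does
  not replicate. Calibration statements (rates vs the 5% band) transfer;
  specific $\lambda$ magnitudes do not.
* With unlinked markers, the dimension of detectable structure equals the
  number of mean-distinct pools minus one. Real panels carry additional
  axes (LD, relatedness), which is the regime where the Eigenstrat
  statistic with few components has been reported to misbehave in
  hierarchical cohorts while the logistic regression on the same
  components stays calibrated. In this generator the five-population
  hierarchy is fully captured by the default five components, and
  Eigenstrat tracks the PC-adjusted regression closely; the package's
  acceptance suite states this expectation honestly rather than forcing
  it.

## Numerical choices

Frequency clipping at $10^{-4}$; $\chi^2_1$ median fixed at its exact
value 0.4549364; PCA via the eigendecomposition of the
individuals-by-individuals cross-product (the efficient side for
$n \ll p$), constant columns dropped with a warning; Tracy-Widom critical
values 0.9793 / 2.0234 / 3.2724 at levels 0.05 / 0.01 / 0.001; k-means
with 20 restarts; zero per-stratum p-values clamped at $10^{-300}$ before
the Fisher log; per-replicate seeds derived from the master seed by a
Lehmer-style counter map kept below $2^{31}$. Result TSVs are written with
a fixed column order, floats at 6 significant digits and LF endings, so
identical runs are byte-identical across platforms.

## A worked run

```{r example, eval = FALSE}
cfg <- scenario_config(4)              # two distant discrete populations
cohort <- build_cohort(cfg, seed = 1)
run_association_tests(cohort)          # one cohort, all default methods

ev <- eval_config(B = 200, seed = 1)
mc <- run_monte_carlo(cfg, ev, rr = 1) # false positive rates
autoplot(mc)

pc <- power_curve(cfg, eval_config(B = 200, seed = 1,
                                   rr_grid = c(1, 1.5, 2, 2.5)))
autoplot(pc)
```

## Known limitations

Single-locus disease model (no epistasis, no covariates other than
ancestry, binary phenotype only); one mating generation per structure
stage; no LD and therefore no realistic pruning questions; the label
estimator is a Tracy-Widom + k-means approximation standing in for more
elaborate model-based clustering; printed inflation factors from real
reference panels are reproduced only directionally, as discussed above.
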