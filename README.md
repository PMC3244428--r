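# stratsim

Simulation-based comparison of the strategies used to correct case-control
genome-wide association studies for **population stratification**.

When a cohort mixes ancestries and the case fraction differs between the
ancestral subgroups, every marker whose allele frequency differs between
those subgroups becomes spuriously associated with the phenotype. stratsim
is for statistical geneticists and methodologists who want to know — under a
*controlled*, reproducible model of population structure — which correction
keeps the false positive rate at its nominal level and what it costs in
power.

The package provides:

* a **cohort simulator**: Balding–Nichols founder pools with configurable
  FST (flat or hierarchical), Hardy–Weinberg founder genotypes, random
  mating and admixture, and a disease susceptibility locus (DSL)
  parameterized by prevalence `K` and genotype relative risks, with
  case/control genotype distributions obtained by Bayes inversion of the
  penetrance model: `P(g_i | case) = f_i p_i / K`,
  `P(g_i | control) = (1 - f_i) p_i / (1 - K)`, where
  `f_0 = K / (p_0 + RR1 p_1 + RR2 p_2)`, `f_1 = RR1 f_0`, `f_2 = RR2 f_0`;
* six **scenario presets** (homogeneous, admixed, close/distant discrete,
  hierarchical, and a case-split sweep design);
* the standard **association strategies**: Armitage trend test
  (`T = N rho^2 ~ chi2(1)`), Genomic Control
  (`lambda = median(T_null) / 0.4549`), the Eigenstrat statistic
  (`(N - k - 1) rho_resid^2` after residualizing on k genotype principal
  components), adjusted logistic/linear regressions (PCs, real labels,
  estimated labels, membership probabilities, labels + PCs), and
  Fisher/Stouffer meta-analyses across strata;
* a **Monte-Carlo evaluator** for false positive rate and power with
  binomial CIs and the `alpha ± 1.96 sqrt(alpha(1-alpha)/B)` reference
  band, plus sweeps over the case-split ratio, the number of principal
  components, and rare-DSL settings.

Everything user-facing takes and returns tibbles, chains with the pipe, and
has `autoplot()`, `tidy()` and `glance()` methods.

## Worked example

Two distant discrete populations (FST 0.11), unbalanced sampling (300/200
cases vs 200/300 controls), one DSL under the null of no association:

```r
library(stratsim)

cfg    <- scenario_config(4)
cohort <- build_cohort(cfg, seed = 1)
cohort
#> <strat_cohort> scenario 4: 1000 individuals (500 cases / 500 controls), 5500 null SNPs + 1 DSL
#>   subpopulations: pop1, pop2
#>   DSL freqs: 0.179, 0.282

run_association_tests(cohort)
#> # A tibble: 7 x 7
#>   method      statistic    df p_value lambda k_pcs note
#>   <chr>           <dbl> <dbl>   <dbl>  <dbl> <int> <chr>
#> 1 trend            8.71     1 0.00317  NA       NA <NA>
#> 2 gc               1.52     1 0.218     5.74    NA <NA>
#> 3 eigenstrat       4.44     1 0.0351   NA        5 <NA>
#> 4 reg_pcs          4.47     1 0.0344   NA        5 <NA>
#> 5 reg_real         4.57     1 0.0326   NA       NA <NA>
#> 6 reg_est          4.70     1 0.0301   NA       NA <NA>
#> 7 meta_fisher      8.43     4 0.0769   NA       NA <NA>
```

Read: this cohort carries real structure (the DSL is differentiated between
the populations, frequencies 0.179 vs 0.282, and the genome-wide inflation
factor is `lambda = 5.74`), and the *uncorrected* trend test calls the null
DSL significant at `p = 0.003`. Every corrected strategy pulls it back to
the 3–8% range. Rates over many replicates are what actually settles the
comparison:

```r
mc <- run_monte_carlo(cfg, eval_config(B = 200, seed = 1), rr = 1)
tidy(mc)[, c("method", "rejection_rate", "band_low", "band_high")]
autoplot(mc)                      # FP per method against the 5% band
```

Whole pipelines can also be driven from a YAML config
(`run_from_config("config.yaml")`, see `inst/scripts/stratsim.R` for the
command-line wrapper) with `simulate`, `test`, `evaluate` and `sweep`
stages, deterministic TSV/JSON outputs and a full config echo.

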