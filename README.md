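# sdvar — sex-differential expression variability analysis

`sdvar` detects genes whose **interindividual expression variability**
differs between the sexes (SDV genes) in bulk RNA-seq count data, and
ships the companion analyses used to characterize such genes.

Standard differential-expression tools compare group *means*. `sdvar`
compares group *dispersions*: counts for each gene are modeled as
negative binomial with variance `mu + sigma * mu^2`, and **both**
parameters are regressed on covariates through a log link
(a location-scale, GAMLSS-style model):

    log mu_i    = x_i' beta_mu + log(library_size_i * norm_factor_i)
    log sigma_i = x_i' beta_sigma

with `x_i` = intercept + sex + age + RIN + ischemic time + genotype
PCs. The overdispersion `sigma` is the squared biological coefficient
of variation, so a sex effect on `sigma` is a sex difference in
biological variability, tested while mean differences are modeled
rather than confounded. Two 1-df likelihood-ratio tests per gene
(`p_sigma_sex`: sex dropped from `sigma`; `p_mu_sex`: sex dropped from
`mu`) are BH-corrected, and genes passing the dispersion screen are
re-calibrated with a sex-label permutation null for
`beta_sigma_sex` — a guard against single-sample outliers fabricating
variance signal. A gene is called SDV when both the BH-adjusted LRT
p-value and the BH-adjusted empirical p-value are below 0.05.

Also included:

* `powerGrid()` — power/FPR simulations comparing the NB LRT with the
  Fligner–Killeen and Levene tests on `ln(counts + 1)`;
* `fisherCombinedPerm()` — cross-tissue overrepresentation
  meta-analysis (`T = -2 * sum(log p)`) with a permutation null,
  because hypergeometric p-values are discrete and break classical
  Fisher's method;
* `eGeneDepletion()` — per-tissue Fisher exact tests plus a
  permutation test of the median fold enrichment of eGenes among SDV
  genes;
* `pseudoBulk()` / `tauIndex()` — cell-type specificity
  (`tau = sum(1 - x/max x) / (n - 1)`) from labeled single-cell counts;
* `runEvoSim()` — forward simulation of a two-sex population under
  sex-specific stabilizing selection (`w = exp(-s * P^2)`), showing how
  stronger constraint in one sex yields SDV expression and reduced
  shared genetic variance;
* `simulateStudy()` and friends — synthetic data generators with known
  planted effects for every input the analyses need.

## Worked example

```r
library(sdvar)

cfg <- synthConfig(nGenes = 300, nMale = 120, nFemale = 120,
                   sdvFraction = 0.1, sdvLogSigmaEffect = 2, seed = 1)
study <- simulateStudy(cfg)
study
#> ExpressionStudy with 300 genes x 240 samples
#>   sex: 120 female / 120 male
#>   synthetic truth: 30 planted SDV genes

res <- runSDVPipeline(study, B = 200, seed = 2)
sdv <- res[res$is_sdv, ]
nrow(sdv)
#> [1] 32
head(as.data.frame(sdv[, c("beta_sigma_sex", "q_sigma_sex",
                           "perm_q", "direction")]), 5)
#>           beta_sigma_sex  q_sigma_sex perm_q     direction
#> gene00004     -2.1692741 2.357456e-20  0.000 female_higher
#> gene00018     -1.4642376 9.181234e-10  0.000 female_higher
#> gene00037      1.8279397 7.846001e-18  0.000   male_higher
#> gene00039      0.5837499 3.972911e-02  0.005   male_higher
#> gene00041     -1.6341994 3.779423e-12  0.000 female_higher
```

`beta_sigma_sex` is the sex effect on log overdispersion under
female-reference coding, so `gene00037` is about `exp(1.83) ≈ 6`-fold
more overdispersed in males; `q_sigma_sex` and `perm_q` are the two
BH-adjusted screens that both must fall below 0.05. Of the 30 planted
genes, 29 are recovered in this run, every called direction matching
the planted one. The specificity index behaves as its closed forms
require, e.g. `tauIndex(c(1, 0.5, 0))` is exactly `0.75`.

A thin command-line wrapper over these functions is installed at
`inst/scripts/sdv.R` (subcommands `simulate-data`, `run`, `power`,
`tau`, `evolve`), each run writing a provenance sidecar next to its
outputs.

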