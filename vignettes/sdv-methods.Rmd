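---
title: "Detecting sex-differential expression variability: models and methods"
author: "sdvar maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-differential expression variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most differential-expression machinery asks whether the *mean* expression
of a gene differs between groups. This package asks a different question:
does the *interindividual variability* of a gene's expression differ
between the sexes? Genes with sex-differentially variable (SDV) expression
are interesting because differences in variability can arise from
sex-specific biology — sex-specific regulatory architecture, hormonal
cycling, cell-type composition differences — and from sex-specific
evolutionary constraint (stronger stabilizing selection in one sex
shrinks that sex's variance).

Bulk RNA-seq counts are well described by a negative binomial (NB)
distribution. We use the NB2 parametrization with overdispersion
$\sigma$ (the reciprocal of the usual size parameter $\theta$):

$$\mathrm{Var}(y) = \mu + \sigma \mu^2.$$

The Poisson term $\mu$ captures counting noise; $\sigma$ is the squared
biological coefficient of variation and carries the biological
variability signal. Testing for a sex difference in variability is
therefore testing for a sex effect on $\sigma$ while *also* modeling any
sex effect on $\mu$, so that mean differences are not mistaken for
variance differences.

## The location-scale model

For each gene, both NB parameters are regressed on covariates through a
log link:

$$\log \mu_i = x_i^\top \beta_\mu + o_i, \qquad
  \log \sigma_i = x_i^\top \beta_\sigma,$$

where $o_i = \log(\text{library size}_i \times \text{normalization
factor}_i)$ is a fixed offset and $x_i$ contains an intercept, the sex
indicator (female = 0, male = 1) and nuisance covariates (age, RIN,
ischemic time, genotype PCs 1–5 when present). Three nested fits are
compared:

* model 1: sex in both $\mu$ and $\sigma$;
* model 2: sex dropped from $\sigma$;
* model 3: sex dropped from $\mu$.

$p_{\sigma,\text{sex}}$ is the 1-df likelihood-ratio test of model 1
against model 2, and $p_{\mu,\text{sex}}$ of model 1 against model 3.
The sign of $\beta_{\sigma,\text{sex}}$ gives the direction
(positive ⇒ males more variable under the female-reference coding; the
coding itself is a convention and flipping it flips all signs without
changing any p-value — a property the tests check).

### Fitting

The joint likelihood is maximized by a GAMLSS-style alternating scheme
implemented in C++: Fisher-scoring IRLS updates for $\beta_\mu$ given
$\sigma$ (cheap — no special functions), then a damped Newton step for
$\beta_\sigma$ given $\mu$ using analytic first and second derivatives
(one digamma/trigamma pass per outer iteration), with step halving on
the likelihood. Convergence requires the maximum absolute score to fall
below $10^{-4}(1 + |\ell|)$; the iteration cap is 200. Rare stalls are
polished by BFGS with analytic gradients from the incumbent and
re-certified by the alternating step. Warm starts matter for speed: the
mean model starts from an offset-aware intercept (first IRLS pass
refines the rest), the dispersion intercept from a Pearson moment
estimate; nested models start from the full-model solution, and
permutation refits start from the observed fit.

Numerical guards: $\sigma$ is floored at $10^{-8}$ through a clamp on
its linear predictor, and for $\sigma < 10^{-6}$ the likelihood and
scores switch to a Poisson-limit branch with a first-order $\sigma$
correction, keeping everything continuous as $\sigma \to 0$ (direct
$\log\Gamma$ evaluation at $1/\sigma$ loses precision there). Fits are
certified against a brute-force lattice search on tiny designs in the
test suite.

## The discovery pipeline

`runSDVPipeline()` applies, in order:

1. **CPM filter.** Genes with zero CPM in *any* sample are removed.
   This is deliberately strict: a single zero in a high-dispersion gene
   can dominate a variance estimate.
2. **Global outlier removal.** PCA on log2(CPM + 1) over samples; on
   every component explaining more than 5% of the variance, samples
   beyond 1.5 IQR of the quartiles are removed, in a single pass. The
   pseudocount is retained because this step precedes the final
   filtering state; for kept genes CPM is strictly positive anyway, so
   the choice is a dialect flag rather than a substantive one.
3. **Normalization.** Library sizes are recomputed on the kept matrix;
   upper-quartile normalization factors (edgeR's `"upperquartile"`)
   rescaled to geometric mean 1 give the offset
   $\log(\text{lib size} \times \text{factor})$.
4. **Per-gene dual LRTs** as above; the two p-value vectors are
   BH-adjusted independently across all converged genes. Non-converged
   genes are flagged and never called.
5. **Permutation calibration.** For genes passing the
   $q_{\sigma,\text{sex}} < 0.05$ screen, the sex labels alone are
   permuted (covariates stay attached to their samples), model 1 is
   refit, and the empirical p-value is the fraction of retained
   permutations with $|\beta_{\sigma,\text{sex}}^{perm}| >
   |\beta_{\sigma,\text{sex}}^{obs}|$ — strict inequality, denominator
   the number of retained permutations, no +1 smoothing. This guards
   the parametric test against per-gene expression outliers, which can
   fabricate dispersion effects. Permutation refits that fail to
   converge are dropped from the null; if more than 20% drop, the gene
   is flagged unreliable. Empirical p-values are BH-adjusted over the
   screened genes (adjusting over all tested genes is available as
   `permScope = "all"`).
6. **Call.** A gene is SDV iff both adjusted values are below
   $\alpha = 0.05$ and all fits converged.

### Replication analysis

`replicationAnalysis()` splits samples 70/30 stratified by sex, runs the
full pipeline on the discovery set, and declares a discovery gene
replicated if, in the replication set, the dispersion LRT p-value and
the permutation p-value are both below 0.05 *and* the more-variable sex
agrees. `nullReplicationRate()` draws random gene sets from all
discovery-tested genes and recomputes the replication rate, giving the
null distribution against which an observed rate should be judged; note
this null is expected to sit above the nominal 5% because random draws
include true signal.

## Power and false-positive-rate simulations

`powerGrid()` reproduces the comparison that motivates the model: NB
pairs with equal means ($\mu = 1500$, total $n = 400$; balanced 200/200
and unbalanced 320/80) and overdispersions $\sigma$ vs
$\sigma + \Delta\sigma$ are tested with (i) Fligner–Killeen and (ii)
mean-centered Levene on $\ln(\text{counts} + 1)$, and (iii) the NB LRT
on raw counts ($\sigma \sim$ group, $\mu \sim$ group vs constant
$\sigma$). The log transform for the rank tests follows the observation
that Levene's power improves markedly on the log scale. The default
grid sweeps $\sigma \in \{0.05, 0.1, 0.2, 0.4\}$ and $\Delta\sigma \in
\{0, 0.25, 0.5, 1\} \times \sigma$; the source publication varied these
parameters without printing the exact values, so the grid is our choice
of stand-in, centered on the $\sigma$ regime typical of expressed
genes. $\Delta\sigma = 0$ rows are FPR estimates. Brown–Forsythe
(median) centering for Levene is available as a flag.

## Overrepresentation meta-analysis

Per tissue, overrepresentation of a label (e.g. male-higher
variability) in a gene set is a one-sided hypergeometric tail
$P(X \ge k)$. Combining tissues with Fisher's statistic
$T = -2\sum_t \ln p_t$ would classically use a $\chi^2$ null — invalid
here because the hypergeometric p-values are discrete and non-uniform
under the null. Instead the null is built by permuting gene labels
within each tissue and recomputing $T$; the empirical p-value is
$\#\{T^{perm} \ge T^{obs}\}/B$ (the $\ge$ makes the test conservative
under ties at $T = 0$). Per-tissue p-values are floored at the smallest
positive double before logging. Tissues enter only with at least 20
genes of either high-variability label, and BH adjustment runs across
sets. The test suite demonstrates the motivation directly: under null
labels the permutation version holds its size where the analytic
$\chi^2$ reference would not be trustworthy.

`eGeneDepletion()` applies the same permutation logic to a depletion
question: per tissue, fold enrichment of eGenes among SDV genes
(observed / expected overlap, expected = product of margins over
universe) plus a two-sided Fisher exact test; across tissues, the
median fold is compared with medians from within-tissue label
permutations, one-sided towards depletion
($\#\{\text{median}^{perm} \le \text{median}^{obs}\}/B$).

## Cell-type specificity

`pseudoBulk()` sums raw counts within cell types and converts each
pseudo-bulk vector to CPM; `tauIndex()` computes
$\tau = \sum_i (1 - x_i/\max x) / (n - 1)$ on log2(CPM + 1). The
pseudocount is our reading of "log-transformed CPM" (a zero CPM has no
log); dropping zero-CPM genes instead is the alternative dialect, and
marker genes give $\tau = 1$ and uniform genes $\tau \approx 0$ under
both.

## Sex-specific stabilizing selection simulator

`runEvoSim()` is a forward Monte Carlo model of one gene's expression
evolving in a diploid, dioecious population of 500: three additive loci
(shared, male-specific, female-specific; two alleles each, initialized
standard normal), phenotype $P = G + E$ with $G$ the sum of the shared
and own-sex locus values and $E$ fresh standard normal each generation,
Gaussian viability selection $w = e^{-sP^2}$ with sex-specific $s$
(equal condition 0.005/0.005; sex-specific 0.005 in males, 0.05 in
females), then 100 surviving males and 100 females drawn with
replacement, paired, five offspring per pair, Mendelian transmission
with free recombination (loci in linkage equilibrium), random offspring
sex, and mutation adding a standard normal deviate to one allele per
locus per individual with probability $5 \times 10^{-3}$. Every 10
generations the phenotypic variance within each sex and the variance of
the shared-locus allelic effects are recorded.

Choices the verbal model leaves open, fixed here: diploidy is realized
as true Mendelian transmission (one allele per parent per locus);
mutation hits one uniformly chosen allele; if a sex has zero survivors
the viability draw for that generation is repeated (selection is soft
at the demographic level); the initial sex ratio is deterministic
250/250; generations are non-overlapping. "Variance of the shared
allelic effects" is computed over the $2N$ alleles, with the
per-individual locus-sum variant available via `sharedVarOver =
"individuals"` — both shrink under increased female constraint.

## The synthetic-data generator

`simulateStudy()` draws NB counts with per-gene baselines
$\log \mu \sim U(\log 150, \log 3000)$ (CPM scale) and
$\sigma \sim U(0.05, 0.15)$, log-uniform library sizes
($5 \times 10^5$–$2 \times 10^6$), small standard-normal-scale effects
of the nuisance covariates on $\log\mu$ (so covariate adjustment is
actually exercised), exact sex counts, and planted effects: a fraction
of genes receives $\pm$`sdvLogSigmaEffect` on $\log\sigma$ in males
(random sign ⇒ random direction) and optionally a mean effect. The
baseline ranges emulate genes that *survive* the zero-CPM filter at
$n \approx 400$ — the regime the original power analysis treats as
typical (means near 1500, overdispersion near 0.1). Genes outside that
regime are mostly removed by the filter before testing, so planting
effects there would test the filter, not the test.

Outlier samples are simulated as whole-sample *profile* perturbations:
each gene of an outlier sample receives an independent
$N(0, \text{outlierScale}^2)$ shift on its log mean. A strictly uniform
shift across genes was rejected because CPM normalization cancels it
exactly, leaving nothing for the PCA rule to find; after depth
normalization, a "global expression outlier" is by definition a sample
whose profile deviates.

What the generator does *not* emulate: tissue-sharing correlation
across genes, batch effects, gene-length effects, realistic covariate
distributions (the source data's covariates are not publicly modeled),
or zero-inflation beyond NB sampling. Passing tests on this generator
therefore show the machinery is correct and calibrated under the NB
location-scale model, not that real-tissue discoveries are immune to
model misspecification — that is what the permutation stage and the
replication analysis are for.

## Problem sizes used by the test suite

The packaged checks run, among others: FPR calibration from 1,000 null
pairs (exact binomial 99% band around $\alpha$); the unbalanced power
grid at 1,000 replicates per point; parameter recovery at $n = 10^4$
and LRT-null uniformity from 2,000 replicates at $n = 100$; twenty
end-to-end studies of 1,000 genes (200/sex, 10% planted at
$\beta_\sigma = 1.5$, $B = 200$ permutations) for average recall and
realized false-discovery proportion; meta-analysis size from 500 null
sets at $B = 2000$; and the selection simulator at 10 replicates ×
1,000 generations per condition. These sizes are scaled-down but
statistically adequate versions of the full study settings (e.g.
$B = 1000$ permutations per gene, 30 × 2,000 generations), which the
package defaults retain.

## Known limitations

* The LRT relies on the $\chi^2_1$ reference; at very small $n$ or for
  genes near the $\sigma \to 0$ boundary it can be conservative, which
  is one reason the pipeline keeps the permutation stage.
* Tissues are processed independently; no cross-tissue sharing model.
* The permutation empirical p-value has resolution $1/B$; at
  $B = 1000$ p-values below $10^{-3}$ are reported as 0 and enter BH
  as such (the published procedure's convention, kept deliberately).
* `uqNormFactors()` requires a positive 75th percentile per sample;
  extremely sparse samples must be excluded upstream.
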