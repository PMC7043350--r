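---
title: "Methods: functional-unit-wide association with stability selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional-unit-wide association with stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fuwas)
```

# Overview

Classical GWAS tests one variant at a time against a phenotype and pays a
genome-wide multiple-testing price. `fuwas` inverts the workflow: variants
are first grouped by *predicted regulatory function* — a variant belongs to
a **functional unit (FU)**, i.e. a (chromatin feature, cell line, optional
treatment) triple, when its predicted allele-specific effect on that
feature is stronger than essentially anything seen among random background
variants — and each FU's variant set is then tested *jointly* in one
multivariate penalized regression with stability selection. The output is a
catalog of **dSNPs**: variants selected at high frequency in at least one
FU model, each annotated with the regulatory context in which it was
selected.

This vignette records the statistical choices the package makes and why.

# Regulatory filtering with e-values

For each variant and FU, two allele-specific scores `p_ref` and `p_alt` in
(0, 1) summarize the predicted probability that the feature is active on
each allele. An effect size is computed per FU by one of two metrics:

* `abs_diff`: `|p_alt - p_ref|`;
* `diff_times_logfold`: `|p_alt - p_ref| * |log2(odds(p_alt) / odds(p_ref))|`,
  which rewards effects that move the score across its dynamic range rather
  than within the saturated tails. Probabilities are clamped away from 0
  and 1 by `1e-6` before the log-odds so the metric is finite.

The **e-value** of an observed effect `e` against an FU-specific background
of `N` effects from random variants is the empirical tail probability

```
e-value = #{background effects >= e} / N
```

Ties count as "greater or equal", and the smallest attainable value is
`1/N`: an empirical tail probability of zero is not evidence of an
infinitely strong effect, only of a background too small to resolve it.
Backgrounds are per-FU because score distributions differ sharply between
features; a global background would let high-variance features dominate.
The filter keeps variants with e-value strictly below the cutoff
(default `5e-5`), so a one-million-variant background is the intended
operating scale — with `N = 1e6` the cutoff keeps roughly the top 50
background-equivalents. `background_distribution()` warns when `N < 1000`.

By construction, e-values of effects drawn from the background law itself
are uniform on `{1/N, 2/N, ..., 1}`; this is the calibration property the
test suite checks by Kolmogorov–Smirnov test, and it is what makes the
cutoff interpretable as an expected background yield of `N * cutoff`.

# The per-FU association model

For FU `k` with variant set `S_k`, dosages `X_j` (expected alternative
allele counts in `[0, 2]`, encoded `2 P(hom-alt) + P(het)`), covariates
`C`, and outcome `y`, the model is the L1-penalized GLM

```
min over (beta, gamma, beta_0):
  (1/n) * NLL(y; X beta + C gamma + beta_0) + lambda * sum_j |beta_j|
```

with a Gaussian or binomial likelihood. Two points are deliberate:

* **Covariates are never penalized.** Sex, age, cohort indicators, and
  ancestry components are forced into every model (`penalty.factor = 0`),
  so shrinkage acts only on SNP effects and confounder adjustment is not
  traded off against sparsity.
* The penalized solver is `glmnet`; coefficients are extracted exactly at
  the requested `lambda` with a convergence threshold of `1e-12`. The
  lambda path is 100 log-spaced values from the data-derived maximum, with
  minimum ratio `1e-3` (`1e-2` when `n < p`), matching the solver's own
  conventions so path-based and single-lambda answers agree.

The suite pins the solver to two independent oracles: the orthonormal-design
soft-thresholding closed form, and the unpenalized MLE at `lambda = 0`.

# Stability selection and error control

A single lasso fit is unstable in LD: tiny perturbations reshuffle which of
several correlated variants carries the coefficient. Stability selection
replaces "selected by one fit" with "selected in a high fraction of
subsample fits":

1. Draw `B = 100` random subsamples of size `floor(n/2)` without
   replacement.
2. On each subsample, take the **first q variables to enter the
   regularization path** (the `q`-rule fit). Forced covariates do not count
   towards `q`.
3. The selection frequency `pi_j` is the fraction of subsamples selecting
   variant `j`; variants with `pi_j >= 0.7` are selected.

`q` is not free: given the frequency cutoff `pi_thr` and a target
**per-family error rate** (PFER — the expected number of falsely selected
variables per FU model), the Meinshausen–Bühlmann bound

```
PFER <= q^2 / ((2 * pi_thr - 1) * p)
```

is inverted to `q = floor(sqrt(PFER * (2 pi_thr - 1) * p))`, capped at `p`.
The defaults `pi_thr = 0.7`, `PFER = 1.0` give `q = floor(sqrt(0.4 p))` —
e.g. `q = 2` for a 10- or 20-SNP FU and `q = 8` for a 200-SNP FU. When the
formula yields `q < 1` the FU is too small to control errors at the
requested level and the package refuses to proceed rather than silently
running an uncontrolled model. A small numeric guard (`+ 1e-8` inside the
floor) protects the integer boundary from floating-point representation of
`2 * 0.7 - 1`.

The bound assumes exchangeability and is conservative in practice; the
package's acceptance suite verifies the operational consequence directly:
under a global null (phenotype independent of all genotypes), the mean
number of selected SNPs per FU model stays at or below the configured PFER.

Two open choices resolved here:

* **Plain subsampling, not complementary pairs.** The original bound uses
  simple random subsamples; complementary-pair variants tighten constants
  but change the meaning of `B`. The package implements the plain scheme
  the bound was derived for.
* Subsample fits that fail numerically are dropped and frequencies are
  computed over the effective number of fits, which is reported as
  `B_effective`.

A variant is a **dSNP** if it reaches the frequency cutoff in at least one
FU model. The same variant can be a dSNP in several FUs; the catalog keeps
one row per (variant, FU) pair, which is also what the dummy-node network
preserves downstream.

# The GWAS baseline

For comparison, `gwas_scan()` runs the standard univariate GLM per variant
with the same covariates and two-sided Wald p-values, and
`fixed_effects_meta()` combines per-cohort estimates with inverse-variance
weights (`w = 1/se^2`). `overlap_report()` then tiers dSNPs by the best
univariate p-value among the dSNP itself and its LD proxies:
`genome_wide` (`p < 5e-8`), `nominal` (`p < 0.05`), or `none`. The tiers
quantify how much of the catalog a univariate analysis would have found —
the motivating claim being that joint, regulatory-informed selection
recovers signal below genome-wide significance.

# Predictive evaluation

`predictive_comparison()` asks whether dSNPs carry predictive information
beyond univariate hits: samples are split 80/20 (stratified on the outcome
for binary traits), an L1 model on the dSNP set and one on the GWAS-hit set
are tuned by 10-fold cross-validation on the training set only
(`lambda.min`, stratified folds for binary outcomes), and both are scored
on the held-out test set by AUC. The AUC is computed by the rank-based
Mann–Whitney identity with average ranks for ties, which the suite checks
against brute-force pairwise counting. No test-set information enters
model fitting or tuning — the suite includes a leakage test in which
permuting the test outcomes leaves training untouched.

# LD handling

`ld_r2()` is the squared Pearson correlation of dosages. Pruning
(`ld_prune()`) follows the indep-pairwise idiom: slide a window of 50
variants in steps of 5 along each chromosome; within a window, greedily
remove the lower-MAF member of any pair with `r^2 > 0.5` (on ties, the
later position). The window is measured in *variants*, not base pairs,
matching the `50 5 0.5` parameterization convention. Proxy search
(`find_proxies()`) is inclusive (`r^2 >= 0.5`) within 1 Mb and always
returns the target itself with `r^2 = 1`, so downstream overlap and
enrichment logic can treat "a variant and its proxies" uniformly.

# QTL integration and enrichment

`cis_pairs()` enumerates variant–trait pairs within an inclusive 1 Mb
window on the same chromosome; `qtl_scan()` fits the linear model per pair
with covariates and adjusts across *all tested pairs* by Benjamini–Hochberg
(`bh_fdr()`, significant at `q < 0.05`).

`permutation_enrichment()` measures overlap of the dSNP set (optionally
expanded by proxies) with an annotation, against `n_perm >= 100` random
same-size draws from the analysis universe. The p-value is add-one
corrected, `(1 + #{null >= observed}) / (1 + n_perm)`, so it is never zero
and is honest about Monte-Carlo resolution; fold change is
`observed / mean(null)`.

# The dummy-node network

Connecting a multi-FU dSNP directly to features and cell lines would
conflate contexts: a variant selected in `TF1:CL1` and `TF2:CL2` would
appear linked to `TF1` *and* `CL2`, a combination in which it was never
selected. `build_network()` therefore inserts one *dummy node* per
(variant, FU) catalog row; the variant, the feature, the cell line, and the
optional treatment all attach to the dummy, never to each other. The
catalog is exactly recoverable from the dummy nodes (a lossless round
trip), and FDR-significant eQTL/meQTL edges plus CpG–gene (eQTM) edges
complete the graph. `three_way_interactions()` enumerates
(variant, CpG, gene) triangles — variants with joint epigenetic and
transcriptomic effects. Because the graph is undirected, edge orientation
is recovered from node kinds, not storage order.

# The synthetic generator

Real genotypes and regulatory scores cannot ship with the package, so every
stage is exercised by `simulate_study()`:

* **Genotypes**: per LD block, two haplotypes per sample are drawn from a
  latent AR(1) Gaussian with parameter `rho` and thresholded at each
  variant's MAF quantile; dosage is the haplotype sum. This is the simplest
  generator with tunable pairwise `r^2` decay. Thresholding attenuates
  correlation, so latent `rho = 0.95` yields dosage `r^2` well below
  `0.9` — adjacent-pair LD is monotone in `rho`, which is the property the
  generator guarantees.
* **Scores**: FU members receive effects placed above the maximum of that
  FU's background draw, so they always survive the e-value filter;
  non-members are drawn from the background law and pass at the cutoff
  rate.
* **Phenotypes**: the additive model on *standardized* causal dosages (so
  planted effect sizes are MAF-independent), plus standardized covariate
  effects; Gaussian noise for the linear family, Bernoulli(expit) for the
  logistic.
* **Seeds**: one master seed fans out to per-stage child seeds
  (`child_seeds()`), so genotypes, scores, and phenotypes are individually
  reproducible, and `with_seed()` restores the caller's RNG state.

Default study size is n = 1,000 with 20 FUs of 10 SNPs and 2 causal SNPs
each at standardized effect 0.5. The FU size and the linear default link
are a deliberate pairing: all 40 planted causal SNPs feed the same
phenotype, so each SNP's marginal signal is diluted by the other 39, and
the logistic link attenuates standardized effects further; meanwhile the MB
rule allows only `q = floor(sqrt(0.4 p))` selections per subsample. Under
these constraints the planted signal is reliably recoverable at the
defaults, which is what the recovery tests require. The generator makes no
claim to coalescent realism — no recombination maps, no population
structure beyond injected ancestry covariates.

# Reproducibility

All stochastic functions take explicit seeds and never mutate the global
RNG state. `scripts/acceptance.R` re-runs the global-null error-control
experiment end to end from a single command-line seed. The test suite
freezes every derived constant (soft-threshold solutions, meta-analysis
closed forms, BH step-up values, hand-computed `r^2`) as an independent
oracle rather than trusting the implementation under test.
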