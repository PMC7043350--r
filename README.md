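# fuwas

Functional-unit-wide association studies: joint, regulatory-informed
variant–phenotype association with penalized regression and stability
selection.

## What it does

A classical GWAS tests each variant marginally and pays a genome-wide
multiple-testing price, leaving most sub-threshold regulatory signal on the
table. `fuwas` turns the analysis around:

1. **Group variants by predicted regulatory function.** Each variant gets
   allele-specific scores for its effect on a *functional unit* (FU) — a
   chromatin feature in a cell line, optionally under a treatment. An
   empirical **e-value** compares the allelic effect against a large
   background of random variants; variants below a strict cutoff
   (default `5e-5`) form that FU's set.
2. **Test each FU set jointly.** Per FU, an L1-penalized regression of the
   phenotype on all member dosages (covariates forced in, unpenalized) is
   wrapped in **stability selection**: 100 subsamples of half the data,
   per-subsample selection count `q` chosen by the Meinshausen–Bühlmann
   bound so that the expected number of false selections per FU model
   (PFER) stays below 1. Variants selected in ≥ 70% of subsamples are
   **dSNPs** — association calls that come with their regulatory context
   attached.
3. **Compare, annotate, integrate.** The package ships a univariate GWAS
   baseline with fixed-effects meta-analysis and tiered overlap reports,
   train/test AUC comparison of dSNP-based vs GWAS-hit-based predictors,
   dosage LD pruning and proxy search, cis eQTL/meQTL scans with BH-FDR,
   permutation enrichment against annotations, and a dummy-node graph that
   links variants, FUs, genes, and CpGs without conflating multi-FU
   contexts.

Because real genotype panels and deep-learning regulatory scores cannot
ship in a package, a seeded synthetic generator (`simulate_study()`)
produces LD-structured genotypes, FU-structured scores, and phenotypes with
known ground truth, so the full pipeline is testable offline.

See the methods vignette (`vignettes/fuwas-methods.Rmd`) for the
statistical details and design decisions.

## Worked example

Simulate a small study with one causal SNP per FU, fit the per-FU
stability-selection models, and compare against the univariate baseline:

```r
library(fuwas)

cfg <- sim_config(n_samples = 800, n_blocks = 6, snps_per_block = 12,
                  n_fus = 6, snps_per_fu = 10, causal_per_fu = 1,
                  causal_beta = 0.6, family = "logistic",
                  background_n = 50000, seed = 42)
study <- simulate_study(cfg)
study
#> sim_study: 800 samples, 72 variants, 6 FUs, 6 causal rows

fit <- fuwas(study$genotypes, study$phenotypes, study$fu_sets,
             config = stability_config(seed = 7))
fit
#> fuwas fit (logistic family): 6 FU models, 0 skipped, n = 800
#> dSNP calls: 6 (6 unique variants across 6 FUs)

fit$catalog
#>   variant_id   fu_id selection_frequency q n_snps_in_fu
#> 1    snp_1_2 CL1:TF1                0.99 2           10
#> 2    snp_2_1 CL2:TF2                0.99 2           10
#> 3    snp_3_5 CL3:TF3                1.00 2           10
#> 4    snp_4_2 CL4:TF4                1.00 2           10
#> 5    snp_5_3 CL5:TF5                1.00 2           10
#> 6    snp_6_3 CL1:TF6                1.00 2           10

dsnps(fit)
#> [1] "snp_1_2" "snp_2_1" "snp_3_5" "snp_4_2" "snp_5_3" "snp_6_3"

study$truth$causal$variant_id   # the planted causal SNPs
#> [1] "snp_1_2" "snp_6_3" "snp_2_1" "snp_3_5" "snp_4_2" "snp_5_3"
```

The six dSNPs are exactly the six planted causal variants. The univariate
baseline shows what a marginal analysis would have concluded about them:

```r
scan <- gwas_scan(study$genotypes, study$phenotypes)
proxies <- find_proxies(dsnps(fit), study$genotypes)
overlap_report(fit$catalog, scan, proxies)
#> dSNP vs GWAS overlap:
#>
#> genome_wide     nominal        none
#>           4           2           0
#>   variant_id        own_p       best_p best_variant        tier
#> 1    snp_1_2 3.010118e-08 3.010118e-08      snp_1_2 genome_wide
#> 2    snp_2_1 6.378446e-07 6.378446e-07      snp_2_1     nominal
#> 3    snp_3_5 9.822137e-14 9.822137e-14      snp_3_5 genome_wide
#> 4    snp_4_2 1.741151e-13 1.741151e-13      snp_4_2 genome_wide
#> 5    snp_5_3 5.692899e-08 5.692899e-08      snp_5_3     nominal
#> 6    snp_6_3 1.146637e-09 1.146637e-09      snp_6_3 genome_wide
```

Two of the six dSNPs sit below genome-wide significance in the marginal
scan — the kind of signal the joint, regulatory-informed analysis is built
to recover.

Real data enters through `read_genotypes()` (VCF with DS/GP/GT fields, or
a dosage TSV), `read_phenotypes()`, and `read_scores()` /
`read_backgrounds()`; `align_samples()` intersects and orders samples
across inputs.

## Testing

The suite uses `testthat` (edition 3) and runs against the installed
package:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "fuwas", load_package = "installed")'
```

Module tests pin every numeric routine to an independent oracle
(closed-form soft-thresholding, brute-force AUC and BH step-up, exhaustive
window scans, hand-computed correlations); the acceptance tests in
`tests/testthat/test-acceptance.R` check the end-to-end statistical
guarantees, including null calibration of the GWAS baseline, permutation
enrichment, and e-values, and recovery of planted causal variants.

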