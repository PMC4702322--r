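# countbench

Benchmarking framework for the analysis of multi-factor RNA-Seq read-count
studies of individual organisms. Motivated by large factorial designs of
the Drosophila Genetic Reference Panel type — genotype (G) x environment
(E) x sex (S) with replicate individuals — where the analyst must choose a
normalization method, a low-expression filtering strategy, a dispersion
estimator and a distributional engine before any biology can be read off.
`countbench` implements the whole chain and the instruments to compare its
branches on synthetic data with known ground truth.

What is inside:

* **Normalization** — total count (TC), upper quartile (UQ), median (Med),
  trimmed mean of M-values (TMM), median-of-ratios size factors (DESeq),
  full quantile (Q), RPKM, raw counts (RC), and a minimal RUVg
  control-gene factor construction. Each method is implemented from its
  defining formula and tested against an independent brute-force oracle.
* **Empirical detection threshold** — the 95th percentile of intergenic
  background counts on the log2(normalized + 1) scale, with three
  filtering workflows (filter after normalization, before it, or not at
  all).
* **Sample QC** — genotype verification from SNP mismatch fractions
  (r_ij = D_ij/M_ij with a per-sample min-max rescale R_ij), sex
  verification by Spearman correlation to per-sex median expression
  standards, a minimum mapped-read filter, and a duplicate-library test
  of technical variation (NB model `log(mu) = b0 + F` with fly `F` as the
  factor).
* **Differential expression** — a per-gene negative-binomial GLM
  (`x ~ NB(mu, mu + mu^2 phi)`, log link) fitted by IRLS at fixed
  dispersion, with likelihood-ratio tests over a nested model ladder for
  `S, G, E, GxE, GxS, ExS, GxExS`, three approaches to the first-order
  interactions, two dispersion modes (trend-maximum and empirical-Bayes
  shrink), and a vectorized ln&ANOVA alternative; Benjamini-Hochberg FDR
  within term.
* **Power** — closed-form noncentral-F power for the factorial design,
  the conservative minimum-noncentrality bound `lambda_min = n d^2 / 2`,
  detectable-fold-change curves, a Monte-Carlo cross-check, and an
  empirical subsampling power procedure.
* **Comparison** — Jaccard/recall agreement between significant-gene
  sets, multi-condition overlaps, and a PCA diagnostic.
* **Synthetic data** — a gamma-Poisson generator emulating the study
  structure (heavy-tailed expression, log-normal dispersions, spike-in
  controls, intergenic background, duplicate libraries, SNP base calls)
  with full ground truth.

## Worked example

Simulate a small factorial study, run the default analysis (DESeq
normalization, workflow 1, NB-GLM ladder), and compare against truth:

```r
library(countbench)

cf  <- simulation_config(n_genes = 2000, n_intergenic = 500,
                         a = 6, b = 3, c = 2, n_per_cell = 4,
                         rng_seed = 20260101)
sim <- simulate_experiment(cf)

cfg <- analysis_config(normalization_method = "DESeq", workflow = 1)
run <- workflow_de(cfg, sim$counts, sim$intergenic, sim$features,
                   sim$design, engine = "nbglm")

run$prep$threshold
#> threshold_result (DESeq): 3.023 log2(normalized+1) at the 95th percentile of 500 intergenic features
sapply(run$de, function(tab) sum(tab$significant))
#>     S     G     E   GxE   GxS   ExS GxExS
#>   494   392   232   158   123    88    53
```

The threshold says: a gene whose DESeq-normalized count never reaches
about 2^3.02 ≈ 7.1 in any library is indistinguishable from intergenic
background and is dropped. The per-term counts are genes significant at
FDR < 0.05 for each model term; with the generator's defaults (20 % of
genes sex-regulated, smaller fractions for the other terms) the ordering
S > G > E > interactions reflects the planted truth.

The numbered scripts under `analysis/` walk the full study end to end and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R               # data + truth + SNP calls
Rscript analysis/02_normalize_threshold.R    # per-method thresholds
Rscript analysis/03_qc.R                     # genotype/sex/tech-rep QC
Rscript analysis/04_differential_expression.R# DE + workflow/engine agreement
Rscript analysis/05_power.R                  # power curve + subsampling
```

`analysis/03_qc.R`, for instance, prints:

```
genotype verification: 100.0% of libraries assigned to their true line (0 ties)
sex verification: 158/158 libraries pass at same-sex correlation >= 0.795
duplicate-library fly-factor test: 767 genic and 0 spike-in genes significant (FDR < 0.05)
PCA: PC1 explains 28.0% of variance; sex silhouette on PC1 = 0.98
```

— genotype and sex labels are fully recoverable from the data, real
fly-to-fly biology shows up in duplicate libraries while the spike-in
controls stay silent, and the first principal component separates the
sexes.

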