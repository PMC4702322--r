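---
title: "Benchmarking normalization and differential expression for multi-factor RNA-Seq counts"
author: "countbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking normalization and differential expression for multi-factor RNA-Seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countbench)
```

## The problem

In a factorial RNA-Seq study of individual organisms — here modeled on a
design with 16 inbred genotypes (G), 3 replicate environments (E), 2 sexes
(S) and up to 8 individuals per cell — every analysis result depends on a
chain of choices made before any hypothesis is tested: how read counts are
normalized across libraries, whether and when low-expression genes are
filtered out, how overdispersion is estimated, and which distributional
engine tests each model term. `countbench` implements that whole chain as
composable, separately testable pieces, so the impact of each choice can be
quantified on data with known ground truth.

## Normalization

Seven methods plus raw counts (`RC`) are implemented exactly from their
defining formulas:

* **TC, UQ, Med** divide sample $k$ by a ratio: its per-sample summary
  (total mapped reads $N_k$, upper-quartile count, or median count) over
  the mean of that summary across samples. The quartile and median are
  computed after discarding genes that are zero in every sample; those
  genes stay in the output.
* **DESeq-style size factors**: the reference pseudo-sample is the
  per-gene geometric mean across samples; $s_k$ is the median over genes
  with a positive geometric mean of $x_{ik}/\mathrm{geomean}_i$, and the
  output is $x_{ik}/s_k$. The median is taken on the ratio scale; when the
  number of usable genes is even this interpolates arithmetically between
  the two middle ratios (a log-scale median would interpolate
  geometrically; the two agree whenever the count is odd).
* **TMM**: per-gene log-ratios $M$ and log-abundances $A$ against a
  reference sample (the one whose upper quartile is closest to the mean
  upper quartile; ties go to the lowest index), computed over genes
  nonzero in both; genes in the middle 40 % of $M$ and middle 90 % of $A$
  are kept; the factor is $2^{\sum wM/\sum w}$ with inverse
  approximate-asymptotic-variance weights
  $w = \left[(N_k-x_{ik})/(N_k x_{ik}) + (N_r-x_{ir})/(N_r x_{ir})\right]^{-1}$.
  Factors are rescaled to geometric mean 1 before use (switchable); the
  normalized values are counts divided by the effective library size
  $f_k N_k$ and rescaled by the mean effective library size so they stay
  count-like.
* **Q** (full quantile) replaces each sample's sorted profile by the mean
  sorted profile; tied counts receive the mean of the slots the tie block
  spans, which makes the result deterministic but means sorted columns are
  exactly equal only in the absence of ties.
* **RPKM** is $x \cdot 10^9 / (N_k \cdot \mathrm{length_{bp}})$.
* **RUVg** (minimal form) extracts $k$ unwanted-variation factors as the
  leading right-singular vectors of the row-centered $\log(x+1)$ submatrix
  of negative-control (spike-in) genes, for use as model covariates. It is
  constructed but not wired into the default pipeline.

All quantiles in the package use linear interpolation between order
statistics (type 7). No convention is stated for the original analyses;
type 7 is the dominant software default, and fixing it makes every test
exact.

Library sizes $N_k$ are computed once from the raw matrix and **frozen**:
filtering never changes them. This is deliberate — depth is a property of
the sequencing run, not of the gene set under analysis — and it is what
makes TC and RPKM exactly invariant to the filtering workflows below.

## Empirical detection threshold and the three workflows

Reads landing in intergenic regions estimate the background a truly silent
gene would show. Genic and intergenic rows are pooled, normalized
*together* by the method under study, and the detection threshold is the
95th percentile of the pooled intergenic values on the
$\log_2(\text{normalized}+1)$ scale. Intergenic features shorter than the
read length (default 76 bp) cannot carry a uniquely mapped read and are
excluded up front. Pooling all samples into one distribution yields a
single scalar threshold per method, matching the one-number-per-method
form in which such thresholds are reported; a per-sample variant would
give a vector with no clear aggregation rule.

A gene is removed only if it is below threshold in **every** sample — one
individual above threshold rescues it. Three workflows order the stages:

1. **Workflow 1**: normalize (and estimate distribution parameters) on all
   genes, then filter.
2. **Workflow 2**: filter the raw counts first, then re-normalize the
   survivors and estimate on them (library sizes stay frozen).
3. **Workflow 3**: no filter.

`apply_workflow()` returns both the test matrix and the *estimation*
matrix, because the difference between workflows 1 and 2 acts through two
routes: normalization parameters (medians, quartiles, rank profiles) that
move when low genes are removed, and the dispersion trend, which is fitted
over a different gene set. TC and RPKM values are workflow-invariant by
construction; the median is not, which is the mechanism behind the
filtering-sensitivity results the comparison module quantifies.

## Sample QC

* **Genotype**: for sample $i$ and reference line $j$, $r_{ij} =
  D_{ij}/M_{ij}$ (mismatched over matched SNP sites, counted over sites
  called in both; pairs with no comparable site are flagged and excluded).
  $R_{ij}$ rescales each row to $[0,1]$ (1 at the minimum $r$, 0 at the
  maximum); the sample is assigned to the line with $R=1$, fails if
  $r > 0.10$ to that line, and ties (duplicated lines) are flagged.
* **Sex**: a standard profile per sex is the per-gene median of normalized
  counts over that sex's samples; each sample needs a Spearman correlation
  of at least 0.795 with its same-sex standard. Standards are computed
  leave-one-out by default: with hundreds of samples per sex the
  difference from the all-samples standard is negligible, but at synthetic
  scale (a handful of samples per sex) including the sample in its own
  standard inflates the correlation. The threshold 0.795 is retained as
  the default for fidelity even though it was originally derived from a
  specific data set's own correlation distribution; it is a plain
  argument.
* **Depth**: libraries under 2.5 million mapped reads (inclusive boundary:
  exactly 2.5 million passes) are flagged.
* **Duplicate libraries**: for individuals sequenced twice, the NB model
  $\log\mu = \beta_0 + F$ with the individual fly $F$ as the only factor
  is tested per gene by likelihood ratio against the intercept. Spike-in
  controls carry no biology, so their significant fraction should not
  exceed the FDR level; genic genes with real fly-to-fly differences
  should exceed it clearly.

## The negative-binomial engine

Counts are modeled as $x_{ik} \sim \mathrm{NB}(\mu_{ik}, \sigma^2_{ik})$
with $\sigma^2_{ik} = \mu_{ik} + \mu_{ik}^2\varphi_i$ and
$\log \mu_{ik} = \beta_0 + S + G + E + G{\times}E + S{\times}G +
S{\times}E + S{\times}G{\times}E$. Each gene is fitted by IRLS at fixed
$\varphi_i$; the reported deviance is relative to the saturated model, so
the difference between nested fits is the likelihood-ratio statistic,
referred to $\chi^2$ with degrees of freedom equal to the difference in
estimated coefficients (aliased columns from empty cells are dropped
before counting). Fitted means are floored at $10^{-10}$; all-zero genes
return $p = 1$ for every term by contract; non-converged genes are
flagged rather than silently dropped.

**Dispersion** is estimated once per gene on the full-model cell structure
and reused for every nested test. The raw estimate is method-of-moments on
within-cell replicates, $\hat\varphi = \max\{0, \sum_c (n_c-1)(v_c-m_c) /
\sum_c (n_c-1)m_c^2\}$; a trend $\varphi(\mu) = a_0 + a_1/\mu$ is fitted
by robust regression through the positive raw estimates; the final value
is either the larger of raw and trend (`trend_max`) or a weighted shrink
of raw toward trend with weight $n_{\text{prior}}/(n_{\text{prior}} +
\text{residual df})$, prior weight 10 (`eb_shrink`).

Calibration trade-off, measured on null simulations (no effects, 4 x 3 x 2
cells, n = 4, $\varphi$ log-normal around 0.1): with *oracle* dispersions
the LRT holds its level (~0.05 per term), so the engine itself is
calibrated. The `trend_max` rule inflates dispersions by roughly 20 %
(median) — the truncation of negative moment estimates biases the fitted
trend upward, and taking the maximum adds more — which makes the low-df
main-effect tests conservative (empirical type-I error ~0.037–0.044).
`eb_shrink` with the default prior is mildly anti-conservative on the
high-df interaction terms (~0.06–0.075). Neither mode is re-tuned to
split the difference: `trend_max` (the default) errs on the safe side,
and the shrink mode's prior weight is exposed for users who want to move
along this trade-off.

**The model ladder.** Main effects are always tested by dropping each term
from the main-effects model. First-order interactions follow one of three
approaches: *sequential* adds $G{\times}E$, then $G{\times}S$, then
$E{\times}S$, testing each addition against the previous model; *add-one*
adds each interaction alone to the main-effects model; *drop-one* removes
each interaction in turn from the model holding all three. Two identities
follow from the shared model pairs and are asserted in the tests: the
$G{\times}E$ test coincides between sequential and add-one, and the
$E{\times}S$ test coincides between sequential and drop-one. The
three-way term is always the full model against the all-first-order
model.

Two count-input modes exist: the default feeds normalized counts rounded
half-to-even back into the NB engine (matching the original practice of
rounding normalized data to integers), and an `offset` mode fits raw
counts with log scaling-factor offsets — the statistically cleaner route,
available for per-sample-scaling methods only.

## The ln&ANOVA engine

The same factorial model is fitted to $\ln(\text{normalized count}+1)$ by
least squares, all genes simultaneously through one QR decomposition per
model matrix. Terms are tested with partial (Type III) F statistics under
sum-to-zero contrasts, because the intended use includes unbalanced data
after QC exclusions; on a balanced design these coincide with the
sequential decomposition, which is the exactness check in the test suite.
Genes with zero residual variance return $p = 1$.

Multiple testing uses the Benjamini-Hochberg step-up rule, applied within
each term across genes (whether correction should instead pool all terms
is genuinely ambiguous; within-term is the choice here and everywhere in
the package). Missing p-values propagate; `m` counts only non-missing
tests.

## Power

For the balanced three-factor fixed-effects ANOVA, the three-way
interaction F test has noncentrality $\lambda = n\sum(\alpha\beta\gamma
)^2_{ijk}/\sigma^2$ (equivalently $\varphi^2 = \lambda/[(a-1)(b-1)(c-1)
+1]$), with $df_1 = (a-1)(b-1)(c-1)$ and $df_2 = abc(n-1)$. Over all
effect patterns whose cell means span a range $D = d\sigma$, the minimum
noncentrality is $nd^2/2$ (two cells at $\pm D/2$), so solving
$\mathrm{power}(nD^2/2\sigma^2) = 0.8$ for $D$ gives a *conservative*
detectable fold-change; `power_curve()` does this over $n = 2..8$ by
bracketed root-finding (tolerance $10^{-10}$). For a first-order
interaction of the first two factors, $df_1 = (a-1)(b-1)$ and the
effective replication per interaction cell is $cn$. The closed form is
cross-validated against a direct Monte-Carlo simulation of the balanced
ANOVA (`mc_anova_power()`), which draws cell means and the residual
chi-square directly — an independent route sharing no code with the
noncentral-F path. $D$ is on the natural-log scale throughout;
$\exp(D)$ is reported alongside. The error variance $\sigma^2$ is a
pooled scalar input (the analysis scripts use 0.6 as an illustrative
value); real per-gene variances vary, so the curve describes a typical
gene, not all genes.

The empirical complement, `empirical_subsample_power()`, redraws `n_sub`
individuals per design cell without replacement, reruns the DE analysis,
and reports the percentage of full-data significant genes recovered per
term and FDR threshold.

## Agreement metrics

"Agreement" between two significant-gene sets defaults to the Jaccard
percentage $100|A \cap B|/|A \cup B|$, with both directed recalls always
reported, since a cell-plot percentage does not pin down which of the
three was meant; every directional conclusion asserted in the tests holds
under any of the three. Two empty sets agree at 100 by convention (two
null results are the same result). `pca_diagnostic()` adds the standard
first-look projection: principal components of centered
$\log_2(\text{normalized}+1)$ with a silhouette score for sex separation
along PC1.

## The synthetic-data generator

`simulate_experiment()` draws genic counts as gamma-Poisson with mean
$s_k \exp(\text{log baseline} + \text{term effects} + \text{fly effect})$,
so the NB mean-variance law holds by construction. Its defaults emulate
the structure of the motivating study:

* **Heavy-tailed expression**: baseline means are log-normal with
  `sdlog = 2`, so a small set of genes carries most reads (the top-50
  share is monotone in this parameter and sits near half the reads at
  default settings).
* **Dispersion**: $\varphi_i$ log-normal around 0.1 (`sdlog = 0.5`). The
  original study never published its dispersion-mean trend; this is a
  modeling choice, exposed in the config, in the range typical for inbred
  lines.
* **Effects**: for a gene differentially expressed in a term, a random
  half of that term's level combinations receive $+e/2$ and the rest
  $-e/2$ on the ln scale, so the max-min range equals the stated effect
  size, aligning with the $d = D/\sigma$ definition used by the power
  module. A consequence worth knowing: a gene given a pure interaction
  offset also acquires marginal main-effect signal, so the per-term truth
  sets are exact for "which genes carry this term's effect" but recovery
  of main effects against them overstates the false-discovery proportion.
* **Spike-ins** (default 32): means depend only on the depth factor
  $s_k$, never on the design.
* **Intergenic background**: Poisson with per-feature rates drawn from a
  low-rate exponential — no biological structure, only a right tail for
  thresholding. Feature lengths are gene-scale with a long tail and an
  occasional fragment below the read length, so the length filter has
  work to do.
* **Duplicate libraries**: a configurable fraction of individuals is
  sequenced twice; the two columns share all biology, including the
  per-fly random effect (`sigma_fly`), and differ only in depth and
  counting noise.
* **SNP data**: `simulate_snp_data()` gives each reference line a base
  call per site; samples copy their line with independent flips at
  `error_rate` and dropouts at `missing_rate`.

What the generator does **not** emulate: GC or length bias beyond the
length field RPKM uses, correlated gene-gene expression, batch or
flow-cell structure, index contamination, and composition effects tied to
chromosome structure. Tests passing on this generator therefore certify
the statistical machinery, not robustness to those real-data phenomena.

## Problem sizes and determinism

The test suite and the acceptance script run the full machinery at desk
scale, chosen so each study is informative yet the whole suite completes
in minutes: formula oracles on matrices up to 10 x 6; ladder identities at
4 x 2 x 2 with n = 3; null calibration at 2000 genes, 4 x 3 x 2, n = 4;
the filtering-sensitivity sign test over 10 seeds at 2000 genes,
6 x 3 x 2, n = 3 (16 genotypes would multiply runtime without changing the
mechanism, which acts through normalization parameters, not the genotype
count); subsampling at n = 6 per cell so draws of 2, 3 and 5 are all
proper subsets. One seed drives each study; every simulation, subsample
and pipeline stage is reproducible bit-for-bit, and the pipeline writes
floats at 17 significant digits so reruns are byte-identical.

## Known limitations

* The NB LRT relies on $\chi^2$ asymptotics; at very small replication
  (n = 2) interaction tests can drift from nominal level in either
  direction depending on the dispersion mode (see the calibration notes
  above).
* The `rounded` count-input mode introduces a quantization artifact for
  methods whose normalized values are small (RPKM especially); the
  `offset` mode avoids it where scaling factors exist.
* DESeq-style normalized output is reported as $x/s_k$ without the
  mean-library-size rescale applied to TMM output; the two conventions
  differ by a constant per matrix, which cancels in rank-based and
  contrast-based analyses but matters if absolute normalized values are
  compared across methods.
* RUVg is a minimal factor construction; evaluating it against real
  technical covariates is out of scope.
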