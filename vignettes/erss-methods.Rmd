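---
title: "Methods: the ERSS prognostic score and its companion statistics"
author: "ERSScore maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ERSS prognostic score and its companion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the model behind each stage, the tunable parameters and
their defaults, what the synthetic generators do and do not emulate,
the numerical choices, and known limitations. No empirical claim is
made here beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The PC1-difference score

Given a gene-by-sample expression matrix (assumed pre-normalized on a
log scale) and per-sample survival, candidate genes are screened twice:

1. **Differential expression**, tumor vs normal, by two-sided Wilcoxon
   rank-sum per gene. The significance flag uses the *raw* p-value at
   0.05 — the conventional permissive screen for a first-pass gene
   pool — with Benjamini–Hochberg adjusted values reported alongside
   so callers can filter on either.
2. **Univariate Cox screening** (partial likelihood, Efron tie
   handling) at Wald `alpha = 0.05`. Retained genes are split by the
   sign of the coefficient: cluster A (hazard-increasing), cluster B
   (protective).

Each gene is z-scored across samples; each cluster's samples × genes
submatrix is decomposed by SVD and each sample receives its coordinate
on the first principal component. The score is `ERSS = PC1A − PC1B`,
with an empty cluster contributing zero. Using PC1 rather than a
coefficient-weighted sum concentrates the score on the largest block of
co-varying cluster genes and down-weights genes that do not track the
rest of the cluster.

**Orientation.** A principal component is defined only up to sign. The
sign is fixed so the scores correlate positively with the cluster's
mean expression, making "high score" mean "high expression of the
cluster". When PC1 is numerically orthogonal to the mean-expression
direction the rule is undecidable; this is not exotic — for a two-gene
cluster whose members are anticorrelated, PC1 is exactly the difference
contrast, which is exactly uncorrelated with the mean — so the sign is
then anchored to the loading of the lexicographically first gene. Both
rules are invariant to gene and sample order and to the linear-algebra
backend, which the suite asserts by recomputing under shuffled gene
order.

**Transfer to a validation cohort.** `scoreNewCohort()` supports two
modes. `refit` (the default) reruns the decomposition on the new cohort
using the training gene clusters — treating the gene lists as the
portable part of the signature, which is how such scores are usually
moved between cohorts on different platforms. `project` applies the
frozen training loadings to the new cohort's z-scores, a strict
transfer. Whether a validation analysis should also re-derive its own
high/low cutpoint or reuse the training one is a genuinely open
choice; both are possible here (`optimalCutpoint()` on the new scores,
or `assignCutpoint()` with the training threshold) and neither is
asserted as canonical.

## Survival machinery

Kaplan–Meier estimation, log-rank tests and multivariable Cox models
are delegated to the `survival` package (Efron ties, Breslow baseline
cumulative hazard). The **optimal cutpoint** is a maximally selected
rank statistic: per-sample log-rank scores `a_i = status_i − H(t_i)`
(Nelson–Aalen cumulative hazard), and for every admissible threshold
the standardized linear rank statistic of the high group, with the
conditional permutation variance. Admissibility requires at least
`minprop` (default 0.1, the cutpoint literature's conventional default)
of the samples on each side. The search is an exhaustive scan over
distinct score values, and the suite checks it against an independently
coded scan on instances up to n = 200. The log-rank p-value reported at
the chosen split is the ordinary test and therefore selection-biased;
it is flagged as such, and no maximally-selected-null correction is
attempted.

Time-dependent ROC uses the cumulative-case / dynamic-control
definition with inverse-probability-of-censoring weights from the
censoring Kaplan–Meier curve; with complete follow-up it reduces
exactly to pair counting, which is how it is tested.

Categorical association tests switch from Pearson chi-square to
Fisher's exact test when any expected cell is below 5, or for 2×2
tables when the total is below 40 (the standard textbook small-sample
rule). Score-by-group comparisons use Wilcoxon (2 levels) or
Kruskal–Wallis (3+).

## Immune scores and mutational burden

`ssgseaScores()` implements the single-sample enrichment statistic: per
sample, genes are ranked by expression and the score is the summed gap
between the rank-weighted in-set empirical CDF (weights
`rank^exponent`, default exponent 0.25) and the unweighted out-of-set
CDF. Scores therefore depend on a sample's expression only through its
ranks, which is asserted under monotone transforms.
`estimateScores()` composes two such signature scores (stromal +
immune) and maps their sum to tumor purity through the published cosine
transform `cos(0.6049872018 + 0.0001467884 × score)`; values outside
[0, 1] are flagged rather than clipped.

The signature GMTs shipped under `inst/extdata/` are *synthetic*
stand-ins drawn from the simulator's gene namespace — they exercise the
machinery but carry no biology. Real analyses must supply the published
signature files.

Tumor mutational burden is mutations per callable megabase. The
defaults are deliberately loud config: 38 Mb callable size and all
nonsynonymous variant classes (the vocabulary minus `Silent`); the
high/low split defaults to the cohort median.

## Risk model

`buildRiskModel()` wraps a multivariable Cox fit (score + age + stage
by default) and derives: a 0–100 points scale per covariate (the
covariate with the largest |β| × range spans 100 points, the standard
nomogram convention), the Breslow baseline survival at the requested
horizons, and predictions `S(t|x) = S0(t)^exp(β·(x − x̄))`. Concordance
is Harrell's C over usable pairs with a percentile bootstrap CI
(default B = 200). Calibration bins subjects by predicted survival into
quantile groups and compares with the group-wise Kaplan–Meier at the
horizon; with B > 0 a bootstrap-refit optimism correction is subtracted
from the apparent predictions. A constant predictor short-circuits to a
single group whose observed and predicted values are both the overall
Kaplan–Meier estimate. Decision curves compute net benefit
`TP/n − FP/n × p_t/(1−p_t)` with event status at the horizon estimated
by Kaplan–Meier within the treated set, so censored subjects are
handled without discarding them; with complete follow-up this is plain
counting.

## Co-expression modules

The network is unsigned, `|cor|^β` — the historical default, chosen
because the sign convention is not externally constrained here. The
soft threshold is the smallest power whose signed scale-free fit R²
(log bin frequency vs log mean connectivity over ten equal-width
connectivity bins, R² negated for a positive slope) reaches 0.9,
otherwise the argmax with a warning. The candidate grid defaults to
1:6: at much larger powers any network — including one built from
independent genes — drifts toward an apparently scale-free degenerate
regime, so large powers make the fit criterion uninformative.

Topological overlap follows the standard formula
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
unit diagonal. Module detection is a *static* cut of the average-linkage
tree on `1 − TOM` — deterministic and simpler than dynamic tree cutting,
whose exact module count is not a quantity this package asserts. When no
cut height is given, the highest height on a quantile grid that yields
at least two modules of at least `min_size` genes is chosen and logged.
Defaults: minimum module size 50 and eigengene merge height 0.3.
Modules whose eigengenes (orientation-fixed PC1, as for the score)
correlate above `1 − merge_height` are merged iteratively. Hub ranking
is by module membership (gene–eigengene correlation) with intramodular
connectivity as tie-break — a deliberate replacement for external
protein-interaction-network centrality rankings, which require
databases this package does not bundle.

## Case-control genetics

Odds ratios are `ad/bc` with Woolf (log-normal) confidence intervals;
any zero cell triggers the Haldane–Anscombe +0.5 correction, flagged.
The logistic route (`logisticFit()`, IRLS via `glm`) retains the full
covariance so that `additiveInteraction()` can compute RERI, AP and the
synergy index with delta-method CIs (S on the log scale), the standard
epidemiological formulation. The identity family `RERI = 0 ⇔ AP = 0 ⇔
S = 1` and delta-vs-parametric-bootstrap CI agreement are property-
tested. S is reported as undefined when `(OR10 − 1) + (OR01 − 1) ≤ 0`.
Genotypes are analyzed under dominant coding (carrier vs homozygous
reference); allele-dose models would need the heterozygote/homozygote
split, which tabulated dominant-coded inputs do not carry, so no
allele-model output is produced from collapsed counts. The IRLS
convergence tolerance is 1e-10 — tight enough that the saturated
single-predictor fit reproduces the closed-form odds ratio and Woolf CI
to 1e-6, the package's dual-route consistency check.

## Synthetic cohorts: what they emulate, and what they do not

`simulateExpressionCohort()` plants: per-gene Gaussian baselines
(mean 6, sd 1, a log-scale-like range), ±`de_effect` tumor shifts on
the DE genes, and two prognostic clusters drawn from the up- and
down-regulated genes respectively (defaults 12 risk and 2 protective
genes — the size asymmetry mirrors the screening outcome such analyses
typically produce). Cluster genes share a per-sample latent factor of
unit variance; this within-cluster co-expression is what makes a
cluster's PC1 estimable at all, and `noise_sd` (default 1) sets the
gene-level noise against it. The latent hazard score is
`β_A × mean(A) + β_B × mean(B)` (defaults ±0.8) driving exponential
event times; uniform censoring is calibrated by root-finding so the
realized censored fraction matches `censor_rate` (default 0.3).
Proportional hazards therefore holds *exactly*, which is what makes Cox
recovery a clean test.

The case-control generator draws genotypes under Hardy–Weinberg,
exposure as Bernoulli, and case status from a logistic model whose
intercept is solved to hit the target case fraction; defaults are the
published study's conditions (467/395 subjects, minor-allele frequency
0.06 giving an 11.6% control carrier frequency, genotype OR 0.596,
exposure prevalence 0.304 with OR 1.803, interaction OR 1.173).
Sampling is prospective-logistic rather than retrospective; for odds
ratios the two coincide in expectation, which is the property under
test.

Not emulated: real cohorts' correlation structure beyond the planted
clusters, platform/batch effects (the batch tools are tested on
constructed shifts), non-proportional hazards, linkage beyond one
biallelic locus, and any actual biology in the gene labels. Passing
tests therefore demonstrate statistical correctness of the machinery
under its stated model, not performance on real tumor data.

## Numerical choices and problem sizes

- Batch adjustment is per-gene location/scale alignment to the pooled
  mean and SD — adequate as preprocessing ahead of merging, with no
  empirical-Bayes shrinkage; genes with zero within-batch variance are
  shifted only, with a warning.
- Preranked GSEA uses gene-label permutation (random same-size sets)
  for its null; NES divides ES by the mean same-sign permuted
  magnitude, nominal p uses `(count + 1)/(m + 1)` smoothing, and FDR q
  follows the pooled-null construction. Phenotype permutation would
  need per-sample data and is out of scope.
- The suite's simulation sizes were chosen to keep the statistical
  assertions sharp at small cost: 2000-replicate null calibrations for
  log-rank/Cox/logistic type-I error, 20-seed recovery loops at n = 400
  for the score and hazard ratios, 50-seed coverage loops at n = 20000
  for the genetics arm, and exhaustive-oracle scans up to n = 200 for
  the cutpoint. The full suite runs in a few minutes on one core.

## Known limitations

- The maximally-selected cutpoint's p-value is not corrected for
  selection; treat it as descriptive.
- ssGSEA/ESTIMATE outputs are only as meaningful as the signature gene
  sets supplied; the bundled GMTs are synthetic.
- The calibration optimism correction resamples model fitting but not
  the grouping quantiles; with very small groups it can be noisy.
- `adjustBatches` deliberately does not implement empirical-Bayes
  shrinkage; cohorts with very few samples per batch will see inflated
  adjustment variance.
- The co-expression stage targets a few hundred to a few thousand
  genes (dense correlation and TOM matrices are O(p²) memory).
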