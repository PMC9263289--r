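---
title: "Methods: cross-species alignment of factorial mouse transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species alignment of factorial mouse transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`loadalign` quantifies how a factorial mouse study — 2 sexes x 2 diets
(control vs high-fat/high-sugar) x 3 genotypes (a baseline risk strain and
two single-variant derivatives) — aligns with human late-onset Alzheimer's
disease (LOAD) references. The core statistical object is the per-gene
ordinary least squares fit

log(expr) = b0 + b1 Sex(Male) + b2 HFD + b3 Mthfr.C677T + b4 Plcg2.M28L +
b5 (HFD x Mthfr.C677T) + b6 (HFD x Plcg2.M28L) + eps,

treatment-coded so that each coefficient is a difference from the reference
cell, with interaction columns formed as elementwise products of their
parents. Everything downstream consumes these coefficient vectors: Pearson
correlation against human module/subtype log2 fold changes, sign-based
coherent-gene extraction, coefficient-ranked GSEA, and NES-PCA.

## Assumptions

- Expression noise on the log scale is approximately homoscedastic per gene;
  OLS with Student-t inference at n - 7 residual degrees of freedom is used,
  with no empirical-Bayes moderation and no per-gene multiple-testing
  correction (multiplicity is only controlled at the pathway level, via
  Benjamini-Hochberg).
- Housekeeping genes are expression-stable, so dividing each sample's counts
  by the geometric mean of its own housekeeping counts removes lane- and
  sample-level technical scale exactly (the operation is invariant to any
  per-sample rescaling).
- Mouse-to-human gene identity is symbol-based (uppercase 1:1) unless an
  explicit ortholog table is supplied.

## Reference-level convention

The intercept is documented ambiguously in this literature: a model that
"sums over sex (male)" implies a female reference, while prose sometimes
describes the intercept as the male reference average. We code the sex
indicator as male = 1 (female reference) because that is the only reading
consistent with an explicit Sex(Male) term; both conventions are available
through `build_design(ref_sex = )`, and all correlation-grid outputs are
invariant to the choice up to a sign-preserving relabelling.

# Tunable parameters

| Parameter | Default | Rationale |
|---|---|---|
| `pseudocount` (log transform) | 0 | zeros after normalization are a hard error, forcing an explicit user decision rather than a silent offset |
| log base | natural | coefficients divide by ln 2 under base 2; correlations are base-invariant, so headline outputs do not depend on this |
| `min_overlap` (grid cells) | 5 | `cor.test` runs at n = 3 but such r values are noise; cells below the floor are reported missing, never zero |
| `alpha` (grid cells) | 0.05 | per-cell, uncorrected — matching the convention of flagging cells at p < 0.05 without across-grid FDR |
| GSEA `weight` | 1 | the classic weighted-KS exponent |
| GSEA `n_perm` | 10,000 | gene-label permutations, seeded; at 10,000 the nominal p has binomial SE below 0.005 everywhere |
| GSEA size bounds | [5, 500] | after intersection with the ranking; whole-ranking sets are degenerate and rejected |
| SUVR `threshold` | 0.80 | cumulative share of SUVR variance regions must explain |
| `dispersion` (generator) | 0.05 | a mid-range NanoString-like overdispersion; 0 selects the deterministic limit |

# The synthetic-data generator

The generator is first-class, tested code: it is the ground truth against
which every downstream stage is verified.

- **Counts** are gamma-Poisson (negative binomial, variance mu + d mu^2)
  around `lane_scale x exp(X beta_true)`, with a single global dispersion.
  The distributional family for NanoString counts is a conventional choice,
  not an extracted one; dispersion 0 is implemented as the deterministic
  limit `round(mu)` so that exact zero-noise recovery tests are possible.
- **Design defaults** follow the study conditions: n = 6 per
  sex/diet/genotype cell for transcriptomics, n = 10 per group for imaging
  subjects, 10 analytes per cytokine panel, lanes of 12 samples with
  positive technical scale factors.
- **Human references** are simulated per module as
  `log2FC = (rho * standardized beta_true + sqrt(1 - rho^2) * noise) * sd`,
  so the correlation with the targeted term's true coefficients has
  expectation rho; rho = 0 modules are independent of every term. Planted
  rho refers to the *true* coefficients — estimation noise attenuates the
  observable correlation by roughly `sd_beta / sqrt(sd_beta^2 + se^2)`
  (about 0.94 under the default settings), which the recovery tests
  account for.
- **VOI tables** are log-normal around region means, with a per-subject
  dose factor that must cancel exactly in the SUVR, and optional
  multiplicative group effects on chosen regions.
- **Cytokine tables** flag a configurable fraction of records below the
  analyte's LLOD.

What the generator does *not* emulate: probe-level background, count
truncation at the cartridge level, batch differences between sites beyond a
lane-scale factor, spatial structure in imaging (values are region means,
not voxels), longitudinal dropout, and correlated multi-module gene
membership in human references. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under the stated
generative model — not robustness to every artefact of real NanoString or
PET data.

# Numerical and design choices

- **"Within a lane" normalization** is implemented per sample (each
  sample's own housekeeping geometric mean), the standard nSolver
  behaviour; a pooled per-lane geometric mean is available via
  `normalize_counts(method = "per_lane")`. The two agree exactly when lane
  effects are pure per-sample scale factors.
- **Per-gene OLS** shares one QR decomposition of the design across genes;
  standard errors come from the per-gene residual variance times the
  diagonal of the normal-equations inverse. A rank-deficient design is
  rejected before any fit.
- **GSEA** evaluates the running sum only at its candidate extrema (just
  after each hit for maxima, just before for minima), which is exact and
  O(set size) per permutation. Ties in ranking scores are broken
  deterministically by gene symbol. NES divides the ES by the mean |null
  ES| of matching sign; nominal p is one-sided within the sign class with
  the standard (k + 1)/(m + 1) estimator. Sets reduced below 2 members by
  intersection are dropped with a warning when the size floor is >= 2; an
  explicit `min_size = 1` permits singletons (whose unweighted ES is 1 when
  the gene tops the ranking).
- **"Regions explaining the top 80% of the variance"** is ambiguous between
  components and regions. The default interpretation ranks regions by their
  eigenvalue-weighted squared loadings summed over all components — which,
  for centered unscaled PCA, equals each region's share of total variance —
  and selects greedily until the cumulative share reaches the threshold.
  This greedy selection provably finds the smallest such region subset. A
  second mode (`mode = "components"`) restricts the loading sum to the
  leading components at the threshold. Both are interpretations, not an
  extracted procedure.
- **Two-way ANOVA** uses Type II sums of squares (via `car::Anova`) so
  unbalanced group sizes are handled sensibly; in balanced designs this
  coincides with the textbook decomposition, which the tests verify against
  independent cell-means algebra. Empty cells drop the interaction with a
  warning, or error under `strict = TRUE`.
- **Repeated-measures ANOVA** is the univariate split-plot form (between
  effects against subject-within-group MS; within and mixed terms against
  the subject x time residual), matching common usage in this literature;
  no sphericity correction is applied by default.
- **Tukey HSD** uses the studentized range with the pooled MSE
  (Tukey-Kramer for unequal sizes); with two groups it reduces to the
  pooled t-test, which is verified numerically to 1e-6.
- **Determinism**: every stochastic routine takes an explicit seed; the
  pipeline writes a manifest with the config hash and per-output checksums,
  and identical configs reproduce identical manifests.

# Verification strategy and problem sizes

The test suite checks each operation against an independent oracle: a
loop-based normalizer, per-gene `lm()` fits, Gaussian-elimination rank,
closed-form correlation p-values, exhaustive enumeration of all C(8,3)
gene-set assignments, combinatorial hypergeometric tails, exhaustive
region-subset search, and cell-means ANOVA algebra. Calibration properties
use seeded Monte-Carlo at sizes chosen to make the assertions sharp but the
suite quick: 500 replicates x 200 genes for coefficient bias and SE
calibration, 200 replicates for correlation-grid sign recovery, 2,000
replicates for null p-value uniformity (KS at alpha = 0.01), and a full
seeded demo run for the end-to-end planted-pattern check. The acceptance
script reruns the same computations from scratch at a caller-supplied seed.

# Known limitations

- Site and genotype are confounded in the motivating two-site design; the
  model deliberately carries no site term by default (an optional covariate
  column is supported), so site effects load onto genotype contrasts.
- Symbol-based orthology misses genes whose mouse and human symbols differ;
  supply `gene_map` for those.
- The coherence criterion is sign agreement only; with near-zero
  coefficients the sign is noisy, and the optional `p_max` filter trades
  sensitivity for stability.
- Preranked GSEA with a gene-label null tests a competitive hypothesis;
  phenotype permutation is out of scope.
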