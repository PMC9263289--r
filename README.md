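# loadalign

Mouse models of late-onset Alzheimer's disease (LOAD) are increasingly
evaluated not by histopathology alone but by how well their molecular
response aligns with human disease signatures. `loadalign` implements that
alignment for factorial mouse studies — sex x diet x genetic variant — as a
tested, reusable R pipeline: it normalizes NanoString-style count panels,
fits a per-gene factorial linear model with diet-by-variant interaction
terms, correlates the resulting effect coefficients with human brain
co-expression modules and molecular subtypes, extracts directionally
coherent genes, runs preranked gene-set enrichment, and analyzes PET /
autoradiography uptake tables as cerebellum-referenced SUVRs. A
synthetic-data module generates every input with known planted structure,
so the whole pipeline is verifiable end to end without access to restricted
cohort data.

## The model

For each panel gene, expression normalized by the per-sample geometric mean
of the housekeeping genes is modelled on the log scale as

    log(expr) = beta0 + beta_sex * Sex(Male) + beta_HFD * HFD
              + beta_M * Mthfr.C677T + beta_P * Plcg2.M28L
              + beta_HM * (HFD x Mthfr.C677T)
              + beta_HP * (HFD x Plcg2.M28L) + eps

with treatment coding (female, control diet, baseline genotype as
references) and ordinary least squares per gene. Each term's coefficient
vector over genes is then compared with human references by Pearson
correlation:

    cor.test( log2FC(AD/control), beta_term )

over the genes shared between the panel and each human co-expression module
or LOAD subtype, giving a term x reference correlation grid with per-cell
significance at p < 0.05. Genes whose mouse coefficient sign agrees with
their human log2 fold change ("directional coherence") are extracted per
consensus cluster and fed to over-representation analysis; preranked GSEA
(weighted Kolmogorov-Smirnov running sum, gene-label permutation null)
scores pathway-level shifts per model term, and PCA of the normalized
enrichment scores (NES) summarises how terms separate in pathway space.

Imaging tables are reduced with `SUVR(s, R) = uptake(s, R) / uptake(s,
cerebellum)` after bilateral averaging, regions are ranked by their share of
total SUVR variance (PCA-based) until a cumulative threshold (default 80%)
is reached, and each selected region is tested with a two-way ANOVA.
Supporting study statistics — Type II two-way ANOVA with Tukey HSD,
split-plot repeated-measures ANOVA, and half-LLOD imputation for cytokine
panels — are included.

## Worked example

Simulate a factorial study in which only the diet-by-Plcg2 interaction
carries true per-gene effects, then align it to synthetic human references
where two immune modules are correlated with that interaction and one
module is null:

```r
library(loadalign)

set.seed(42)
eff <- planted_effects(n_genes = 100, n_housekeeping = 6,
                       planted = list("HFD*Plcg2.M28L" = rnorm(100, 0, 0.35)),
                       dispersion = 0.05)
study <- generate_study(study_design(n_per_cell = 6), eff, seed = 42)
expr  <- log_transform(normalize_counts(study$counts), pseudocount = 0)
fit   <- fit_effects(expr, build_design(study$samples))

spec <- data.frame(module = c("immune1", "immune2", "nullmod"),
                   cluster = c("B", "B", "C"),
                   region = c("DLPFC", "TCX", "FP"),
                   term = "HFD*Plcg2.M28L", n_genes = 40,
                   rho = c(0.8, 0.8, 0))
ref  <- generate_human_reference(eff, spec, seed = 43)
correlate_effects(fit, ref, terms = "HFD*Plcg2.M28L")
#>             term reference cluster region          r            p  n significant
#> 1 HFD*Plcg2.M28L   immune1       B  DLPFC  0.7487186 2.763445e-08 40        TRUE
#> 2 HFD*Plcg2.M28L   immune2       B    TCX  0.6673973 2.555631e-06 40        TRUE
#> 3 HFD*Plcg2.M28L   nullmod       C     FP -0.2471270 1.242045e-01 40       FALSE
```

Both modules planted at rho = 0.8 come out with strong, significant
positive correlations (r of about 0.7 after estimation noise attenuates the
planted value), while the null module does not. The coherent-gene
extraction then returns the sign-concordant members of cluster B:

```r
coh <- extract_coherent_genes(fit, ref, "HFD*Plcg2.M28L", "B")
length(attr(coh, "genes"))
#> [1] 47
```

`demo_inputs()` writes a complete synthetic input bundle (counts, sample
table, module and subtype references, GMT gene sets, VOI uptake table,
cytokine panel) and `run_pipeline()` executes every stage from a single
config, persisting all intermediates plus a seeded run manifest.

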