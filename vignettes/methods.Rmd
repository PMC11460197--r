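---
title: "Models and methods behind hepplasma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hepplasma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepplasma)
```

## Overview

`hepplasma` implements the quantitative analysis of a two-cohort,
multi-batch TMT plasma proteomics case/control study of Alzheimer's
disease, with heparin-affinity enrichment upstream of quantification. The
chain is: channel-sum normalization, missingness filtering, log2
transform, GIS-anchored two-way median polish batch harmonization,
bootstrap covariate regression, per-set Student's t differential
abundance with Benjamini–Hochberg control, Fisher meta-analysis across the
two sets, Z-score/biomarker-trait correlation, projection of proteins onto
consensus brain co-expression modules by biweight midcorrelation (kME),
Fisher-exact over-representation with hypergeometric Z-scores, and
logistic-panel ROC classification with DeLong inference.

Because the study's deposited data live behind a data-use portal, the
package ships a first-class synthetic-data generator that emulates the
study design with known ground truth, and every stage is exercised and
accepted against that generator plus closed-form and brute-force oracles.

## The data model

A dataset is a protein-by-sample intensity matrix with explicit missing
values and a scale state (`raw`, `scaled`, `log2`, `corrected`), plus
per-sample metadata: set (cohort), TMT batch, channel, a GIS flag
(pooled global-internal-standard channels placed in every batch),
diagnosis, demographics, and biomarker traits (MoCA cognition score, CSF
A\\(\beta_{1\text{-}42}\\), CSF total tau, CSF pTau181, plasma pTau181, in
pg/ml except MoCA). Zero reporter intensity is read as missing by default:
a zero means the channel contributed no quantifiable signal, not that the
protein's abundance was zero.

## Normalization and filtering

Channel loading differences are removed by dividing each intensity by its
channel's total observed intensity and multiplying by the maximum channel
total, so all channels end with equal totals. Channel sums are taken over
the proteins observed in that channel, because missing cells contribute no
reporter signal; whether GIS channels enter the maximum is immaterial
since the maximum only sets a global scale. Proteins missing in *more*
than 50% of samples are removed — strictly more, so a protein missing in
exactly half survives. The TMT path performs no imputation; the label-free
path offers the conventional down-shifted normal imputation (per-sample
mean − 1.8 SD, width 0.3 SD), with both constants exposed because they are
conventions, not estimates.

## Batch harmonization (GIS-anchored median polish)

Within each set, every log2 abundance is expressed as a ratio to the
median of its batch's GIS channels (per protein). Since each batch
carries an aliquot of the same pool, any multiplicative batch effect — the
model being a protein-specific additive offset in log2 — cancels in the
ratio. A Tukey two-way median polish then alternately sweeps column and
row medians from the ratio matrix until the largest effect change drops
below `tol` (default 1e-6, capped at 100 sweeps; the cap guards against
cycling on ties, and the even-count median is the midpoint convention).
Corrected abundance is reconstructed as residual + row effect +
per-protein grand median of the input, discarding column effects as pure
technical loading while preserving each protein's central tendency for
concentration-rank displays. When GIS channels are absent the batch
all-sample median is the fallback anchor (`use_gis = FALSE`).

Two properties are asserted in the tests: a uniform +1 log2 batch shift is
removed to within `tol`, and corrected GIS values agree across batches per
protein.

## Covariate regression and why batch-only is the primary path

Residual covariate effects are removed by non-parametric bootstrap
regression: per protein, OLS of abundance on protected (diagnosis) plus
unprotected terms on each of B = 200 resamples of samples with
replacement; the coefficient is the median over resamples; only the
unprotected, mean-centred terms are subtracted. Proteins with fewer
complete observations than model terms + 2 are left untouched and
flagged.

The pipeline's default removes **batch only**. Regressing fitted
demographic effects (age, sex, race: about four design columns) out of
cohorts of 36–85 samples and then re-testing the residuals underestimates
the residual variance by roughly a factor \\(1 - k/n\\) and inflates the
t-test's false-positive rate to ~0.065–0.08 in our simulations, even with
exact OLS. The demographic path is therefore a sensitivity analysis
(`covariates = c("age", "sex", "race", "batch")` in the configuration),
not the primary inference.

## Differential and meta-analysis

Per set, a pooled-variance Student's t-test on pairwise-complete values
(Welch available by flag), two-sided p on \\(n_1+n_2-2\\) df, BH q-values
within each analysis table, and log2 fold-change AD − control. Samples
enter the two-set comparison only if biomarker-consistent (AT+ rule): AD
requires CSF tTau/A\\(\beta_{1\text{-}42}\\) > 0.226 and MoCA ≤ 24,
controls the complements; at MoCA exactly 24 the diagnosis label decides,
mirroring the quoted cutoffs. Across sets, the meta p is Fisher's
\\(X^2 = -2\sum\ln p\\) on 2k df (Stouffer available by configuration);
proteins quantified in a single set pass through unchanged so that
set-specific markers stay available downstream. Effects are averaged
across available sets.

## Module projection (kME) and enrichment

A module eigenprotein is the first right-singular vector of the
standardized member-by-sample matrix (missing standardized values
zero-filled), sign-oriented so the mean member correlation is positive
(exact ties align to the first member). A protein maps to the module with
the highest positive biweight midcorrelation to an eigenprotein if that
kME ≥ 0.30, else grey. `bicor` uses the raw median absolute deviation
(no 1.4826 consistency constant) inside the 9·MAD biweight, matching the
canonical definition; a zero MAD falls back to Pearson with a flag, and no
outlier-probability capping is applied. Over-representation uses the
one-tailed hypergeometric tail with BH control per collection, plus the
standardized hypergeometric deviate as the Z-score — the natural reading
of a "Z-score from the one-tailed FET", stated here because the source
convention is not a formula. Both the 1.96 and 1.3 Z gates appear in
practice; the threshold is configuration, never hard-coded.

## Classification

Panels are binomial GLM fits (IRLS, 100 iterations, 1e-8 tolerance) on
internally standardized features; separation is detected from fitted
probabilities at machine bounds and flagged rather than silenced. ROC
analysis reports the Mann–Whitney AUC, DeLong variance and normal 95% CI,
a threshold table with the Youden-optimal row (ties to the lower
threshold), and DeLong's paired test between correlated AUCs; identical
score rankings are reported as p = 1 with a degeneracy flag. Only
proteins with meta p strictly below 1e-4 and no missing values across the
de-duplicated ROC cohort are eligible; single-marker AUCs below 0.5 are
sign-flipped and flagged so ranking reflects discriminative ability.
Panels are fitted and evaluated in-sample, mirroring the source workflow;
no cross-validation claims are made.

## What the synthetic generator emulates

The generator reproduces the study design: set 1 with 18 control + 18 AD
samples in three TMT batches, set 2 with 36 + 49 in five, one pooled GIS
channel per batch, and optionally 13 controls shared between sets
(default off). Base abundances are log10-uniform over ten orders of
magnitude. True group effects hit a 10% minority of proteins with
N(0, 0.5) log2 fold-changes. Batch effects are protein-specific additive
log2 offsets (SD 0.5) — exactly the structure the median polish removes.
Noise is split into between-subject biological variation (SD 0.5 log2)
and technical measurement noise (SD 0.1 log2, a typical TMT technical
CV); pooling averages the biological component away, so GIS channels
carry only technical noise, as a physical pooled aliquot does.
Missingness is logistic in log2 abundance (MNAR). The documented
convention is only zero-equals-missing; the mechanism here is an explicit,
configurable assumption. Traits are Gaussian per diagnosis group with
published cohort means/SDs, truncated to plausible ranges (MoCA in
[0, 30]), and coupled (r = 0.5) to each subject's effect-protein burden
with signs matching clinical direction. A latent block structure gives
module members within-block correlation `module_purity` via shared
factors.

The generator does **not** emulate spectrum-level phenomena (co-isolation
interference, ratio compression), peptide-to-protein roll-up, shared
peptides, or non-Gaussian heavy-tailed noise. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not robustness to every artifact of real reporter-ion
data.

## Problem sizes, numerical choices, known limitations

The test and acceptance runs use 1000–2000 proteins and the study's
sample sizes (or a balanced 30 + 30 per set for recovery checks), sizes at
which every Monte-Carlo window in the tests is stable across seeds.
Deterministic behavior is part of the contract: a configuration carries a
seed, derived seeds are fixed offsets of it, and a seeded run writes
byte-identical result bundles.

Numerical conventions worth knowing: medians of even counts are midpoints;
clustering ties break by input index; module-assignment ties break by
label order and are flagged; p = 0 inputs to Fisher combination are
clamped to the smallest positive double with a warning; BH families are
per analysis table.

Two limitations deserve emphasis. First, the 13 overlapping controls
violate the independence assumption of Fisher's combination when both
sets are analyzed together; the combination is implemented as described,
and de-duplication is available (and always applied for ROC). Second, the
kME ≥ 0.30 assignment rule takes a maximum over all module eigenproteins:
with 60 reference samples the null kME has SD ≈ 0.13, so each eigenprotein
has a ~1% false-assignment tail, and a background protein escapes all m
modules with probability only about \\(0.99^m\\) (~90% at m = 10). Reliable
grey assignment at this cutoff needs either few modules or a larger
reference cohort (≳75 samples; the published consensus network's 456
samples make the issue vanish). The package reports this property honestly
rather than tightening the cutoff.
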