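---
title: "Constrained PCA of cytokine panels: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained PCA of cytokine panels: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytonet)
```

This vignette is the package's own account of its statistical machinery:
the model behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-cohort generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The data model

A `CytokinePanel` holds a p x n concentration matrix (pg/mL) for p
analytes over n children, a per-analyte lower limit of detection (LOD),
a group label per child among the four study cells — `C/TD`, `C/ND`,
`A/TD`, `A/ND` (control vs alcohol-exposed mother crossed with typical
development vs neurodevelopmental delay) — and four covariates: maternal
smoking (0/1), pre-pregnancy BMI, child sex (0/1) and child age at blood
draw (years). It extends `SummarizedExperiment`, so the usual subsetting
and accessor idioms apply.

## Preprocessing

The pipeline order is fixed: **below-LOD zeroing → undetectable-analyte
exclusion → Winsorization → Blom transformation**, with the full panel
forked after zeroing for the heatmap path (the heatmap shows all
analytes; the analysis does not).

* **Zeroing.** Multiplex immunoassays cannot quantify below the LOD;
  cells strictly below it are set to exactly 0. A value equal to the LOD
  counts as detected.
* **Exclusion.** An analyte undetectable in *strictly more than* 10% of
  samples carries mostly censoring information, not signal, and is
  dropped from analysis. The threshold (default 0.10) is strict because
  "over 10%" is strict; 6/59 samples (10.2%) already exceeds it.
* **Winsorization** (`zBound = 3.29`, two-sided p ≈ 0.001 under
  normality). The per-analyte mean and *sample* SD (n − 1 denominator)
  are computed once, including prospective outliers, and offending cells
  are replaced by the boundary value `mean ± 3.29·SD` in a single pass.
  No iteration: re-estimating moments after clipping and repeating would
  make the operation order-dependent and can cascade. A consequence worth
  knowing: because clipping shrinks the recomputed SD, a clipped cell can
  sit marginally outside the bound of the *new* moments; the single-pass
  rule is the contract, not a fixed point. Zero-SD analytes are skipped
  with a warning. Boundary replacement (rather than the
  next-most-extreme observed value) was chosen as the replacement rule
  and is recorded in the report.
* **Blom transformation.** Cytokine concentrations are strongly
  right-skewed; each analyte is mapped to
  `qnorm((r - 3/8)/(n + 1/4))` of its ascending rank r, with average
  ranks for ties so tied inputs stay tied. Zeros (censored cells that
  survive exclusion) simply occupy the bottom ranks. The transform is
  monotone, so Winsorization beforehand only matters when clipping
  creates ties — on tie-free data the two orders agree, and the applied
  order is logged in the `PreprocessReport`.

## Univariate models

For each analyte, a hierarchical linear regression is fit on the Blom
scale: Step 1 uses the four covariates; Step 2 adds the group factor with
`C/TD` as the reference cell, so the three indicator coefficients are
directly the contrasts against the control-typical group, and all six
pairwise contrasts follow by Wald tests on the Step-2 fit. The group
effect is judged by the F test of the R² increment. Per-analyte p values
are reported unadjusted (each analyte is its own hypothesis in this
tradition); a flag enables Holm adjustment across analytes. For the
group-characteristics tables, continuous variables use Kruskal–Wallis and
categorical variables use Fisher's exact test when any expected cell
count is below 5, otherwise chi-square — the dispatch is overridable per
variable since no universal rule exists — with Holm-adjusted pairwise
post hocs throughout (delegated to `stats::p.adjust`).

## The CPCA

The cytokine matrix is regressed on the four group indicators with a
pseudoinverse — the intercept-free indicator design makes coefficients
rank-deficient but the projection unique, and the projection (the
group-mean matrix) is the object of interest. PCA of the centred
predicted matrix can yield at most g − 1 = 3 informative components, so
a four-group study is a three-network study by construction; the
`extractComponents()` default retains eigenvalues above 1e-10 of the
largest (an automated, reproducible stand-in for reading a scree plot),
with an elbow heuristic (largest second difference) and a manual
override available and logged.

Loadings are scaled eigenvector × √eigenvalue and scores are unit
variance, so `centred predicted = scores %*% t(loadings)`. Varimax with
Kaiser normalization is implemented in-package by pairwise planar
rotations (criterion improvement < 1e-8 or 1000 sweeps); rotated columns
are ordered by explained sum of squares and sign-oriented so the
largest-magnitude loading is positive — pure presentation conventions
that keep runs comparable (`stats::varimax` serves as an independent
cross-check in the tests). Because rotation is orthogonal and scores have
identity covariance, rotated scores remain unit variance without
re-scaling.

Group involvement is scored by the Pearson correlation between each
group's indicator and each component's scores (two-sided t on n − 2 df,
unadjusted, with optional Holm adjustment across the 4 × K table), and
network membership uses |rotated loading| ≥ 0.40 — a conventional
salience threshold for correlation-scaled loadings, exposed prominently
because it is a judgement call. Covariates are deliberately *not* in the
CPCA design (adjustment belongs to the univariate models); a
`partialCovariates` flag allows residualizing them first as a
sensitivity analysis, and `scoresFrom = "raw"` projects the raw rather
than predicted matrix onto the rotated loadings.

## The synthetic-cohort generator

The generator emulates the study conditions: four groups of 15/12/15/17
children, a 40-analyte panel, three planted networks with disjoint
supports — {IL-2, TNF-β, IL-10, IL-15}, {MIP-1β, MDC, MCP-4, PlGF(−),
CRP(−)}, {eotaxin-3, eotaxin, bFGF} — lognormal concentrations
(`exp(mu + sigma·latent)`, mu one decade above LOD, sigma 1), LOD
censoring by deterministic count `round(rate × n)` at the six reported
undetectable rates (27/49/58/73/73/92%), and covariates drawn
independently of the planted scores unless a confounding knob is turned.
Uncensored cells are floored at the LOD (the *detection guarantee*), so
the planted censor rate is exactly the below-LOD rate and fixture tests
are exact.

Two defaults deserve explanation:

* **Noise scales.** `subjectScoreSD = 0.5` and `analyteNoiseSD = 0.125`:
  a child's network activity varies about its group mean by half a
  latent SD, and analyte-level measurement noise is a quarter of that —
  the network-dominated regime the generator is meant to emulate, in
  which same-network analytes correlate more strongly than cross-network
  pairs.
* **Activation magnitudes.** The signs of the groups × networks
  activation matrix follow the reported involvement pattern (network 1
  up in C/ND and down with alcohol; network 2 splitting A/TD from A/ND;
  network 3 up with alcohol exposure and down in C/TD). The magnitudes
  (2.15, 1.44/−1.05, −2.42 for the hallmark groups; ±0.2 elsewhere) were
  calibrated once so that the group-size-weighted activation profiles
  are mutually orthogonal **as seen after the Blom transform**.
  Orthogonality on that scale — not the latent scale — is the
  identifiability condition for recovering the planted networks by
  orthogonal rotation, because the rank transform distorts the group
  profiles nonlinearly. With correlated profiles, no orthogonal rotation
  of the PCA solution can reach the sparse planted structure, and the
  networks would blur into each other by construction rather than by
  estimation error.

What the generator does **not** emulate: plate and batch effects,
standard-curve nonlinearity at the quantification boundary, skewed or
heavy-tailed subject-level biology beyond lognormality, correlated
"background" loadings of non-network analytes (real cytokines correlate
broadly; here non-members are pure noise), or any dependence of
covariates on group (the confounding knob exists but defaults to off).
Passing recovery tests therefore demonstrate that the *pipeline*
recovers what it assumes, not that real panels satisfy those
assumptions.

## What recovery can and cannot achieve at this design size

Two structural facts bound parameter recovery at n = 59 and are worth
stating because they are properties of the design, not of the
implementation:

* After the Blom transform every analyte has (near-)unit variance, so
  the ~22 retained non-network analytes contribute sampling noise to the
  group means with expected between-group variance (g − 1)/n each —
  about 0.37 summed squared loading per component. This floor is
  independent of every generator setting.
* The rank transform compresses group separation: a network whose
  activation profile separates only one group caps its member loadings
  near 0.71, against 0.88 for a two-sided profile.

Together these imply that the Tucker congruence between estimated
rotated loadings and the sparse 0/1 planted supports plateaus around
0.88–0.94 per network (lowest for the 3-member network), and that with a
0.40 membership threshold a spurious member appears in roughly one
replicate in seven. The recovery tests therefore check medians and rates
against pilot-calibrated levels consistent with these bounds; sign
recovery of true members is essentially perfect.

## Heatmaps and orchestration

The group-profile heatmap z-scores each analyte over *all* samples and
averages within group, so the group-size-weighted combination of the
four group means is exactly zero per analyte; it is computed on the
post-zeroing, pre-Winsorization panel by default (the feeding stage is a
config option) over all 40 analytes, in panel order (display order is
configurable), with a diverging palette centred at 0. `runPipeline()`
chains simulate → preprocess → univariate → cpca → report from a YAML
config, aborts naming the failing stage, and writes a run log with
versions and seeds; identical config and seed give byte-identical JSON
and CSV outputs.

## Problem sizes used in the test-suite simulations

Null calibrations use 2000 replicates at n = 59 (binomial SE ≈ 0.005 at
the 0.05 level); recovery simulations use 200 replicates in the
acceptance script and 25–30 in the routine suite; the power check for a
1.5 SD pairwise shift uses 150 replicates; convergence of group means
uses 1000 children per group. These sizes keep Monte-Carlo error well
inside the asserted margins.

## Known limitations

Coefficients of the CPCA regression are not interpreted (only the
projection is); bootstrap confidence intervals for loadings are out of
scope; censored values are zeroed, not imputed, following the assay
convention — with heavy censoring below the exclusion threshold this
still distorts ranks; and the membership threshold, though conventional,
remains a judgement call that should be varied in sensitivity analyses.
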