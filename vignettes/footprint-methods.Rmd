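---
title: "Methods: exometabolome footprinting with footprintMS"
author: "footprintMS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exometabolome footprinting with footprintMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintMS)
```

## Scope and measurement model

footprintMS analyses exometabolome footprints measured by dilute-and-shoot
flow-injection tandem MS (DS-FIA-MS/MS) of culture supernatants, as used in
bioprocess development for amino-acid producing *Corynebacterium
glutamicum*. Two measurement modes are covered:

* **targeted**: a small analyte panel quantified absolutely by isotope
  dilution (IDMS) — each analyte's peak area is normalized by the area of a
  uniformly ^13^C^15^N-labelled internal standard and calibrated against a
  dilution series;
* **semi-targeted**: a few hundred MRM transitions recorded without
  internal standards, interpreted as relative intensities after
  QC-anchored drift correction.

The central container is `FootprintExperiment`, a `SummarizedExperiment`
with assays `intensity` (non-negative peak areas; missing is `NA`, never
0) and `snr`, plus per-sample metadata: role (`qc`, `sample`, `standard`,
`blank`), injection order (unique within an analytical batch), class
label, biological/technical replicate indices and dilution factor. Missing
values are treated as information — they feed the MAR/MNAR decision during
imputation — which is why writers emit empty cells rather than zeros.

## Preprocessing

**Signal-to-noise filter.** Measurements with S/N not *exceeding* 10 are
masked (`filterSNR`). The inequality is strict: a measurement at exactly
S/N = 10 is removed.

**QC-anchored drift correction.** Pooled-QC samples injected at every
k-th position monitor instrument drift. Per feature and batch,
`fitDriftModel` fits a locally weighted *linear* (degree-1, tricube)
smoother of QC intensity against injection order; the span is chosen from
the grid {0.3, 0.4, ..., 0.9} by leave-one-out cross-validation, and a
natural cubic spline through the smoother's fitted QC values yields a
correction function defined over the whole injection-order range (natural
boundary conditions extrapolate linearly beyond the outermost QCs). The
correction is multiplicative: each observed intensity is rescaled by
`reference / spline(order)`, with the reference level taken as the
*median* of the fitted QC values, which is robust against unusual QCs at
the run edges.

Two numerical guards matter in practice. First, local windows are
required to contain at least four points: with fewer, the tricube weight
of the farthest neighbour is zero and a degree-1 local fit passes exactly
through the remaining two points, so the "smoother" would interpolate the
QC noise instead of removing drift (for very short QC series the grid
collapses to a single global weighted linear fit). Second, a feature-batch
whose correction function is non-positive anywhere, or which has fewer
than four observed QCs, is marked uncorrectable and passed through
unchanged with a warning rather than silently distorted.

**Feature thresholding.** After correction, a feature is retained for
statistics only if its QC relative standard deviation (sd/mean of observed
QC intensities) is below 20% *and* its fraction of missing QC
measurements is below 30%. Features with fewer than four observed QCs can
be neither corrected nor assessed and are dropped with an explicit reason.
The QC report is a partition: every feature appears exactly once, kept or
dropped with an exhaustive reason.

**Imputation.** Missing sample cells are imputed per feature and class.
A cell counts as missing-not-at-random (left-censored at the detection
limit) if (a) its class has no observed value for that feature, or (b)
the class's observed minimum lies within a factor 2 of the feature's
global observed minimum while the feature's missingness rate exceeds
twice the table-wide rate; such cells receive *half of the feature's
global observed minimum*. All other cells are treated as missing at
random and receive the *within-class mean*, which preserves the class
contrasts that PLS-DA models afterwards (a global mean would shrink
them). The assignment is logged per cell in the table metadata. No
published rule exists for this MAR/MNAR split at the level of single
cells; the rule above is this package's stated operational definition.
Drift correction acts on raw intensities, not log-transformed ones; the
multiplicative correction is equivalent to an additive one on the log
scale, and downstream scaling operates on the natural scale.

## Multivariate modelling

**Range scaling.** Each feature is centered at its training mean and
divided by its training range (van den Berg convention). Parameters are
learned on training data only and applied unchanged to test data, so
cross-validation never leaks test statistics; constant features scale to
0. This predictor scaling is distinct from the heatmap normalization
below.

**PCA / PLS-DA.** PCA uses the singular value decomposition; Q²X comes
from k-fold cross-validated reconstruction error. PLS-DA is NIPALS PLS2
against the one-hot class matrix with deflation of the predictor block
only; predicted class is the argmax of the predicted responses. Scores
are sign-fixed (largest-magnitude loading positive) so results are
bit-reproducible. R²X/R²Y report explained predictor/response variance
per component.

**Double cross-validation.** Model validation uses stratified double
7-fold cross-validation: the outer loop estimates prediction (Q²Y =
1 − PRESS/TSS on held-out one-hot responses, centered at training class
frequencies; accuracy as the argmax hit rate), the inner loop tunes the
number of latent variables. A component is only added while Q² grows by
at least 5% *relative to the magnitude of the current Q²* — the rule base
is `|Q²(k)|`, a documented choice since a relative gain needs a
denominator; folds are reduced with a warning when a class is smaller
than the fold count, and singleton classes are rejected.

**Bootstrap variable selection.** The tuned PLS-DA is refitted on r = 100
stratified bootstrap resamples (with replacement, class proportions
preserved — plain resampling could lose a class entirely). From each
refit we collect per-class regression coefficients and *class-specific
VIP scores*

$$\mathrm{VIP}_k(j) = \sqrt{p \cdot \frac{\sum_a w_{ja}^2\,
\mathrm{SSY}_{k,a}}{\sum_a \mathrm{SSY}_{k,a}}},\qquad
\mathrm{SSY}_{k,a} = c_{ak}^2\, \mathbf{t}_a^\top\mathbf{t}_a ,$$

i.e. squared weights averaged with the share of class *k*'s response
variance explained by each component, normalized so the mean squared VIP
over features is 1. A feature is selected for a class when the 2.5%
bound of its VIP exceeds 1 *and* its beta percentile CI excludes 0.
Exclusion of an outlier class from the model is available as an explicit
`exclude_classes` argument — it is an analyst decision and never applied
automatically.

## Univariate statistics and clustering

Group differences are screened with the Kruskal–Wallis omnibus test
(tie-corrected, chi-square approximation; the all-tied degenerate case is
defined as H = 0, p = 1), followed by parametric pairwise post-hoc tests —
Welch's t for independent samples, the paired t for dependent ones —
Benjamini–Hochberg corrected across the pair set. Pairing a parametric
post-hoc with a non-parametric omnibus is unusual but kept as the
pipeline's convention; Dunn's rank-based test is available as an
alternative (`method = "dunn"`).

Hierarchical clustering uses the correlation distance `1 − r` (a constant
profile, whose correlation is undefined, is assigned distance 1 to
everything) with average linkage (UPGMA). Heatmaps are normalized per
feature by subtracting the minimum and dividing by the maximum of the
min-subtracted values, mapping every non-constant feature onto [0, 1].

## Pathway analysis

Over-representation uses the one-sided hypergeometric test of the
selected compound set against the background of assayable compounds, BH
corrected across pathways. Pathway topology impact is the normalized
betweenness-centrality ratio: the summed raw directed betweenness of the
hit compounds over the total betweenness of all pathway compounds
(denominator configurable to the maximum centrality). An edgeless
pathway has total centrality 0 and impact 0 by definition. Pathways are
simple directed compound graphs loaded from JSON; compound identity is
exact string identity, with no name matching.

## Bioprocess KPIs

The specific growth rate is the least-squares slope of log signal against
time over an explicit window (or the maximal-R² sliding window with
`window = "auto"`); it is invariant to multiplicative rescaling of the
biomass proxy. Molar yields convert mM or g/L inputs through a small
built-in molar-mass table (His, Gly, Ala, Val, Glc; overridable) and fold
changes are plain ratios with a guarded positive reference.

## What the synthetic data emulate — and what they do not

`generateRun` reproduces the structural features the pipeline relies on:
interleaved pooled-QC injections every k-th position (QCs drawn around
the pooled mean of class means, bracketing the run), smooth multiplicative
injection-order drift (linear or one-period sinusoidal), multiplicative
lognormal noise (positive, heteroscedastic intensities whose QC RSD is
approximately the lognormal sigma), class-structured multiplicative
effects over biological-by-technical replicate nesting, uniform MAR
missingness, left-censoring below a limit of detection, and S/N emitted
as intensity over a per-feature noise floor. Defaults mirror the study
design: 3 biological x 4 technical replicates per class, ~10% measurement
RSD, QC every 6th injection (the study does not report its QC interval;
6 is this package's choice, fixed once).

Not emulated: chromatographic peak shapes (flow injection has no
separation), ion suppression and cross-talk between transitions,
replicate-correlated (non-independent) noise, and batch-to-batch
instrument effects beyond one drift term per batch. Tests passing on
synthetic runs therefore demonstrate algorithmic correctness under the
stated noise model, not robustness to every failure mode of real
spectrometers.

## Problem sizes and verification

The test-suite simulations are sized for sharp checks at desk scale:
drift recovery uses 60 features over ~30 injections with QC every 6th
position; PLS-DA validation uses 24 samples x 30 features with 5 planted
discriminating features, 20 label permutations, and r = 100 bootstrap
resamples; error-control checks use 1000 all-null repetitions of m = 50
tests and 1000 uniform random ORA selections. Every closed-form statistic
is verified against an independent brute-force oracle (rank-sum formula,
exhaustive hypergeometric enumeration, BFS path counting, exhaustive
agglomeration) on small instances, and `scripts/acceptance.R` recomputes
the headline quantities end-to-end from a fresh seed.

## Known limitations

* The LOESS span grid assumes a reasonably dense QC series; with the
  minimum of four QCs the fit degenerates to a global weighted line.
* Half-minimum imputation is biased low by construction; it is the
  conventional choice for left-censored cells, not an estimator of the
  censored mean.
* Q²Y of the double CV is a pooled (not per-fold-averaged) statistic;
  with very small classes individual folds are noisy and the component
  rule may select conservatively.
* Pathway impact depends on the curated topology; missing edges deflate
  betweenness and hence impact.
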