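---
title: "Cell-cycle state analysis for mass cytometry: models and methods"
author: "cytocycle maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle state analysis for mass cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cytocycle` analyses single-cell mass cytometry (CyTOF) measurements of
cell-cycle-related proteins. Ion-count intensities for a panel of
metal-tagged antibodies — cyclins, licensing factors (CDT1/Geminin),
phospho-marks (pH3-S10, pRb-S780), replication readouts (IdU incorporation,
DNA intercalator, SLBP, PCNA), proliferation markers (Ki67, PLK1) and
chromatin/size channels — are preprocessed, gated into the four major
cell-cycle phases, discretized into canonical versus noncanonical
cell-cycle states, and scored for multivariate deviation from a reference
population. Two summary statistics sit at the centre: a graph-connectivity
measure of cell-state diversity, and nearest-neighbour aberrancy scores
with companion differential and variance-decomposition models.

Everything is exercised end to end on a synthetic data generator whose
defaults encode the study conditions the analysis assumes, so every stage
is testable without any external download.

# The data container

`CycloSet` extends `SingleCellExperiment`: channels in rows, cells in
columns. The `"counts"` assay keeps raw nonnegative ion counts; the
`"exprs"` assay carries the analysis scale and `metadata(x)$scale_state`
tracks its position on the fixed chain raw → asinh → normalized. The chain
only moves forward; each stage checks its precondition, which prevents the
classic mistake of normalizing twice or gating untransformed data.

# Preprocessing

1. **Arcsinh transform**, `asinh(x / cofactor)` with cofactor 5 — the
   standard variance-stabilizing transform for mass cytometry ion counts.
2. **Percentile normalization**: each channel is divided by its 99.9th
   percentile (linear interpolation between order statistics). Values
   above 1 are *not* censored by default (`clip = FALSE`), preserving
   within-channel rank order; censoring is available as a flag since some
   published workflows cap at 1.
3. **Anchor batch adjustment** operates on the *raw* scale, before the
   transform: for each channel and batch the adjustment factor is the
   ratio of anchor-sample medians, reference over batch. A multiplicative
   ion-count correction commutes with the downstream transforms only
   approximately, so the correction is applied where the physics is
   multiplicative — on raw counts. A zero anchor median leaves the channel
   untouched with a warning rather than producing infinite factors.
4. **Cleanup filters** remove cells outside per-channel intervals on the
   asinh scale: cPARP above threshold (pre-apoptotic) and DNA outside an
   intact-cell window standing in for debris/doublet removal. The retained
   set is the intersection of per-rule keeps, so rule order is irrelevant;
   per-rule counts may overlap when a cell violates several rules. The
   shipped intervals are calibrated to the synthetic templates only — real
   panels must supply their own.

# Phase gating

Phases are assigned by thresholds with the precedence **M > S > G2 >
G0G1**: pH3(S10)-positive cells are mitotic; of the rest, IdU-positive
cells are replicating (S); of the rest, Cyclin B1-high cells are G2;
everything else is G0G1. The precedence encodes two biological facts:
mitotic cells do not incorporate IdU, and Cyclin B1 peaks in M, so the
pH3 gate must dominate both. An optional G0-like sub-gate (Ki67-low and
pRb-S780-low within G0G1) is available but disabled by default because no
consensus cutoffs exist.

Thresholds come from three derivation methods. `valley` (the default)
places the cutoff at the density minimum between the two largest modes of
a kernel density estimate; a candidate valley must dip below half the
lower peak, otherwise the channel is treated as unimodal and the method
falls back to a stated quantile with a warning — this prominence rule
stops KDE ripples on a single mode from being mistaken for bimodality.
`quantile` and `manual` are for workflows with external knowledge of the
gates.

# Canonical and noncanonical states

A declarative rule table (TSV; user-replaceable) states the
literature-expected marker state per phase: Ki67 high in S, CDT1 not
expressed after S, pRb(S780) high in G2, PLK1 low in G0G1, SLBP degraded
by G2, Geminin low in G0G1. A cell violates a rule when its gated phase is
in the rule's phase set and its marker value contradicts the expectation
relative to the resolved threshold; quantile thresholds are resolved per
marker over all cells at evaluation time. A cell is **canonical iff it
violates no rule** — the strictest reading of a binary discretization —
and the per-cell violation count is kept for graded analyses. Violation
counts are monotone in the rule set by construction.

The shipped quantile choices place each threshold inside the gap between
the canonically-high and canonically-low subpopulations implied by the
default occupancy, which keeps the false-noncanonical rate on clean data
below a few percent while leaving decisively-violating cells detectable.

# Cell-state diversity

For a feature subset S, the cosine distance
`d(i,j) = 1 − x_i·x_j / (‖x_i‖‖x_j‖)` is computed over a fixed subsample
of cells (default 2000), an edge joins every pair with `d ≥ τ` (default
τ = 0.5), and the statistic is the graph's edge density,
edges / C(n, 2). The curve of mean density versus subset size, over all
(or a seeded sample of) subsets of the 17-marker pool, quantifies how much
state diversity additional features reveal.

The edge convention deserves a note: with edges joining *distant* pairs
(dissimilarity convention), higher connectivity means a population spread
over many well-separated states — the diversity reading — so that is the
default; the complementary similarity convention (`d < τ`) is retained as
an option. Exhaustive enumeration is exact for pools up to ~12 features;
beyond that a seeded uniform sample without replacement (default 500
subsets per size) caps the cost, and a cap at least as large as
`choose(p, s)` reproduces the exhaustive curve exactly.

# Aberrancy scoring

Three per-cell scores quantify deviation:

* **Nearest-neighbour aberrancy**: the mean Euclidean distance of a cell
  to its k nearest reference (e.g. untreated) cells on the core panel,
  with k = 10 by default (the choice is reported and configurable; the
  score is insensitive to k over 5–20 in our simulations). The search is
  exact — blocked full distance computation, no approximate index — which
  is cheap at the package's scales. The aberrancy threshold is the 0.95
  quantile of *leave-self-out* reference self-scores; leave-self-out
  avoids the zero-inflation a cell's own presence in the reference would
  cause, and by construction ~5% of reference-like cells exceed the
  threshold.
* **Mahalanobis phase deviation**: distance of each cell from its phase
  centroid under the phase's covariance, pooling canonical and
  noncanonical cells alike, with a ridge `λI` (default 1e-6) for
  numerical stability.
* **kNN condition score**: the fraction of a cell's k pooled nearest
  neighbours carrying each condition label, divided by the label's global
  prevalence — a simple density-ratio heuristic for condition enrichment
  around a cell, documented as such (it is not a re-implementation of any
  published graph-signal perturbation method; the pipeline exposes hooks
  where such external scores can be substituted).

# Statistics

Features are mean-centred and unit-scaled before modelling, so
coefficients are in per-channel SD units. Differential abundance fits, per
marker and stratum, a linear model of scaled abundance on the contrast and
Wald-tests each non-reference level; p-values are Benjamini–Hochberg
adjusted across every (marker, stratum, contrast) test of the call, and
significance uses the dual rule padj ≤ 0.1 **and** |coefficient| ≥ 0.5.
Fixed-effects least squares with large per-stratum n stands in for a
mixed-model framework — a deliberate simplification, since replicate
structure is better handled here at the pseudobulk level
(`pseudobulkAggregate`, median by default).

Variance decomposition comes in two forms: one-way ANOVA percent variance
(between-group SS over total SS, identically 100·R²) and a crossed
fixed-effects partition over cell line × phase × treatment × aberrancy
with all interactions up to 4-way, reporting sequential (type-I) SS
proportions in R's standard term order (main effects, then 2-way, …). On
balanced designs the proportions are order-invariant; on unbalanced ones
the term order matters and is therefore fixed and documented.

Cell-line classification uses multinomial logistic regression
(`nnet::multinom`) with a fixed L2 penalty (decay 0.1) on balanced
per-line training samples, evaluated on disjoint balanced test cells:
overall accuracy, one-vs-rest sensitivity/specificity/accuracy per class,
and pairwise metrics per line pair. Correlation-pattern similarity between
groups is the Pearson correlation between the vectorized upper triangles
of the groups' marker correlation matrices.

# The synthetic generator

The generator emulates the statistical structure the analysis assumes:

* **Phase structure.** Phases are drawn multinomially; the default
  occupancy is the activated-T-cell profile (42% G0G1, 51% S, 5.1% G2,
  1.8% M — the printed fractions sum to 0.999 and are renormalized
  proportionally).
* **Marker templates** encode the qualitative orderings the literature
  reports (IdU only in S, pH3 only in M, CyclinB1 ramp, CDT1/Geminin
  reciprocity, SLBP degradation at S/G2, Ki67/PCNA/PLK1 progression).
  Quantitative per-phase levels are not published, so the template values
  are chosen once to give realistic overlap at the default noise; they
  are a package design choice, not measured values.
* **Noise** is multiplicative lognormal with the template as median;
  default CV 0.35, typical of antibody-based cytometry channels. S-phase
  cells carry a uniform pseudo-position u that interpolates DNA content
  2N→4N (the data are treated as one S gate downstream, matching
  practice).
* **Cell lines** apply per-marker multiplicative offsets and optionally
  distinct occupancy profiles; **perturbations** replace the occupancy
  (drug arrest), apply phase-restricted marker effects and can realise
  mitotic slippage (G0G1-labelled cells with re-replicated >4N DNA,
  flagged noncanonical).
* **Noncanonical injections** force a rule's marker into its violating
  state for a random fraction of one phase and flip the ground-truth
  flag for exactly those cells. Violating levels are *negative-level*
  (0.1× the marker's lowest phase level) for "low" violations and the
  marker's highest phase level for "high" ones, so forced values remain
  decisively beyond the rule threshold even after the injected cells
  themselves shift the all-cell quantile the threshold is computed from.

What the generator does **not** model: doublets, beads, barcode chemistry,
acquisition drift, spillover, heavy-tailed outlier events, or correlated
noise across channels. Tests passing on synthetic data therefore validate
the *algorithms* under the stated statistical assumptions; they do not
certify performance on real acquisitions, where gating and cleanup
thresholds need per-experiment attention.

# Numerical and design choices

* Quantiles use R's default linear interpolation (type 7) everywhere.
* Cosine distances clamp tiny negative values from `tcrossprod` to zero;
  zero-norm cells carry no direction and are excluded with a logged count.
* The kNN partial sort is exact; ties are resolved by the stable partial
  sort, which cannot change the mean-of-k statistic.
* A single global pipeline seed fans out to per-stage seeds by fixed
  offsets, so a stage can be re-run in isolation and reproduce its
  pipeline behaviour; identical config + seed gives byte-identical output
  tables (timings are kept out of result files for this reason).
* The panel benchmark (`simulateCellLinePanel`) confines marker offsets to
  complete-panel-exclusive chromatin/size channels *and* gives lines
  distinct occupancy profiles. Occupancy differences are what real lines
  show, and they make the panel information ordering strict: minimal sees
  occupancy only through graded phase markers, core adds the direct
  DNA/IdU readouts, complete adds the offset channels. Without them the
  core-vs-minimal comparison would be an exact statistical tie and its
  direction a coin flip. Its noise CV of 0.5 makes graded markers
  noticeably noisy while the binary IdU gate stays clean.
* Problem sizes used in the shipped checks (10–50k cells, 500-subset
  diversity caps, 5000-cell aberrancy references, 50-seed power
  simulations) were chosen as the smallest sizes at which the targeted
  properties are statistically stable.

# Known limitations

* Gating quality depends on genuinely bimodal gating channels; on
  populations lacking a phase (e.g. pure arrest), the valley method falls
  back to quantiles and manual thresholds are preferable.
* Quantile-resolved rule thresholds shift with heavy contamination
  (>~30% violators of one rule), biasing violation calls conservative;
  absolute thresholds are the remedy when contamination is expected.
* The fixed-effects variance partition attributes variance, it does not
  estimate variance components; with unbalanced designs sequential SS
  depends on the documented term order.
* FCS support covers list-mode float data (the format this package
  writes); it is not a general-purpose FCS implementation.
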