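# cytocycle

Single-cell cell-cycle state analysis for mass cytometry (CyTOF).

Antibody panels against cell-cycle proteins — cyclins, the licensing pair
CDT1/Geminin, phospho-marks like pH3(S10) and pRb(S780), replication
readouts (IdU incorporation, DNA content, SLBP, PCNA) and proliferation
markers (Ki67, PLK1) — measure far more cell-cycle structure than the
classic four-phase gate captures. `cytocycle` is for analysts who want to
use that structure: it preprocesses raw ion counts, gates phases
programmatically, discretizes cells into canonical versus noncanonical
cell-cycle states from a declarative rule table, and quantifies both the
diversity of cell states and each cell's deviation from a reference
population, with differential and variance statistics on top.

## The statistics at the core

**Cell-state diversity.** For a feature subset *S* and cells *i*, *j*
with profiles *x<sub>i</sub>*, the cosine distance
*d(i,j) = 1 − x<sub>i</sub>·x<sub>j</sub> / (‖x<sub>i</sub>‖‖x<sub>j</sub>‖)*
defines a graph with an edge wherever *d(i,j) ≥ τ* (default τ = 0.5, 2000
cells). The statistic is the edge density *|E| / C(n,2)* ∈ [0,1]; its mean
over feature subsets of each size, as a function of size, measures how
much state diversity additional features reveal.

**Aberrancy.** Each cell's score is its mean Euclidean distance to its
*k* = 10 nearest reference (untreated) cells on the core panel; the
aberrancy threshold is the 0.95 quantile of leave-self-out reference
self-scores, so ~5% of reference-like cells exceed it by construction.
Mahalanobis distance to the phase centroid,
*√((x−μ<sub>g</sub>)ᵀ(Σ<sub>g</sub>+λI)<sup>−1</sup>(x−μ<sub>g</sub>))*,
gives the within-phase multivariate deviation.

**Canonical discretization.** Rules of the form "marker *m* should be
high/low in phases *P*" are evaluated against per-marker thresholds; a
cell is canonical iff it violates no rule.

**Differential & variance models.** Linear models on mean-centred,
unit-scaled features with Wald tests and Benjamini–Hochberg adjustment
(significant: padj ≤ 0.1 and |coefficient| ≥ 0.5 SD), one-way ANOVA
percent variance, a crossed fixed-effects variance partition with up to
4-way interactions, and multinomial panel classification
(sensitivity/specificity/accuracy per class and line pair).

A ground-truth-labelled synthetic generator (four-phase structure,
phase-specific marker templates, lognormal noise, cell-line offsets,
drug-arrest perturbations, injectable noncanonical states) makes the whole
chain testable end to end.

## Worked example

Simulate an activated-T-cell-like population with 20% Ki67-low violations
injected into S phase, run the chain, and quantify:

```r
library(cytocycle)

cfg <- generatorConfig(n_cells = 10000, seed = 1, noncanonical = list(
    list(rule = "Ki67_high_in_S", phase = "S", fraction = 0.2)))
cc <- simulatePopulation(cfg)
cc <- asinhTransform(cc, cofactor = 5)
cc <- cleanupFilter(cc)
cc <- percentileNormalize(cc, q = 99.9)
cc <- assignPhases(cc, deriveThresholds(cc, method = "valley"))
cc <- evaluateRules(cc)
cc
#> CycloSet: 18 channels x 9937 cells [scale: normalized]
#>  assays: counts, exprs
#>  phases: G0G1=4151 S=5063 G2=548 M=175
#>  cell metadata: truth_phase, truth_canonical, line, treatment, sample, ...

noncanonicalFraction(cc, by = "phase")
#>   phase    n noncanonical_fraction
#> 1  G0G1 4151           0.000000000
#> 2    G2  548           0.149635036
#> 3     M  175           0.005714286
#> 4     S 5063           0.191783528
```

The cleanup stage removed 63 cells (cPARP/DNA intervals); gated phase
counts track the 42/51/5.1/1.8% occupancy; and the S-phase noncanonical
fraction recovers the injected 20% (0.192, within binomial error). The
elevated G2 fraction is instructive rather than alarming: the few truly
S-phase cells whose IdU noise drops them into the G2 gate still carry
S-high SLBP, which violates the "SLBP degraded by G2" rule — gating error
propagates into rule calls, which is exactly how such cells would read in
a real experiment.

```r
curve <- diversityCurve(cc,
    features = c("Ki67", "CDT1", "IdU", "CyclinB1", "Geminin"),
    params = diversityParams(n_cells_subsample = 1000, seed = 1))
curve$means
#>   group size mean_density
#> 1   all    1    0.0000000
#> 2   all    2    0.1452460
#> 3   all    3    0.2311069
#> 4   all    4    0.3050959
#> 5   all    5    0.3660881
```

Mean connectivity grows with feature count: each added cell-cycle marker
separates states that the smaller subsets conflated. Single features score
zero because cosine distance carries no information in one nonnegative
dimension.

The full chain — simulate/ingest, preprocess, gate, rules, diversity,
aberrancy, statistics — also runs as one call with a single seed:

```r
report <- runPipeline(pipelineConfig(n_cells = 50000, seed = 1,
                                     output_dir = "out"))
```

Identical config and seed give byte-identical output tables.

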