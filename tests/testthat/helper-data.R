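## Shared fixture builders (all fixtures are generated in code).

suppressPackageStartupMessages({
    library(SummarizedExperiment)   # assay/colData/metadata in tests
})

## tiny raw CycloSet from an explicit cells x channels matrix
makeSet <- function(mat, meta = NULL) {
    CycloSet(mat, cell_meta = meta, cells_in_rows = TRUE)
}

## small default-noise population, preprocessed to the normalized scale
makeNormalized <- function(n = 2000, seed = 42, ...) {
    x <- simulatePopulation(generatorConfig(n_cells = n, seed = seed, ...))
    percentileNormalize(asinhTransform(x))
}

## absolute-threshold rule table for hand-checkable rule evaluation
absRule <- function(rule_id, marker, phases, expectation, value) {
    data.frame(rule_id = rule_id, marker = marker, phases = phases,
               expectation = expectation, threshold_mode = "absolute",
               threshold_value = value, stringsAsFactors = FALSE)
}
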