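#' @importFrom stats aggregate setNames
NULL

.EXPECTATIONS <- c("high", "low", "positive", "negative")

#' Load a canonical-rule table
#'
#' Rules declare the literature-expected state of a marker within a set of
#' phases: a cell whose gated phase is in `phases` and whose marker value
#' contradicts `expectation` relative to the resolved threshold violates the
#' rule. `"high"`/`"positive"` expect the value at or above the threshold
#' (violation below); `"low"`/`"negative"` expect it below (violation at or
#' above). Quantile thresholds are resolved per marker over all cells at
#' evaluation time; absolute thresholds are used as given.
#'
#' @param path tab-delimited file with columns `rule_id`, `marker`,
#'   `phases` ('+'-joined tokens, e.g. `"G2+M"`), `expectation`,
#'   `threshold_mode` (`quantile`/`absolute`), `threshold_value`
#' @return validated rule `data.frame`
#' @export
loadRules <- function(path) {
    if (!file.exists(path)) stop("rule file not found: ", path)
    rules <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    need <- c("rule_id", "marker", "phases", "expectation",
              "threshold_mode", "threshold_value")
    miss <- setdiff(need, colnames(rules))
    if (length(miss))
        stop("rule table lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(rules) == 0L) stop("rule table is empty: ", path)
    dup <- rules$rule_id[duplicated(rules$rule_id)]
    if (length(dup))
        stop("duplicate rule_id: ", paste(unique(dup), collapse = ", "))
    for (i in seq_len(nrow(rules))) {
        r <- rules[i, ]
        if (!r$expectation %in% .EXPECTATIONS)
            stop(sprintf("line %d: unknown expectation '%s'", i + 1L,
                         r$expectation))
        if (!r$threshold_mode %in% c("quantile", "absolute"))
            stop(sprintf("line %d: unknown threshold_mode '%s'", i + 1L,
                         r$threshold_mode))
        ph <- strsplit(r$phases, "+", fixed = TRUE)[[1]]
        if (length(ph) == 0L || !all(ph %in% .PHASES))
            stop(sprintf("line %d: bad phase set '%s'", i + 1L, r$phases))
        if (r$threshold_mode == "quantile" &&
            (r$threshold_value <= 0 || r$threshold_value >= 1))
            stop(sprintf("line %d: quantile threshold must lie in (0,1)",
                         i + 1L))
    }
    rules
}

#' The shipped default canonical-rule table
#'
#' Six quantile-threshold rules encoding the textbook expectations: Ki67
#' high in S (proliferative signature while replicating), CDT1 not expressed
#' after S (no relicensing in G2/M), pRb(S780) high in G2, PLK1 low in G0G1,
#' SLBP low in G2 (degraded at the S/G2 transition), and Geminin low in
#' G0G1. User tables in the same format replace it via [loadRules()].
#'
#' @return rule `data.frame`
#' @export
defaultRules <- function() {
    loadRules(system.file("extdata", "canonical_rules.tsv",
                          package = "cytocycle", mustWork = TRUE))
}

#' Discretize cells into canonical and noncanonical states
#'
#' Evaluates every rule against every cell of the rule's phases on the
#' normalized asinh scale. A cell is canonical iff it violates no rule;
#' per-cell violation counts are retained for graded analysis. Adding rules
#' can only increase violation counts (monotone in the rule set).
#'
#' @param x a normalized, phase-gated [CycloSet-class]
#' @param rules rule table from [loadRules()] / [defaultRules()]
#' @param phase_col `colData` column holding the phase labels
#' @return `x` with `violation_count` and `canonical` in `colData`; the
#'   cells x rules violation matrix and the resolved thresholds are stored
#'   in `metadata(x)$rule_evaluation`
#' @export
evaluateRules <- function(x, rules = defaultRules(), phase_col = "phase") {
    stopifnot(is(x, "CycloSet"))
    if (!phase_col %in% colnames(colData(x)))
        stop("no phase labels; run assignPhases() first")
    miss <- setdiff(unique(rules$marker), rownames(x))
    if (length(miss))
        stop("rule marker(s) missing from panel: ",
             paste(miss, collapse = ", "))
    phase <- as.character(colData(x)[[phase_col]])
    viol <- matrix(FALSE, ncol(x), nrow(rules),
                   dimnames = list(NULL, rules$rule_id))
    thresholds <- numeric(nrow(rules))
    for (i in seq_len(nrow(rules))) {
        r <- rules[i, ]
        v <- .cellMatrix(x, r$marker)[, 1]
        t_i <- if (r$threshold_mode == "quantile")
            quantile(v, r$threshold_value, names = FALSE)
        else r$threshold_value
        thresholds[i] <- t_i
        in_phase <- phase %in% strsplit(r$phases, "+", fixed = TRUE)[[1]]
        bad <- if (r$expectation %in% c("high", "positive")) v < t_i
               else v >= t_i
        viol[, i] <- in_phase & bad
    }
    colData(x)$violation_count <- as.integer(rowSums(viol))
    colData(x)$canonical <- colData(x)$violation_count == 0L
    metadata(x)$rule_evaluation <-
        list(violations = viol,
             thresholds = stats::setNames(thresholds, rules$rule_id))
    x
}

#' Noncanonical fraction per group
#'
#' @param x a [CycloSet-class] after [evaluateRules()]
#' @param by character vector of `colData` columns to group by
#'   (default cell line and phase)
#' @return `data.frame` with the grouping columns, `n` and
#'   `noncanonical_fraction`; empty groups are absent
#' @export
noncanonicalFraction <- function(x, by = c("line", "phase")) {
    stopifnot(is(x, "CycloSet"))
    if (!"canonical" %in% colnames(colData(x)))
        stop("no canonical calls; run evaluateRules() first")
    miss <- setdiff(by, colnames(colData(x)))
    if (length(miss))
        stop("grouping column(s) not in colData: ",
             paste(miss, collapse = ", "))
    cd <- as.data.frame(colData(x)[, by, drop = FALSE])
    agg <- aggregate(!colData(x)$canonical, by = cd, FUN = mean)
    cnt <- aggregate(rep(1L, ncol(x)), by = cd, FUN = sum)
    out <- merge(cnt, agg, by = by, sort = TRUE)
    names(out)[names(out) == "x.x"] <- "n"
    names(out)[names(out) == "x.y"] <- "noncanonical_fraction"
    out
}
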