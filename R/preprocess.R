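#' @importFrom stats quantile median
NULL

#' Arcsinh-transform raw intensities
#'
#' Replaces every raw count x by `asinh(x / cofactor)` into the `"exprs"`
#' assay, advancing `scale_state` to `"asinh"`. The transform is strictly
#' monotone, so within-channel rank order is preserved. Cofactor 5 is the
#' standard choice for mass cytometry ion counts.
#'
#' @param x raw-scale [CycloSet-class]
#' @param cofactor positive scale cofactor (default 5)
#' @return the transformed `CycloSet`
#' @export
asinhTransform <- function(x, cofactor = 5) {
    stopifnot(is(x, "CycloSet"))
    .requireState(x, "raw", "asinhTransform")
    if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
        stop("'cofactor' must be a single positive number")
    assay(x, "exprs") <- asinh(assay(x, "counts") / cofactor)
    metadata(x)$scale_state <- "asinh"
    metadata(x)$cofactor <- cofactor
    x
}

#' Per-channel percentile normalization
#'
#' Divides each channel of the `"exprs"` assay by its q-th percentile
#' (linear interpolation between order statistics), advancing `scale_state`
#' to `"normalized"`. With `clip = TRUE` values above 1 are censored at 1;
#' the default leaves them uncensored so rank order is preserved.
#'
#' @param x an asinh-scale [CycloSet-class]
#' @param q percentile in (0, 100] (default 99.9)
#' @param clip censor values at 1 after division
#' @return the normalized `CycloSet`; divisors are recorded in
#'   `metadata(x)$percentile_divisors`
#' @export
percentileNormalize <- function(x, q = 99.9, clip = FALSE) {
    stopifnot(is(x, "CycloSet"))
    .requireState(x, "asinh", "percentileNormalize")
    if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 100)
        stop("'q' must be in (0, 100]")
    e <- assay(x, "exprs")
    div <- apply(e, 1L, quantile, probs = q / 100, names = FALSE)
    bad <- div <= 0
    if (any(bad))
        stop("degenerate channel(s) with nonpositive ", q,
             "th percentile: ", paste(rownames(e)[bad], collapse = ", "))
    e <- e / div
    if (clip) e[e > 1] <- 1
    assay(x, "exprs") <- e
    metadata(x)$scale_state <- "normalized"
    metadata(x)$percentile_divisors <- stats::setNames(div, rownames(e))
    metadata(x)$percentile_q <- q
    x
}

#' Anchor-sample batch adjustment
#'
#' Multiplicative per-channel batch correction on the raw ion-count scale:
#' for channel c and batch b, the factor is
#' `median(anchor cells, reference batch, c) / median(anchor cells, b, c)`,
#' and every cell of batch b is multiplied by it. The reference batch is
#' unchanged; a zero anchor median leaves that channel untouched with a
#' warning. Re-running on adjusted data yields factors of 1 (idempotence).
#'
#' @param x raw-scale [CycloSet-class]
#' @param anchor logical per-cell anchor mask, or the name of a logical
#'   colData column
#' @param batch per-cell batch labels, or a colData column name
#' @param reference reference batch id
#' @return the adjusted `CycloSet`; factors in
#'   `metadata(x)$batch_factors` (channels x batches)
#' @export
anchorBatchAdjust <- function(x, anchor, batch, reference) {
    stopifnot(is(x, "CycloSet"))
    .requireState(x, "raw", "anchorBatchAdjust")
    anchor <- as.logical(.cellAnnotation(x, anchor, "anchor"))
    batch <- as.character(.cellAnnotation(x, batch, "batch"))
    if (!reference %in% batch)
        stop("reference batch not present: ", reference)
    batches <- unique(batch)
    no_anchor <- batches[!vapply(batches,
                                 function(b) any(anchor & batch == b), NA)]
    if (length(no_anchor))
        stop("batch(es) without anchor cells: ",
             paste(no_anchor, collapse = ", "))
    cnt <- assay(x, "counts")
    ref_med <- apply(cnt[, anchor & batch == reference, drop = FALSE], 1L,
                     median)
    factors <- matrix(1, nrow(cnt), length(batches),
                      dimnames = list(rownames(cnt), batches))
    for (b in setdiff(batches, reference)) {
        bm <- apply(cnt[, anchor & batch == b, drop = FALSE], 1L, median)
        f <- ref_med / bm
        zero <- bm == 0 | ref_med == 0
        if (any(zero)) {
            warning("zero anchor median in batch ", b, " for channel(s) ",
                    paste(rownames(cnt)[zero], collapse = ", "),
                    "; factor set to 1")
            f[zero] <- 1
        }
        factors[, b] <- f
        cnt[, batch == b] <- cnt[, batch == b] * f
    }
    assay(x, "counts") <- cnt
    metadata(x)$batch_factors <- factors
    x
}

#' Default cleanup thresholds for the synthetic panel
#'
#' Asinh-scale intervals standing in for the manual debris/doublet/apoptosis
#' gates: cPARP-positive (pre-apoptotic) cells above the cPARP maximum are
#' removed, and cells outside the DNA window (debris below 2N, doublet-like
#' above ~8N) are removed. Tuned to the synthetic generator's templates;
#' real panels should supply their own intervals.
#'
#' @return named list of `c(min, max)` intervals on the asinh scale
#' @export
defaultCleanupThresholds <- function() {
    list(cPARP = c(-Inf, 1.0), DNA = c(0.4, 2.7))
}

#' Threshold cleanup filter
#'
#' Removes every cell lying outside any channel's `(min, max)` interval on
#' the asinh scale (e.g. cPARP above its maximum, DNA outside the intact-cell
#' window). The retained set is the intersection of the per-rule keeps, so
#' it does not depend on rule order; per-rule removal counts may overlap
#' when one cell violates several rules.
#'
#' @param x an asinh- or normalized-scale [CycloSet-class]
#' @param thresholds named list of `c(min, max)` per channel
#' @return the filtered `CycloSet`; a per-rule report `data.frame`
#'   (`channel`, `removed`) plus totals is stored in
#'   `metadata(x)$cleanup_report`
#' @export
cleanupFilter <- function(x, thresholds = defaultCleanupThresholds()) {
    stopifnot(is(x, "CycloSet"))
    if (!scaleState(x) %in% c("asinh", "normalized"))
        stop("cleanupFilter expects asinh or normalized scale_state")
    miss <- setdiff(names(thresholds), rownames(x))
    if (length(miss))
        stop("unknown cleanup channel(s): ", paste(miss, collapse = ", "))
    ## thresholds are stated on the asinh scale; rescale if already
    ## percentile-normalized
    div <- metadata(x)$percentile_divisors
    e <- assay(x, "exprs")
    keep <- rep(TRUE, ncol(x))
    removed <- integer(length(thresholds))
    for (i in seq_along(thresholds)) {
        ch <- names(thresholds)[i]
        lim <- thresholds[[i]]
        v <- e[ch, ]
        if (identical(scaleState(x), "normalized") && !is.null(div))
            v <- v * div[[ch]]
        ok <- v >= lim[1] & v <= lim[2]
        removed[i] <- sum(!ok)
        keep <- keep & ok
    }
    report <- data.frame(channel = names(thresholds), removed = removed)
    out <- x[, keep]
    if (ncol(out) == 0L)
        warning("cleanupFilter removed every cell")
    metadata(out)$cleanup_report <-
        list(per_rule = report, n_in = ncol(x), n_out = ncol(out))
    out
}
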