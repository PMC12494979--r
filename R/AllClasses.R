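#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assay<- assays assayNames rowData
#'   rowData<- colData colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

.SCALE_STATES <- c("raw", "asinh", "normalized")

#' CycloSet: cells-by-channels cytometry container
#'
#' `CycloSet` extends [SingleCellExperiment::SingleCellExperiment] to hold a
#' mass-cytometry intensity matrix (channels in rows, cells in columns, the
#' Bioconductor convention) together with per-cell metadata and a panel
#' annotation. The `"counts"` assay always carries the raw nonnegative ion
#' counts; preprocessing adds an `"exprs"` assay (asinh-transformed, then
#' percentile-normalized) and, optionally, a `"scaled"` assay
#' (mean-centred/unit-variance view used by the statistical models). The
#' preprocessing position on that chain is tracked in
#' `metadata(x)$scale_state`, one of `"raw"`, `"asinh"`, `"normalized"`,
#' and only ever advances in that order.
#'
#' Cell-level annotations accumulate in `colData`: `line`, `treatment`,
#' `sample` and (for synthetic data) `truth_phase` / `truth_canonical`;
#' [assignPhases()] adds `phase`, [evaluateRules()] adds `violation_count`
#' and `canonical`.
#'
#' @name CycloSet-class
#' @aliases CycloSet-class
#' @exportClass CycloSet
setClass("CycloSet", contains = "SingleCellExperiment")

setValidity("CycloSet", function(object) {
    msg <- character()
    st <- metadata(object)$scale_state
    if (is.null(st) || !is.character(st) || length(st) != 1L ||
        !st %in% .SCALE_STATES)
        msg <- c(msg, sprintf("metadata(x)$scale_state must be one of %s",
                              paste(.SCALE_STATES, collapse = ", ")))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "channel names (rownames) must be present and unique")
    if ("counts" %in% assayNames(object)) {
        cnt <- assay(object, "counts")
        if (nrow(cnt) > 0L && ncol(cnt) > 0L && min(cnt) < 0)
            msg <- c(msg, "raw counts must be nonnegative")
    } else msg <- c(msg, "a 'counts' assay is required")
    if (length(msg)) msg else TRUE
})

#' Construct a CycloSet
#'
#' @param counts numeric matrix of raw intensities. Either channels x cells
#'   with `cells_in_rows = FALSE` (default) or cells x channels with
#'   `cells_in_rows = TRUE`; must have channel names.
#' @param cell_meta `data.frame`/`DataFrame` of per-cell metadata (one row
#'   per cell), or `NULL`.
#' @param panel optional `data.frame` with columns `marker` and `category`
#'   (one of `"minimal"`, `"core"`, `"complete"`, `"cleanup"`, `"other"`)
#'   annotating channels; defaults to the package panel for known markers.
#' @param cells_in_rows logical; set `TRUE` when `counts` is cells x channels.
#' @return a [CycloSet-class] object with `scale_state = "raw"`.
#' @examples
#' m <- matrix(rpois(60, 10), nrow = 3,
#'             dimnames = list(c("Ki67", "IdU", "DNA"), NULL))
#' cs <- CycloSet(m)
#' scaleState(cs)
#' @export
CycloSet <- function(counts, cell_meta = NULL, panel = NULL,
                     cells_in_rows = FALSE) {
    if (cells_in_rows) counts <- t(counts)
    if (is.null(rownames(counts)))
        stop("'counts' must carry channel names")
    n <- ncol(counts)
    if (is.null(cell_meta)) cell_meta <- S4Vectors::make_zero_col_DFrame(n)
    cell_meta <- as(cell_meta, "DataFrame")
    rownames(cell_meta) <- NULL
    if (nrow(cell_meta) != n)
        stop("'cell_meta' must have one row per cell")
    if (is.null(panel)) panel <- defaultPanel(rownames(counts))
    panel <- panel[match(rownames(counts), panel$marker), , drop = FALSE]
    panel$marker <- rownames(counts)
    panel$category[is.na(panel$category)] <- "other"
    sce <- SingleCellExperiment(assays = list(counts = counts),
                                colData = cell_meta,
                                rowData = DataFrame(panel),
                                metadata = list(scale_state = "raw"))
    new("CycloSet", sce)
}

#' Accessors for CycloSet
#'
#' `scaleState` reports the preprocessing position (`"raw"`, `"asinh"` or
#' `"normalized"`); `phaseLabels` returns the gated phase factor (or `NULL`
#' before gating); `panelFeatures` lists the channels belonging to a nested
#' panel (`minimal` \eqn{\subset} `core` \eqn{\subset} `complete`);
#' `cellData` returns the per-cell metadata as a `DataFrame`.
#'
#' @param x a [CycloSet-class]
#' @param panel one of `"minimal"`, `"core"`, `"complete"`
#' @return `scaleState`: character scalar; `phaseLabels`: factor or `NULL`;
#'   `panelFeatures`: character vector of channel names; `cellData`:
#'   `DataFrame`.
#' @name CycloSet-accessors
NULL

#' @rdname CycloSet-accessors
#' @export
scaleState <- function(x) metadata(x)$scale_state

#' @rdname CycloSet-accessors
#' @export
phaseLabels <- function(x) {
    if ("phase" %in% colnames(colData(x))) colData(x)$phase else NULL
}

#' @rdname CycloSet-accessors
#' @export
cellData <- function(x) colData(x)

#' @rdname CycloSet-accessors
#' @export
panelFeatures <- function(x, panel = c("core", "minimal", "complete")) {
    panel <- match.arg(panel)
    cat <- rowData(x)$category
    keep <- switch(panel,
        minimal  = cat == "minimal",
        core     = cat %in% c("minimal", "core"),
        complete = cat %in% c("minimal", "core", "complete"))
    rownames(x)[keep]
}

setMethod("show", "CycloSet", function(object) {
    cat(sprintf("CycloSet: %d channels x %d cells [scale: %s]\n",
                nrow(object), ncol(object), scaleState(object)))
    cat(" assays:", paste(assayNames(object), collapse = ", "), "\n")
    ph <- phaseLabels(object)
    if (!is.null(ph)) {
        tb <- table(ph)
        cat(" phases:", paste(sprintf("%s=%d", names(tb), tb),
                              collapse = " "), "\n")
    }
    cd <- setdiff(colnames(colData(object)), "phase")
    if (length(cd)) cat(" cell metadata:", paste(cd, collapse = ", "), "\n")
})

## internal: cells x features numeric matrix on the requested assay
.cellMatrix <- function(x, features = NULL, assay_name = NULL) {
    if (is.null(assay_name))
        assay_name <- if ("exprs" %in% assayNames(x)) "exprs" else "counts"
    if (!assay_name %in% assayNames(x))
        stop(sprintf("assay '%s' not present; run the preprocessing chain first",
                     assay_name))
    m <- t(assay(x, assay_name))
    if (!is.null(features)) {
        miss <- setdiff(features, colnames(m))
        if (length(miss))
            stop("channel(s) not found: ", paste(miss, collapse = ", "))
        m <- m[, features, drop = FALSE]
    }
    m
}

.requireState <- function(x, state, what) {
    if (!identical(scaleState(x), state))
        stop(sprintf("%s expects scale_state '%s' (got '%s')",
                     what, state, scaleState(x)))
    invisible(TRUE)
}
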