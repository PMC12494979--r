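#' @importFrom stats mahalanobis cov
NULL

## blocked exact k-nearest-neighbour mean distances from rows of Q to rows
## of R; `exclude` gives, per query row, a row of R to ignore (self).
.knnMeanDist <- function(Q, R, k, metric = c("euclidean", "cosine"),
                         exclude = NULL, block = 2048L) {
    metric <- match.arg(metric)
    if (k > nrow(R) - as.integer(!is.null(exclude)))
        stop(sprintf("k = %d exceeds the usable reference size %d", k,
                     nrow(R) - as.integer(!is.null(exclude))))
    if (metric == "cosine") {
        Q <- Q / pmax(sqrt(rowSums(Q^2)), .Machine$double.eps)
        R <- R / pmax(sqrt(rowSums(R^2)), .Machine$double.eps)
    }
    r2 <- rowSums(R^2)
    out <- numeric(nrow(Q))
    for (beg in seq(1L, nrow(Q), by = block)) {
        end <- min(beg + block - 1L, nrow(Q))
        Qb <- Q[beg:end, , drop = FALSE]
        d <- if (metric == "euclidean") {
            d2 <- outer(rowSums(Qb^2), r2, "+") - 2 * tcrossprod(Qb, R)
            d2[d2 < 0] <- 0
            sqrt(d2)
        } else {
            dc <- 1 - tcrossprod(Qb, R)
            dc[dc < 0] <- 0
            dc
        }
        if (!is.null(exclude)) {
            ex <- exclude[beg:end]
            ok <- !is.na(ex)
            d[cbind(which(ok), ex[ok])] <- Inf
        }
        out[beg:end] <- apply(d, 1L, function(r)
            mean(sort.int(r, partial = k)[seq_len(k)]))
    }
    out
}

#' Nearest-neighbour aberrancy score
#'
#' Scores every query cell by its mean distance to its k nearest cells of a
#' reference population (e.g. untreated cells) on a shared feature set —
#' the phenotypic cell-cycle distance from the unperturbed state. The
#' search is exact (full blocked distance computation, no approximation).
#'
#' @param query a [CycloSet-class] or cells x features matrix
#' @param reference reference population, same type and features
#' @param k number of neighbours (default 10)
#' @param metric `"euclidean"` (default) or `"cosine"`
#' @param features feature set (default: the core panel for `CycloSet`
#'   input)
#' @return numeric vector of nonnegative scores, one per query cell
#' @export
nnAberrancy <- function(query, reference, k = 10,
                        metric = c("euclidean", "cosine"),
                        features = NULL) {
    metric <- match.arg(metric)
    if (is(query, "CycloSet")) {
        if (is.null(features)) features <- panelFeatures(query, "core")
        Q <- .cellMatrix(query, features)
    } else Q <- as.matrix(query)
    R <- if (is(reference, "CycloSet"))
        .cellMatrix(reference, if (is.null(features)) NULL else features)
    else as.matrix(reference)
    if (ncol(Q) != ncol(R)) stop("query and reference feature sets differ")
    .knnMeanDist(Q, R, k, metric)
}

#' Leave-self-out reference self-scores
#'
#' Scores each reference cell against the rest of the reference (its own
#' row excluded), giving the null distribution from which the aberrancy
#' threshold is drawn.
#'
#' @inheritParams nnAberrancy
#' @return numeric vector of self-scores
#' @export
selfAberrancy <- function(reference, k = 10,
                          metric = c("euclidean", "cosine"),
                          features = NULL) {
    metric <- match.arg(metric)
    if (is(reference, "CycloSet")) {
        if (is.null(features)) features <- panelFeatures(reference, "core")
        R <- .cellMatrix(reference, features)
    } else R <- as.matrix(reference)
    .knnMeanDist(R, R, k, metric, exclude = seq_len(nrow(R)))
}

#' Aberrancy threshold from the reference distribution
#'
#' @param self_scores leave-self-out scores from [selfAberrancy()]
#' @param alpha quantile in (0, 1) (default 0.95): roughly `1 - alpha` of
#'   held-out reference-like cells exceed it by construction
#' @return threshold value
#' @export
aberrancyThreshold <- function(self_scores, alpha = 0.95) {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
        alpha >= 1)
        stop("'alpha' must lie in (0, 1)")
    quantile(self_scores, alpha, names = FALSE)
}

#' Classify cells as aberrant
#'
#' @param scores scores from [nnAberrancy()]
#' @param threshold threshold from [aberrancyThreshold()]
#' @return logical vector, `TRUE` where `score > threshold`
#' @export
classifyAberrant <- function(scores, threshold) scores > threshold

#' Per-cell Mahalanobis distance to the phase centroid
#'
#' Distance of each cell from its own group's centroid under the group's
#' (ridge-regularized) covariance, the multivariate per-phase deviation
#' measure: `sqrt((x - mu_g)' (Sigma_g + lambda I)^-1 (x - mu_g))`. Group
#' statistics pool every cell of the group (canonical and noncanonical
#' alike), so noncanonical cells are scored against the whole-phase
#' population.
#'
#' @param x a normalized [CycloSet-class]
#' @param group `colData` column name or per-cell vector (typically the
#'   phase labels)
#' @param features feature set (default core panel)
#' @param lambda ridge added to each group covariance diagonal
#'   (default 1e-6); with `lambda = 0` a singular covariance is an error
#' @return numeric vector of distances, one per cell
#' @export
mahalanobisByGroup <- function(x, group = "phase", features = NULL,
                               lambda = 1e-6) {
    stopifnot(is(x, "CycloSet"))
    if (is.null(features)) features <- panelFeatures(x, "core")
    g <- as.character(.cellAnnotation(x, group, "group"))
    m <- .cellMatrix(x, features)
    out <- numeric(nrow(m))
    for (lev in unique(g)) {
        idx <- which(g == lev)
        if (length(idx) < ncol(m) + 2L && lambda <= 0)
            stop("group ", lev, " too small for an unregularized covariance")
        mu <- colMeans(m[idx, , drop = FALSE])
        S <- cov(m[idx, , drop = FALSE]) + diag(lambda, ncol(m))
        ok <- tryCatch({solve(S); TRUE}, error = function(e) FALSE)
        if (!ok)
            stop("singular covariance in group ", lev,
                 "; increase 'lambda'")
        out[idx] <- sqrt(mahalanobis(m[idx, , drop = FALSE], mu, S))
    }
    out
}

#' Simplified kNN condition score
#'
#' A documented stand-in for graph-based perturbation scoring: for each
#' cell, the fraction of its k nearest neighbours (pooled over all
#' conditions, leave-self-out) carrying each condition label, divided by
#' that label's global prevalence. Scores near 1 mean the neighbourhood is
#' exchangeable with the pool; a cell of a perfectly separated condition
#' scores ~`1/prevalence` for its own label. This is a density-ratio
#' heuristic, not a re-implementation of any published graph-signal method.
#'
#' @param x a normalized [CycloSet-class]
#' @param condition `colData` column or per-cell labels (>= 2 levels, none
#'   empty)
#' @param k number of neighbours (default 10)
#' @param features feature set (default core panel)
#' @return cells x conditions numeric matrix of enrichment scores
#' @export
knnConditionScore <- function(x, condition = "treatment", k = 10,
                              features = NULL) {
    stopifnot(is(x, "CycloSet"))
    if (is.null(features)) features <- panelFeatures(x, "core")
    cond <- as.character(.cellAnnotation(x, condition, "condition"))
    lev <- sort(unique(cond))
    if (length(lev) < 2L) stop("need >= 2 conditions")
    m <- .cellMatrix(x, features)
    n <- nrow(m)
    if (k >= n) stop("k must be smaller than the number of cells")
    prev <- table(factor(cond, levels = lev)) / n
    counts <- matrix(0L, n, length(lev), dimnames = list(NULL, lev))
    r2 <- rowSums(m^2)
    block <- 2048L
    for (beg in seq(1L, n, by = block)) {
        end <- min(beg + block - 1L, n)
        d2 <- outer(r2[beg:end], r2, "+") -
            2 * tcrossprod(m[beg:end, , drop = FALSE], m)
        d2[cbind(seq_len(end - beg + 1L), beg:end)] <- Inf
        for (i in seq_len(end - beg + 1L)) {
            nb <- order(d2[i, ])[seq_len(k)]
            tb <- table(factor(cond[nb], levels = lev))
            counts[beg + i - 1L, ] <- as.integer(tb)
        }
    }
    sweep(counts / k, 2L, as.numeric(prev), "/")
}
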