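#' Cosine distance matrix over a feature subset
#'
#' `d(i, j) = 1 - x_i . x_j / (||x_i|| ||x_j||)` computed on the subset's
#' columns of the normalized expression matrix. Cells with zero norm on the
#' subset carry no direction and are excluded (their count is messaged).
#' For nonnegative data the distance lies in `[0, 1]`.
#'
#' @param x a [CycloSet-class] or a cells x features numeric matrix
#' @param features character subset of channels (ignored for plain matrices
#'   when `NULL`)
#' @return symmetric distance matrix with zero diagonal over the usable
#'   cells; the indices kept are in `attr(, "cells_used")`
#' @export
cosineDistanceMatrix <- function(x, features = NULL) {
    m <- if (is(x, "CycloSet")) .cellMatrix(x, features)
         else if (is.null(features)) as.matrix(x)
         else as.matrix(x)[, features, drop = FALSE]
    nrm <- sqrt(rowSums(m^2))
    usable <- nrm > 0
    if (sum(usable) < 2L)
        stop("fewer than 2 cells with nonzero norm on the subset")
    if (any(!usable))
        message(sum(!usable), " zero-norm cell(s) excluded")
    mu <- m[usable, , drop = FALSE] / nrm[usable]
    d <- 1 - tcrossprod(mu)
    d[d < 0] <- 0            # numerical negatives from tcrossprod
    diag(d) <- 0
    attr(d, "cells_used") <- which(usable)
    d
}

#' Graph edge density at a distance threshold
#'
#' Builds the cell graph implied by thresholding a pairwise distance matrix
#' and returns its edge density: edges divided by `choose(n, 2)`. Under the
#' default dissimilarity convention an edge joins cells at distance
#' `>= tau`, so density grows with the spread of cell states (the diversity
#' reading); the similarity convention (`< tau`) is the complementary
#' neighbourhood graph.
#'
#' @param d square symmetric distance matrix (n >= 2)
#' @param tau distance threshold (default 0.5)
#' @param convention `"dissimilarity"` (edge when `d >= tau`) or
#'   `"similarity"` (edge when `d < tau`)
#' @return density in `[0, 1]`, with the convention in
#'   `attr(, "convention")`
#' @export
graphDensity <- function(d, tau = 0.5,
                         convention = c("dissimilarity", "similarity")) {
    convention <- match.arg(convention)
    d <- as.matrix(d)
    n <- nrow(d)
    if (n < 2L || n != ncol(d)) stop("'d' must be square with n >= 2")
    ut <- d[upper.tri(d)]
    edges <- if (convention == "dissimilarity") sum(ut >= tau)
             else sum(ut < tau)
    structure(edges / choose(n, 2), convention = convention)
}

#' Parameters for the diversity curve
#'
#' @param tau cosine-distance threshold (default 0.5)
#' @param n_cells_subsample cells used per run (default 2000; all cells when
#'   fewer are available)
#' @param max_subsets_per_size cap on enumerated subsets per size, sampled
#'   uniformly without replacement when `choose(p, s)` exceeds it
#'   (default 500; `Inf` forces exhaustive enumeration)
#' @param convention edge convention, as in [graphDensity()]
#' @param seed seed controlling the cell subsample and subset sampling
#' @return list of class `"DiversityParams"`
#' @export
diversityParams <- function(tau = 0.5, n_cells_subsample = 2000,
                            max_subsets_per_size = 500,
                            convention = c("dissimilarity", "similarity"),
                            seed = 1L) {
    convention <- match.arg(convention)
    if (tau <= 0 || tau >= 2) stop("'tau' must lie in (0, 2)")
    if (n_cells_subsample < 2) stop("'n_cells_subsample' must be >= 2")
    structure(list(tau = tau, n_cells_subsample = n_cells_subsample,
                   max_subsets_per_size = max_subsets_per_size,
                   convention = convention, seed = as.integer(seed)),
              class = "DiversityParams")
}

## seeded sample of `k` distinct size-`s` subsets of `pool` (exhaustive via
## combn when within the cap)
.sampleSubsets <- function(pool, s, k) {
    total <- choose(length(pool), s)
    if (total <= k)
        return(utils::combn(pool, s, simplify = FALSE))
    seen <- new.env(hash = TRUE)
    out <- vector("list", k)
    got <- 0L
    while (got < k) {
        cand <- sort(sample(pool, s))
        key <- paste(cand, collapse = "\r")
        if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            got <- got + 1L
            out[[got]] <- cand
        }
    }
    out
}

#' Cell-state diversity as a function of feature count
#'
#' For each subset size s of the feature pool, enumerates all (or a seeded
#' sample of) the size-s feature subsets, computes the cosine-distance
#' graph density of a once-per-run cell subsample on each subset, and
#' averages densities within each size. The resulting mean-connectivity
#' curve quantifies how much cell-state diversity additional features
#' reveal. With `by`, the curve is computed separately per group (e.g. per
#' cell line) on per-group subsamples.
#'
#' @param x a normalized [CycloSet-class]
#' @param features feature pool (default: the 17-marker diversity pool
#'   intersected with the panel)
#' @param params a [diversityParams()]
#' @param by optional `colData` column (or per-cell vector) to stratify by
#' @return list of class `"DiversityCurve"`: `records` (one row per subset:
#'   `group`, `size`, `subset`, `density`, `n_cells_used`) and `means`
#'   (per group and size)
#' @export
diversityCurve <- function(x, features = NULL, params = diversityParams(),
                           by = NULL) {
    stopifnot(is(x, "CycloSet"), inherits(params, "DiversityParams"))
    if (is.null(features))
        features <- intersect(defaultDiversityFeatures(), rownames(x))
    if (length(features) == 0L) stop("empty feature pool")
    groups <- if (is.null(by)) rep("all", ncol(x))
              else as.character(.cellAnnotation(x, by, "by"))
    m_all <- .cellMatrix(x, features)
    recs <- .withSeed(params$seed, {
        out <- list()
        for (g in unique(groups)) {
            idx <- which(groups == g)
            if (length(idx) > params$n_cells_subsample)
                idx <- sample(idx, params$n_cells_subsample)
            mg <- m_all[idx, , drop = FALSE]
            for (s in seq_along(features)) {
                subs <- .sampleSubsets(features, s,
                                       params$max_subsets_per_size)
                dens <- vapply(subs, function(fs) {
                    d <- cosineDistanceMatrix(mg[, fs, drop = FALSE])
                    as.numeric(graphDensity(d, params$tau,
                                            params$convention))
                }, 0)
                out[[length(out) + 1L]] <- data.frame(
                    group = g, size = s,
                    subset = vapply(subs, paste, "", collapse = "+"),
                    density = dens, n_cells_used = length(idx))
            }
        }
        do.call(rbind, out)
    })
    means <- aggregate(density ~ group + size, data = recs, FUN = mean)
    names(means)[names(means) == "density"] <- "mean_density"
    structure(list(records = recs, means = means[order(means$group,
                                                       means$size), ],
                   params = params, features = features),
              class = "DiversityCurve")
}

#' @export
print.DiversityCurve <- function(x, ...) {
    cat(sprintf("DiversityCurve: %d features, %d subsets, tau = %g (%s)\n",
                length(x$features), nrow(x$records), x$params$tau,
                x$params$convention))
    print(x$means, row.names = FALSE)
    invisible(x)
}
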