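#' @importFrom stats lm anova pt p.adjust cor predict sd terms as.formula
#' @importFrom nnet multinom
NULL

#' Mean-centre and unit-scale features
#'
#' Adds a `"scaled"` assay: per channel, subtract the mean and divide by the
#' standard deviation across all cells. Constant channels become all zeros
#' with a warning. Statistical models (differential testing,
#' classification) operate on this view, so coefficients are in
#' per-channel SD units.
#'
#' @param x a normalized [CycloSet-class]
#' @return `x` with a `"scaled"` assay
#' @export
scaleFeatures <- function(x) {
    stopifnot(is(x, "CycloSet"))
    .requireState(x, "normalized", "scaleFeatures")
    e <- assay(x, "exprs")
    mu <- rowMeans(e)
    s <- apply(e, 1L, sd)
    zero <- s == 0
    if (any(zero)) {
        warning("constant channel(s) set to 0: ",
                paste(rownames(e)[zero], collapse = ", "))
        s[zero] <- 1
    }
    sc <- (e - mu) / s
    sc[zero, ] <- 0
    assay(x, "scaled") <- sc
    x
}

.scaledMatrix <- function(x, features = NULL) {
    if (!"scaled" %in% assayNames(x)) x <- scaleFeatures(x)
    .cellMatrix(x, features, assay_name = "scaled")
}

## matrix-response OLS Wald tests: per response column, coefficients of the
## non-intercept terms with two-sided p-values
.lmWald <- function(X, Y) {
    qrX <- qr(X)
    beta <- qr.coef(qrX, Y)
    res <- Y - X %*% beta
    df <- nrow(X) - qrX$rank
    sigma2 <- colSums(res^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(outer(diag(XtXinv), sigma2))
    tstat <- beta / se
    pval <- 2 * pt(-abs(tstat), df)
    list(coef = beta, p = pval, df = df)
}

#' Differential marker abundance
#'
#' Per marker (and optionally per stratum, e.g. per cell-cycle phase), fits
#' a linear model of the scaled abundance on the contrast variable and
#' Wald-tests each non-reference level against the reference. p-values are
#' Benjamini-Hochberg adjusted across all (marker, stratum, contrast) tests
#' of the call, and a feature is called significant under the dual
#' criterion `padj <= padj_max` and `|coefficient| >= coef_min` (defaults
#' 0.1 and 0.5 SD units).
#'
#' @param x a normalized [CycloSet-class] (a `"scaled"` assay is added if
#'   absent)
#' @param contrast `colData` column with >= 2 levels; the first factor
#'   level (or `reference`) is the control
#' @param strata optional `colData` column to stratify by; strata where the
#'   contrast is single-level are skipped with a warning
#' @param reference reference level of the contrast
#' @param features features to test (default: all channels)
#' @param padj_max,coef_min dual significance thresholds
#' @return `data.frame` with columns `marker`, `stratum`, `contrast`,
#'   `coefficient`, `wald_p`, `padj`, `significant`
#' @export
differentialTest <- function(x, contrast = "treatment", strata = NULL,
                             reference = NULL, features = NULL,
                             padj_max = 0.1, coef_min = 0.5) {
    stopifnot(is(x, "CycloSet"))
    Y <- .scaledMatrix(x, features)
    g <- factor(.cellAnnotation(x, contrast, "contrast"))
    if (!is.null(reference)) g <- stats::relevel(g, reference)
    st <- if (is.null(strata)) factor(rep("all", ncol(x)))
          else factor(.cellAnnotation(x, strata, "strata"))
    rows <- list()
    for (s in levels(st)) {
        idx <- st == s
        gs <- droplevels(g[idx])
        if (nlevels(gs) < 2L) {
            warning("stratum ", s, " has a single contrast level; skipped")
            next
        }
        X <- stats::model.matrix(~ gs)
        w <- .lmWald(X, Y[idx, , drop = FALSE])
        for (j in seq_len(nlevels(gs) - 1L)) {
            lev <- levels(gs)[j + 1L]
            rows[[length(rows) + 1L]] <- data.frame(
                marker = colnames(Y), stratum = s,
                contrast = paste0(lev, "_vs_", levels(gs)[1L]),
                coefficient = w$coef[j + 1L, ],
                wald_p = w$p[j + 1L, ], row.names = NULL)
        }
    }
    if (!length(rows)) stop("no testable stratum")
    out <- do.call(rbind, rows)
    out$padj <- p.adjust(out$wald_p, method = "BH")
    out$significant <- out$padj <= padj_max &
        abs(out$coefficient) >= coef_min
    out
}

#' Percent variance explained by a factor (one-way ANOVA)
#'
#' Per marker, the between-group sum of squares of the grouping factor
#' divided by the total sum of squares, as a percent — identical to 100 x
#' R-squared of the one-way linear model of abundance on the factor.
#'
#' @param x a normalized [CycloSet-class]
#' @param group `colData` column or per-cell labels with >= 2 levels
#' @param features features to score (default all channels)
#' @param assay_name assay to use (default the scaled view)
#' @return `data.frame` with `marker` and `pct_variance`
#' @export
varianceExplained <- function(x, group = "line", features = NULL,
                              assay_name = "scaled") {
    stopifnot(is(x, "CycloSet"))
    g <- factor(.cellAnnotation(x, group, "group"))
    if (nlevels(g) < 2L) stop("grouping factor needs >= 2 levels")
    Y <- if (assay_name == "scaled") .scaledMatrix(x, features)
         else .cellMatrix(x, features, assay_name)
    mu <- colMeans(Y)
    sst <- colSums(sweep(Y, 2L, mu)^2)
    gm <- rowsum(Y, g) / as.vector(table(g))
    ssb <- colSums(sweep(gm, 2L, mu)^2 * as.vector(table(g)))
    data.frame(marker = colnames(Y),
               pct_variance = 100 * ssb / sst, row.names = NULL)
}

#' Pseudobulk aggregation
#'
#' Per sample and marker, the chosen statistic (median by default) of the
#' single-cell values. With `normalize = TRUE` every marker column is
#' divided by its grand median across samples, the per-line-relative view
#' used for cross-line comparisons.
#'
#' @param x a [CycloSet-class]
#' @param sample `colData` column or per-cell sample labels
#' @param statistic summary function (default [median])
#' @param features features to aggregate (default all channels)
#' @param assay_name assay to aggregate (default `"exprs"` when present)
#' @param normalize divide each marker by its grand median across samples
#' @return samples x markers numeric matrix
#' @export
pseudobulkAggregate <- function(x, sample = "sample", statistic = median,
                                features = NULL, assay_name = NULL,
                                normalize = FALSE) {
    stopifnot(is(x, "CycloSet"))
    s <- factor(.cellAnnotation(x, sample, "sample"))
    empty <- levels(s)[table(s) == 0L]
    if (length(empty)) {
        warning("empty sample(s) dropped: ", paste(empty, collapse = ", "))
        s <- droplevels(s)
    }
    m <- .cellMatrix(x, features, assay_name)
    out <- t(vapply(levels(s), function(lv)
        apply(m[s == lv, , drop = FALSE], 2L, statistic),
        numeric(ncol(m))))
    if (normalize) {
        gm <- apply(out, 2L, median)
        if (any(gm == 0)) warning("zero grand median; channel left as is")
        gm[gm == 0] <- 1
        out <- sweep(out, 2L, gm, "/")
    }
    out
}

#' Variance partitioning across crossed factors
#'
#' Per marker, fits a fixed-effects linear model containing the main
#' effects and all interactions of the supplied factors up to `max_order`,
#' and reports each term's sequential (type-I) sum of squares as a
#' proportion of the total, plus the residual. Terms enter in R's standard
#' order — all main effects, then all two-way interactions, and so on — so
#' on balanced (orthogonal) designs the proportions do not depend on term
#' order. Aliased terms are dropped by the fit and absorb zero SS.
#'
#' @param values samples x markers numeric matrix (e.g. from
#'   [pseudobulkAggregate()])
#' @param design `data.frame` of factors, one row per sample
#' @param max_order highest interaction order (default `min(4, n factors)`)
#' @return `data.frame` with `marker`, `term`, `proportion`; proportions
#'   per marker sum to 1
#' @export
partitionVariance <- function(values, design, max_order = NULL) {
    values <- as.matrix(values)
    stopifnot(nrow(values) == nrow(design))
    design <- as.data.frame(lapply(design, factor))
    k <- ncol(design)
    if (is.null(max_order)) max_order <- min(4L, k)
    rhs <- if (max_order >= k)
        paste(colnames(design), collapse = " * ")
    else sprintf("(%s)^%d", paste(colnames(design), collapse = " + "),
                 max_order)
    out <- list()
    for (j in seq_len(ncol(values))) {
        df <- cbind(.y = values[, j], design)
        fit <- lm(as.formula(paste(".y ~", rhs)), data = df)
        av <- anova(fit)
        prop <- av$`Sum Sq` / sum(av$`Sum Sq`)
        out[[j]] <- data.frame(marker = colnames(values)[j],
                               term = rownames(av), proportion = prop,
                               row.names = NULL)
    }
    do.call(rbind, out)
}

.classMetrics <- function(truth, pred, classes) {
    vapply(classes, function(cl) {
        tp <- sum(truth == cl & pred == cl)
        fn <- sum(truth == cl & pred != cl)
        fp <- sum(truth != cl & pred == cl)
        tn <- sum(truth != cl & pred != cl)
        c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
          accuracy = (tp + tn) / length(truth))
    }, numeric(3))
}

#' Multinomial cell-line classification by panel
#'
#' Trains an L2-regularized multinomial logistic regression on a balanced
#' per-line sample of scaled features from the chosen panel, and evaluates
#' it on balanced held-out cells (training and test cells are disjoint).
#' Reports the overall test accuracy, one-vs-rest sensitivity / specificity
#' / accuracy per class, and pairwise metrics per line pair (each pair's
#' test cells classified by their larger fitted probability between the two
#' classes).
#'
#' @param x a normalized [CycloSet-class]
#' @param line `colData` column or per-cell line labels (>= 2 lines)
#' @param panel `"minimal"`, `"core"` or `"complete"`, or a character
#'   vector of features
#' @param train_n training cells per line
#' @param test_n test cells per line (default: up to `train_n`, from the
#'   held-out cells)
#' @param decay L2 penalty passed to [nnet::multinom()] (default 0.1)
#' @param seed seed for the balanced sampling
#' @return list of class `"ClassificationReport"`: `overall_accuracy`,
#'   `class_metrics`, `pairwise`, `confusion`, `panel`
#' @export
classifyCellLines <- function(x, line = "line", panel = "core",
                              train_n = 2000, test_n = NULL, decay = 0.1,
                              seed = 1L) {
    stopifnot(is(x, "CycloSet"))
    feats <- if (length(panel) == 1L &&
                 panel %in% c("minimal", "core", "complete"))
        panelFeatures(x, panel) else panel
    miss <- setdiff(feats, rownames(x))
    if (length(miss))
        stop("panel feature(s) missing: ", paste(miss, collapse = ", "))
    g <- factor(.cellAnnotation(x, line, "line"))
    if (nlevels(g) < 2L) stop("need >= 2 cell lines")
    Y <- .scaledMatrix(x, feats)
    if (is.null(test_n)) test_n <- train_n
    sel <- .withSeed(seed, {
        tr <- te <- integer()
        for (lv in levels(g)) {
            idx <- sample(which(g == lv))
            if (length(idx) < 2L) stop("line ", lv, " has < 2 cells")
            ntr <- min(train_n, length(idx) - 1L)
            tr <- c(tr, idx[seq_len(ntr)])
            te <- c(te, idx[ntr + seq_len(min(test_n, length(idx) - ntr))])
        }
        list(tr = tr, te = te)
    })
    dtrain <- data.frame(.line = g[sel$tr], Y[sel$tr, , drop = FALSE],
                         check.names = FALSE)
    fit <- multinom(.line ~ ., data = dtrain, decay = decay, trace = FALSE,
                    maxit = 300, MaxNWts = 10000)
    dtest <- data.frame(Y[sel$te, , drop = FALSE], check.names = FALSE)
    truth <- g[sel$te]
    pred <- predict(fit, dtest, type = "class")
    prob <- predict(fit, dtest, type = "probs")
    if (is.null(dim(prob)))  # two-class multinom returns a vector
        prob <- cbind(1 - prob, prob, deparse.level = 0)
    colnames(prob) <- levels(g)
    cm <- .classMetrics(truth, pred, levels(g))
    pairs <- utils::combn(levels(g), 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(pairs, function(pr) {
        keep <- truth %in% pr
        pp <- ifelse(prob[keep, pr[1]] >= prob[keep, pr[2]], pr[1], pr[2])
        tt <- as.character(truth[keep])
        m <- .classMetrics(tt, pp, pr)
        data.frame(line_a = pr[1], line_b = pr[2],
                   sensitivity = m["sensitivity", pr[1]],
                   specificity = m["specificity", pr[1]],
                   accuracy = mean(pp == tt), row.names = NULL)
    }))
    structure(list(overall_accuracy = mean(pred == truth),
                   class_metrics = as.data.frame(t(cm)),
                   pairwise = pw,
                   confusion = table(truth = truth, predicted = pred),
                   panel = panel, n_train = length(sel$tr),
                   n_test = length(sel$te)),
              class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
    cat(sprintf("ClassificationReport [%s panel]: accuracy %.3f (%d train / %d test)\n",
                paste(x$panel, collapse = ","), x$overall_accuracy,
                x$n_train, x$n_test))
    print(round(x$class_metrics, 3))
    invisible(x)
}

#' Correlation-pattern similarity between groups
#'
#' Per group, the Pearson correlation matrix over the feature set; the
#' similarity of two groups is the Pearson correlation between the
#' vectorized upper triangles of their correlation matrices. Constant
#' features within a group contribute zero correlations (with a warning).
#'
#' @param x a normalized [CycloSet-class]
#' @param group `colData` column or per-cell labels, each group >= 3 cells
#' @param features feature set (>= 2 features; default core panel)
#' @return symmetric group x group similarity matrix with unit diagonal
#' @export
correlationSimilarity <- function(x, group = "line", features = NULL) {
    stopifnot(is(x, "CycloSet"))
    if (is.null(features)) features <- panelFeatures(x, "core")
    if (length(features) < 2L) stop("need >= 2 features")
    g <- factor(.cellAnnotation(x, group, "group"))
    m <- .cellMatrix(x, features)
    tri <- lapply(levels(g), function(lv) {
        sub <- m[g == lv, , drop = FALSE]
        if (nrow(sub) < 3L) stop("group ", lv, " has < 3 cells")
        const <- apply(sub, 2L, sd) == 0
        cc <- suppressWarnings(cor(sub))
        if (any(const)) {
            warning("constant feature(s) in group ", lv,
                    ": correlations set to 0")
            cc[const, ] <- 0; cc[, const] <- 0
        }
        cc[is.na(cc)] <- 0
        cc[upper.tri(cc)]
    })
    k <- nlevels(g)
    out <- diag(1, k)
    dimnames(out) <- list(levels(g), levels(g))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
        out[i, j] <- out[j, i] <- cor(tri[[i]], tri[[j]])
    out
}
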