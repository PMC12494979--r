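test_that("feature scaling centres and unit-scales channels", {
    mat <- cbind(A = c(0, 2, 0, 2), B = rep(3, 4), C = 1:4)
    x <- makeSet(mat)
    metadata(x)$scale_state <- "normalized"
    assay(x, "exprs") <- t(mat)
    expect_warning(xs <- scaleFeatures(x), "constant channel")
    sc <- assay(xs, "scaled")
    expect_equal(unname(sc["A", ]), c(-1, 1, -1, 1) * 2 / sd(c(0, 2, 0, 2)) / 2)
    expect_equal(unname(sc["B", ]), rep(0, 4))
    expect_lt(abs(mean(sc["C", ])), 1e-12)
    expect_equal(sd(sc["C", ]), 1)
})

test_that("two-group coefficients equal scaled mean differences", {
    x <- makeNormalized(2000, seed = 41)
    colData(x)$treatment <- rep(c("control", "treated"), 1000)
    x <- scaleFeatures(x)
    de <- differentialTest(x, contrast = "treatment")
    sc <- assay(x, "scaled")
    tr <- colData(x)$treatment == "treated"
    for (mk in c("Ki67", "DNA", "SLBP")) {
        diff_means <- mean(sc[mk, tr]) - mean(sc[mk, !tr])
        expect_equal(de$coefficient[de$marker == mk], diff_means,
                     tolerance = 1e-9)
    }
    ## padj >= p within the family, and BH equals the textbook step-up
    expect_true(all(de$padj >= de$wald_p - 1e-15))
    p <- de$wald_p
    n <- length(p); o <- order(p, decreasing = TRUE)
    stepup <- pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
    expect_equal(de$padj, stepup)
})

test_that("null contrasts yield no significant features", {
    x <- makeNormalized(3000, seed = 42)
    set.seed(43)
    colData(x)$treatment <- sample(rep(c("control", "treated"), length.out = 3000))
    de <- differentialTest(x, contrast = "treatment")
    expect_true(all(abs(de$coefficient) < 0.25))
    expect_false(any(de$significant))
})

test_that("a one-SD single-marker shift is detected under the dual rule", {
    hits <- logical(5)
    for (i in 1:5) {
        x <- makeNormalized(4000, seed = 50 + i)
        set.seed(60 + i)
        treated <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
        colData(x)$treatment <- ifelse(treated, "treated", "control")
        e <- assay(x, "exprs")
        e["Geminin", treated] <- e["Geminin", treated] + sd(e["Geminin", ])
        assay(x, "exprs") <- e
        de <- differentialTest(x, contrast = "treatment")
        hits[i] <- de$significant[de$marker == "Geminin"]
        expect_false(any(de$significant[de$marker != "Geminin"]))
    }
    expect_true(all(hits))
})

test_that("stratified testing skips degenerate strata with a warning", {
    x <- makeNormalized(1000, seed = 44)
    colData(x)$treatment <- c(rep("control", 500), rep("treated", 500))
    colData(x)$stratum <- c(rep("s1", 500), rep(c("s1", "s2"), 250))
    expect_warning(de <- differentialTest(x, contrast = "treatment",
                                          strata = "stratum"),
                   "single contrast level")
    expect_true(all(de$stratum == "s1"))
})

test_that("variance explained equals one-way R-squared", {
    x <- makeNormalized(4000, seed = 45)
    ## perfectly line-separated channel
    g <- rep(c("a", "b"), 2000)
    e <- assay(x, "exprs")
    e["WGA", ] <- ifelse(g == "a", 1, 3)
    assay(x, "exprs") <- e
    suppressWarnings(ve <- varianceExplained(x, group = g))
    expect_equal(ve$pct_variance[ve$marker == "WGA"], 100)
    ## equals 100 x R^2 of lm for an arbitrary channel
    y <- t(assay(x, "exprs"))[, "Ki67"]
    r2 <- summary(lm(scale(y) ~ g))$r.squared
    ve_raw <- varianceExplained(x, group = g)
    expect_equal(ve_raw$pct_variance[ve_raw$marker == "Ki67"], 100 * r2,
                 tolerance = 1e-9)
    expect_true(all(ve_raw$pct_variance >= 0 & ve_raw$pct_variance <= 100))
    ## permuted labels land near the chance level (k-1)/(n-1)
    set.seed(46)
    perm <- sample(rep(letters[1:5], 800))
    vp <- varianceExplained(x, group = perm)
    expect_lt(mean(vp$pct_variance), 0.5)
    expect_error(varianceExplained(x, group = rep("one", 4000)),
                 ">= 2 levels")
})

test_that("variance partitioning recovers known components", {
    set.seed(47)
    des <- expand.grid(line = LETTERS[1:5], phase = c("G0G1", "S", "G2", "M"),
                       treatment = c("c", "t1", "t2"), rep = 1:3)
    eff <- function(n, v) {
        e <- rnorm(n); e <- e - mean(e); e * sqrt(v / mean(e^2))
    }
    le <- eff(5, 60); pe <- eff(4, 25); te <- eff(3, 10)
    y <- le[as.integer(des$line)] + pe[as.integer(des$phase)] +
        te[as.integer(des$treatment)] + eff(nrow(des), 5)
    vp <- partitionVariance(matrix(y, dimnames = list(NULL, "mk")),
                            des[, c("line", "phase", "treatment")])
    getp <- function(term) vp$proportion[vp$term == term]
    expect_lt(abs(getp("line") - 0.60), 0.05)
    expect_lt(abs(getp("phase") - 0.25), 0.05)
    expect_lt(abs(getp("treatment") - 0.10), 0.05)
    expect_equal(sum(vp$proportion), 1, tolerance = 1e-9)
    ## line-only marker loads entirely on line
    y2 <- le[as.integer(des$line)]
    vp2 <- suppressWarnings(  # perfect fit: F-statistics are irrelevant
        partitionVariance(matrix(y2, dimnames = list(NULL, "mk")),
                          des[, c("line", "phase", "treatment")]))
    expect_gt(vp2$proportion[vp2$term == "line"], 0.999)
    ## balanced orthogonal design: proportions invariant to factor order
    vp3 <- partitionVariance(matrix(y, dimnames = list(NULL, "mk")),
                             des[, c("treatment", "phase", "line")])
    for (tm in c("line", "phase", "treatment"))
        expect_equal(getp(tm), vp3$proportion[vp3$term == tm],
                     tolerance = 1e-9)
})

test_that("pseudobulk aggregation takes medians and normalizes", {
    mat <- cbind(M1 = c(1, 2, 9, 4), M2 = c(2, 2, 4, 4))
    x <- makeSet(mat, meta = data.frame(sample = c("s1", "s1", "s1", "s2")))
    pb <- pseudobulkAggregate(x, "sample")
    expect_equal(pb["s1", "M1"], 2)          # median of 1, 2, 9
    expect_equal(pb["s2", "M1"], 4)          # single-cell sample
    ## normalization: medians {2, 4} against grand median 3
    pbn <- pseudobulkAggregate(x, "sample", normalize = TRUE)
    expect_equal(unname(pbn[, "M2"]), c(2 / 3, 4 / 3))
})

test_that("panel classification separates constructed lines", {
    ## disjoint strong offsets on many markers: near-perfect accuracy
    offs <- list(L1 = NULL,
                 L2 = c(Ki67 = 4, WGA = 4, PCNA = 4, CTCF = 4))
    x <- simulatePopulation(generatorConfig(n_cells = 6000, seed = 48,
                                            cell_line_offsets = offs,
                                            noise_cv = 0.2))
    x <- percentileNormalize(asinhTransform(x))
    r <- classifyCellLines(x, panel = "complete", train_n = 1500,
                           test_n = 1000, seed = 49)
    expect_gte(r$overall_accuracy, 0.99)
    ## metrics agree with direct confusion-matrix counting
    cm <- r$confusion
    acc_direct <- sum(diag(cm)) / sum(cm)
    expect_equal(r$overall_accuracy, acc_direct)
    sens_L2 <- cm["L2", "L2"] / sum(cm["L2", ])
    expect_equal(r$class_metrics["L2", "sensitivity"], sens_L2)
    ## training and test cells are disjoint by construction
    expect_lte(r$n_train + r$n_test, ncol(x))
    ## permuted labels fall to chance
    set.seed(51)
    perm <- sample(as.character(cellData(x)$line))
    rp <- classifyCellLines(x, line = perm, panel = "complete",
                            train_n = 1500, test_n = 1000, seed = 52)
    expect_lt(abs(rp$overall_accuracy - 0.5), 0.05)
})

test_that("correlation-pattern similarity behaves at its extremes", {
    x <- makeNormalized(4000, seed = 53)
    ## the same population split at random: similarity ~ 1
    set.seed(54)
    half <- sample(rep(c("g1", "g2"), 2000))
    s <- correlationSimilarity(x, group = half)
    expect_gt(s["g1", "g2"], 0.95)
    expect_equal(diag(s), c(g1 = 1, g2 = 1))
    ## independent noise groups: similarity ~ 0. The similarity of two
    ## noise correlation patterns over p features has SD ~ 1/sqrt(C(p,2)-1)
    ## whatever the cell count, so the bound is 3 SD for p = 10.
    set.seed(55)
    mr <- matrix(abs(rnorm(8000 * 10)), 8000,
                 dimnames = list(NULL, paste0("F", 1:10)))
    xr <- makeSet(mr)
    metadata(xr)$scale_state <- "normalized"
    assay(xr, "exprs") <- t(mr)
    sr <- correlationSimilarity(xr, group = rep(c("a", "b"), 4000),
                                features = paste0("F", 1:10))
    expect_lt(abs(sr["a", "b"]), 3 / sqrt(choose(10, 2) - 1))
    ## feature-permuted copy is less similar than the identical copy
    xp <- makeNormalized(3000, seed = 56)
    feats <- panelFeatures(xp, "core")
    m <- t(assay(xp, "exprs"))
    permuted <- m
    permuted[, feats] <- permuted[, sample(feats)]
    both <- rbind(m, permuted)
    xb <- makeSet(matrix(1, nrow(both), ncol(both),
                         dimnames = dimnames(both)))
    metadata(xb)$scale_state <- "normalized"
    assay(xb, "exprs") <- t(both)
    sb <- correlationSimilarity(xb, group = rep(c("orig", "perm"),
                                                each = 3000),
                                features = feats)
    expect_lt(sb["orig", "perm"], 0.9)
})
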