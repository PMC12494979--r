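test_that("NN aberrancy matches hand arithmetic and brute force", {
    ## mean of distances 0 and 5
    expect_equal(nnAberrancy(rbind(c(0, 0)), rbind(c(0, 0), c(3, 4)), k = 2),
                 2.5)
    ## exact zero for a duplicated reference cell
    expect_equal(nnAberrancy(rbind(c(1, 2)), rbind(c(1, 2), c(9, 9)), k = 1),
                 0)
    ## brute-force oracle, euclidean and cosine
    set.seed(31)
    Q <- matrix(abs(rnorm(100 * 4)) + 0.01, 100)
    R <- matrix(abs(rnorm(500 * 4)) + 0.01, 500)
    D <- as.matrix(dist(rbind(Q, R)))[1:100, 101:600]
    oracle <- apply(D, 1, function(r) mean(sort(r)[1:10]))
    expect_lt(max(abs(nnAberrancy(Q, R, k = 10) - oracle)), 1e-9)
    Qn <- Q / sqrt(rowSums(Q^2)); Rn <- R / sqrt(rowSums(R^2))
    Dc <- 1 - tcrossprod(Qn, Rn)
    oc <- apply(Dc, 1, function(r) mean(sort(r)[1:10]))
    expect_lt(max(abs(nnAberrancy(Q, R, k = 10, metric = "cosine") - oc)),
              1e-9)
    ## k beyond the reference errors
    expect_error(nnAberrancy(Q, R[1:5, ], k = 10), "exceeds")
})

test_that("NN score is translation invariant and shrinks with duplicates", {
    set.seed(32)
    Q <- matrix(rnorm(40), 20); R <- matrix(rnorm(100), 50)
    s1 <- nnAberrancy(Q, R, k = 5)
    s2 <- nnAberrancy(Q + 7, R + 7, k = 5)
    expect_equal(s1, s2)
    ## k duplicates of each query in the reference drive the score to 0
    s3 <- nnAberrancy(Q, rbind(Q, Q, Q, Q, Q), k = 5)
    expect_lt(max(abs(s3)), 1e-6)
    expect_true(all(s1 >= 0))
})

test_that("leave-self-out thresholding flags the expected tail", {
    set.seed(33)
    R <- matrix(rnorm(2000 * 3), 2000)
    self <- selfAberrancy(R, k = 10)
    expect_true(all(self > 0))                 # self excluded
    t95 <- aberrancyThreshold(self, 0.95)
    expect_lte(aberrancyThreshold(self, 0.5), t95)
    ## held-out draws from the same distribution: ~5% flagged
    H <- matrix(rnorm(2000 * 3), 2000)
    flag <- classifyAberrant(nnAberrancy(H, R, k = 10), t95)
    expect_lt(abs(mean(flag) - 0.05), 0.02)
    expect_error(aberrancyThreshold(self, 1.2), "\\(0, 1\\)")
})

test_that("shifted populations are flagged at high rates", {
    x <- makeNormalized(8000, seed = 34)
    feats <- panelFeatures(x, "core")
    m <- t(assay(x, "exprs"))[, feats]
    set.seed(35)
    ref_i <- sample(nrow(m), 4000)
    hold <- setdiff(seq_len(nrow(m)), ref_i)
    thr <- aberrancyThreshold(selfAberrancy(m[ref_i, ], k = 10), 0.95)
    base_rate <- mean(classifyAberrant(
        nnAberrancy(m[hold, ], m[ref_i, ], k = 10), thr))
    expect_lt(abs(base_rate - 0.05), 0.02)
    sds <- apply(m, 2, sd)
    shifted <- m[hold, ]
    for (mk in c("Ki67", "CyclinB1", "PCNA"))
        shifted[, mk] <- shifted[, mk] + 2 * sds[mk]
    shift_rate <- mean(classifyAberrant(
        nnAberrancy(shifted, m[ref_i, ], k = 10), thr))
    expect_gte(shift_rate, 0.90)
    ## untreated-vs-shifted median ordering
    expect_lt(median(nnAberrancy(m[hold, ], m[ref_i, ], k = 10)),
              median(nnAberrancy(shifted, m[ref_i, ], k = 10)))
})

test_that("Mahalanobis distances match explicit matrix algebra", {
    set.seed(36)
    m <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("A", "B")))
    m[, 2] <- m[, 1] * 0.6 + m[, 2]
    x <- makeSet(abs(m) + 5)
    metadata(x)$scale_state <- "normalized"
    assay(x, "exprs") <- t(m)
    g <- rep("g1", 200)
    d <- mahalanobisByGroup(x, g, features = c("A", "B"), lambda = 0)
    ## explicit 2x2 inverse oracle
    mu <- colMeans(m); S <- cov(m)
    inv <- solve(S)
    ctr <- sweep(m, 2, mu)
    oracle <- sqrt(rowSums((ctr %*% inv) * ctr))
    expect_lt(max(abs(d - oracle)), 1e-9)
    ## a cell at the centroid scores zero
    m2 <- rbind(m, mu)
    x2 <- makeSet(abs(m2) + 5)
    metadata(x2)$scale_state <- "normalized"
    assay(x2, "exprs") <- t(m2)
    d2 <- mahalanobisByGroup(x2, rep("g", 201), features = c("A", "B"))
    expect_lt(d2[201], 0.05)
    ## identity covariance reduces to euclidean distance
    set.seed(37)
    iid <- matrix(rnorm(4000), 2000, 2, dimnames = list(NULL, c("A", "B")))
    xs <- makeSet(abs(iid) + 5)
    metadata(xs)$scale_state <- "normalized"
    assay(xs, "exprs") <- t(iid)
    ds <- mahalanobisByGroup(xs, rep("g", 2000), features = c("A", "B"))
    eu <- sqrt(rowSums(sweep(iid, 2, colMeans(iid))^2))
    ## empirical covariance ~ identity, so ratios stay near 1
    expect_lt(max(abs(ds / eu - 1)), 0.1)
    ## singular covariance demands regularization
    sing <- cbind(A = rnorm(50), B = 0)
    xg <- makeSet(abs(sing) + 5)
    metadata(xg)$scale_state <- "normalized"
    assay(xg, "exprs") <- t(sing)
    expect_error(mahalanobisByGroup(xg, rep("g", 50),
                                    features = c("A", "B"), lambda = 0),
                 "lambda|singular|too small")
})

test_that("kNN condition scores behave like density ratios", {
    ## k = 1 arithmetic: neighbour shares the label, prevalence 1/2
    m <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
    colnames(m) <- c("A", "B")
    x <- makeSet(m + 20)
    metadata(x)$scale_state <- "normalized"
    assay(x, "exprs") <- t(m)
    sc <- knnConditionScore(x, condition = c("a", "a", "b", "b"), k = 1,
                            features = c("A", "B"))
    expect_equal(unname(sc[1, "a"]), 2)
    expect_equal(unname(sc[3, "b"]), 2)
    ## random labels concentrate near 1
    set.seed(38)
    n <- 2000
    mr <- matrix(abs(rnorm(n * 3)), n, dimnames = list(NULL, c("A", "B", "C")))
    xr <- makeSet(mr + 1)
    metadata(xr)$scale_state <- "normalized"
    assay(xr, "exprs") <- t(mr)
    lab <- sample(rep(c("u", "v"), each = n / 2))
    sr <- knnConditionScore(xr, lab, k = 20, features = c("A", "B", "C"))
    expect_lt(abs(mean(sr[, "u"]) - 1), 0.05)
    ## perfectly separated conditions score ~ 1/prevalence
    ms <- rbind(matrix(abs(rnorm(500 * 2)), 500),
                matrix(abs(rnorm(1500 * 2)) + 50, 1500))
    colnames(ms) <- c("A", "B")
    xs <- makeSet(ms + 1)
    metadata(xs)$scale_state <- "normalized"
    assay(xs, "exprs") <- t(ms)
    ls <- rep(c("t", "c"), c(500, 1500))
    ss <- knnConditionScore(xs, ls, k = 10, features = c("A", "B"))
    expect_equal(mean(ss[ls == "t", "t"]), 4, tolerance = 0.01)
    expect_error(knnConditionScore(xs, rep("one", 2000)), ">= 2 conditions")
})
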