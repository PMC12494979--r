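test_that("realized phase fractions track the configured occupancy", {
    occ <- defaultPhaseOccupancy()
    x <- simulatePopulation(generatorConfig(n_cells = 20000, seed = 1))
    frac <- prop.table(table(cellData(x)$truth_phase))
    sds <- sqrt(occ * (1 - occ) / 20000)
    expect_true(all(abs(frac - occ) <= 3 * sds))
    ## convergence check at larger n
    y <- simulatePopulation(generatorConfig(n_cells = 1e5, seed = 2))
    fy <- prop.table(table(cellData(y)$truth_phase))
    expect_true(all(abs(fy - occ) <= 3 * sqrt(occ * (1 - occ) / 1e5)))
})

test_that("zero-noise cells sit exactly on their phase templates", {
    x <- simulatePopulation(generatorConfig(n_cells = 500, seed = 3,
                                            noise_cv = 0))
    tpl <- defaultMarkerTemplates()
    cnt <- t(SummarizedExperiment::assay(x, "counts"))
    phase <- as.character(cellData(x)$truth_phase)
    for (j in seq_len(nrow(tpl))) {
        mk <- tpl$marker[j]
        expected <- unlist(tpl[j, c("G0G1", "S", "G2", "M")])[
            match(phase, c("G0G1", "S", "G2", "M"))]
        if (mk == "DNA") {
            in_s <- phase == "S"
            expect_equal(cnt[!in_s, mk], unname(expected[!in_s]))
            ## S-phase DNA interpolates 2N -> 4N along the S position
            dna2n <- tpl$G0G1[tpl$marker == "DNA"]
            expect_equal(cnt[in_s, mk],
                         dna2n * (1 + cellData(x)$s_position[in_s]))
        } else {
            expect_equal(cnt[, mk], unname(expected))
        }
    }
})

test_that("generation is seed-deterministic and seed-sensitive", {
    cfg <- generatorConfig(n_cells = 3000, seed = 7)
    a <- simulatePopulation(cfg)
    b <- simulatePopulation(cfg)
    expect_identical(SummarizedExperiment::assay(a, "counts"),
                     SummarizedExperiment::assay(b, "counts"))
    cfg2 <- cfg; cfg2$seed <- 8L
    c2 <- simulatePopulation(cfg2)
    expect_false(identical(SummarizedExperiment::assay(a, "counts"),
                           SummarizedExperiment::assay(c2, "counts")))
    ## same occupancy within sampling error despite different draws
    fa <- prop.table(table(cellData(a)$truth_phase))
    fc <- prop.table(table(cellData(c2)$truth_phase))
    expect_true(all(abs(fa - fc) < 6 * sqrt(0.51 * 0.49 / 3000)))
})

test_that("configuration invariants are enforced", {
    expect_error(generatorConfig(phase_occupancy = c(0.5, 0.5, 0.1, 0.1)),
                 "summing to 1")
    expect_error(generatorConfig(
        cell_line_offsets = list(A = c(NotAMarker = 2))), "unknown marker")
    expect_error(generatorConfig(
        cell_line_offsets = list(A = c(Ki67 = -1))), "positive")
    expect_error(
        generatorConfig(noncanonical = list(list(rule = "x", phase = "S",
                                                 fraction = 1.5))),
        "\\[0, 1\\]")
})

test_that("noncanonical injection flags exactly the forced cells", {
    x <- simulatePopulation(generatorConfig(n_cells = 20000, seed = 11))
    ## fraction 0 is a no-op
    x0 <- injectNoncanonical(x, "Ki67_high_in_S", "S", 0)
    expect_identical(SummarizedExperiment::assay(x0, "counts"),
                     SummarizedExperiment::assay(x, "counts"))
    expect_true(all(cellData(x0)$truth_canonical))
    ## binomial count at fraction 0.2
    xi <- injectNoncanonical(x, "Ki67_high_in_S", "S", 0.2, seed = 5)
    nS <- sum(cellData(x)$truth_phase == "S")
    flagged <- sum(!cellData(xi)$truth_canonical)
    expect_lt(abs(flagged - 0.2 * nS), 3 * sqrt(0.2 * 0.8 * nS))
    ## flagged cells are S-phase only and have lowered Ki67
    cd <- cellData(xi)
    expect_true(all(cd$truth_phase[!cd$truth_canonical] == "S"))
    ## fraction 1.0: every G2 cell forced above the CDT1 positivity level
    xg <- injectNoncanonical(x, "CDT1_neg_after_S", "G2", 1, seed = 6)
    g2 <- cellData(xg)$truth_phase == "G2"
    expect_true(all(!cellData(xg)$truth_canonical[g2]))
    cdt1 <- SummarizedExperiment::assay(xg, "counts")["CDT1", g2]
    cdt1_before <- SummarizedExperiment::assay(x, "counts")["CDT1", g2]
    expect_gt(median(cdt1), median(cdt1_before))
    ## errors
    expect_error(injectNoncanonical(x, "Ki67_high_in_S", "S", 2), "\\[0, 1\\]")
    expect_error(injectNoncanonical(x, "Ki67_high_in_S", "S2", 0.1),
                 "unknown phase")
    expect_error(injectNoncanonical(x, "NoSuchRule", "S", 0.1),
                 "unknown rule")
})

test_that("perturbations shift occupancy and realise slippage", {
    base <- generatorConfig(n_cells = 20000, seed = 21)
    ## identity spec: same occupancy, no effects -> bit-identical draw
    ident <- applyPerturbation(base, perturbationSpec(
        occupancy_shift = defaultPhaseOccupancy(), label = "control"))
    a <- simulatePopulation(base); b <- simulatePopulation(ident)
    expect_identical(SummarizedExperiment::assay(a, "counts"),
                     SummarizedExperiment::assay(b, "counts"))
    ## G0G1 pile-up
    pile <- applyPerturbation(base, perturbationSpec(
        occupancy_shift = c(G0G1 = 0.90, S = 0.05, G2 = 0.04, M = 0.01),
        slippage_fraction = 0.1))
    y <- simulatePopulation(pile)
    fG0 <- mean(cellData(y)$truth_phase == "G0G1")
    expect_lt(abs(fG0 - 0.90), 3 * sqrt(0.9 * 0.1 / 20000))
    ## slipped cells stay G0G1-labelled, noncanonical, with >4N DNA;
    ## expected 4N-gate exceedance from the lognormal noise model
    cd <- cellData(y)
    g0 <- cd$truth_phase == "G0G1"
    expect_true(all(cd$truth_phase[!cd$truth_canonical] == "G0G1"))
    dna <- SummarizedExperiment::assay(y, "counts")["DNA", g0]
    sdlog <- sqrt(log(1 + 0.35^2))
    p_exceed <- 0.9 * plnorm(20, log(10), sdlog, lower.tail = FALSE) +
        0.1 * plnorm(20, log(30), sdlog, lower.tail = FALSE)
    obs <- mean(dna > 20)
    expect_lt(abs(obs - p_exceed),
              4 * sqrt(p_exceed * (1 - p_exceed) / sum(g0)))
    expect_error(perturbationSpec(defaultPhaseOccupancy(),
                                  marker_effects = list(list(marker = "Ki67",
                                                             phases = "S",
                                                             factor = -2))),
                 "positive")
})

test_that("export/import round-trips delimited and FCS data", {
    x <- simulatePopulation(generatorConfig(n_cells = 200, seed = 31))
    tmp <- withr::local_tempdir()
    ## delimited: exact
    exportDataset(x, file.path(tmp, "d"), "delimited")
    y <- importDataset(file.path(tmp, "d"), "delimited")
    expect_equal(SummarizedExperiment::assay(y, "counts"),
                 SummarizedExperiment::assay(x, "counts"),
                 ignore_attr = TRUE)
    expect_equal(as.character(cellData(y)$truth_phase),
                 as.character(cellData(x)$truth_phase))
    ## FCS: single-precision tolerance
    exportDataset(x, file.path(tmp, "f"), "fcs")
    z <- importDataset(file.path(tmp, "f"), "fcs")
    expect_equal(SummarizedExperiment::assay(z, "counts"),
                 SummarizedExperiment::assay(x, "counts"),
                 tolerance = 1e-6, ignore_attr = TRUE)
    ## empty dataset refuses to write
    empty <- x[, 0]
    expect_error(exportDataset(empty, file.path(tmp, "e")), "empty")
    expect_false(file.exists(file.path(tmp, "e.tsv")))
})

test_that("FCS writer emits parseable 3.1 files with keywords", {
    m <- matrix(abs(rnorm(50 * 3, 10)), 50,
                dimnames = list(NULL, c("A", "B", "C")))
    f <- withr::local_tempfile(fileext = ".fcs")
    writeFCS(m, f, extra_keywords = c(SEED = "17"))
    out <- readFCS(f)
    expect_equal(out$exprs, m, tolerance = 1e-6, ignore_attr = TRUE)
    expect_identical(colnames(out$exprs), colnames(m))
    expect_identical(unname(out$keywords[["SEED"]]), "17")
    expect_identical(unname(out$keywords[["$DATATYPE"]]), "F")
})
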