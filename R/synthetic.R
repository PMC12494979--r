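#' @importFrom stats rnorm runif
NULL

.PHASES <- c("G0G1", "S", "G2", "M")

#' Default phase templates for the simulated cell-cycle panel
#'
#' One row per marker with its median raw-intensity level in each of the four
#' phases, the phase (if any) in which the marker is binary-positive, and its
#' panel category. Levels encode the literature dynamics the panel is built
#' around: IdU incorporation only during S; pH3(S10) only in M; Cyclin B1
#' ramping to a G2/M peak; CDT1 licensing restricted to G0G1 with Geminin
#' rising reciprocally S through M; SLBP high in S then degraded at the S/G2
#' transition; Ki67, PCNA and PLK1 increasing with progression; pRb(S780)
#' elevated in cycling phases; DNA content doubling 2N to 4N across S
#' (interpolated via a per-cell S position, so its S entry is `NA` here);
#' chromatin/size channels (WGA, HH3, EZH2, CTCF, MLL1) growing mildly; and
#' a low cPARP background used by the cleanup stage.
#'
#' @return `data.frame` with columns `marker`, `G0G1`, `S`, `G2`, `M`,
#'   `positive_phase`, `category`.
#' @export
defaultMarkerTemplates <- function() {
    tpl <- read.table(header = TRUE, text = "
marker   G0G1   S    G2   M   positive_phase category
Ki67      4    10    16   20  NA             minimal
pRbS780   8    12    10   10  NA             minimal
pH3_s10   1     1     1   80  M              minimal
CDT1     15     2   1.5  1.5  NA             minimal
IdU       1    80     1    1  S              core
Geminin   1.5   8    15   20  NA             minimal
PLK1      2     8    15   25  NA             minimal
DNA      10    NA    20   20  NA             core
CyclinB1  2     8    25   40  NA             minimal
PCNA      5    12    15   15  NA             core
SLBP      3    15     2    2  NA             core
CyclinE  10    12     3    2  NA             minimal
WGA      10    13    16   16  NA             complete
HH3      10    15    20   20  NA             complete
EZH2      6     8    10   10  NA             complete
CTCF      6     7     8    8  NA             complete
MLL1      5     6     8    8  NA             complete
cPARP     0.5   0.5   0.5 0.5 NA             cleanup
", stringsAsFactors = FALSE)
    tpl$positive_phase[tpl$positive_phase == "NA"] <- NA_character_
    tpl
}

#' Default panel annotation for known markers
#'
#' @param markers character vector of channel names
#' @return `data.frame` with columns `marker`, `category`; markers absent
#'   from the default template table are categorised `"other"`.
#' @export
defaultPanel <- function(markers) {
    tpl <- defaultMarkerTemplates()
    data.frame(marker = markers,
               category = tpl$category[match(markers, tpl$marker)],
               stringsAsFactors = FALSE)
}

#' The 17-marker feature pool used by the diversity statistic
#'
#' @return character vector of marker names.
#' @export
defaultDiversityFeatures <- function() {
    c("Ki67", "pRbS780", "pH3_s10", "CDT1", "IdU", "Geminin", "PLK1", "DNA",
      "CyclinB1", "PCNA", "SLBP", "CyclinE", "WGA", "HH3", "EZH2", "CTCF",
      "MLL1")
}

#' Default phase occupancy: the activated-T-cell profile
#'
#' The reported fractions (42\% G0G1, 51\% S, 5.1\% G2, 1.8\% M) sum to
#' 0.999 as printed; they are renormalized proportionally so the occupancy
#' is a proper probability vector.
#'
#' @return named probability 4-vector over G0G1/S/G2/M
#' @export
defaultPhaseOccupancy <- function() {
    occ <- c(G0G1 = 0.42, S = 0.51, G2 = 0.051, M = 0.018)
    occ / sum(occ)
}

#' Generator configuration for synthetic cytometry data
#'
#' Bundles and validates everything [simulatePopulation()] needs. The default
#' phase occupancy is the activated-T-cell profile (42\% G0G1, 51\% S, 5.1\%
#' G2, 1.8\% M, renormalized to sum to one); the default multiplicative
#' lognormal noise has a 0.35 coefficient of variation.
#'
#' @param n_cells number of cells to draw
#' @param phase_occupancy probability 4-vector over G0G1/S/G2/M (sums to 1)
#' @param templates marker template table ([defaultMarkerTemplates()] format)
#' @param noise_cv lognormal coefficient of variation (>= 0; 0 = noiseless)
#' @param cell_line_offsets named list, one entry per cell line; each entry
#'   is `NULL` (all factors 1) or a named positive vector of per-marker
#'   multiplicative scale factors. Cells are assigned to lines uniformly.
#' @param line_occupancy optional named list of per-line occupancy 4-vectors
#'   overriding `phase_occupancy` for specific lines
#' @param perturbation optional [perturbationSpec()]
#' @param noncanonical optional list of injections, each
#'   `list(rule, phase, fraction)` passed to [injectNoncanonical()]
#' @param seed integer seed; simulation is bit-reproducible given the config
#' @return validated list of class `"GeneratorConfig"`
#' @export
generatorConfig <- function(n_cells = 10000,
                            phase_occupancy = defaultPhaseOccupancy(),
                            templates = defaultMarkerTemplates(),
                            noise_cv = 0.35,
                            cell_line_offsets = list(LINE1 = NULL),
                            line_occupancy = NULL,
                            perturbation = NULL,
                            noncanonical = NULL,
                            seed = 1L) {
    stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 1)
    .checkOccupancy(phase_occupancy)
    if (!is.numeric(noise_cv) || noise_cv < 0)
        stop("'noise_cv' must be nonnegative")
    if (!is.list(cell_line_offsets) || is.null(names(cell_line_offsets)) ||
        any(!nzchar(names(cell_line_offsets))))
        stop("'cell_line_offsets' must be a named list (one entry per line)")
    for (ln in names(cell_line_offsets)) {
        off <- cell_line_offsets[[ln]]
        if (is.null(off)) next
        .checkPositive(off, sprintf("offsets for line %s", ln))
        unknown <- setdiff(names(off), templates$marker)
        if (length(unknown))
            stop("unknown marker(s) in cell_line_offsets: ",
                 paste(unknown, collapse = ", "))
    }
    if (!is.null(line_occupancy)) {
        unknown <- setdiff(names(line_occupancy), names(cell_line_offsets))
        if (length(unknown))
            stop("line_occupancy for unknown line(s): ",
                 paste(unknown, collapse = ", "))
        lapply(line_occupancy, .checkOccupancy)
    }
    if (!is.null(perturbation) && !inherits(perturbation, "PerturbationSpec"))
        stop("'perturbation' must come from perturbationSpec()")
    if (!is.null(noncanonical)) {
        stopifnot(is.list(noncanonical))
        for (inj in noncanonical)
            .checkFraction(inj$fraction, "injection fraction")
    }
    structure(list(n_cells = as.integer(n_cells),
                   phase_occupancy = phase_occupancy,
                   templates = templates, noise_cv = noise_cv,
                   cell_line_offsets = cell_line_offsets,
                   line_occupancy = line_occupancy,
                   perturbation = perturbation,
                   noncanonical = noncanonical,
                   seed = as.integer(seed)),
              class = "GeneratorConfig")
}

.checkOccupancy <- function(occ) {
    if (!is.numeric(occ) || length(occ) != 4L || any(occ < 0) ||
        abs(sum(occ) - 1) > 1e-9)
        stop("phase occupancy must be a nonnegative 4-vector summing to 1")
    if (!is.null(names(occ)) && !identical(names(occ), .PHASES))
        stop("occupancy names must be G0G1, S, G2, M in order")
    invisible(occ)
}

#' Drug-arrest perturbation specification
#'
#' Describes a treatment as an occupancy shift (cell-cycle arrest), a set of
#' phase-restricted multiplicative marker effects, and an optional mitotic
#' slippage fraction: slipped cells keep the G0G1 truth label but receive
#' re-replicated DNA content beyond 4N and are marked noncanonical.
#'
#' @param occupancy_shift probability 4-vector replacing the baseline
#' @param marker_effects list of `list(marker, phases, factor)` entries;
#'   `factor` multiplies the marker's template level within `phases`
#' @param slippage_fraction fraction of G0G1 cells given >4N DNA
#' @param label treatment label recorded in the cell metadata
#' @param slippage_dna_factor multiplier applied to the 2N DNA level of
#'   slipped cells (default 3, i.e. ~6N re-replicated content)
#' @return list of class `"PerturbationSpec"`
#' @export
perturbationSpec <- function(occupancy_shift,
                             marker_effects = list(),
                             slippage_fraction = 0,
                             label = "treated",
                             slippage_dna_factor = 3) {
    .checkOccupancy(occupancy_shift)
    .checkFraction(slippage_fraction, "slippage_fraction")
    for (eff in marker_effects) {
        stopifnot(is.character(eff$marker), all(eff$phases %in% .PHASES))
        .checkPositive(eff$factor, "marker effect factor")
    }
    .checkPositive(slippage_dna_factor, "slippage_dna_factor")
    structure(list(occupancy_shift = occupancy_shift,
                   marker_effects = marker_effects,
                   slippage_fraction = slippage_fraction,
                   label = label,
                   slippage_dna_factor = slippage_dna_factor),
              class = "PerturbationSpec")
}

#' Attach a perturbation to a generator configuration
#'
#' Returns a copy of `config` that [simulatePopulation()] will realise under
#' the perturbed occupancy and marker effects. Operating on the configuration
#' (rather than an already-drawn dataset) keeps an identity perturbation
#' bit-identical to the unperturbed simulation at the same seed.
#'
#' @param config a [generatorConfig()]
#' @param spec a [perturbationSpec()]
#' @return the modified `GeneratorConfig`
#' @export
applyPerturbation <- function(config, spec) {
    stopifnot(inherits(config, "GeneratorConfig"),
              inherits(spec, "PerturbationSpec"))
    config$perturbation <- spec
    config
}

#' Simulate a ground-truth-labelled cytometry population
#'
#' Draws phases multinomially from the configured occupancy, assigns every
#' cell its per-marker template level (scaled by its cell line's offsets and
#' any perturbation effects), interpolates DNA content 2N to 4N across a
#' uniform S-phase position, applies multiplicative lognormal noise with the
#' configured coefficient of variation (the template level is the noise
#' median, so `noise_cv = 0` reproduces the templates exactly), realises
#' mitotic slippage, and finally applies any configured noncanonical
#' injections. Fully deterministic for a fixed config.
#'
#' @param config a [generatorConfig()]
#' @return a [CycloSet-class] (raw scale) whose `colData` carries
#'   `truth_phase`, `truth_canonical`, `line`, `treatment`, `sample` and
#'   `s_position`
#' @export
simulatePopulation <- function(config) {
    stopifnot(inherits(config, "GeneratorConfig"))
    tpl <- config$templates
    markers <- tpl$marker
    n <- config$n_cells
    pert <- config$perturbation
    ds <- .withSeed(config$seed, {
        lines <- sample(names(config$cell_line_offsets), n, replace = TRUE)
        occ_base <- if (is.null(pert)) config$phase_occupancy else
            pert$occupancy_shift
        phase <- character(n)
        for (ln in unique(lines)) {
            occ <- occ_base
            if (is.null(pert) && !is.null(config$line_occupancy[[ln]]))
                occ <- config$line_occupancy[[ln]]
            idx <- which(lines == ln)
            phase[idx] <- sample(.PHASES, length(idx), replace = TRUE,
                                 prob = occ)
        }
        u <- runif(n)                       # S pseudo-position
        loc <- matrix(NA_real_, n, length(markers),
                      dimnames = list(NULL, markers))
        for (j in seq_along(markers))
            loc[, j] <- unlist(tpl[j, .PHASES])[match(phase, .PHASES)]
        in_s <- phase == "S"
        loc[in_s, "DNA"] <- tpl$G0G1[tpl$marker == "DNA"] * (1 + u[in_s])
        if (!is.null(pert))
            for (eff in pert$marker_effects) {
                if (!eff$marker %in% markers)
                    stop("unknown marker in perturbation: ", eff$marker)
                sel <- phase %in% eff$phases
                loc[sel, eff$marker] <- loc[sel, eff$marker] * eff$factor
            }
        for (ln in names(config$cell_line_offsets)) {
            off <- config$cell_line_offsets[[ln]]
            if (is.null(off)) next
            sel <- lines == ln
            for (mk in names(off))
                loc[sel, mk] <- loc[sel, mk] * off[[mk]]
        }
        canonical <- rep(TRUE, n)
        if (!is.null(pert) && pert$slippage_fraction > 0) {
            g0 <- which(phase == "G0G1")
            slip <- g0[runif(length(g0)) < pert$slippage_fraction]
            loc[slip, "DNA"] <- loc[slip, "DNA"] * pert$slippage_dna_factor
            canonical[slip] <- FALSE
        }
        if (config$noise_cv > 0) {
            sdlog <- .sdlogFromCV(config$noise_cv)
            vals <- loc * exp(sdlog * matrix(rnorm(n * ncol(loc)), n))
        } else vals <- loc
        meta <- DataFrame(
            truth_phase = factor(phase, levels = .PHASES),
            truth_canonical = canonical,
            line = lines,
            treatment = if (is.null(pert)) "control" else pert$label,
            sample = paste(lines,
                           if (is.null(pert)) "control" else pert$label,
                           sep = "_"),
            s_position = ifelse(in_s, u, NA_real_))
        obj <- CycloSet(vals, cell_meta = meta, cells_in_rows = TRUE)
        metadata(obj)$generator <- list(seed = config$seed,
                                        noise_cv = config$noise_cv,
                                        occupancy = occ_base)
        obj
    })
    if (!is.null(config$noncanonical))
        for (i in seq_along(config$noncanonical)) {
            inj <- config$noncanonical[[i]]
            ds <- injectNoncanonical(ds, inj$rule, inj$phase, inj$fraction,
                                     seed = config$seed + 7817L + i)
        }
    ds
}

## Resolve an injection reference to (marker, violating level).
## `rule` is a rule_id from the shipped canonical-rule table, or
## list(marker =, direction = "low"|"high"). Violating levels must stay
## decisively beyond the rule threshold even when the injected cells
## themselves shift the all-cell quantile the threshold is drawn from:
## "low" violations are negative-level expression (0.1x the marker's lowest
## phase level, i.e. near antibody background), "high" violations sit at the
## marker's highest phase level.
.violationSpec <- function(rule, templates) {
    if (is.character(rule)) {
        rules <- defaultRules()
        row <- rules[rules$rule_id == rule, , drop = FALSE]
        if (nrow(row) != 1L)
            stop("unknown rule reference: ", rule)
        marker <- row$marker
        direction <- if (row$expectation %in% c("high", "positive"))
            "low" else "high"
    } else {
        marker <- rule$marker
        direction <- match.arg(rule$direction, c("low", "high"))
    }
    if (!marker %in% templates$marker)
        stop("rule marker not in templates: ", marker)
    lv <- unlist(templates[templates$marker == marker, .PHASES])
    lv <- lv[is.finite(lv)]
    level <- if (direction == "low") 0.1 * min(lv) else max(lv)
    list(marker = marker, direction = direction, level = level)
}

#' Inject labelled noncanonical cells
#'
#' Forces the marker of a canonical rule into its violating state for a
#' random fraction of the cells of one phase (each eligible cell is selected
#' independently with probability `fraction`), and flips `truth_canonical`
#' to `FALSE` for exactly the selected cells. The forced value is drawn
#' lognormally around a level far beyond the rule threshold (0.1x the
#' marker's lowest phase level for "low" violations; its highest phase level
#' for "high"), so injected violations are detectable by construction.
#'
#' @param ds a raw-scale [CycloSet-class] from [simulatePopulation()]
#' @param rule a `rule_id` from [defaultRules()] (e.g. `"Ki67_high_in_S"`),
#'   or `list(marker =, direction = "low"|"high")`
#' @param phase target phase, one of G0G1/S/G2/M
#' @param fraction injection probability in `[0, 1]`
#' @param seed integer seed for the cell selection and forced draws
#' @return the modified `CycloSet`
#' @export
injectNoncanonical <- function(ds, rule, phase, fraction, seed = 1L) {
    stopifnot(is(ds, "CycloSet"))
    .requireState(ds, "raw", "injectNoncanonical")
    .checkFraction(fraction)
    if (!phase %in% .PHASES) stop("unknown phase: ", phase)
    if (!any(colData(ds)$truth_phase == phase))
        stop("no cells in phase ", phase)
    if (fraction == 0) return(ds)
    tpl <- defaultMarkerTemplates()
    tpl <- tpl[tpl$marker %in% rownames(ds), , drop = FALSE]
    vs <- .violationSpec(rule, tpl)
    noise_cv <- metadata(ds)$generator$noise_cv
    if (is.null(noise_cv)) noise_cv <- 0
    .withSeed(seed, {
        idx <- which(colData(ds)$truth_phase == phase)
        hit <- idx[runif(length(idx)) < fraction]
        if (length(hit)) {
            cnt <- assay(ds, "counts")
            draw <- if (noise_cv > 0)
                vs$level * exp(.sdlogFromCV(noise_cv) * rnorm(length(hit)))
            else rep(vs$level, length(hit))
            cnt[vs$marker, hit] <- draw
            assay(ds, "counts") <- cnt
            colData(ds)$truth_canonical[hit] <- FALSE
        }
        ds
    })
}

#' Simulate a multi-cell-line panel benchmark
#'
#' A fixed four-line study design for panel-classification experiments:
#' lines differ (i) in chromatin-state and cell-size channels — features
#' exclusive to the complete panel — through multiplicative offsets, and
#' (ii) in cell-cycle phase occupancy, as real cell lines do. Information
#' about line identity is therefore layered: the minimal panel sees
#' occupancy only through graded phase markers, the core panel adds the
#' direct DNA-content and IdU readouts, and the complete panel adds the
#' strongly offset chromatin/size channels, giving the strict accuracy
#' ordering complete > core > minimal that panel comparisons probe. The
#' noise level is set at 0.5 CV so graded markers are noticeably noisy
#' while the binary IdU gate stays clean.
#'
#' @param n_cells total cells (default 24000, ~6000 per line)
#' @param seed simulation seed
#' @param noise_cv lognormal noise CV (default 0.5)
#' @return a raw-scale [CycloSet-class] with `line` labels
#' @export
simulateCellLinePanel <- function(n_cells = 24000, seed = 1L,
                                  noise_cv = 0.5) {
    offs <- list(
        NALM6 = c(WGA = 1.0, HH3 = 1.0, EZH2 = 1.0, CTCF = 1.0, MLL1 = 1.0),
        U937  = c(WGA = 1.7, HH3 = 0.6, EZH2 = 1.4, CTCF = 0.7, MLL1 = 1.0),
        HEL   = c(WGA = 0.6, HH3 = 1.6, EZH2 = 0.7, CTCF = 1.5, MLL1 = 1.6),
        T293  = c(WGA = 1.4, HH3 = 1.3, EZH2 = 0.6, CTCF = 1.2, MLL1 = 0.55))
    occ <- list(
        NALM6 = c(G0G1 = 0.25, S = 0.65, G2 = 0.08, M = 0.02),
        U937  = c(G0G1 = 0.45, S = 0.45, G2 = 0.08, M = 0.02),
        HEL   = c(G0G1 = 0.62, S = 0.28, G2 = 0.08, M = 0.02),
        T293  = c(G0G1 = 0.78, S = 0.12, G2 = 0.08, M = 0.02))
    cfg <- generatorConfig(n_cells = n_cells, seed = seed,
                           noise_cv = noise_cv, cell_line_offsets = offs,
                           line_occupancy = occ)
    simulatePopulation(cfg)
}

#' Export a dataset to disk
#'
#' Writes the raw expression matrix either as a tab-delimited cell table
#' (`<prefix>.tsv`, cells in rows, header row) or as an FCS 3.1 file
#' (`<prefix>.fcs`, single-precision floats), plus a sidecar tab-delimited
#' truth/metadata table `<prefix>_cells.tsv` keyed by cell index.
#'
#' @param ds a [CycloSet-class]
#' @param prefix output path prefix (directories must exist)
#' @param format `"delimited"` or `"fcs"`
#' @return invisibly, the paths written
#' @export
exportDataset <- function(ds, prefix, format = c("delimited", "fcs")) {
    format <- match.arg(format)
    stopifnot(is(ds, "CycloSet"))
    if (ncol(ds) == 0L) stop("refusing to export an empty dataset")
    mat <- t(assay(ds, "counts"))
    main <- paste0(prefix, if (format == "fcs") ".fcs" else ".tsv")
    if (format == "delimited") {
        utils::write.table(mat, main, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        writeFCS(mat, main)
    }
    side <- paste0(prefix, "_cells.tsv")
    meta <- as.data.frame(colData(ds))
    meta <- cbind(cell_index = seq_len(nrow(meta)), meta)
    utils::write.table(meta, side, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(main, side))
}

#' Import a dataset written by [exportDataset()]
#'
#' @param prefix path prefix used at export time
#' @param format `"delimited"` or `"fcs"`
#' @return a raw-scale [CycloSet-class]; the sidecar metadata table is
#'   restored into `colData` when present
#' @export
importDataset <- function(prefix, format = c("delimited", "fcs")) {
    format <- match.arg(format)
    main <- paste0(prefix, if (format == "fcs") ".fcs" else ".tsv")
    if (!file.exists(main)) stop("file not found: ", main)
    mat <- if (format == "delimited") {
        as.matrix(utils::read.table(main, header = TRUE, sep = "\t",
                                    check.names = FALSE))
    } else readFCS(main)$exprs
    side <- paste0(prefix, "_cells.tsv")
    meta <- NULL
    if (file.exists(side)) {
        meta <- utils::read.table(side, header = TRUE, sep = "\t",
                                  check.names = FALSE)
        meta$cell_index <- NULL
        if ("truth_phase" %in% colnames(meta))
            meta$truth_phase <- factor(meta$truth_phase, levels = .PHASES)
    }
    CycloSet(mat, cell_meta = meta, cells_in_rows = TRUE)
}
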