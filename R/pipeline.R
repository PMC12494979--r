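#' Default pipeline configuration
#'
#' Returns the nested-list configuration [runPipeline()] consumes. A stage
#' runs iff its entry is non-`NULL`; stages are `simulate` (or `input` for
#' files on disk), `preprocess`, `gate`, `rules`, `diversity`, `aberrancy`
#' and `stats`. The single global `seed` is fanned out to per-stage seeds by
#' fixed offsets so any stage can be re-run in isolation reproducibly.
#' Configurations may equally be given as a YAML file with the same keys.
#'
#' @param n_cells cells to simulate
#' @param seed global seed
#' @param output_dir where stage tables are written (`NULL`: nowhere)
#' @return configuration list
#' @export
pipelineConfig <- function(n_cells = 50000, seed = 1L, output_dir = NULL) {
    list(seed = as.integer(seed),
         output_dir = output_dir,
         simulate = list(n_cells = n_cells, noise_cv = 0.35),
         preprocess = list(cofactor = 5, percentile = 99.9, clip = FALSE,
                           cleanup = TRUE),
         gate = list(method = "valley"),
         rules = list(path = NULL),
         diversity = list(tau = 0.5, n_cells_subsample = 2000,
                          max_subsets_per_size = 50),
         aberrancy = list(k = 10, alpha = 0.95,
                          reference_treatment = "control",
                          max_reference = 5000),
         stats = list(contrast = "treatment", strata = "phase",
                      group = "line"))
}

.writeStageTable <- function(df, dir, name) {
    if (is.null(dir)) return(invisible(NULL))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, preprocessing (asinh, percentile
#' normalization, cleanup), phase gating, canonical-rule discretization,
#' the diversity curve, aberrancy scoring against the untreated reference,
#' and the differential/variance statistics, in order, skipping any stage
#' whose config entry is `NULL`. Identical configuration and seed give
#' byte-identical output tables. A stage failure aborts with the stage
#' name; tables written by earlier stages are preserved.
#'
#' @param config configuration list from [pipelineConfig()] (possibly
#'   modified), or the path of a YAML file with the same structure
#' @param data optional pre-built raw [CycloSet-class] used instead of the
#'   `simulate`/`input` stage
#' @return list of class `"RunReport"`: `counts` (per-stage in/out cell
#'   counts), `outputs` (result objects), `config`, `warnings`,
#'   `elapsed_s`
#' @export
runPipeline <- function(config, data = NULL) {
    t0 <- proc.time()[["elapsed"]]
    if (is.character(config)) config <- yaml::read_yaml(config)
    stages <- c("simulate", "input", "preprocess", "gate", "rules",
                "diversity", "aberrancy", "stats")
    active <- intersect(stages, names(config))
    active <- active[!vapply(config[active], is.null, NA)]
    if (length(active) == 0L && is.null(data))
        stop("pipeline configuration enables no stage")
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    dir <- config$output_dir
    warns <- character()
    counts <- data.frame(stage = character(), n_in = integer(),
                         n_out = integer())
    note <- function(stage, n_in, n_out)
        counts <<- rbind(counts, data.frame(stage = stage, n_in = n_in,
                                            n_out = n_out))
    run <- function(stage, code) {
        withCallingHandlers(
            tryCatch(code, error = function(e)
                stop(sprintf("pipeline stage '%s' failed: %s", stage,
                             conditionMessage(e)), call. = FALSE)),
            warning = function(w) {
                warns <<- c(warns, paste0(stage, ": ",
                                          conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
    }
    outputs <- list()

    ## --- ingest / simulate
    if (!is.null(data)) {
        x <- data
        note("input", ncol(x), ncol(x))
    } else if ("simulate" %in% active) {
        x <- run("simulate", {
            sc <- config$simulate
            sc$seed <- if (is.null(sc$seed)) seed else sc$seed
            cfg <- do.call(generatorConfig, sc)
            simulatePopulation(cfg)
        })
        note("simulate", 0L, ncol(x))
    } else if ("input" %in% active) {
        x <- run("input", importDataset(config$input$prefix,
                                        config$input$format))
        note("input", ncol(x), ncol(x))
    } else stop("no input: supply 'data', or a simulate/input stage")

    ## --- preprocess
    if ("preprocess" %in% active) {
        x <- run("preprocess", {
            pp <- config$preprocess
            n_in <- ncol(x)
            x <- asinhTransform(x, cofactor = pp$cofactor %||% 5)
            if (isTRUE(pp$cleanup))
                x <- cleanupFilter(x)
            else if (is.list(pp$cleanup))
                x <- cleanupFilter(x, pp$cleanup)
            x <- percentileNormalize(x, q = pp$percentile %||% 99.9,
                                     clip = isTRUE(pp$clip))
            rep <- metadata(x)$cleanup_report
            if (!is.null(rep))
                .writeStageTable(rep$per_rule, dir, "cleanup_report")
            note("preprocess", n_in, ncol(x))
            x
        })
    }

    ## --- gate
    if ("gate" %in% active) {
        x <- run("gate", {
            gc <- config$gate
            th <- deriveThresholds(x, method = gc$method %||% "valley")
            x <- assignPhases(x, th)
            note("gate", ncol(x), ncol(x))
            x
        })
    }

    ## --- rules
    if ("rules" %in% active) {
        x <- run("rules", {
            rl <- if (is.null(config$rules$path)) defaultRules()
                  else loadRules(config$rules$path)
            x <- evaluateRules(x, rl)
            by <- intersect(c("line", "phase"), colnames(colData(x)))
            frac <- noncanonicalFraction(x, by = by)
            outputs$noncanonical_fractions <- frac
            .writeStageTable(frac, dir, "noncanonical_fractions")
            note("rules", ncol(x), ncol(x))
            x
        })
    }

    ## --- diversity
    if ("diversity" %in% active) {
        run("diversity", {
            dc <- config$diversity
            pars <- diversityParams(
                tau = dc$tau %||% 0.5,
                n_cells_subsample = dc$n_cells_subsample %||% 2000,
                max_subsets_per_size = dc$max_subsets_per_size %||% 500,
                seed = seed + 101L)
            by <- if ("line" %in% colnames(colData(x)) &&
                      length(unique(colData(x)$line)) > 1L) "line" else NULL
            curve <- diversityCurve(x, params = pars, by = by)
            outputs$diversity <- curve
            .writeStageTable(curve$records, dir, "diversity_records")
            .writeStageTable(curve$means, dir, "diversity_means")
            note("diversity", ncol(x), ncol(x))
        })
    }

    ## --- aberrancy
    if ("aberrancy" %in% active) {
        x <- run("aberrancy", {
            ac <- config$aberrancy
            k <- ac$k %||% 10
            ref_lab <- ac$reference_treatment %||% "control"
            is_ref <- colData(x)$treatment == ref_lab
            if (!any(is_ref)) stop("no reference cells with treatment ",
                                   ref_lab)
            ref_idx <- which(is_ref)
            max_ref <- ac$max_reference %||% 5000
            ref_idx <- .withSeed(seed + 202L,
                if (length(ref_idx) > max_ref) sample(ref_idx, max_ref)
                else ref_idx)
            feats <- panelFeatures(x, "core")
            ref <- .cellMatrix(x, feats)[ref_idx, , drop = FALSE]
            self <- .knnMeanDist(ref, ref, k, "euclidean",
                                 exclude = seq_len(nrow(ref)))
            thr <- aberrancyThreshold(self, ac$alpha %||% 0.95)
            sc <- nnAberrancy(x, ref, k = k, features = feats)
            colData(x)$aberrancy_score <- sc
            colData(x)$aberrant <- classifyAberrant(sc, thr)
            outputs$aberrancy_threshold <- thr
            note("aberrancy", ncol(x), ncol(x))
            x
        })
    }

    ## --- stats
    if ("stats" %in% active) {
        run("stats", {
            st <- config$stats
            x <- scaleFeatures(x)
            tr <- colData(x)[[st$contrast %||% "treatment"]]
            if (!is.null(tr) && length(unique(tr)) > 1L) {
                strata <- st$strata %||% "phase"
                if (!strata %in% colnames(colData(x))) strata <- NULL
                de <- differentialTest(x, contrast = st$contrast,
                                       strata = strata)
                outputs$differential <- de
                .writeStageTable(de, dir, "differential")
            }
            gp <- colData(x)[[st$group %||% "line"]]
            if (!is.null(gp) && length(unique(gp)) > 1L) {
                ve <- varianceExplained(x, group = st$group)
                outputs$variance_explained <- ve
                .writeStageTable(ve, dir, "variance_explained")
            }
            note("stats", ncol(x), ncol(x))
        })
    }

    cd <- as.data.frame(colData(x))
    cd <- cbind(cell_index = seq_len(nrow(cd)), cd)
    .writeStageTable(cd, dir, "cell_data")
    .writeStageTable(counts, dir, "run_report")
    outputs$data <- x
    structure(list(counts = counts, outputs = outputs, config = config,
                   warnings = warns,
                   elapsed_s = proc.time()[["elapsed"]] - t0),
              class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
    cat(sprintf("RunReport: %d stage(s), %.1f s elapsed\n",
                nrow(x$counts), x$elapsed_s))
    print(x$counts, row.names = FALSE)
    if (length(x$warnings))
        cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
    invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
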