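#' @importFrom stats density
NULL

#' Gate thresholds for phase assignment
#'
#' @param idu_pos IdU positivity threshold (S gate)
#' @param ph3_pos pH3(S10) positivity threshold (M gate)
#' @param cyclinb1_high Cyclin B1 high threshold (G2 gate)
#' @param dna_window optional `c(min, max)` DNA window
#' @param g0_rules optional list with `ki67_low` and/or `prb_low` cutoffs
#'   defining the G0-like sub-gate of G0G1
#' @param method how the thresholds were derived
#' @return list of class `"GateThresholds"`
#' @export
gateThresholds <- function(idu_pos, ph3_pos, cyclinb1_high,
                           dna_window = NULL, g0_rules = NULL,
                           method = "manual") {
    th <- c(idu_pos, ph3_pos, cyclinb1_high)
    if (!is.numeric(th) || any(!is.finite(th)))
        stop("gate thresholds must be finite numbers")
    if (!is.null(dna_window) && (length(dna_window) != 2L ||
                                 dna_window[1] > dna_window[2]))
        stop("'dna_window' must be an ordered pair")
    structure(list(idu_pos = idu_pos, ph3_pos = ph3_pos,
                   cyclinb1_high = cyclinb1_high, dna_window = dna_window,
                   g0_rules = g0_rules, method = method),
              class = "GateThresholds")
}

## valley of a kernel density estimate: lowest density point between the two
## highest local maxima; NULL when the KDE is effectively unimodal. The
## valley must dip below half the lower peak (prominence), otherwise the
## "modes" are ripples on one mode.
.kdeValley <- function(v) {
    d <- density(v, n = 512)
    y <- d$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1L
    if (length(peaks) < 2L) return(NULL)
    top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)[1:2]])
    seg <- seq(top2[1], top2[2])
    y_val <- min(y[seg])
    if (y_val > 0.5 * min(y[top2])) return(NULL)
    d$x[seg[which.min(y[seg])]]
}

#' Derive gating thresholds from the data
#'
#' `"valley"` places each threshold at the density minimum between the two
#' largest modes of a kernel density estimate of the channel (falling back
#' per channel to the quantile method, with a warning, when the estimate is
#' unimodal); `"quantile"` uses stated per-channel quantiles; `"manual"`
#' passes supplied values through.
#'
#' @param x a normalized [CycloSet-class]
#' @param method `"valley"`, `"quantile"` or `"manual"`
#' @param channels named character vector mapping gates to channels
#'   (`idu`, `ph3`, `cyclinb1`)
#' @param quantiles per-gate quantiles for the quantile method (and the
#'   valley fallback)
#' @param manual named list of thresholds for the manual method
#' @return a [gateThresholds()] object on the normalized asinh scale
#' @export
deriveThresholds <- function(x,
                             method = c("valley", "quantile", "manual"),
                             channels = c(idu = "IdU", ph3 = "pH3_s10",
                                          cyclinb1 = "CyclinB1"),
                             quantiles = c(idu = 0.99, ph3 = 0.99,
                                           cyclinb1 = 0.95),
                             manual = NULL) {
    method <- match.arg(method)
    stopifnot(is(x, "CycloSet"))
    if (method == "manual") {
        if (is.null(manual)) stop("manual method needs 'manual' thresholds")
        return(gateThresholds(manual$idu_pos, manual$ph3_pos,
                              manual$cyclinb1_high,
                              dna_window = manual$dna_window,
                              g0_rules = manual$g0_rules, method = "manual"))
    }
    m <- .cellMatrix(x, unname(channels))
    th <- numeric(3)
    names(th) <- c("idu", "ph3", "cyclinb1")
    for (g in names(th)) {
        v <- m[, channels[[g]]]
        t_g <- if (method == "valley") .kdeValley(v) else NULL
        if (is.null(t_g)) {
            if (method == "valley")
                warning("channel ", channels[[g]],
                        " looks unimodal; falling back to quantile ",
                        quantiles[[g]])
            t_g <- quantile(v, quantiles[[g]], names = FALSE)
        }
        th[g] <- t_g
    }
    gateThresholds(th[["idu"]], th[["ph3"]], th[["cyclinb1"]],
                   method = method)
}

#' Assign cell-cycle phases by threshold gating
#'
#' Mirrors the classical gating strategy: pH3(S10)-positive cells are M;
#' of the rest, IdU-positive cells are S (active DNA replication); of the
#' rest, Cyclin B1-high cells are G2; everything else is G0G1. Precedence
#' M > S > G2 > G0G1 makes the assignment total and exclusive (mitotic
#' cells do not incorporate IdU, and Cyclin B1 peaks in M, so pH3 must
#' dominate). When `g0_rules` are present in the thresholds, G0G1 cells
#' that are Ki67-low and pRb(S780)-low are additionally flagged `g0like`.
#'
#' @param x a normalized [CycloSet-class]
#' @param thresholds a [gateThresholds()] object
#' @param channels gate-to-channel mapping, as in [deriveThresholds()]
#' @return `x` with a `phase` factor (levels G0G1, S, G2, M) in `colData`,
#'   plus `g0like` when G0 rules are given
#' @export
assignPhases <- function(x, thresholds,
                         channels = c(idu = "IdU", ph3 = "pH3_s10",
                                      cyclinb1 = "CyclinB1")) {
    stopifnot(is(x, "CycloSet"), inherits(thresholds, "GateThresholds"))
    m <- .cellMatrix(x, unname(channels))
    idu <- m[, channels[["idu"]]]
    ph3 <- m[, channels[["ph3"]]]
    cyc <- m[, channels[["cyclinb1"]]]
    phase <- rep("G0G1", ncol(x))
    phase[cyc >= thresholds$cyclinb1_high] <- "G2"
    phase[idu >= thresholds$idu_pos] <- "S"
    phase[ph3 >= thresholds$ph3_pos] <- "M"
    colData(x)$phase <- factor(phase, levels = .PHASES)
    g0 <- thresholds$g0_rules
    if (!is.null(g0)) {
        ok <- phase == "G0G1"
        if (!is.null(g0$ki67_low))
            ok <- ok & .cellMatrix(x, "Ki67")[, 1] < g0$ki67_low
        if (!is.null(g0$prb_low))
            ok <- ok & .cellMatrix(x, "pRbS780")[, 1] < g0$prb_low
        colData(x)$g0like <- ok
    }
    x
}
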