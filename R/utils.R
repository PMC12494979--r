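## internal helpers shared across modules

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched. `seed = NULL` runs in the current stream.
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

.checkFraction <- function(f, what = "fraction") {
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
        stop(sprintf("'%s' must be a single value in [0, 1]", what))
    invisible(f)
}

.checkPositive <- function(v, what) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
        stop(sprintf("'%s' must be positive and finite", what))
    invisible(v)
}

## resolve a per-cell annotation given either a colData column name or a
## vector of the right length
.cellAnnotation <- function(x, value, what) {
    if (is.character(value) && length(value) == 1L &&
        value %in% colnames(colData(x)))
        return(colData(x)[[value]])
    if (length(value) != ncol(x))
        stop(sprintf("'%s' must be a colData column name or a length-%d vector",
                     what, ncol(x)))
    value
}

## lognormal sdlog for a multiplicative coefficient of variation
.sdlogFromCV <- function(cv) sqrt(log(1 + cv^2))
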