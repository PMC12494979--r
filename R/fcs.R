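## Minimal FCS 3.1 reader/writer for list-mode single-precision float data.
## Covers what this package exports and re-imports: one data segment,
## $DATATYPE F (read also supports D), $MODE L, little- or big-endian
## $BYTEORD. Not a general-purpose FCS implementation.

#' Write an FCS 3.1 file
#'
#' Events are stored as 32-bit floats in list mode, little-endian, with
#' channel names in both $PnN and $PnS.
#'
#' @param mat numeric matrix, cells in rows, named channels in columns
#' @param file output path
#' @param extra_keywords optional named character vector of additional TEXT
#'   keywords (e.g. a seed record)
#' @return invisibly, `file`
#' @export
writeFCS <- function(mat, file, extra_keywords = NULL) {
    stopifnot(is.matrix(mat), !is.null(colnames(mat)))
    n <- nrow(mat); p <- ncol(mat)
    if (n < 1L) stop("refusing to write an FCS file with no events")
    delim <- "/"
    ch <- gsub(delim, "_", colnames(mat), fixed = TRUE)
    kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
            "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
            "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
            "$NEXTDATA" = "0", "$TOT" = as.character(n),
            "$PAR" = as.character(p))
    for (j in seq_len(p)) {
        rng <- max(1, ceiling(max(mat[, j], na.rm = TRUE)))
        kw[sprintf("$P%dB", j)] <- "32"
        kw[sprintf("$P%dE", j)] <- "0,0"
        kw[sprintf("$P%dR", j)] <- as.character(rng)
        kw[sprintf("$P%dN", j)] <- ch[j]
        kw[sprintf("$P%dS", j)] <- ch[j]
    }
    if (!is.null(extra_keywords))
        kw[names(extra_keywords)] <- as.character(extra_keywords)
    header_len <- 58L
    data_len <- 4L * n * p
    ## TEXT length depends on the data offsets it quotes; iterate to a
    ## fixed point (converges immediately in practice)
    text_for <- function(data_beg, data_end) {
        kw2 <- c(kw, "$BEGINDATA" = as.character(data_beg),
                 "$ENDDATA" = as.character(data_end))
        paste0(delim, paste0(names(kw2), delim, unname(kw2), delim,
                             collapse = ""))
    }
    ## all segment offsets are 0-based byte positions, per the standard
    data_beg <- header_len
    repeat {
        txt <- text_for(data_beg, data_beg + data_len - 1L)
        new_beg <- header_len + nchar(txt, type = "bytes")
        if (new_beg == data_beg) break
        data_beg <- new_beg
    }
    data_end <- data_beg + data_len - 1L
    text_beg <- header_len
    text_end <- text_beg + nchar(txt, type = "bytes") - 1L
    off <- function(x) formatC(x, width = 8, flag = " ")
    header <- paste0("FCS3.1    ", off(text_beg), off(text_end),
                     off(data_beg), off(data_end), off(0), off(0))
    con <- file(file, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL, useBytes = TRUE)
    writeChar(txt, con, eos = NULL, useBytes = TRUE)
    writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
    invisible(file)
}

#' Read an FCS file written in list mode
#'
#' @param file path to an FCS 3.0/3.1 file with float ($DATATYPE F) or
#'   double (D) list-mode data
#' @return list with `exprs` (cells x channels matrix, names from $PnS
#'   falling back to $PnN) and `keywords` (named character vector)
#' @export
readFCS <- function(file) {
    raw <- readBin(file, "raw", n = file.size(file))
    magic <- rawToChar(raw[1:6])
    if (!magic %in% c("FCS3.0", "FCS3.1"))
        stop("not an FCS 3.0/3.1 file: ", file)
    offs <- as.integer(vapply(0:5, function(i)
        trimws(rawToChar(raw[(11 + 8 * i):(18 + 8 * i)])), ""))
    text_beg <- offs[1]; text_end <- offs[2]
    txt <- rawToChar(raw[(text_beg + 1):(text_end + 1)])
    delim <- substr(txt, 1, 1)
    parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
    if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
    kw <- parts[seq(2, length(parts), 2)]
    names(kw) <- toupper(parts[seq(1, length(parts), 2)])
    data_beg <- offs[3]; data_end <- offs[4]
    if (data_beg == 0L) {
        data_beg <- as.integer(kw[["$BEGINDATA"]])
        data_end <- as.integer(kw[["$ENDDATA"]])
    }
    n <- as.integer(kw[["$TOT"]]); p <- as.integer(kw[["$PAR"]])
    dtype <- toupper(kw[["$DATATYPE"]])
    size <- switch(dtype, F = 4L, D = 8L,
                   stop("unsupported $DATATYPE: ", dtype))
    endian <- if (grepl("^1", kw[["$BYTEORD"]])) "little" else "big"
    vals <- readBin(raw[(data_beg + 1):(data_end + 1)], "numeric",
                    n = n * p, size = size, endian = endian)
    mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
    nm <- vapply(seq_len(p), function(j) {
        s <- kw[sprintf("$P%dS", j)]
        if (is.na(s) || !nzchar(s)) s <- kw[sprintf("$P%dN", j)]
        unname(s)
    }, "")
    colnames(mat) <- nm
    list(exprs = mat, keywords = kw)
}
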