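#' Canonicalize gene symbols
#'
#' Upper-cases and strips surrounding whitespace. No alias resolution is
#' attempted.
#'
#' @param symbols character vector.
#' @return canonical character vector.
#' @export
canonicalSymbols <- function(symbols) {
    toupper(trimws(as.character(symbols)))
}

#' Filter a scored gene list by relevancy Z score
#'
#' Keeps genes whose relevancy Z score (standard deviations above the
#' mean relevancy) strictly exceeds \code{zMin}, preserving input
#' order. Every record must carry a score; curated-source lists without
#' scores are not passed through this filter (they bypass it by
#' design).
#'
#' @param genes \code{data.frame} with columns \code{symbol} and
#'   \code{z_score} (optional \code{source}).
#' @param zMin strict lower threshold (default 1.0).
#' @return the filtered \code{data.frame}.
#' @export
filterByZscore <- function(genes, zMin = 1.0) {
    if (!is.data.frame(genes) ||
        !all(c("symbol", "z_score") %in% names(genes)))
        stop("'genes' must have columns symbol, z_score")
    if (nrow(genes) == 0L) return(genes)
    miss <- !is.finite(genes$z_score)
    if (any(miss))
        stop("missing z_score for symbol(s): ",
             paste(utils::head(genes$symbol[miss], 5L), collapse = ", "))
    genes[genes$z_score > zMin, , drop = FALSE]
}

#' Merge two gene lists removing redundant symbols
#'
#' Union by canonical symbol. When a symbol occurs in both lists the
#' merged record keeps the maximum available Z score and carries both
#' provenance tags (comma-joined). Order: all of \code{listA} first,
#' then the novel symbols of \code{listB}.
#'
#' @param listA,listB \code{data.frame}s with column \code{symbol} and
#'   optional \code{z_score}, \code{source}.
#' @return merged \code{data.frame} with columns symbol, z_score,
#'   source.
#' @export
mergeGeneLists <- function(listA, listB) {
    norm <- function(df) {
        if (!is.data.frame(df) || !"symbol" %in% names(df))
            stop("gene lists must have a 'symbol' column")
        out <- data.frame(symbol = canonicalSymbols(df$symbol))
        out$z_score <- if ("z_score" %in% names(df))
            as.numeric(df$z_score) else NA_real_
        out$source <- if ("source" %in% names(df))
            as.character(df$source) else NA_character_
        # collapse duplicates within one list
        out[!duplicated(out$symbol), , drop = FALSE]
    }
    a <- norm(listA); b <- norm(listB)
    shared <- intersect(a$symbol, b$symbol)
    if (length(shared)) {
        ib <- match(shared, b$symbol); ia <- match(shared, a$symbol)
        a$z_score[ia] <- pmax(a$z_score[ia], b$z_score[ib], na.rm = TRUE)
        a$z_score[ia][!is.finite(a$z_score[ia])] <- NA_real_
        a$source[ia] <- mapply(function(x, y)
            paste(unique(stats::na.omit(c(
                strsplit(x %||% "", ",")[[1L]],
                strsplit(y %||% "", ",")[[1L]]))), collapse = ","),
            a$source[ia], b$source[ib])
    }
    out <- rbind(a, b[!b$symbol %in% a$symbol, , drop = FALSE])
    rownames(out) <- NULL
    out
}

`%||%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

#' Read a scored gene list from TSV
#'
#' Columns: \code{symbol}, optional \code{z_score} and \code{source}.
#'
#' @param path TSV file path.
#' @return \code{data.frame}.
#' @export
readGeneList <- function(path) {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (!"symbol" %in% names(df))
        stop("gene list must have a 'symbol' column")
    df$symbol <- canonicalSymbols(df$symbol)
    df
}

#' Write a gene list to TSV
#'
#' @param genes \code{data.frame} with a \code{symbol} column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneList <- function(genes, path) {
    utils::write.table(genes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
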