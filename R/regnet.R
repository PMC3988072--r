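#' Filter TF binding evidence by binding-site count
#'
#' Keeps (TF, target) pairs supported by at least \code{minSites}
#' promoter binding sites. Multiple records for the same pair are summed
#' before filtering (site counts are additive over repeated promoter
#' scans). The default \code{minSites = 2} implements the usual
#' "evidence of more than one binding site" rule.
#'
#' @param records \code{data.frame} with columns \code{tf},
#'   \code{target}, \code{n_sites} (an optional \code{family} column is
#'   carried as annotation only).
#' @param minSites minimum summed binding-site count (default 2).
#' @return named list mapping each target gene to its character vector
#'   of retained TFs.
#' @export
filterEvidence <- function(records, minSites = 2L) {
    need <- c("tf", "target", "n_sites")
    if (!is.data.frame(records) || !all(need %in% names(records)))
        stop("'records' must have columns ", paste(need, collapse = ", "))
    bad <- which(!is.finite(records$n_sites) | records$n_sites < 0)
    if (length(bad))
        stop("negative or missing n_sites in record(s): ",
             paste(utils::head(bad, 5L), collapse = ", "))
    agg <- stats::aggregate(n_sites ~ tf + target, data = records, FUN = sum)
    agg <- agg[agg$n_sites >= minSites, , drop = FALSE]
    out <- lapply(split(agg$tf, agg$target), function(x) sort(unique(x)))
    out[sort(names(out))]
}

#' Union of TFs over all targets
#'
#' @param tfSets named list of per-target TF character vectors (from
#'   \code{\link{filterEvidence}}).
#' @return sorted character vector of unique TFs.
#' @export
uniqueTFUnion <- function(tfSets) {
    sort(unique(unlist(tfSets, use.names = FALSE)))
}

#' Build the bipartite TF-target regulatory network
#'
#' One edge per retained (TF, target) pair. TF and target symbol
#' namespaces must be disjoint; a symbol appearing on both sides is
#' prefixed with \code{"TF:"} on the TF side, with a warning.
#'
#' @param tfSets named list of per-target TF sets.
#' @return a \code{\link{RegulatoryNetwork}}.
#' @export
buildRegulatoryNetwork <- function(tfSets) {
    targets <- names(tfSets)
    if (is.null(targets) && length(tfSets))
        stop("'tfSets' must be a named list (names = target genes)")
    if (!length(tfSets))
        return(new("RegulatoryNetwork",
                   edges = data.frame(tf = character(),
                                      target = character()),
                   tfs = character(), targets = character()))
    edges <- data.frame(
        tf = unlist(tfSets, use.names = FALSE),
        target = rep(targets, lengths(tfSets)))
    clash <- intersect(unique(edges$tf), targets)
    if (length(clash)) {
        warning("symbol(s) appear as both TF and target, prefixing TF ",
                "side with 'TF:': ", paste(clash, collapse = ", "))
        edges$tf[edges$tf %in% clash] <-
            paste0("TF:", edges$tf[edges$tf %in% clash])
    }
    edges <- unique(edges)
    new("RegulatoryNetwork", edges = edges,
        tfs = sort(unique(edges$tf)), targets = as.character(targets))
}

#' Rank transcription factors by target connectivity
#'
#' Orders TFs by the number of target genes they bind (descending),
#' breaking ties lexicographically, and returns the top \code{topN}.
#' The default \code{topN = 3} reports the core regulators.
#'
#' @param net a \code{\link{RegulatoryNetwork}}.
#' @param topN how many TFs to return (default 3; \code{Inf} for all).
#' @return \code{data.frame} with columns \code{tf} and
#'   \code{connectivity}.
#' @export
rankTFConnectivity <- function(net, topN = 3L) {
    stopifnot(is(net, "RegulatoryNetwork"))
    if (nrow(net@edges) == 0L) stop("regulatory network has no edges")
    conn <- table(net@edges$tf)
    df <- data.frame(tf = names(conn), connectivity = as.integer(conn))
    df <- df[order(-df$connectivity, df$tf), , drop = FALSE]
    rownames(df) <- NULL
    utils::head(df, topN)
}

#' Read a TF binding-evidence table from TSV
#'
#' Columns: \code{tf}, \code{family}, \code{target}, \code{n_sites}
#' (\code{family} optional).
#'
#' @param path TSV file path.
#' @return \code{data.frame}.
#' @export
readTFTable <- function(path) {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("tf", "target", "n_sites")
    if (!all(need %in% names(df)))
        stop("TF table must have columns ", paste(need, collapse = ", "))
    df
}

#' Export a regulatory network as SIF
#'
#' One \code{tf <tab> reg <tab> target} line per regulatory edge.
#'
#' @param net a \code{\link{RegulatoryNetwork}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRegulatorySIF <- function(net, path) {
    stopifnot(is(net, "RegulatoryNetwork"))
    writeLines(paste(net@edges$tf, "reg", net@edges$target, sep = "\t"),
               path)
    invisible(path)
}
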