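#' Node degrees of a PPI graph
#'
#' @param g a \code{\link{PPIGraph}}.
#' @return named integer vector, one entry per node (isolated nodes
#'   have degree 0).
#' @export
nodeDegrees <- function(g) {
    stopifnot(is(g, "PPIGraph"))
    d <- igraph::degree(g@graph, loops = FALSE)
    storage.mode(d) <- "integer"
    d
}

#' Normalized betweenness centrality
#'
#' Fraction of all-pairs unweighted shortest paths passing through each
#' node: for node v, the sum over unordered pairs \{s, t\} (s, t != v)
#' of sigma_st(v) / sigma_st, divided by (n-1)(n-2)/2, where n is the
#' total node count of the graph including disconnected nodes. Pairs in
#' different components contribute zero. Edge confidences are ignored
#' (hop-count shortest paths).
#'
#' @param g a \code{\link{PPIGraph}}.
#' @return named numeric vector of centralities in [0, 1]. For graphs
#'   with fewer than 3 nodes the normalizer vanishes; all values are
#'   defined as 0 with a warning.
#' @export
betweennessCentrality <- function(g) {
    stopifnot(is(g, "PPIGraph"))
    n <- igraph::vcount(g@graph)
    if (n < 3L) {
        warning("betweenness centrality undefined for fewer than 3 nodes; ",
                "returning 0 for all nodes")
        return(stats::setNames(numeric(n), igraph::V(g@graph)$name))
    }
    igraph::betweenness(g@graph, directed = FALSE, weights = NA,
                        normalized = TRUE)
}

#' Per-node topology statistics
#'
#' Computes degree and normalized betweenness centrality for every node.
#'
#' @param g a \code{\link{PPIGraph}}.
#' @return a \code{\link{TopologyStats}} object.
#' @export
nodeStats <- function(g) {
    deg <- nodeDegrees(g)
    bc <- suppressWarnings(betweennessCentrality(g))
    new("TopologyStats",
        stats = data.frame(node = names(deg), degree = unname(deg),
                           betweenness = unname(bc[names(deg)])))
}

#' Construct TopologyStats from plain vectors
#'
#' Convenience constructor for externally computed statistics (e.g. a
#' network-analyzer export).
#'
#' @param node character vector of symbols.
#' @param degree integer vector of degrees.
#' @param betweenness numeric vector of normalized centralities.
#' @return a \code{\link{TopologyStats}} object.
#' @export
TopologyStats <- function(node, degree, betweenness) {
    new("TopologyStats",
        stats = data.frame(node = as.character(node),
                           degree = as.integer(degree),
                           betweenness = as.numeric(betweenness)))
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least-squares fit of log(count of nodes with degree d)
#' against log(d), over the raw degree histogram restricted to degrees
#' d >= 1 that occur at least once (no binning, no cumulative
#' transform). Returns count(d) ~ a * d^b with a = exp(intercept),
#' b = slope, and the r-squared of the log-log regression; r-squared
#' near 1 with negative b indicates scale-free architecture.
#'
#' @param degrees integer vector of node degrees (typically
#'   \code{nodeDegrees(g)}).
#' @return a \code{\link{PowerLawFit}}.
#' @export
fitPowerLaw <- function(degrees) {
    degrees <- as.integer(degrees)
    tab <- table(degrees[degrees >= 1L])
    d <- as.numeric(names(tab))
    cnt <- as.numeric(tab)
    if (length(d) < 3L)
        stop("insufficient degree diversity: need at least 3 distinct ",
             "positive degree values, got ", length(d))
    fit <- stats::lm(log(cnt) ~ log(d))
    # summary.lm warns on exact fits; the r^2 itself is still valid
    r2 <- suppressWarnings(summary(fit)$r.squared)
    # a perfect fit can report r^2 marginally above 1 through rounding
    r2 <- min(max(r2, 0), 1)
    new("PowerLawFit",
        coefficient = exp(unname(stats::coef(fit)[1L])),
        exponent = unname(stats::coef(fit)[2L]),
        rSquared = r2)
}

#' Write node statistics to a TSV file
#'
#' @param stats a \code{\link{TopologyStats}}.
#' @param path output path; columns node, degree, betweenness.
#' @return \code{path}, invisibly.
#' @export
writeStatsTSV <- function(stats, path) {
    stopifnot(is(stats, "TopologyStats"))
    utils::write.table(statsTable(stats), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeStatsTSV
#' @export
readStatsTSV <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    TopologyStats(df$node, df$degree, df$betweenness)
}
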