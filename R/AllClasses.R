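#' @import methods
NULL

setOldClass("igraph")

#' PPIGraph: a confidence-weighted protein-protein interaction graph
#'
#' Thin S4 wrapper around an undirected simple \pkg{igraph} graph whose
#' edges carry a \code{confidence} attribute in [0, 1] (a STRING-style
#' combined score). All topology functions in the package operate on this
#' class; the confidence is used only for edge inclusion, never for
#' shortest-path weighting.
#'
#' @slot graph an undirected simple \code{igraph} object with named
#'   vertices and a numeric \code{confidence} edge attribute.
#' @export
setClass("PPIGraph", representation(graph = "igraph"))

setValidity("PPIGraph", function(object) {
    g <- object@graph
    msg <- character()
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (igraph::any_loop(g))
        msg <- c(msg, "graph must not contain self-loops")
    if (igraph::any_multiple(g))
        msg <- c(msg, "graph must not contain duplicate edges")
    if (is.null(igraph::V(g)$name) || any(!nzchar(igraph::V(g)$name)))
        msg <- c(msg, "all vertices must carry non-empty names")
    conf <- igraph::E(g)$confidence
    if (igraph::ecount(g) > 0) {
        if (is.null(conf))
            msg <- c(msg, "edges must carry a 'confidence' attribute")
        else if (any(!is.finite(conf)) || any(conf < 0 | conf > 1))
            msg <- c(msg, "edge confidences must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' TopologyStats: per-node degree and betweenness centrality
#'
#' Container for the topological statistics used for gene prioritization:
#' the degree (number of incident edges) and the normalized betweenness
#' centrality (fraction of all-pairs shortest paths through the node,
#' normalizer (n-1)(n-2)/2) of every node of a graph.
#'
#' @slot stats \code{data.frame} with columns \code{node} (character),
#'   \code{degree} (integer) and \code{betweenness} (numeric in [0, 1]).
#' @export
setClass("TopologyStats", representation(stats = "data.frame"))

setValidity("TopologyStats", function(object) {
    s <- object@stats
    msg <- character()
    need <- c("node", "degree", "betweenness")
    if (!all(need %in% names(s)))
        return(sprintf("stats must have columns %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(s$node))
        msg <- c(msg, "duplicate node symbols in stats")
    # note: a stats table may describe a subset of a larger graph's
    # nodes, so degree is not bounded by nrow(s) - 1 here
    if (nrow(s) > 0) {
        if (any(s$degree < 0) || any(s$degree != round(s$degree)))
            msg <- c(msg, "degrees must be non-negative integers")
        if (any(!is.finite(s$betweenness)) ||
            any(s$betweenness < 0 | s$betweenness > 1))
            msg <- c(msg, "betweenness values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' PowerLawFit: least-squares power-law fit of a degree distribution
#'
#' Result of fitting count(d) = a * d^b by ordinary least squares on
#' log-log axes over the raw degree histogram (degrees >= 1 with at
#' least one node; no binning, no cumulative transform).
#'
#' @slot coefficient positive scale coefficient a.
#' @slot exponent slope b of the log-log fit (negative for scale-free
#'   degree distributions).
#' @slot rSquared coefficient of determination of the log-log fit,
#'   in [0, 1].
#' @export
setClass("PowerLawFit",
         representation(coefficient = "numeric", exponent = "numeric",
                        rSquared = "numeric"))

setValidity("PowerLawFit", function(object) {
    msg <- character()
    if (length(object@coefficient) != 1L || object@coefficient <= 0)
        msg <- c(msg, "coefficient must be a single positive number")
    if (length(object@rSquared) != 1L ||
        object@rSquared < 0 || object@rSquared > 1)
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' HubSelection: hub genes passing the dual topological cutoff
#'
#' Nodes selected as hubs because their degree exceeds \code{degreeCut}
#' or their betweenness centrality exceeds \code{bcCut} (both strict),
#' ordered by the canonical ranking (betweenness desc, degree desc,
#' symbol).
#'
#' @slot hubs ordered character vector of hub gene symbols.
#' @slot degreeCut integer degree threshold (strict).
#' @slot bcCut numeric betweenness threshold (strict).
#' @slot stats the \code{TopologyStats} the selection was made from.
#' @export
setClass("HubSelection",
         representation(hubs = "character", degreeCut = "numeric",
                        bcCut = "numeric", stats = "TopologyStats"))

setValidity("HubSelection", function(object) {
    s <- object@stats@stats
    sel <- s[match(object@hubs, s$node), , drop = FALSE]
    if (length(object@hubs) &&
        (anyNA(sel$node) ||
         !all(sel$degree > object@degreeCut | sel$betweenness > object@bcCut)))
        return("every hub must strictly exceed the degree or the BC cutoff")
    TRUE
})

#' DeletionDesign: the leave-k-out test-network design
#'
#' The full set of node-deletion sets used to build test networks: at
#' level 1 one singleton per pool member; at each level k >= 2, for every
#' hub and every repeat, a set of k distinct nodes containing exactly
#' that hub plus k-1 nodes sampled without replacement from the rest of
#' the pool.
#'
#' @slot sets named list (one element per level, names "1", "2", ...);
#'   each element is a list of character vectors of deleted node symbols.
#' @slot pool the ranked candidate pool the deletions are drawn from.
#' @slot hubs the designated hub genes.
#' @slot repeats repeats per hub at levels >= 2.
#' @slot seed RNG seed that makes the design reproducible.
#' @export
setClass("DeletionDesign",
         representation(sets = "list", pool = "character",
                        hubs = "character", repeats = "integer",
                        seed = "integer"))

setValidity("DeletionDesign", function(object) {
    msg <- character()
    for (lev in names(object@sets)) {
        k <- as.integer(lev)
        sizes <- lengths(object@sets[[lev]])
        if (any(sizes != k))
            msg <- c(msg, sprintf("level %d contains a set of wrong size", k))
        bad <- vapply(object@sets[[lev]],
                      function(s) anyDuplicated(s) > 0 ||
                                  !all(s %in% object@pool),
                      logical(1))
        if (any(bad))
            msg <- c(msg, sprintf(
                "level %d contains duplicated or out-of-pool symbols", k))
        if (k >= 2L) {
            nh <- vapply(object@sets[[lev]],
                         function(s) sum(s %in% object@hubs), integer(1))
            if (any(nh < 1L))
                msg <- c(msg, sprintf(
                    "level %d has a set without its designated hub", k))
        }
    }
    if (length(msg)) msg else TRUE
})

#' RetentionTable: hub retention frequencies and accuracy per level
#'
#' Per deletion level, the number of test networks whose recomputed
#' top-5 ranking retains each hub, together with the number of test
#' networks and the per-level accuracy statistic
#' sum(frequencies) / (n_hubs * n_networks).
#'
#' @slot frequency integer matrix, rows = deletion levels, columns = hubs.
#' @slot nNetworks integer vector of test networks per level.
#' @slot accuracy numeric per-level accuracies (unrounded).
#' @export
setClass("RetentionTable",
         representation(frequency = "matrix", nNetworks = "integer",
                        accuracy = "numeric"))

setValidity("RetentionTable", function(object) {
    msg <- character()
    if (nrow(object@frequency) != length(object@nNetworks) ||
        nrow(object@frequency) != length(object@accuracy))
        msg <- c(msg, "rows of frequency must match nNetworks and accuracy")
    if (any(object@frequency < 0) ||
        any(object@frequency > object@nNetworks[row(object@frequency)]))
        msg <- c(msg, "frequencies must lie in [0, nNetworks]")
    if (any(object@accuracy < 0 | object@accuracy > 1))
        msg <- c(msg, "accuracies must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' RegulatoryNetwork: bipartite TF-to-target regulatory network
#'
#' A bipartite graph between transcription factors and their target
#' genes, with an edge wherever promoter-scan evidence passed the
#' binding-site filter. TF and target namespaces are disjoint.
#'
#' @slot edges \code{data.frame} with columns \code{tf} and \code{target}.
#' @slot tfs character vector of TF symbols (one per unique TF).
#' @slot targets character vector of target gene symbols.
#' @export
setClass("RegulatoryNetwork",
         representation(edges = "data.frame", tfs = "character",
                        targets = "character"))

setValidity("RegulatoryNetwork", function(object) {
    msg <- character()
    if (!all(c("tf", "target") %in% names(object@edges)))
        return("edges must have columns tf, target")
    if (length(intersect(object@tfs, object@targets)))
        msg <- c(msg, "TF and target namespaces must be disjoint")
    if (nrow(object@edges)) {
        if (!all(object@edges$tf %in% object@tfs) ||
            !all(object@edges$target %in% object@targets))
            msg <- c(msg, "edge endpoints must be registered TFs/targets")
        if (anyDuplicated(object@edges[c("tf", "target")]))
            msg <- c(msg, "duplicate TF-target edges")
    }
    if (length(msg)) msg else TRUE
})
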