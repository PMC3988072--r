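#' Canonical node ranking
#'
#' Orders nodes by betweenness centrality (descending), breaking ties by
#' degree (descending) and then lexicographically by symbol. This is the
#' ranking used for hub selection, for choosing the top-k candidate pool
#' of the robustness validation, and for the top-5 of every test
#' network.
#'
#' @param stats a \code{\link{TopologyStats}}.
#' @return character vector of node symbols, best first.
#' @export
rankNodes <- function(stats) {
    stopifnot(is(stats, "TopologyStats"))
    s <- statsTable(stats)
    if (nrow(s) == 0L) stop("cannot rank an empty statistics table")
    s$node[order(-s$betweenness, -s$degree, s$node)]
}

#' Select hub genes by a dual strict topological cutoff
#'
#' A node is a hub when its degree strictly exceeds \code{degreeCut}
#' or its betweenness centrality strictly exceeds \code{bcCut} (union
#' of the two criteria). Defaults follow the conventional prioritization
#' thresholds degree > 50 and BC > 0.05. Hubs are returned in canonical
#' rank order.
#'
#' @param stats a \code{\link{TopologyStats}}.
#' @param degreeCut strict degree threshold (default 50).
#' @param bcCut strict betweenness threshold (default 0.05).
#' @return a \code{\link{HubSelection}} (possibly with zero hubs).
#' @export
selectHubs <- function(stats, degreeCut = 50, bcCut = 0.05) {
    stopifnot(is(stats, "TopologyStats"))
    if (degreeCut < 0 || bcCut < 0)
        stop("cutoffs must be non-negative")
    s <- statsTable(stats)
    pass <- s$node[s$degree > degreeCut | s$betweenness > bcCut]
    ranked <- rankNodes(stats)
    new("HubSelection", hubs = ranked[ranked %in% pass],
        degreeCut = as.numeric(degreeCut), bcCut = as.numeric(bcCut),
        stats = stats)
}

#' Extract the hub backbone subnetwork
#'
#' The backbone is the node-induced subgraph on the hubs and all their
#' direct neighbors: every edge of the input graph whose both endpoints
#' lie in that node set is retained, including edges between two
#' non-hub neighbors.
#'
#' @param g a \code{\link{PPIGraph}}.
#' @param hubs character vector of hub symbols, all present in \code{g}.
#' @return the backbone as a \code{\link{PPIGraph}}.
#' @export
extractBackbone <- function(g, hubs) {
    stopifnot(is(g, "PPIGraph"))
    missing <- setdiff(hubs, nodeNames(g))
    if (length(missing))
        stop("hub(s) not in graph: ", paste(missing, collapse = ", "))
    nbr <- unique(unlist(lapply(hubs, function(h)
        names(igraph::neighbors(g@graph, h)))))
    keep <- union(hubs, nbr)
    new("PPIGraph",
        graph = igraph::induced_subgraph(g@graph, keep))
}

#' Fraction of backbone edges incident to a hub
#'
#' Quantifies how much of the backbone's wiring is carried by the hub
#' genes themselves: the proportion of backbone edges with at least one
#' hub endpoint.
#'
#' @param backbone a \code{\link{PPIGraph}} (typically from
#'   \code{\link{extractBackbone}}).
#' @param hubs character vector of hub symbols, all in the backbone.
#' @return a proportion in (0, 1].
#' @export
hubEdgeFraction <- function(backbone, hubs) {
    stopifnot(is(backbone, "PPIGraph"))
    missing <- setdiff(hubs, nodeNames(backbone))
    if (length(missing))
        stop("hub(s) not in backbone: ", paste(missing, collapse = ", "))
    et <- edgeTable(backbone)
    if (nrow(et) == 0L)
        stop("backbone has no edges")
    mean(et$node_a %in% hubs | et$node_b %in% hubs)
}
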