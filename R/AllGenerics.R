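#' @rdname PPIGraph-class
#' @param object,x a package object.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname PPIGraph-class
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname PPIGraph-class
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname PPIGraph-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname TopologyStats-class
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))

#' @rdname HubSelection-class
#' @export
setGeneric("hubGenes", function(x) standardGeneric("hubGenes"))

#' @rdname DeletionDesign-class
#' @export
setGeneric("deletionSets", function(x, level) standardGeneric("deletionSets"))

#' @rdname RetentionTable-class
#' @export
setGeneric("accuracyTable", function(x) standardGeneric("accuracyTable"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("regulatoryEdges", function(x) standardGeneric("regulatoryEdges"))

# ---- PPIGraph accessors -------------------------------------------------

#' @rdname PPIGraph-class
#' @export
setMethod("nodeNames", "PPIGraph", function(x) igraph::V(x@graph)$name)

#' @rdname PPIGraph-class
#' @export
setMethod("nodeCount", "PPIGraph", function(x) igraph::vcount(x@graph))

#' @rdname PPIGraph-class
#' @export
setMethod("edgeCount", "PPIGraph", function(x) igraph::ecount(x@graph))

#' @rdname PPIGraph-class
#' @export
setMethod("edgeTable", "PPIGraph", function(x) {
    if (igraph::ecount(x@graph) == 0L)
        return(data.frame(node_a = character(), node_b = character(),
                          confidence = numeric()))
    el <- igraph::as_edgelist(x@graph, names = TRUE)
    data.frame(node_a = el[, 1L], node_b = el[, 2L],
               confidence = igraph::E(x@graph)$confidence)
})

setMethod("show", "PPIGraph", function(object) {
    cat("PPIGraph with", nodeCount(object), "nodes and",
        edgeCount(object), "edges\n")
    if (edgeCount(object) > 0L) {
        conf <- igraph::E(object@graph)$confidence
        cat(sprintf("  edge confidence range: [%.3f, %.3f]\n",
                    min(conf), max(conf)))
    }
})

#' Underlying igraph object of a PPIGraph
#'
#' @param x a \code{PPIGraph}.
#' @return the wrapped \code{igraph} object.
#' @export
asIgraph <- function(x) {
    stopifnot(is(x, "PPIGraph"))
    x@graph
}

# ---- TopologyStats ------------------------------------------------------

#' @rdname TopologyStats-class
#' @export
setMethod("statsTable", "TopologyStats", function(x) x@stats)

setMethod("show", "TopologyStats", function(object) {
    s <- object@stats
    cat("TopologyStats for", nrow(s), "nodes\n")
    top <- utils::head(s[order(-s$betweenness, -s$degree, s$node), ], 5L)
    print(top, row.names = FALSE)
})

# ---- PowerLawFit --------------------------------------------------------

setMethod("show", "PowerLawFit", function(object) {
    cat(sprintf(
        "PowerLawFit: count(d) ~ %.3g * d^%.3f  (log-log r^2 = %.3f)\n",
        object@coefficient, object@exponent, object@rSquared))
})

# ---- HubSelection -------------------------------------------------------

#' @rdname HubSelection-class
#' @export
setMethod("hubGenes", "HubSelection", function(x) x@hubs)

setMethod("show", "HubSelection", function(object) {
    cat(sprintf(
        "HubSelection: %d hub(s) with degree > %g or BC > %g\n",
        length(object@hubs), object@degreeCut, object@bcCut))
    if (length(object@hubs))
        cat("  ", paste(object@hubs, collapse = ", "), "\n")
})

# ---- DeletionDesign -----------------------------------------------------

#' @rdname DeletionDesign-class
#' @param level a single deletion level (number of removed nodes).
#' @export
setMethod("deletionSets", "DeletionDesign", function(x, level) {
    lev <- as.character(level)
    if (!lev %in% names(x@sets))
        stop("no deletion level ", level, " in this design")
    x@sets[[lev]]
})

#' Total number of test networks in a deletion design
#'
#' @param design a \code{DeletionDesign}.
#' @return integer count of deletion sets across all levels.
#' @export
designSize <- function(design) {
    stopifnot(is(design, "DeletionDesign"))
    sum(lengths(design@sets) * 0L + vapply(design@sets, length, integer(1)))
}

setMethod("show", "DeletionDesign", function(object) {
    per <- vapply(object@sets, length, integer(1))
    cat("DeletionDesign:", sum(per), "test networks",
        sprintf("(levels %s; %s sets)\n",
                paste(names(per), collapse = ","),
                paste(per, collapse = "+")))
    cat("  pool of", length(object@pool), "nodes,",
        length(object@hubs), "hubs, seed", object@seed, "\n")
})

# ---- RetentionTable -----------------------------------------------------

#' @rdname RetentionTable-class
#' @export
setMethod("accuracyTable", "RetentionTable", function(x) {
    df <- data.frame(level = rownames(x@frequency),
                     as.data.frame(x@frequency),
                     accuracy = round(x@accuracy, 3L),
                     n_networks = x@nNetworks,
                     check.names = FALSE, row.names = NULL)
    overall <- data.frame(level = "Overall",
                          t(colSums(x@frequency)),
                          accuracy = round(mean(x@accuracy), 3L),
                          n_networks = sum(x@nNetworks),
                          check.names = FALSE)
    names(overall) <- names(df)
    rbind(df, overall)
})

setMethod("show", "RetentionTable", function(object) {
    cat("RetentionTable (hub retention across test networks)\n")
    print(accuracyTable(object), row.names = FALSE)
})

# ---- RegulatoryNetwork --------------------------------------------------

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("regulatoryEdges", "RegulatoryNetwork", function(x) x@edges)

setMethod("show", "RegulatoryNetwork", function(object) {
    cat("RegulatoryNetwork:", length(object@tfs), "TFs ->",
        length(object@targets), "targets,", nrow(object@edges), "edges\n")
})
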