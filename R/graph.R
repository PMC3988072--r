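#' Build a confidence-filtered PPI graph from an edge list
#'
#' Constructs an undirected simple graph from STRING-style interaction
#' rows, keeping only edges whose combined confidence score reaches
#' \code{minConfidence}. Scores above 1 are interpreted as STRING's
#' 0-999 integer scale and divided by 1000 before thresholding.
#' Duplicate rows for the same unordered node pair are collapsed keeping
#' the maximum confidence; self-loop rows are dropped with a warning.
#'
#' @param edges \code{data.frame} whose first three columns are
#'   interactor A, interactor B and the confidence score (the
#'   conventional column names are \code{node_a}, \code{node_b},
#'   \code{score}).
#' @param minConfidence minimum confidence for an edge to be kept
#'   (default 0.7, STRING's "high confidence").
#' @return a \code{\link{PPIGraph}}.
#' @examples
#' ed <- data.frame(node_a = c("A", "B", "A"), node_b = c("B", "C", "C"),
#'                  score = c(0.9, 0.8, 0.75))
#' buildGraph(ed, minConfidence = 0.7)
#' @export
buildGraph <- function(edges, minConfidence = 0.7) {
    if (!is.data.frame(edges) || ncol(edges) < 3L)
        stop("'edges' must be a data.frame with at least 3 columns")
    if (!is.numeric(minConfidence) || length(minConfidence) != 1L ||
        minConfidence < 0 || minConfidence > 1)
        stop("'minConfidence' must be a single proportion in [0, 1]")
    a <- trimws(as.character(edges[[1L]]))
    b <- trimws(as.character(edges[[2L]]))
    s <- suppressWarnings(as.numeric(edges[[3L]]))
    bad <- which(!nzchar(a) | !nzchar(b) | is.na(a) | is.na(b) |
                 !is.finite(s) | s < 0)
    if (length(bad))
        stop("malformed edge row(s) at line(s): ",
             paste(utils::head(bad, 5L), collapse = ", "))
    # STRING exports combined scores either as 0-1 proportions or as
    # 0-999 integers; auto-detect by the presence of values above 1.
    if (any(s > 1)) s <- s / 1000
    if (any(s > 1))
        stop("confidence scores exceed 1 even after 0-999 rescaling")
    loops <- a == b
    if (any(loops)) {
        warning(sum(loops), " self-loop row(s) dropped")
        a <- a[!loops]; b <- b[!loops]; s <- s[!loops]
    }
    # canonical unordered pair, dedup keeping max confidence
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    s <- vapply(split(s, key), max, numeric(1))
    pairs <- do.call(rbind, strsplit(names(s), "\r", fixed = TRUE))
    keep <- s >= minConfidence
    if (!any(keep))
        stop("empty graph: no edges with confidence >= ", minConfidence)
    g <- igraph::graph_from_data_frame(
        data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
                   confidence = unname(s[keep])),
        directed = FALSE)
    new("PPIGraph", graph = g)
}

#' Read a STRING-style edge list from a TSV file
#'
#' Expects a tab-separated file with a header line and columns
#' \code{node_a}, \code{node_b}, \code{score}; lines starting with
#' \code{#} are skipped.
#'
#' @param path path to the TSV file.
#' @return \code{data.frame} with columns node_a, node_b, score.
#' @export
readEdgeList <- function(path) {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("node_a", "node_b", "score")
    if (!all(need %in% names(df)))
        stop("edge list must have columns: ", paste(need, collapse = ", "))
    df[need]
}

#' Write a graph in SIF format
#'
#' Simple interaction format: one \code{node_a <tab> pp <tab> node_b}
#' line per edge (relation type "pp" = protein-protein); isolated nodes
#' are written as bare single-column lines so the node set round-trips.
#'
#' @param g a \code{PPIGraph}.
#' @param path output file path.
#' @param relation interaction type string (default \code{"pp"}).
#' @return \code{path}, invisibly.
#' @export
writeSIF <- function(g, path, relation = "pp") {
    stopifnot(is(g, "PPIGraph"))
    et <- edgeTable(g)
    lines <- character()
    if (nrow(et))
        lines <- paste(et$node_a, relation, et$node_b, sep = "\t")
    iso <- setdiff(nodeNames(g), unique(c(et$node_a, et$node_b)))
    writeLines(c(lines, iso), path)
    invisible(path)
}

#' Write / read a graph in GraphML format
#'
#' GraphML keeps vertex names and the edge confidence attribute, so a
#' graph written with \code{writeGraphML} and read back with
#' \code{readGraphML} is identical in node set, edge set and
#' confidences.
#'
#' @param g a \code{PPIGraph}.
#' @param path file path.
#' @return \code{writeGraphML}: \code{path} invisibly;
#'   \code{readGraphML}: a \code{PPIGraph}.
#' @export
writeGraphML <- function(g, path) {
    stopifnot(is(g, "PPIGraph"))
    igraph::write_graph(g@graph, path, format = "graphml")
    invisible(path)
}

#' @rdname writeGraphML
#' @export
readGraphML <- function(path) {
    g <- igraph::read_graph(path, format = "graphml")
    if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$id))
        igraph::V(g)$name <- igraph::V(g)$id
    g <- igraph::delete_vertex_attr(g, "id")
    new("PPIGraph", graph = g)
}

#' Delete nodes (and incident edges) from a graph
#'
#' @param g a \code{PPIGraph}.
#' @param nodes character vector of node symbols to remove.
#' @return the reduced \code{PPIGraph}.
#' @export
deleteNodes <- function(g, nodes) {
    stopifnot(is(g, "PPIGraph"))
    missing <- setdiff(nodes, nodeNames(g))
    if (length(missing))
        stop("node(s) not in graph: ", paste(missing, collapse = ", "))
    new("PPIGraph", graph = igraph::delete_vertices(g@graph, nodes))
}
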