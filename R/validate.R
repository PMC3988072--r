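#' Design the leave-1-to-4-node deletion scheme
#'
#' Builds the test-network design used to assess hub robustness. At
#' level 1 every pool member is deleted once (|pool| singleton sets).
#' At each level k >= 2, for every hub and each of \code{repeats}
#' repeats, one set is formed from that hub plus k-1 further nodes
#' sampled without replacement from the remainder of the pool. With the
#' defaults (pool of 22 top-ranked nodes, 5 hubs, 5 repeats, levels
#' 1-4) this yields 22 + 3 x 25 = 97 test networks.
#'
#' @param pool character vector of top-ranked candidate symbols
#'   (conventionally the top 22 by the canonical ranking).
#' @param hubs character vector of designated hub symbols, a subset of
#'   \code{pool}.
#' @param repeats repeats per hub at levels >= 2 (default 5).
#' @param levels integer deletion levels, subset of 1:4 (default 1:4).
#' @param seed integer RNG seed; the whole design is reproducible given
#'   the seed.
#' @return a \code{\link{DeletionDesign}}.
#' @export
designDeletions <- function(pool, hubs, repeats = 5L, levels = 1:4,
                            seed = 1L) {
    pool <- as.character(pool); hubs <- as.character(hubs)
    if (anyDuplicated(pool)) stop("pool contains duplicate symbols")
    missing <- setdiff(hubs, pool)
    if (length(missing))
        stop("hub(s) not in pool: ", paste(missing, collapse = ", "))
    repeats <- as.integer(repeats)
    if (repeats < 1L) stop("'repeats' must be >= 1")
    levels <- sort(unique(as.integer(levels)))
    if (!all(levels %in% 1:4))
        stop("'levels' must be a subset of 1:4")
    if (max(levels) - 1L > length(pool) - 1L)
        stop("pool too small for deletion level ", max(levels))
    set.seed(as.integer(seed))
    sets <- list()
    for (k in levels) {
        if (k == 1L) {
            sets[["1"]] <- lapply(pool, function(p) p)
        } else {
            lev <- list()
            for (h in hubs) {
                others <- setdiff(pool, h)
                for (r in seq_len(repeats))
                    lev[[length(lev) + 1L]] <-
                        c(h, sample(others, k - 1L))
            }
            sets[[as.character(k)]] <- lev
        }
    }
    new("DeletionDesign", sets = sets, pool = pool, hubs = hubs,
        repeats = repeats, seed = as.integer(seed))
}

#' Top-5 nodes of a test network
#'
#' Removes the given nodes (and incident edges) from the graph,
#' recomputes degree and betweenness centrality on the reduced graph,
#' and returns the first five nodes of the canonical ranking.
#'
#' @param g the main \code{\link{PPIGraph}}.
#' @param deletion character vector of node symbols to remove.
#' @param topN how many top-ranked nodes to report (default 5).
#' @return character vector of length \code{topN}.
#' @export
runTestNetwork <- function(g, deletion, topN = 5L) {
    stopifnot(is(g, "PPIGraph"))
    if (nodeCount(g) - length(deletion) < topN)
        stop("fewer than ", topN, " nodes would remain after deletion")
    reduced <- deleteNodes(g, deletion)
    utils::head(rankNodes(nodeStats(reduced)), topN)
}

#' Hub retention frequencies across test networks
#'
#' Counts, per deletion level and per hub, in how many of that level's
#' test networks the hub appears in the recomputed top-5.
#'
#' @param results named list (one element per level, names "1", "2",
#'   ...), each a list of top-5 character vectors as returned by
#'   \code{\link{runTestNetwork}}.
#' @param hubs character vector of hub symbols.
#' @return a \code{\link{RetentionTable}}.
#' @export
retentionFrequencies <- function(results, hubs) {
    if (!length(results)) stop("'results' must be non-empty")
    hubs <- as.character(hubs)
    counts <- vapply(results, function(tops)
        vapply(hubs, function(h)
            sum(vapply(tops, function(x) h %in% x, logical(1))),
            integer(1)),
        integer(length(hubs)))
    freq <- t(matrix(counts, nrow = length(hubs),
                     dimnames = list(hubs, names(results))))
    n <- vapply(results, length, integer(1))
    acc <- rowSums(freq) / (length(hubs) * n)
    new("RetentionTable", frequency = freq, nNetworks = unname(n),
        accuracy = unname(acc))
}

#' Per-level backbone accuracy
#'
#' Accuracy of one deletion level: the proportion of hub slots retained
#' across that level's test networks,
#' sum(frequencies) / (nHubs * nNetworks), rounded to 3 decimals for
#' reporting.
#'
#' @param frequencies integer retention counts, one per hub.
#' @param nNetworks number of test networks at this level.
#' @param nHubs number of hubs in the main network (default 5).
#' @param digits decimals for reporting (default 3); use \code{NULL}
#'   for the unrounded value.
#' @return the accuracy, a proportion in [0, 1].
#' @examples
#' levelAccuracy(c(21, 21, 21, 21, 20), 22)  # 0.945
#' @export
levelAccuracy <- function(frequencies, nNetworks, nHubs = 5L,
                          digits = 3L) {
    if (nNetworks == 0L) stop("'nNetworks' must be positive")
    if (any(frequencies < 0) || any(frequencies > nNetworks))
        stop("frequencies must lie in [0, nNetworks]")
    acc <- sum(frequencies) / (nHubs * nNetworks)
    if (is.null(digits)) acc else round(acc, digits)
}

#' Overall backbone accuracy
#'
#' Unweighted arithmetic mean of the per-level accuracies (not the
#' pooled ratio of summed frequencies).
#'
#' @param levelAccuracies numeric vector of per-level accuracies.
#' @return the mean accuracy (unrounded).
#' @examples
#' overallAccuracy(c(0.945, 0.792, 0.696, 0.672))  # 0.77625
#' @export
overallAccuracy <- function(levelAccuracies) {
    if (!length(levelAccuracies)) stop("no level accuracies given")
    if (any(levelAccuracies < 0 | levelAccuracies > 1))
        stop("accuracies must lie in [0, 1]")
    mean(levelAccuracies)
}

#' Run the full hub-robustness validation
#'
#' Convenience driver: ranks the nodes of \code{g}, takes the top
#' \code{poolSize} as the deletion pool, builds the deletion design,
#' recomputes the top-5 of every test network, and tabulates hub
#' retention and accuracy.
#'
#' @param g the main \code{\link{PPIGraph}}.
#' @param hubs character vector of hub symbols (default: top 5 of the
#'   canonical ranking).
#' @param poolSize size of the deletion candidate pool (default 22).
#' @param repeats,levels,seed passed to \code{\link{designDeletions}}.
#' @return list with elements \code{design} (\code{DeletionDesign}),
#'   \code{results} (per-level top-5 lists), \code{retention}
#'   (\code{RetentionTable}) and \code{overall} (mean accuracy).
#' @export
runValidation <- function(g, hubs = NULL, poolSize = 22L, repeats = 5L,
                          levels = 1:4, seed = 1L) {
    stopifnot(is(g, "PPIGraph"))
    ranked <- rankNodes(nodeStats(g))
    if (length(ranked) < poolSize)
        stop("graph has fewer than ", poolSize, " nodes")
    pool <- ranked[seq_len(poolSize)]
    if (is.null(hubs)) hubs <- ranked[1:5]
    design <- designDeletions(pool, hubs, repeats = repeats,
                              levels = levels, seed = seed)
    results <- lapply(design@sets, function(lev)
        lapply(lev, function(del) runTestNetwork(g, del)))
    retention <- retentionFrequencies(results, hubs)
    list(design = design, results = results, retention = retention,
         overall = overallAccuracy(retention@accuracy))
}

#' Write a retention/accuracy table to TSV
#'
#' Emits the per-level hub frequencies, accuracy and network counts
#' (plus an Overall row) in a tab-separated file.
#'
#' @param retention a \code{\link{RetentionTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRetentionTSV <- function(retention, path) {
    stopifnot(is(retention, "RetentionTable"))
    utils::write.table(accuracyTable(retention), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
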