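# Independent oracles used to cross-check the implementation. These are
# deliberately written from first principles (explicit path enumeration,
# textbook formulas) and share no code path with the package.

# ---- graph fixtures -----------------------------------------------------

# PPIGraph from a 0/1 adjacency matrix (confidence 1 on every edge)
ppiFromAdj <- function(adj, names = NULL) {
    n <- nrow(adj)
    if (is.null(names)) names <- sprintf("N%02d", seq_len(n))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- names
    if (igraph::ecount(g) > 0) igraph::E(g)$confidence <- 1
    new("PPIGraph", graph = g)
}

# PPIGraph from an explicit edge data.frame, default confidence 1
ppiFromEdges <- function(a, b, conf = 1) {
    buildGraph(data.frame(node_a = a, node_b = b,
                          score = rep_len(conf, length(a))),
               minConfidence = 0)
}

adjFromPPI <- function(g) {
    m <- as.matrix(igraph::as_adjacency_matrix(asIgraph(g)))
    m[m > 1] <- 1
    m
}

# all connected labelled graphs on n nodes, as adjacency matrices
allConnectedAdj <- function(n) {
    pairs <- utils::combn(n, 2)
    nE <- ncol(pairs)
    out <- list()
    for (mask in seq_len(2^nE) - 1L) {
        adj <- matrix(0L, n, n)
        for (e in seq_len(nE)) {
            if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) != 0L) {
                adj[pairs[1, e], pairs[2, e]] <- 1L
                adj[pairs[2, e], pairs[1, e]] <- 1L
            }
        }
        if (isConnectedAdj(adj)) out[[length(out) + 1L]] <- adj
    }
    out
}

isConnectedAdj <- function(adj) {
    n <- nrow(adj)
    seen <- rep(FALSE, n); seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
        nxt <- unique(unlist(lapply(frontier, function(u) which(adj[u, ] == 1))))
        nxt <- nxt[!seen[nxt]]
        seen[nxt] <- TRUE
        frontier <- nxt
    }
    all(seen)
}

randomConnectedAdj <- function(n, p) {
    repeat {
        adj <- matrix(0L, n, n)
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
        }
        if (isConnectedAdj(adj)) return(adj)
    }
}

# ---- betweenness oracle: explicit shortest-path enumeration -------------

bfsDistances <- function(adj) {
    n <- nrow(adj)
    dist <- matrix(Inf, n, n); diag(dist) <- 0
    for (s in seq_len(n)) {
        frontier <- s; d <- 0
        while (length(frontier)) {
            d <- d + 1
            nxt <- unique(unlist(lapply(frontier,
                                        function(u) which(adj[u, ] == 1))))
            nxt <- nxt[!is.finite(dist[s, nxt])]
            dist[s, nxt] <- d
            frontier <- nxt
        }
    }
    dist
}

# every shortest path between a pair, by depth-bounded DFS
enumerateShortestPaths <- function(adj, s, t, len) {
    paths <- list()
    rec <- function(path) {
        u <- path[length(path)]
        if (u == t) {
            if (length(path) - 1L == len)
                paths[[length(paths) + 1L]] <<- path
            return(invisible())
        }
        if (length(path) - 1L >= len) return(invisible())
        for (v in which(adj[u, ] == 1))
            if (!(v %in% path)) rec(c(path, v))
        invisible()
    }
    rec(s)
    paths
}

# normalized betweenness by brute force, normalizer (n-1)(n-2)/2
bcOracle <- function(adj) {
    n <- nrow(adj)
    bc <- numeric(n)
    if (n < 3) return(bc)
    dist <- bfsDistances(adj)
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        if (!is.finite(dist[s, t]) || dist[s, t] == 0) next
        paths <- enumerateShortestPaths(adj, s, t, dist[s, t])
        sigma <- length(paths)
        for (v in seq_len(n)) {
            if (v == s || v == t) next
            through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
            bc[v] <- bc[v] + through / sigma
        }
    }
    bc / ((n - 1) * (n - 2) / 2)
}

# ---- regression / test-statistic oracles --------------------------------

lsFitOracle <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sxy <- sum((x - mx) * (y - my))
    sxx <- sum((x - mx)^2)
    syy <- sum((y - my)^2)
    b <- sxy / sxx
    list(intercept = my - b * mx, slope = b, r2 = sxy^2 / (sxx * syy))
}

tTestOracle <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
        (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

pearsonOracle <- function(x, y) {
    n <- length(x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}
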