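test_that("betweenness matches hand-derived values on canonical graphs", {
    path <- ppiFromEdges(c("A", "B"), c("B", "C"))
    bc <- betweennessCentrality(path)
    expect_equal(unname(bc[c("A", "B", "C")]), c(0, 1, 0))

    star <- ppiFromEdges(rep("H", 4), c("L1", "L2", "L3", "L4"))
    bc <- betweennessCentrality(star)
    expect_equal(unname(bc["H"]), 1)
    expect_equal(unname(bc[c("L1", "L2", "L3", "L4")]), rep(0, 4))

    # 5-cycle: brute-force enumeration confirms every node mediates
    # exactly one of the six normalized pair-units
    ring <- ppiFromEdges(c("A", "B", "C", "D", "E"),
                         c("B", "C", "D", "E", "A"))
    bc <- betweennessCentrality(ring)
    expect_equal(unname(bc), rep(1 / 6, 5), tolerance = 1e-12)
    expect_equal(unname(bc), bcOracle(adjFromPPI(ring)), tolerance = 1e-12)
})

test_that("betweenness is zero on complete graphs and bounded in [0,1]", {
    for (n in 3:6) {
        adj <- matrix(1L, n, n); diag(adj) <- 0L
        expect_equal(unname(betweennessCentrality(ppiFromAdj(adj))),
                     rep(0, n))
    }
    set.seed(7)
    for (i in 1:20) {
        g <- ppiFromAdj(randomConnectedAdj(sample(4:15, 1), 0.3))
        bc <- betweennessCentrality(g)
        expect_true(all(bc >= 0 & bc <= 1))
    }
})

test_that("graphs with fewer than 3 nodes give zero betweenness with a warning", {
    pair <- ppiFromEdges("A", "B")
    expect_warning(bc <- betweennessCentrality(pair), "fewer than 3")
    expect_equal(unname(bc), c(0, 0))
})

test_that("betweenness equals the path-enumeration oracle on every connected graph up to 5 nodes", {
    for (n in 3:5) {
        for (adj in allConnectedAdj(n)) {
            g <- ppiFromAdj(adj)
            bc <- betweennessCentrality(g)
            expect_equal(unname(bc), bcOracle(adj), tolerance = 1e-9)
        }
    }
})

test_that("betweenness equals the oracle on random connected graphs of 6 to 8 nodes", {
    set.seed(41)
    for (n in 6:8) {
        for (i in 1:12) {
            adj <- randomConnectedAdj(n, stats::runif(1, 0.25, 0.6))
            bc <- betweennessCentrality(ppiFromAdj(adj))
            expect_equal(unname(bc), bcOracle(adj), tolerance = 1e-9)
        }
    }
})

test_that("betweenness handles disconnected graphs (unreachable pairs contribute 0)", {
    # two triangles, no bridge: all zero; with a bridge the bridge ends rise
    adj <- matrix(0L, 6, 6)
    for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
        adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1L
    bc <- betweennessCentrality(ppiFromAdj(adj))
    expect_equal(unname(bc), bcOracle(adj), tolerance = 1e-12)
    expect_equal(unname(bc), rep(0, 6))
})

test_that("adding a shortcut never raises betweenness of former path mediators", {
    # path A-B-C-D-E; adding the chord A-C cannot increase bc(B)
    pathAdj <- matrix(0L, 5, 5)
    for (i in 1:4) pathAdj[i, i + 1] <- pathAdj[i + 1, i] <- 1L
    before <- betweennessCentrality(ppiFromAdj(pathAdj))
    withChord <- pathAdj; withChord[1, 3] <- withChord[3, 1] <- 1L
    after <- betweennessCentrality(ppiFromAdj(withChord))
    expect_lte(after[2], before[2])
    # and every mediator on longer path graphs
    for (n in 4:8) {
        p <- matrix(0L, n, n)
        for (i in seq_len(n - 1)) p[i, i + 1] <- p[i + 1, i] <- 1L
        b0 <- betweennessCentrality(ppiFromAdj(p))
        q <- p; q[1, n] <- q[n, 1] <- 1L   # close the cycle
        b1 <- betweennessCentrality(ppiFromAdj(q))
        expect_true(all(b1[2:(n - 1)] <= b0[2:(n - 1)] + 1e-12))
    }
})

test_that("power-law fit is exact on data proportional to d^-2", {
    # counts proportional to d^-2 over d in {1,2,4,8}: 64, 16, 4, 1
    degrees <- rep(c(1L, 2L, 4L, 8L), c(64L, 16L, 4L, 1L))
    fit <- fitPowerLaw(degrees)
    expect_equal(fit@rSquared, 1.0, tolerance = 1e-12)
    expect_equal(fit@exponent, -2, tolerance = 1e-12)
    expect_equal(fit@coefficient, 64, tolerance = 1e-9)
})

test_that("power-law fit rejects degenerate degree spectra", {
    expect_error(fitPowerLaw(rep(3L, 10)), "insufficient degree diversity")
    expect_error(fitPowerLaw(c(1L, 1L, 2L, 2L)),
                 "insufficient degree diversity")
})

test_that("power-law fit matches an independent least-squares computation", {
    set.seed(19)
    sim <- simulatePPI(seed = 19)
    fit <- fitPowerLaw(nodeDegrees(sim$graph))
    tab <- table(nodeDegrees(sim$graph))
    tab <- tab[as.integer(names(tab)) >= 1]
    o <- lsFitOracle(log(as.numeric(names(tab))), log(as.numeric(tab)))
    expect_equal(fit@exponent, o$slope, tolerance = 1e-9)
    expect_equal(fit@coefficient, exp(o$intercept), tolerance = 1e-9)
    expect_equal(fit@rSquared, o$r2, tolerance = 1e-9)
})

test_that("nodeStats assembles a valid TopologyStats and TSV round-trips", {
    set.seed(5)
    g <- ppiFromAdj(randomConnectedAdj(12, 0.3))
    st <- nodeStats(g)
    expect_s4_class(st, "TopologyStats")
    s <- statsTable(st)
    expect_setequal(s$node, nodeNames(g))
    expect_equal(sum(s$degree), 2 * edgeCount(g))

    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeStatsTSV(st, tsv)
    st2 <- readStatsTSV(tsv)
    expect_equal(statsTable(st2), s, tolerance = 1e-12)
})
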