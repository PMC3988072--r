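poolFixture <- function() sprintf("P%02d", 1:22)
hubFixture <- function() sprintf("P%02d", 1:5)

test_that("deletion design yields the prescribed combinatorics", {
    d <- designDeletions(poolFixture(), hubFixture(), seed = 9)
    expect_equal(designSize(d), 97L)
    expect_equal(vapply(d@sets, length, integer(1)),
                 c(`1` = 22L, `2` = 25L, `3` = 25L, `4` = 25L))

    d1 <- designDeletions(poolFixture(), hubFixture(), levels = 1, seed = 9)
    expect_equal(designSize(d1), 22L)
    expect_setequal(unlist(deletionSets(d1, 1)), poolFixture())

    # every level-3 set has 3 distinct members and exactly one
    # designated hub for its (hub, repeat) slot
    lvl3 <- deletionSets(d, 3)
    expect_true(all(lengths(lvl3) == 3L))
    expect_true(all(vapply(lvl3, function(s) !anyDuplicated(s), logical(1))))
    designated <- rep(hubFixture(), each = 5L)
    expect_true(all(mapply(function(s, h) h %in% s, lvl3, designated)))
    # non-designated members are drawn from the pool
    expect_true(all(unlist(lvl3) %in% poolFixture()))
})

test_that("deletion design validates inputs and is seed-reproducible", {
    expect_error(designDeletions(poolFixture(), c("P01", "ZZ"), seed = 1),
                 "ZZ")
    expect_error(designDeletions(c("A", "B"), "A", levels = 1:4, seed = 1),
                 "pool too small")
    d1 <- designDeletions(poolFixture(), hubFixture(), seed = 77)
    d2 <- designDeletions(poolFixture(), hubFixture(), seed = 77)
    expect_identical(d1@sets, d2@sets)
    d3 <- designDeletions(poolFixture(), hubFixture(), seed = 78)
    expect_false(identical(d1@sets, d3@sets))
})

test_that("test networks re-rank the reduced graph", {
    set.seed(2)
    sim <- simulatePPI(nNodes = 60, targetEdges = 250, hubDegreeMin = 25,
                       seed = 2)
    g <- sim$graph

    # deleting a hub: it cannot appear in the returned top-5
    top <- runTestNetwork(g, sim$hubs[1])
    expect_false(sim$hubs[1] %in% top)
    expect_length(top, 5L)

    # deleting an isolated node leaves all other statistics unchanged
    gIso <- ppiFromAdj(rbind(cbind(adjFromPPI(g), 0L), 0L),
                       c(nodeNames(g), "LONER"))
    expect_identical(runTestNetwork(gIso, "LONER"),
                     utils::head(rankNodes(nodeStats(g)), 5L))

    # top-5 after deletion matches a brute-force recomputation with the
    # oracle betweenness
    small <- ppiFromAdj(randomConnectedAdj(8, 0.4))
    del <- nodeNames(small)[1]
    top <- runTestNetwork(small, del)
    keep <- setdiff(nodeNames(small), del)
    adj <- adjFromPPI(small)[keep, keep]
    oracleBc <- bcOracle(adj)
    oracleDeg <- rowSums(adj)
    ord <- order(-oracleBc, -oracleDeg, keep)
    expect_identical(top, keep[ord][1:5])

    expect_error(runTestNetwork(small, nodeNames(small)[1:4]),
                 "fewer than 5")
})

test_that("retention frequencies tally hub membership per level", {
    hubs <- c("H1", "H2")
    results <- list(
        `1` = list(c("H1", "H2", "A", "B", "C"),
                   c("H1", "A", "B", "C", "D"),
                   c("A", "B", "C", "D", "E")),
        `2` = list(c("H2", "A", "B", "C", "D")))
    rt <- retentionFrequencies(results, hubs)
    # hand tally: level 1 retains H1 twice and H2 once; level 2
    # retains only H2
    expect_identical(rt@frequency,
                     matrix(c(2L, 1L, 0L, 1L), 2, 2, byrow = TRUE,
                            dimnames = list(c("1", "2"), hubs)))
    expect_equal(rt@nNetworks, c(3L, 1L))
    expect_equal(rt@accuracy, c(3 / 6, 1 / 2))

    # single-hub tally keeps the level-by-hub orientation
    one <- retentionFrequencies(results, "H1")
    expect_identical(dim(one@frequency), c(2L, 1L))
    expect_equal(unname(one@frequency[, 1]), c(2L, 0L))
})

test_that("level accuracy reproduces the worked frequency rows", {
    fx <- retentionFixture()
    acc <- mapply(function(i) levelAccuracy(fx$freq[i, ], fx$n[i]), 1:4)
    expect_equal(acc, c(0.945, 0.792, 0.696, 0.672))
    expect_equal(levelAccuracy(rep(25L, 5), 25L), 1.0)
    expect_error(levelAccuracy(c(1, 2), 0), "positive")
    expect_error(levelAccuracy(c(26, 2, 2, 2, 2), 25), "frequencies")
})

test_that("overall accuracy is the unweighted mean of level accuracies", {
    expect_equal(round(overallAccuracy(c(0.945, 0.792, 0.696, 0.672)), 3),
                 0.776)
    expect_equal(overallAccuracy(0.5), 0.5)
    # the pooled-ratio alternative would give a different number
    fx <- retentionFixture()
    pooled <- sum(fx$freq) / (5 * sum(fx$n))
    unroundedLevels <- mapply(
        function(i) levelAccuracy(fx$freq[i, ], fx$n[i], digits = NULL), 1:4)
    expect_gt(abs(overallAccuracy(unroundedLevels) - pooled), 0.004)
})

test_that("full validation run is reproducible with bounded accuracy", {
    sim <- simulatePPI(seed = 12)
    v1 <- runValidation(sim$graph, seed = 12)
    v2 <- runValidation(sim$graph, seed = 12)
    expect_identical(accuracyTable(v1$retention),
                     accuracyTable(v2$retention))
    expect_true(all(v1$retention@accuracy >= 0 &
                    v1$retention@accuracy <= 1))
    expect_gte(v1$overall, 0)
    expect_lte(v1$overall, 1)

    # a hub's frequency is capped by the networks that do not delete it
    for (lev in names(v1$design@sets)) {
        sets <- v1$design@sets[[lev]]
        for (h in colnames(v1$retention@frequency)) {
            deleted <- sum(vapply(sets, function(s) h %in% s, logical(1)))
            expect_lte(v1$retention@frequency[lev, h],
                       length(sets) - deleted)
        }
    }

    # level-1: each hub is deleted in exactly one of the 22 networks
    lvl1 <- v1$design@sets[["1"]]
    hubs <- colnames(v1$retention@frequency)
    expect_true(all(vapply(hubs, function(h)
        sum(vapply(lvl1, function(s) h %in% s, logical(1))) == 1L,
        logical(1))))
})
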