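ctFixture <- function() {
    # 3 cases + 3 controls, one target gene + reference, duplicates
    samples <- c("C1", "C2", "C3", "K1", "K2", "K3")
    groups <- rep(c("case", "control"), each = 3)
    tgt <- c(24.0, 24.5, 23.8, 26.0, 26.2, 25.9)
    ref <- rep(25, 6)
    rbind(
        data.frame(sample = rep(samples, each = 2), group = rep(groups, each = 2),
                   gene = "IL6", replicate = rep(1:2, 6),
                   ct = rep(tgt, each = 2) + c(-0.05, 0.05)),
        data.frame(sample = rep(samples, each = 2), group = rep(groups, each = 2),
                   gene = "GUSB", replicate = rep(1:2, 6),
                   ct = rep(ref, each = 2) + c(-0.05, 0.05)))
}

test_that("replicate QC averages tight duplicates and flags dispersed ones", {
    expect_equal(replicateQC(c(24.0, 24.2))$ct, 24.1)
    expect_false(replicateQC(c(24.0, 24.2))$flagged)
    qc <- replicateQC(c(24.0, 26.0))       # sd ~ 1.41 > 0.5
    expect_true(qc$flagged)
    expect_true(is.na(qc$ct))
    expect_warning(qc1 <- replicateQC(25.0), "single replicate")
    expect_equal(qc1$ct, 25.0)
})

test_that("delta-Ct is the target minus reference difference", {
    expect_equal(deltaCt(25, 25), 0)
    expect_equal(deltaCt(28, 25), 3)
    expect_equal(deltaCt(23.5, 25), -1.5)
    expect_error(deltaCt(NA, 25), "finite")
})

test_that("delta-Ct table normalizes per sample and names missing references", {
    col <- collapseReplicates(ctFixture())
    dct <- deltaCtTable(col)
    expect_equal(dct$dct[dct$sample == "C1"], -1.0, tolerance = 1e-9)
    expect_equal(dct$dct[dct$sample == "K1"], 1.0, tolerance = 1e-9)

    noRef <- ctFixture()
    noRef <- noRef[!(noRef$gene == "GUSB" & noRef$sample == "K2"), ]
    expect_error(deltaCtTable(collapseReplicates(noRef)), "K2")
})

test_that("2^-ddCt identities hold", {
    expect_equal(relativeExpression(5, 5), 1.0)   # calibrator identity
    expect_equal(relativeExpression(6, 5), 0.5)   # ddCt = 1
    expect_equal(relativeExpression(3, 5), 4.0)   # ddCt = -2
})

test_that("a designated calibrator sample has fold change exactly 1", {
    col <- collapseReplicates(ctFixture())
    dct <- deltaCtTable(col)
    rel <- relativeExpressionTable(dct, calibrator = "K1")
    expect_equal(rel$rel_expr[rel$sample == "K1"], 1.0)
    expect_error(relativeExpressionTable(dct, calibrator = "NOPE"),
                 "NOPE")
})

test_that("lowering a target Ct by one cycle doubles relative expression", {
    base <- ctFixture()
    shifted <- base
    sel <- shifted$gene == "IL6" & shifted$sample == "C1"
    shifted$ct[sel] <- shifted$ct[sel] - 1
    rel0 <- relativeExpressionTable(deltaCtTable(collapseReplicates(base)))
    rel1 <- relativeExpressionTable(deltaCtTable(collapseReplicates(shifted)))
    r0 <- rel0$rel_expr[rel0$sample == "C1"]
    r1 <- rel1$rel_expr[rel1$sample == "C1"]
    expect_equal(r1 / r0, 2, tolerance = 1e-9)
})

test_that("group comparison matches the textbook pooled t-test", {
    cmp <- compareGroups(c(1, 2, 3), c(1, 2, 3))
    expect_equal(cmp$t, 0)
    expect_equal(cmp$p, 1)

    x <- c(2.1, 2.3, 1.9, 2.2); y <- c(1.0, 1.2, 0.9, 1.1)
    cmp <- compareGroups(x, y)
    o <- tTestOracle(x, y)
    expect_equal(cmp$t, o$t, tolerance = 1e-9)
    expect_equal(cmp$p, o$p, tolerance = 1e-9)
    expect_equal(cmp$sem_case, stats::sd(x) / 2, tolerance = 1e-12)

    expect_error(compareGroups(1, c(1, 2)), "at least 2")
})

test_that("correlation matrix is symmetric with unit diagonal and oracle-exact", {
    set.seed(6)
    m <- cbind(g1 = rnorm(20), g2 = rnorm(20))
    m <- cbind(m, dup = m[, "g1"], neg = -m[, "g1"], const = 5)
    cm <- correlationMatrix(m)
    expect_equal(cm$r["g1", "dup"], 1)
    expect_equal(cm$r["g1", "neg"], -1)
    expect_true(all(is.na(cm$r["const", ])))
    expect_equal(cm$r, t(cm$r))
    expect_equal(unname(diag(cm$r)[1:4]), rep(1, 4))

    o <- pearsonOracle(m[, "g1"], m[, "g2"])
    expect_equal(cm$r["g1", "g2"], o$r, tolerance = 1e-9)
    expect_equal(cm$p["g1", "g2"], o$p, tolerance = 1e-9)
})

test_that("correlation accepts the long table format", {
    set.seed(8)
    ct <- simulateCt(seed = 8, nCases = 10, nControls = 10)
    rel <- relativeExpressionTable(deltaCtTable(collapseReplicates(ct)))
    cm <- correlationMatrix(rel)
    genes <- sort(unique(rel$gene))
    expect_identical(colnames(cm$r), genes)
    wide <- do.call(cbind, lapply(genes, function(g)
        rel$rel_expr[rel$gene == g][order(rel$sample[rel$gene == g])]))
    expect_equal(unname(cm$r["IL6", "TNF"]),
                 pearsonOracle(wide[, which(genes == "IL6")],
                               wide[, which(genes == "TNF")])$r,
                 tolerance = 1e-9)
})

test_that("persistent delta-Ct outliers are excluded", {
    set.seed(9)
    ct <- simulateCt(seed = 9, nCases = 20, nControls = 20)
    dct <- deltaCtTable(collapseReplicates(ct))
    spoiled <- dct
    idx <- which(spoiled$group == "case" & spoiled$gene == "IL6")[1]
    spoiled$dct[idx] <- spoiled$dct[idx] + 50
    expect_message(clean <- dropDctOutliers(spoiled), "outlier")
    expect_equal(nrow(clean), nrow(spoiled) - 1L)
    expect_true(all(clean$dct < 40))
    expect_equal(nrow(dropDctOutliers(dct[dct$gene == "IL6" &
                                          dct$group == "case", ])),
                 sum(dct$gene == "IL6" & dct$group == "case"))
})

test_that("Ct CSV round-trips", {
    ct <- simulateCt(seed = 3, nCases = 4, nControls = 4)
    csv <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(ct, csv, row.names = FALSE)
    back <- readCtTable(csv)
    expect_equal(back$ct, ct$ct, tolerance = 1e-12)
})
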