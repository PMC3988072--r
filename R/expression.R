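#' Collapse technical qPCR replicates with a dispersion QC
#'
#' Averages the replicate threshold cycles of one sample x gene well
#' group; groups whose replicate standard deviation exceeds
#' \code{sdCut} cycles are flagged as outliers and excluded downstream.
#'
#' @param cts numeric vector of replicate Ct values for one sample and
#'   gene.
#' @param sdCut maximum tolerated replicate standard deviation in
#'   cycles (default 0.5).
#' @return list with \code{ct} (mean Ct, \code{NA} when flagged) and
#'   \code{flagged} (logical). A single replicate is accepted with a
#'   warning.
#' @export
replicateQC <- function(cts, sdCut = 0.5) {
    cts <- cts[is.finite(cts)]
    if (!length(cts)) stop("no finite Ct replicates")
    if (length(cts) == 1L) {
        warning("single replicate; no dispersion check possible")
        return(list(ct = cts, flagged = FALSE))
    }
    s <- stats::sd(cts)
    if (s > sdCut) list(ct = NA_real_, flagged = TRUE)
    else list(ct = mean(cts), flagged = FALSE)
}

#' Collapse a long Ct table over replicates
#'
#' Applies \code{\link{replicateQC}} to every sample x gene group of a
#' long-format Ct table.
#'
#' @param ct \code{data.frame} with columns \code{sample}, \code{group},
#'   \code{gene}, \code{replicate}, \code{ct}.
#' @param sdCut replicate standard-deviation cutoff in cycles.
#' @return \code{data.frame} with columns sample, group, gene, ct,
#'   flagged; flagged wells have \code{ct = NA}.
#' @export
collapseReplicates <- function(ct, sdCut = 0.5) {
    need <- c("sample", "group", "gene", "replicate", "ct")
    if (!is.data.frame(ct) || !all(need %in% names(ct)))
        stop("'ct' must have columns ", paste(need, collapse = ", "))
    key <- interaction(ct$sample, ct$gene, drop = TRUE)
    pieces <- lapply(split(ct, key), function(d) {
        qc <- suppressWarnings(replicateQC(d$ct, sdCut))
        data.frame(sample = d$sample[1L], group = d$group[1L],
                   gene = d$gene[1L], ct = qc$ct, flagged = qc$flagged)
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out[order(out$sample, out$gene), , drop = FALSE]
}

#' Delta-Ct of a target against the endogenous reference
#'
#' @param ctTarget target-gene Ct.
#' @param ctReference reference-gene Ct of the same sample (e.g. GUSB).
#' @return \code{ctTarget - ctReference}.
#' @export
deltaCt <- function(ctTarget, ctReference) {
    if (any(!is.finite(ctTarget)) || any(!is.finite(ctReference)))
        stop("Ct values must be finite")
    ctTarget - ctReference
}

#' Per-sample delta-Ct table
#'
#' Normalizes every target gene's Ct to the endogenous reference gene of
#' the same sample; target wells flagged by replicate QC are dropped.
#' Samples whose reference well was measured but failed replicate QC are
#' dropped entirely (with a message); samples for which the reference
#' gene was never measured raise an error naming them.
#'
#' @param collapsed output of \code{\link{collapseReplicates}}.
#' @param referenceGene symbol of the endogenous control (default
#'   \code{"GUSB"}).
#' @return \code{data.frame} with columns sample, group, gene, dct.
#' @export
deltaCtTable <- function(collapsed, referenceGene = "GUSB") {
    refAll <- collapsed[collapsed$gene == referenceGene, , drop = FALSE]
    missing <- setdiff(unique(collapsed$sample), refAll$sample)
    if (length(missing))
        stop("reference gene '", referenceGene, "' missing for sample(s): ",
             paste(utils::head(missing, 5L), collapse = ", "))
    qcDropped <- refAll$sample[refAll$flagged | !is.finite(refAll$ct)]
    if (length(qcDropped))
        message("dropping sample(s) with QC-flagged reference wells: ",
                paste(utils::head(qcDropped, 5L), collapse = ", "))
    d <- collapsed[!collapsed$flagged & is.finite(collapsed$ct) &
                   !collapsed$sample %in% qcDropped, , drop = FALSE]
    ref <- d[d$gene == referenceGene, c("sample", "ct")]
    tgt <- d[d$gene != referenceGene, , drop = FALSE]
    tgt$dct <- tgt$ct - ref$ct[match(tgt$sample, ref$sample)]
    tgt[c("sample", "group", "gene", "dct")]
}

#' Drop persistent delta-Ct outliers
#'
#' Removes sample x gene delta-Ct values further than \code{nSd} group
#' standard deviations from their (group, gene) mean, reporting the
#' exclusions via \code{message}.
#'
#' @param dct output of \code{\link{deltaCtTable}}.
#' @param nSd exclusion threshold in group standard deviations
#'   (default 3).
#' @return the filtered \code{data.frame}.
#' @export
dropDctOutliers <- function(dct, nSd = 3) {
    key <- interaction(dct$group, dct$gene, drop = TRUE)
    keep <- unsplit(lapply(split(dct$dct, key), function(x) {
        if (length(x) < 3L) return(rep(TRUE, length(x)))
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0) rep(TRUE, length(x))
        else abs(x - mean(x)) <= nSd * s
    }), key)
    if (any(!keep))
        message(sum(!keep), " persistent outlier value(s) excluded")
    dct[keep, , drop = FALSE]
}

#' Relative expression by the comparative Ct method
#'
#' Fold change of one sample against the calibrator,
#' \code{2^-(dctSample - dctCalibrator)}, under the efficiency-2
#' (doubling per cycle) assumption.
#'
#' @param dctSample delta-Ct of the sample.
#' @param dctCalibrator delta-Ct of the calibrator.
#' @return fold change \code{2^-ddCt}, a positive number; 1 when the
#'   sample is its own calibrator.
#' @export
relativeExpression <- function(dctSample, dctCalibrator) {
    if (any(!is.finite(dctSample)) || any(!is.finite(dctCalibrator)))
        stop("delta-Ct values must be finite")
    2^-(dctSample - dctCalibrator)
}

#' Per-sample relative-expression table
#'
#' Scales every sample's delta-Ct against a calibrator: either a named
#' calibrator sample (whose fold change is then exactly 1 for every
#' gene) or, by default, the pooled mean control-group delta-Ct of each
#' gene.
#'
#' @param dct output of \code{\link{deltaCtTable}} (optionally filtered
#'   by \code{\link{dropDctOutliers}}).
#' @param calibrator a sample identifier, or \code{NULL} (default) for
#'   the pooled mean control delta-Ct per gene.
#' @param controlGroup label of the control group (default
#'   \code{"control"}), used for the pooled calibrator.
#' @return \code{data.frame} with columns sample, group, gene,
#'   rel_expr.
#' @export
relativeExpressionTable <- function(dct, calibrator = NULL,
                                    controlGroup = "control") {
    if (!is.null(calibrator)) {
        cal <- dct[dct$sample == calibrator, c("gene", "dct")]
        if (nrow(cal) == 0L)
            stop("calibrator sample '", calibrator, "' not found")
        calRef <- stats::setNames(cal$dct, cal$gene)
    } else {
        ctrl <- dct[dct$group == controlGroup, , drop = FALSE]
        if (nrow(ctrl) == 0L)
            stop("no samples in control group '", controlGroup,
                 "' to form the pooled calibrator")
        calRef <- vapply(split(ctrl$dct, ctrl$gene), mean, numeric(1))
    }
    ref <- calRef[dct$gene]
    if (anyNA(ref))
        stop("no calibrator delta-Ct for gene(s): ",
             paste(unique(dct$gene[is.na(ref)]), collapse = ", "))
    out <- dct[c("sample", "group", "gene")]
    out$rel_expr <- relativeExpression(dct$dct, unname(ref))
    out
}

#' Compare case and control expression with Student's t-test
#'
#' Two-sided equal-variance t-test plus group means and standard errors
#' of the mean.
#'
#' @param caseValues numeric expression values of the cases (>= 2).
#' @param controlValues numeric expression values of the controls
#'   (>= 2).
#' @return list with \code{mean_case}, \code{sem_case},
#'   \code{mean_control}, \code{sem_control}, \code{t}, \code{p}.
#' @export
compareGroups <- function(caseValues, controlValues) {
    if (length(caseValues) < 2L || length(controlValues) < 2L)
        stop("need at least 2 values per group")
    tt <- stats::t.test(caseValues, controlValues, var.equal = TRUE)
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    list(mean_case = mean(caseValues), sem_case = sem(caseValues),
         mean_control = mean(controlValues),
         sem_control = sem(controlValues),
         t = unname(tt$statistic), p = tt$p.value)
}

#' Per-gene case/control comparison table
#'
#' Applies \code{\link{compareGroups}} to every gene of a long
#' relative-expression table.
#'
#' @param relExpr output of \code{\link{relativeExpressionTable}}.
#' @param caseGroup,controlGroup group labels (defaults \code{"case"},
#'   \code{"control"}).
#' @return \code{data.frame} with one row per gene: mean +/- SEM per
#'   group, fold change of group means, t and p.
#' @export
groupComparisonTable <- function(relExpr, caseGroup = "case",
                                 controlGroup = "control") {
    genes <- sort(unique(relExpr$gene))
    rows <- lapply(genes, function(g) {
        d <- relExpr[relExpr$gene == g, , drop = FALSE]
        cmp <- compareGroups(d$rel_expr[d$group == caseGroup],
                             d$rel_expr[d$group == controlGroup])
        data.frame(gene = g, mean_case = cmp$mean_case,
                   sem_case = cmp$sem_case,
                   mean_control = cmp$mean_control,
                   sem_control = cmp$sem_control,
                   fold_change = cmp$mean_case / cmp$mean_control,
                   t = cmp$t, p = cmp$p)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Pairwise Pearson correlation of gene expression
#'
#' Symmetric gene x gene Pearson correlation matrix with pairwise
#' two-sided p-values. Pairs with fewer than 3 complete samples or a
#' constant column are reported as \code{NA}.
#'
#' @param relExpr long relative-expression table (sample, gene,
#'   rel_expr), or a numeric sample x gene matrix.
#' @return list with matrices \code{r} (diagonal 1 where defined) and
#'   \code{p} (diagonal \code{NA}).
#' @export
correlationMatrix <- function(relExpr) {
    if (is.data.frame(relExpr)) {
        wide <- stats::xtabs(rel_expr ~ sample + gene, data = relExpr,
                             sparse = FALSE)
        present <- stats::xtabs(~ sample + gene, data = relExpr) > 0
        wide[!present] <- NA
        m <- as.matrix(unclass(wide))
    } else m <- as.matrix(relExpr)
    genes <- colnames(m)
    k <- length(genes)
    r <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
    p <- r
    for (i in seq_len(k)) for (j in seq_len(k)) {
        if (j < i) next
        ok <- is.finite(m[, i]) & is.finite(m[, j])
        if (sum(ok) < 3L) next
        if (i == j) {
            if (stats::sd(m[ok, i]) > 0) r[i, i] <- 1
            next
        }
        if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) next
        ct <- stats::cor.test(m[ok, i], m[ok, j], method = "pearson")
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
    }
    list(r = r, p = p)
}

#' Read a long-format Ct table from CSV
#'
#' Columns: \code{sample}, \code{group}, \code{gene}, \code{replicate},
#' \code{ct}.
#'
#' @param path CSV file path.
#' @return \code{data.frame}.
#' @export
readCtTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample", "group", "gene", "replicate", "ct")
    if (!all(need %in% names(df)))
        stop("Ct table must have columns ", paste(need, collapse = ", "))
    df
}
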