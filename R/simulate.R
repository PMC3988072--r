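#' Default qPCR simulation gene panel
#'
#' Eight inflammatory genes with the per-gene case/control fold changes
#' and control-group delta-Ct baselines the Ct generator emulates by
#' default. Fold changes are ratios of typical case and control mean
#' relative-expression levels for these markers in whole blood
#' (IL6 2.08/1.48, VEGFA 1.91/1.15, IL1B 1.19/0.93, TNF 1.93/1.26,
#' PTGS2 6.12/1.63, NFKB1 0.31/0.21, STAT3 0.61/0.41, JUN 2.95/1.43);
#' baselines are 6 - log2(control level) so simulated magnitudes track
#' those levels.
#'
#' @return \code{data.frame} with columns gene, control_dct,
#'   fold_change.
#' @export
defaultCtPanel <- function() {
    ctrl <- c(IL6 = 1.48, VEGFA = 1.15, IL1B = 0.93, TNF = 1.26,
              PTGS2 = 1.63, NFKB1 = 0.21, STAT3 = 0.41, JUN = 1.43)
    case <- c(IL6 = 2.08, VEGFA = 1.91, IL1B = 1.19, TNF = 1.93,
              PTGS2 = 6.12, NFKB1 = 0.31, STAT3 = 0.61, JUN = 2.95)
    data.frame(gene = names(ctrl),
               control_dct = 6 - log2(unname(ctrl)),
               fold_change = unname(case / ctrl))
}

#' Simulate a scale-free PPI network with planted hubs
#'
#' Grows an undirected simple graph by preferential attachment (the
#' standard scale-free emulator), designates the \code{nHubs}
#' highest-degree nodes as hubs and wires additional random edges to
#' each until its degree exceeds \code{hubDegreeMin}, then tops up with
#' random edges until the edge count reaches \code{targetEdges} (within
#' 2\%). Edge confidences are drawn uniformly from [0.7, 1]. The result
#' is connected and bit-reproducible given the seed. Defaults emulate a
#' 145-node / 1234-edge high-confidence interaction network with 5
#' dominant hubs.
#'
#' @param nNodes number of nodes (default 145).
#' @param targetEdges target edge count (default 1234).
#' @param nHubs number of planted hubs (default 5); 0 gives a plain
#'   preferential-attachment graph.
#' @param hubDegreeMin every planted hub ends with degree strictly
#'   above this (default 55).
#' @param attachmentEdges preferential-attachment edges per added node;
#'   default scales so growth plus hub boosting lands near
#'   \code{targetEdges}.
#' @param seed integer RNG seed.
#' @return list with \code{graph} (a \code{\link{PPIGraph}}) and
#'   \code{hubs} (character vector of planted hub symbols).
#' @export
simulatePPI <- function(nNodes = 145L, targetEdges = 1234L, nHubs = 5L,
                        hubDegreeMin = 55L, attachmentEdges = NULL,
                        seed = 1L) {
    nNodes <- as.integer(nNodes); targetEdges <- as.integer(targetEdges)
    if (nHubs >= nNodes) stop("nHubs must be smaller than nNodes")
    if (targetEdges > nNodes * (nNodes - 1L) / 2L)
        stop("targetEdges exceeds the complete graph")
    if (nHubs > 0L && hubDegreeMin >= nNodes)
        stop("hubDegreeMin infeasible for this node count")
    if (is.null(attachmentEdges))
        attachmentEdges <- max(1L, floor(
            (targetEdges - nHubs * hubDegreeMin) / nNodes))
    set.seed(as.integer(seed))
    g <- igraph::sample_pa(nNodes, power = 1, m = attachmentEdges,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("G%03d", seq_len(nNodes))
    deg <- igraph::degree(g)
    hubs <- character(0)
    if (nHubs > 0L) {
        hubs <- names(sort(deg, decreasing = TRUE))[seq_len(nHubs)]
        for (h in hubs) {
            while (igraph::degree(g, h) <= hubDegreeMin) {
                cand <- setdiff(igraph::V(g)$name,
                                c(h, names(igraph::neighbors(g, h))))
                if (!length(cand)) break
                need <- hubDegreeMin + 1L - igraph::degree(g, h)
                pick <- sample(cand, min(need, length(cand)))
                g <- igraph::add_edges(g, rbind(h, pick))
            }
        }
    }
    # top up with random non-hub edges to hit the target edge count
    guard <- 0L
    while (igraph::ecount(g) < targetEdges && guard < 50L * targetEdges) {
        pair <- sample(igraph::V(g)$name, 2L)
        if (!igraph::are_adjacent(g, pair[1L], pair[2L]))
            g <- igraph::add_edges(g, pair)
        guard <- guard + 1L
    }
    if (abs(igraph::ecount(g) - targetEdges) > 0.02 * targetEdges)
        stop("infeasible config: could not approach the target edge count")
    igraph::E(g)$confidence <- stats::runif(igraph::ecount(g), 0.7, 1.0)
    out <- new("PPIGraph", graph = g)
    validObject(out)
    list(graph = out, hubs = hubs)
}

#' Simulate a TF binding-evidence table with planted core regulators
#'
#' Emits promoter-scan style records (tf, family, target, n_sites) for
#' \code{length(perTargetTFCounts)} target genes such that, after the
#' minimum-binding-site filter, each target has exactly its prescribed
#' TF count, the union of all retained TFs has size \code{unionSize},
#' and \code{nCore} planted core TFs bind every target (all other TFs
#' bind at most \code{length(targets) - 1} targets, so connectivity
#' ranking always recovers the core). A configurable fraction of decoy
#' records with a single binding site is added; these fail the default
#' filter.
#'
#' @param targets character vector of target gene symbols (default the
#'   five inflammatory hubs IL6, VEGFA, IL1B, TNF, PTGS2).
#' @param perTargetTFCounts retained TFs per target (default
#'   69, 75, 74, 70, 37).
#' @param nCore number of planted core TFs (default 3).
#' @param coreTFs symbols for the core TFs (default NFKB1, STAT3, JUN).
#' @param unionSize size of the union of retained TFs (default 184).
#' @param decoyFraction fraction of emitted records that are
#'   single-site decoys (default 0.1); at 1 every record is a decoy and
#'   the filtered network is empty.
#' @param seed integer RNG seed.
#' @return \code{data.frame} with columns tf, family, target, n_sites.
#' @export
simulateTFTable <- function(targets = c("IL6", "VEGFA", "IL1B", "TNF",
                                        "PTGS2"),
                            perTargetTFCounts = c(69L, 75L, 74L, 70L, 37L),
                            nCore = 3L,
                            coreTFs = c("NFKB1", "STAT3", "JUN"),
                            unionSize = 184L, decoyFraction = 0.1,
                            seed = 1L) {
    nT <- length(targets)
    if (length(perTargetTFCounts) != nT)
        stop("perTargetTFCounts must match the number of targets")
    if (nCore > min(perTargetTFCounts))
        stop("nCore exceeds the smallest per-target TF count")
    if (length(coreTFs) < nCore) stop("not enough core TF symbols")
    coreTFs <- coreTFs[seq_len(nCore)]
    rest <- perTargetTFCounts - nCore        # non-core slots per target
    nOther <- unionSize - nCore              # non-core TFs in the union
    extra <- sum(rest) - nOther              # memberships beyond 1 per TF
    if (nOther < 0L || extra < 0L ||
        any(rest < 0L) || extra > nOther * (nT - 2L))
        stop("infeasible overlap arithmetic for the requested union size")
    set.seed(as.integer(seed))
    others <- sprintf("TF%03d", seq_len(nOther))
    member <- matrix(FALSE, nOther, nT,
                     dimnames = list(others, targets))
    # primary target per TF: largest-remainder apportionment over rest
    quota <- rest / sum(rest) * nOther
    primary <- floor(quota)
    rem <- nOther - sum(primary)
    if (rem > 0L) {
        ord <- order(quota - primary, decreasing = TRUE)
        primary[ord[seq_len(rem)]] <- primary[ord[seq_len(rem)]] + 1L
    }
    idx <- 1L
    for (j in seq_len(nT)) {
        if (primary[j] > 0L)
            member[idx:(idx + primary[j] - 1L), j] <- TRUE
        idx <- idx + primary[j]
    }
    # distribute remaining per-target capacity; cap non-core TFs at
    # nT - 1 targets so the planted core stays strictly top-ranked
    capacity <- rest - primary
    for (j in seq_len(nT)) {
        while (capacity[j] > 0L) {
            elig <- which(!member[, j] & rowSums(member) < nT - 1L)
            if (!length(elig))
                stop("infeasible overlap arithmetic: no eligible TF left")
            pick <- if (length(elig) == 1L) elig else
                sample(elig, min(capacity[j], length(elig)))
            member[pick, j] <- TRUE
            capacity[j] <- capacity[j] - length(pick)
        }
    }
    stopifnot(all(colSums(member) == rest), all(rowSums(member) >= 1L))
    recs <- data.frame(
        tf = c(rep(coreTFs, each = nT), rep(others, rowSums(member))),
        target = c(rep(targets, nCore),
                   targets[unlist(apply(member, 1L, which))]),
        stringsAsFactors = FALSE)
    recs$n_sites <- sample(2:8, nrow(recs), replace = TRUE)
    fams <- sprintf("V$FAM%02d", 1:21)
    recs$family <- fams[1L + (as.integer(factor(recs$tf)) %% length(fams))]
    if (decoyFraction >= 1) {
        recs$n_sites <- 1L
    } else if (decoyFraction > 0) {
        nDecoy <- round(decoyFraction / (1 - decoyFraction) * nrow(recs))
        if (nDecoy > 0L) {
            decoys <- data.frame(
                tf = sprintf("DECOY%03d", seq_len(nDecoy)),
                target = sample(targets, nDecoy, replace = TRUE),
                n_sites = 1L,
                family = "V$DECOY", stringsAsFactors = FALSE)
            recs <- rbind(recs, decoys)
        }
    }
    rownames(recs) <- NULL
    recs[c("tf", "family", "target", "n_sites")]
}

#' Simulate a long-format qPCR Ct table
#'
#' Generates duplicate-well threshold cycles for a case/control cohort
#' under the comparative-Ct model: per sample the reference-gene
#' (GUSB) Ct is Normal(25, biologicalSd); each target gene's delta-Ct
#' is its control baseline minus log2(fold change) for cases, plus
#' Normal(0, biologicalSd) biological noise; technical replicates add
#' Normal(0, replicateSd). The log2 mapping from fold change to
#' delta-Ct encodes the doubling-per-cycle assumption.
#'
#' @param panel \code{data.frame} with columns gene, control_dct,
#'   fold_change (default \code{\link{defaultCtPanel}()}).
#' @param nCases,nControls cohort sizes (defaults 64 and 64).
#' @param referenceGene endogenous control symbol (default
#'   \code{"GUSB"}).
#' @param replicateSd technical replicate SD in cycles (default 0.15).
#' @param biologicalSd biological SD in delta-Ct units (default 0.6).
#' @param nReplicates technical replicates per well (default 2).
#' @param seed integer RNG seed.
#' @return long \code{data.frame} with columns sample, group, gene,
#'   replicate, ct.
#' @export
simulateCt <- function(panel = defaultCtPanel(), nCases = 64L,
                       nControls = 64L, referenceGene = "GUSB",
                       replicateSd = 0.15, biologicalSd = 0.6,
                       nReplicates = 2L, seed = 1L) {
    if (any(panel$fold_change <= 0)) stop("fold changes must be positive")
    if (replicateSd < 0 || biologicalSd < 0) stop("SDs must be >= 0")
    set.seed(as.integer(seed))
    samples <- c(sprintf("CASE%03d", seq_len(nCases)),
                 sprintf("CTRL%03d", seq_len(nControls)))
    groups <- rep(c("case", "control"), c(nCases, nControls))
    nS <- length(samples)
    refCt <- stats::rnorm(nS, 25, biologicalSd)
    rows <- vector("list", nrow(panel) + 1L)
    for (i in seq_len(nrow(panel))) {
        shift <- ifelse(groups == "case",
                        -log2(panel$fold_change[i]), 0)
        dct <- panel$control_dct[i] + shift +
            stats::rnorm(nS, 0, biologicalSd)
        well <- refCt + dct
        rows[[i]] <- data.frame(
            sample = rep(samples, each = nReplicates),
            group = rep(groups, each = nReplicates),
            gene = panel$gene[i],
            replicate = rep(seq_len(nReplicates), nS),
            ct = rep(well, each = nReplicates) +
                stats::rnorm(nS * nReplicates, 0, replicateSd))
    }
    rows[[nrow(panel) + 1L]] <- data.frame(
        sample = rep(samples, each = nReplicates),
        group = rep(groups, each = nReplicates),
        gene = referenceGene,
        replicate = rep(seq_len(nReplicates), nS),
        ct = rep(refCt, each = nReplicates) +
            stats::rnorm(nS * nReplicates, 0, replicateSd))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Simulate a pair of scored seed-gene lists
#'
#' Emulates a text-mining list (with relevancy Z scores) and a curated
#' list overlapping it, for exercising the gene-list assembly stage.
#' Defaults give lists of 78 and 68 symbols sharing 22, merging to 124
#' unique genes.
#'
#' @param nA size of the scored (text-mining) list, default 78.
#' @param nB size of the curated list, default 68.
#' @param overlap symbols shared between the lists, default 22.
#' @param seed integer RNG seed.
#' @return list of two \code{data.frame}s (\code{textMining},
#'   \code{curated}) with columns symbol, z_score, source.
#' @export
simulateGeneLists <- function(nA = 78L, nB = 68L, overlap = 22L,
                              seed = 1L) {
    if (overlap > min(nA, nB)) stop("overlap exceeds a list size")
    set.seed(as.integer(seed))
    total <- nA + nB - overlap
    syms <- sprintf("GENE%03d", seq_len(total))
    aSyms <- syms[seq_len(nA)]
    bSyms <- c(syms[sample(seq_len(nA), overlap)],
               syms[nA + seq_len(nB - overlap)])
    list(
        textMining = data.frame(
            symbol = aSyms,
            z_score = round(stats::runif(nA, 1.01, 6), 3),
            source = "text-mining"),
        curated = data.frame(
            symbol = bSyms, z_score = NA_real_, source = "curated"))
}
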