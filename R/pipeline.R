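#' Default pipeline configuration
#'
#' Collects every analysis threshold with its conventional default:
#' edge confidence 0.7, hub cutoffs degree > 50 and BC > 0.05,
#' candidate pool of the top 22 ranked nodes, 5 repeats per hub at
#' deletion levels 2-4, minimum binding-site evidence 2, relevancy
#' Z > 1, and a required seed for every stochastic stage.
#'
#' @param ... named overrides of individual defaults.
#' @return named list of configuration values.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        edges = NULL,          # path to edge-list TSV (NULL = simulate)
        gene_lists = NULL,     # paths to scored gene-list TSVs
        tf_table = NULL,       # path to TF evidence TSV (NULL = simulate)
        ct_table = NULL,       # path to Ct CSV (NULL = simulate)
        min_confidence = 0.7,
        degree_cut = 50,
        bc_cut = 0.05,
        pool_size = 22L,
        repeats = 5L,
        levels = 1:4,
        min_sites = 2L,
        z_min = 1.0,
        reference_gene = "GUSB",
        calibrator = NULL,
        seed = 1L,
        out_dir = "hubnet-out")
    override <- list(...)
    unknown <- setdiff(names(override), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    utils::modifyList(cfg, override)
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror \code{\link{pipelineConfig}}; unset fields keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals)
}

stageError <- function(stage, e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE)
}

#' Run the full prioritization pipeline
#'
#' Chains all stages: seed-gene assembly, graph construction,
#' topological statistics and power-law fit, hub selection and backbone
#' extraction, leave-k-out robustness validation, regulatory-network
#' ranking, and comparative-Ct expression analysis. Per-stage outputs
#' (TSV/SIF/GraphML) and a JSON summary are written under
#' \code{cfg$out_dir}. Stages with no configured input fall back to the
#' seeded synthetic generators so the whole pipeline runs
#' self-contained. Any stage failure aborts with a stage-named error;
#' outputs of completed stages are retained.
#'
#' @param cfg configuration list from \code{\link{pipelineConfig}} or
#'   \code{\link{readConfig}}.
#' @param quiet suppress progress messages (default FALSE).
#' @return the summary list, invisibly.
#' @export
runPipeline <- function(cfg = pipelineConfig(), quiet = FALSE) {
    note <- function(...) if (!quiet) message("hubnet: ", ...)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    note("config: seed=", cfg$seed, " min_confidence=",
         cfg$min_confidence, " degree_cut=", cfg$degree_cut,
         " bc_cut=", cfg$bc_cut, " pool_size=", cfg$pool_size)
    summary <- list(seed = cfg$seed)

    # -- genelist ---------------------------------------------------------
    tryCatch({
        lists <- if (is.null(cfg$gene_lists)) {
            note("genelist: simulating scored gene lists")
            simulateGeneLists(seed = cfg$seed)
        } else lapply(cfg$gene_lists, readGeneList)
        scored <- filterByZscore(lists[[1L]], cfg$z_min)
        merged <- mergeGeneLists(scored, lists[[2L]])
        writeGeneList(merged, file.path(cfg$out_dir, "seed_genes.tsv"))
        summary$n_seed_genes <- nrow(merged)
        note("genelist: ", nrow(merged), " unique seed genes")
    }, error = function(e) stageError("genelist", e))

    # -- graph ------------------------------------------------------------
    plantedHubs <- NULL
    tryCatch({
        if (is.null(cfg$edges)) {
            note("graph: simulating scale-free PPI network")
            sim <- simulatePPI(seed = cfg$seed)
            g <- sim$graph; plantedHubs <- sim$hubs
        } else {
            g <- buildGraph(readEdgeList(cfg$edges), cfg$min_confidence)
        }
        stats <- nodeStats(g)
        pl <- fitPowerLaw(nodeDegrees(g))
        writeStatsTSV(stats, file.path(cfg$out_dir, "node_stats.tsv"))
        writeGraphML(g, file.path(cfg$out_dir, "network.graphml"))
        summary$n_nodes <- nodeCount(g)
        summary$n_edges <- edgeCount(g)
        summary$power_law_r2 <- pl@rSquared
        summary$power_law_exponent <- pl@exponent
        note("graph: ", nodeCount(g), " nodes, ", edgeCount(g),
             " edges, power-law r2 ", round(pl@rSquared, 3))
    }, error = function(e) stageError("graph", e))

    # -- prioritize -------------------------------------------------------
    tryCatch({
        sel <- selectHubs(stats, cfg$degree_cut, cfg$bc_cut)
        hubs <- hubGenes(sel)
        if (!length(hubs)) stop("no hubs pass the cutoffs")
        backbone <- extractBackbone(g, hubs)
        writeSIF(backbone, file.path(cfg$out_dir, "backbone.sif"))
        writeGraphML(backbone, file.path(cfg$out_dir, "backbone.graphml"))
        summary$hubs <- hubs
        summary$backbone_nodes <- nodeCount(backbone)
        summary$backbone_edges <- edgeCount(backbone)
        summary$hub_edge_fraction <- hubEdgeFraction(backbone, hubs)
        note("prioritize: ", length(hubs), " hubs (",
             paste(hubs, collapse = ", "), "); backbone ",
             nodeCount(backbone), "/", edgeCount(backbone))
    }, error = function(e) stageError("prioritize", e))

    # -- validate ---------------------------------------------------------
    tryCatch({
        val <- runValidation(g, hubs = utils::head(hubs, 5L),
                             poolSize = cfg$pool_size,
                             repeats = cfg$repeats,
                             levels = cfg$levels, seed = cfg$seed)
        writeRetentionTSV(val$retention,
                          file.path(cfg$out_dir, "validation.tsv"))
        acc <- accuracyTable(val$retention)
        summary$n_test_networks <- designSize(val$design)
        summary$accuracy_table <- acc
        summary$overall_accuracy <- val$overall
        note("validate: ", summary$n_test_networks,
             " test networks, overall accuracy ",
             round(val$overall, 4))
    }, error = function(e) stageError("validate", e))

    # -- regnet -----------------------------------------------------------
    tryCatch({
        tfRecords <- if (is.null(cfg$tf_table)) {
            note("regnet: simulating TF binding-evidence table")
            simulateTFTable(targets = utils::head(hubs, 5L),
                            seed = cfg$seed)
        } else readTFTable(cfg$tf_table)
        tfSets <- filterEvidence(tfRecords, cfg$min_sites)
        net <- buildRegulatoryNetwork(tfSets)
        top <- rankTFConnectivity(net, topN = 3L)
        writeRegulatorySIF(net, file.path(cfg$out_dir, "regnet.sif"))
        utils::write.table(rankTFConnectivity(net, topN = Inf),
                           file.path(cfg$out_dir, "tf_rank.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary$n_unique_tfs <- length(uniqueTFUnion(tfSets))
        summary$top_tfs <- top$tf
        note("regnet: ", summary$n_unique_tfs, " unique TFs; top: ",
             paste(top$tf, collapse = ", "))
    }, error = function(e) stageError("regnet", e))

    # -- expression -------------------------------------------------------
    tryCatch({
        ctTab <- if (is.null(cfg$ct_table)) {
            note("expression: simulating qPCR Ct table")
            simulateCt(referenceGene = cfg$reference_gene,
                       seed = cfg$seed)
        } else readCtTable(cfg$ct_table)
        collapsed <- collapseReplicates(ctTab)
        dct <- dropDctOutliers(
            deltaCtTable(collapsed, cfg$reference_gene))
        rel <- relativeExpressionTable(dct, calibrator = cfg$calibrator)
        cmpTab <- groupComparisonTable(rel)
        utils::write.table(rel,
                           file.path(cfg$out_dir, "relative_expression.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(cmpTab,
                           file.path(cfg$out_dir, "group_comparison.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        corr <- correlationMatrix(rel)
        utils::write.table(corr$r,
                           file.path(cfg$out_dir, "correlation.tsv"),
                           sep = "\t", quote = FALSE)
        summary$group_comparison <- cmpTab
        note("expression: ", nrow(cmpTab), " genes compared, ",
             sum(cmpTab$p < 0.05), " at p < 0.05")
    }, error = function(e) stageError("expression", e))

    summary$planted_hubs <- plantedHubs
    jsonlite::write_json(summary,
                         file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(summary)
}

#' Validate a pipeline summary against the shipped schema
#'
#' Light structural check of the JSON summary written by
#' \code{\link{runPipeline}} against the field/type schema shipped at
#' \code{inst/extdata/summary-schema.json}.
#'
#' @param summary the summary list, or a path to a summary.json file.
#' @return \code{TRUE} invisibly, or an error describing the violation.
#' @export
validateSummary <- function(summary) {
    if (is.character(summary))
        summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
    schema <- jsonlite::read_json(
        system.file("extdata", "summary-schema.json", package = "hubnet"),
        simplifyVector = TRUE)
    for (field in names(schema$required)) {
        if (is.null(summary[[field]]))
            stop("summary is missing required field '", field, "'")
        type <- schema$required[[field]]
        val <- summary[[field]]
        ok <- switch(type,
            number = is.numeric(val) && length(val) == 1L,
            integer = is.numeric(val) && length(val) == 1L &&
                val == round(val),
            string_array = is.character(val) ||
                (is.list(val) && all(vapply(val, is.character, logical(1)))),
            table = is.data.frame(val) || is.list(val),
            TRUE)
        if (!ok)
            stop("summary field '", field, "' is not of type '", type, "'")
    }
    invisible(TRUE)
}
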