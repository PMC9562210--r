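#' Read and validate a pipeline configuration
#'
#' YAML with a versioned schema. Required: \code{workflow} ("binary" or
#' "subtype"), \code{seed}, \code{output_dir}, and either \code{datasets}
#' (a list of \code{matrix}/\code{metadata} path pairs; cohort roles come
#' from the metadata) or \code{synthetic} ("binary" or "subtype", simulating
#' the standard two-platform fixture with platform A as train and platform B
#' as test). Optional blocks with defaults mirroring the method's stated
#' constants: \code{boruta} (cycles 250, runs 100, tau 0.90, trees 100,
#' importance "permutation"), \code{forest} (trees 450), \code{sfs}
#' (enabled false, max_size 7, folds 5, trees 100), \code{de} (alpha 0.05),
#' \code{ora} (alpha 0.001, gmt null), \code{panel} (gene-list path; default
#' all common genes), \code{top_k} (20).
#'
#' @param path path to the YAML file, or a list already in config shape.
#' @return Validated config list (class \code{PipelineConfig}).
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (is.character(path)) yaml::read_yaml(path) else path
    if (is.null(cfg$workflow) ||
        !cfg$workflow %in% c("binary", "subtype"))
        stop("config: workflow must be 'binary' or 'subtype'")
    if (is.null(cfg$seed)) stop("config: seed is required")
    if (is.null(cfg$output_dir)) stop("config: output_dir is required")
    if (is.null(cfg$datasets) && is.null(cfg$synthetic))
        stop("config: provide either datasets or synthetic")
    defaults <- list(
        boruta = list(cycles = 250, runs = 100, tau = 0.90, trees = 100,
                      importance = "permutation"),
        forest = list(trees = 450),
        sfs = list(enabled = FALSE, max_size = 7, folds = 5, trees = 100),
        de = list(alpha = 0.05),
        ora = list(alpha = 0.001, gmt = NULL),
        top_k = 20, panel = NULL)
    for (blk in names(defaults)) {
        if (is.list(defaults[[blk]])) {
            cfg[[blk]] <- utils::modifyList(defaults[[blk]],
                                            cfg[[blk]] %||% list())
        } else if (is.null(cfg[[blk]])) cfg[[blk]] <- defaults[[blk]]
    }
    if (cfg$boruta$tau <= 0 || cfg$boruta$tau > 1)
        stop("config: boruta tau must lie in (0, 1]")
    if (!is.null(cfg$datasets))
        for (d in cfg$datasets)
            for (p in c(d$matrix, d$metadata))
                if (!file.exists(p))
                    stop(sprintf("config: referenced file missing: %s", p))
    if (!is.null(cfg$ora$gmt) && !file.exists(cfg$ora$gmt))
        stop(sprintf("config: GMT file missing: %s", cfg$ora$gmt))
    structure(cfg, class = "PipelineConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.loadCohorts <- function(cfg) {
    if (!is.null(cfg$datasets))
        return(lapply(cfg$datasets, function(d)
            readExpressionMatrix(d$matrix, d$metadata)))
    simCfg <- switch(cfg$synthetic$family %||% cfg$synthetic,
        binary = binaryFixtureConfig(
            nPerClass = cfg$synthetic$n_per_class %||% 150,
            seed = cfg$seed),
        subtype = subtypeFixtureConfig(
            nPerClass = cfg$synthetic$n_per_class %||% 60,
            seed = cfg$seed),
        stop("config: synthetic must be 'binary' or 'subtype'"))
    cohorts <- simulateCohorts(simCfg)
    roles <- c("train", "test")
    for (i in seq_along(cohorts))
        colData(cohorts[[i]])$cohort_role <- roles[min(i, 2L)]
    cohorts
}

#' Run a full binary or subtype workflow
#'
#' Executes, in order: read (or simulate) the cohorts, intersect the gene
#' universe, rank within samples, subset to the user panel, consensus Boruta
#' selection on the training samples only, fit the rank forest on the
#' selected genes, evaluate on the test samples, exact Shapley attribution
#' with a top-k summary, the matching differential-expression stage on the
#' largest test cohort's expression values, over-representation analysis if
#' gene sets are supplied, and (binary workflow, optional) the floating
#' minimal-panel search. Every stage's artifact is written to the output
#' directory together with a manifest (config, seeds, package version, file
#' checksums). Test-role samples never reach selection, panel search or
#' fitting.
#'
#' @param config a \code{PipelineConfig} (or path to one).
#' @return Invisibly, a list of the stage results and artifact paths.
#' @export
runWorkflow <- function(config) {
    cfg <- if (inherits(config, "PipelineConfig")) config
           else readPipelineConfig(config)
    out <- cfg$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    stage <- "read"
    res <- tryCatch({
        cohorts <- .loadCohorts(cfg)
        labelsOf <- function(d) sampleLabels(d)
        nClasses <- length(unique(unlist(lapply(cohorts, labelsOf))))
        if (cfg$workflow == "subtype" && nClasses < 3L)
            stop("workflow 'subtype' requires multi-class labels")
        if (cfg$workflow == "binary" && nClasses != 2L)
            stop("workflow 'binary' requires exactly two classes")

        stage <- "intersect_gene_universe"
        common <- intersectGeneUniverse(cohorts)

        stage <- "rank_within_samples"
        ranked <- lapply(common$datasets, rankWithinSamples)

        stage <- "subset_to_panel"
        panel <- if (!is.null(cfg$panel)) readGeneList(cfg$panel)
                 else common$genes
        panel <- intersect(panel, common$genes)
        if (!length(panel)) stop("panel does not overlap the common universe")
        ranked <- lapply(ranked, subsetToPanel, geneList = panel)

        roleOf <- function(d) unique(cohortRole(d))
        isTrain <- vapply(ranked, function(d)
            identical(roleOf(d), "train"), logical(1))
        isTest <- vapply(ranked, function(d)
            identical(roleOf(d), "test"), logical(1))
        if (!any(isTrain) || !any(isTest))
            stop("both train and test cohort roles are required")
        mergeRanked <- function(ds) {
            m <- do.call(cbind, lapply(ds, rankValues))
            lab <- unlist(lapply(ds, function(d)
                colData(d)$label), use.names = FALSE)
            list(ranked = new("RankedDataset",
                     .asRanked(ds[[1L]], m, lab),
                     rankUniverseSize = ds[[1L]]@rankUniverseSize),
                 labels = lab)
        }
        train <- mergeRanked(ranked[isTrain])
        test <- mergeRanked(ranked[isTest])

        seeds <- spawnSeeds(cfg$seed, 4)
        stage <- "consensus_select"
        consensus <- consensusSelect(
            train$ranked, labels = train$labels, R = cfg$boruta$runs,
            tau = cfg$boruta$tau, nCycles = cfg$boruta$cycles,
            nTrees = cfg$boruta$trees,
            importance = cfg$boruta$importance, seed = seeds[1],
            keepRuns = FALSE)
        writeConsensus(consensus, file.path(out, "consensus.tsv"),
                       file.path(out, "consensus.json"))
        if (!length(consensus@selected))
            stop("consensus selection returned no genes")
        writeGeneList(consensus@selected,
                      file.path(out, "selected_panel.txt"))

        stage <- "fit_rank_forest"
        model <- fitRankForest(
            subsetToPanel(train$ranked, consensus@selected),
            labels = train$labels, nTrees = cfg$forest$trees,
            seed = seeds[2])

        stage <- "evaluate"
        testPanel <- subsetToPanel(test$ranked, consensus@selected)
        report <- evaluateModel(model, testPanel, labels = test$labels)
        writeEvalReport(report, file.path(out, "eval.json"),
                        file.path(out, "confusion.tsv"))

        stage <- "compute_attributions"
        attr <- computeAttributions(model, testPanel)
        writeAttributionSummary(attr, file.path(out, "attribution.tsv"),
                                file.path(out, "attribution.json"))
        top <- topInfluential(attr, min(cfg$top_k,
                                        length(attr@overallRank)))
        utils::write.table(top, file.path(out, "top_influential.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

        stage <- "differential_expression"
        testRaw <- common$datasets[isTest]
        largest <- testRaw[[which.max(vapply(testRaw, ncol, numeric(1)))]]
        largest <- largest[intersect(consensus@selected,
                                     geneIds(largest)), ]
        de <- if (cfg$workflow == "binary")
            binaryDe(largest, alpha = cfg$de$alpha)
        else subtypeDe(largest, alpha = cfg$de$alpha)
        writeStatsResult(de, file.path(out, "de.tsv"),
                         file.path(out, "de.json"))

        oraRes <- NULL
        if (!is.null(cfg$ora$gmt)) {
            stage <- "ora"
            oraRes <- ora(consensus@selected, panel,
                          readGMT(cfg$ora$gmt), alpha = cfg$ora$alpha)
            writeStatsResult(oraRes, file.path(out, "ora.tsv"),
                             file.path(out, "ora.json"))
        }

        sfsRes <- NULL
        if (isTRUE(cfg$sfs$enabled) && cfg$workflow == "binary") {
            stage <- "sffs"
            sfsRes <- sffs(subsetToPanel(train$ranked,
                                         consensus@selected),
                           labels = train$labels,
                           candidateGenes = consensus@selected,
                           maxSize = min(cfg$sfs$max_size,
                                         length(consensus@selected)),
                           folds = cfg$sfs$folds,
                           nTrees = cfg$sfs$trees, seed = seeds[3])
            writeSfsTrace(sfsRes, file.path(out, "sfs_trace.tsv"),
                          file.path(out, "sfs_trace.json"),
                          file.path(out, "minimal_panel.txt"))
        }

        list(consensus = consensus, model = model, report = report,
             attribution = attr, de = de, ora = oraRes, sfs = sfsRes)
    }, error = function(e) {
        writeLines(sprintf("failed at stage '%s': %s", stage,
                           conditionMessage(e)),
                   file.path(out, "FAILED"))
        stop(sprintf("stage '%s': %s", stage, conditionMessage(e)),
             call. = FALSE)
    })

    stage <- "manifest"
    arts <- list.files(out, full.names = TRUE)
    arts <- arts[!basename(arts) %in% "manifest.json"]
    manifest <- list(
        config = unclass(cfg),
        package_version = as.character(utils::packageVersion("rankRF")),
        stage_checksums = as.list(stats::setNames(
            unname(tools::md5sum(arts)), basename(arts))))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(res)
}

# rebuild an ExpressionDataset around merged assay values/labels
.asRanked <- function(template, values, labels) {
    ExpressionDataset(values, labels = labels,
                      platformId = "merged",
                      datasetId = "merged",
                      cohortRole = unique(cohortRole(template)))
}
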