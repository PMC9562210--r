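#' Stratified cross-validated ROC-AUC of a gene panel
#'
#' Assigns samples to \code{folds} stratified folds (each class dealt
#' round-robin after a seeded shuffle), fits a rank forest on each training
#' split, and scores ROC-AUC (macro one-vs-rest for > 2 classes) on the held
#' out fold. The reported uncertainty is the half-width of the 95\%
#' normal-approximation interval of the fold scores,
#' \code{1.96 * sd(folds) / sqrt(folds)}.
#'
#' @param ranked a \linkS4class{RankedDataset}.
#' @param labels class labels; defaults to the dataset's own.
#' @param panel character vector of genes to score.
#' @param folds number of folds (>= 2).
#' @param nTrees trees per fold model (default 100).
#' @param seed integer; fixes both fold assignment and the fold models.
#' @param foldIds optional precomputed fold assignment (overrides seed-based
#'   assignment; used internally so a whole selection run shares folds).
#' @return List with \code{mean}, \code{ciBound} and \code{foldScores}.
#' @export
cvScore <- function(ranked, labels = NULL, panel = geneIds(ranked),
                    folds = 5, nTrees = 100, seed = 1, foldIds = NULL) {
    if (folds < 2L) stop("folds must be >= 2")
    labels <- .labelsOrStop(ranked, labels)
    if (is.null(foldIds))
        foldIds <- .stratifiedFolds(labels, folds, seed)
    sub <- subsetToPanel(ranked, panel)
    scores <- numeric(folds)
    for (f in seq_len(folds)) {
        testIdx <- which(foldIds == f)
        trainIdx <- which(foldIds != f)
        if (length(unique(labels[trainIdx])) < 2L ||
            length(unique(labels[testIdx])) < 2L)
            stop("a fold contains a single class; use stratified folds with enough samples per class")
        model <- fitRankForest(sub[, trainIdx], labels = labels[trainIdx],
                               nTrees = nTrees, seed = seed)
        prob <- predictProba(model, sub[, testIdx])
        truth <- labels[testIdx]
        classes <- colnames(prob)
        scores[f] <- if (length(classes) == 2L)
            .rocAuc(prob[, classes[2L]], truth == classes[2L])
        else
            mean(vapply(intersect(classes, unique(truth)), function(cl)
                .rocAuc(prob[, cl], truth == cl), numeric(1)))
    }
    list(mean = mean(scores),
         ciBound = 1.96 * stats::sd(scores) / sqrt(folds),
         foldScores = scores)
}

.stratifiedFolds <- function(labels, folds, seed) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    ids <- integer(length(labels))
    for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        ids[idx] <- rep_len(seq_len(folds), length(idx))
    }
    ids
}

#' Sequential floating forward selection of a minimal gene panel
#'
#' Greedy forward selection maximising cross-validated ROC-AUC: each forward
#' step adds the candidate gene whose addition gives the highest CV score
#' (ties break lexicographically); after each addition, backward "floating"
#' steps remove any already-selected gene (never the one just added) whose
#' removal strictly improves the score, repeating until no removal helps.
#' The full trace is recorded; the best panel is the smallest recorded panel
#' attaining the maximum CV score. Fold assignment is fixed once per call so
#' every recorded score is exactly reproducible by re-scoring its panel.
#'
#' @param ranked a \linkS4class{RankedDataset} of training samples.
#' @param labels class labels; defaults to the dataset's own.
#' @param candidateGenes candidate pool (subset of the dataset's genes).
#' @param maxSize largest panel size to grow to.
#' @param folds CV folds (default 5, stratified).
#' @param nTrees trees per CV model (default 100; re-score the final panel
#'   with 450 via \code{\link{cvScore}} for reporting).
#' @param floating enable backward removals (default TRUE; FALSE gives plain
#'   sequential forward selection).
#' @param seed integer seed.
#' @return An \linkS4class{SfsTrace}.
#' @export
sffs <- function(ranked, labels = NULL, candidateGenes = geneIds(ranked),
                 maxSize = length(candidateGenes), folds = 5, nTrees = 100,
                 floating = TRUE, seed = 1) {
    if (maxSize < 1L) stop("maxSize must be >= 1")
    missing <- setdiff(candidateGenes, geneIds(ranked))
    if (length(missing))
        stop(sprintf("candidate gene(s) absent from dataset: %s",
                     paste(missing, collapse = ", ")))
    if (maxSize > length(candidateGenes))
        stop("maxSize cannot exceed the candidate pool")
    labels <- .labelsOrStop(ranked, labels)
    foldIds <- .stratifiedFolds(labels, folds, seed)
    cache <- new.env(parent = emptyenv())
    score <- function(panel) {
        key <- paste(sort(panel), collapse = "|")
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit)
        res <- cvScore(ranked, labels = labels, panel = panel,
                       folds = folds, nTrees = nTrees, seed = seed,
                       foldIds = foldIds)
        cache[[key]] <- res
        res
    }

    panel <- character()
    steps <- list()
    maxSteps <- 10L * maxSize + 10L  # guards against add/remove cycling
    record <- function(action, gene, res) {
        steps[[length(steps) + 1L]] <<- data.frame(
            step = length(steps) + 1L, action = action, gene = gene,
            panel = paste(panel, collapse = ","),
            size = length(panel), score = res$mean, ciBound = res$ciBound)
    }

    while (length(panel) < maxSize && length(steps) < maxSteps) {
        pool <- setdiff(candidateGenes, panel)
        if (!length(pool)) break
        cand <- vapply(pool, function(g) score(c(panel, g))$mean,
                       numeric(1))
        best <- sort(pool[cand == max(cand)])[1L]  # lexicographic tie-break
        panel <- c(panel, best)
        record("add", best, score(panel))
        justAdded <- best
        while (floating && length(panel) > 2L) {
            cur <- score(panel)$mean
            removable <- setdiff(panel, justAdded)
            drops <- vapply(removable, function(g)
                score(setdiff(panel, g))$mean, numeric(1))
            if (max(drops) <= cur + 1e-12) break
            worst <- sort(removable[drops == max(drops)])[1L]
            panel <- setdiff(panel, worst)
            record("remove", worst, score(panel))
        }
    }

    steps <- do.call(rbind, steps)
    # best = highest score; prefer smaller panels, then earlier steps
    ord <- order(-steps$score, steps$size, steps$step)
    bestRow <- steps[ord[1L], ]
    bestPanel <- strsplit(bestRow$panel, ",", fixed = TRUE)[[1L]]
    new("SfsTrace", steps = steps, bestPanel = bestPanel,
        bestScore = bestRow$score, seed = as.integer(seed))
}

#' Write an SfsTrace as TSV (one row per step) + JSON summary
#'
#' @param trace an \linkS4class{SfsTrace}.
#' @param tsvPath,jsonPath,panelPath output paths (NULL skips); panelPath
#'   writes the best panel as a plain-text gene list.
#' @return Invisibly, the written paths.
#' @export
writeSfsTrace <- function(trace, tsvPath = NULL, jsonPath = NULL,
                          panelPath = NULL) {
    if (!is.null(tsvPath))
        utils::write.table(trace@steps, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(jsonPath))
        jsonlite::write_json(
            list(best_panel = trace@bestPanel,
                 best_score = trace@bestScore, seed = trace@seed),
            jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(panelPath)) writeGeneList(trace@bestPanel, panelPath)
    invisible(c(tsvPath, jsonPath, panelPath))
}
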