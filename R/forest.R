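#' Fit a rank Random Forest classifier
#'
#' Fits an ensemble of \code{nTrees} decision trees (majority vote) on the
#' within-sample ranks of a panel-restricted dataset. Hyperparameters beyond
#' the tree count follow common Random Forest defaults (features-per-split
#' = sqrt(M), unlimited depth). The training matrix and in-bag counts are
#' retained for exact Shapley attribution.
#'
#' @param ranked a panel-restricted \linkS4class{RankedDataset}.
#' @param labels class labels; defaults to the dataset's own.
#' @param nTrees number of trees (default 450).
#' @param seed integer seed; fits are deterministic given it.
#' @param mtry features per split (default sqrt of panel size).
#' @param minNodeSize minimal terminal node size (default 1).
#' @param maxDepth maximal tree depth (NULL/0 = unlimited; 1 = stumps).
#' @return A \linkS4class{RankForestModel}.
#' @export
fitRankForest <- function(ranked, labels = NULL, nTrees = 450, seed = 1,
                          mtry = NULL, minNodeSize = 1, maxDepth = NULL) {
    if (nTrees < 1L) stop("nTrees must be >= 1")
    labels <- .labelsOrStop(ranked, labels)
    if (min(table(labels)) < 2L)
        stop("need at least 2 samples per class")
    x <- t(rankValues(ranked))
    y <- factor(labels)
    fit <- ranger::ranger(x = x, y = y, num.trees = nTrees, mtry = mtry,
                          min.node.size = minNodeSize,
                          max.depth = maxDepth, seed = seed,
                          keep.inbag = TRUE, num.threads = 1L)
    new("RankForestModel", forest = fit, genes = colnames(x),
        classes = levels(y), nTrees = as.integer(nTrees),
        seed = as.integer(seed), trainX = x,
        params = list(mtry = if (is.null(mtry)) floor(sqrt(ncol(x)))
                      else mtry,
                      min_node_size = minNodeSize))
}

.alignToModel <- function(model, ranked) {
    missing <- setdiff(model@genes, geneIds(ranked))
    if (length(missing))
        stop(sprintf("test data lacks panel gene(s): %s",
                     paste(missing, collapse = ", ")))
    t(rankValues(ranked)[model@genes, , drop = FALSE])
}

#' Predict class-vote fractions for new samples
#'
#' Probabilities are the fractions of trees voting for each class; each
#' probability vector is non-negative and sums to one. Test genes are
#' re-aligned to the model's training order automatically; a missing panel
#' gene is an error.
#'
#' @param model a \linkS4class{RankForestModel}.
#' @param ranked a \linkS4class{RankedDataset} containing the panel genes.
#' @return Numeric matrix samples x classes of vote fractions.
#' @export
predictProba <- function(model, ranked) {
    x <- .alignToModel(model, ranked)
    votes <- stats::predict(model@forest, data = x, predict.all = TRUE,
                            num.threads = 1L)$predictions
    k <- length(model@classes)
    prob <- vapply(seq_len(k),
                   function(ci) rowMeans(votes == ci),
                   numeric(nrow(x)))
    if (nrow(x) == 1L) prob <- matrix(prob, nrow = 1L)
    dimnames(prob) <- list(rownames(x), model@classes)
    prob
}

# trapezoid ROC-AUC by threshold sweep over unique scores
.rocAuc <- function(scores, positive) {
    if (anyNA(scores)) stop("NaN/NA scores are not allowed")
    pos <- sum(positive)
    neg <- sum(!positive)
    if (pos == 0L || neg == 0L)
        stop("ROC-AUC undefined: only one class present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- positive[ord]
    cuts <- c(which(diff(s) != 0), length(s))
    tpr <- c(0, cumsum(y)[cuts] / pos)
    fpr <- c(0, cumsum(!y)[cuts] / neg)
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# PR-AUC by the same sweep, linear interpolation in recall (trapezoid)
.prAuc <- function(scores, positive) {
    if (anyNA(scores)) stop("NaN/NA scores are not allowed")
    pos <- sum(positive)
    if (pos == 0L) stop("PR-AUC undefined: no positive samples")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- positive[ord]
    cuts <- c(which(diff(s) != 0), length(s))
    tp <- cumsum(y)[cuts]
    n <- cuts
    recall <- c(0, tp / pos)
    precision <- c(if (tp[1] > 0) tp[1] / n[1] else 1, tp / n)
    sum(diff(recall) * (utils::head(precision, -1) +
                        utils::tail(precision, -1)) / 2)
}

#' Compute the evaluation metric panel
#'
#' Balanced accuracy (unweighted mean of per-class recalls), ROC-AUC and
#' PR-AUC by threshold sweep over unique scores (multiclass: macro
#' one-vs-rest average on vote-fraction scores), macro and support-weighted
#' F1, and the confusion matrix (true class x predicted class, ordered by
#' the score-column class list). All metrics are invariant to sample order.
#'
#' @param trueLabels character vector of true classes.
#' @param scoreMatrix samples x classes score matrix with class colnames;
#'   for binary problems the second column is treated as the positive class.
#' @param predictedLabels predicted classes; defaults to the per-row argmax
#'   of \code{scoreMatrix} (ties to the earlier class column).
#' @return An \linkS4class{EvalReport}.
#' @export
computeMetrics <- function(trueLabels, scoreMatrix,
                           predictedLabels = NULL) {
    classes <- colnames(scoreMatrix)
    trueLabels <- as.character(trueLabels)
    if (length(trueLabels) != nrow(scoreMatrix))
        stop("trueLabels length must match scoreMatrix rows")
    if (anyNA(scoreMatrix)) stop("NaN/NA scores are not allowed")
    if (!all(trueLabels %in% classes))
        stop("true label outside the score-matrix class list")
    if (length(unique(trueLabels)) < 2L)
        stop("single-class test set: ROC-AUC undefined; compute accuracy-type metrics on a labelled multi-class subset instead")
    if (is.null(predictedLabels))
        predictedLabels <- classes[apply(scoreMatrix, 1, which.max)]

    confusion <- table(factor(trueLabels, levels = classes),
                       factor(predictedLabels, levels = classes))
    confusion <- matrix(as.integer(confusion), nrow = length(classes),
                        dimnames = list(true = classes,
                                        predicted = classes))
    present <- classes[rowSums(confusion) > 0]
    recall <- vapply(present, function(cl)
        confusion[cl, cl] / sum(confusion[cl, ]), numeric(1))
    f1c <- vapply(classes, function(cl) {
        tp <- confusion[cl, cl]
        prec <- if (sum(confusion[, cl]) > 0) tp / sum(confusion[, cl]) else 0
        rec <- if (sum(confusion[cl, ]) > 0) tp / sum(confusion[cl, ]) else 0
        if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }, numeric(1))
    support <- rowSums(confusion)

    if (length(classes) == 2L) {
        pos <- classes[2L]
        roc <- .rocAuc(scoreMatrix[, pos], trueLabels == pos)
        pr <- .prAuc(scoreMatrix[, pos], trueLabels == pos)
    } else {
        roc <- mean(vapply(present, function(cl)
            .rocAuc(scoreMatrix[, cl], trueLabels == cl), numeric(1)))
        pr <- mean(vapply(present, function(cl)
            .prAuc(scoreMatrix[, cl], trueLabels == cl), numeric(1)))
    }
    new("EvalReport",
        balancedAccuracy = mean(recall), rocAuc = roc, prAuc = pr,
        f1 = mean(f1c[present]),
        f1Weighted = sum(f1c * support) / sum(support),
        confusion = confusion, perClassRecall = recall)
}

#' Evaluate a fitted model on a labelled test cohort
#'
#' @param model a \linkS4class{RankForestModel}.
#' @param ranked labelled \linkS4class{RankedDataset} with >= 2 classes.
#' @param labels optional labels overriding the dataset's own.
#' @return An \linkS4class{EvalReport}.
#' @export
evaluateModel <- function(model, ranked, labels = NULL) {
    labels <- .labelsOrStop(ranked, labels)
    prob <- predictProba(model, ranked)
    computeMetrics(labels, prob)
}

#' Write an EvalReport as JSON (+ confusion matrix TSV)
#'
#' @param report an \linkS4class{EvalReport}.
#' @param jsonPath,confusionTsvPath output paths (NULL skips).
#' @return Invisibly, the written paths.
#' @export
writeEvalReport <- function(report, jsonPath = NULL,
                            confusionTsvPath = NULL) {
    if (!is.null(jsonPath))
        jsonlite::write_json(
            list(balanced_accuracy = report@balancedAccuracy,
                 roc_auc = report@rocAuc, pr_auc = report@prAuc,
                 f1_macro = report@f1, f1_weighted = report@f1Weighted,
                 per_class_recall = as.list(report@perClassRecall)),
            jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(confusionTsvPath)) {
        out <- data.frame(true = rownames(report@confusion),
                          report@confusion, check.names = FALSE)
        utils::write.table(out, confusionTsvPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(c(jsonPath, confusionTsvPath))
}
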