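#' @useDynLib rankRF, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Extract one tree of a fitted model into flat arrays (0-based children and
# split features, -1 at terminals; leaf classes 0-based) plus in-bag covers.
.treeArrays <- function(model, treeIdx) {
    ti <- ranger::treeInfo(model@forest, treeIdx)
    nnode <- nrow(ti)
    left <- ifelse(is.na(ti$leftChild), -1L, as.integer(ti$leftChild))
    right <- ifelse(is.na(ti$rightChild), -1L, as.integer(ti$rightChild))
    splitvar <- ifelse(ti$terminal, -1L, as.integer(ti$splitvarID))
    splitval <- ifelse(ti$terminal, 0, ti$splitval)
    pred <- ti$prediction
    leafclass <- ifelse(ti$terminal,
                        as.integer(factor(as.character(pred),
                                          levels = model@classes)) - 1L,
                        -1L)
    leafclass[is.na(leafclass)] <- -1L
    inbag <- model@forest$inbag.counts[[treeIdx]]
    if (is.null(inbag))
        stop("model lacks in-bag counts; refit with fitRankForest()")
    cover <- cppNodeCovers(left, right, splitvar, splitval, model@trainX,
                           as.numeric(inbag))
    list(left = left, right = right, splitvar = splitvar,
         splitval = splitval, leafclass = leafclass, cover = cover)
}

#' Exact per-sample, per-class Shapley attributions for a rank forest
#'
#' Computes exact Shapley values of every panel gene for every sample and
#' class, using the tree-path conditional-expectation value function (the
#' TreeSHAP game): for a feature coalition S each tree is traversed
#' following the sample on features in S and weighting branches by in-bag
#' cover fractions on the rest; leaf values are the one-hot class votes, so
#' forest attributions are in units of predicted vote fraction. Local
#' accuracy holds exactly: for every sample and class, base value plus the
#' attribution sum equals the predicted class probability.
#'
#' @param model a \linkS4class{RankForestModel} (fitted with in-bag counts,
#'   as \code{\link{fitRankForest}} does).
#' @param ranked a \linkS4class{RankedDataset} aligned to (or containing)
#'   the model panel; typically the evaluation cohort.
#' @return An \linkS4class{AttributionSummary}.
#' @export
computeAttributions <- function(model, ranked) {
    x <- .alignToModel(model, ranked)
    nsamp <- nrow(x); nfeat <- ncol(x); k <- length(model@classes)
    phi <- array(0, c(nsamp, nfeat, k))
    base <- numeric(k)
    for (t in seq_len(model@nTrees)) {
        tr <- .treeArrays(model, t)
        phi <- phi + array(cppTreeShap(tr$left, tr$right, tr$splitvar,
                                       tr$splitval, tr$leafclass, tr$cover,
                                       x, k),
                           c(nsamp, nfeat, k))
        leaves <- which(tr$splitvar < 0L)
        lv <- tr$cover[leaves] / tr$cover[1L]
        base <- base + vapply(seq_len(k) - 1L, function(cls)
            sum(lv[tr$leafclass[leaves] == cls]), numeric(1))
    }
    phi <- phi / model@nTrees
    base <- base / model@nTrees
    attributions <- aperm(phi, c(1, 3, 2))
    dimnames(attributions) <- list(rownames(x), model@classes, model@genes)
    meanAbs <- t(apply(abs(attributions), c(2, 3), mean))
    overall <- rowSums(meanAbs)
    new("AttributionSummary", attributions = attributions,
        baseValues = stats::setNames(base, model@classes),
        meanAbsPerClass = meanAbs,
        overallRank = names(sort(overall, decreasing = TRUE)))
}

#' Brute-force Shapley oracle by coalition enumeration
#'
#' Independent reference computation of the same tree-path Shapley game as
#' \code{\link{computeAttributions}}: for every coalition of the model's
#' features the value function is evaluated by explicit tree traversal
#' (follow the sample on in-coalition features, average by in-bag cover
#' fractions otherwise) and Shapley values are assembled from the defining
#' weighted sum over all 2^M coalitions. Exponential in the panel size;
#' refuses more than 12 features. Intended for validating the
#' polynomial-time implementation on toy forests.
#'
#' @inheritParams computeAttributions
#' @return List with \code{attributions} (sample x class x gene array) and
#'   \code{baseValues}.
#' @export
bruteForceShapley <- function(model, ranked) {
    x <- .alignToModel(model, ranked)
    M <- ncol(x)
    if (M > 12L) stop("coalition enumeration is limited to <= 12 features")
    k <- length(model@classes)
    trees <- lapply(seq_len(model@nTrees), function(t) .treeArrays(model, t))

    traverse <- function(tr, node, inS, xs) {
        if (tr$splitvar[node + 1L] < 0L) {
            v <- numeric(k)
            v[tr$leafclass[node + 1L] + 1L] <- 1
            return(v)
        }
        f <- tr$splitvar[node + 1L] + 1L
        l <- tr$left[node + 1L]; r <- tr$right[node + 1L]
        if (inS[f]) {
            nxt <- if (xs[f] <= tr$splitval[node + 1L]) l else r
            return(traverse(tr, nxt, inS, xs))
        }
        wl <- tr$cover[l + 1L] / tr$cover[node + 1L]
        wr <- tr$cover[r + 1L] / tr$cover[node + 1L]
        wl * traverse(tr, l, inS, xs) + wr * traverse(tr, r, inS, xs)
    }
    vfun <- function(inS, xs) {
        Reduce(`+`, lapply(trees, traverse, node = 0L, inS = inS,
                           xs = xs)) / model@nTrees
    }

    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), M))
    phi <- array(0, c(nrow(x), k, M),
                 dimnames = list(rownames(x), model@classes, model@genes))
    base <- NULL
    for (s in seq_len(nrow(x))) {
        xs <- x[s, ]
        vals <- apply(subsets, 1, function(inS)
            vfun(as.logical(inS), xs))  # k x 2^M
        if (k == 1L) vals <- matrix(vals, nrow = 1L)
        sizes <- rowSums(subsets)
        if (is.null(base)) base <- vals[, 1L]
        for (i in seq_len(M)) {
            has <- subsets[[i]]
            for (si in which(!has)) {
                sz <- sizes[si]
                w <- factorial(sz) * factorial(M - sz - 1) / factorial(M)
                withI <- si + 2^(i - 1)  # flip bit i on
                phi[s, , i] <- phi[s, , i] +
                    w * (vals[, withI] - vals[, si])
            }
        }
    }
    list(attributions = phi,
         baseValues = stats::setNames(base, model@classes))
}

#' Top influential genes by overall attribution
#'
#' Orders genes by summed mean |attribution| across classes and returns the
#' top k with their per-class means — the tabular analogue of an attribution
#' summary plot.
#'
#' @param summary an \linkS4class{AttributionSummary}.
#' @param k number of genes (default 20).
#' @return data.frame: gene, overall mean |attribution|, one column per
#'   class.
#' @export
topInfluential <- function(summary, k = 20) {
    if (k < 1L) stop("k must be >= 1")
    if (k > length(summary@overallRank))
        stop("k exceeds the panel size")
    genes <- summary@overallRank[seq_len(k)]
    m <- summary@meanAbsPerClass[genes, , drop = FALSE]
    data.frame(gene = genes, overall = rowSums(m), m, check.names = FALSE,
               row.names = NULL)
}

#' Write an attribution summary as TSV (gene x class mean |attribution|) +
#' JSON
#'
#' @param summary an \linkS4class{AttributionSummary}.
#' @param tsvPath,jsonPath output paths (NULL skips).
#' @return Invisibly, the written paths.
#' @export
writeAttributionSummary <- function(summary, tsvPath = NULL,
                                    jsonPath = NULL) {
    if (!is.null(tsvPath)) {
        out <- data.frame(gene = rownames(summary@meanAbsPerClass),
                          summary@meanAbsPerClass, check.names = FALSE)
        utils::write.table(out, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    if (!is.null(jsonPath))
        jsonlite::write_json(
            list(base_values = as.list(summary@baseValues),
                 overall_rank = summary@overallRank),
            jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(tsvPath, jsonPath))
}
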