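#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom SummarizedExperiment "assay<-" "colData<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

#' ExpressionDataset: a gene-by-sample expression cohort
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment} holding one cohort:
#' a numeric gene-by-sample matrix on its platform-native (any strictly
#' monotone) scale, optional per-sample class labels, and cohort identity
#' (platform and dataset ids, train/test role). Gene symbols are opaque,
#' case-sensitive strings and must be unique within a dataset.
#'
#' Column data columns: \code{label} (NA when unlabelled) and
#' \code{cohort_role} (\code{"train"}, \code{"test"}, or NA).
#' Metadata entries: \code{platform_id}, \code{dataset_id}.
#'
#' @seealso \code{\link{ExpressionDataset}} (constructor),
#'   \code{\link{rankWithinSamples}}, \code{\link{readExpressionMatrix}}
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

.validExpressionDataset <- function(object) {
    msg <- character()
    v <- assay(object)
    if (!is.numeric(v))
        msg <- c(msg, "expression values must be numeric")
    if (any(!is.finite(v)))
        msg <- c(msg, "expression values must be finite (no NA/NaN/Inf)")
    g <- rownames(object)
    if (is.null(g) || anyNA(g))
        msg <- c(msg, "gene symbols (rownames) are required")
    else if (anyDuplicated(g)) {
        dup <- unique(g[duplicated(g)])
        msg <- c(msg, sprintf("duplicate gene symbol(s): %s",
                              paste(dup, collapse = ", ")))
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    cd <- colData(object)
    if (!all(c("label", "cohort_role") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'label' and 'cohort_role'")
    else {
        lab <- cd$label
        if (!all(is.na(lab)) && anyNA(lab))
            msg <- c(msg, "labels must be present for every sample or absent for all")
    }
    for (field in c("platform_id", "dataset_id"))
        if (!is.character(metadata(object)[[field]]))
            msg <- c(msg, sprintf("metadata '%s' must be a string", field))
    if (length(msg)) msg else TRUE
}
setValidity("ExpressionDataset", .validExpressionDataset)

#' RankedDataset: within-sample ranks of an expression cohort
#'
#' An \linkS4class{ExpressionDataset} whose assay holds within-sample ranks
#' (1 = lowest expression, average ranks for ties) computed over a ranking
#' universe of \code{rankUniverseSize} genes. While the dataset still carries
#' the full universe every column sums to G(G+1)/2; after
#' \code{\link{subsetToPanel}} the ranks keep their original values (they are
#' never recomputed), so only the range invariant is enforced.
#'
#' @slot rankUniverseSize integer, the number of genes ranks were computed
#'   over (the value G such that ranks lie in [1, G]).
#' @exportClass RankedDataset
setClass("RankedDataset", contains = "ExpressionDataset",
         representation(rankUniverseSize = "integer"))

setValidity("RankedDataset", function(object) {
    msg <- character()
    r <- assay(object)
    G <- object@rankUniverseSize
    if (length(G) != 1L || is.na(G) || G < 1L)
        return("rankUniverseSize must be a positive integer")
    if (nrow(r) > 0 && (min(r) < 1 - 1e-9 || max(r) > G + 1e-9))
        msg <- c(msg, sprintf("ranks must lie in [1, %d]", G))
    if (nrow(r) == G && ncol(r) > 0) {
        want <- G * (G + 1) / 2
        if (max(abs(colSums(r) - want)) > 1e-6)
            msg <- c(msg, "each full-universe rank column must sum to G(G+1)/2")
    }
    if (length(msg)) msg else TRUE
})

#' BorutaRunResult: one run of the shadow-feature selection
#'
#' Per-gene hit counts over \code{nCycles} shadow-comparison cycles, the
#' exact binomial acceptance threshold, and the resulting three-way decision.
#'
#' @slot hitCounts named integer vector, cycles in which the gene's
#'   importance strictly exceeded the cycle's maximum shadow importance.
#' @slot nCycles integer, number of cycles.
#' @slot threshold integer k*, the 99.5\% quantile of Binomial(nCycles, 1/2);
#'   genes are accepted when hits > k*.
#' @slot decision named character, one of "accepted", "rejected", "tentative".
#' @slot seed integer seed of the run.
#' @exportClass BorutaRunResult
setClass("BorutaRunResult",
         representation(hitCounts = "integer", nCycles = "integer",
                        threshold = "integer", decision = "character",
                        seed = "integer"))

setValidity("BorutaRunResult", function(object) {
    h <- object@hitCounts
    if (any(h < 0L) || any(h > object@nCycles))
        return("hit counts must lie in [0, nCycles]")
    k <- object@threshold
    acc <- object@decision == "accepted"
    if (!identical(unname(acc), unname(h > k)))
        return("decisions inconsistent with hit counts and threshold")
    TRUE
})

#' ConsensusSelection: repeated-run Boruta consensus
#'
#' Selection frequencies of each gene over R independent Boruta runs and the
#' genes accepted in at least a fraction tau of them.
#'
#' @slot frequency named numeric, per-gene acceptance frequency in [0, 1].
#' @slot nRuns integer R.
#' @slot tau numeric consensus threshold (selection is inclusive: freq >= tau).
#' @slot selected character, consensus gene panel.
#' @slot runs list of \linkS4class{BorutaRunResult}.
#' @slot seed integer master seed.
#' @exportClass ConsensusSelection
setClass("ConsensusSelection",
         representation(frequency = "numeric", nRuns = "integer",
                        tau = "numeric", selected = "character",
                        runs = "list", seed = "integer"))

setValidity("ConsensusSelection", function(object) {
    f <- object@frequency
    if (any(f < 0 | f > 1)) return("frequencies must lie in [0, 1]")
    want <- names(f)[f >= object@tau - 1e-12]
    if (!identical(sort(want), sort(object@selected)))
        return("selected set inconsistent with frequencies and tau")
    TRUE
})

#' RankForestModel: a rank Random Forest classifier
#'
#' A fitted forest of decision trees over within-sample gene ranks, plus the
#' bookkeeping needed for aligned prediction and exact attribution: the gene
#' panel in training order, the class list, the training matrix and in-bag
#' counts (used to compute per-node covers for Shapley values), and the seed.
#'
#' @slot forest the underlying \code{ranger} object.
#' @slot genes character, panel in training order.
#' @slot classes character, class levels in score-column order.
#' @slot nTrees integer.
#' @slot seed integer.
#' @slot trainX numeric matrix (samples x genes) the forest was fitted on.
#' @slot params list of forest hyperparameters.
#' @exportClass RankForestModel
setClass("RankForestModel",
         representation(forest = "ANY", genes = "character",
                        classes = "character", nTrees = "integer",
                        seed = "integer", trainX = "matrix",
                        params = "list"))

#' EvalReport: the metric panel for a fitted classifier
#'
#' @slot balancedAccuracy unweighted mean of per-class recalls.
#' @slot rocAuc binary: standard ROC-AUC for the positive class; multiclass:
#'   macro one-vs-rest average over vote-fraction scores.
#' @slot prAuc precision-recall AUC (same averaging scheme).
#' @slot f1 macro-averaged F1.
#' @slot f1Weighted support-weighted F1 (reported alongside macro).
#' @slot confusion integer matrix, true class (rows) x predicted class.
#' @slot perClassRecall named numeric.
#' @exportClass EvalReport
setClass("EvalReport",
         representation(balancedAccuracy = "numeric", rocAuc = "numeric",
                        prAuc = "numeric", f1 = "numeric",
                        f1Weighted = "numeric", confusion = "matrix",
                        perClassRecall = "numeric"))

setValidity("EvalReport", function(object) {
    msg <- character()
    ms <- c(object@balancedAccuracy, object@rocAuc, object@prAuc, object@f1)
    if (any(ms < -1e-9 | ms > 1 + 1e-9))
        msg <- c(msg, "all metrics must lie in [0, 1]")
    ba <- mean(object@perClassRecall)
    if (abs(ba - object@balancedAccuracy) > 1e-9)
        msg <- c(msg, "balanced accuracy must equal the mean per-class recall")
    if (length(msg)) msg else TRUE
})

#' SfsTrace: record of a sequential floating forward selection
#'
#' @slot steps data.frame with columns step, action ("add"/"remove"), gene,
#'   panel (comma-joined panel after the step), size, score (CV mean ROC-AUC),
#'   ciBound (95\% normal half-width over fold scores).
#' @slot bestPanel character, the panel maximising the CV score (smallest such
#'   panel on ties).
#' @slot bestScore numeric.
#' @slot seed integer.
#' @exportClass SfsTrace
setClass("SfsTrace",
         representation(steps = "data.frame", bestPanel = "character",
                        bestScore = "numeric", seed = "integer"))

#' AttributionSummary: exact per-sample, per-class Shapley attributions
#'
#' @slot attributions numeric array sample x class x gene, in units of
#'   predicted-probability contribution.
#' @slot baseValues named numeric, per-class expected prediction (cover-
#'   weighted mean leaf value averaged over trees).
#' @slot meanAbsPerClass gene x class matrix of mean |attribution|.
#' @slot overallRank character, genes ordered by decreasing summed
#'   mean |attribution| across classes.
#' @exportClass AttributionSummary
setClass("AttributionSummary",
         representation(attributions = "array", baseValues = "numeric",
                        meanAbsPerClass = "matrix", overallRank = "character"))

#' DEResult: two-group differential expression
#'
#' @slot table data.frame: gene, statistic (Mann-Whitney U of group A),
#'   p, padj, direction ("up"/"down"/"ns"), medianA, medianB.
#' @slot groups character(2), the group labels (A, B); "up" means higher in
#'   group A.
#' @slot alpha FDR level.
#' @exportClass DEResult
setClass("DEResult",
         representation(table = "data.frame", groups = "character",
                        alpha = "numeric"))

#' SubtypeDEResult: ANOVA-filtered one-vs-rest subtype differential expression
#'
#' @slot anova data.frame: gene, F, p, padj, pass.
#' @slot followUp data.frame of one-sided one-vs-rest Mann-Whitney tests for
#'   ANOVA-passing genes: gene, subtype, U, p, padj, significant.
#' @slot upregulated named list: subtype -> character vector of genes assigned
#'   to it (each gene in at most one list).
#' @slot alpha FDR level used at both stages.
#' @exportClass SubtypeDEResult
setClass("SubtypeDEResult",
         representation(anova = "data.frame", followUp = "data.frame",
                        upregulated = "list", alpha = "numeric"))

#' OraResult: hypergeometric over-representation analysis
#'
#' @slot table data.frame: set, overlap (k), setSize (K, after background
#'   intersection), querySize (n), backgroundSize (N), p, padj, significant.
#' @slot alpha adjusted-p significance level.
#' @exportClass OraResult
setClass("OraResult",
         representation(table = "data.frame", alpha = "numeric"))
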