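#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, genes x samples, with gene symbols as
#'   rownames and sample ids as colnames. Platform-native scale; any strictly
#'   monotone transform of the underlying signal is acceptable because all
#'   modelling happens on within-sample ranks.
#' @param labels per-sample class labels (character), or NULL when the cohort
#'   is unlabelled.
#' @param platformId,datasetId strings identifying the measurement platform
#'   and the cohort.
#' @param cohortRole per-sample "train"/"test" role, a single value recycled
#'   to all samples, or NULL. Fixed at construction; downstream code never
#'   rewrites it (no train/test leakage by construction).
#' @return An \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' ExpressionDataset(m, labels = c("tumor", "normal"),
#'                   platformId = "p1", datasetId = "d1")
#' @export
ExpressionDataset <- function(values, labels = NULL, platformId = "unknown",
                              datasetId = "unknown", cohortRole = NULL) {
    values <- as.matrix(values)
    n <- ncol(values)
    if (n == 0L)
        stop("refusing to build a dataset with no samples")
    if (is.null(labels)) labels <- rep(NA_character_, n)
    if (is.null(cohortRole)) cohortRole <- rep(NA_character_, n)
    if (length(cohortRole) == 1L) cohortRole <- rep(cohortRole, n)
    se <- SummarizedExperiment(
        assays = list(values = values),
        colData = DataFrame(label = as.character(labels),
                            cohort_role = as.character(cohortRole),
                            row.names = colnames(values)))
    metadata(se) <- list(platform_id = as.character(platformId),
                         dataset_id = as.character(datasetId))
    new("ExpressionDataset", se)
}

#' Accessors for expression datasets
#'
#' \code{geneIds} and \code{sampleIds} return the ordered gene symbols and
#' sample ids; \code{exprValues} the numeric matrix; \code{sampleLabels} the
#' per-sample class labels (NULL when the cohort is unlabelled);
#' \code{platformId}, \code{datasetId} and \code{cohortRole} the cohort
#' identity fields; \code{rankValues} the rank matrix of a
#' \linkS4class{RankedDataset}.
#'
#' @param x an \linkS4class{ExpressionDataset} or \linkS4class{RankedDataset}.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
geneIds <- function(x) rownames(x)

#' @rdname accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname accessors
#' @export
exprValues <- function(x) assay(x)

#' @rdname accessors
#' @export
sampleLabels <- function(x) {
    lab <- colData(x)$label
    if (all(is.na(lab))) return(NULL)
    stats::setNames(lab, colnames(x))
}

#' @rdname accessors
#' @export
platformId <- function(x) metadata(x)$platform_id

#' @rdname accessors
#' @export
datasetId <- function(x) metadata(x)$dataset_id

#' @rdname accessors
#' @export
cohortRole <- function(x) stats::setNames(colData(x)$cohort_role, colnames(x))

#' @rdname accessors
#' @export
rankValues <- function(x) {
    stopifnot(is(x, "RankedDataset"))
    assay(x)
}

setMethod("show", "ExpressionDataset", function(object) {
    cat(sprintf("%s: %d genes x %d samples\n", class(object),
                nrow(object), ncol(object)))
    cat(sprintf("  platform: %s | dataset: %s\n",
                platformId(object), datasetId(object)))
    lab <- sampleLabels(object)
    if (is.null(lab)) {
        cat("  labels: absent\n")
    } else {
        tab <- table(lab)
        cat(sprintf("  labels: %s\n",
                    paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    }
    role <- cohortRole(object)
    if (!all(is.na(role))) {
        tab <- table(role, useNA = "no")
        cat(sprintf("  roles: %s\n",
                    paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    }
    if (is(object, "RankedDataset"))
        cat(sprintf("  within-sample ranks over a %d-gene universe\n",
                    object@rankUniverseSize))
    invisible(NULL)
})

setMethod("show", "ConsensusSelection", function(object) {
    cat(sprintf("ConsensusSelection: %d/%d genes selected (tau = %.2f, R = %d)\n",
                length(object@selected), length(object@frequency),
                object@tau, object@nRuns))
    if (length(object@selected))
        cat("  ", paste(utils::head(object@selected, 10), collapse = ", "),
            if (length(object@selected) > 10) "..." else "", "\n")
    invisible(NULL)
})

setMethod("show", "EvalReport", function(object) {
    cat("EvalReport\n")
    cat(sprintf("  balanced accuracy: %.4f\n", object@balancedAccuracy))
    cat(sprintf("  ROC-AUC: %.4f | PR-AUC: %.4f\n",
                object@rocAuc, object@prAuc))
    cat(sprintf("  F1 (macro): %.4f | F1 (weighted): %.4f\n",
                object@f1, object@f1Weighted))
    cat("  confusion matrix (true x predicted):\n")
    print(object@confusion)
    invisible(NULL)
})

setMethod("show", "SfsTrace", function(object) {
    cat(sprintf("SfsTrace: %d steps; best panel (%d genes, score %.4f):\n",
                nrow(object@steps), length(object@bestPanel),
                object@bestScore))
    cat("  ", paste(object@bestPanel, collapse = ", "), "\n")
    invisible(NULL)
})

# internal: replace the assay of a dataset-like object, keeping annotation
.withValues <- function(x, values) {
    SummarizedExperiment::assay(x, withDimnames = FALSE) <- values
    x
}
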