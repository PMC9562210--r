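#' Intersect the gene universes of several cohorts
#'
#' Platform differences mean each cohort measures a different (overlapping)
#' gene universe; all downstream analysis runs on the common intersection so
#' rank scales are comparable across platforms.
#'
#' @param datasets list of \linkS4class{ExpressionDataset} (>= 2).
#' @return List with \code{genes} (the intersection, in the first dataset's
#'   order) and \code{datasets} (each restricted to it, identical gene order).
#' @export
intersectGeneUniverse <- function(datasets) {
    if (length(datasets) < 2L)
        stop("need at least 2 datasets to intersect")
    common <- Reduce(intersect, lapply(datasets, geneIds))
    if (!length(common))
        stop("gene universes are disjoint: empty intersection")
    common <- geneIds(datasets[[1L]])[geneIds(datasets[[1L]]) %in% common]
    list(genes = common,
         datasets = lapply(datasets, function(d) d[common, ]))
}

#' Rank genes within each sample
#'
#' Replaces each sample's expression values by their within-sample ranks
#' (ascending, 1 = lowest; ties get average ranks), the nonparametric
#' transform that makes cohorts from different platforms mergeable: the rank
#' vector is invariant under any strictly increasing per-sample transform of
#' the values. Ranks should be computed over the intersected common universe
#' before any panel subsetting so rank magnitudes are platform-comparable.
#'
#' @param dataset an \linkS4class{ExpressionDataset} restricted to the
#'   working gene universe.
#' @return A \linkS4class{RankedDataset}.
#' @export
rankWithinSamples <- function(dataset) {
    stopifnot(is(dataset, "ExpressionDataset"))
    v <- exprValues(dataset)
    constant <- apply(v, 2, function(col) length(unique(col)) == 1L)
    if (any(constant) && nrow(v) > 1L)
        warning(sprintf("sample(s) with all-equal values (all ranks (G+1)/2): %s",
                        paste(colnames(v)[constant], collapse = ", ")))
    r <- apply(v, 2, rank, ties.method = "average")
    if (nrow(v) == 1L) r <- matrix(r, nrow = 1L, dimnames = dimnames(v))
    new("RankedDataset", .withValues(dataset, r),
        rankUniverseSize = nrow(v))
}

#' Restrict a ranked dataset to a gene panel
#'
#' Rank values are NOT recomputed: each gene keeps the rank it held in the
#' full working universe, so panel subsetting commutes with sample selection
#' and panels from different platforms stay comparable.
#'
#' @param ranked a \linkS4class{RankedDataset}.
#' @param geneList character vector of panel genes (subset of the ranked
#'   genes); output follows this order.
#' @return A \linkS4class{RankedDataset} restricted to the panel.
#' @export
subsetToPanel <- function(ranked, geneList) {
    stopifnot(is(ranked, "RankedDataset"))
    missing <- setdiff(geneList, geneIds(ranked))
    if (length(missing))
        stop(sprintf("panel gene(s) absent from dataset: %s",
                     paste(missing, collapse = ", ")))
    ranked[geneList, ]
}

#' Select the k most variable genes by pooled rank variance
#'
#' Variance is computed on within-sample ranks pooled across all provided
#' cohorts' samples (not on raw values), so the measure is meaningful
#' across platforms. Ties break by gene-symbol lexicographic order for
#' determinism.
#'
#' @param datasets list of \linkS4class{RankedDataset} sharing a gene
#'   universe (same genes, same order).
#' @param k number of genes to keep.
#' @return Character vector of k gene symbols, by decreasing pooled variance.
#' @export
selectTopVariable <- function(datasets, k) {
    if (!is.list(datasets)) datasets <- list(datasets)
    genes <- geneIds(datasets[[1L]])
    for (d in datasets)
        if (!identical(geneIds(d), genes))
            stop("datasets must share an identical gene universe")
    if (k < 1L) stop("k must be >= 1")
    pooled <- do.call(cbind, lapply(datasets, rankValues))
    v <- apply(pooled, 1, stats::var)
    if (k > length(genes)) {
        warning(sprintf("k = %d exceeds universe size %d; returning all genes",
                        k, length(genes)))
        k <- length(genes)
    }
    ord <- order(-v, genes)
    genes[ord][seq_len(k)]
}
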