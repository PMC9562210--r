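.META_COLS <- c("sample_id", "label", "platform_id", "dataset_id",
                "cohort_role")

#' Read a gene-by-sample expression matrix with its sample metadata
#'
#' The matrix is tab-delimited with gene symbols in the first column and a
#' header row of sample ids; the metadata file is tab-delimited with columns
#' \code{sample_id}, \code{label}, \code{platform_id}, \code{dataset_id},
#' \code{cohort_role}. Missing values are rejected (the pipeline has no
#' imputation step); duplicate gene symbols and samples missing from the
#' metadata are errors.
#'
#' @param path path to the expression matrix TSV.
#' @param metadataPath path to the metadata TSV.
#' @return An \linkS4class{ExpressionDataset}.
#' @export
readExpressionMatrix <- function(path, metadataPath) {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (nrow(raw) == 0L || ncol(raw) < 2L)
        stop("expression matrix must have at least one gene and one sample")
    genes <- raw[[1L]]
    if (anyDuplicated(genes))
        stop(sprintf("duplicate gene symbol(s) in %s: %s", path,
                     paste(unique(genes[duplicated(genes)]), collapse = ", ")))
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
    if (anyNA(num)) {
        bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                     genes[bad[1L]], colnames(vals)[bad[2L]]))
    }
    dimnames(num) <- list(genes, colnames(vals))

    meta <- utils::read.delim(metadataPath, header = TRUE, sep = "\t",
                              check.names = FALSE, colClasses = "character")
    missingCols <- setdiff(.META_COLS, colnames(meta))
    if (length(missingCols))
        stop(sprintf("metadata is missing column(s): %s",
                     paste(missingCols, collapse = ", ")))
    if (anyDuplicated(meta$sample_id))
        stop("duplicate sample_id in metadata")
    unmatched <- setdiff(colnames(num), meta$sample_id)
    if (length(unmatched))
        stop(sprintf("sample(s) in matrix but not metadata: %s",
                     paste(unmatched, collapse = ", ")))
    meta <- meta[match(colnames(num), meta$sample_id), , drop = FALSE]
    labels <- meta$label
    labels[!nzchar(labels) | is.na(labels)] <- NA_character_
    roles <- meta$cohort_role
    roles[!nzchar(roles) | is.na(roles)] <- NA_character_
    ExpressionDataset(num, labels = labels,
                      platformId = unique(meta$platform_id)[1L],
                      datasetId = unique(meta$dataset_id)[1L],
                      cohortRole = roles)
}

#' Write an expression dataset to matrix + metadata TSVs
#'
#' Values are written at full double precision so that
#' \code{\link{readExpressionMatrix}} reproduces the dataset exactly.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param path,metadataPath output paths.
#' @return Invisibly, \code{c(path, metadataPath)}.
#' @export
writeExpressionMatrix <- function(dataset, path, metadataPath) {
    stopifnot(is(dataset, "ExpressionDataset"))
    validObject(dataset)
    v <- exprValues(dataset)
    if (ncol(v) == 0L)
        stop("refusing to write a dataset with no samples")
    fmt <- apply(v, 2, function(col) sprintf("%.17g", col))
    if (nrow(v) == 1L) fmt <- matrix(fmt, nrow = 1L)
    out <- cbind(gene = rownames(v), as.data.frame(fmt))
    colnames(out) <- c("gene", colnames(v))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    lab <- colData(dataset)$label
    lab[is.na(lab)] <- ""
    role <- colData(dataset)$cohort_role
    role[is.na(role)] <- ""
    meta <- data.frame(sample_id = colnames(v), label = lab,
                       platform_id = platformId(dataset),
                       dataset_id = datasetId(dataset),
                       cohort_role = role)
    utils::write.table(meta, metadataPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(path, metadataPath))
}

#' Read a plain-text gene list
#'
#' One symbol per line; duplicates are collapsed (order of first appearance)
#' with a warning; an empty file is an error.
#'
#' @param path path to the gene list.
#' @return Character vector of unique gene symbols.
#' @export
readGeneList <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        stop(sprintf("gene list '%s' is empty", path))
    if (anyDuplicated(lines)) {
        warning(sprintf("collapsing %d duplicate symbol(s) in '%s'",
                        sum(duplicated(lines)), path))
        lines <- unique(lines)
    }
    lines
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, \code{name TAB description TAB member...}.
#'
#' @param path path to the .gmt file.
#' @return Named list of character vectors of member genes.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        stop(sprintf("GMT file '%s' is empty", path))
    sets <- list()
    for (ln in lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 3L)
            stop(sprintf("malformed GMT line (need name, description, members): %s",
                         substr(ln, 1, 60)))
        sets[[parts[1L]]] <- unique(parts[-(1:2)])
    }
    sets
}

#' Write a gene list, one symbol per line
#' @param genes character vector of symbols.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneList <- function(genes, path) {
    writeLines(genes, path)
    invisible(path)
}
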