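#' Mann-Whitney U test
#'
#' Exact-enumeration p-value when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction. The degenerate case of two identical constant
#' groups carries no evidence and returns p = 1.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param alternative "two.sided" (default), "greater" (A tends larger), or
#'   "less".
#' @return List with \code{U} (the U statistic of group A) and \code{p}.
#' @export
mannWhitney <- function(a, b, alternative = c("two.sided", "greater",
                                              "less")) {
    alternative <- match.arg(alternative)
    if (!length(a) || !length(b)) stop("both groups must be non-empty")
    hasTies <- anyDuplicated(c(a, b)) > 0L
    exact <- !hasTies && (length(a) + length(b)) <= 12L
    U <- sum(rank(c(a, b))[seq_along(a)]) -
        length(a) * (length(a) + 1) / 2
    if (stats::sd(c(a, b)) == 0)
        return(list(U = U, p = 1))
    wt <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                           correct = TRUE))
    p <- wt$p.value
    if (is.na(p)) p <- 1
    list(U = unname(U), p = min(p, 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR-controlling step-up procedure: sorted ascending,
#' \code{q_(i) = min_{j >= i} p_(j) * m / j}, clipped at 1 and returned in
#' the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression of a gene panel
#'
#' Per-gene two-sided Mann-Whitney test on platform-native expression values
#' (not ranks; run this within one cohort where raw values are comparable),
#' Benjamini-Hochberg adjusted. Significant genes are labelled "up" or
#' "down" by group-median comparison (relative to the first group), the rest
#' "ns".
#'
#' @param dataset an \linkS4class{ExpressionDataset} of the panel genes.
#' @param labels two-group labels; defaults to the dataset's own.
#' @param groups optional character(2) choosing/ordering the two groups;
#'   defaults to the sorted unique labels. "up" means higher in
#'   \code{groups[1]}.
#' @param alpha FDR level (default 0.05).
#' @return A \linkS4class{DEResult}.
#' @export
binaryDe <- function(dataset, labels = NULL, groups = NULL, alpha = 0.05) {
    labels <- .labelsOrStop(dataset, labels)
    if (is.null(groups)) groups <- sort(unique(labels))
    if (length(groups) != 2L || !all(labels %in% groups))
        stop("binaryDe needs exactly two groups covering all samples")
    if (min(table(labels)) < 2L) stop("each group needs >= 2 samples")
    v <- exprValues(dataset)
    idxA <- labels == groups[1L]
    res <- lapply(seq_len(nrow(v)), function(i) {
        mw <- mannWhitney(v[i, idxA], v[i, !idxA], "two.sided")
        c(U = mw$U, p = mw$p,
          medianA = stats::median(v[i, idxA]),
          medianB = stats::median(v[i, !idxA]))
    })
    res <- do.call(rbind, res)
    padj <- bhAdjust(res[, "p"])
    direction <- ifelse(padj >= alpha, "ns",
                        ifelse(res[, "medianA"] > res[, "medianB"],
                               "up", "down"))
    new("DEResult",
        table = data.frame(gene = rownames(v), statistic = res[, "U"],
                           p = res[, "p"], padj = padj,
                           direction = direction,
                           medianA = res[, "medianA"],
                           medianB = res[, "medianB"], row.names = NULL),
        groups = groups, alpha = alpha)
}

#' Subtype differential expression: ANOVA filter, one-vs-rest follow-up
#'
#' Stage one applies the classical one-way F-test across subtypes to each
#' gene's expression values, Benjamini-Hochberg adjusted; genes with
#' zero variance everywhere are skipped with a warning. Stage two, computed
#' only for ANOVA-passing genes, tests each subtype against the pooled rest
#' with a one-sided (greater) Mann-Whitney test, adjusting jointly across
#' the whole gene-by-subtype follow-up family. A gene is assigned to the
#' subtype where it is significantly upregulated; if several subtypes
#' qualify, the smallest adjusted p (then lexicographic subtype) wins, so
#' each gene lands in at most one subtype list.
#'
#' @param dataset an \linkS4class{ExpressionDataset} of the panel genes.
#' @param labels subtype labels (4 subtypes, >= 2 samples each); defaults to
#'   the dataset's own.
#' @param alpha FDR level for both stages (default 0.05).
#' @return A \linkS4class{SubtypeDEResult}.
#' @export
subtypeDe <- function(dataset, labels = NULL, alpha = 0.05) {
    labels <- .labelsOrStop(dataset, labels)
    subtypes <- sort(unique(labels))
    if (length(subtypes) < 2L)
        stop("need at least 2 subtypes")
    if (min(table(labels)) < 2L)
        stop(sprintf("every subtype needs >= 2 samples (missing/short: %s)",
                     paste(names(which(table(labels) < 2L)),
                           collapse = ", ")))
    v <- exprValues(dataset)
    fl <- factor(labels)

    anovaRows <- lapply(seq_len(nrow(v)), function(i) {
        y <- v[i, ]
        if (all(vapply(split(y, fl), stats::sd, numeric(1)) == 0)) {
            warning(sprintf("gene %s has zero variance in every subtype; skipped",
                            rownames(v)[i]))
            return(c(F = NA_real_, p = NA_real_))
        }
        ow <- stats::oneway.test(y ~ fl, var.equal = TRUE)
        c(F = unname(ow$statistic), p = unname(ow$p.value))
    })
    anovaRows <- do.call(rbind, anovaRows)
    ok <- !is.na(anovaRows[, "p"])
    padj <- rep(NA_real_, nrow(v))
    padj[ok] <- bhAdjust(anovaRows[ok, "p"])
    pass <- !is.na(padj) & padj < alpha
    anovaTab <- data.frame(gene = rownames(v), F = anovaRows[, "F"],
                           p = anovaRows[, "p"], padj = padj, pass = pass,
                           row.names = NULL)

    follow <- list()
    for (i in which(pass)) {
        for (st in subtypes) {
            inSt <- labels == st
            mw <- mannWhitney(v[i, inSt], v[i, !inSt], "greater")
            follow[[length(follow) + 1L]] <-
                data.frame(gene = rownames(v)[i], subtype = st,
                           U = mw$U, p = mw$p)
        }
    }
    if (length(follow)) {
        follow <- do.call(rbind, follow)
        follow$padj <- bhAdjust(follow$p)
        follow$significant <- follow$padj < alpha
    } else {
        follow <- data.frame(gene = character(), subtype = character(),
                             U = numeric(), p = numeric(),
                             padj = numeric(), significant = logical())
    }

    up <- stats::setNames(vector("list", length(subtypes)), subtypes)
    for (g in unique(follow$gene[follow$significant])) {
        rows <- follow[follow$gene == g & follow$significant, ]
        rows <- rows[order(rows$padj, rows$subtype), ]
        st <- rows$subtype[1L]
        up[[st]] <- c(up[[st]], g)
    }
    new("SubtypeDEResult", anova = anovaTab, followUp = follow,
        upregulated = up, alpha = alpha)
}

#' Hypergeometric over-representation analysis
#'
#' Exact upper-tail hypergeometric test of the overlap between a query gene
#' list and each gene set, against a stated background universe (the panel
#' present in all cohorts, per the pipeline's convention). Gene sets are
#' intersected with the background before testing; p-values are
#' Benjamini-Hochberg adjusted across sets.
#'
#' @param queryGenes character vector, must be a subset of the background.
#' @param backgroundGenes character vector, the background universe.
#' @param geneSets named list of character vectors (e.g. from
#'   \code{\link{readGMT}}).
#' @param alpha adjusted-p significance level (default 0.001).
#' @return An \linkS4class{OraResult}.
#' @export
ora <- function(queryGenes, backgroundGenes, geneSets, alpha = 0.001) {
    queryGenes <- unique(queryGenes)
    backgroundGenes <- unique(backgroundGenes)
    outside <- setdiff(queryGenes, backgroundGenes)
    if (length(outside))
        stop(sprintf("query gene(s) outside the background: %s",
                     paste(outside, collapse = ", ")))
    N <- length(backgroundGenes)
    n <- length(queryGenes)
    rows <- lapply(names(geneSets), function(nm) {
        set <- intersect(geneSets[[nm]], backgroundGenes)
        K <- length(set)
        k <- length(intersect(set, queryGenes))
        p <- if (K == 0L) 1 else
            stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(set = nm, overlap = k, setSize = K, querySize = n,
                   backgroundSize = N, p = p)
    })
    tab <- do.call(rbind, rows)
    tab$padj <- bhAdjust(tab$p)
    tab$significant <- tab$padj < alpha
    new("OraResult", table = tab, alpha = alpha)
}

#' Write DE / subtype DE / ORA tables as TSV (+ JSON summaries)
#'
#' @param x a \linkS4class{DEResult}, \linkS4class{SubtypeDEResult} or
#'   \linkS4class{OraResult}.
#' @param tsvPath,jsonPath output paths (NULL skips).
#' @return Invisibly, the written paths.
#' @export
writeStatsResult <- function(x, tsvPath = NULL, jsonPath = NULL) {
    tab <- if (is(x, "SubtypeDEResult")) x@followUp else x@table
    if (!is.null(tsvPath))
        utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(jsonPath)) {
        summ <- if (is(x, "DEResult"))
            list(alpha = x@alpha, groups = x@groups,
                 n_up = sum(x@table$direction == "up"),
                 n_down = sum(x@table$direction == "down"))
        else if (is(x, "SubtypeDEResult"))
            list(alpha = x@alpha,
                 n_pass_anova = sum(x@anova$pass),
                 upregulated = x@upregulated)
        else
            list(alpha = x@alpha,
                 significant = x@table$set[x@table$significant])
        jsonlite::write_json(summ, jsonPath, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    }
    invisible(c(tsvPath, jsonPath))
}
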