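#' Exact binomial acceptance threshold for shadow-feature hit counts
#'
#' Under the null, a feature beats the maximum shadow importance in each of
#' \code{nCycles} independent cycles with probability at most 1/2, so hit
#' counts are stochastically dominated by Binomial(nCycles, 1/2). The
#' acceptance threshold is the smallest k whose exact CDF reaches \code{q}:
#' \code{k* = min\{k : P(Bin(nCycles, 1/2) <= k) >= q\}}, computed by exact
#' CDF summation (no normal approximation). A feature is accepted when its
#' hit count strictly exceeds k*.
#'
#' @param nCycles number of cycles (>= 1).
#' @param q quantile level in (0.5, 1); default 0.995.
#' @return Integer k*.
#' @examples
#' binomialAcceptanceThreshold(10)  # 9
#' @export
binomialAcceptanceThreshold <- function(nCycles, q = 0.995) {
    nCycles <- as.integer(nCycles)
    if (is.na(nCycles) || nCycles < 1L)
        stop("nCycles must be a positive integer")
    if (q <= 0.5 || q >= 1)
        stop("q must lie in (0.5, 1)")
    cdf <- cumsum(stats::dbinom(0:nCycles, nCycles, 0.5))
    as.integer(which(cdf >= q - 1e-12)[1L] - 1L)
}

#' Augment a feature matrix with shuffled shadow copies
#'
#' Each shadow column is a uniformly random permutation of its source column
#' (breaking any association with the labels while keeping the marginal
#' distribution); the shadow block is concatenated to the original block,
#' shadow columns named \code{shadow_<feature>}.
#'
#' @param x numeric matrix, samples x features.
#' @param seed integer seed for the shuffles.
#' @return Matrix samples x (2 * features).
#' @export
shadowAugment <- function(x, seed) {
    if (nrow(x) < 2L) stop("need at least 2 samples to shuffle")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0("shadow_", colnames(x))
    cbind(x, shadow)
}

.labelsOrStop <- function(ranked, labels) {
    if (is.null(labels)) labels <- sampleLabels(ranked)
    if (is.null(labels)) stop("labels are required")
    labels <- as.character(labels)
    if (length(unique(labels)) < 2L)
        stop("need at least 2 classes in the labels")
    labels
}

#' One Boruta run: shadow-feature selection by exact binomial test
#'
#' In each cycle the rank matrix is augmented with freshly shuffled shadow
#' columns, a Random Forest is fitted on the merged matrix, and every real
#' gene whose importance strictly exceeds the maximum shadow importance
#' scores one hit. After \code{nCycles} cycles a gene is accepted when its
#' hit count exceeds the exact 99.5\% Binomial(nCycles, 1/2) quantile,
#' rejected when below the symmetric lower tail, and tentative otherwise.
#'
#' @param ranked a panel-restricted \linkS4class{RankedDataset} of training
#'   samples (features are within-sample ranks).
#' @param labels class labels; defaults to the dataset's own.
#' @param nCycles number of shadow cycles (default 250).
#' @param nTrees trees per within-cycle forest (default 100; the final
#'   classifier, not this step, uses 450).
#' @param importance \code{"permutation"} (out-of-bag mean decrease in
#'   accuracy, the classic choice) or \code{"impurity"} (faster).
#' @param q acceptance quantile (default 0.995).
#' @param seed integer; per-cycle seeds are spawned deterministically.
#' @return A \linkS4class{BorutaRunResult}.
#' @export
borutaRun <- function(ranked, labels = NULL, nCycles = 250, nTrees = 100,
                      importance = c("permutation", "impurity"),
                      q = 0.995, seed = 1) {
    importance <- match.arg(importance)
    labels <- .labelsOrStop(ranked, labels)
    x <- t(rankValues(ranked))
    if (ncol(x) < 2L) stop("need at least 2 features")
    genes <- colnames(x)
    y <- factor(labels)
    hits <- stats::setNames(integer(length(genes)), genes)
    cycleSeeds <- spawnSeeds(seed, 2L * nCycles)
    for (cyc in seq_len(nCycles)) {
        merged <- shadowAugment(x, seed = cycleSeeds[2L * cyc - 1L])
        fit <- ranger::ranger(x = merged, y = y, num.trees = nTrees,
                              importance = importance,
                              seed = cycleSeeds[2L * cyc],
                              num.threads = 1L)
        imp <- fit$variable.importance
        shadowMax <- max(imp[startsWith(names(imp), "shadow_")])
        hits <- hits + as.integer(imp[genes] > shadowMax)
    }
    kstar <- binomialAcceptanceThreshold(nCycles, q)
    decision <- ifelse(hits > kstar, "accepted",
                       ifelse(hits < nCycles - kstar, "rejected",
                              "tentative"))
    new("BorutaRunResult", hitCounts = hits, nCycles = as.integer(nCycles),
        threshold = kstar, decision = stats::setNames(decision, genes),
        seed = as.integer(seed))
}

#' Consensus gene selection over repeated Boruta runs
#'
#' Runs \code{\link{borutaRun}} R times with independently spawned seeds and
#' selects the genes accepted in at least a fraction \code{tau} of the runs
#' (inclusive: accepted in exactly \code{tau * R} runs counts). Tentative
#' and rejected genes count as not accepted.
#'
#' @inheritParams borutaRun
#' @param R number of runs (default 100).
#' @param tau consensus threshold in (0, 1] (default 0.90).
#' @param keepRuns keep the individual \linkS4class{BorutaRunResult}s
#'   (default TRUE; disable to save memory in long scans).
#' @return A \linkS4class{ConsensusSelection}.
#' @export
consensusSelect <- function(ranked, labels = NULL, R = 100, tau = 0.90,
                            nCycles = 250, nTrees = 100,
                            importance = c("permutation", "impurity"),
                            seed = 1, keepRuns = TRUE) {
    if (R < 1L) stop("R must be >= 1")
    if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
    importance <- match.arg(importance)
    labels <- .labelsOrStop(ranked, labels)
    runSeeds <- spawnSeeds(seed, R)
    genes <- geneIds(ranked)
    acceptCount <- stats::setNames(integer(length(genes)), genes)
    runs <- vector("list", R)
    for (r in seq_len(R)) {
        res <- borutaRun(ranked, labels = labels, nCycles = nCycles,
                         nTrees = nTrees, importance = importance,
                         seed = runSeeds[r])
        acceptCount <- acceptCount +
            as.integer(res@decision[genes] == "accepted")
        if (keepRuns) runs[[r]] <- res
    }
    freq <- acceptCount / R
    selected <- genes[freq >= tau - 1e-12]
    new("ConsensusSelection", frequency = freq, nRuns = as.integer(R),
        tau = tau, selected = selected,
        runs = if (keepRuns) runs else list(), seed = as.integer(seed))
}

#' Write a consensus selection as TSV (gene, frequency, selected) + JSON
#'
#' @param consensus a \linkS4class{ConsensusSelection}.
#' @param tsvPath,jsonPath output paths (either may be NULL to skip).
#' @return Invisibly, the written paths.
#' @export
writeConsensus <- function(consensus, tsvPath = NULL, jsonPath = NULL) {
    tab <- data.frame(gene = names(consensus@frequency),
                      frequency = unname(consensus@frequency),
                      selected = names(consensus@frequency) %in%
                          consensus@selected)
    if (!is.null(tsvPath))
        utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(jsonPath))
        jsonlite::write_json(
            list(n_runs = consensus@nRuns, tau = consensus@tau,
                 seed = consensus@seed, selected = consensus@selected),
            jsonPath, auto_unbox = TRUE, pretty = TRUE)
    invisible(c(tsvPath, jsonPath))
}
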