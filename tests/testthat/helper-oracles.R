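# Independent brute-force oracles used to validate the package's
# implementations, plus small cached fixtures shared across test files.

.fixtureCache <- new.env(parent = emptyenv())
cachedFixture <- function(key, expr) {
    if (is.null(.fixtureCache[[key]]))
        assign(key, force(expr), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

# small labelled binary cohort pair (two platforms), ranked
smallBinaryRanked <- function() cachedFixture("smallBinaryRanked", {
    cfg <- binaryFixtureConfig(nGenes = 40, nInformative = 4,
                               nPerClass = 30, seed = 401)
    common <- intersectGeneUniverse(simulateCohorts(cfg))
    lapply(common$datasets, rankWithinSamples)
})

# exact binomial CDF threshold by direct summation of binomial coefficients
oracleBinomThreshold <- function(n, q = 0.995) {
    logp <- lchoose(n, 0:n) - n * log(2)
    cdf <- cumsum(exp(logp))
    which(cdf >= q - 1e-12)[1L] - 1L
}

# Mann-Whitney exact p by enumeration of all label assignments
oracleMannWhitneyP <- function(a, b,
                               alternative = c("two.sided", "greater",
                                               "less")) {
    alternative <- match.arg(alternative)
    pool <- c(a, b)
    m <- length(a)
    uOf <- function(idx) sum(rank(pool)[idx]) - m * (m + 1) / 2
    uObs <- uOf(seq_len(m))
    allU <- combn(length(pool), m, uOf)
    switch(alternative,
        greater = mean(allU >= uObs),
        less = mean(allU <= uObs),
        two.sided = min(1, 2 * min(mean(allU >= uObs),
                                   mean(allU <= uObs))))
}

# ROC-AUC as the pairwise concordance probability (ties count 1/2)
oracleAucPairwise <- function(scores, positive) {
    ps <- scores[positive]
    ns <- scores[!positive]
    grid <- outer(ps, ns, function(p, q)
        (p > q) + 0.5 * (p == q))
    mean(grid)
}

# BH step-up written out directly from the defining formula
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
}
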