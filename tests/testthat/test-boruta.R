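test_that("binomial acceptance threshold matches exact CDF worked examples", {
    # n = 4: CDF(3) = 15/16 < 0.995 <= CDF(4) -> k* = 4 (acceptance
    # impossible at 4 cycles since hits cannot exceed 4)
    expect_identical(binomialAcceptanceThreshold(4), 4L)
    # n = 10: CDF(8) = 1013/1024 < 0.995 <= CDF(9) = 1023/1024
    expect_identical(binomialAcceptanceThreshold(10), 9L)
    expect_error(binomialAcceptanceThreshold(0), "positive")
    expect_error(binomialAcceptanceThreshold(10, q = 0.4), "0.5")
})

test_that("threshold equals brute-force CDF summation on a spot-check range", {
    for (n in c(1:20, 50, 137, 250))
        expect_identical(binomialAcceptanceThreshold(n),
                         as.integer(oracleBinomThreshold(n)),
                         info = paste("n =", n))
})

test_that("shadow augmentation permutes each column in place", {
    set.seed(31)
    x <- matrix(rnorm(40), 10, 4,
                dimnames = list(NULL, sprintf("g%d", 1:4)))
    x[, 4] <- 7  # constant column
    aug <- shadowAugment(x, seed = 5)
    expect_identical(dim(aug), c(10L, 8L))
    expect_identical(colnames(aug)[5:8], paste0("shadow_g", 1:4))
    for (j in 1:4)
        expect_identical(sort(aug[, 4 + j]), sort(x[, j]))
    expect_identical(aug[, "shadow_g4"], x[, 4])
    expect_identical(shadowAugment(x, seed = 5), aug)
    expect_error(shadowAugment(x[1, , drop = FALSE], 1), "2 samples")
})

test_that("shuffling destroys the label association on average", {
    set.seed(32)
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    x <- matrix(y + rnorm(n, 0, 0.2), ncol = 1,
                dimnames = list(NULL, "g"))
    cors <- vapply(1:500, function(i)
        cor(shadowAugment(x, seed = i)[, "shadow_g"], y), numeric(1))
    # mean correlation of the shuffled copy with the label is 0 within MC error
    expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(500))
})

test_that("a Boruta run accepts planted genes and respects its invariants", {
    rk <- smallBinaryRanked()$platformA
    res <- borutaRun(rk, nCycles = 12, nTrees = 60, seed = 42)
    expect_true(all(res@hitCounts >= 0 & res@hitCounts <= 12))
    k <- res@threshold
    expect_identical(unname(res@decision == "accepted"),
                     unname(res@hitCounts > k))
    expect_identical(unname(res@decision == "rejected"),
                     unname(res@hitCounts < 12 - k))
    # strong planted genes collect near-maximal hit counts
    planted <- intersect(sprintf("G%04d", 1:4), geneIds(rk))
    expect_true(mean(res@hitCounts[planted]) >
                    mean(res@hitCounts[setdiff(geneIds(rk), planted)]))
    # determinism
    res2 <- borutaRun(rk, nCycles = 12, nTrees = 60, seed = 42)
    expect_identical(res2@hitCounts, res@hitCounts)
})

test_that("degenerate Boruta inputs error out", {
    rk <- smallBinaryRanked()$platformA
    expect_error(borutaRun(rk, labels = rep("x", ncol(rk))), "2 classes")
    expect_error(borutaRun(subsetToPanel(rk, geneIds(rk)[1])),
                 "2 features")
})

test_that("consensus selection is inclusive at the tau boundary", {
    # the class contract encodes 'selected iff frequency >= tau'
    ok <- new("ConsensusSelection",
              frequency = c(g1 = 0.90, g2 = 0.89), nRuns = 100L,
              tau = 0.90, selected = "g1", runs = list(), seed = 1L)
    expect_s4_class(ok, "ConsensusSelection")
    expect_error(new("ConsensusSelection",
                     frequency = c(g1 = 0.90, g2 = 0.89), nRuns = 100L,
                     tau = 0.90, selected = c("g1", "g2"), runs = list(),
                     seed = 1L),
                 "inconsistent")
})

test_that("consensus runs are deterministic and frequencies live on the 1/R grid", {
    rk <- subsetToPanel(smallBinaryRanked()$platformA,
                        geneIds(smallBinaryRanked()$platformA)[1:12])
    cs1 <- consensusSelect(rk, R = 4, tau = 0.75, nCycles = 8,
                           nTrees = 40, seed = 7)
    cs2 <- consensusSelect(rk, R = 4, tau = 0.75, nCycles = 8,
                           nTrees = 40, seed = 7)
    expect_identical(cs1@frequency, cs2@frequency)
    expect_identical(cs1@selected, cs2@selected)
    expect_true(all(abs(cs1@frequency * 4 -
                            round(cs1@frequency * 4)) < 1e-12))
    expect_identical(cs1@selected,
                     names(cs1@frequency)[cs1@frequency >= 0.75])
    expect_error(consensusSelect(rk, R = 0), "R")
    expect_error(consensusSelect(rk, tau = 1.5), "tau")
})

test_that("planted-gene acceptance grows with effect size (common random numbers)", {
    freqs <- vapply(c(0.5, 1.0, 1.5), function(eff) {
        inf <- matrix(c(0, eff), 1, 2,
                      dimnames = list("G0001", c("normal", "tumor")))
        hits <- 0
        for (s in 1:3) {
            cfg <- simConfig(nGenes = 30, informativeGenes = inf,
                             nSamplesPerClass = 100, seed = 700 + s)
            rk <- rankWithinSamples(simulateCohorts(cfg)[[1]])
            res <- borutaRun(rk, nCycles = 15, nTrees = 60, seed = 800 + s)
            hits <- hits + res@hitCounts["G0001"]
        }
        hits / (3 * 15)
    }, numeric(1))
    expect_true(all(diff(freqs) >= 0))
    expect_gt(freqs[3], 0.9)
})
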