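test_that("rank forest fitting is deterministic and validated", {
    rk <- smallBinaryRanked()
    m1 <- fitRankForest(rk$platformA, nTrees = 80, seed = 3)
    m2 <- fitRankForest(rk$platformA, nTrees = 80, seed = 3)
    p1 <- predictProba(m1, rk$platformB)
    p2 <- predictProba(m2, rk$platformB)
    expect_identical(p1, p2)
    expect_error(fitRankForest(rk$platformA, nTrees = 0), "nTrees")
    expect_error(fitRankForest(rk$platformA,
                               labels = rep("a", ncol(rk$platformA))),
                 "2 classes")
})

test_that("vote-fraction probabilities are proper and aligned", {
    rk <- smallBinaryRanked()
    m <- fitRankForest(rk$platformA, nTrees = 33, seed = 4)
    p <- predictProba(m, rk$platformB)
    expect_true(all(p >= 0))
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))
    expect_identical(colnames(p), c("normal", "tumor"))
    # single tree: one vote, probabilities in {0, 1}
    m1 <- fitRankForest(rk$platformA, nTrees = 1, seed = 4)
    p1 <- predictProba(m1, rk$platformB)
    expect_true(all(p1 %in% c(0, 1)))
    # gene order in the test set is irrelevant; missing genes are fatal
    shuffled <- rk$platformB[rev(geneIds(rk$platformB)), ]
    expect_equal(predictProba(m, shuffled), p)
    expect_error(predictProba(m, subsetToPanel(rk$platformB,
                                               geneIds(rk$platformB)[1:5])),
                 "G00")
})

test_that("a saturated forest reproduces its training labels", {
    rk <- smallBinaryRanked()$platformA
    m <- fitRankForest(rk, nTrees = 200, seed = 5)
    p <- predictProba(m, rk)
    pred <- colnames(p)[apply(p, 1, which.max)]
    expect_gte(mean(pred == sampleLabels(rk)), 0.99)
})

test_that("out-of-bag error is low on the planted binary fixture", {
    cfg <- binaryFixtureConfig(seed = 402)  # 200 genes, 10 @ 1.5 SD
    rk <- rankWithinSamples(simulateCohorts(cfg)$platformA)
    m <- fitRankForest(rk, nTrees = 200, seed = 5)
    expect_lt(m@forest$prediction.error, 0.1)
})

test_that("metric panel matches hand-computed confusion examples", {
    # TP = 9, FN = 1, TN = 8, FP = 2 -> balanced accuracy 0.85
    truth <- c(rep("tumor", 10), rep("normal", 10))
    pred <- c(rep("tumor", 9), "normal",
              rep("normal", 8), rep("tumor", 2))
    scores <- cbind(normal = as.numeric(pred == "normal"),
                    tumor = as.numeric(pred == "tumor"))
    rep1 <- computeMetrics(truth, scores, pred)
    expect_equal(rep1@balancedAccuracy, (0.9 + 0.8) / 2)
    expect_identical(sum(rep1@confusion), 20L)
    expect_equal(rep1@confusion["tumor", "tumor"], 9L)
    expect_equal(unname(rep1@perClassRecall["tumor"]), 0.9)

    # perfect predictions
    perf <- computeMetrics(truth,
                           cbind(normal = as.numeric(truth == "normal"),
                                 tumor = as.numeric(truth == "tumor")))
    expect_equal(perf@balancedAccuracy, 1)
    expect_equal(perf@f1, 1)
    expect_equal(perf@rocAuc, 1)
    expect_equal(perf@prAuc, 1)
})

test_that("ROC-AUC follows pairwise concordance, including the 0.75 example", {
    scores <- cbind(neg = 1 - c(0.9, 0.8, 0.3, 0.2),
                    pos = c(0.9, 0.8, 0.3, 0.2))
    truth <- c("pos", "neg", "pos", "neg")
    expect_equal(computeMetrics(truth, scores)@rocAuc, 0.75)
    # constant scores, balanced labels: no ranking information
    const <- cbind(neg = rep(0.5, 10), pos = rep(0.5, 10))
    expect_equal(computeMetrics(rep(c("neg", "pos"), 5),
                                const)@rocAuc, 0.5)
})

test_that("metrics agree with brute-force oracles on random tiny instances", {
    set.seed(51)
    for (i in 1:50) {
        n <- sample(4:12, 1)
        truth <- sample(c("a", "b"), n, replace = TRUE)
        if (length(unique(truth)) < 2) truth[1:2] <- c("a", "b")
        s <- round(runif(n), 2)  # duplicates exercise tie handling
        scores <- cbind(a = 1 - s, b = s)
        got <- computeMetrics(truth, scores)@rocAuc
        expect_equal(got, oracleAucPairwise(s, truth == "b"),
                     tolerance = 1e-12)
    }
})

test_that("metrics are invariant to sample order", {
    set.seed(52)
    truth <- sample(c("a", "b"), 30, replace = TRUE)
    s <- runif(30)
    scores <- cbind(a = 1 - s, b = s)
    r1 <- computeMetrics(truth, scores)
    perm <- sample(30)
    r2 <- computeMetrics(truth[perm], scores[perm, ])
    expect_equal(r1@rocAuc, r2@rocAuc)
    expect_equal(r1@prAuc, r2@prAuc)
    expect_equal(r1@balancedAccuracy, r2@balancedAccuracy)
    expect_identical(r1@confusion, r2@confusion)
})

test_that("degenerate metric inputs fail clearly", {
    scores <- cbind(a = c(0.4, 0.6), b = c(0.6, 0.4))
    expect_error(computeMetrics(c("a", "a"), scores), "single-class")
    expect_error(computeMetrics(c("a", "b"),
                                cbind(a = c(NaN, 1), b = c(1, 0))),
                 "NaN")
})

test_that("multiclass metrics use macro one-vs-rest averaging", {
    set.seed(53)
    classes <- c("w", "x", "y", "z")
    truth <- rep(classes, each = 10)
    scores <- matrix(runif(160), 40, 4, dimnames = list(NULL, classes))
    scores <- scores / rowSums(scores)
    got <- computeMetrics(truth, scores)
    want <- mean(vapply(classes, function(cl)
        oracleAucPairwise(scores[, cl], truth == cl), numeric(1)))
    expect_equal(got@rocAuc, want, tolerance = 1e-12)
    expect_equal(got@balancedAccuracy, mean(got@perClassRecall))
})
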