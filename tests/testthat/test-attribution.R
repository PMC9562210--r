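tinyRanked <- function(nGenes, nPerClass, seed,
                       classes = c("normal", "tumor"), effect = 1.5) {
    inf <- matrix(0, min(2, nGenes), length(classes),
                  dimnames = list(sprintf("G%04d", seq_len(min(2, nGenes))),
                                  classes))
    inf[, length(classes)] <- effect
    cfg <- simConfig(nGenes = nGenes, informativeGenes = inf,
                     nSamplesPerClass = nPerClass, classLabels = classes,
                     seed = seed)
    rankWithinSamples(simulateCohorts(cfg)[[1]])
}

test_that("tree traversal reconstruction matches ranger's own predictions", {
    rk <- tinyRanked(6, 15, seed = 901)
    m <- fitRankForest(rk, nTrees = 5, seed = 2, minNodeSize = 3)
    x <- t(rankValues(rk))
    votes <- predict(m@forest, data = x, predict.all = TRUE,
                     num.threads = 1)$predictions
    for (t in 1:5) {
        tr <- rankRF:::.treeArrays(m, t)
        own <- apply(x, 1, function(xs) {
            node <- 1L
            while (tr$splitvar[node] >= 0L) {
                node <- if (xs[tr$splitvar[node] + 1L] <=
                            tr$splitval[node]) tr$left[node] + 1L
                        else tr$right[node] + 1L
            }
            tr$leafclass[node] + 1L
        })
        expect_equal(unname(own), unname(votes[, t]), ignore_attr = TRUE)
    }
})

test_that("fast Shapley equals brute-force coalition enumeration on toy forests", {
    for (seed in 1:4) {
        rk <- tinyRanked(3, 12, seed = 910 + seed)
        m <- fitRankForest(rk, nTrees = 2, seed = seed, minNodeSize = 4)
        test <- rk[, seq(1, 24, by = 3)]
        fast <- computeAttributions(m, test)
        brute <- bruteForceShapley(m, test)
        expect_lt(max(abs(fast@attributions - brute$attributions)), 1e-9)
        expect_lt(max(abs(fast@baseValues - brute$baseValues)), 1e-9)
    }
})

test_that("local accuracy holds for every sample and class", {
    rk <- smallBinaryRanked()
    m <- fitRankForest(rk$platformA, nTrees = 60, seed = 6)
    test <- rk$platformB[, 1:25]
    att <- computeAttributions(m, test)
    p <- predictProba(m, test)
    recon <- apply(att@attributions, c(1, 2), sum) +
        matrix(att@baseValues, nrow(p), ncol(p), byrow = TRUE)
    expect_lt(max(abs(recon - p)), 1e-6)
})

test_that("constant-prediction forests attribute nothing", {
    # all features constant: trees cannot split, prediction is the
    # majority vote and every attribution is exactly zero
    m0 <- matrix(5, 4, 20,
                 dimnames = list(sprintf("g%d", 1:4),
                                 sprintf("s%d", 1:20)))
    ds <- ExpressionDataset(m0, labels = rep(c("a", "b"), 10),
                            platformId = "p", datasetId = "d")
    rk <- suppressWarnings(rankWithinSamples(ds))
    m <- fitRankForest(rk, nTrees = 10, seed = 1)
    att <- computeAttributions(m, rk)
    expect_true(all(att@attributions == 0))
    expect_equal(sum(att@baseValues), 1)
})

test_that("stump forests put all attribution mass on the split gene", {
    rk <- tinyRanked(5, 20, seed = 905, effect = 3)
    m <- fitRankForest(rk, nTrees = 1, seed = 3, maxDepth = 1)
    ti <- ranger::treeInfo(m@forest, 1)
    g <- ti$splitvarName[1]
    att <- computeAttributions(m, rk[, 1:10])
    nz <- apply(att@attributions != 0, 3, any)
    expect_true(all(names(nz)[nz] == g))
})

test_that("genes never used in any split get exactly zero attribution", {
    set.seed(906)
    n <- 40
    y <- rep(c("a", "b"), each = n / 2)
    m <- rbind(sig = (y == "b") * 3 + rnorm(n),
               n1 = rnorm(n), n2 = rnorm(n),
               floor = rep(-1e6, n))  # always the lowest rank
    colnames(m) <- sprintf("s%03d", 1:n)
    rk <- rankWithinSamples(ExpressionDataset(m, labels = y,
                                              platformId = "p",
                                              datasetId = "d"))
    mod <- fitRankForest(rk, nTrees = 30, seed = 4)
    used <- unique(unlist(lapply(1:30, function(t)
        stats::na.omit(ranger::treeInfo(mod@forest, t)$splitvarName))))
    expect_false("floor" %in% used)  # rank-constant, unsplittable
    att <- computeAttributions(mod, rk[, 1:10])
    expect_true(all(att@attributions[, , "floor"] == 0))
})

test_that("duplicated genes share attribution approximately symmetrically", {
    set.seed(907)
    n <- 60
    y <- rep(c("a", "b"), each = n / 2)
    sig <- (y == "b") * 2 + rnorm(n)
    m <- rbind(dup1 = sig, dup2 = sig, n1 = rnorm(n), n2 = rnorm(n))
    colnames(m) <- sprintf("s%03d", 1:n)
    ds <- ExpressionDataset(m, labels = y, platformId = "p",
                            datasetId = "d")
    rk <- rankWithinSamples(ds)
    mod <- fitRankForest(rk, nTrees = 500, seed = 5, mtry = 1)
    att <- computeAttributions(mod, rk[, 1:30])
    m1 <- mean(abs(att@attributions[, , "dup1"]))
    m2 <- mean(abs(att@attributions[, , "dup2"]))
    # identical columns: the ensemble splits its usage between the twins,
    # so their average attribution magnitudes agree up to forest noise
    expect_lt(abs(m1 - m2) / max(m1, m2), 0.2)
})

test_that("top influential genes are ordered and order-invariant", {
    rk <- smallBinaryRanked()
    m <- fitRankForest(rk$platformA, nTrees = 50, seed = 7)
    test <- rk$platformB[, 1:30]
    att1 <- computeAttributions(m, test)
    att2 <- computeAttributions(m, test[, sample(30)])
    expect_identical(att1@overallRank, att2@overallRank)
    top <- topInfluential(att1, k = 5)
    expect_identical(nrow(top), 5L)
    expect_true(all(diff(top$overall) <= 0))
    full <- topInfluential(att1, k = length(att1@overallRank))
    expect_setequal(full$gene, geneIds(rk$platformA))
    expect_error(topInfluential(att1, k = 0), "k")
    expect_error(topInfluential(att1, k = 10000), "panel")
})

test_that("local accuracy survives deep trees and tiny cover fractions", {
    # deep 450-tree forests produce long paths with very small per-node
    # cover fractions; the elementary-symmetric recurrences must stay
    # numerically stable there
    cfg <- binaryFixtureConfig(seed = 908)
    common <- intersectGeneUniverse(simulateCohorts(cfg))
    rk <- lapply(common$datasets, rankWithinSamples)
    m <- fitRankForest(rk$platformA, nTrees = 450, seed = 4)
    test <- rk$platformB[, 1:20]
    att <- computeAttributions(m, test)
    p <- predictProba(m, test)
    recon <- apply(att@attributions, c(1, 2), sum) +
        matrix(att@baseValues, nrow(p), ncol(p), byrow = TRUE)
    expect_lt(max(abs(recon - p)), 1e-9)
})
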