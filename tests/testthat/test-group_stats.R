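test_that("Mann-Whitney worked examples hold", {
    res <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
    expect_equal(res$U, 0)
    expect_equal(res$p, 0.1)  # 2 * 1 / C(6,3)
    expect_equal(mannWhitney(c(7, 7, 7), c(7, 7, 7))$p, 1)
    expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p matches assignment enumeration", {
    set.seed(61)
    for (i in 1:100) {
        m <- sample(2:6, 1); n <- sample(2:6, 1)
        a <- round(runif(m), 6); b <- round(runif(n) + 0.3, 6)
        alt <- sample(c("two.sided", "greater", "less"), 1)
        expect_equal(mannWhitney(a, b, alt)$p,
                     oracleMannWhitneyP(a, b, alt),
                     tolerance = 1e-12,
                     info = sprintf("i=%d alt=%s", i, alt))
    }
})

test_that("normal-approximation mode tracks the exact mode at the boundary", {
    # at combined n = 12 the continuity-corrected normal approximation
    # deviates from the exact enumeration by ~0.014 at worst and well
    # under 0.01 typically
    set.seed(62)
    deltas <- vapply(1:40, function(i) {
        a <- runif(6); b <- runif(6) + 0.2
        exact <- oracleMannWhitneyP(a, b, "two.sided")
        approx <- suppressWarnings(
            stats::wilcox.test(a, b, exact = FALSE,
                               correct = TRUE)$p.value)
        abs(exact - approx)
    }, numeric(1))
    expect_lt(max(deltas), 0.02)
    expect_lt(stats::median(deltas), 0.01)
})

test_that("BH adjustment reproduces the step-up formula", {
    expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.5)),
                 c(0.04, 0.0533333333333333, 0.0533333333333333, 0.5),
                 tolerance = 1e-12)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    set.seed(63)
    for (i in 1:1000) {
        p <- runif(sample(1:20, 1))
        expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
    }
})

test_that("binary DE finds planted genes with the right direction", {
    eff <- 2
    inf <- matrix(c(0, eff, 0, -eff), 2, 2, byrow = TRUE,
                  dimnames = list(c("G0001", "G0002"),
                                  c("normal", "tumor")))
    cfg <- simConfig(nGenes = 30, informativeGenes = inf,
                     nSamplesPerClass = 100, seed = 64)
    ds <- simulateCohorts(cfg)[[1]]
    de <- binaryDe(ds, groups = c("tumor", "normal"))
    tab <- de@table
    expect_identical(tab$direction[tab$gene == "G0001"], "up")
    expect_identical(tab$direction[tab$gene == "G0002"], "down")
    expect_lt(tab$padj[tab$gene == "G0001"], 0.05)
    # label swap flips directions, p-values unchanged
    de2 <- binaryDe(ds, groups = c("normal", "tumor"))
    expect_equal(de2@table$p, tab$p)
    expect_true(all(de2@table$direction[tab$direction == "up"] == "down"))
    expect_true(all(de2@table$direction[tab$direction == "ns"] == "ns"))
    # adjusted p respects monotonicity and the ns rule
    expect_true(all(tab$padj >= tab$p - 1e-15))
    expect_identical(tab$direction == "ns", tab$padj >= de@alpha)
})

test_that("subtype DE assigns planted markers to their subtypes", {
    cfg <- subtypeFixtureConfig(nGenes = 40, markersPerClass = 1,
                                effect = 2, nPerClass = 40, seed = 65)
    ds <- simulateCohorts(cfg)[[1]]
    de <- subtypeDe(ds)
    # G0001..G0004 planted in LumA, LumB, HER2, Basal respectively
    markers <- c(LumA = "G0001", LumB = "G0002", HER2 = "G0003",
                 Basal = "G0004")
    for (st in names(markers))
        expect_true(markers[[st]] %in% de@upregulated[[st]],
                    label = sprintf("%s marker in %s list", st, st))
    # each gene lands in at most one subtype list
    assigned <- unlist(de@upregulated)
    expect_identical(anyDuplicated(assigned), 0L)
    # structural stage order: follow-up only for ANOVA passers
    expect_true(all(de@followUp$gene %in%
                        de@anova$gene[de@anova$pass]))
})

test_that("subtype DE handles degenerate genes and missing subtypes", {
    set.seed(66)
    v <- matrix(rnorm(4 * 40), 4, 40,
                dimnames = list(sprintf("g%d", 1:4),
                                sprintf("s%d", 1:40)))
    v[1, ] <- 3  # constant everywhere: zero within-group variance
    lab <- rep(c("LumA", "LumB", "HER2", "Basal"), each = 10)
    ds <- ExpressionDataset(v, labels = lab, platformId = "p",
                            datasetId = "d")
    expect_warning(de <- subtypeDe(ds), "zero variance")
    expect_true(is.na(de@anova$p[de@anova$gene == "g1"]))
    # a subtype reduced to a single sample is rejected
    expect_error(subtypeDe(ds[, c(1:10, 11)]), ">= 2 samples")
})

test_that("hypergeometric ORA matches closed-form examples", {
    bg <- sprintf("B%02d", 1:10)
    res <- ora(bg[1:2], bg, list(hit = bg[1:2],
                                 disjoint = c("Z1", "Z2"),
                                 all = bg))
    tab <- res@table
    # N=10, K=2, n=2, k=2 -> C(2,2) C(8,0) / C(10,2) = 1/45
    expect_equal(tab$p[tab$set == "hit"], 1 / 45, tolerance = 1e-12)
    expect_equal(tab$p[tab$set == "disjoint"], 1)
    # query = background: saturated overlap carries no surprise
    sat <- ora(bg, bg, list(all = bg, half = bg[1:5]))
    expect_true(all(sat@table$p == 1))
    expect_error(ora(c(bg[1], "OUTSIDE"), bg, list(s = bg)), "OUTSIDE")
    expect_true(all(tab$overlap <= pmin(tab$setSize, tab$querySize)))
})
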