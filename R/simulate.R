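#' Deterministically spawn child seeds from a master seed
#'
#' All randomness in the package funnels through one master seed; repeated
#' stages draw their own child seeds through this helper so any single stage
#' is reproducible in isolation.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return Integer vector of n seeds in [1, 2^31 - 2].
#' @export
spawnSeeds <- function(seed, n) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
    sample.int(2147483646L, n)
}

#' Describe a measurement platform
#'
#' A platform applies a strictly increasing transform to the latent log-scale
#' expression signal (emulating scanner/chemistry/pipeline differences
#' between microarray generations and RNA-seq processing) and may lack a
#' fraction of the gene universe.
#'
#' @param platformId string.
#' @param transform one of \code{"affine"} (a*x + b, a > 0), \code{"exp"}
#'   (2^x, an unlogged-intensity scale), \code{"log"} (log1p(exp(x)), a
#'   softplus squashing), \code{"spline"} (a random strictly increasing
#'   monotone cubic spline, rank-preserving by construction).
#' @param a,b affine coefficients (used by \code{"affine"} only).
#' @param geneDropoutFraction fraction of the non-informative gene universe
#'   absent from this platform, in [0, 0.5].
#' @return A \code{PlatformSpec} list.
#' @export
platformSpec <- function(platformId, transform = c("affine", "exp", "log",
                                                   "spline"),
                         a = 1, b = 0, geneDropoutFraction = 0) {
    transform <- match.arg(transform)
    if (transform == "affine" && a <= 0)
        stop("affine slope must be positive (strictly increasing transform)")
    if (geneDropoutFraction < 0 || geneDropoutFraction > 0.5)
        stop("geneDropoutFraction must lie in [0, 0.5]")
    structure(list(platform_id = platformId, transform = transform,
                   a = a, b = b,
                   gene_dropout_fraction = geneDropoutFraction),
              class = "PlatformSpec")
}

#' Configure the multi-platform cohort simulator
#'
#' The generator draws a latent additive-Gaussian signal on a log-like scale,
#' \code{x[g, s] = mu[g] + beta[g, class(s)] + eps[g, s]}, with
#' \code{eps ~ Normal(0, sigma^2)}, and then pushes it through each
#' platform's monotone transform. Informative genes shift their latent mean
#' by \code{effect * sigma} in the stated classes; all other genes are
#' exchangeable noise. Baseline means are drawn once per configuration as
#' \code{mu[g] ~ Normal(6, 2^2)} (a typical log2-expression scale).
#'
#' @param nGenes size of the gene universe (symbols "G0001", ...).
#' @param informativeGenes numeric matrix (informative genes x classes) of
#'   per-class effects in latent SD units, with rownames giving the gene
#'   symbols and colnames the class labels; or NULL for a pure-noise cohort.
#' @param nSamplesPerClass samples per class per platform (scalar or named
#'   by class). May be unbalanced to emulate skewed test cohorts.
#' @param classLabels character vector of 2 or 4 class labels.
#' @param platforms list of \code{\link{platformSpec}} objects.
#' @param noiseSd latent noise SD sigma (> 0).
#' @param baselineMean,baselineSd parameters of the mu[g] draw.
#' @param sharedLatent if TRUE all platforms transform the same latent
#'   matrix (identical virtual samples measured twice) — used to demonstrate
#'   rank invariance; default FALSE draws independent cohorts per platform.
#' @param seed integer master seed.
#' @return A \code{SimConfig} list.
#' @export
simConfig <- function(nGenes = 200, informativeGenes = NULL,
                      nSamplesPerClass = 50,
                      classLabels = c("normal", "tumor"),
                      platforms = list(platformSpec("platformA")),
                      noiseSd = 1, baselineMean = 6, baselineSd = 2,
                      sharedLatent = FALSE, seed = 1) {
    if (length(classLabels) < 2L)
        stop("at least 2 classes are required")
    if (length(nSamplesPerClass) == 1L)
        nSamplesPerClass <- stats::setNames(
            rep(nSamplesPerClass, length(classLabels)), classLabels)
    if (any(nSamplesPerClass < 2L))
        stop("need at least 2 samples per class")
    if (noiseSd <= 0) stop("noiseSd must be positive")
    genes <- sprintf("G%04d", seq_len(nGenes))
    if (!is.null(informativeGenes)) {
        informativeGenes <- as.matrix(informativeGenes)
        if (is.null(rownames(informativeGenes)))
            stop("informativeGenes needs gene symbols as rownames")
        if (!identical(ncol(informativeGenes), length(classLabels)))
            stop("informativeGenes needs one effect column per class")
        if (is.null(colnames(informativeGenes)))
            colnames(informativeGenes) <- classLabels
        extra <- setdiff(rownames(informativeGenes), genes)
        if (length(extra))
            stop(sprintf("informative gene(s) outside the universe: %s",
                         paste(extra, collapse = ", ")))
    }
    structure(list(n_genes = nGenes, genes = genes,
                   informative_genes = informativeGenes,
                   n_samples_per_class = nSamplesPerClass,
                   class_labels = classLabels, platforms = platforms,
                   noise_sd = noiseSd, baseline_mean = baselineMean,
                   baseline_sd = baselineSd,
                   shared_latent = isTRUE(sharedLatent),
                   seed = as.integer(seed)),
              class = "SimConfig")
}

.applyTransform <- function(x, spec, seed) {
    switch(spec$transform,
        affine = spec$a * x + spec$b,
        exp = 2^x,
        log = log1p(exp(pmin(x, 700))),
        spline = {
            # random strictly increasing cubic spline over the value range
            old <- if (exists(".Random.seed", envir = globalenv()))
                get(".Random.seed", envir = globalenv()) else NULL
            on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                              envir = globalenv()))
            set.seed(seed)
            kx <- seq(min(x) - 1, max(x) + 1, length.out = 8)
            ky <- cumsum(stats::runif(8, 0.2, 2))
            f <- stats::splinefun(kx, ky, method = "hyman")
            array(f(x), dim(x), dimnames(x))
        })
}

#' Simulate multi-platform expression cohorts with planted markers
#'
#' One \linkS4class{ExpressionDataset} per platform. Identical seed, identical
#' output. Informative genes differ in latent mean between classes by exactly
#' their configured effects; every other gene is exchangeable noise; platform
#' transforms distort the scale monotonically so that within-sample gene
#' ranks are preserved. Gene dropout removes a platform-specific random
#' subset of the *non-informative* universe, so planted markers survive
#' universe intersection (see the methods vignette).
#'
#' @param config a \code{\link{simConfig}}.
#' @return Named list of \linkS4class{ExpressionDataset}, one per platform.
#' @export
simulateCohorts <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(config$seed)
    genes <- config$genes
    G <- length(genes)
    mu <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
    names(mu) <- genes
    beta <- matrix(0, G, length(config$class_labels),
                   dimnames = list(genes, config$class_labels))
    if (!is.null(config$informative_genes))
        beta[rownames(config$informative_genes), ] <-
            config$informative_genes * config$noise_sd

    labels <- rep(config$class_labels,
                  times = config$n_samples_per_class[config$class_labels])
    n <- length(labels)
    drawLatent <- function() {
        eps <- matrix(stats::rnorm(G * n, 0, config$noise_sd), G, n)
        mu + beta[, labels, drop = FALSE] + eps
    }
    shared <- if (config$shared_latent) drawLatent() else NULL

    out <- list()
    for (i in seq_along(config$platforms)) {
        spec <- config$platforms[[i]]
        latent <- if (config$shared_latent) shared else drawLatent()
        keep <- genes
        nDrop <- round(spec$gene_dropout_fraction * G)
        if (nDrop > 0) {
            informative <- rownames(config$informative_genes)
            droppable <- setdiff(genes, informative)
            drop <- sample(droppable, min(nDrop, length(droppable)))
            keep <- setdiff(genes, drop)
        }
        vals <- .applyTransform(latent, spec,
                                seed = config$seed + 7919L * i)
        dimnames(vals) <- list(genes,
                               sprintf("%s_s%03d", spec$platform_id,
                                       seq_len(n)))
        vals <- vals[keep, , drop = FALSE]
        out[[spec$platform_id]] <- ExpressionDataset(
            vals, labels = labels, platformId = spec$platform_id,
            datasetId = spec$platform_id)
    }
    out
}

#' Write the standard synthetic fixture families
#'
#' Three small cohort families used throughout the test suite: a binary
#' two-platform cohort (200 genes, 10 informative at 1.5 latent SD, 150
#' samples per class and platform), a 4-class cohort (200 genes, 4 markers
#' per subtype at 2 latent SD), and a pure-noise binary cohort. Regenerating
#' with the same seed reproduces identical files.
#'
#' @param outDir writable directory.
#' @param seed master seed.
#' @return Named list of written file paths per family.
#' @export
makeFixtureSuite <- function(outDir, seed = 20220925) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seeds <- spawnSeeds(seed, 3)
    fams <- list(
        binary = binaryFixtureConfig(seed = seeds[1]),
        subtype = subtypeFixtureConfig(seed = seeds[2]),
        noise = noiseFixtureConfig(seed = seeds[3]))
    paths <- list()
    for (fam in names(fams)) {
        cohorts <- simulateCohorts(fams[[fam]])
        for (pid in names(cohorts)) {
            mp <- file.path(outDir, sprintf("%s_%s_matrix.tsv", fam, pid))
            dp <- file.path(outDir, sprintf("%s_%s_metadata.tsv", fam, pid))
            writeExpressionMatrix(cohorts[[pid]], mp, dp)
            paths[[fam]] <- c(paths[[fam]], mp, dp)
        }
    }
    paths
}

#' Canned simulator configurations for the standard fixtures
#'
#' \code{binaryFixtureConfig}: tumor/normal, two platforms (affine and
#' exp-scale), 10 planted genes at \code{effect} latent SD in tumor.
#' \code{subtypeFixtureConfig}: four intrinsic subtypes with
#' \code{markersPerClass} planted markers each at \code{effect} latent SD.
#' \code{noiseFixtureConfig}: no informative genes.
#'
#' @param nGenes gene universe size.
#' @param nInformative planted genes (binary).
#' @param effect latent-SD effect size.
#' @param nPerClass samples per class per platform.
#' @param markersPerClass planted markers per subtype.
#' @param seed master seed.
#' @name fixtureConfigs
NULL

#' @rdname fixtureConfigs
#' @export
binaryFixtureConfig <- function(nGenes = 200, nInformative = 10,
                                effect = 1.5, nPerClass = 150, seed = 1) {
    inf <- matrix(c(rep(0, nInformative), rep(effect, nInformative)),
                  ncol = 2,
                  dimnames = list(sprintf("G%04d", seq_len(nInformative)),
                                  c("normal", "tumor")))
    simConfig(nGenes = nGenes, informativeGenes = inf,
              nSamplesPerClass = nPerClass,
              classLabels = c("normal", "tumor"),
              platforms = list(
                  platformSpec("platformA", "affine", a = 2, b = 5,
                               geneDropoutFraction = 0.1),
                  platformSpec("platformB", "exp",
                               geneDropoutFraction = 0.1)),
              seed = seed)
}

#' @rdname fixtureConfigs
#' @export
subtypeFixtureConfig <- function(nGenes = 200, markersPerClass = 4,
                                 effect = 2, nPerClass = 60, seed = 1) {
    classes <- c("LumA", "LumB", "HER2", "Basal")
    nInf <- markersPerClass * length(classes)
    inf <- matrix(0, nInf, length(classes),
                  dimnames = list(sprintf("G%04d", seq_len(nInf)), classes))
    for (ci in seq_along(classes)) {
        rows <- (ci - 1) * markersPerClass + seq_len(markersPerClass)
        inf[rows, ci] <- effect
    }
    simConfig(nGenes = nGenes, informativeGenes = inf,
              nSamplesPerClass = nPerClass, classLabels = classes,
              platforms = list(
                  platformSpec("platformA", "affine", a = 1.5, b = 2,
                               geneDropoutFraction = 0.1),
                  platformSpec("platformB", "log",
                               geneDropoutFraction = 0.1)),
              seed = seed)
}

#' @rdname fixtureConfigs
#' @export
noiseFixtureConfig <- function(nGenes = 200, nPerClass = 150, seed = 1) {
    simConfig(nGenes = nGenes, informativeGenes = NULL,
              nSamplesPerClass = nPerClass,
              classLabels = c("normal", "tumor"),
              platforms = list(platformSpec("platformA")),
              seed = seed)
}

#' Constructed redundancy benchmark for floating feature selection
#'
#' A cohort engineered so that greedy forward selection needs the floating
#' (backward-removal) step: genes \code{gA} and \code{gB} carry an
#' XOR-coupled class signal that is only informative jointly, while
#' \code{gC} is a noisy single predictor. \code{gC} wins the first forward
#' step (strongest alone), but once \code{gA} and \code{gB} are both in the
#' panel it is jointly redundant and its removal strictly improves the
#' cross-validated score. The rest of the universe is exchangeable noise.
#'
#' @param n samples (even; two balanced classes "no"/"yes").
#' @param nNoise additional pure-noise genes padding the universe.
#' @param sdAB Gaussian noise SD on the XOR component genes.
#' @param sdC noise SD on the redundant single predictor (controls how good
#'   it is alone).
#' @param seed integer seed.
#' @return An \linkS4class{ExpressionDataset} with genes gA, gB, gC, gN1,
#'   gN2 and \code{nNoise} padding genes.
#' @export
xorRedundancyFixture <- function(n = 120, nNoise = 15, sdAB = 0.15,
                                 sdC = 0.8, seed = 1) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    y <- rep(c("no", "yes"), each = n / 2)
    h <- stats::rbinom(n, 1, 0.5)
    A <- h + stats::rnorm(n, 0, sdAB) + 0.15 * (y == "yes")
    B <- as.integer(xor(h == 1, y == "yes")) + stats::rnorm(n, 0, sdAB)
    C <- (y == "yes") + stats::rnorm(n, 0, sdC)
    m <- rbind(gA = A, gB = B, gC = C,
               gN1 = stats::rnorm(n), gN2 = stats::rnorm(n),
               matrix(stats::rnorm(nNoise * n), nNoise, n,
                      dimnames = list(sprintf("gP%02d", seq_len(nNoise)),
                                      NULL)))
    colnames(m) <- sprintf("s%03d", seq_len(n))
    ExpressionDataset(m, labels = y, platformId = "synthetic",
                      datasetId = "xor_redundancy")
}
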