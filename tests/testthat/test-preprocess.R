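# QC, normalization, variable genes, regression, PCA.

test_that("qcFilter applies the detected-gene and mito thresholds", {
    set.seed(1)
    counts <- matrix(rpois(300 * 30, 2), 300, 30,
                     dimnames = list(c(sprintf("G%03d", 1:290),
                                       sprintf("MT-%d", 1:10)),
                                     sprintf("c%02d", 1:30)))
    # cell 1: only 150 genes detected; cell 2: exactly 201
    counts[, 1] <- 0; counts[sample(300, 150), 1] <- 1
    counts[, 2] <- 0; counts[sample(300, 201), 2] <- 1
    # cells 3..12: half their counts mitochondrial
    hot <- 3:12
    counts[291:300, hot] <- 60
    out <- qcFilter(counts, minGenes = 200, maxMitoFrac = 0.2)
    expect_false("c01" %in% colnames(out))      # 150 genes: removed
    expect_true("c02" %in% colnames(out))       # 201 genes, 0% mito: kept
    expect_false(any(sprintf("c%02d", hot) %in% colnames(out)))
    expect_equal(attr(out, "qcLog")$nRemoved, 11)
    expect_error(qcFilter(counts, minGenes = 1e5), "every cell")
})

test_that("filterGenes uses a strict detection-fraction cutoff", {
    counts <- matrix(0, 3, 100,
                     dimnames = list(c("zero", "one", "many"), NULL))
    counts["one", 1] <- 5
    counts["many", 1:30] <- 1
    out <- filterGenes(counts, minCellFrac = 0.01)
    expect_false("zero" %in% rownames(out))     # 0 cells: removed
    expect_true("one" %in% rownames(out))       # exactly 1%: retained
    expect_true("many" %in% rownames(out))
})

test_that("normalizeLog matches its closed form and duplication invariance", {
    set.seed(2)
    counts <- matrix(rpois(20, 5) + 1, 5, 4,
                     dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
    norm <- normalizeLog(counts, scaleFactor = 1e4)
    expected <- log(1 + 1e4 * sweep(counts, 2, colSums(counts), "/"))
    expect_lt(max(abs(as.matrix(norm) - expected)), 1e-12)
    # zero count -> zero value; single-gene cell -> log(1 + sf)
    one <- matrix(c(7, 0), 2, 1, dimnames = list(c("a", "b"), "c"))
    n1 <- as.matrix(normalizeLog(one, 1e4))
    expect_equal(n1["a", 1], log(1 + 1e4))
    expect_equal(n1["b", 1], 0)
    # doubling a cell's counts leaves its normalized profile unchanged
    expect_equal(as.matrix(normalizeLog(counts * 2))[, 1],
                 as.matrix(normalizeLog(counts))[, 1])
    zero <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
    expect_error(normalizeLog(zero), "x")
})

test_that("variable-gene ranking tracks excess dispersion", {
    set.seed(3)
    nGenes <- 400; nCells <- 300
    mu <- rlnorm(nGenes, log(1), 0.8)
    counts <- matrix(rnbinom(nGenes * nCells, mu = mu, size = 10),
                     nGenes, nCells,
                     dimnames = list(sprintf("g%04d", 1:nGenes), NULL))
    counts["g0001", ] <- rnbinom(nCells, mu = mu[1], size = 0.3) # overdispersed
    counts["g0002", ] <- 5                                       # zero variance
    vg <- selectVariableGenes(counts, n = 50)
    expect_lte(vg["g0001", "rank"], nGenes / 10)
    expect_equal(vg["g0002", "rank"], nGenes)
    expect_true(setequal(vg$rank, seq_len(nGenes)))     # ranks a permutation
    expect_equal(sum(vg$selected), 50)
    # ranking statistic invariant under gene reordering (ranks themselves can
    # swap between numerically tied genes)
    vg2 <- selectVariableGenes(counts[rev(rownames(counts)), ], n = 50)
    expect_equal(vg2[rownames(vg), "varianceStandardized"],
                 vg$varianceStandardized, tolerance = 1e-8)
    expect_gte(length(intersect(rownames(vg)[vg$selected],
                                rownames(vg2)[vg2$selected])), 48)
    expect_error(selectVariableGenes(counts, n = nGenes + 1), "exceeds")
    all50 <- selectVariableGenes(counts, n = nGenes)
    expect_true(all(all50$selected))
})

test_that("covariate regression leaves residuals orthogonal to the design", {
    set.seed(4)
    nCells <- 200
    cov <- data.frame(mito = runif(nCells), numi = rnorm(nCells))
    m <- randomGeneMatrix(30, nCells, seed = 5)
    m[1, ] <- 2 * cov$mito                       # exact linear dependence
    res <- scaleAndRegress(m, cov)
    # the exactly covariate-determined gene has nothing left after regression
    expect_equal(unname(res[1, ]), rep(0, nCells))
    for (j in 1:2)
        expect_lt(max(abs(cor(t(res[-1, ]), cov[[j]]))), 1e-10)
    # uncorrelated covariate: residuals track the centered original
    indep <- data.frame(z = rnorm(nCells))
    res2 <- scaleAndRegress(m[2, , drop = FALSE], indep)
    expect_gt(cor(res2[1, ], m[2, ]), 0.99)
    bad <- data.frame(a = cov$mito, b = cov$mito)
    expect_error(scaleAndRegress(m, bad), "rank-deficient")
})

test_that("PCA recovers low-rank structure and permutes with the cells", {
    set.seed(6)
    u <- rnorm(40); v <- rnorm(100)
    m <- outer(u, v) + randomGeneMatrix(40, 100, seed = 7, sd = 1e-3)
    p <- runPCA(m, nComponents = 5)
    ve <- p$sdev^2 / sum(p$sdev^2)
    expect_gt(ve[1], 0.999)
    expect_true(all(diff(p$sdev) <= 1e-12))      # non-increasing variance
    perm <- sample(ncol(m))
    p2 <- runPCA(m[, perm], nComponents = 5)
    expect_equal(abs(p2$scores[, 1]), abs(p$scores[perm, 1]), tolerance = 1e-6)
    expect_error(runPCA(m, nComponents = 1000), "exceeds")
})

test_that("cell and gene filters commute on their respective axes", {
    set.seed(8)
    counts <- matrix(rpois(500 * 60, 1), 500, 60,
                     dimnames = list(sprintf("g%03d", 1:500),
                                     sprintf("c%02d", 1:60)))
    a <- filterGenes(qcFilter(counts, minGenes = 100), 0.05)
    b <- qcFilter(filterGenes(counts, 0.05), minGenes = 100)
    # same cells survive either order; gene sets may differ only through
    # cells removed, which qcFilter decides on the full gene panel
    expect_identical(colnames(a), colnames(b))
})
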