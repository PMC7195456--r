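# Ground-truth generator: overlap geometry, pooling/barcoding, screens,
# determinism.

test_that("overlap geometry is honoured by construction", {
    # full overlap: identical response sets
    cfg1 <- panelConfig(nConditions = 2, cellsPerSample = 5, nGenes = 200,
                        nResponseGenes = 20, pairwiseOverlap = 1, seed = 1)
    p1 <- simulateConditionPanel(cfg1)
    sets <- lapply(p1$truth@responseSets, function(s) sort(c(s$up, s$down)))
    expect_identical(sets[[1]], sets[[2]])
    expect_equal(jaccardMatrix(sets)$meanOffdiag, 1)

    # zero overlap (no conserved core): disjoint sets
    cfg0 <- panelConfig(nConditions = 2, cellsPerSample = 5, nGenes = 200,
                        nResponseGenes = 20, pairwiseOverlap = 0,
                        fracConserved = 0, seed = 1)
    p0 <- simulateConditionPanel(cfg0)
    sets0 <- lapply(p0$truth@responseSets, function(s) c(s$up, s$down))
    expect_length(intersect(sets0[[1]], sets0[[2]]), 0)
    expect_equal(jaccardMatrix(sets0)$meanOffdiag, 0)
})

test_that("default-geometry truth Jaccard lands within 0.05 of the target", {
    cfg <- panelConfig(nConditions = 12, cellsPerSample = 2, nGenes = 2000,
                       nResponseGenes = 150, pairwiseOverlap = 0.2,
                       fracConserved = 0.2, seed = 1)
    p <- simulateConditionPanel(cfg)
    sets <- lapply(p$truth@responseSets, function(s) c(s$up, s$down))
    # independent set arithmetic, not the generator's own bookkeeping
    K <- length(sets)
    vals <- c()
    for (i in seq_len(K - 1)) for (j in (i + 1):K)
        vals <- c(vals, length(intersect(sets[[i]], sets[[j]])) /
                        length(union(sets[[i]], sets[[j]])))
    expect_lt(abs(mean(vals) - 0.2), 0.05)
    # truth Jaccard equals the compare module's computation on the same sets
    expect_equal(mean(vals), jaccardMatrix(sets)$meanOffdiag)
})

test_that("infeasible overlap geometries are rejected", {
    # conserved core larger than the target intersection
    expect_error(simulateConditionPanel(
        panelConfig(nConditions = 3, cellsPerSample = 2, nGenes = 500,
                    nResponseGenes = 50, pairwiseOverlap = 0.05,
                    fracConserved = 0.9, seed = 1)),
        "infeasible")
    # gene budget exhausted
    expect_error(simulateConditionPanel(
        panelConfig(nConditions = 12, cellsPerSample = 2, nGenes = 100,
                    nResponseGenes = 90, pairwiseOverlap = 0.2,
                    fracConserved = 0.2, seed = 1)),
        "infeasible")
})

test_that("latent time decays after withdrawal and stays in [0,1]", {
    sc <- smallCourse()
    expect_true(all(sc$truth@latentTime >= 0 & sc$truth@latentTime <= 1))
    byTp <- tapply(sc$truth@latentTime[colnames(sc$counts)],
                   sc$cd$timepoint, mean)
    treatTp <- levels(sc$cd$timepoint)[1:5]
    expect_true(all(diff(byTp[treatTp]) > 0))
    wTp <- setdiff(levels(sc$cd$timepoint), treatTp)
    expect_true(all(diff(byTp[wTp]) < 0))    # reversion toward baseline
    expect_lt(byTp[[wTp[3]]], 0.2)           # near-complete after 3 days
})

test_that("pooling produces the programmed doublet/negative composition", {
    cfg <- panelConfig(nConditions = 1, cellsPerSample = 250, nGenes = 100,
                       nResponseGenes = 10, fracConserved = 1,
                       pairwiseOverlap = 1, doubletRate = 0.05,
                       negativeRate = 0.02, seed = 7)
    pool <- poolAndBarcode(simulateConditionPanel(cfg), cfg)
    st <- pool$truth@poolStatus
    expect_length(st, 2000)
    nd <- sum(st == "doublet")
    expect_identical(nd, sum(pool$truth@doubletLabels))
    expect_gt(nd, 70)   # binomial(2000, 0.05)
    expect_lt(nd, 135)
    # doublets list two different samples; barcode rows align with cells
    dl <- pool$truth@sampleOfCell[st == "doublet"]
    expect_true(all(grepl(",", dl)))
    expect_identical(rownames(pool$barcodes), colnames(pool$sce))

    # no doublets / no negatives => every cell a labelled singlet
    cfg0 <- panelConfig(nConditions = 1, cellsPerSample = 50, nGenes = 100,
                        nResponseGenes = 10, fracConserved = 1,
                        pairwiseOverlap = 1, doubletRate = 0,
                        negativeRate = 0, seed = 7)
    pool0 <- poolAndBarcode(simulateConditionPanel(cfg0), cfg0)
    expect_true(all(pool0$truth@poolStatus == "singlet"))
    expect_false(any(grepl(",", pool0$truth@sampleOfCell)))
})

test_that("screen generative means follow the programmed inhibitor effects", {
    sc <- smallCourse()
    rs <- sc$truth@responseSets[[1]]
    resp <- c(rs$up, rs$down)
    set.seed(9)
    module <- sample(resp, round(0.4 * length(resp)))
    scr <- simulateScreen(sc$panel, 1, inhibitors = list(
        inert = list(type = "none"),
        fullB = list(type = "full_block"),
        partB = list(type = "partial_block", module = module)),
        cellsPerSample = 150)
    m <- as.matrix(SummarizedExperiment::assay(scr$sce, "counts"))
    grp <- SingleCellExperiment::colData(scr$sce)$inhibitor
    mu <- function(g) vapply(split(seq_along(grp), grp),
                             function(i) mean(m[g, i]), numeric(1))
    up <- rs$up[1]
    mus <- mu(up)
    # full block: response gene at baseline; inert: induced
    expect_lt(abs(log1p(mus["fullB"]) - log1p(mus["untreated"])), 0.5)
    expect_gt(mus["inert"], 2 * mus["untreated"])
    # partial block: module genes at baseline, non-module induced
    modUp <- intersect(module, rs$up)
    freeUp <- setdiff(rs$up, module)
    mMod <- rowMeans(m[modUp, grp == "partB", drop = FALSE])
    mMod0 <- rowMeans(m[modUp, grp == "untreated", drop = FALSE])
    mFree <- rowMeans(m[freeUp, grp == "partB", drop = FALSE])
    mFree1 <- rowMeans(m[freeUp, grp == "inert", drop = FALSE])
    expect_lt(median(abs(log1p(mMod) - log1p(mMod0))), 0.3)
    expect_lt(median(abs(log1p(mFree) - log1p(mFree1))), 0.3)
    # a partial-block module outside the response set is rejected
    expect_error(simulateScreen(sc$panel, 1, inhibitors = list(
        bad = list(type = "partial_block", module = "NOT_A_GENE"))),
        "subset")
})

test_that("generation is reproducible for a fixed seed", {
    cfg <- panelConfig(nConditions = 2, cellsPerSample = 20, nGenes = 150,
                       nResponseGenes = 15, seed = 42)
    a <- simulateConditionPanel(cfg)
    b <- simulateConditionPanel(cfg)
    expect_identical(
        SummarizedExperiment::assay(a$sces[[1]], "counts"),
        SummarizedExperiment::assay(b$sces[[1]], "counts"))
    pa <- poolAndBarcode(a, cfg); pb <- poolAndBarcode(b, cfg)
    expect_identical(pa$barcodes, pb$barcodes)
    expect_identical(pa$truth@poolStatus, pb$truth@poolStatus)
})
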