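# Gene-set and regulon scoring, preranked enrichment,
# over-representation.

test_that("aucellScore equals brute-force recovery-curve integration", {
    set.seed(30)
    m <- randomGeneMatrix(200, 50, seed = 30)
    targets <- sample(rownames(m), 20)
    auc <- aucellScore(m, targets, topFrac = 0.05)
    expect_lt(max(abs(auc - bruteAUC(m, targets, 0.05))), 1e-10)
    # matrix version agrees with per-regulon scoring
    regs <- list(r1 = targets, r2 = sample(rownames(m), 10))
    am <- aucellScoreMatrix(m, regs, topFrac = 0.05)
    expect_equal(am["r1", ], auc)
    expect_equal(am["r2", ], aucellScore(m, regs$r2, 0.05))
})

test_that("aucellScore attains its extremes and is rank-based", {
    m <- matrix(0, 100, 2, dimnames = list(sprintf("g%03d", 1:100),
                                           c("top", "bottom")))
    m[1:5, "top"] <- 10:6            # all targets at the very top
    m[96:100, "bottom"] <- 10:6      # targets crowded out of the top 5%
    targets <- sprintf("g%03d", 1:5)
    auc <- aucellScore(m, targets, topFrac = 0.05)
    expect_equal(auc[["top"]], 1)
    expect_equal(aucellScore(m, sprintf("g%03d", 96:100), 0.05)[["top"]], 0)
    # monotone transforms of a cell's profile leave the score unchanged
    set.seed(31)
    r <- randomGeneMatrix(100, 5, seed = 31)
    rTargets <- rownames(r)[11:25]
    t1 <- aucellScore(r, rTargets, 0.1)
    t2 <- aucellScore(exp(2 * r) + 5, rTargets, 0.1)
    expect_equal(t1, t2)
    expect_error(aucellScore(r, rTargets, topFrac = 0), "topFrac")
    expect_error(aucellScore(r, "absent", 0.1), "target")
})

test_that("moduleScore centers against expression-matched controls", {
    # identical expression everywhere: score exactly zero
    flat <- matrix(3, 60, 8, dimnames = list(sprintf("g%02d", 1:60),
                                             sprintf("c%d", 1:8)))
    expect_equal(unname(moduleScore(flat, sprintf("g%02d", 1:6))),
                 rep(0, 8))
    # spiked set: positive in spiked cells, near zero elsewhere; baseline
    # abundances vary so the members spread across expression bins, and the
    # spike is confined to a few cells so bin assignment stays faithful
    set.seed(32)
    m <- randomGeneMatrix(300, 40, seed = 32, sd = 0.3) +
        rnorm(300, mean = 2, sd = 1.5)
    members <- sample(rownames(m), 15)
    spiked <- 1:4
    m[members, spiked] <- m[members, spiked] + 1
    sc <- moduleScore(m, members, seed = 7)
    expect_true(all(sc[spiked] > 0.5))
    expect_lt(mean(abs(sc[-spiked])), 0.25)
    # deterministic for a fixed seed
    expect_identical(sc, moduleScore(m, members, seed = 7))
    # independent recomputation of the documented algorithm, same seed
    avg <- rowMeans(m)
    bin <- cut(rank(avg, ties.method = "first"), breaks = 24, labels = FALSE)
    names(bin) <- rownames(m)
    set.seed(7)
    ctrl <- unique(unlist(lapply(members, function(g) {
        pool <- names(bin)[bin == bin[[g]]]
        sample(pool, min(100, length(pool)))
    })))
    expected <- colMeans(m[members, ]) - colMeans(m[ctrl, ])
    expect_equal(sc, expected)
    expect_error(moduleScore(m, "absent"), "member")
})

test_that("moduleScore with one bin is centered on the global mean", {
    set.seed(33)
    m <- randomGeneMatrix(200, 10, seed = 33)
    members <- rownames(m)[1:20]
    # with a single bin and nCtrl >= nGenes the control set is all genes
    sc <- moduleScore(m, members, nBins = 1, nCtrl = 200, seed = 1)
    expected <- colMeans(m[members, ]) - colMeans(m)
    expect_equal(sc, expected)
})

test_that("gseaPreranked reproduces the hand-enumerated running sum", {
    rk <- setNames(10:1, paste0("g", 1:10))
    # unweighted: two hits at the top -> ES = 2/2 = 1 before any miss
    res <- gseaPreranked(rk, c("g1", "g2"), nPerm = 200, weight = 0)
    expect_equal(res$ES, 1)
    expect_setequal(res$leadingEdge, c("g1", "g2"))
    # reversing the ranking negates the unweighted ES
    rev <- gseaPreranked(setNames(rev(10:1), paste0("g", 1:10)),
                         c("g1", "g2"), nPerm = 200, weight = 0)
    expect_equal(rev$ES, -1)
    # weighted ES agrees with an independent implementation
    set.seed(34)
    stat <- setNames(rnorm(100), paste0("x", 1:100))
    set <- sample(names(stat), 15)
    mine <- gseaPreranked(stat, set, nPerm = 200, weight = 1)
    fg <- suppressWarnings(
        fgsea::fgsea(list(s = set), stat, eps = 0, nPermSimple = 500))
    expect_equal(mine$ES, fg$ES, tolerance = 1e-12)
    expect_identical(sign(mine$NES), sign(mine$ES))
    expect_error(gseaPreranked(rk, names(rk), nPerm = 200), "covers")
    expect_error(gseaPreranked(rk, "g1", nPerm = 10), "nPerm")
})

test_that("gseaPreranked permutation p-values are calibrated under the null", {
    set.seed(35)
    stat <- setNames(rnorm(150), paste0("y", 1:150))
    ps <- vapply(1:40, function(i) {
        gseaPreranked(stat, sample(names(stat), 12), nPerm = 200,
                      seed = i)$p
    }, numeric(1))
    expect_gt(mean(ps < 0.05), 0)
    expect_lt(mean(ps < 0.05), 0.2)
    expect_gt(median(ps), 0.2)
})

test_that("nesDifference isolates list-specific enrichment", {
    genes <- sprintf("g%03d", 1:200)
    set.seed(36)
    collection <- list(modA = genes[1:20], modB = genes[21:40],
                       modC = genes[41:60], modD = genes[61:80])
    # each collection set ranks its own members first
    rankings <- lapply(collection, function(s)
        c(s, setdiff(genes, s)))
    listA <- c(collection$modA, genes[81:100])
    listB <- c(collection$modB, genes[101:120])
    d <- nesDifference(listA, listB, collection, rankings)
    expect_equal(d$set[1], "modA")                # enriched only in A
    expect_equal(d$set[nrow(d)], "modB")          # enriched only in B
    expect_gt(d$deltaNES[1], 0)
    same <- nesDifference(listA, listA, collection, rankings)
    expect_equal(same$deltaNES, rep(0, 4))
    expect_error(nesDifference(listA, listB, list(), rankings), "empty")
})

test_that("hypergeomEnrichment matches closed forms", {
    universe <- paste0("u", 1:100)
    query <- universe[1:10]
    res <- hypergeomEnrichment(query,
                               list(exact = universe[1:10],
                                    disjoint = universe[51:60],
                                    expected = c(universe[1], universe[11:19])),
                               universe)
    expect_equal(unname(res["exact", "p_value"]), 1 / choose(100, 10))
    expect_equal(unname(res["disjoint", "p_value"]), 1) # upper tail incl. 0
    # overlap at expectation (1 of 10 with K = 10, n = 10, N = 100)
    expect_gt(res["expected", "p_value"], 0.3)
    expect_true(all(res$adj_p >= res$p_value))
    expect_error(hypergeomEnrichment("notin", list(a = universe[1]),
                                     universe), "outside")
    expect_error(hypergeomEnrichment(query, list(a = query), character()),
                 "empty")
})

test_that("GMT files round-trip", {
    sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
    path <- tempfile(fileext = ".gmt")
    writeGMT(sets, path)
    expect_identical(readGMT(path), sets)
})
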