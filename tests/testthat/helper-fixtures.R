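# Shared fixtures, built once per test run. Kept small: unit tests exercise
# behaviour, the acceptance suite exercises the study-scale conditions.

.fixtures <- new.env(parent = emptyenv())

# one small single-condition time course with identical response geometry
smallPanel <- function() {
    if (is.null(.fixtures$panel)) {
        cfg <- panelConfig(nConditions = 1, cellsPerSample = 60,
                           nGenes = 400, nResponseGenes = 40,
                           fracConserved = 1, pairwiseOverlap = 1, seed = 3)
        .fixtures$panel <- list(cfg = cfg,
                                panel = simulateConditionPanel(cfg))
    }
    .fixtures$panel
}

# log-normalized matrix + metadata of the small panel
smallCourse <- function() {
    if (is.null(.fixtures$course)) {
        p <- smallPanel()
        sce <- p$panel$sces[[1]]
        cd <- SingleCellExperiment::colData(sce)
        counts <- SummarizedExperiment::assay(sce, "counts")
        .fixtures$course <- list(
            counts = counts,
            logc = normalizeLog(counts),
            cd = cd,
            truth = p$panel$truth,
            panel = p$panel)
    }
    .fixtures$course
}

randomGeneMatrix <- function(nGenes, nCells, seed = 1, sd = 1) {
    set.seed(seed)
    matrix(rnorm(nGenes * nCells, sd = sd), nGenes, nCells,
           dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                           sprintf("c%04d", seq_len(nCells))))
}

# independent recovery-curve integration (explicit rank loop), used to
# cross-check the package's AUC scorer
bruteAUC <- function(m, targets, topFrac) {
    N <- ceiling(topFrac * nrow(m))
    mT <- sum(rownames(m) %in% targets)
    apply(m, 2, function(v) {
        ord <- order(-v, seq_along(v), method = "radix")
        hit <- rownames(m)[ord] %in% targets
        run <- 0; area <- 0
        for (r in seq_len(N)) {
            run <- run + hit[r]
            area <- area + run
        }
        area / sum(pmin(seq_len(N), mT))
    })
}

f1Score <- function(found, truth) {
    tp <- length(intersect(found, truth))
    if (!length(found) || !tp) return(0)
    prec <- tp / length(found)
    rec <- tp / length(truth)
    2 * prec * rec / (prec + rec)
}
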