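# Synthetic multiplexed EMT time-course and inhibitor-screen generator.
# Every downstream stage of the pipeline can be exercised against the ground
# truth this module emits, without any external accession.

shapeValue <- function(shape, t) {
    switch(shape,
        linear = t,
        sigmoid = {
            lo <- plogis(-5); hi <- plogis(5)
            (plogis(10 * (t - 0.5)) - lo) / (hi - lo)
        },
        transient = exp(-((t - 0.5)^2) / (2 * 0.15^2)),
        stop("unknown dynamics shape: ", shape))
}

# Response-program geometry: a conserved core present in every condition plus
# a common pool each condition samples its remaining response genes from.
# Pool size is chosen so the expected pairwise intersection (hypergeometric)
# hits the target Jaccard; infeasible geometries are rejected.
.responseGeometry <- function(config) {
    m <- config@nResponseGenes
    K <- config@nConditions
    J <- config@pairwiseOverlap
    if (J >= 1 - 1e-12)
        return(list(coreSize = m, poolSize = 0L, poolDraw = 0L))
    targetInt <- 2 * m * J / (1 + J)
    coreSize <- round(config@fracConserved * m)
    if (coreSize > targetInt + 1e-9)
        stop("infeasible overlap geometry: conserved core alone (",
             coreSize, " genes) forces a pairwise intersection above the ",
             "pairwiseOverlap target")
    poolDraw <- m - coreSize
    extraInt <- targetInt - coreSize
    if (extraInt < 0.5) {
        # effectively disjoint non-core programs: private genes per condition
        need <- coreSize + K * poolDraw
        if (need > config@nGenes)
            stop("infeasible overlap geometry: ", need,
                 " response genes required but only ", config@nGenes,
                 " genes in the panel")
        return(list(coreSize = as.integer(coreSize), poolSize = NA_integer_,
                    poolDraw = as.integer(poolDraw)))
    }
    poolSize <- round(poolDraw^2 / extraInt)
    if (poolSize < poolDraw)
        stop("infeasible overlap geometry: requested overlap too high for ",
             "fracConserved = ", config@fracConserved,
             "; increase fracConserved or pairwise overlap target")
    if (coreSize + poolSize > config@nGenes)
        stop("infeasible overlap geometry: core + pool (",
             coreSize + poolSize, ") exceeds nGenes (", config@nGenes, ")")
    list(coreSize = as.integer(coreSize), poolSize = as.integer(poolSize),
         poolDraw = as.integer(poolDraw))
}

.withdrawDays <- function(n) 3^(seq_len(n) - 1) / 3

.timepointLabels <- function(config) {
    tr <- if (config@nTreatTimepoints == 5L) c("0d", "8h", "1d", "3d", "7d")
          else paste0("t", seq_len(config@nTreatTimepoints))
    wd <- if (config@nWithdrawTimepoints > 0L)
        paste0("w", format(.withdrawDays(config@nWithdrawTimepoints),
                           trim = TRUE, digits = 3), "d")
    else character()
    list(treat = tr, withdraw = wd)
}

#' Simulate a panel of EMT time-course experiments
#'
#' Draws a multi-condition panel of gene x cell UMI count matrices from a
#' negative-binomial observation model. Each condition has its own signed
#' response program whose genes follow linear, sigmoid or transient trends
#' along a latent progression coordinate; treatment time points tile the
#' latent coordinate and withdrawal time points decay back toward baseline
#' with the configured half-life. Programs share a conserved core (consistent
#' sign in all conditions) and overlap pairwise at the configured target
#' Jaccard index. Two batches receive gene-wise log-mean shifts.
#'
#' @param config a \code{\link{panelConfig}}.
#' @return A list with \code{sces} (one
#'   \code{\link[SingleCellExperiment]{SingleCellExperiment}} per condition,
#'   with colData columns condition, timepoint, phase, batch, sample,
#'   latentTime), \code{truth} (a \code{SyntheticTruth}) and \code{params}
#'   (generative parameters, consumed by \code{\link{simulateScreen}}).
#' @examples
#' panel <- simulateConditionPanel(panelConfig(nConditions = 2,
#'     cellsPerSample = 20, nGenes = 200, nResponseGenes = 20, seed = 1))
#' panel$truth
#' @export
simulateConditionPanel <- function(config) {
    stopifnot(is(config, "PanelConfig"))
    validObject(config)
    set.seed(config@seed)
    K <- config@nConditions
    nGenes <- config@nGenes
    geneIds <- sprintf("GENE%04d", seq_len(nGenes))
    geom <- .responseGeometry(config)

    # assign response-gene identities
    if (is.na(geom$poolSize)) {            # disjoint non-core programs
        universe <- sample(geneIds, geom$coreSize + K * geom$poolDraw)
        core <- universe[seq_len(geom$coreSize)]
        privates <- split(setdiff(universe, core),
                          rep(seq_len(K), each = geom$poolDraw))
        memberGenes <- lapply(seq_len(K), function(k) c(core, privates[[k]]))
        pool <- unlist(privates, use.names = FALSE)
    } else {
        universe <- sample(geneIds, geom$coreSize + geom$poolSize)
        core <- universe[seq_len(geom$coreSize)]
        pool <- setdiff(universe, core)
        memberGenes <- lapply(seq_len(K), function(k)
            c(core, if (geom$poolDraw > 0) sample(pool, geom$poolDraw)))
    }
    respUniverse <- unique(c(core, pool))

    # global per-gene sign (consistent wherever shared), magnitude and shape;
    # the conserved core is kept monotone so directional calls agree
    sign <- setNames(ifelse(runif(length(respUniverse)) < 0.835, 1, -1),
                     respUniverse)
    mag <- setNames(runif(length(respUniverse), 1.0, 2.0), respUniverse)
    monotoneShapes <- intersect(config@dynamicsShapes, c("linear", "sigmoid"))
    if (!length(monotoneShapes)) monotoneShapes <- "linear"
    shape <- setNames(sample(config@dynamicsShapes, length(respUniverse),
                             replace = TRUE), respUniverse)
    shape[core] <- sample(monotoneShapes, length(core), replace = TRUE)

    baseMean <- setNames(rlnorm(nGenes, meanlog = log(0.3), sdlog = 1.2),
                         geneIds)
    # response genes are drawn from the detectable expression stratum: a
    # programmed response on a gene with essentially no counts is
    # unobservable at scRNA-seq depth and would make the truth labels
    # unidentifiable for any method
    baseMean[respUniverse] <- pmax(
        rlnorm(length(respUniverse), meanlog = log(1), sdlog = 0.8), 0.3)
    batchShift <- setNames(rnorm(nGenes, 0, config@batchEffectSD), geneIds)

    labs <- .timepointLabels(config)
    Tt <- config@nTreatTimepoints
    latentByTp <- c(
        if (Tt > 1) (seq_len(Tt) - 1) / (Tt - 1) else 1,
        exp(-.withdrawDays(config@nWithdrawTimepoints) * log(2) /
            config@withdrawHalfLife))
    tpLabels <- c(labs$treat, labs$withdraw)
    phase <- c(rep("treatment", Tt),
               rep("withdrawal", config@nWithdrawTimepoints))

    condNames <- sprintf("cond%02d", seq_len(K))
    sces <- vector("list", K)
    names(sces) <- condNames
    latentAll <- numeric(0)
    responseSets <- vector("list", K)
    names(responseSets) <- condNames

    nTp <- length(tpLabels)
    nCell <- config@cellsPerSample
    for (k in seq_len(K)) {
        genes <- memberGenes[[k]]
        responseSets[[k]] <- list(up = genes[sign[genes] > 0],
                                  down = genes[sign[genes] < 0])
        tTp <- rep(latentByTp, each = nCell)
        t <- pmin(pmax(tTp + rnorm(nTp * nCell, 0, 0.05), 0), 1)
        batch <- rep(rep(1:2, length.out = nCell), nTp)
        # log-mean: baseline + programmed effect + batch shift
        logMu <- matrix(log(baseMean), nGenes, nTp * nCell,
                        dimnames = list(geneIds, NULL))
        for (g in genes) {
            sv <- shapeValue(shape[[g]], t)
            logMu[g, ] <- logMu[g, ] + sign[[g]] * mag[[g]] * sv
        }
        logMu[, batch == 2] <- logMu[, batch == 2] + batchShift
        mu <- exp(logMu)
        counts <- matrix(rnbinom(length(mu), size = 1 / config@nbDispersion,
                                 mu = mu), nrow = nGenes)
        cellIds <- sprintf("%s_c%05d", condNames[k], seq_len(nTp * nCell))
        dimnames(counts) <- list(geneIds, cellIds)
        cd <- S4Vectors::DataFrame(
            condition = condNames[k],
            timepoint = factor(rep(tpLabels, each = nCell), levels = tpLabels),
            phase = rep(phase, each = nCell),
            batch = factor(batch),
            sample = paste(condNames[k], rep(tpLabels, each = nCell),
                           sep = "."),
            latentTime = t,
            row.names = cellIds)
        sces[[k]] <- SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = methods::as(counts, "CsparseMatrix")),
            colData = cd)
        latentAll <- c(latentAll, setNames(t, cellIds))
    }

    # embedded regulons: one broad (core-driven, active everywhere) plus
    # narrow ones driven by single-condition programs
    regulons <- list()
    coreUp <- core[sign[core] > 0]
    if (length(coreUp) >= 5)
        regulons$TFcore <- sample(coreUp, min(15, length(coreUp)))
    for (k in seq_len(min(3, K))) {
        up <- responseSets[[k]]$up
        if (length(up) >= 5)
            regulons[[paste0("TF", condNames[k])]] <-
                sample(up, min(15, length(up)))
    }

    freq <- table(unlist(lapply(responseSets, function(s) c(s$up, s$down))))
    minCond <- ceiling(2 * K / 3)
    conserved <- as.character(names(freq)[freq >= minCond])
    truth <- new("SyntheticTruth",
                 latentTime = latentAll,
                 responseSets = responseSets,
                 conservedUp = conserved[sign[conserved] > 0],
                 conservedDown = conserved[sign[conserved] < 0],
                 regulons = regulons,
                 doubletLabels = logical(0),
                 poolStatus = character(0),
                 sampleOfCell = character(0),
                 inhibitorEffects = list())
    params <- list(geneIds = geneIds, baseMean = baseMean,
                   batchShift = batchShift, sign = sign, mag = mag,
                   shape = shape, config = config)
    list(sces = sces, truth = truth, params = params)
}

#' Pool a simulated panel and attach sample barcodes
#'
#' Emulates lipid-barcode sample multiplexing: all cells of the panel are
#' pooled, each singlet receives log-normally distributed counts for exactly
#' its sample's barcode and low ambient (Poisson) counts for all others.
#' A configured fraction of cells become doublets (expression is the sum of
#' two random cells; both barcodes positive) or barcode negatives (ambient
#' counts only).
#'
#' @param panel output of \code{\link{simulateConditionPanel}}.
#' @param config the \code{\link{panelConfig}} used to build the panel.
#' @return List with \code{sce} (pooled counts + annotation), \code{barcodes}
#'   (cell x barcode sparse count matrix) and the updated \code{truth}.
#' @export
poolAndBarcode <- function(panel, config) {
    stopifnot(is(config, "PanelConfig"))
    if (config@doubletRate + config@negativeRate >= 1)
        stop("doubletRate + negativeRate must be < 1")
    set.seed(config@seed + 1L)
    counts <- do.call(cbind, lapply(panel$sces,
                                    function(s) SummarizedExperiment::assay(s, "counts")))
    cd <- do.call(rbind, lapply(panel$sces, SummarizedExperiment::colData))
    nCells <- ncol(counts)
    cellIds <- colnames(counts)
    samples <- cd$sample
    barcodes <- sort(unique(samples))

    u <- runif(nCells)
    status <- ifelse(u < config@doubletRate, "doublet",
              ifelse(u < config@doubletRate + config@negativeRate,
                     "negative", "singlet"))
    partner <- rep(NA_integer_, nCells)
    dbl <- which(status == "doublet")
    if (length(dbl)) {
        # partner drawn from a different sample so both barcodes light up
        # (same-sample doublets carry one barcode and are indistinguishable
        # from singlets by construction of the assay)
        partner[dbl] <- vapply(dbl, function(i)
            sample(which(samples != samples[i]), 1L), integer(1))
        counts[, dbl] <- counts[, dbl] + counts[, partner[dbl]]
    }

    # barcode counts: positive mode log-normal, ambient Poisson
    bc <- matrix(rpois(nCells * length(barcodes), lambda = 1),
                 nrow = nCells, dimnames = list(cellIds, barcodes))
    pos <- function(n) round(rlnorm(n, meanlog = log(300), sdlog = 0.3))
    sing <- which(status == "singlet")
    bc[cbind(sing, match(samples[sing], barcodes))] <- pos(length(sing))
    if (length(dbl)) {
        bc[cbind(dbl, match(samples[dbl], barcodes))] <- pos(length(dbl))
        bc[cbind(dbl, match(samples[partner[dbl]], barcodes))] <-
            pos(length(dbl))
    }

    sampleOf <- samples
    sampleOf[dbl] <- paste(samples[dbl], samples[partner[dbl]], sep = ",")
    truth <- panel$truth
    truth@doubletLabels <- setNames(status == "doublet", cellIds)
    truth@poolStatus <- setNames(status, cellIds)
    truth@sampleOfCell <- setNames(sampleOf, cellIds)

    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(counts, "CsparseMatrix")),
        colData = cd)
    list(sce = sce, barcodes = methods::as(bc, "CsparseMatrix"),
         truth = truth)
}

#' Simulate a kinase-inhibitor screen for one panel condition
#'
#' Generates end-point (day 7) expression for a set of inhibitors using the
#' generative parameters of a trained condition: an inert inhibitor leaves
#' the day-7 program intact, a full block holds every response gene at its
#' day-0 level, and a partial block holds only a stated module of response
#' genes at day 0 while the rest of the program proceeds. Untreated (day 0,
#' no inhibitor) control cells are always included. Cytotoxic inhibitors are
#' emulated by reduced cell numbers.
#'
#' @param panel output of \code{\link{simulateConditionPanel}}.
#' @param condition condition name (or index) whose program the screen uses.
#' @param inhibitors named list; each element is \code{list(type =
#'   c("none","full_block","partial_block"), module = <genes>, cytotoxic =
#'   FALSE)}. \code{module} is required for partial blocks and must be a
#'   subset of the condition's response set.
#' @param cellsPerSample cells per inhibitor (default from config).
#' @return List with \code{sce} (colData: inhibitor, group), \code{barcodes},
#'   and \code{truth} with \code{inhibitorEffects} filled in.
#' @export
simulateScreen <- function(panel, condition = 1, inhibitors,
                           cellsPerSample = NULL) {
    params <- panel$params
    config <- params$config
    if (is.numeric(condition)) condition <- names(panel$sces)[condition]
    rs <- panel$truth@responseSets[[condition]]
    respGenes <- c(rs$up, rs$down)
    if (is.null(cellsPerSample)) cellsPerSample <- config@cellsPerSample
    set.seed(config@seed + 2L)

    groups <- c(list(untreated = list(type = "untreated")), inhibitors)
    nGenes <- length(params$geneIds)
    mats <- list(); cds <- list()
    effects <- list()
    for (nm in names(groups)) {
        inhSpec <- groups[[nm]]
        type <- inhSpec$type
        n <- cellsPerSample
        if (isTRUE(inhSpec$cytotoxic)) n <- max(2L, round(n * 0.1))
        t <- if (type == "untreated") pmin(pmax(rnorm(n, 0, 0.03), 0), 1)
             else pmin(pmax(rnorm(n, 1, 0.03), 0), 1)
        blocked <- switch(type,
            untreated = character(),
            none = character(),
            full_block = respGenes,
            partial_block = {
                if (is.null(inhSpec$module))
                    stop("partial_block requires a module")
                if (!all(inhSpec$module %in% respGenes))
                    stop("partial_block module is not a subset of the ",
                         "response set of ", condition)
                inhSpec$module
            },
            stop("unknown inhibitor type: ", type))
        logMu <- matrix(log(params$baseMean), nGenes, n,
                        dimnames = list(params$geneIds, NULL))
        active <- setdiff(respGenes, blocked)
        for (g in active) {
            sv <- shapeValue(params$shape[[g]], t)
            logMu[g, ] <- logMu[g, ] + params$sign[[g]] * params$mag[[g]] * sv
        }
        mu <- exp(logMu)
        m <- matrix(rnbinom(length(mu), size = 1 / config@nbDispersion,
                            mu = mu), nrow = nGenes)
        ids <- sprintf("scr_%s_c%04d", nm, seq_len(n))
        dimnames(m) <- list(params$geneIds, ids)
        mats[[nm]] <- m
        cds[[nm]] <- S4Vectors::DataFrame(
            inhibitor = rep(nm, n),
            group = rep(if (type == "untreated") "untreated" else "induced",
                        n),
            row.names = ids)
        if (!nm %in% "untreated")
            effects[[nm]] <- list(type = type,
                                  module = if (type == "partial_block")
                                      inhSpec$module else character())
    }
    counts <- do.call(cbind, mats)
    cd <- do.call(rbind, cds)
    cellIds <- rownames(cd)
    bcNames <- names(groups)
    bc <- matrix(rpois(length(cellIds) * length(bcNames), 1),
                 nrow = length(cellIds),
                 dimnames = list(cellIds, bcNames))
    idx <- match(cd$inhibitor, bcNames)
    bc[cbind(seq_along(cellIds), idx)] <-
        round(rlnorm(length(cellIds), log(300), 0.3))
    truth <- panel$truth
    truth@inhibitorEffects <- effects
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(counts, "CsparseMatrix")),
        colData = cd)
    list(sce = sce, barcodes = methods::as(bc, "CsparseMatrix"),
         truth = truth, condition = condition)
}
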