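# Kinase-inhibitor screen interpretation: project inhibited cells onto the
# matching time-course pseudotime model, classify each inhibitor's effect on
# EMT progression, partition the induced response program into inhibited vs
# unaffected genes, and test the temporal-block alternative.

#' Mean projected pseudotime per screen condition
#'
#' Projects every screen cell onto the pseudotime model trained on the
#' matching time course (same cell line and inducer), rescales with the
#' model's stored training range, and summarizes per inhibitor. Conditions
#' with fewer than \code{minCells} cells are flagged and not scored
#' (cytotoxic drop-out stays visible through the cell counts).
#'
#' @param model \code{\linkS4class{PseudotimeModel}} of the matching time
#'   course.
#' @param x gene x cell expression matrix of the screen (same representation
#'   as training).
#' @param inhibitor per-cell inhibitor annotation.
#' @param minCells minimum cells for a condition to be scored.
#' @return list with \code{table} (data.frame inhibitor, n, meanPt, sdPt,
#'   scored), \code{scores} (per-cell rescaled pseudotime) and
#'   \code{flagged} (inhibitors below minCells).
#' @export
scoreScreen <- function(model, x, inhibitor, minCells = 20) {
    pt <- projectPseudotime(model, x)
    f <- factor(inhibitor)
    n <- as.integer(table(f))
    names(n) <- levels(f)
    meanPt <- tapply(pt$rescaled, f, mean)
    sdPt <- tapply(pt$rescaled, f, sd)
    scored <- n >= minCells
    tab <- data.frame(inhibitor = levels(f), n = n,
                      meanPt = ifelse(scored, meanPt, NA_real_),
                      sdPt = ifelse(scored, sdPt, NA_real_),
                      scored = scored, row.names = levels(f))
    list(table = tab, scores = setNames(pt$rescaled, rownames(pt)),
         flagged = levels(f)[!scored])
}

#' Classify an inhibitor's effect on EMT progression
#'
#' Rank-sum (Wilcoxon) bracketing of the inhibitor's pseudotime scores:
#' \code{"none"} if not significantly lower than the uninhibited induced
#' control; otherwise \code{"full"} block if not significantly higher than
#' the untreated cells, \code{"partial"} if it sits significantly above
#' untreated and below the induced control.
#'
#' @param screenScores pseudotime scores of the inhibitor-treated induced
#'   cells.
#' @param inducedControlScores scores of induced, uninhibited control cells.
#' @param untreatedScores scores of untreated cells.
#' @param alpha one-sided test level.
#' @return list with \code{class} ("none"/"partial"/"full") and the two
#'   one-sided p-values.
#' @export
classifyBlock <- function(screenScores, inducedControlScores,
                          untreatedScores, alpha = 0.05) {
    if (length(screenScores) < 3 || length(inducedControlScores) < 3 ||
        length(untreatedScores) < 3)
        stop("degenerate group: need at least 3 scores per group")
    pLower <- wilcox.test(screenScores, inducedControlScores,
                          alternative = "less", exact = FALSE)$p.value
    pAbove <- wilcox.test(screenScores, untreatedScores,
                          alternative = "greater", exact = FALSE)$p.value
    cls <- if (pLower >= alpha) "none"
           else if (pAbove < alpha) "partial"
           else "full"
    list(class = cls, pVsInduced = pLower, pVsUntreated = pAbove)
}

#' Partition the induced response program by inhibitor effect
#'
#' For each significant induced response gene, the induced effect
#' Delta = mean(induced) - mean(untreated) and the residual effect under the
#' inhibitor Delta' = mean(induced + inhibitor) - mean(untreated) are
#' compared: the gene is "inhibited" when |Delta'| < f |Delta| or Delta'
#' changes sign, otherwise "unaffected". The partition is exhaustive and
#' exclusive over the induced DE universe.
#'
#' @param inducedDE \code{GeneDynamics} of the induced time course, or a
#'   character vector of significant induced genes.
#' @param exprUntreated,exprInduced,exprInducedInhibited gene x cell
#'   expression matrices of the three groups.
#' @param f residual-effect fraction below which a gene counts as inhibited.
#' @return list with \code{inhibited}, \code{unaffected} (character
#'   vectors) and \code{effects} (data.frame gene, delta, deltaResidual).
#' @export
partitionResponseGenes <- function(inducedDE, exprUntreated, exprInduced,
                                   exprInducedInhibited, f = 0.5) {
    genes <- if (is(inducedDE, "GeneDynamics")) significantGenes(inducedDE)
             else as.character(inducedDE)
    for (m in list(exprUntreated, exprInduced, exprInducedInhibited))
        if (is.null(m) || !ncol(.getCounts(m)))
            stop("missing expression group")
    genes <- Reduce(intersect, list(genes, rownames(.getCounts(exprUntreated)),
                                    rownames(.getCounts(exprInduced)),
                                    rownames(.getCounts(exprInducedInhibited))))
    mu0 <- rowMeans(as.matrix(.getCounts(exprUntreated))[genes, , drop = FALSE])
    mu1 <- rowMeans(as.matrix(.getCounts(exprInduced))[genes, , drop = FALSE])
    mu2 <- rowMeans(as.matrix(.getCounts(exprInducedInhibited))[genes, ,
                                                                drop = FALSE])
    delta <- mu1 - mu0
    deltaRes <- mu2 - mu0
    inhibited <- abs(deltaRes) < f * abs(delta) |
        sign(deltaRes) * sign(delta) < 0
    list(inhibited = genes[inhibited], unaffected = genes[!inhibited],
         effects = data.frame(gene = genes, delta = unname(delta),
                              deltaResidual = unname(deltaRes),
                              row.names = genes))
}

#' Activation times from fitted trends
#'
#' The pseudotime of half-maximal change for each gene: the first grid point
#' where the fitted trend crosses half of its total change from the start of
#' the trajectory.
#'
#' @param dyn a \code{\linkS4class{GeneDynamics}}.
#' @param genes genes to report (default all).
#' @return named numeric of activation pseudotimes.
#' @export
activationTimes <- function(dyn, genes = NULL) {
    tr <- trendMatrix(dyn)
    grid <- trendGrid(dyn)
    if (is.null(genes)) genes <- rownames(tr)
    vapply(genes, function(g) {
        y <- tr[g, ]
        total <- y[length(y)] - y[1]
        if (abs(total) < 1e-12) return(grid[1])
        rel <- (y - y[1]) / total
        grid[which(rel >= 0.5)[1]]
    }, numeric(1))
}

#' Test the temporal-block alternative
#'
#' If an inhibitor merely froze EMT progression at an earlier stage, the
#' genes it blocks would be the late-activating ones. Compares the
#' activation-time distributions of inhibited versus unaffected genes with a
#' two-sample Kolmogorov-Smirnov test; a non-significant result argues
#' against a temporal block (the inhibitor removes a module, not a phase).
#'
#' @param inhibited,unaffected character gene vectors from
#'   \code{\link{partitionResponseGenes}}.
#' @param times named activation times from \code{\link{activationTimes}}.
#' @return list with \code{D}, \code{p}.
#' @export
temporalBlockCheck <- function(inhibited, unaffected, times) {
    a <- times[intersect(inhibited, names(times))]
    b <- times[intersect(unaffected, names(times))]
    if (length(a) < 3 || length(b) < 3)
        stop("need at least 3 genes with activation times in each set")
    kt <- suppressWarnings(ks.test(a, b))
    list(D = unname(kt$statistic), p = unname(kt$p.value))
}
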