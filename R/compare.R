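# Cross-condition context-specificity statistics: how much do the EMT
# response programs of different conditions actually overlap?

#' Pairwise Jaccard matrix of differential-expression sets
#'
#' J(A,B) = |A n B| / |A u B| for every pair of conditions, plus the mean of
#' the off-diagonal entries (the headline context-specificity number).
#'
#' @param deSets named list of per-condition gene sets.
#' @return list with \code{matrix} (K x K, symmetric, unit diagonal) and
#'   \code{meanOffdiag}.
#' @export
jaccardMatrix <- function(deSets) {
    if (length(deSets) < 2) stop("need at least two sets")
    empty <- lengths(lapply(deSets, unique)) == 0
    if (any(empty))
        stop("empty DE set for condition: ",
             paste(names(deSets)[empty], collapse = ", "))
    K <- length(deSets)
    J <- matrix(1, K, K, dimnames = list(names(deSets), names(deSets)))
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
        a <- unique(deSets[[i]]); b <- unique(deSets[[j]])
        J[i, j] <- J[j, i] <- length(intersect(a, b)) / length(union(a, b))
    }
    list(matrix = J, meanOffdiag = mean(J[upper.tri(J)]))
}

#' Differential-expression frequency spectrum
#'
#' For every gene, in how many conditions it is called significant; plus
#' the histogram of those counts (how many genes are condition-restricted
#' versus broadly shared).
#'
#' @param deResults named list of per-condition \code{GeneDynamics} objects
#'   or significant gene-set character vectors.
#' @return list with \code{frequency} (named integer per gene in the union)
#'   and \code{histogram} (table over 1..K).
#' @export
deFrequency <- function(deResults) {
    sets <- lapply(deResults, function(d)
        if (is(d, "GeneDynamics")) significantGenes(d) else as.character(d))
    allGenes <- unlist(sets, use.names = FALSE)
    freq <- table(allGenes)
    freq <- setNames(as.integer(freq), names(freq))
    hist <- table(factor(freq, levels = seq_len(length(sets))))
    list(frequency = freq, histogram = hist)
}

#' Conserved signed response gene sets
#'
#' Genes significant in at least \code{minConditions} conditions are
#' assigned to the conserved up (down) set when their pseudotime beta is
#' positive (negative) in every condition where they are significant; genes
#' with mixed signs are reported as conflicted and excluded from both sets.
#' The default threshold is two-thirds of the conditions.
#'
#' @param deResults named list of per-condition \code{GeneDynamics} objects.
#' @param minConditions minimum number of significant conditions; default
#'   \code{ceiling(2/3 * K)}.
#' @return list with \code{up}, \code{down}, \code{conflicted} character
#'   vectors and the frequency table used.
#' @export
conservedSets <- function(deResults, minConditions = NULL) {
    K <- length(deResults)
    if (is.null(minConditions)) minConditions <- ceiling(2 * K / 3)
    if (minConditions > K)
        stop("minConditions exceeds the number of conditions")
    freq <- deFrequency(deResults)$frequency
    candidates <- names(freq)[freq >= minConditions]
    up <- character(); down <- character(); conflicted <- character()
    for (g in candidates) {
        betas <- vapply(deResults, function(d) {
            tab <- dynTable(d)
            i <- match(g, tab$gene)
            if (!is.na(i) && tab$significant[i]) tab$beta[i] else NA_real_
        }, numeric(1))
        betas <- betas[!is.na(betas)]
        if (all(betas > 0)) up <- c(up, g)
        else if (all(betas < 0)) down <- c(down, g)
        else conflicted <- c(conflicted, g)
    }
    list(up = up, down = down, conflicted = conflicted, frequency = freq)
}

#' Frequency of differential regulon activity across conditions
#'
#' Given per-condition directional tests of regulon activity scores
#' (\code{\link{linearDirection}} on AUC scores: data.frames with gene/beta/
#' p columns, one row per regulon), counts the conditions where each regulon
#' changes significantly (BH-adjusted within condition), and returns the
#' regulons meeting the threshold together with their per-condition beta
#' matrix.
#'
#' @param regulonTests named list (condition -> data.frame with columns
#'   gene, beta, p).
#' @param minConditions retention threshold (default 6).
#' @param alpha BH-adjusted significance level.
#' @return list with \code{counts} (per regulon), \code{conserved} (names
#'   meeting the threshold) and \code{betaMatrix} (conserved regulon x
#'   condition).
#' @export
regulonFrequency <- function(regulonTests, minConditions = 6, alpha = 0.05) {
    sig <- lapply(regulonTests, function(d) {
        adj <- p.adjust(d$p, method = "BH")
        setNames(adj < alpha, d$gene)
    })
    regs <- unique(unlist(lapply(sig, names)))
    counts <- setNames(integer(length(regs)), regs)
    for (s in sig) {
        hit <- names(s)[s]
        counts[hit] <- counts[hit] + 1L
    }
    conserved <- names(counts)[counts >= minConditions]
    betaMatrix <- matrix(NA_real_, length(conserved), length(regulonTests),
                         dimnames = list(conserved, names(regulonTests)))
    for (cn in names(regulonTests)) {
        d <- regulonTests[[cn]]
        i <- match(conserved, d$gene)
        betaMatrix[, cn] <- d$beta[i]
    }
    list(counts = counts, conserved = conserved, betaMatrix = betaMatrix)
}

#' Exclusive intersection table of gene sets (UpSet-style)
#'
#' For every observed membership pattern over the input sets, the number of
#' genes belonging exactly to that pattern; pattern counts sum to the size
#' of the union.
#'
#' @param sets named list of character vectors (e.g. per-condition top
#'   variable genes).
#' @return data.frame with columns \code{pattern} (comma-separated set
#'   names) and \code{count}, sorted by decreasing count.
#' @export
setIntersections <- function(sets) {
    if (!length(sets)) stop("need at least one set")
    if (is.null(names(sets))) names(sets) <- paste0("S", seq_along(sets))
    genes <- unique(unlist(sets))
    memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
    if (length(genes) == 1) memb <- matrix(memb, nrow = 1)
    pattern <- apply(memb, 1, function(r)
        paste(names(sets)[r], collapse = ","))
    tab <- table(pattern)
    out <- data.frame(pattern = names(tab), count = as.integer(tab))
    out[order(-out$count), , drop = FALSE]
}
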