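# Per-cell gene-set and regulon scoring, preranked enrichment, and
# over-representation statistics. Gene sets and regulons are plain named
# lists of character vectors (GMT convention, as in fgsea).

#' Read / write GMT gene-set files
#'
#' @param path file path.
#' @return \code{readGMT}: named list of character vectors.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1]]
        setNames(list(unique(f[-(1:2)])), f[1])
    })
    do.call(c, out)
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param description optional per-set description column.
#' @export
writeGMT <- function(sets, path, description = names(sets)) {
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Per-cell module score with expression-matched controls
#'
#' Mean expression of the set's genes minus the mean of control genes; each
#' set gene contributes controls drawn from its average-expression bin
#' (equal-frequency binning of all genes), so the score is centered against
#' genes of comparable abundance.
#'
#' @param x gene x cell expression matrix (log-normalized).
#' @param set character vector of member genes.
#' @param nBins number of average-expression bins.
#' @param nCtrl control genes drawn per member.
#' @param seed RNG seed for the control draw.
#' @return named per-cell numeric score.
#' @export
moduleScore <- function(x, set, nBins = 24, nCtrl = 100, seed = 1) {
    m <- as.matrix(.getCounts(x))
    members <- intersect(set, rownames(m))
    if (!length(members)) stop("no set member present in the matrix")
    avg <- rowMeans(m)
    bin <- if (nBins <= 1) rep(1L, nrow(m))
           else cut(rank(avg, ties.method = "first"), breaks = nBins,
                    labels = FALSE)
    names(bin) <- rownames(m)
    set.seed(seed)
    ctrl <- unique(unlist(lapply(members, function(g) {
        pool <- names(bin)[bin == bin[[g]]]
        sample(pool, min(nCtrl, length(pool)))
    })))
    colMeans(m[members, , drop = FALSE]) - colMeans(m[ctrl, , drop = FALSE])
}

# recovery-curve AUC of `targetIdx` positions within a ranking order,
# integrated to maxRank and normalized to the maximum attainable area
.recoveryAUC <- function(isHit, maxRank, nTargets) {
    if (nTargets == 0) return(0)
    R <- cumsum(isHit[seq_len(maxRank)])
    sum(R) / sum(pmin(seq_len(maxRank), nTargets))
}

#' Rank-based regulon activity score (recovery-curve AUC)
#'
#' Per cell, genes are ranked by decreasing expression (ties broken by the
#' fixed input gene order, keeping the score deterministic across
#' platforms); the score is the area under the cumulative recovery curve of
#' the regulon's targets within the top \code{topFrac} of the ranking,
#' normalized by the maximum attainable area. Being rank-based, the score
#' is invariant to monotone transforms of a cell's expression profile.
#'
#' @param x gene x cell expression matrix.
#' @param targets character vector of regulon target genes.
#' @param topFrac fraction of the ranking integrated (default 0.05).
#' @return named per-cell AUC in [0,1].
#' @export
aucellScore <- function(x, targets, topFrac = 0.05) {
    if (topFrac <= 0 || topFrac > 1) stop("topFrac must be in (0, 1]")
    m <- as.matrix(.getCounts(x))
    hit <- rownames(m) %in% targets
    if (!any(hit)) stop("no regulon target present in the matrix")
    nGenes <- nrow(m)
    maxRank <- ceiling(topFrac * nGenes)
    nT <- sum(hit)
    apply(m, 2, function(v) {
        ord <- order(-v, seq_along(v), method = "radix")
        .recoveryAUC(hit[ord], maxRank, nT)
    })
}

#' @rdname aucellScore
#' @param regulons named list of target-gene vectors.
#' @return \code{aucellScoreMatrix}: regulon x cell matrix of AUCs.
#' @export
aucellScoreMatrix <- function(x, regulons, topFrac = 0.05) {
    m <- as.matrix(.getCounts(x))
    nGenes <- nrow(m)
    maxRank <- ceiling(topFrac * nGenes)
    ords <- apply(m, 2, function(v) order(-v, seq_along(v), method = "radix"))
    out <- matrix(0, length(regulons), ncol(m),
                  dimnames = list(names(regulons), colnames(m)))
    for (r in seq_along(regulons)) {
        hit <- rownames(m) %in% regulons[[r]]
        if (!any(hit)) next
        nT <- sum(hit)
        out[r, ] <- vapply(seq_len(ncol(m)), function(j)
            .recoveryAUC(hit[ords[, j]], maxRank, nT), numeric(1))
    }
    out
}

.runningES <- function(stat, isHit, weight) {
    N <- length(stat)
    Nh <- sum(isHit)
    w <- abs(stat)^weight
    inc <- numeric(N)
    inc[isHit] <- w[isHit] / sum(w[isHit])
    inc[!isHit] <- -1 / (N - Nh)
    rs <- cumsum(inc)
    peak <- which.max(abs(rs))
    list(ES = rs[peak], peak = peak, running = rs)
}

#' Preranked gene-set enrichment (running-sum ES / permutation NES)
#'
#' Genes are ordered by decreasing statistic; the running sum increments by
#' |statistic|^weight at set members (normalized over members) and
#' decrements by a constant at non-members. ES is the maximum deviation.
#' NES normalizes ES by the mean |ES| of sign-matched gene-label
#' permutations; the p-value is the permutation tail probability.
#'
#' @param ranking named numeric vector (gene-level statistics).
#' @param set character vector of member genes; members missing from the
#'   ranking are dropped with a warning.
#' @param nPerm number of gene permutations.
#' @param weight running-sum weight exponent (0 = unweighted
#'   Kolmogorov-Smirnov style).
#' @param seed RNG seed for the permutations.
#' @return list with ES, NES, p, leadingEdge.
#' @export
gseaPreranked <- function(ranking, set, nPerm = 1000, weight = 1, seed = 1) {
    if (nPerm < 100) stop("nPerm must be >= 100")
    ord <- order(-ranking, seq_along(ranking), method = "radix")
    stat <- ranking[ord]
    genes <- names(stat)
    members <- intersect(set, genes)
    if (length(members) < length(unique(set)))
        warning(length(unique(set)) - length(members),
                " set members absent from the ranking; dropped")
    if (!length(members)) stop("no set member present in the ranking")
    if (length(members) == length(genes))
        stop("set covers all ranked genes; miss penalty undefined")
    isHit <- genes %in% members
    obs <- .runningES(stat, isHit, weight)
    le <- if (obs$ES >= 0) genes[seq_len(obs$peak)][isHit[seq_len(obs$peak)]]
          else genes[obs$peak:length(genes)][isHit[obs$peak:length(genes)]]
    set.seed(seed)
    Nh <- length(members)
    permES <- vapply(seq_len(nPerm), function(i) {
        ph <- logical(length(genes))
        ph[sample(length(genes), Nh)] <- TRUE
        .runningES(stat, ph, weight)$ES
    }, numeric(1))
    same <- if (obs$ES >= 0) permES[permES >= 0] else permES[permES < 0]
    nes <- if (length(same)) obs$ES / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$ES))) / (1 + length(same))
    list(ES = unname(obs$ES), NES = unname(nes), p = unname(p),
         leadingEdge = le)
}

#' Difference of recovery-based enrichment between two gene lists
#'
#' For each collection set (e.g. a transcription-factor target set with its
#' own ranking of all genes), the recovery-curve AUC of list A and of list B
#' within that ranking is computed and converted to an NES by standardizing
#' across the collection ((AUC - mean) / sd, the convention of
#' recovery-based motif-ranking tools). Returns NES_A - NES_B per collection
#' set, ranked by the difference. Positive values mark sets uniquely
#' enriched in list A.
#'
#' @param listA,listB character gene vectors (e.g. inhibited vs unaffected
#'   response genes).
#' @param collection named list of collection sets (used for names and for
#'   default rankings).
#' @param rankings named list parallel to \code{collection}: for each set, a
#'   character vector of all genes ranked best-first. A single unnamed
#'   character vector is recycled for every set.
#' @param topFrac fraction of each ranking integrated.
#' @return data.frame with columns set, nesA, nesB, deltaNES, sorted by
#'   decreasing deltaNES. Metadata attribute records the AUC formula used.
#' @export
nesDifference <- function(listA, listB, collection, rankings,
                          topFrac = 0.05) {
    if (!length(collection)) stop("empty collection")
    if (!length(listA) || !length(listB)) stop("empty gene list")
    if (is.character(rankings))
        rankings <- setNames(rep(list(rankings), length(collection)),
                             names(collection))
    aucOf <- function(lst) vapply(names(collection), function(s) {
        rk <- rankings[[s]]
        maxRank <- ceiling(topFrac * length(rk))
        hit <- rk %in% lst
        .recoveryAUC(hit, maxRank, sum(hit))
    }, numeric(1))
    aucA <- aucOf(listA); aucB <- aucOf(listB)
    z <- function(a) if (sd(a) > 0) (a - mean(a)) / sd(a) else a * 0
    nesA <- z(aucA); nesB <- z(aucB)
    out <- data.frame(set = names(collection), nesA = nesA, nesB = nesB,
                      deltaNES = nesA - nesB)
    out <- out[order(-out$deltaNES), ]
    attr(out, "method") <- "recovery-AUC NES, standardized across collection"
    out
}

#' Hypergeometric over-representation of annotations in a query list
#'
#' Upper-tail hypergeometric p-value per annotation set (observed overlap or
#' larger), BH-adjusted across annotations.
#'
#' @param query character gene vector; must be a subset of universe.
#' @param annotations named list of annotation gene sets.
#' @param universe character vector of all assayable genes.
#' @return \code{\link[S4Vectors]{DataFrame}} with annotation, overlap,
#'   setSize, p_value, adj_p.
#' @export
hypergeomEnrichment <- function(query, annotations, universe) {
    if (!length(universe)) stop("empty universe")
    if (!all(query %in% universe))
        stop("query genes outside the universe: ",
             paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
    N <- length(unique(universe))
    n <- length(unique(query))
    res <- t(vapply(annotations, function(ann) {
        K <- length(intersect(ann, universe))
        k <- length(intersect(ann, query))
        c(k, K, phyper(k - 1, K, N - K, n, lower.tail = FALSE))
    }, numeric(3)))
    S4Vectors::DataFrame(
        annotation = names(annotations), overlap = as.integer(res[, 1]),
        setSize = as.integer(res[, 2]), p_value = res[, 3],
        adj_p = p.adjust(res[, 3], method = "BH"),
        row.names = names(annotations))
}
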