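# QC, normalization, variable genes, covariate regression, PCA.
# Functions accept either a gene x cell matrix (dense or sparse) or a
# SingleCellExperiment and return the same kind of object.

.isSCE <- function(x) is(x, "SingleCellExperiment")
.getCounts <- function(x) {
    if (.isSCE(x)) SummarizedExperiment::assay(x, "counts") else x
}

#' Quality-control filter on cells
#'
#' Retains cells with more than \code{minGenes} detected genes and a
#' mitochondrial fraction no greater than \code{maxMitoFrac}. Mitochondrial
#' genes are identified by an explicit list or a name prefix.
#'
#' @param x gene x cell count matrix or SingleCellExperiment.
#' @param minGenes cells must have strictly more detected genes than this.
#' @param maxMitoFrac maximum tolerated mitochondrial UMI fraction.
#' @param mitoGenes character vector of mitochondrial gene ids, or NULL to
#'   use \code{mitoPrefix}.
#' @param mitoPrefix gene-name prefix marking mitochondrial genes.
#' @return The filtered object, with a \code{"qcLog"} attribute recording the
#'   thresholds and the removed cells.
#' @export
qcFilter <- function(x, minGenes = 200, maxMitoFrac = 0.2,
                     mitoGenes = NULL, mitoPrefix = "MT-") {
    counts <- .getCounts(x)
    detected <- Matrix::colSums(counts > 0)
    if (is.null(mitoGenes))
        mitoGenes <- grep(paste0("^", mitoPrefix), rownames(counts),
                          value = TRUE)
    tot <- Matrix::colSums(counts)
    mito <- if (length(mitoGenes))
        Matrix::colSums(counts[rownames(counts) %in% mitoGenes, ,
                               drop = FALSE]) / pmax(tot, 1)
    else rep(0, ncol(counts))
    keep <- detected > minGenes & mito <= maxMitoFrac
    if (!any(keep))
        stop("qcFilter removed every cell (minGenes = ", minGenes,
             ", maxMitoFrac = ", maxMitoFrac, "; median detected = ",
             stats::median(detected), ", median mito = ",
             signif(stats::median(mito), 3), ")")
    out <- x[, keep]
    attr(out, "qcLog") <- list(minGenes = minGenes,
                               maxMitoFrac = maxMitoFrac,
                               removed = colnames(counts)[!keep],
                               nRemoved = sum(!keep))
    out
}

#' Remove rarely detected genes
#'
#' Genes detected in fewer than \code{minCellFrac} of cells (strict
#' inequality) are removed.
#'
#' @inheritParams qcFilter
#' @param minCellFrac minimum detection fraction.
#' @return The filtered object.
#' @export
filterGenes <- function(x, minCellFrac = 0.01) {
    counts <- .getCounts(x)
    frac <- Matrix::rowSums(counts > 0) / ncol(counts)
    x[frac >= minCellFrac, ]
}

#' Library-size log-normalization
#'
#' \code{value = log(1 + scaleFactor * count / cellTotal)}.
#'
#' @inheritParams qcFilter
#' @param scaleFactor library-size scale factor.
#' @return For a matrix input, the normalized gene x cell matrix; for a
#'   SingleCellExperiment, the object with a \code{"logcounts"} assay added.
#' @export
normalizeLog <- function(x, scaleFactor = 1e4) {
    counts <- .getCounts(x)
    tot <- Matrix::colSums(counts)
    if (any(tot == 0))
        stop("cells with zero total counts: ",
             paste(colnames(counts)[tot == 0], collapse = ", "))
    norm <- log1p(t(t(counts) * (scaleFactor / tot)))
    if (.isSCE(x)) {
        SummarizedExperiment::assay(x, "logcounts") <- norm
        x
    } else norm
}

#' Variance-stabilizing selection of variable genes
#'
#' Ranks genes by standardized variance computed from a fitted mean-variance
#' trend: a local (loess) regression of log10 variance on log10 mean predicts
#' each gene's expected standard deviation; raw counts are standardized with
#' it, clipped at sqrt(n cells), and the variance of the clipped values is
#' the ranking statistic.
#'
#' @inheritParams qcFilter
#' @param n number of genes to flag as variable.
#' @param loessSpan span of the mean-variance trend fit.
#' @return \code{\link[S4Vectors]{DataFrame}} with columns gene, mean,
#'   variance, varianceStandardized, rank, selected.
#' @export
selectVariableGenes <- function(x, n = 3000, loessSpan = 0.3) {
    counts <- .getCounts(x)
    if (n > nrow(counts))
        stop("n (", n, ") exceeds the number of genes (", nrow(counts), ")")
    m <- as.matrix(counts)
    mu <- rowMeans(m)
    v <- apply(m, 1, var)
    varStd <- numeric(length(mu))
    ok <- v > 0 & mu > 0
    if (sum(ok) >= 10) {
        fit <- loess(log10(v[ok]) ~ log10(mu[ok]), span = loessSpan,
                     degree = 2)
        sdExp <- sqrt(10^predict(fit))
        clip <- sqrt(ncol(m))
        z <- (m[ok, , drop = FALSE] - mu[ok]) / sdExp
        z <- pmin(z, clip)
        varStd[ok] <- apply(z, 1, var)
    } else {
        varStd[ok] <- v[ok]
    }
    rk <- rank(-varStd, ties.method = "first")
    S4Vectors::DataFrame(gene = rownames(m), mean = mu, variance = v,
                         varianceStandardized = varStd, rank = rk,
                         selected = rk <= n, row.names = rownames(m))
}

#' Scale expression and regress out technical covariates
#'
#' Per gene, ordinary least squares of expression on the covariates (for
#' example mitochondrial fraction, UMI count, cell-cycle scores, batch);
#' residuals are z-scored across cells and clipped.
#'
#' @param x gene x cell expression matrix (log-normalized values).
#' @param covariates data.frame of per-cell covariates (numeric or factor);
#'   NULL centers and scales without regression.
#' @param clip magnitude at which scaled residuals are clipped.
#' @return gene x cell matrix of scaled residuals.
#' @export
scaleAndRegress <- function(x, covariates = NULL, clip = 10) {
    m <- as.matrix(.getCounts(x))
    if (!is.null(covariates)) {
        X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
        qrX <- qr(X)
        if (qrX$rank < ncol(X)) {
            bad <- colnames(X)[-seq_len(qrX$rank)]
            stop("rank-deficient covariate design; offending columns: ",
                 paste(bad, collapse = ", "))
        }
        m <- t(qr.resid(qrX, t(m)))
    }
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    # rows with (numerically) no residual variation carry no signal: zero out
    # rather than amplifying floating-point noise
    tiny <- s < 1e-10 * pmax(1, abs(mu))
    s[tiny] <- Inf
    z <- (m - mu) / s
    pmin(pmax(z, -clip), clip)
}

#' Principal component analysis of cells
#'
#' @param x gene x cell expression matrix (typically scaled residuals over
#'   variable genes).
#' @param nComponents number of components to return.
#' @return List with \code{scores} (cell x component), \code{sdev} and
#'   \code{rotation}.
#' @export
runPCA <- function(x, nComponents = 30) {
    m <- as.matrix(.getCounts(x))
    if (nComponents > min(dim(m)))
        stop("nComponents exceeds min(n_genes, n_cells)")
    p <- prcomp(t(m), center = TRUE, scale. = FALSE, rank. = nComponents)
    list(scores = p$x, sdev = p$sdev, rotation = p$rotation)
}
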