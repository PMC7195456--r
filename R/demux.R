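# Sample-barcode demultiplexing: per-barcode bimodal thresholding on
# normalized log counts, with a global quantile chosen to maximize the
# singlet yield.

.normalizeBarcodes <- function(counts) {
    log1p(as.matrix(counts))
}

.barcodeModes <- function(v, minSeparation = 2) {
    d <- density(v, bw = "nrd0", n = 512)
    y <- d$y
    locmax <- which(diff(sign(diff(y))) == -2) + 1L
    # suppress noise modes below 1% of the tallest peak
    locmax <- locmax[y[locmax] > 0.01 * max(y)]
    if (length(locmax) < 2) return(NULL)
    lo <- d$x[min(locmax)]
    hi <- d$x[max(locmax)]
    # discreteness of low counts can produce several ripples within the
    # ambient mass; a genuine positive mode must sit well above it
    if (hi - lo < minSeparation) return(NULL)
    list(lo = lo, hi = hi)
}

#' Fit per-barcode positivity thresholds
#'
#' For each barcode, cell counts are log-scaled (log of count plus a unit
#' pseudocount) and density-smoothed (Gaussian kernel, Silverman bandwidth,
#' 512-point grid).
#' The lowest and highest local density maxima define the negative and
#' positive modes; for each candidate quantile q the threshold is placed at
#' the q-quantile of the inter-mode interval. The single global q that
#' maximizes the fraction of cells classified as singlets is selected; ties
#' break toward the smaller q. Barcodes with a unimodal distribution are
#' deemed absent (threshold above the mode) and recorded as warnings.
#'
#' @param barcodes cell x barcode count matrix.
#' @param quantileGrid candidate quantiles (default 0.01..0.99 step 0.01).
#' @return A list with \code{thresholds} (named numeric), \code{quantile}
#'   (chosen q), \code{warnings}, and \code{singletFraction} per grid value.
#' @export
fitBarcodeThresholds <- function(barcodes,
                                 quantileGrid = seq(0.01, 0.99, by = 0.01)) {
    if (length(quantileGrid) == 0) stop("quantileGrid must be non-empty")
    if (ncol(barcodes) < 2) stop("need at least 2 barcodes")
    norm <- .normalizeBarcodes(barcodes)
    nb <- ncol(norm)
    modes <- vector("list", nb)
    warnings <- character()
    for (j in seq_len(nb)) {
        m <- .barcodeModes(norm[, j])
        if (is.null(m)) {
            warnings <- c(warnings, paste0(
                "barcode ", colnames(norm)[j],
                ": unimodal count distribution; deemed absent"))
        }
        modes[j] <- list(m)
    }
    thrAt <- function(q) vapply(seq_len(nb), function(j) {
        m <- modes[[j]]
        if (is.null(m)) max(norm[, j]) + 1 else m$lo + q * (m$hi - m$lo)
    }, numeric(1))
    singFrac <- vapply(quantileGrid, function(q) {
        npos <- rowSums(norm > rep(thrAt(q), each = nrow(norm)))
        mean(npos == 1)
    }, numeric(1))
    best <- quantileGrid[which.max(singFrac)]  # which.max: first = smallest q
    thresholds <- setNames(thrAt(best), colnames(norm))
    list(thresholds = thresholds, quantile = best, warnings = warnings,
         singletFraction = setNames(singFrac, quantileGrid))
}

#' Classify cells from barcode thresholds
#'
#' A cell positive for exactly one barcode is a singlet carrying that
#' barcode's sample label; positive for more than one, a doublet; positive
#' for none, a negative. Only singlets are retained for downstream analysis.
#'
#' @param barcodes cell x barcode count matrix.
#' @param fit result of \code{\link{fitBarcodeThresholds}} (or a named
#'   threshold vector covering all barcodes).
#' @return A \code{\linkS4class{DemuxResult}}.
#' @export
classifyCells <- function(barcodes, fit) {
    thresholds <- if (is.list(fit)) fit$thresholds else fit
    q <- if (is.list(fit)) as.numeric(fit$quantile) else NA_real_
    warns <- if (is.list(fit)) fit$warnings else character()
    if (!all(colnames(barcodes) %in% names(thresholds)))
        stop("thresholds do not cover all barcodes")
    thresholds <- thresholds[colnames(barcodes)]
    norm <- .normalizeBarcodes(barcodes)
    posMat <- norm > rep(thresholds, each = nrow(norm))
    npos <- rowSums(posMat)
    status <- factor(ifelse(npos == 0, "negative",
                     ifelse(npos == 1, "singlet", "doublet")),
                     levels = c("singlet", "doublet", "negative"))
    label <- rep(NA_character_, nrow(norm))
    sing <- npos == 1
    label[sing] <- colnames(norm)[max.col(posMat[sing, , drop = FALSE])]
    names(label) <- rownames(barcodes)
    new("DemuxResult", status = status, label = label,
        thresholds = thresholds, quantile = q, warnings = warns)
}

#' One-shot demultiplexing
#'
#' Convenience wrapper: fit thresholds, then classify.
#'
#' @inheritParams fitBarcodeThresholds
#' @return A \code{\linkS4class{DemuxResult}}.
#' @export
demultiplex <- function(barcodes,
                        quantileGrid = seq(0.01, 0.99, by = 0.01)) {
    classifyCells(barcodes, fitBarcodeThresholds(barcodes, quantileGrid))
}
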