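# Supervised pseudotime: penalized cumulative-logit (ordinal logistic)
# regression on ordered time-point labels. The ordinal likelihood is fit in
# its binary-expansion form: each cell contributes K-1 binary outcomes
# I(y <= k) sharing one gene coefficient vector w, with threshold-specific
# unpenalized intercepts (the cutpoints). Elastic-net penalty on w keeps the
# model sparse; lambda is chosen by cross-validated ordinal classification
# accuracy with the one-standard-error rule.

.expandOrdinal <- function(Z, yInt, K) {
    n <- nrow(Z)
    Xg <- do.call(rbind, rep(list(Z), K - 1))
    D <- Matrix::sparseMatrix(
        i = seq_len(n * (K - 1)),
        j = rep(seq_len(K - 1), each = n),
        x = 1, dims = c(n * (K - 1), K - 1))
    resp <- as.numeric(rep(yInt, times = K - 1) <=
                       rep(seq_len(K - 1), each = n))
    list(X = cbind(Xg, as.matrix(D)), y = resp)
}

.ordinalPredict <- function(Z, w, theta) {
    s <- as.numeric(Z %*% w)
    K <- length(theta) + 1
    Fk <- vapply(theta, function(th) plogis(th - s),
                 numeric(length(s)))            # n x (K-1)
    Fk <- cbind(Fk, 1)
    P <- Fk - cbind(0, Fk[, -K, drop = FALSE])
    list(score = s, class = max.col(P, ties.method = "first"))
}

.coefAt <- function(fit, lambda, nGenes, K) {
    b <- as.matrix(coef(fit, s = lambda))[-1, , drop = TRUE]  # drop intercept
    w <- -b[seq_len(nGenes)]
    theta <- b[nGenes + seq_len(K - 1)]
    if (is.unsorted(theta)) theta <- sort(theta)  # enforce cutpoint order
    list(w = w, theta = theta)
}

#' Fit a supervised ordinal-regression pseudotime model
#'
#' Trains a cumulative-logit model P(y <= k | x) = logistic(theta_k - w.x)
#' on cells with ordered time-point labels, with an elastic-net penalty on
#' the gene coefficients w. Features are standardized internally. The
#' penalty is selected by stratified cross-validated ordinal classification
#' accuracy with the one-standard-error rule (ties toward the stronger
#' penalty). Withdrawal cells must be excluded by the caller and projected
#' afterwards with \code{\link{projectPseudotime}}.
#'
#' @param x gene x cell expression matrix over the training features
#'   (typically the condition's top variable genes, log-normalized).
#' @param labels per-cell ordered factor (or coercible) of time points.
#' @param alpha elastic-net mixing (1 = lasso, 0 = ridge).
#' @param nlambda length of the automatically generated penalty path.
#' @param lambda optional explicit penalty path (decreasing); overrides
#'   \code{nlambda}.
#' @param nfolds cross-validation folds, stratified by label.
#' @param seed seed for the fold assignment.
#' @return A \code{\linkS4class{PseudotimeModel}}.
#' @export
fitPseudotime <- function(x, labels, alpha = 0.5, nlambda = 50,
                          lambda = NULL, nfolds = 5, seed = 1) {
    m <- as.matrix(.getCounts(x))
    if (!is.ordered(labels)) labels <- factor(labels, ordered = TRUE)
    labels <- droplevels(labels)
    K <- nlevels(labels)
    if (K < 2) stop("need at least two ordered labels")
    if (any(table(labels) < 2)) stop("every label needs at least 2 cells")
    if (ncol(m) != length(labels))
        stop("labels must match the number of cells")
    yInt <- as.integer(labels)
    genes <- rownames(m)
    nGenes <- length(genes)

    ctr <- rowMeans(m)
    scl <- apply(m, 1, sd)
    scl[scl == 0] <- 1
    Z <- t((m - ctr) / scl)                      # cells x genes

    full <- .expandOrdinal(Z, yInt, K)
    pf <- c(rep(1, nGenes), rep(0, K - 1))
    fit <- if (is.null(lambda))
        glmnet::glmnet(full$X, full$y, family = "binomial", alpha = alpha,
                       nlambda = nlambda, penalty.factor = pf,
                       standardize = FALSE, intercept = FALSE)
    else
        glmnet::glmnet(full$X, full$y, family = "binomial", alpha = alpha,
                       lambda = lambda, penalty.factor = pf,
                       standardize = FALSE, intercept = FALSE)
    lam <- fit$lambda

    set.seed(seed)
    foldOf <- integer(length(yInt))
    for (k in seq_len(K)) {
        idx <- which(yInt == k)
        foldOf[idx] <- sample(rep(seq_len(nfolds), length.out = length(idx)))
    }
    accMat <- matrix(NA_real_, nfolds, length(lam))
    for (f in seq_len(nfolds)) {
        tr <- foldOf != f
        ex <- .expandOrdinal(Z[tr, , drop = FALSE], yInt[tr], K)
        ff <- glmnet::glmnet(ex$X, ex$y, family = "binomial", alpha = alpha,
                             lambda = lam, penalty.factor = pf,
                             standardize = FALSE, intercept = FALSE)
        for (l in seq_along(lam)) {
            if (l > length(ff$lambda)) break
            cf <- .coefAt(ff, ff$lambda[l], nGenes, K)
            pred <- .ordinalPredict(Z[!tr, , drop = FALSE], cf$w, cf$theta)
            accMat[f, l] <- mean(pred$class == yInt[!tr])
        }
    }
    accMean <- colMeans(accMat)
    accSE <- apply(accMat, 2, sd) / sqrt(nfolds)
    best <- which.max(accMean)
    # one-standard-error rule: strongest penalty within 1 SE of the best
    ok <- which(accMean >= accMean[best] - accSE[best])
    chosen <- min(ok)                            # lambda path is decreasing
    cf <- .coefAt(fit, lam[chosen], nGenes, K)
    scores <- as.numeric(Z %*% cf$w)
    rng <- range(scores)
    if (rng[1] >= rng[2]) rng <- c(rng[1] - 0.5, rng[1] + 0.5)
    new("PseudotimeModel",
        genes = genes, coefficients = unname(cf$w),
        cutpoints = unname(cf$theta), lambda = lam[chosen], alpha = alpha,
        center = unname(ctr), scale = unname(scl), scoreRange = rng,
        labels = levels(labels), cvAccuracy = accMean[chosen])
}

#' Project cells onto a trained pseudotime model
#'
#' The raw pseudotime of a cell is the linear predictor w.x after applying
#' the model's stored standardization; a matrix multiplication, so any cells
#' (withdrawal samples, inhibitor-treated screens) can be scored. Genes of
#' the model absent from the new matrix contribute zero after
#' standardization (mean imputation in raw space); more than 20% absent is
#' an error.
#'
#' @param model a \code{\linkS4class{PseudotimeModel}}.
#' @param x gene x cell expression matrix in the representation used for
#'   training.
#' @return \code{\link[S4Vectors]{DataFrame}} with columns \code{raw} and
#'   \code{rescaled} (training-range rescaling clipped to [0,1]).
#' @export
projectPseudotime <- function(model, x) {
    m <- as.matrix(.getCounts(x))
    present <- model@genes %in% rownames(m)
    if (mean(!present) > 0.2)
        stop(sprintf("%.0f%% of model genes absent from the new matrix",
                     100 * mean(!present)))
    if (any(!present))
        warning(sum(!present), " model genes absent; contributing zero")
    Z <- matrix(0, ncol(m), length(model@genes))
    idx <- which(present)
    Z[, idx] <- t((m[model@genes[idx], , drop = FALSE] -
                   model@center[idx]) / model@scale[idx])
    raw <- as.numeric(Z %*% model@coefficients)
    S4Vectors::DataFrame(
        raw = raw,
        rescaled = rescale01(raw, model@scoreRange),
        row.names = colnames(m))
}

#' Rescale values to the unit interval
#'
#' \code{(v - min) / (max - min)}. With a stored range (for example a
#' model's training score range) values are clipped to [0,1], so projected
#' cells below the training minimum map to 0.
#'
#' @param values numeric vector.
#' @param range optional c(min, max); defaults to the range of
#'   \code{values}.
#' @return numeric vector in [0,1].
#' @export
rescale01 <- function(values, range = NULL) {
    clip <- !is.null(range)
    if (is.null(range)) range <- base::range(values)
    if (range[1] >= range[2])
        stop("constant values and no stored range: cannot rescale")
    v <- (values - range[1]) / (range[2] - range[1])
    if (clip) v <- pmin(pmax(v, 0), 1)
    v
}

#' Serialize / restore a pseudotime model
#'
#' JSON round-trip preserving scores bit-identically (numbers are written at
#' full precision).
#'
#' @param model a \code{PseudotimeModel}.
#' @param path file path.
#' @return \code{writePseudotimeModel} returns \code{path} invisibly;
#'   \code{readPseudotimeModel} returns the restored model.
#' @export
writePseudotimeModel <- function(model, path) {
    obj <- list(genes = model@genes, coefficients = model@coefficients,
                cutpoints = model@cutpoints, lambda = model@lambda,
                alpha = model@alpha, center = model@center,
                scale = model@scale, scoreRange = model@scoreRange,
                labels = model@labels, cvAccuracy = model@cvAccuracy)
    writeLines(jsonlite::serializeJSON(obj, digits = 17), path)
    invisible(path)
}

#' @rdname writePseudotimeModel
#' @export
readPseudotimeModel <- function(path) {
    obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
    new("PseudotimeModel",
        genes = obj$genes, coefficients = obj$coefficients,
        cutpoints = obj$cutpoints, lambda = obj$lambda, alpha = obj$alpha,
        center = obj$center, scale = obj$scale, scoreRange = obj$scoreRange,
        labels = obj$labels, cvAccuracy = obj$cvAccuracy)
}
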