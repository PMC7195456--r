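# Gene dynamics along pseudotime: penalized-spline significance testing
# (exp ~ s(pseudotime, k = 4) + batch, REML), directional no-smoother
# coefficients, and fitted trend grids.

#' Fit a smooth pseudotime trend for one gene
#'
#' Gaussian generalized additive model \code{expr ~ s(t, k) + batch} with a
#' penalized cubic regression spline; the smoothing parameter maximizes the
#' REML criterion. The returned p-value is the approximate test of the
#' smooth term (effective-degrees-of-freedom based); its null calibration is
#' checked by simulation in the test suite.
#'
#' @param expr per-cell expression (or score) values.
#' @param t per-cell pseudotime.
#' @param batch optional per-cell batch factor.
#' @param k basis dimension of the smooth (>= 3).
#' @return list with \code{p_value}, \code{fitted}, \code{edf}, and the
#'   underlying \code{gam} fit plus the data used (for trend grids).
#' @export
fitGeneSmooth <- function(expr, t, batch = NULL, k = 4) {
    if (k < 3) stop("k must be >= 3")
    if (length(unique(t)) < 2) stop("constant pseudotime")
    df <- data.frame(expr = expr, t = t)
    useBatch <- !is.null(batch) && length(unique(batch)) > 1
    if (useBatch) df$batch <- factor(batch)
    nb <- if (useBatch) nlevels(df$batch) else 1
    if (nrow(df) <= k + nb)
        stop("too few observations for the requested basis dimension")
    # an (effectively) constant response carries no trend; the REML
    # machinery cannot profile it, so short-circuit to the null answer
    if (var(expr) < 1e-12 * (1 + mean(expr)^2))
        return(list(p_value = 1, fitted = rep(mean(expr), nrow(df)),
                    edf = 0, gam = NULL, data = df, useBatch = useBatch,
                    constant = mean(expr)))
    form <- if (useBatch) expr ~ s(t, k = k, bs = "cr") + batch
            else expr ~ s(t, k = k, bs = "cr")
    fit <- mgcv::gam(form, data = df, method = "REML")
    st <- summary(fit)$s.table
    list(p_value = unname(st[1, "p-value"]), fitted = unname(fitted(fit)),
         edf = unname(st[1, "edf"]), gam = fit, data = df,
         useBatch = useBatch, constant = NULL)
}

#' Evaluate a fitted trend on an even pseudotime grid
#'
#' The grid spans [min(t), max(t)] inclusive. Batch is held at its most
#' frequent level.
#'
#' @param fit result of \code{\link{fitGeneSmooth}}.
#' @param nPoints grid size (default 200).
#' @return list with \code{grid}, \code{fit} (trend values) and \code{se}.
#' @export
smoothTrendGrid <- function(fit, nPoints = 200) {
    if (nPoints < 2) stop("nPoints must be >= 2")
    t <- fit$data$t
    grid <- seq(min(t), max(t), length.out = nPoints)
    if (!is.null(fit$constant))
        return(list(grid = grid, fit = rep(fit$constant, nPoints),
                    se = rep(0, nPoints)))
    nd <- data.frame(t = grid)
    if (fit$useBatch) {
        tab <- table(fit$data$batch)
        nd$batch <- factor(names(tab)[which.max(tab)],
                           levels = levels(fit$data$batch))
    }
    pr <- predict(fit$gam, newdata = nd, se.fit = TRUE)
    list(grid = grid, fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit))
}

# Vectorized OLS of every gene on a shared design; returns the coefficient
# and p-value of the column named `term`.
.lmAllGenes <- function(m, df, term) {
    X <- stats::model.matrix(~ ., data = df)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("collinear covariates in the linear model")
    Yt <- t(m)
    B <- qr.coef(qrX, Yt)
    R <- qr.resid(qrX, Yt)
    n <- nrow(X); p <- ncol(X)
    sigma2 <- colSums(R^2) / (n - p)
    XtXinv <- chol2inv(qr.R(qrX))
    j <- which(colnames(X) == term)
    seB <- sqrt(sigma2 * XtXinv[j, j])
    beta <- B[j, ]
    tval <- beta / seB
    pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
    list(beta = beta, p = pval)
}

#' Directional (no-smoother) pseudotime coefficient
#'
#' Ordinary linear model \code{values ~ t + batch}; returns the pseudotime
#' coefficient (beta) and its p-value. Used where only the direction of
#' change matters, e.g. regulon activity or cytokine scores.
#'
#' @param values per-cell values (vector) or gene x cell matrix.
#' @param t per-cell pseudotime.
#' @param batch optional per-cell batch factor.
#' @return For a vector, list(beta, p); for a matrix, a data.frame with one
#'   row per gene.
#' @export
linearDirection <- function(values, t, batch = NULL) {
    vec <- is.null(dim(values))
    m <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
    df <- data.frame(t = t)
    if (!is.null(batch) && length(unique(batch)) > 1)
        df$batch <- factor(batch)
    res <- .lmAllGenes(m, df, "t")
    if (vec) list(beta = unname(res$beta), p = unname(res$p))
    else data.frame(gene = rownames(m), beta = unname(res$beta),
                    p = unname(res$p), row.names = rownames(m))
}

#' Differential expression along pseudotime
#'
#' Fits \code{\link{fitGeneSmooth}} to every gene of the matrix, adjusts the
#' smooth-term p-values across all tested genes with Benjamini-Hochberg, and
#' flags as significant the genes with adjusted p below \code{alpha} that
#' are also inside the variable-gene \code{universe} (the effect-size guard:
#' genes outside the top variable set are never flagged). Directional betas
#' come from the matching no-smoother linear model, and each gene's fitted
#' trend is evaluated on an even grid.
#'
#' @param x gene x cell expression matrix (log-normalized values or scores).
#' @param t per-cell pseudotime.
#' @param batch optional per-cell batch factor.
#' @param universe character vector of genes eligible for the significance
#'   flag (typically the condition's top 2000 variable genes).
#' @param k smooth basis dimension.
#' @param alpha BH-adjusted significance level.
#' @param nGrid trend grid size.
#' @return A \code{\linkS4class{GeneDynamics}}.
#' @export
deOverPseudotime <- function(x, t, batch = NULL, universe = NULL,
                             k = 4, alpha = 0.05, nGrid = 200) {
    m <- as.matrix(.getCounts(x))
    if (is.null(universe)) universe <- rownames(m)
    if (length(universe) == 0) stop("empty variable-gene universe")
    genes <- rownames(m)
    n <- length(genes)
    p <- numeric(n)
    trend <- matrix(NA_real_, n, nGrid, dimnames = list(genes, NULL))
    trendSE <- trend
    grid <- seq(min(t), max(t), length.out = nGrid)
    for (i in seq_len(n)) {
        fit <- fitGeneSmooth(m[i, ], t, batch, k = k)
        p[i] <- fit$p_value
        gr <- smoothTrendGrid(fit, nGrid)
        trend[i, ] <- gr$fit
        trendSE[i, ] <- gr$se
    }
    lin <- linearDirection(m, t, batch)
    adj <- p.adjust(p, method = "BH")
    tab <- S4Vectors::DataFrame(
        gene = genes, p_value = p, adj_p = adj, beta = lin$beta,
        significant = adj < alpha & genes %in% universe,
        row.names = genes)
    new("GeneDynamics", table = tab, trend = trend, trendSE = trendSE,
        grid = grid)
}

#' Inhibitor-only differential expression
#'
#' Linear model \code{expr ~ inhibitor} with the no-inhibitor controls as
#' the intercept; per-gene F-test of the inhibitor term, BH-adjusted. Used
#' to count expression changes caused by an inhibitor without EMT induction.
#'
#' @param x gene x cell expression matrix.
#' @param inhibitor per-cell factor; its reference level is the control.
#' @param alpha BH significance level.
#' @return data.frame with gene, p_value, adj_p, significant.
#' @export
deInhibitor <- function(x, inhibitor, alpha = 0.05) {
    m <- as.matrix(.getCounts(x))
    f <- factor(inhibitor)
    if (nlevels(f) < 2) stop("inhibitor must have at least two levels")
    X <- stats::model.matrix(~ f)
    qrX <- qr(X)
    Yt <- t(m)
    R1 <- qr.resid(qrX, Yt)
    rss1 <- colSums(R1^2)
    rss0 <- colSums(scale(Yt, scale = FALSE)^2)
    n <- nrow(X); pfull <- ncol(X)
    Fstat <- ((rss0 - rss1) / (pfull - 1)) / (rss1 / (n - pfull))
    p <- stats::pf(Fstat, pfull - 1, n - pfull, lower.tail = FALSE)
    adj <- p.adjust(p, method = "BH")
    data.frame(gene = rownames(m), p_value = unname(p), adj_p = unname(adj),
               significant = unname(adj < alpha), row.names = rownames(m))
}
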