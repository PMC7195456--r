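#' @import methods
#' @importFrom stats density quantile rnbinom rlnorm rpois rnorm runif rbinom
#'   setNames lm coef predict p.adjust phyper wilcox.test ks.test prcomp
#'   var sd loess plogis na.omit resid fitted model.matrix pf pt median
#' @importClassesFrom S4Vectors DFrame
#' @importFrom S4Vectors DataFrame
#' @importFrom Matrix t rowSums colSums rowMeans colMeans
NULL

#' Configuration of a synthetic multiplexed EMT time-course panel
#'
#' Parameters of the synthetic-data generator that emulates a panel of EMT
#' time-course experiments (several cell line x inducer conditions, each with
#' ordered treatment time points and post-withdrawal time points), profiled
#' by sample-multiplexed scRNA-seq.
#'
#' @slot nConditions number of conditions (cell line x inducer combinations).
#' @slot nTreatTimepoints ordered treatment time points per condition.
#' @slot nWithdrawTimepoints withdrawal time points appended after treatment.
#' @slot cellsPerSample cells simulated per (condition, time point) sample.
#' @slot nGenes genes in the panel.
#' @slot nResponseGenes programmed response genes per condition.
#' @slot pairwiseOverlap target Jaccard index between any two conditions'
#'   response sets.
#' @slot fracConserved fraction of each condition's response genes that belong
#'   to the conserved core shared by all conditions.
#' @slot dynamicsShapes subset of \code{c("linear","sigmoid","transient")}
#'   used for response-gene trends along latent time.
#' @slot nbDispersion negative-binomial dispersion (1/size) of counts.
#' @slot batchEffectSD standard deviation of the per-gene additive log-mean
#'   batch shift (two batches, mirroring paired replicate mixes).
#' @slot doubletRate,negativeRate fractions of pooled cells that are doublets
#'   or barcode-negative.
#' @slot withdrawHalfLife latent-time decay half-life (days) after stimulus
#'   withdrawal.
#' @slot seed integer seed making the panel reproducible.
#' @export
setClass("PanelConfig", representation(
    nConditions = "integer",
    nTreatTimepoints = "integer",
    nWithdrawTimepoints = "integer",
    cellsPerSample = "integer",
    nGenes = "integer",
    nResponseGenes = "integer",
    pairwiseOverlap = "numeric",
    fracConserved = "numeric",
    dynamicsShapes = "character",
    nbDispersion = "numeric",
    batchEffectSD = "numeric",
    doubletRate = "numeric",
    negativeRate = "numeric",
    withdrawHalfLife = "numeric",
    seed = "integer"
))

setValidity("PanelConfig", function(object) {
    msg <- character()
    cnt <- c(nConditions = object@nConditions,
             nTreatTimepoints = object@nTreatTimepoints,
             cellsPerSample = object@cellsPerSample,
             nGenes = object@nGenes,
             nResponseGenes = object@nResponseGenes)
    if (any(cnt < 1L))
        msg <- c(msg, paste("counts must be positive:",
                            paste(names(cnt)[cnt < 1L], collapse = ", ")))
    if (object@nWithdrawTimepoints < 0L)
        msg <- c(msg, "nWithdrawTimepoints must be >= 0")
    frac <- c(pairwiseOverlap = object@pairwiseOverlap,
              fracConserved = object@fracConserved,
              doubletRate = object@doubletRate,
              negativeRate = object@negativeRate)
    if (any(frac < 0 | frac > 1))
        msg <- c(msg, paste("fractions must lie in [0,1]:",
                            paste(names(frac)[frac < 0 | frac > 1],
                                  collapse = ", ")))
    if (object@doubletRate + object@negativeRate >= 1)
        msg <- c(msg, "doubletRate + negativeRate must be < 1")
    if (object@nResponseGenes > object@nGenes)
        msg <- c(msg, "nResponseGenes exceeds nGenes")
    if (!all(object@dynamicsShapes %in% c("linear", "sigmoid", "transient")))
        msg <- c(msg, "dynamicsShapes must be among linear/sigmoid/transient")
    if (length(object@dynamicsShapes) < 1L)
        msg <- c(msg, "at least one dynamics shape required")
    if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
    if (object@batchEffectSD < 0) msg <- c(msg, "batchEffectSD must be >= 0")
    if (object@withdrawHalfLife <= 0)
        msg <- c(msg, "withdrawHalfLife must be > 0")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic panel
#'
#' Everything the generator knows about the data it emitted: the latent
#' EMT progression coordinate of each cell, the signed per-condition response
#' programs, the conserved core, embedded regulons, doublet labels of the
#' pooled barcode experiment, and programmed inhibitor effects of a screen.
#'
#' @slot latentTime named per-cell latent progression in [0,1].
#' @slot responseSets per-condition list with elements \code{up}, \code{down}
#'   (character gene vectors).
#' @slot conservedUp,conservedDown genes responding with consistent sign in at
#'   least two-thirds of conditions.
#' @slot regulons named list (TF -> target genes) of co-activated modules.
#' @slot doubletLabels named logical per pooled cell; empty until pooling.
#' @slot poolStatus named character per pooled cell: singlet / doublet /
#'   negative; empty until pooling.
#' @slot sampleOfCell named character, the sample each pooled singlet came
#'   from (doublets carry both, comma-separated).
#' @slot inhibitorEffects named list per inhibitor: \code{list(type, module)}
#'   with type in none/full_block/partial_block; empty until a screen is
#'   generated.
#' @export
setClass("SyntheticTruth", representation(
    latentTime = "numeric",
    responseSets = "list",
    conservedUp = "character",
    conservedDown = "character",
    regulons = "list",
    doubletLabels = "logical",
    poolStatus = "character",
    sampleOfCell = "character",
    inhibitorEffects = "list"
))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (any(object@latentTime < -1e-9 | object@latentTime > 1 + 1e-9))
        msg <- c(msg, "latentTime must lie in [0,1]")
    if (length(intersect(object@conservedUp, object@conservedDown)))
        msg <- c(msg, "conservedUp and conservedDown overlap")
    if (length(msg)) msg else TRUE
})

#' Result of barcode demultiplexing
#'
#' @slot status factor per cell: singlet / doublet / negative.
#' @slot label character per cell; the winning sample barcode for singlets,
#'   NA otherwise.
#' @slot thresholds named per-barcode positivity threshold on the normalized
#'   log scale.
#' @slot quantile the globally chosen quantile q.
#' @slot warnings character vector of per-barcode diagnostics (e.g. unimodal
#'   count distributions).
#' @export
setClass("DemuxResult", representation(
    status = "factor",
    label = "character",
    thresholds = "numeric",
    quantile = "numeric",
    warnings = "character"
))

setValidity("DemuxResult", function(object) {
    msg <- character()
    if (length(object@status) != length(object@label))
        msg <- c(msg, "status and label lengths differ")
    if (!all(levels(object@status) %in% c("singlet", "doublet", "negative")))
        msg <- c(msg, "status levels must be singlet/doublet/negative")
    sing <- object@status == "singlet"
    if (any(is.na(object@label[sing])))
        msg <- c(msg, "singlets must carry a label")
    if (length(msg)) msg else TRUE
})

#' Supervised ordinal-regression pseudotime model
#'
#' A cumulative-logit (ordinal logistic) model trained on ordered time-point
#' labels: the linear predictor w.x orders cells along the transition and the
#' cutpoints separate the K ordered labels. The elastic-net penalty keeps the
#' gene coefficient vector sparse. Stores the feature standardization and the
#' training score range so that projected cells can be rescaled to [0,1] on
#' the training scale.
#'
#' @slot genes training feature genes.
#' @slot coefficients per-gene weights w (same order as \code{genes}).
#' @slot cutpoints strictly increasing thresholds between the K labels.
#' @slot lambda selected penalty; \code{alpha} the elastic-net mixing.
#' @slot center,scale per-gene standardization applied before w.x.
#' @slot scoreRange min/max of training-cell raw scores, used by
#'   \code{\link{rescale01}}.
#' @slot labels the ordered label levels the model was trained on.
#' @slot cvAccuracy mean cross-validated ordinal accuracy at \code{lambda}.
#' @export
setClass("PseudotimeModel", representation(
    genes = "character",
    coefficients = "numeric",
    cutpoints = "numeric",
    lambda = "numeric",
    alpha = "numeric",
    center = "numeric",
    scale = "numeric",
    scoreRange = "numeric",
    labels = "character",
    cvAccuracy = "numeric"
))

setValidity("PseudotimeModel", function(object) {
    msg <- character()
    if (length(object@genes) != length(object@coefficients))
        msg <- c(msg, "genes and coefficients lengths differ")
    if (length(object@cutpoints) > 1 && any(diff(object@cutpoints) <= 0))
        msg <- c(msg, "cutpoints must be strictly increasing")
    if (length(object@scoreRange) != 2 ||
        object@scoreRange[1] >= object@scoreRange[2])
        msg <- c(msg, "scoreRange must be c(min, max) with min < max")
    if (length(object@center) != length(object@genes) ||
        length(object@scale) != length(object@genes))
        msg <- c(msg, "standardization parameters must match genes")
    if (length(msg)) msg else TRUE
})

#' Pseudotime-resolved gene dynamics
#'
#' Per-gene spline-fit summary along pseudotime: smooth-term p-value, BH
#' adjusted p, the directional (no-smoother) pseudotime coefficient beta, a
#' fitted trend evaluated on an even pseudotime grid, and the significance
#' flag (adjusted p < alpha AND membership in the variable-gene universe).
#'
#' @slot table DataFrame with columns gene, p_value, adj_p, beta, significant.
#' @slot trend gene x grid matrix of fitted values.
#' @slot trendSE matching matrix of standard errors.
#' @slot grid the pseudotime grid the trends are evaluated on.
#' @export
setClass("GeneDynamics", representation(
    table = "DFrame",
    trend = "matrix",
    trendSE = "matrix",
    grid = "numeric"
))

setValidity("GeneDynamics", function(object) {
    msg <- character()
    need <- c("gene", "p_value", "adj_p", "beta", "significant")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste("table must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (nrow(object@table) != nrow(object@trend))
            msg <- c(msg, "trend rows must match table rows")
        ok <- !is.na(object@table$adj_p)
        if (any(object@table$adj_p[ok] < object@table$p_value[ok] - 1e-12))
            msg <- c(msg, "adj_p must be >= p_value")
    }
    if (ncol(object@trend) != length(object@grid))
        msg <- c(msg, "trend columns must match grid length")
    if (length(msg)) msg else TRUE
})
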