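#' @rdname PanelConfig-class
#' @param nConditions,nTreatTimepoints,nWithdrawTimepoints,cellsPerSample
#'   panel geometry; see the class slots.
#' @param nGenes,nResponseGenes,pairwiseOverlap,fracConserved response-program
#'   geometry.
#' @param dynamicsShapes,nbDispersion,batchEffectSD,doubletRate,negativeRate,withdrawHalfLife,seed
#'   observation-model and multiplexing parameters.
#' @return A validated \code{PanelConfig}.
#' @examples
#' cfg <- panelConfig(nConditions = 2, cellsPerSample = 30, nGenes = 300,
#'                    nResponseGenes = 30, seed = 1)
#' @export
panelConfig <- function(nConditions = 12, nTreatTimepoints = 5,
                        nWithdrawTimepoints = 3, cellsPerSample = 200,
                        nGenes = 2000, nResponseGenes = 150,
                        pairwiseOverlap = 0.2, fracConserved = 0.2,
                        dynamicsShapes = c("linear", "sigmoid", "transient"),
                        nbDispersion = 0.1, batchEffectSD = 0.1,
                        doubletRate = 0.05, negativeRate = 0.02,
                        withdrawHalfLife = 1, seed = 1) {
    new("PanelConfig",
        nConditions = as.integer(nConditions),
        nTreatTimepoints = as.integer(nTreatTimepoints),
        nWithdrawTimepoints = as.integer(nWithdrawTimepoints),
        cellsPerSample = as.integer(cellsPerSample),
        nGenes = as.integer(nGenes),
        nResponseGenes = as.integer(nResponseGenes),
        pairwiseOverlap = as.numeric(pairwiseOverlap),
        fracConserved = as.numeric(fracConserved),
        dynamicsShapes = as.character(dynamicsShapes),
        nbDispersion = as.numeric(nbDispersion),
        batchEffectSD = as.numeric(batchEffectSD),
        doubletRate = as.numeric(doubletRate),
        negativeRate = as.numeric(negativeRate),
        withdrawHalfLife = as.numeric(withdrawHalfLife),
        seed = as.integer(seed))
}

#' Accessors
#'
#' Small accessor family for the package's S4 result objects.
#'
#' @param x an S4 object of this package.
#' @return The named component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dynTable", function(x) standardGeneric("dynTable"))
#' @rdname accessors
#' @export
setMethod("dynTable", "GeneDynamics", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("trendMatrix", function(x) standardGeneric("trendMatrix"))
#' @rdname accessors
#' @export
setMethod("trendMatrix", "GeneDynamics", function(x) x@trend)

#' @rdname accessors
#' @export
setGeneric("trendGrid", function(x) standardGeneric("trendGrid"))
#' @rdname accessors
#' @export
setMethod("trendGrid", "GeneDynamics", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("significantGenes", function(x) standardGeneric("significantGenes"))
#' @rdname accessors
#' @export
setMethod("significantGenes", "GeneDynamics", function(x) {
    as.character(x@table$gene[x@table$significant])
})

#' @rdname accessors
#' @export
setGeneric("demuxStatus", function(x) standardGeneric("demuxStatus"))
#' @rdname accessors
#' @export
setMethod("demuxStatus", "DemuxResult", function(x) {
    setNames(as.character(x@status), names(x@label))
})

#' @rdname accessors
#' @export
setGeneric("demuxLabel", function(x) standardGeneric("demuxLabel"))
#' @rdname accessors
#' @export
setMethod("demuxLabel", "DemuxResult", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("demuxThresholds", function(x) standardGeneric("demuxThresholds"))
#' @rdname accessors
#' @export
setMethod("demuxThresholds", "DemuxResult", function(x) x@thresholds)

#' @rdname accessors
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))
#' @rdname accessors
#' @export
setMethod("modelGenes", "PseudotimeModel", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))
#' @rdname accessors
#' @export
setMethod("modelCoefficients", "PseudotimeModel", function(x) {
    setNames(x@coefficients, x@genes)
})

#' @rdname accessors
#' @export
setGeneric("modelCutpoints", function(x) standardGeneric("modelCutpoints"))
#' @rdname accessors
#' @export
setMethod("modelCutpoints", "PseudotimeModel", function(x) x@cutpoints)

#' @rdname accessors
#' @export
setGeneric("scoreRange", function(x) standardGeneric("scoreRange"))
#' @rdname accessors
#' @export
setMethod("scoreRange", "PseudotimeModel", function(x) x@scoreRange)

setMethod("show", "PanelConfig", function(object) {
    cat("PanelConfig:", object@nConditions, "conditions x",
        object@nTreatTimepoints, "+", object@nWithdrawTimepoints,
        "time points,", object@cellsPerSample, "cells/sample\n")
    cat("  genes:", object@nGenes, "(", object@nResponseGenes,
        "response/condition, target Jaccard", object@pairwiseOverlap, ")\n")
    cat("  doublets:", object@doubletRate, " negatives:",
        object@negativeRate, " seed:", object@seed, "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@latentTime), "cells,",
        length(object@responseSets), "conditions\n")
    cat("  conserved: ", length(object@conservedUp), " up / ",
        length(object@conservedDown), " down; ",
        length(object@regulons), " regulons\n", sep = "")
    if (length(object@doubletLabels))
        cat("  pooled:", sum(object@doubletLabels), "doublets of",
            length(object@doubletLabels), "cells\n")
    if (length(object@inhibitorEffects))
        cat("  inhibitors:",
            paste(names(object@inhibitorEffects), collapse = ", "), "\n")
})

setMethod("show", "DemuxResult", function(object) {
    tab <- table(object@status)
    cat("DemuxResult:", length(object@status), "cells (q =",
        format(object@quantile, digits = 3), ")\n")
    cat(" ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
    if (length(object@warnings))
        cat("  warnings:", length(object@warnings), "\n")
})

setMethod("show", "PseudotimeModel", function(object) {
    nz <- sum(object@coefficients != 0)
    cat("PseudotimeModel:", length(object@labels), "ordered labels,",
        length(object@genes), "genes (", nz, "non-zero )\n")
    cat("  lambda:", format(object@lambda, digits = 4),
        " alpha:", object@alpha,
        " CV accuracy:", format(object@cvAccuracy, digits = 3), "\n")
    cat("  training score range: [",
        format(object@scoreRange[1], digits = 4), ",",
        format(object@scoreRange[2], digits = 4), "]\n")
})

setMethod("show", "GeneDynamics", function(object) {
    cat("GeneDynamics:", nrow(object@table), "genes,",
        sum(object@table$significant), "significant;",
        length(object@grid), "grid points\n")
})
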