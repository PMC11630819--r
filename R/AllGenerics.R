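#' @include AllClasses.R
NULL

#' Accessors for vomeroseq S4 objects
#'
#' Small accessor family: slot access is internal, these are the supported
#' interface.
#'
#' @param x a \linkS4class{PresenceMatrix}, \linkS4class{AssociationTable},
#'   \linkS4class{SimilarityMatrix} or \linkS4class{JaccardGrid}.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))
#' @rdname accessors
#' @export
setGeneric("retainedReceptors", function(x) standardGeneric("retainedReceptors"))
#' @rdname accessors
#' @export
setGeneric("countThreshold", function(x) standardGeneric("countThreshold"))
#' @rdname accessors
#' @export
setGeneric("minCells", function(x) standardGeneric("minCells"))
#' @rdname accessors
#' @export
setGeneric("meanExpression", function(x) standardGeneric("meanExpression"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("pAdjusted", function(x) standardGeneric("pAdjusted"))
#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @rdname accessors
#' @export
setGeneric("similarityKind", function(x) standardGeneric("similarityKind"))
#' @rdname accessors
#' @export
setGeneric("jaccardValues", function(x) standardGeneric("jaccardValues"))
#' @rdname accessors
#' @export
setGeneric("alphaHat", function(x) standardGeneric("alphaHat"))

#' @rdname accessors
#' @export
setMethod("presence", "PresenceMatrix", function(x) x@presence)
#' @rdname accessors
#' @export
setMethod("retainedReceptors", "PresenceMatrix", function(x) x@retainedReceptors)
#' @rdname accessors
#' @export
setMethod("countThreshold", "PresenceMatrix", function(x) x@countThreshold)
#' @rdname accessors
#' @export
setMethod("minCells", "PresenceMatrix", function(x) x@minCells)

#' @rdname accessors
#' @export
setMethod("meanExpression", "AssociationTable", function(x) x@meanExpr)
#' @rdname accessors
#' @export
setMethod("pValues", "AssociationTable", function(x) x@pValue)
#' @rdname accessors
#' @export
setMethod("pAdjusted", "AssociationTable", function(x) x@pAdjusted)

#' @rdname accessors
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("similarityKind", "SimilarityMatrix", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("jaccardValues", "JaccardGrid", function(x) x@jaccard)

#' @rdname accessors
#' @export
setMethod("alphaHat", "PowerLawFit", function(x) x@alphaHat)

setMethod("show", "PresenceMatrix", function(object) {
    cat("PresenceMatrix:", nrow(object@presence), "receptors x",
        ncol(object@presence), "cells\n")
    cat("  count threshold >=", object@countThreshold,
        "| min cells >=", object@minCells, "\n")
    cat("  retained receptors:", length(object@retainedReceptors), "\n")
})

setMethod("show", "PowerLawFit", function(object) {
    cat(sprintf(
        "PowerLawFit: alpha = %.4f (R^2 = %.4f) over ranks %d..%d (%d receptors, floor >= %d cells)\n",
        object@alphaHat, object@rSquared, object@fitRange[1],
        object@fitRange[2], object@nFitted, object@minCellsFloor))
})

setMethod("show", "AssociationTable", function(object) {
    cat("AssociationTable (", object@panel, " panel): ",
        nrow(object@meanExpr), " receptors x ", ncol(object@meanExpr),
        " genes\n", sep = "")
    cat("  thresholds: receptor >=", object@receptorThreshold,
        ", panel gene >=", object@panelThreshold, "\n")
    if (length(object@flaggedReceptors))
        cat("  untested receptors (no presence cells):",
            length(object@flaggedReceptors), "\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
    cat("SimilarityMatrix (", object@kind, "): ", nrow(object@values),
        " x ", ncol(object@values), "\n", sep = "")
    if (length(object@flagged))
        cat("  excluded:", length(object@flagged), "\n")
})

setMethod("show", "JaccardGrid", function(object) {
    cat("JaccardGrid for", object@receptor, "(", object@nCells,
        "presence cells ):", length(object@tfIds), "TF x",
        length(object@agIds), "AG\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth (seed", object@seed, ")\n")
    cat("  receptors:", paste(names(object@nReceptorsPerClass),
        object@nReceptorsPerClass, sep = "=", collapse = ", "), "\n")
    cat("  alpha =", object@alpha, "| planted pairs:",
        nrow(object@plantedPairs), "| coded receptors:",
        length(object@codeMap), "\n")
    cat("  ambient =", object@ambientRate, "| capture =",
        object@captureRate, "\n")
})
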