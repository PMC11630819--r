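#' @import methods
#' @importClassesFrom Matrix lgCMatrix
NULL

#' PresenceMatrix: thresholded receptor presence calls
#'
#' Boolean receptor x cell matrix obtained by thresholding raw counts.
#' A receptor is "present" in a cell when its raw count is at least
#' \code{countThreshold} (default 10); receptors present in fewer than
#' \code{minCells} cells (default 5) are excluded from
#' \code{retainedReceptors} and hence from all pairwise tests.
#'
#' @slot presence logical sparse matrix, rows = receptors, columns = cells.
#' @slot countThreshold integer, minimal raw count for a presence call.
#' @slot minCells integer, minimal number of presence cells for retention.
#' @slot retainedReceptors character, receptors passing the cell filter.
#'
#' @seealso [binarizePresence()], [pairwiseFisher()]
#' @exportClass PresenceMatrix
setClass("PresenceMatrix",
    slots = c(
        presence = "lgCMatrix",
        countThreshold = "integer",
        minCells = "integer",
        retainedReceptors = "character"
    )
)

setValidity("PresenceMatrix", function(object) {
    msg <- NULL
    if (length(object@countThreshold) != 1L || object@countThreshold < 1L)
        msg <- c(msg, "countThreshold must be a single integer >= 1")
    if (length(object@minCells) != 1L || object@minCells < 1L)
        msg <- c(msg, "minCells must be a single integer >= 1")
    if (is.null(rownames(object@presence)))
        msg <- c(msg, "presence matrix must have receptor rownames")
    if (!all(object@retainedReceptors %in% rownames(object@presence)))
        msg <- c(msg, "retainedReceptors must be a subset of presence rownames")
    if (is.null(msg)) TRUE else msg
})

#' PowerLawFit: least-squares power-law fit on the rank-probability curve
#'
#' @slot alphaHat numeric, fitted exponent (minus the log-log slope).
#' @slot intercept numeric, log-log intercept.
#' @slot rSquared numeric in [0, 1].
#' @slot fitRange integer length 2, first and last rank used.
#' @slot nFitted integer, number of receptors entering the fit.
#' @slot minCellsFloor integer, dropout-tail exclusion floor used.
#'
#' @seealso [fitPowerLaw()]
#' @exportClass PowerLawFit
setClass("PowerLawFit",
    slots = c(
        alphaHat = "numeric",
        intercept = "numeric",
        rSquared = "numeric",
        fitRange = "integer",
        nFitted = "integer",
        minCellsFloor = "integer"
    )
)

setValidity("PowerLawFit", function(object) {
    msg <- NULL
    if (object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8)
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (length(object@fitRange) != 2L || object@fitRange[1] < 1L)
        msg <- c(msg, "fitRange must be two ranks with rank_min >= 1")
    if (is.null(msg)) TRUE else msg
})

#' AssociationTable: receptor x panel-gene co-expression code
#'
#' For each receptor (rows, presence at >= \code{receptorThreshold} raw
#' counts) and each panel gene (columns, presence at >= \code{panelThreshold}
#' raw counts, default 3) the table stores the mean normalized expression of
#' the panel gene over the receptor's presence cells and a one-sided Fisher
#' enrichment p-value with BH adjustment across the whole table.
#'
#' @slot meanExpr numeric matrix (receptors x panel genes), mean log1p
#'   median-scaled expression over presence cells.
#' @slot pValue,pAdjusted numeric matrices of the same shape.
#' @slot panel character, \code{"TF"} or \code{"AG"}.
#' @slot receptorThreshold,panelThreshold integer presence thresholds.
#' @slot flaggedReceptors character, receptors with zero presence cells
#'   (rows kept but untested).
#'
#' @seealso [buildAssociation()], [profileCorrelation()], [tfAgJaccard()]
#' @exportClass AssociationTable
setClass("AssociationTable",
    slots = c(
        meanExpr = "matrix",
        pValue = "matrix",
        pAdjusted = "matrix",
        panel = "character",
        receptorThreshold = "integer",
        panelThreshold = "integer",
        flaggedReceptors = "character"
    )
)

setValidity("AssociationTable", function(object) {
    msg <- NULL
    d <- dim(object@meanExpr)
    if (!identical(d, dim(object@pValue)) || !identical(d, dim(object@pAdjusted)))
        msg <- c(msg, "meanExpr, pValue and pAdjusted must share dimensions")
    if (any(object@meanExpr < 0, na.rm = TRUE))
        msg <- c(msg, "meanExpr must be nonnegative")
    ok <- !is.na(object@pValue) & !is.na(object@pAdjusted)
    if (any(object@pAdjusted[ok] < object@pValue[ok] - 1e-12))
        msg <- c(msg, "pAdjusted must be >= pValue elementwise")
    if (!object@panel %in% c("TF", "AG"))
        msg <- c(msg, "panel must be 'TF' or 'AG'")
    if (is.null(msg)) TRUE else msg
})

#' SimilarityMatrix: square receptor-by-receptor similarity
#'
#' @slot values square symmetric numeric matrix over a receptor set.
#' @slot kind one of \code{"tf_profile"}, \code{"ag_profile"},
#'   \code{"sequence"}, \code{"combined"}; correlation kinds have diagonal 1
#'   and entries in [-1, 1], sequence identity is in percent with diagonal 100.
#' @slot flagged character, receptors excluded (e.g. zero-variance profiles).
#'
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
    slots = c(
        values = "matrix",
        kind = "character",
        flagged = "character"
    )
)

setValidity("SimilarityMatrix", function(object) {
    msg <- NULL
    v <- object@values
    if (nrow(v) != ncol(v))
        msg <- c(msg, "values must be square")
    if (max(abs(v - t(v)), na.rm = TRUE) > 1e-8)
        msg <- c(msg, "values must be symmetric")
    if (!object@kind %in% c("tf_profile", "ag_profile", "sequence", "combined"))
        msg <- c(msg, "unknown similarity kind")
    if (object@kind == "sequence") {
        if (any(v < -1e-8 | v > 100 + 1e-8, na.rm = TRUE))
            msg <- c(msg, "sequence identities must lie in [0, 100]")
    } else if (any(abs(v) > 1 + 1e-8, na.rm = TRUE)) {
        msg <- c(msg, "correlations must lie in [-1, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' JaccardGrid: TF x AG co-detection structure within one receptor's cells
#'
#' For the cells expressing one receptor (>= 10 raw counts), the Jaccard
#' index of the barcode sets in which each significantly associated TF and
#' AG gene is detected (>= 3 raw counts).
#'
#' @slot receptor character, the receptor id.
#' @slot jaccard numeric matrix TF x AG with entries in [0, 1].
#' @slot tfIds,agIds character, the significant panel genes (grid axes).
#' @slot nCells integer, number of presence cells of the receptor.
#'
#' @seealso [tfAgJaccard()]
#' @exportClass JaccardGrid
setClass("JaccardGrid",
    slots = c(
        receptor = "character",
        jaccard = "matrix",
        tfIds = "character",
        agIds = "character",
        nCells = "integer"
    )
)

setValidity("JaccardGrid", function(object) {
    msg <- NULL
    if (length(object@jaccard) &&
        any(object@jaccard < -1e-12 | object@jaccard > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "Jaccard entries must lie in [0, 1]")
    if (!identical(dim(object@jaccard),
                   c(length(object@tfIds), length(object@agIds))))
        msg <- c(msg, "jaccard dimensions must match tfIds x agIds")
    if (is.null(msg)) TRUE else msg
})

#' SyntheticTruth: planted generative parameters for synthetic VNO data
#'
#' Holds every parameter of the synthetic-data generator together with the
#' seed, so that generated annotations, count matrices and spatial layouts
#' are pure functions of this object, and recovery tests can compare
#' analysis output against the planted structure.
#'
#' @slot alpha power-law exponent of receptor choice probability vs rank.
#' @slot nReceptorsPerClass named integer, receptors generated per class.
#' @slot plantedPairs data.frame with columns receptor_a, receptor_b,
#'   co_prob, same_chromosome.
#' @slot codeMap named list (receptor id -> list(tf = named means,
#'   ag = named means)): the planted receptor-specific TF/AG program.
#' @slot nTF,nAG integer, total panel sizes (planted genes plus background).
#' @slot ambientRate mean stray counts per off-target receptor per cell
#'   (before capture thinning).
#' @slot captureRate per-transcript binomial capture probability in (0, 1].
#' @slot nbSize negative-binomial size (dispersion) of signal counts.
#' @slot primaryMean,partnerMean negative-binomial means of the primary and
#'   co-expressed partner receptor.
#' @slot panelBackgroundMean Poisson mean of unplanted TF/AG expression.
#' @slot panelPlantedMean default Poisson mean of planted TF/AG genes.
#' @slot immatureCoexMultiplier,juvenileCoexMultiplier multipliers on the
#'   planted co-expression probability for immature cells and P14 animals.
#' @slot composition named numeric cell-type proportions summing to 1.
#' @slot zoneEnrichment named numeric >= 1, marginal-zone density multiplier
#'   per cell type.
#' @slot nChromosomes integer, chromosomes in the generated annotation.
#' @slot pseudogeneFraction fraction of each receptor class flagged as
#'   pseudogenes (lowest-ranked receptors).
#' @slot seed integer RNG seed.
#'
#' @seealso [SyntheticTruth()], [generateAnnotation()], [simulateCounts()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    slots = c(
        alpha = "numeric",
        nReceptorsPerClass = "integer",
        plantedPairs = "data.frame",
        codeMap = "list",
        nTF = "integer",
        nAG = "integer",
        ambientRate = "numeric",
        captureRate = "numeric",
        nbSize = "numeric",
        primaryMean = "numeric",
        partnerMean = "numeric",
        panelBackgroundMean = "numeric",
        panelPlantedMean = "numeric",
        immatureCoexMultiplier = "numeric",
        juvenileCoexMultiplier = "numeric",
        composition = "numeric",
        zoneEnrichment = "numeric",
        nChromosomes = "integer",
        pseudogeneFraction = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticTruth", function(object) {
    msg <- NULL
    if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
    if (any(object@nReceptorsPerClass < 1L))
        msg <- c(msg, "nReceptorsPerClass entries must be positive")
    pp <- object@plantedPairs
    need <- c("receptor_a", "receptor_b", "co_prob", "same_chromosome")
    if (!all(need %in% names(pp)))
        msg <- c(msg, "plantedPairs needs receptor_a, receptor_b, co_prob, same_chromosome")
    else if (nrow(pp)) {
        if (any(pp$co_prob < 0 | pp$co_prob > 1))
            msg <- c(msg, "co_prob must lie in [0, 1]")
        if (anyDuplicated(c(pp$receptor_a, pp$receptor_b)))
            msg <- c(msg, "each receptor may belong to at most one planted pair")
    }
    if (object@captureRate <= 0 || object@captureRate > 1)
        msg <- c(msg, "captureRate must lie in (0, 1]")
    if (object@ambientRate < 0) msg <- c(msg, "ambientRate must be >= 0")
    if (abs(sum(object@composition) - 1) > 1e-6)
        msg <- c(msg, "composition probabilities must sum to 1")
    if (any(object@zoneEnrichment < 1))
        msg <- c(msg, "zoneEnrichment multipliers must be >= 1")
    if (object@pseudogeneFraction < 0 || object@pseudogeneFraction >= 1)
        msg <- c(msg, "pseudogeneFraction must lie in [0, 1)")
    if (is.null(msg)) TRUE else msg
})
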