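#' Construct the planted truth of a synthetic VNO experiment
#'
#' Bundles every generative parameter with a seed. All generators
#' ([generateAnnotation()], [simulateCounts()], [simulateSpatial()]) are
#' pure functions of this object. Defaults describe a deliberately
#' simplified vomeronasal neuroepithelium: receptor choice follows a
#' power law over within-class ranks, most cells express a single
#' receptor, a small set of planted pairs is co-expressed (mostly from the
#' same chromosome), each coded receptor drives a private set of TF and
#' axon-guidance genes, and ambient contamination plus binomial capture
#' loss corrupt the counts.
#'
#' @param alpha power-law exponent (> 0) of receptor choice probability vs
#'   within-class rank. Default 1.2.
#' @param nReceptorsPerClass named integer vector of receptors per class.
#' @param plantedPairs data.frame(receptor_a, receptor_b, co_prob,
#'   same_chromosome); \code{NULL} builds the default 12-pair set (8
#'   intra-chromosomal, co_prob 0.8) over mid-rank receptors of the largest
#'   class via [makePlantedPairs()].
#' @param codeMap receptor -> TF/AG program; \code{NULL} wires the top
#'   receptors of each class to 2 TFs and 3 AGs at mean
#'   \code{panelPlantedMean} via [makeCodeMap()].
#' @param nTF,nAG total panel sizes including unwired background genes.
#' @param ambientRate mean stray counts per off-target receptor per cell
#'   before capture thinning. Default 0.5 — well below the presence
#'   threshold in expectation.
#' @param captureRate binomial per-transcript capture probability.
#' @param nbSize negative-binomial size of signal counts.
#' @param primaryMean,partnerMean NB means of primary / partner receptor.
#' @param panelBackgroundMean,panelPlantedMean Poisson means of unwired and
#'   wired panel genes.
#' @param immatureCoexMultiplier,juvenileCoexMultiplier co-expression
#'   probability multipliers for immature VSNs and P14 animals (capped at
#'   probability 1).
#' @param composition named cell-type proportions summing to 1.
#' @param zoneEnrichment named marginal-zone density multipliers (>= 1).
#' @param nChromosomes chromosomes in the generated annotation.
#' @param pseudogeneFraction fraction of each class flagged pseudogene.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SyntheticTruth}.
#' @examples
#' truth <- SyntheticTruth(seed = 7)
#' truth
#' @export
SyntheticTruth <- function(alpha = 1.2,
                           nReceptorsPerClass = c(V1R = 60L, V2R = 40L),
                           plantedPairs = NULL,
                           codeMap = NULL,
                           nTF = 40L, nAG = 60L,
                           ambientRate = 0.5,
                           captureRate = 0.8,
                           nbSize = 5,
                           primaryMean = 60,
                           partnerMean = 40,
                           panelBackgroundMean = 0.3,
                           panelPlantedMean = 8,
                           immatureCoexMultiplier = 2,
                           juvenileCoexMultiplier = 1.5,
                           composition = c(GBC = 0.05, INP = 0.10,
                                           iVSN = 0.20, `mVSN-V1R` = 0.35,
                                           `mVSN-V2R` = 0.25, sVSN = 0.05),
                           zoneEnrichment = c(GBC = 3, INP = 3, iVSN = 2),
                           nChromosomes = 5L,
                           pseudogeneFraction = 0.1,
                           seed = 1L) {
    nReceptorsPerClass <- stats::setNames(as.integer(nReceptorsPerClass),
                                          names(nReceptorsPerClass))
    if (is.null(names(nReceptorsPerClass)))
        stop("nReceptorsPerClass must be a named vector of receptor classes")
    if (is.null(plantedPairs))
        plantedPairs <- makePlantedPairs(nReceptorsPerClass)
    if (is.null(codeMap))
        codeMap <- makeCodeMap(.defaultCodedReceptors(nReceptorsPerClass),
                               nTF = nTF, nAG = nAG,
                               plantedMean = panelPlantedMean)
    if (abs(sum(composition) - 1) > 1e-6)
        stop("configuration error: composition probabilities must sum to 1")
    comp <- composition[composition > 0]
    obj <- methods::new("SyntheticTruth",
        alpha = alpha, nReceptorsPerClass = nReceptorsPerClass,
        plantedPairs = plantedPairs, codeMap = codeMap,
        nTF = as.integer(nTF), nAG = as.integer(nAG),
        ambientRate = ambientRate, captureRate = captureRate,
        nbSize = nbSize, primaryMean = primaryMean,
        partnerMean = partnerMean,
        panelBackgroundMean = panelBackgroundMean,
        panelPlantedMean = panelPlantedMean,
        immatureCoexMultiplier = immatureCoexMultiplier,
        juvenileCoexMultiplier = juvenileCoexMultiplier,
        composition = comp, zoneEnrichment = zoneEnrichment,
        nChromosomes = as.integer(nChromosomes),
        pseudogeneFraction = pseudogeneFraction,
        seed = as.integer(seed))
    .checkTruthReferences(obj)
    obj
}

# receptor ids are deterministic: <class>_<rank> with zero-padded rank,
# rank 1 being the most probable receptor of its class
receptorIdsFor <- function(class, n) sprintf("%s_%03d", class, seq_len(n))

.allReceptorIds <- function(nPerClass) {
    unlist(lapply(names(nPerClass), function(cl)
        receptorIdsFor(cl, nPerClass[[cl]])), use.names = FALSE)
}

.defaultCodedReceptors <- function(nPerClass) {
    unlist(lapply(names(nPerClass), function(cl) {
        k <- min(12L, nPerClass[[cl]])
        receptorIdsFor(cl, nPerClass[[cl]])[seq_len(k)]
    }), use.names = FALSE)
}

.checkTruthReferences <- function(truth) {
    ids <- .allReceptorIds(truth@nReceptorsPerClass)
    pp <- truth@plantedPairs
    bad <- setdiff(c(pp$receptor_a, pp$receptor_b, names(truth@codeMap)), ids)
    if (length(bad))
        stop("planted structure references receptors that are not generated: ",
             paste(bad, collapse = ", "))
    invisible(TRUE)
}

#' Default planted co-expressed pair set
#'
#' Pairs consecutive mid-rank receptors of the largest class — ranks low
#' enough that every planted receptor is expected to clear the >= 5-cell
#' retention filter at a few thousand cells, so the pairs are testable by
#' construction. Two thirds of the pairs are marked intra-chromosomal.
#'
#' @param nReceptorsPerClass named integer vector as in [SyntheticTruth()].
#' @param nPairs number of pairs (default 12, reduced if the class is small).
#' @param nSameChromosome pairs placed on a shared chromosome (default
#'   \code{round(2/3 * nPairs)}).
#' @param coProb planted co-expression probability (default 0.8).
#' @param firstRank rank of the first paired receptor (default 3).
#' @return data.frame(receptor_a, receptor_b, co_prob, same_chromosome).
#' @export
makePlantedPairs <- function(nReceptorsPerClass, nPairs = 12L,
                             nSameChromosome = round(2 / 3 * nPairs),
                             coProb = 0.8, firstRank = 3L) {
    cl <- names(nReceptorsPerClass)[which.max(nReceptorsPerClass)]
    k <- nReceptorsPerClass[[cl]]
    nPairs <- min(nPairs, (k - firstRank + 1L) %/% 2L)
    if (nPairs < 1L)
        return(data.frame(receptor_a = character(), receptor_b = character(),
                          co_prob = numeric(), same_chromosome = logical()))
    ids <- receptorIdsFor(cl, k)
    a <- firstRank + 2L * (seq_len(nPairs) - 1L)
    data.frame(receptor_a = ids[a], receptor_b = ids[a + 1L],
               co_prob = coProb,
               same_chromosome = seq_len(nPairs) <= nSameChromosome)
}

#' An empty planted-pair table
#'
#' Convenience for truths without planted receptor co-expression.
#'
#' @return zero-row data.frame with the planted-pair columns.
#' @export
emptyPlantedPairs <- function() {
    data.frame(receptor_a = character(), receptor_b = character(),
               co_prob = numeric(), same_chromosome = logical())
}

#' Build a receptor -> TF/AG code map
#'
#' Each receptor is wired to \code{tfsPerReceptor} transcription factors and
#' \code{agsPerReceptor} axon-guidance genes expressed at
#' \code{plantedMean} in that receptor's cells. With \code{blocks}, all
#' receptors of a block share one TF/AG set (block-structured code, used to
#' test profile-similarity recovery).
#'
#' @param receptors character receptor ids.
#' @param nTF,nAG panel sizes; wired genes are drawn cyclically from
#'   \code{TF_001..} / \code{AG_001..}.
#' @param tfsPerReceptor,agsPerReceptor wired genes per receptor (or block).
#' @param plantedMean Poisson mean of wired genes.
#' @param blocks optional named vector mapping receptor -> block label.
#' @return named list: receptor -> list(tf = named means, ag = named means).
#' @export
makeCodeMap <- function(receptors, nTF = 40L, nAG = 60L,
                        tfsPerReceptor = 2L, agsPerReceptor = 3L,
                        plantedMean = 8, blocks = NULL) {
    tfIds <- sprintf("TF_%03d", seq_len(nTF))
    agIds <- sprintf("AG_%03d", seq_len(nAG))
    key <- if (is.null(blocks)) stats::setNames(seq_along(receptors), receptors)
           else stats::setNames(match(blocks[receptors], unique(blocks[receptors])),
                                receptors)
    pick <- function(ids, per, j) ids[((j - 1L) * per + seq_len(per) - 1L) %%
                                      length(ids) + 1L]
    out <- lapply(receptors, function(r) {
        j <- key[[r]]
        list(tf = stats::setNames(rep(plantedMean, tfsPerReceptor),
                                  pick(tfIds, tfsPerReceptor, j)),
             ag = stats::setNames(rep(plantedMean, agsPerReceptor),
                                  pick(agIds, agsPerReceptor, j)))
    })
    names(out) <- receptors
    out
}
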