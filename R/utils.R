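# shared internals: seeded evaluation, enrichment p, normalization

# evaluate expr under a fixed RNG state, restoring the caller's stream
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' One-sided Fisher enrichment p-value from 2x2 counts
#'
#' The p-value of observing at least \code{n11} cells positive for both
#' features, given the marginals, under the hypergeometric null — identical
#' to a one-sided (\code{alternative = "greater"}) Fisher exact test on the
#' contingency table \code{(n11, n10; n01, n00)}. Vectorized over tables.
#'
#' @param n11,n10,n01,n00 integer vectors: both / first-only / second-only /
#'   neither counts. Recycled to a common length.
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' fisherEnrichmentP(3, 0, 0, 3)  # 1/choose(6,3) = 0.05
#' @export
fisherEnrichmentP <- function(n11, n10, n01, n00) {
    n <- max(length(n11), length(n10), length(n01), length(n00))
    n11 <- rep_len(as.numeric(n11), n); n10 <- rep_len(as.numeric(n10), n)
    n01 <- rep_len(as.numeric(n01), n); n00 <- rep_len(as.numeric(n00), n)
    if (any(c(n11, n10, n01, n00) < 0)) stop("cell counts must be nonnegative")
    ka <- n11 + n10          # cells positive for the first feature
    kb <- n11 + n01          # cells positive for the second feature
    N <- n11 + n10 + n01 + n00
    stats::phyper(n11 - 1, ka, N - ka, kb, lower.tail = FALSE)
}

# sample odds ratio with the conventions used throughout: Inf when the
# discordant product vanishes but co-occurrence exists, 0 when n11 = 0
.oddsRatio <- function(n11, n10, n01, n00) {
    den <- n10 * n01
    ifelse(den > 0, (n11 * n00) / den, ifelse(n11 > 0, Inf, 0))
}

# BH step-up across a vector that may contain NAs (untested entries)
.adjustBH <- function(p) stats::p.adjust(p, method = "BH")

#' Median-of-totals log-normalization
#'
#' Scales each cell's counts to the median total count across cells, then
#' applies \code{log1p}. Used for the mean-expression entries of
#' association tables, where only the ordering of means matters.
#'
#' @param counts genes x cells count matrix (base or \pkg{Matrix}).
#' @return a matrix of the same class and dimensions.
#' @export
normalizeCounts <- function(counts) {
    totals <- Matrix::colSums(counts)
    med <- stats::median(totals[totals > 0])
    sf <- ifelse(totals > 0, med / totals, 0)
    log1p(counts %*% Matrix::Diagonal(x = sf, names = FALSE))
}

# assert a SingleCellExperiment-like object with counts + gene_class rowData
.getCounts <- function(x) {
    if (is(x, "SummarizedExperiment"))
        return(SummarizedExperiment::assay(x, "counts"))
    if (is.matrix(x) || is(x, "Matrix")) return(x)
    stop("expected a SummarizedExperiment/SingleCellExperiment or a matrix")
}

.getAnnotation <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        ann <- SummarizedExperiment::rowData(x)
        if (!"gene_class" %in% colnames(ann))
            stop("rowData must carry a 'gene_class' column")
        return(ann)
    }
    stop("gene annotation required: supply a SummarizedExperiment")
}

.classGenes <- function(annotation, classes) {
    rownames(annotation)[annotation$gene_class %in% classes]
}
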