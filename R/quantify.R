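#' Summarize receptor expression for one receptor class
#'
#' One row per annotated receptor of the class: total raw counts, number of
#' cells with any nonzero detection, mean counts per expressing cell, and
#' the within-class rank by that mean. Undetected receptors are retained
#' with zeros and flagged (dropout candidates), mirroring rank-abundance
#' summaries where absent receptors still occupy ranks.
#'
#' Detection here is any nonzero count — the presence threshold (>= 10)
#' belongs to co-expression calling, not to expression summaries.
#'
#' @param sce annotated SingleCellExperiment.
#' @param geneClass one of the annotated receptor classes (e.g. "V1R").
#' @param includePseudogenes keep pseudogenes in the table (default TRUE).
#' @return data.frame with columns gene_id, gene_class, pseudogene,
#'   total_counts, n_cells_expressing, mean_counts_per_expressing_cell,
#'   rank_by_mean, undetected.
#' @export
summarizeReceptors <- function(sce, geneClass, includePseudogenes = TRUE) {
    ann <- .getAnnotation(sce)
    ids <- .classGenes(ann, geneClass)
    if (!length(ids))
        stop("no genes of class '", geneClass, "' in the annotation")
    if (!includePseudogenes)
        ids <- ids[!ann[ids, "pseudogene"]]
    counts <- .getCounts(sce)[ids, , drop = FALSE]
    total <- Matrix::rowSums(counts)
    ncells <- Matrix::rowSums(counts > 0)
    mean_expr <- ifelse(ncells > 0, total / ncells, 0)
    ord <- order(-mean_expr, ids)          # ties broken by gene_id
    rank_by_mean <- integer(length(ids))
    rank_by_mean[ord] <- seq_along(ids)
    data.frame(
        gene_id = ids,
        gene_class = geneClass,
        pseudogene = as.logical(ann[ids, "pseudogene"]),
        total_counts = as.integer(total),
        n_cells_expressing = as.integer(ncells),
        mean_counts_per_expressing_cell = mean_expr,
        rank_by_mean = rank_by_mean,
        undetected = ncells == 0,
        row.names = NULL)
}

#' Fit the rank-probability power law of receptor choice
#'
#' The expression probability of receptor r is its share of expressing
#' cells, p_r = n_cells_r / sum(n_cells). Receptors are ranked by
#' decreasing probability and a least-squares line is fitted on
#' (log rank, log p), restricted to receptors detected in at least
#' \code{minCellsFloor} cells — the low-rank dropout tail deviates from the
#' power law for technical reasons and is excluded by this floor rather
#' than by a rank cutoff. The exponent estimate is minus the slope.
#'
#' @param summary a table from [summarizeReceptors()].
#' @param minCellsFloor dropout-tail exclusion floor (default 10 cells).
#' @return a \linkS4class{PowerLawFit}.
#' @export
fitPowerLaw <- function(summary, minCellsFloor = 10L) {
    n <- summary$n_cells_expressing
    ord <- order(-n, summary$gene_id)
    n <- n[ord]
    p <- n / sum(n)
    rank <- seq_along(p)
    keep <- n >= minCellsFloor
    if (sum(keep) < 5L)
        stop("fewer than 5 receptors at or above the cell floor; cannot fit")
    fit <- stats::lm(log(p[keep]) ~ log(rank[keep]))
    methods::new("PowerLawFit",
        alphaHat = -unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        rSquared = summary(fit)$r.squared,
        fitRange = as.integer(range(rank[keep])),
        nFitted = as.integer(sum(keep)),
        minCellsFloor = as.integer(minCellsFloor))
}

#' Relation between total expression and number of expressing cells
#'
#' Ordinary least squares of total counts on the number of expressing
#' cells, plus the Pearson correlation, across the receptors of a summary
#' table. A tight relation (r near 1) indicates roughly uniform per-cell
#' expression across receptors; receptor-specific per-cell levels weaken it.
#'
#' @param summary a table from [summarizeReceptors()].
#' @return list(pearson_r, slope, intercept, n).
#' @export
expressionCellsRelation <- function(summary) {
    keep <- summary$total_counts > 0
    if (sum(keep) < 3L)
        stop("need at least 3 receptors with nonzero totals")
    x <- summary$n_cells_expressing[keep]
    y <- summary$total_counts[keep]
    if (stats::var(x) == 0)
        stop("zero variance in the number of expressing cells; ",
             "correlation undefined")
    fit <- stats::lm(y ~ x)
    list(pearson_r = stats::cor(x, y),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n = sum(keep))
}

#' Histogram of receptors by mean expression per expressing cell
#'
#' Half-open bins [lo, hi): a receptor with mean exactly at an edge falls
#' into the upper bin. Default edges split at the decade boundaries 10 and
#' 100 counts per cell.
#'
#' @param summary a table from [summarizeReceptors()].
#' @param binEdges ascending numeric edges (default c(0, 10, 100, Inf)).
#' @return named integer vector of receptor counts per bin; sums to
#'   \code{nrow(summary)}.
#' @export
binMeanExpression <- function(summary, binEdges = c(0, 10, 100, Inf)) {
    if (is.unsorted(binEdges, strictly = TRUE))
        stop("binEdges must be strictly ascending")
    m <- summary$mean_counts_per_expressing_cell
    bin <- findInterval(m, binEdges)
    labels <- paste0("[", utils::head(binEdges, -1), ",",
                     utils::tail(binEdges, -1), ")")
    out <- stats::setNames(integer(length(labels)), labels)
    tab <- table(factor(bin, levels = seq_along(labels)))
    out[] <- as.integer(tab)
    out
}
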