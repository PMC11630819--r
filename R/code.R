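#' Receptor x panel-gene association table
#'
#' Builds the co-expression "code" between receptors and one panel of
#' candidate genes (transcription factors or axon-guidance molecules).
#' Receptor presence requires >= \code{receptorThreshold} raw counts
#' (default 10), panel-gene presence >= \code{panelThreshold} (default 3).
#' Each receptor x gene cell gets a one-sided Fisher enrichment p-value on
#' the presence/absence 2x2 table over all cells, BH-adjusted across the
#' full table, plus the mean normalized (log1p, median-scaled) expression
#' of the gene over the receptor's presence cells. Receptors without any
#' presence cell are kept as flagged, untested rows.
#'
#' @param sce annotated SingleCellExperiment.
#' @param receptorClasses receptor classes forming the rows.
#' @param panel \code{"TF"} or \code{"AG"}.
#' @param receptorThreshold,panelThreshold raw-count presence thresholds.
#' @return an \linkS4class{AssociationTable}.
#' @export
buildAssociation <- function(sce, receptorClasses = c("V1R", "V2R"),
                             panel = c("TF", "AG"),
                             receptorThreshold = 10L, panelThreshold = 3L) {
    panel <- match.arg(panel)
    ann <- .getAnnotation(sce)
    recIds <- .classGenes(ann, receptorClasses)
    panelIds <- .classGenes(ann, panel)
    if (!length(recIds))
        stop("no receptors of class(es) ",
             paste(receptorClasses, collapse = "/"), " in the annotation")
    if (!length(panelIds))
        stop("panel '", panel, "' has no genes in the annotation")
    counts <- .getCounts(sce)
    N <- ncol(counts)
    recP <- counts[recIds, , drop = FALSE] >= receptorThreshold
    panP <- counts[panelIds, , drop = FALSE] >= panelThreshold
    nRec <- Matrix::rowSums(recP)
    nPan <- Matrix::rowSums(panP)
    n11 <- as.matrix(Matrix::tcrossprod(recP * 1, panP * 1))
    n10 <- outer(nRec, rep(1, length(panelIds))) - n11
    n01 <- outer(rep(1, length(recIds)), nPan) - n11
    n00 <- N - n11 - n10 - n01
    p <- matrix(fisherEnrichmentP(n11, n10, n01, n00),
                nrow = length(recIds),
                dimnames = list(recIds, panelIds))
    flagged <- recIds[nRec == 0]
    p[nRec == 0, ] <- NA_real_
    padj <- matrix(.adjustBH(as.vector(p)), nrow = nrow(p),
                   dimnames = dimnames(p))
    norm <- normalizeCounts(counts)[panelIds, , drop = FALSE]
    sums <- as.matrix(Matrix::tcrossprod(norm, recP * 1))   # panel x receptor
    meanExpr <- t(sums) / ifelse(nRec > 0, nRec, NA)
    dimnames(meanExpr) <- list(recIds, panelIds)
    methods::new("AssociationTable",
        meanExpr = as.matrix(meanExpr), pValue = p, pAdjusted = padj,
        panel = panel,
        receptorThreshold = as.integer(receptorThreshold),
        panelThreshold = as.integer(panelThreshold),
        flaggedReceptors = flagged)
}

# Pearson correlation across rows, excluding zero-variance rows
.rowProfileCorrelation <- function(M, kind) {
    vars <- apply(M, 1, stats::var)
    flagged <- rownames(M)[is.na(vars) | vars == 0]
    keep <- setdiff(rownames(M), flagged)
    if (length(keep) < 2L)
        stop("fewer than 2 receptors with variable profiles; ",
             "correlation undefined")
    cc <- stats::cor(t(M[keep, , drop = FALSE]))
    methods::new("SimilarityMatrix", values = cc, kind = kind,
                 flagged = flagged)
}

#' Receptor-receptor correlation of panel expression profiles
#'
#' Pearson correlation between the rows (receptors) of an association
#' table's mean-expression matrix — the similarity of receptors in terms of
#' the TF (or AG) programs their cells express. Receptors with constant
#' profiles are excluded and reported as flagged.
#'
#' @param assoc an \linkS4class{AssociationTable}.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{tf_profile} or
#'   \code{ag_profile}.
#' @export
profileCorrelation <- function(assoc) {
    kind <- if (assoc@panel == "TF") "tf_profile" else "ag_profile"
    .rowProfileCorrelation(meanExpression(assoc), kind)
}

#' Pairwise receptor protein sequence identity
#'
#' Global pairwise alignment (BLOSUM62, affine gaps: open 11, extend 1)
#' percent identity, defined as identities over alignment length (gaps
#' included) x 100.
#'
#' @param seqs an \link[Biostrings]{AAStringSet} (>= 2 sequences) or a named
#'   character vector of amino-acid sequences.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{sequence} with
#'   diagonal 100.
#' @export
sequenceSimilarity <- function(seqs) {
    if (!is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(seqs)
    if (length(seqs) < 2L) stop("need at least 2 sequences")
    if (any(Biostrings::width(seqs) == 0L)) stop("empty sequence supplied")
    n <- length(seqs)
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_len(n))
    out <- matrix(100, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) {
        aln <- Biostrings::pairwiseAlignment(
            rep(seqs[i], n - i), seqs[(i + 1L):n],
            type = "global", substitutionMatrix = "BLOSUM62",
            gapOpening = 11, gapExtension = 1)
        pid <- 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
        out[i, (i + 1L):n] <- pid
        out[(i + 1L):n, i] <- pid
    }
    methods::new("SimilarityMatrix", values = out, kind = "sequence",
                 flagged = character())
}

#' Relation between expression-profile similarity and sequence similarity
#'
#' Pools all off-diagonal receptor pairs, bins one similarity into
#' \code{nBins} equal-width bins and reports per-bin mean and median of the
#' other (in both directions), plus the overall Spearman correlation — a
#' binned summary of whether receptors with similar axon-guidance programs
#' also have similar protein sequences.
#'
#' @param seqSim sequence \linkS4class{SimilarityMatrix}.
#' @param profSim profile \linkS4class{SimilarityMatrix} over the same
#'   receptor set.
#' @param nBins number of equal-width bins (default 20).
#' @return list(spearman_rho, n_pairs, by_profile_bin, by_sequence_bin)
#'   where the tables carry bin midpoints, counts, means and medians.
#' @export
similarityRelation <- function(seqSim, profSim, nBins = 20L) {
    A <- similarityValues(seqSim)
    B <- similarityValues(profSim)
    common <- intersect(rownames(A), rownames(B))
    if (!setequal(rownames(A), rownames(B)))
        stop("similarity matrices cover different receptor sets")
    A <- A[common, common]; B <- B[common, common]
    ut <- upper.tri(A)
    x <- B[ut]   # profile similarity
    y <- A[ut]   # sequence similarity
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    binTable <- function(by, of) {
        edges <- seq(min(by), max(by), length.out = nBins + 1L)
        bin <- pmin(findInterval(by, edges, rightmost.closed = TRUE), nBins)
        data.frame(
            bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
            n = as.integer(table(factor(bin, levels = seq_len(nBins)))),
            mean = as.numeric(tapply(of, factor(bin, levels = seq_len(nBins)),
                                     mean)),
            median = as.numeric(tapply(of, factor(bin,
                                                  levels = seq_len(nBins)),
                                       stats::median)))
    }
    list(spearman_rho = stats::cor(x, y, method = "spearman"),
         n_pairs = length(x),
         by_profile_bin = binTable(x, y),
         by_sequence_bin = binTable(y, x))
}

#' TF x AG Jaccard grid for one receptor
#'
#' Within the presence cells of one receptor (>= receptor threshold raw
#' counts), and restricted to the TF and AG genes significantly associated
#' with that receptor (adjusted p <= \code{alpha}), the Jaccard index of
#' the barcode sets in which each TF and each AG gene is detected at the
#' panel threshold: J = |T intersect A| / |T union A|.
#'
#' @param sce annotated SingleCellExperiment.
#' @param assocTF,assocAG \linkS4class{AssociationTable}s for the TF and AG
#'   panels (supplying thresholds and significance).
#' @param receptor receptor id (a row of both tables).
#' @param alpha significance cutoff on adjusted p (default 0.05).
#' @return a \linkS4class{JaccardGrid}; empty (0 x 0) when the receptor has
#'   no significant partner in one of the panels.
#' @export
tfAgJaccard <- function(sce, assocTF, assocAG, receptor, alpha = 0.05) {
    stopifnot(assocTF@panel == "TF", assocAG@panel == "AG")
    if (!receptor %in% rownames(meanExpression(assocTF)) ||
        !receptor %in% rownames(meanExpression(assocAG)))
        stop("receptor '", receptor, "' is not a row of both tables")
    counts <- .getCounts(sce)
    cells <- which(counts[receptor, ] >= assocTF@receptorThreshold)
    sigTF <- colnames(pAdjusted(assocTF))[
        !is.na(pAdjusted(assocTF)[receptor, ]) &
        pAdjusted(assocTF)[receptor, ] <= alpha]
    sigAG <- colnames(pAdjusted(assocAG))[
        !is.na(pAdjusted(assocAG)[receptor, ]) &
        pAdjusted(assocAG)[receptor, ] <= alpha]
    if (!length(sigTF) || !length(sigAG) || !length(cells)) {
        return(methods::new("JaccardGrid", receptor = receptor,
                            jaccard = matrix(numeric(), length(sigTF),
                                             length(sigAG),
                                             dimnames = list(sigTF, sigAG)),
                            tfIds = sigTF, agIds = sigAG,
                            nCells = length(cells)))
    }
    tfSet <- counts[sigTF, cells, drop = FALSE] >= assocTF@panelThreshold
    agSet <- counts[sigAG, cells, drop = FALSE] >= assocAG@panelThreshold
    inter <- as.matrix(Matrix::tcrossprod(tfSet * 1, agSet * 1))
    sizeT <- Matrix::rowSums(tfSet)
    sizeA <- Matrix::rowSums(agSet)
    uni <- outer(sizeT, sizeA, "+") - inter
    J <- ifelse(uni > 0, inter / uni, 0)
    dimnames(J) <- list(sigTF, sigAG)
    methods::new("JaccardGrid", receptor = receptor, jaccard = J,
                 tfIds = sigTF, agIds = sigAG, nCells = length(cells))
}

#' Receptor-type correlation from the combined TF + AG code
#'
#' Pearson correlation between receptors over their concatenated TF and AG
#' mean-expression profiles. If one panel is empty (no columns), the
#' computation falls back to the other panel with a warning.
#'
#' @param assocTF,assocAG \linkS4class{AssociationTable}s over a shared
#'   receptor set.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{combined}.
#' @export
receptorTypeCorrelation <- function(assocTF, assocAG) {
    Mt <- meanExpression(assocTF)
    Ma <- meanExpression(assocAG)
    common <- intersect(rownames(Mt), rownames(Ma))
    if (!length(common)) stop("no shared receptors between the two tables")
    Mt <- Mt[common, , drop = FALSE]
    Ma <- Ma[common, , drop = FALSE]
    if (ncol(Mt) == 0L && ncol(Ma) == 0L)
        stop("both panels are empty")
    if (ncol(Mt) == 0L || ncol(Ma) == 0L) {
        warning("one panel is empty; falling back to the other panel alone")
        M <- if (ncol(Mt)) Mt else Ma
    } else {
        M <- cbind(Mt, Ma)
    }
    .rowProfileCorrelation(M, "combined")
}
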