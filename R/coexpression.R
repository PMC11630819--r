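#' Threshold receptor counts into presence calls
#'
#' A receptor is called present in a cell at >= \code{countThreshold} raw
#' counts (default 10, boundary inclusive); receptors present in fewer than
#' \code{minCells} cells (default 5) are dropped from the retained set that
#' feeds the pairwise tests. All class receptors remain as rows so the
#' filter is transparent.
#'
#' @param sce annotated SingleCellExperiment.
#' @param classes receptor classes to include (default the four
#'   chemoreceptor families).
#' @param countThreshold presence threshold on raw counts (>= 1).
#' @param minCells retention threshold on presence cells (>= 1).
#' @return a \linkS4class{PresenceMatrix}.
#' @export
binarizePresence <- function(sce, classes = c("V1R", "V2R", "OR", "Fpr"),
                             countThreshold = 10L, minCells = 5L) {
    if (!length(classes)) stop("classes must be nonempty")
    if (countThreshold < 1L)
        stop("countThreshold must be >= 1")
    ann <- .getAnnotation(sce)
    ids <- .classGenes(ann, classes)
    if (!length(ids))
        stop("no genes of class(es) ", paste(classes, collapse = "/"),
             " in the annotation")
    pres <- methods::as(.getCounts(sce)[ids, , drop = FALSE] >=
                        countThreshold, "lgCMatrix")
    retained <- ids[Matrix::rowSums(pres) >= minCells]
    methods::new("PresenceMatrix", presence = pres,
                 countThreshold = as.integer(countThreshold),
                 minCells = as.integer(minCells),
                 retainedReceptors = retained)
}

#' Per-cell receptor diversity and dominance statistics
#'
#' Shannon diversity (natural log, via \code{vegan::diversity}) of each
#' cell's raw counts over the chemoreceptor classes, together with the
#' number of receptors passing the presence threshold, the count shares of
#' the cell's three most expressed receptors, and the receptor fraction of
#' the cell's total counts. Cells without any receptor count get an
#' undefined (NA) index and are flagged.
#'
#' @param sce annotated SingleCellExperiment.
#' @param classes receptor classes included in the diversity computation.
#' @param countThreshold presence threshold used for
#'   \code{n_receptors_present}.
#' @return data.frame with one row per cell: barcode, shannon_H,
#'   n_receptors_present, top1_share, top2_share, top3_share,
#'   class_fraction_of_total, no_receptor_counts.
#' @export
shannonPerCell <- function(sce, classes = c("V1R", "V2R", "OR", "Fpr"),
                           countThreshold = 10L) {
    ann <- .getAnnotation(sce)
    ids <- .classGenes(ann, classes)
    if (!length(ids))
        stop("no genes of class(es) ", paste(classes, collapse = "/"),
             " in the annotation")
    counts <- .getCounts(sce)
    sub <- as.matrix(counts[ids, , drop = FALSE])
    clsTotal <- colSums(sub)
    cellTotal <- Matrix::colSums(counts)
    H <- suppressWarnings(vegan::diversity(t(sub), index = "shannon"))
    H[clsTotal == 0] <- NA_real_
    shares <- apply(sub, 2, function(v) {
        s <- c(sort(v, decreasing = TRUE), 0, 0, 0)[1:3]
        tot <- sum(v)
        if (tot == 0) rep(NA_real_, 3) else s / tot
    })
    data.frame(
        barcode = colnames(counts),
        shannon_H = unname(H),
        n_receptors_present = unname(colSums(sub >= countThreshold)),
        top1_share = unname(shares[1, ]),
        top2_share = unname(shares[2, ]),
        top3_share = unname(shares[3, ]),
        class_fraction_of_total = unname(
            ifelse(cellTotal > 0, clsTotal / cellTotal, NA_real_)),
        no_receptor_counts = unname(clsTotal == 0),
        row.names = NULL)
}

#' Receptor multiplicity fractions per cell group
#'
#' Fractions of cells expressing 0, 1, 2 or 3+ retained receptors at the
#' presence threshold, per group defined by cell metadata columns
#' (cell type, age group, or their combination).
#'
#' @param presence a \linkS4class{PresenceMatrix}.
#' @param cells colData-like table aligned to the presence matrix columns
#'   (matched by barcode / rownames).
#' @param groupBy subset of c("cell_type", "age_group").
#' @return data.frame with group columns, n_cells and fractions
#'   frac_0, frac_1, frac_2, frac_3plus summing to 1 per group (NA and
#'   flagged for empty groups when grouping columns are factors with unused
#'   levels).
#' @export
multiplicityTable <- function(presence, cells, groupBy = "cell_type") {
    bad <- setdiff(groupBy, c("cell_type", "age_group"))
    if (length(bad))
        stop("unknown grouping key(s): ", paste(bad, collapse = ", "))
    P <- presence(presence)
    keep <- retainedReceptors(presence)
    bc <- colnames(P)
    idx <- match(bc, if (!is.null(rownames(cells))) rownames(cells)
                     else cells$barcode)
    if (anyNA(idx))
        stop("cells table does not cover all barcodes of the presence matrix")
    nrec <- Matrix::colSums(P[keep, , drop = FALSE])
    mult <- cut(nrec, c(-Inf, 0, 1, 2, Inf), labels = c("0", "1", "2", "3plus"))
    groups <- lapply(groupBy, function(g) {
        v <- cells[[g]][idx]
        if (is.factor(v)) v else factor(v)
    })
    names(groups) <- groupBy
    tab <- table(interaction(groups, sep = " / ", drop = FALSE), mult)
    n <- rowSums(tab)
    frac <- tab / ifelse(n > 0, n, NA)
    out <- data.frame(group = rownames(tab), n_cells = as.integer(n),
                      frac_0 = frac[, "0"], frac_1 = frac[, "1"],
                      frac_2 = frac[, "2"], frac_3plus = frac[, "3plus"],
                      empty_group = n == 0, row.names = NULL)
    out
}

#' All-pairs one-sided Fisher co-expression tests
#'
#' For every unordered pair of retained receptors, the 2x2 table of
#' presence/absence over all cells of the matrix (the test universe), a
#' one-sided (enrichment) Fisher exact p-value, and BH adjustment applied
#' jointly across all tested pairs. Pairs with no co-occurring cell are
#' still tested. When an annotation is supplied, each pair is labelled
#' with chromosome identity and the midpoint distance for same-chromosome
#' pairs.
#'
#' @param presence a \linkS4class{PresenceMatrix}.
#' @param annotation optional gene annotation (DataFrame keyed by gene id).
#' @param alternative \code{"greater"} (enrichment, default) or
#'   \code{"two.sided"}.
#' @param adjustWithin \code{"all"} (default: one BH family across every
#'   pair) or \code{"class"} (requires annotation; BH within same-class
#'   pairs and cross-class pairs separately).
#' @return data.frame: gene_a, gene_b, n11, n10, n01, n00, odds_ratio,
#'   p_value, p_adjusted, same_chromosome, genomic_distance_bp.
#' @export
pairwiseFisher <- function(presence, annotation = NULL,
                           alternative = c("greater", "two.sided"),
                           adjustWithin = c("all", "class")) {
    alternative <- match.arg(alternative)
    adjustWithin <- match.arg(adjustWithin)
    keep <- retainedReceptors(presence)
    if (length(keep) < 2L)
        stop("need at least 2 retained receptors")
    P <- presence(presence)[keep, , drop = FALSE]
    N <- ncol(P)
    M <- as.matrix(Matrix::tcrossprod(P * 1))   # co-occurrence counts
    k <- Matrix::rowSums(P)
    ut <- which(upper.tri(M), arr.ind = TRUE)
    a <- ut[, 1]; b <- ut[, 2]
    n11 <- M[ut]
    n10 <- k[a] - n11
    n01 <- k[b] - n11
    n00 <- N - n11 - n10 - n01
    p <- if (alternative == "greater") {
        fisherEnrichmentP(n11, n10, n01, n00)
    } else {
        vapply(seq_along(n11), function(i)
            stats::fisher.test(matrix(c(n11[i], n10[i], n01[i], n00[i]), 2),
                               alternative = "two.sided")$p.value,
            numeric(1))
    }
    res <- data.frame(
        gene_a = keep[a], gene_b = keep[b],
        n11 = as.integer(n11), n10 = as.integer(n10),
        n01 = as.integer(n01), n00 = as.integer(n00),
        odds_ratio = .oddsRatio(n11, n10, n01, n00),
        p_value = p,
        p_adjusted = NA_real_,
        same_chromosome = NA,
        genomic_distance_bp = NA_real_,
        row.names = NULL)
    if (!is.null(annotation)) {
        ia <- match(res$gene_a, rownames(annotation))
        ib <- match(res$gene_b, rownames(annotation))
        if (anyNA(ia) || anyNA(ib))
            stop("gene(s) absent from annotation: ",
                 paste(unique(c(res$gene_a[is.na(ia)],
                                res$gene_b[is.na(ib)])), collapse = ", "))
        res$same_chromosome <- annotation$chromosome[ia] ==
                               annotation$chromosome[ib]
        mid <- (annotation$start_bp + annotation$end_bp) / 2
        res$genomic_distance_bp <- ifelse(res$same_chromosome,
                                          abs(mid[ia] - mid[ib]), NA_real_)
    }
    if (adjustWithin == "class") {
        if (is.null(annotation))
            stop("adjustWithin = 'class' requires an annotation")
        ia <- match(res$gene_a, rownames(annotation))
        ib <- match(res$gene_b, rownames(annotation))
        fam <- ifelse(annotation$gene_class[ia] == annotation$gene_class[ib],
                      annotation$gene_class[ia], "cross")
        for (f in unique(fam))
            res$p_adjusted[fam == f] <- .adjustBH(res$p_value[fam == f])
    } else {
        res$p_adjusted <- .adjustBH(res$p_value)
    }
    res
}

#' Genomic co-localization of significant co-expressed pairs
#'
#' Restricts the pair tests to \code{p_adjusted <= alpha} and reports how
#' many significant pairs share a chromosome, the same-chromosome fraction
#' (both pair-level and gene-level, since either reading of "co-expressed
#' receptors on the same chromosome" is defensible), and the per-pair
#' midpoint distances for intra-chromosomal pairs.
#'
#' @param results data.frame from [pairwiseFisher()].
#' @param annotation gene annotation (used when the results carry no
#'   chromosome labels yet).
#' @param alpha significance cutoff on adjusted p (default 0.05).
#' @return list(n_significant, n_same_chromosome, fraction_same_chromosome,
#'   gene_fraction_same_chromosome, distances, no_significant_pairs). With
#'   no significant pairs the fractions are NA (flagged), not 0.
#' @export
genomicColocalization <- function(results, annotation = NULL, alpha = 0.05) {
    if (!is.null(annotation) && all(is.na(results$same_chromosome))) {
        ia <- match(results$gene_a, rownames(annotation))
        ib <- match(results$gene_b, rownames(annotation))
        if (anyNA(ia) || anyNA(ib))
            stop("gene(s) absent from annotation: ",
                 paste(unique(c(results$gene_a[is.na(ia)],
                                results$gene_b[is.na(ib)])), collapse = ", "))
        results$same_chromosome <- annotation$chromosome[ia] ==
                                   annotation$chromosome[ib]
        mid <- (annotation$start_bp + annotation$end_bp) / 2
        results$genomic_distance_bp <- ifelse(results$same_chromosome,
                                              abs(mid[ia] - mid[ib]),
                                              NA_real_)
    }
    sig <- results[!is.na(results$p_adjusted) & results$p_adjusted <= alpha, ,
                   drop = FALSE]
    if (!nrow(sig)) {
        return(list(n_significant = 0L, n_same_chromosome = 0L,
                    fraction_same_chromosome = NA_real_,
                    gene_fraction_same_chromosome = NA_real_,
                    distances = sig[, c("gene_a", "gene_b",
                                        "genomic_distance_bp")],
                    no_significant_pairs = TRUE))
    }
    genes <- unique(c(sig$gene_a, sig$gene_b))
    sameGenes <- unique(c(sig$gene_a[sig$same_chromosome],
                          sig$gene_b[sig$same_chromosome]))
    list(n_significant = nrow(sig),
         n_same_chromosome = sum(sig$same_chromosome),
         fraction_same_chromosome = mean(sig$same_chromosome),
         gene_fraction_same_chromosome = length(sameGenes) / length(genes),
         distances = sig[sig$same_chromosome,
                         c("gene_a", "gene_b", "genomic_distance_bp")],
         no_significant_pairs = FALSE)
}
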