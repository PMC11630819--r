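#' Write a count matrix
#'
#' Inverse of [readCountMatrix()]: \code{mtx_triplet} writes a directory with
#' \code{matrix.mtx}, \code{features.tsv} (id, symbol) and
#' \code{barcodes.tsv}; \code{dense_tsv} writes a single TSV with gene ids in
#' the first column and barcodes as the header. Round trips are exact.
#'
#' @param sce SingleCellExperiment (or genes x cells matrix with dimnames).
#' @param path output directory or file.
#' @param dialect \code{"mtx_triplet"} or \code{"dense_tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeCountMatrix <- function(sce, path, dialect = c("mtx_triplet", "dense_tsv")) {
    dialect <- match.arg(dialect)
    counts <- .getCounts(sce)
    if (dialect == "mtx_triplet") {
        dir.create(path, showWarnings = FALSE, recursive = TRUE)
        Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                        file.path(path, "matrix.mtx"))
        symbol <- rownames(counts)
        if (is(sce, "SummarizedExperiment") &&
            "symbol" %in% colnames(SummarizedExperiment::rowData(sce)))
            symbol <- SummarizedExperiment::rowData(sce)$symbol
        utils::write.table(
            data.frame(rownames(counts), symbol),
            file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
        writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
    } else {
        tab <- data.frame(gene_id = rownames(counts),
                          as.matrix(counts), check.names = FALSE)
        colnames(tab) <- c("gene_id", colnames(counts))
        utils::write.table(tab, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Write circos link lines for significant co-expressed pairs
#'
#' One line per pair with \code{p_adjusted <= alpha}:
#' \code{chromA startA endA chromB startB endB n_cells_coexpressing}, with
#' 1-based inclusive coordinates copied verbatim from the annotation (the
#' circos convention). The co-expressing cell count is the n11 cell of the
#' pair's contingency table. An empty significant set still produces the
#' header comment.
#'
#' @param pairs data.frame from [pairwiseFisher()].
#' @param annotation gene annotation DataFrame (or rowData).
#' @param path output text file.
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @return \code{path}, invisibly.
#' @export
writeCircosLinks <- function(pairs, annotation, path, alpha = 0.05) {
    sig <- pairs[!is.na(pairs$p_adjusted) & pairs$p_adjusted <= alpha, ,
                 drop = FALSE]
    genes <- unique(c(sig$gene_a, sig$gene_b))
    absent <- setdiff(genes, rownames(annotation))
    if (length(absent))
        stop("gene(s) absent from annotation: ",
             paste(absent, collapse = ", "))
    lines <- "# chrom_a start_a end_a chrom_b start_b end_b n_cells_coexpressing"
    if (nrow(sig)) {
        a <- match(sig$gene_a, rownames(annotation))
        b <- match(sig$gene_b, rownames(annotation))
        lines <- c(lines, sprintf("%s %d %d %s %d %d %d",
            annotation$chromosome[a], annotation$start_bp[a],
            annotation$end_bp[a], annotation$chromosome[b],
            annotation$start_bp[b], annotation$end_bp[b],
            as.integer(sig$n11)))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Write / read result tables
#'
#' Plain-TSV persistence used by every subcommand so that each emitted table
#' can be re-read by the package itself.
#'
#' @param x a data.frame.
#' @param path TSV file.
#' @return \code{writeResultTable} returns \code{path} invisibly;
#'   \code{readResultTable} returns the data.frame.
#' @export
writeResultTable <- function(x, path) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
    utils::read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
}

#' Write a gene annotation table
#'
#' @param annotation DataFrame as returned by [readGeneAnnotation()] or
#'   [generateAnnotation()].
#' @param path TSV file.
#' @return \code{path}, invisibly.
#' @export
writeGeneAnnotation <- function(annotation, path) {
    keep <- intersect(c("gene_id", "symbol", "gene_class", "chromosome",
                        "start_bp", "end_bp", "pseudogene"),
                      colnames(annotation))
    writeResultTable(as.data.frame(annotation[, keep, drop = FALSE]), path)
}
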