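#' Read a genes x cells raw count matrix
#'
#' Supports the 10x-style MatrixMarket triplet layout (a directory with
#' \code{matrix.mtx}, \code{features.tsv} and \code{barcodes.tsv}) and a
#' dense TSV (first column gene ids, header row barcodes). Counts are
#' validated as nonnegative integers; MatrixMarket 1-based coordinates are
#' handled by the reader.
#'
#' @param path directory (\code{mtx_triplet}) or file (\code{dense_tsv}).
#' @param dialect \code{"mtx_triplet"} or \code{"dense_tsv"}.
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} with a sparse
#'   integer \code{counts} assay, gene ids as rownames and barcodes as
#'   colnames.
#' @seealso [writeCountMatrix()] for the inverse operation.
#' @export
readCountMatrix <- function(path, dialect = c("mtx_triplet", "dense_tsv")) {
    dialect <- match.arg(dialect)
    if (dialect == "mtx_triplet") {
        files <- c(matrix = "matrix.mtx", features = "features.tsv",
                   barcodes = "barcodes.tsv")
        paths <- file.path(path, files)
        missing <- files[!file.exists(paths)]
        if (length(missing))
            stop("count matrix directory is missing required file(s): ",
                 paste(missing, collapse = ", "))
        m <- Matrix::readMM(paths[1])
        feat <- utils::read.delim(paths[2], header = FALSE,
                                  stringsAsFactors = FALSE)
        bc <- utils::read.delim(paths[3], header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
        if (nrow(feat) != nrow(m) || length(bc) != ncol(m))
            stop("feature/barcode lengths do not match the matrix dimensions")
        ids <- as.character(feat[[1]])
        counts <- methods::as(m, "CsparseMatrix")
        symbol <- if (ncol(feat) >= 2) as.character(feat[[2]]) else ids
    } else {
        tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                                 stringsAsFactors = FALSE)
        ids <- as.character(tab[[1]])
        num <- as.matrix(tab[, -1, drop = FALSE])
        storage.mode(num) <- "double"
        bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)
        if (nrow(bad))
            stop(sprintf("non-integer count at gene row %d, cell column %d",
                         bad[1, 1], bad[1, 2]))
        counts <- methods::as(num, "CsparseMatrix")
        bc <- colnames(tab)[-1]
        symbol <- ids
    }
    .checkIntegerCounts(counts)
    if (anyDuplicated(ids))
        stop("duplicate feature id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (anyDuplicated(bc))
        stop("duplicate cell barcode(s): ",
             paste(unique(bc[duplicated(bc)]), collapse = ", "))
    dimnames(counts) <- list(ids, bc)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(symbol = symbol, row.names = ids))
}

.checkIntegerCounts <- function(counts) {
    x <- counts@x
    bad <- which(is.na(x) | x != round(x) | x < 0)
    if (length(bad)) {
        rc <- which(counts != 0, arr.ind = TRUE)[bad[1], ]
        stop(sprintf("non-integer count at gene row %d, cell column %d",
                     rc[1], rc[2]))
    }
    invisible(TRUE)
}

# fixed, case-insensitive gene-class alias table; unknowns demote to "other"
.CLASS_ALIASES <- c(
    v1r = "V1R", vmn1r = "V1R", vomeronasal_type1 = "V1R",
    v2r = "V2R", vmn2r = "V2R", vomeronasal_type2 = "V2R",
    or = "OR", olfr = "OR", odorant_receptor = "OR", olfactory_receptor = "OR",
    fpr = "Fpr", formyl_peptide_receptor = "Fpr",
    tf = "TF", transcription_factor = "TF",
    ag = "AG", axon_guidance = "AG",
    other = "other"
)

.resolveGeneClass <- function(x) {
    key <- tolower(trimws(as.character(x)))
    out <- unname(.CLASS_ALIASES[key])
    unknown <- is.na(out)
    if (any(unknown)) {
        warning("unknown gene_class value(s) mapped to 'other': ",
                paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
        out[unknown] <- "other"
    }
    out
}

#' Read a gene annotation table
#'
#' Expects a TSV with header columns \code{gene_id}, \code{gene_class},
#' \code{chromosome}, \code{start_bp}, \code{end_bp}; \code{symbol},
#' \code{pseudogene} and \code{protein_seq} are optional. Class labels are
#' resolved through a fixed case-insensitive alias table (e.g.
#' \code{"axon_guidance"} maps to \code{AG}); unknown labels demote to
#' \code{other} with a warning so partial annotations remain usable.
#'
#' @param path TSV file.
#' @return a \link[S4Vectors]{DataFrame} keyed by \code{gene_id} with 1-based
#'   inclusive coordinates.
#' @export
readGeneAnnotation <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene_id", "gene_class", "chromosome", "start_bp", "end_bp")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("annotation is missing required column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(tab$gene_id))
        stop("duplicated gene_id in annotation: ",
             paste(unique(tab$gene_id[duplicated(tab$gene_id)]),
                   collapse = ", "))
    start <- as.integer(tab$start_bp); end <- as.integer(tab$end_bp)
    if (any(is.na(start) | is.na(end) | start < 1L))
        stop("start_bp/end_bp must be integers >= 1")
    bad <- which(start > end)
    if (length(bad))
        stop("start_bp > end_bp for gene(s): ",
             paste(tab$gene_id[bad], collapse = ", "))
    pseudo <- if ("pseudogene" %in% names(tab)) {
        tolower(as.character(tab$pseudogene)) %in% c("true", "t", "1", "yes")
    } else rep(FALSE, nrow(tab))
    S4Vectors::DataFrame(
        gene_id = tab$gene_id,
        symbol = if ("symbol" %in% names(tab)) tab$symbol else tab$gene_id,
        gene_class = .resolveGeneClass(tab$gene_class),
        chromosome = as.character(tab$chromosome),
        start_bp = start,
        end_bp = end,
        pseudogene = pseudo,
        row.names = tab$gene_id)
}

#' Read per-cell metadata
#'
#' TSV with a \code{barcode} column plus any of \code{cell_type},
#' \code{age_group}, \code{sex}, \code{sample_id}, \code{x_px}, \code{y_px},
#' \code{prediction_score}, \code{exclude}.
#'
#' @param path TSV file.
#' @return a \link[S4Vectors]{DataFrame} keyed by barcode.
#' @export
readCellMetadata <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!"barcode" %in% names(tab))
        stop("cell metadata must have a 'barcode' column")
    if (anyDuplicated(tab$barcode))
        stop("duplicated barcodes in cell metadata")
    if ("prediction_score" %in% names(tab)) {
        ps <- tab$prediction_score
        if (any(!is.na(ps) & (ps < 0 | ps > 1)))
            stop("prediction_score must lie in [0, 1]")
    }
    if ("age_group" %in% names(tab)) {
        bad <- !tab$age_group %in% c("P14", "P56", "unknown")
        if (any(bad)) tab$age_group[bad] <- "unknown"
    }
    S4Vectors::DataFrame(tab, row.names = tab$barcode)
}

#' Assemble a fully annotated experiment
#'
#' Attaches a gene annotation and cell metadata to a count
#' SingleCellExperiment, matching by gene id and barcode. Genes absent from
#' the annotation are kept with class \code{other}; cells absent from the
#' metadata get \code{unknown} labels.
#'
#' @param sce SingleCellExperiment from [readCountMatrix()] or
#'   [simulateCounts()].
#' @param annotation DataFrame from [readGeneAnnotation()].
#' @param cells optional DataFrame from [readCellMetadata()].
#' @return the annotated SingleCellExperiment.
#' @export
makeVNOExperiment <- function(sce, annotation, cells = NULL) {
    ids <- rownames(sce)
    hit <- match(ids, rownames(annotation))
    if (anyNA(hit))
        warning(sum(is.na(hit)),
                " gene(s) absent from the annotation kept with class 'other'")
    rd <- S4Vectors::DataFrame(
        gene_id = ids,
        symbol = ifelse(is.na(hit), ids, annotation$symbol[hit]),
        gene_class = ifelse(is.na(hit), "other", annotation$gene_class[hit]),
        chromosome = ifelse(is.na(hit), NA_character_,
                            annotation$chromosome[hit]),
        start_bp = ifelse(is.na(hit), NA_integer_, annotation$start_bp[hit]),
        end_bp = ifelse(is.na(hit), NA_integer_, annotation$end_bp[hit]),
        pseudogene = ifelse(is.na(hit), FALSE, annotation$pseudogene[hit]),
        row.names = ids)
    SummarizedExperiment::rowData(sce) <- rd
    if (!is.null(cells)) {
        chit <- match(colnames(sce), rownames(cells))
        cd <- cells[ifelse(is.na(chit), 1L, chit), , drop = FALSE]
        for (col in names(cd)) cd[[col]][is.na(chit)] <- NA
        cd$barcode <- colnames(sce)
        rownames(cd) <- colnames(sce)
        SummarizedExperiment::colData(sce) <- cd
    }
    sce
}
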