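# independent oracles and tiny in-code fixtures shared across the suite

# brute-force one-sided Fisher p: sum hypergeometric masses over the
# enrichment tail using binomial coefficients only
fisherOracle <- function(n11, n10, n01, n00) {
    ka <- n11 + n10; kb <- n11 + n01; N <- n11 + n10 + n01 + n00
    ks <- n11:min(ka, kb)
    sum(choose(ka, ks) * choose(N - ka, kb - ks)) / choose(N, kb)
}

# textbook BH step-up, written independently of stats::p.adjust
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
}

# hand-built experiment: explicit counts, annotation, cells
tinyExperiment <- function(counts, classes = NULL, chromosomes = NULL,
                           starts = NULL, cells = NULL) {
    genes <- rownames(counts)
    if (is.null(classes)) classes <- rep("V1R", length(genes))
    if (is.null(chromosomes)) chromosomes <- rep("chr1", length(genes))
    if (is.null(starts)) starts <- seq(1e6, by = 5e6,
                                       length.out = length(genes))
    ann <- S4Vectors::DataFrame(
        gene_id = genes, symbol = genes, gene_class = classes,
        chromosome = chromosomes, start_bp = as.integer(starts),
        end_bp = as.integer(starts + 999), pseudogene = FALSE,
        row.names = genes)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(as.matrix(counts),
                                           "CsparseMatrix")),
        rowData = ann)
    if (!is.null(cells)) SummarizedExperiment::colData(sce) <- cells
    sce
}

# a matrix with named dims from a plain vector spec
cmat <- function(..., nrow, genes = NULL, cells = NULL) {
    m <- matrix(c(...), nrow = nrow, byrow = TRUE)
    rownames(m) <- if (is.null(genes)) sprintf("V1R_%03d", seq_len(nrow(m)))
                   else genes
    colnames(m) <- if (is.null(cells)) sprintf("cell_%03d", seq_len(ncol(m)))
                   else cells
    m
}

# truth used by several recovery tests: single receptor class, no panels
pairRecoveryTruth <- function(seed, nReceptors = 60L, nPairs = 12L,
                              nSame = 8L, coProb = 0.8) {
    SyntheticTruth(
        nReceptorsPerClass = c(V1R = nReceptors),
        plantedPairs = makePlantedPairs(c(V1R = nReceptors), nPairs = nPairs,
                                        nSameChromosome = nSame,
                                        coProb = coProb),
        codeMap = list(), nTF = 2L, nAG = 2L, seed = seed)
}

# truth for code-recovery: coded receptors, no planted receptor pairs
codeRecoveryTruth <- function(seed, nReceptors = 20L, blocks = NULL) {
    ids <- sprintf("V1R_%03d", seq_len(nReceptors))
    SyntheticTruth(
        nReceptorsPerClass = c(V1R = nReceptors),
        plantedPairs = data.frame(receptor_a = character(),
                                  receptor_b = character(),
                                  co_prob = numeric(),
                                  same_chromosome = logical()),
        codeMap = makeCodeMap(ids, nTF = 40L, nAG = 60L, blocks = blocks),
        nTF = 40L, nAG = 60L, seed = seed)
}
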