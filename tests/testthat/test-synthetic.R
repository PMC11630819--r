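test_that("generators are deterministic given the truth's seed", {
    t1 <- SyntheticTruth(seed = 42)
    t2 <- SyntheticTruth(seed = 42)
    expect_identical(as.data.frame(generateAnnotation(t1)),
                     as.data.frame(generateAnnotation(t2)))
    a <- simulateCounts(t1, 200); b <- simulateCounts(t2, 200)
    expect_identical(as.matrix(SummarizedExperiment::assay(a)),
                     as.matrix(SummarizedExperiment::assay(b)))
    ca <- simulateSpatial(t1, SummarizedExperiment::colData(a))
    cb <- simulateSpatial(t2, SummarizedExperiment::colData(b))
    expect_identical(ca$x_px, cb$x_px)
    expect_identical(ca$y_px, cb$y_px)
})

test_that("planted pair layout respects chromosome structure", {
    truth <- SyntheticTruth(seed = 5)
    ann <- generateAnnotation(truth)
    pp <- truth@plantedPairs
    chr <- function(g) ann[g, "chromosome"]
    mid <- function(g) (ann[g, "start_bp"] + ann[g, "end_bp"]) / 2
    same <- pp$same_chromosome
    expect_true(all(chr(pp$receptor_a[same]) == chr(pp$receptor_b[same])))
    expect_true(all(abs(mid(pp$receptor_a[same]) - mid(pp$receptor_b[same]))
                    < 1e6))
    expect_true(all(chr(pp$receptor_a[!same]) != chr(pp$receptor_b[!same])))

    one <- SyntheticTruth(
        seed = 5, nChromosomes = 1,
        plantedPairs = makePlantedPairs(c(V1R = 60L), nSameChromosome = 12L))
    expect_identical(unique(generateAnnotation(one)$chromosome), "chr1")
})

test_that("invalid planted configurations are rejected", {
    expect_error(SyntheticTruth(
        nReceptorsPerClass = c(V1R = 4L),
        plantedPairs = data.frame(receptor_a = "V1R_009",
                                  receptor_b = "V1R_010",
                                  co_prob = 1, same_chromosome = TRUE),
        codeMap = list()), "not generated")
    expect_error(SyntheticTruth(composition = c(GBC = 0.5, INP = 0.4)),
                 "sum to 1")
    expect_error(SyntheticTruth(captureRate = 0), "captureRate")
})

test_that("noise-free limit gives exactly one well-expressed receptor per cell", {
    truth <- SyntheticTruth(
        nReceptorsPerClass = c(V1R = 30L),
        plantedPairs = data.frame(receptor_a = character(),
                                  receptor_b = character(),
                                  co_prob = numeric(),
                                  same_chromosome = logical()),
        codeMap = list(), nTF = 2L, nAG = 2L,
        ambientRate = 0, captureRate = 1, seed = 9)
    sce <- simulateCounts(truth, 800)
    cd <- SummarizedExperiment::colData(sce)
    rec <- as.matrix(SummarizedExperiment::assay(sce)[
        SummarizedExperiment::rowData(sce)$gene_class == "V1R", ])
    bearing <- !is.na(cd$primary_receptor)
    expect_true(all(colSums(rec[, bearing] > 0) == 1))
    expect_true(all(colSums(rec[, !bearing]) == 0))
    # NB(mu = 60, size = 5) mass below 10 is ~2e-4: essentially all >= 10
    expect_gte(mean(colSums(rec[, bearing] >= 10) == 1), 0.99)
    # detection bookkeeping matches the planted allocation exactly
    summ <- summarizeReceptors(sce, "V1R")
    alloc <- table(factor(cd$primary_receptor, levels = summ$gene_id))
    expect_identical(summ$n_cells_expressing, as.integer(alloc))
})

test_that("a co_prob = 1 pair co-occurs in every choosing cell (no thinning)", {
    truth <- SyntheticTruth(
        nReceptorsPerClass = c(V1R = 20L),
        plantedPairs = data.frame(receptor_a = "V1R_001",
                                  receptor_b = "V1R_002",
                                  co_prob = 1, same_chromosome = TRUE),
        codeMap = list(), nTF = 2L, nAG = 2L,
        ambientRate = 0, captureRate = 1, seed = 4)
    sce <- simulateCounts(truth, 600)
    cd <- SummarizedExperiment::colData(sce)
    counts <- SummarizedExperiment::assay(sce)
    chooses <- !is.na(cd$primary_receptor) &
               cd$primary_receptor %in% c("V1R_001", "V1R_002")
    n11 <- sum(counts["V1R_001", ] > 0 & counts["V1R_002", ] > 0)
    expect_identical(n11, sum(chooses))
})

test_that("primary choice frequencies follow the planted power law", {
    truth <- SyntheticTruth(
        alpha = 1, nReceptorsPerClass = c(V1R = 100L),
        plantedPairs = data.frame(receptor_a = character(),
                                  receptor_b = character(),
                                  co_prob = numeric(),
                                  same_chromosome = logical()),
        codeMap = list(), nTF = 2L, nAG = 2L,
        composition = c(`mVSN-V1R` = 1), seed = 17)
    sce <- simulateCounts(truth, 50000)
    prim <- SummarizedExperiment::colData(sce)$primary_receptor
    n <- length(prim)
    p <- (1 / 1:100) / sum(1 / 1:100)
    phat <- as.vector(table(factor(prim, sprintf("V1R_%03d", 1:100)))) / n
    se <- sqrt(p * (1 - p) / n)
    z <- abs(phat - p) / se
    expect_gte(mean(z <= 3), 0.95)   # per-rank 3-SE band, multinomial noise
    expect_lt(max(z), 5)
})

test_that("expected receptor counts per cell are conserved through the noise chain", {
    truth <- SyntheticTruth(seed = 11)
    sce <- simulateCounts(truth, 20000)
    cd <- SummarizedExperiment::colData(sce)
    ann <- SummarizedExperiment::rowData(sce)
    rec <- SummarizedExperiment::assay(sce)[
        ann$gene_class %in% names(truth@nReceptorsPerClass), ]
    nRec <- sum(truth@nReceptorsPerClass)
    expected <- truth@captureRate *
        (truth@primaryMean * mean(!is.na(cd$primary_receptor)) +
         truth@partnerMean * mean(!is.na(cd$partner_receptor)) +
         nRec * truth@ambientRate)
    observed <- mean(Matrix::colSums(rec))
    expect_lt(abs(observed - expected) / expected, 0.01)
})

test_that("spatial placement follows the closed-form enrichment rule", {
    base <- SyntheticTruth(seed = 21)
    cells <- S4Vectors::DataFrame(
        barcode = sprintf("c%04d", 1:4000),
        cell_type = rep(c("GBC", "mVSN-V1R"), c(800, 3200)))

    # null: no type enriched -> marginal fraction matches area fraction
    null <- SyntheticTruth(seed = 21, zoneEnrichment = c(GBC = 1))
    cd0 <- simulateSpatial(null, cells)
    lm <- vomeroseq:::.defaultLandmarks(6000)
    f <- marginalAreaFraction(6000, 3000, lm)
    d0 <- vomeroseq:::.nearestLandmarkDistance(cbind(cd0$x_px, cd0$y_px), lm)
    byType <- tapply(d0 <= 750, cd0$cell_type, mean)
    expect_true(all(abs(byType - f) < 3 * sqrt(f * (1 - f) / 800)))

    # planted 3x enrichment: marginal fraction = q + (1 - q) f with
    # q = f(e - 1)/(1 - f)
    enr <- SyntheticTruth(seed = 22, zoneEnrichment = c(GBC = 3))
    cd1 <- simulateSpatial(enr, cells)
    d1 <- vomeroseq:::.nearestLandmarkDistance(cbind(cd1$x_px, cd1$y_px), lm)
    q <- f * (3 - 1) / (1 - f)
    target <- q + (1 - q) * f
    got <- mean((d1 <= 750)[cd1$cell_type == "GBC"])
    expect_lt(abs(got - target), 3 * sqrt(target * (1 - target) / 800))

    expect_error(simulateSpatial(base, cells, width = 2000, height = 2000),
                 "degenerate")
    expect_error(simulateSpatial(base, cells, landmarks = matrix(0, 0, 2)),
                 "landmark")
})

test_that("simulated receptor sequences carry family structure", {
    ids <- sprintf("V1R_%03d", 1:12)
    seqs <- simulateReceptorSequences(ids, nFamilies = 3, seed = 2)
    sim <- similarityValues(sequenceSimilarity(seqs))
    fam <- attr(seqs, "family")
    same <- outer(fam, fam, "==") & upper.tri(sim)
    diff <- !outer(fam, fam, "==") & upper.tri(sim)
    expect_gt(min(sim[same]), max(sim[diff]))
})
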