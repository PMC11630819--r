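# a small experiment with explicit receptor / TF / AG structure
codeFixture <- function() {
    # 2 receptors, 2 TFs, 2 AGs over 8 cells
    m <- rbind(
        R1 = c(20, 20, 20, 0, 0, 0, 0, 0),
        R2 = c(0, 0, 0, 0, 20, 20, 20, 0),
        T1 = c(5, 5, 5, 0, 0, 0, 0, 0),    # exactly R1's cells
        T2 = c(2, 2, 2, 2, 2, 2, 2, 2),    # always below the >= 3 threshold
        A1 = c(5, 5, 0, 0, 0, 0, 0, 0),
        A2 = c(0, 5, 5, 5, 0, 0, 0, 0))
    colnames(m) <- paste0("c", 1:8)
    tinyExperiment(m, classes = c("V1R", "V1R", "TF", "TF", "AG", "AG"))
}

test_that("association tables apply the panel threshold exclusively below 3", {
    sce <- codeFixture()
    aTF <- buildAssociation(sce, "V1R", "TF")
    # T2 never reaches 3 counts: never present, every test p = 1
    expect_equal(unname(pValues(aTF)[, "T2"]), c(1, 1))
    # T1 covers exactly R1's presence cells: minimal p in R1's row
    expect_identical(names(which.min(pValues(aTF)["R1", ])), "T1")
    expect_lt(pValues(aTF)["R1", "T1"], pValues(aTF)["R2", "T1"])
    expect_true(all(pAdjusted(aTF) >= pValues(aTF) - 1e-12, na.rm = TRUE))
})

test_that("association Fisher p agrees with the pairwise-test machinery", {
    sce <- codeFixture()
    aTF <- buildAssociation(sce, "V1R", "TF")
    counts <- SummarizedExperiment::assay(sce)
    rp <- counts["R1", ] >= 10
    tp <- counts["T1", ] >= 3
    n11 <- sum(rp & tp); n10 <- sum(rp & !tp)
    n01 <- sum(!rp & tp); n00 <- sum(!rp & !tp)
    expect_equal(pValues(aTF)["R1", "T1"],
                 fisherEnrichmentP(n11, n10, n01, n00), tolerance = 1e-14)
    expect_equal(pValues(aTF)["R1", "T1"],
                 fisher.test(matrix(c(n11, n10, n01, n00), 2),
                             alternative = "greater")$p.value,
                 tolerance = 1e-12)
})

test_that("receptors with no presence cells are flagged, not tested", {
    m <- cmat(20, 20, 0, 0,
              5, 5, 5, 5, nrow = 2)   # second receptor never reaches 10
    sce <- tinyExperiment(rbind(m, T1 = c(4, 4, 0, 0)),
                          classes = c("V1R", "V1R", "TF"))
    aTF <- buildAssociation(sce, "V1R", "TF")
    expect_identical(aTF@flaggedReceptors, "V1R_002")
    expect_true(all(is.na(pValues(aTF)["V1R_002", ])))
})

test_that("profile correlation recognizes identity and anti-correlation", {
    M <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
               c = c(4, 3, 2, 1), d = c(5, 5, 5, 5))
    assoc <- methods::new("AssociationTable",
        meanExpr = M, pValue = M * 0 + 0.5, pAdjusted = M * 0 + 0.5,
        panel = "TF", receptorThreshold = 10L, panelThreshold = 3L,
        flaggedReceptors = character())
    cc <- profileCorrelation(assoc)
    v <- similarityValues(cc)
    expect_equal(v["a", "b"], 1)
    expect_equal(v["a", "c"], -1)
    expect_identical(cc@flagged, "d")       # zero-variance profile excluded
    expect_equal(unname(diag(v)), rep(1, 3))

    flat <- methods::new("AssociationTable",
        meanExpr = M[c("d", "d"), ], pValue = M[1:2, ] * 0 + 0.5,
        pAdjusted = M[1:2, ] * 0 + 0.5, panel = "TF",
        receptorThreshold = 10L, panelThreshold = 3L,
        flaggedReceptors = character())
    expect_error(profileCorrelation(flat), "undefined")
})

test_that("sequence identity matches hand-countable alignments", {
    seqs <- Biostrings::AAStringSet(c(a = "AAAA", b = "AATA", c = "AAAA"))
    sim <- similarityValues(sequenceSimilarity(seqs))
    expect_equal(sim["a", "c"], 100)
    expect_equal(sim["a", "b"], 75)
    expect_equal(unname(diag(sim)), rep(100, 3))
    expect_equal(sim, t(sim))
    expect_error(sequenceSimilarity(Biostrings::AAStringSet("AAAA")),
                 "at least 2")
    expect_error(sequenceSimilarity(c(a = "AAAA", b = "")), "empty")
})

test_that("shuffling a sequence lowers its self-identity", {
    seqs <- simulateReceptorSequences("V1R_001", nFamilies = 1,
                                      length = 200, seed = 8)
    ref <- as.character(seqs[[1]])
    set.seed(8)
    below <- replicate(100, {
        shuf <- paste(sample(strsplit(ref, "")[[1]]), collapse = "")
        s <- sequenceSimilarity(c(a = ref, b = shuf))
        similarityValues(s)["a", "b"] < 100
    })
    expect_gte(mean(below), 0.95)
})

test_that("similarity relation recovers identity and null relations", {
    set.seed(12)
    n <- 50
    ids <- sprintf("r%02d", 1:n)
    A <- matrix(runif(n * n, 0, 100), n, dimnames = list(ids, ids))
    A <- (A + t(A)) / 2; diag(A) <- 100
    mkSim <- function(v, kind) methods::new("SimilarityMatrix", values = v,
                                            kind = kind, flagged = character())
    self <- similarityRelation(mkSim(A, "sequence"),
                               mkSim(A / 100, "ag_profile"))
    expect_equal(self$spearman_rho, 1)

    B <- matrix(runif(n * n, -1, 1), n, dimnames = list(ids, ids))
    B <- (B + t(B)) / 2; diag(B) <- 1
    null <- similarityRelation(mkSim(A, "sequence"), mkSim(B, "ag_profile"))
    expect_lt(abs(null$spearman_rho), 0.1)
    expect_identical(sum(null$by_profile_bin$n), null$n_pairs)

    C <- B[1:10, 1:10]
    expect_error(similarityRelation(mkSim(A, "sequence"),
                                    mkSim(C, "ag_profile")),
                 "different receptor sets")
})

test_that("Jaccard grids hit exact closed-form values", {
    # within R's 5 presence cells: T covers c1..c3, A1 covers c2..c4,
    # A2 covers c1..c3 (identical to T), A3 covers c4..c5 (disjoint from T)
    m <- rbind(
        R = c(20, 20, 20, 20, 20, 0),
        T1 = c(5, 5, 5, 0, 0, 5),
        A1 = c(0, 5, 5, 5, 0, 0),
        A2 = c(5, 5, 5, 0, 0, 0),
        A3 = c(0, 0, 0, 5, 5, 5))
    colnames(m) <- paste0("c", 1:6)
    sce <- tinyExperiment(m, classes = c("V1R", "TF", "AG", "AG", "AG"))
    aTF <- buildAssociation(sce, "V1R", "TF")
    aAG <- buildAssociation(sce, "V1R", "AG")
    g <- tfAgJaccard(sce, aTF, aAG, "R", alpha = 1)  # keep all genes in grid
    J <- jaccardValues(g)
    expect_equal(J["T1", "A1"], 0.5)      # {c1,c2,c3} vs {c2,c3,c4}: 2/4
    expect_equal(J["T1", "A2"], 1)        # identical sets
    expect_equal(J["T1", "A3"], 0)        # disjoint within presence cells
    expect_true(all(J >= 0 & J <= 1))
    expect_identical(g@nCells, 5L)
})

test_that("receptors without significant partners give an empty flagged grid", {
    sce <- codeFixture()
    aTF <- buildAssociation(sce, "V1R", "TF")
    aAG <- buildAssociation(sce, "V1R", "AG")
    g <- tfAgJaccard(sce, aTF, aAG, "R2", alpha = 1e-6)
    expect_identical(dim(jaccardValues(g)), c(0L, 0L))
    expect_error(tfAgJaccard(sce, aTF, aAG, "nope"), "not a row")
})

test_that("combined receptor-type correlation concatenates both panels", {
    M <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 1, 2))
    mkA <- function(M, panel) methods::new("AssociationTable",
        meanExpr = M, pValue = M * 0 + 0.5, pAdjusted = M * 0 + 0.5,
        panel = panel, receptorThreshold = 10L, panelThreshold = 3L,
        flaggedReceptors = character())
    cc <- receptorTypeCorrelation(mkA(M, "TF"), mkA(M * 2, "AG"))
    expect_equal(similarityValues(cc)["a", "b"], 1)   # duplicate profiles
    expect_identical(similarityKind(cc), "combined")

    emptyAG <- mkA(M[, 0, drop = FALSE], "AG")
    expect_warning(cc2 <- receptorTypeCorrelation(mkA(M, "TF"), emptyAG),
                   "falling back")
    expect_equal(similarityValues(cc2)["a", "b"], 1)
})
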