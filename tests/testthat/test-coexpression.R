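test_that("presence thresholds are boundary-inclusive and retention filters apply", {
    m <- cmat(9, 10, 11, 0, 0, 0,
              10, 10, 10, 10, 0, 0,
              1, 1, 1, 1, 1, 0, nrow = 3)
    pres <- binarizePresence(tinyExperiment(m), "V1R",
                             countThreshold = 10, minCells = 5)
    P <- as.matrix(presence(pres))
    expect_identical(sum(P["V1R_001", ]), 2L)          # 10 and 11, not 9
    expect_identical(sum(P["V1R_002", ]), 4L)
    expect_identical(retainedReceptors(pres), character(0))  # 2 and 4 < 5

    pres2 <- binarizePresence(tinyExperiment(m), "V1R",
                              countThreshold = 1, minCells = 1)
    expect_identical(unname(as.matrix(presence(pres2))), unname(m >= 1))
    expect_error(binarizePresence(tinyExperiment(m), "V1R",
                                  countThreshold = 0), "countThreshold")
})

test_that("Shannon index matches closed forms and bounds", {
    m <- cmat(10, 10, 5, 0,
              10, 0, 3, 0,
              0, 0, 2, 0, nrow = 3)
    st <- shannonPerCell(tinyExperiment(m), "V1R")
    expect_equal(st$shannon_H[1], log(2), tolerance = 1e-12)  # (10,10)
    expect_equal(st$shannon_H[2], 0)                          # single species
    expect_equal(st$shannon_H[3], 1.0297, tolerance = 1e-4)   # (5,3,2)
    expect_true(is.na(st$shannon_H[4]) && st$no_receptor_counts[4])
    # dominance shares
    expect_equal(st$top1_share[3], 0.5)
    expect_equal(st$top2_share[3], 0.3)
    expect_equal(st$top3_share[3], 0.2)
    expect_true(all(st$top1_share >= st$top2_share, na.rm = TRUE))
})

test_that("Shannon H is bounded by ln(k) with exact equality cases", {
    set.seed(31)
    for (i in 1:25) {
        k <- sample(2:8, 1)
        v <- matrix(rpois(k, 20) + 1L, ncol = 1,
                    dimnames = list(sprintf("V1R_%03d", 1:k), "c1"))
        H <- shannonPerCell(tinyExperiment(v), "V1R")$shannon_H
        expect_lte(H, log(k) + 1e-12)
        expect_gte(H, 0)
    }
    u <- matrix(rep(7L, 5), ncol = 1,
                dimnames = list(sprintf("V1R_%03d", 1:5), "c1"))
    expect_equal(shannonPerCell(tinyExperiment(u), "V1R")$shannon_H, log(5))
})

test_that("multiplicity fractions sum to one per group", {
    m <- cmat(rep(c(10, 0), c(10, 10)),
              rep(0, 20), nrow = 2)
    cells <- S4Vectors::DataFrame(
        barcode = colnames(m),
        cell_type = rep(c("iVSN", "mVSN-V1R"), each = 10),
        row.names = colnames(m))
    pres <- binarizePresence(tinyExperiment(m), "V1R", minCells = 1)
    tab <- multiplicityTable(pres, cells)
    expect_equal(tab$frac_1[tab$group == "iVSN"], 1)
    expect_equal(tab$frac_0[tab$group == "mVSN-V1R"], 1)
    sums <- rowSums(tab[, c("frac_0", "frac_1", "frac_2", "frac_3plus")])
    expect_equal(unname(sums), rep(1, nrow(tab)))
    expect_error(multiplicityTable(pres, cells, groupBy = "sex"),
                 "unknown grouping")
    # empty factor level reported flagged, not dropped
    cells$cell_type <- factor(cells$cell_type,
                              levels = c("iVSN", "mVSN-V1R", "GBC"))
    tab2 <- multiplicityTable(pres, cells)
    expect_true(tab2$empty_group[tab2$group == "GBC"])
    expect_true(is.na(tab2$frac_1[tab2$group == "GBC"]))
})

test_that("pairwise Fisher matches hand-enumerated hypergeometric cases", {
    # A in 3 cells, B in the disjoint other 3: enrichment tail covers all
    m <- cmat(10, 10, 10, 0, 0, 0,
              0, 0, 0, 10, 10, 10, nrow = 2)
    pres <- binarizePresence(tinyExperiment(m), "V1R", minCells = 1)
    res <- pairwiseFisher(pres)
    expect_equal(res$p_value, 1)
    expect_identical(res$n11, 0L)
    expect_equal(res$odds_ratio, 0)

    # identical supports: p = 1 / C(6,3) = 0.05
    m2 <- cmat(10, 10, 10, 0, 0, 0,
               10, 10, 10, 0, 0, 0, nrow = 2)
    pres2 <- binarizePresence(tinyExperiment(m2), "V1R", minCells = 1)
    res2 <- pairwiseFisher(pres2)
    expect_equal(res2$p_value, 0.05, tolerance = 1e-12)
    expect_identical(res2$n11, 3L)
    expect_equal(res2$odds_ratio, Inf)
})

test_that("pairwise Fisher agrees with fisher.test across random tables", {
    set.seed(7)
    m <- matrix(rpois(30 * 120, 4), nrow = 30,
                dimnames = list(sprintf("V1R_%03d", 1:30),
                                sprintf("c%03d", 1:120)))
    pres <- binarizePresence(tinyExperiment(m), "V1R",
                             countThreshold = 5, minCells = 1)
    res <- pairwiseFisher(pres)
    idx <- seq(1, nrow(res), by = 17)
    for (i in idx) {
        ft <- fisher.test(matrix(c(res$n11[i], res$n10[i],
                                   res$n01[i], res$n00[i]), 2),
                          alternative = "greater")
        expect_equal(res$p_value[i], ft$p.value, tolerance = 1e-9)
    }
    expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
    # marginals conserved
    expect_true(all(res$n11 + res$n10 + res$n01 + res$n00 == 120L))
})

test_that("BH adjustment reproduces the hand-evaluated step-up case", {
    res <- data.frame(p_value = c(0.01, 0.02, 0.03, 0.04))
    expect_equal(vomeroseq:::.adjustBH(res$p_value), rep(0.04, 4))
})

test_that("colocalization summary handles empty and forced cases", {
    empty <- data.frame(gene_a = character(), gene_b = character(),
                        n11 = integer(), p_adjusted = numeric(),
                        same_chromosome = logical(),
                        genomic_distance_bp = numeric())
    out <- genomicColocalization(empty)
    expect_true(out$no_significant_pairs)
    expect_true(is.na(out$fraction_same_chromosome))

    res <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                      n11 = c(5L, 4L), p_adjusted = c(0.01, 0.002),
                      same_chromosome = c(TRUE, TRUE),
                      genomic_distance_bp = c(1e5, 2e5))
    out2 <- genomicColocalization(res)
    expect_equal(out2$fraction_same_chromosome, 1)
    expect_identical(out2$n_significant, 2L)
})

test_that("immature cells co-express more receptors than mature cells", {
    pooled <- sapply(1:6, function(s) {
        truth <- pairRecoveryTruth(seed = s)
        sce <- simulateCounts(truth, 1500)
        pres <- binarizePresence(sce, "V1R")
        cd <- SummarizedExperiment::colData(sce)
        tab <- multiplicityTable(pres, cd, "cell_type")
        two <- function(g) sum(tab[tab$group == g, c("frac_2", "frac_3plus")])
        c(imm = two("iVSN"), mat = two("mVSN-V1R"))
    })
    expect_gte(sum(pooled["imm", ] > pooled["mat", ]), 5)
    expect_gt(mean(pooled["imm", ]), mean(pooled["mat", ]))
})
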