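#' Generate a gene annotation with planted genomic structure
#'
#' Receptors are laid out along \code{nChromosomes} chromosomes so that
#' planted same-chromosome pairs sit within 1 Mb of each other while
#' cross-chromosome pairs land on distinct chromosomes; remaining receptors
#' rotate across chromosomes at > 1 Mb spacing. TF and AG panel genes are
#' placed uniformly. Deterministic given the truth's seed.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param geneLength generated gene length in bp.
#' @param pairGap separation of planted same-chromosome pair members (bp,
#'   < 1 Mb).
#' @param interGeneGap separation of unrelated receptors on a chromosome.
#' @return annotation \link[S4Vectors]{DataFrame} keyed by gene_id
#'   (columns gene_id, symbol, gene_class, chromosome, start_bp, end_bp,
#'   pseudogene).
#' @export
generateAnnotation <- function(truth, geneLength = 1000L, pairGap = 2e5,
                               interGeneGap = 2.5e6) {
    stopifnot(is(truth, "SyntheticTruth"))
    nChrom <- truth@nChromosomes
    chroms <- paste0("chr", seq_len(nChrom))
    nPer <- truth@nReceptorsPerClass
    pp <- truth@plantedPairs
    if (nrow(pp) && any(!pp$same_chromosome) && nChrom < 2L)
        stop("cross-chromosome planted pairs need nChromosomes >= 2")

    recIds <- .allReceptorIds(nPer)
    chrom <- stats::setNames(rep(NA_character_, length(recIds)), recIds)
    start <- stats::setNames(rep(NA_real_, length(recIds)), recIds)
    cursor <- stats::setNames(rep(1e6, nChrom), chroms)

    place <- function(id, ch, pos) {
        chrom[[id]] <<- ch
        start[[id]] <<- pos
    }
    if (nrow(pp)) {
        for (i in seq_len(nrow(pp))) {
            if (pp$same_chromosome[i] || nChrom == 1L) {
                ch <- chroms[(i - 1L) %% nChrom + 1L]
                place(pp$receptor_a[i], ch, cursor[[ch]])
                place(pp$receptor_b[i], ch, cursor[[ch]] + pairGap)
                cursor[[ch]] <- cursor[[ch]] + pairGap + interGeneGap
            } else {
                cha <- chroms[(i - 1L) %% nChrom + 1L]
                chb <- chroms[i %% nChrom + 1L]
                place(pp$receptor_a[i], cha, cursor[[cha]])
                cursor[[cha]] <- cursor[[cha]] + interGeneGap
                place(pp$receptor_b[i], chb, cursor[[chb]])
                cursor[[chb]] <- cursor[[chb]] + interGeneGap
            }
        }
    }
    rest <- recIds[is.na(chrom)]
    for (j in seq_along(rest)) {
        ch <- chroms[(j - 1L) %% nChrom + 1L]
        place(rest[j], ch, cursor[[ch]])
        cursor[[ch]] <- cursor[[ch]] + interGeneGap
    }

    recClass <- rep(names(nPer), nPer)
    recRank <- unlist(lapply(nPer, seq_len), use.names = FALSE)
    pseudo <- recRank > ceiling((1 - truth@pseudogeneFraction) * nPer[recClass])

    tfIds <- sprintf("TF_%03d", seq_len(truth@nTF))
    agIds <- sprintf("AG_%03d", seq_len(truth@nAG))
    nPanel <- length(tfIds) + length(agIds)
    panel <- .withSeed(truth@seed, data.frame(
        gene_id = c(tfIds, agIds),
        gene_class = rep(c("TF", "AG"), c(length(tfIds), length(agIds))),
        chromosome = sample(chroms, nPanel, replace = TRUE),
        start_bp = round(stats::runif(nPanel, 1e6, 1e8))))

    ids <- c(recIds, panel$gene_id)
    S4Vectors::DataFrame(
        gene_id = ids,
        symbol = ids,
        gene_class = c(recClass, panel$gene_class),
        chromosome = c(unname(chrom), panel$chromosome),
        start_bp = as.integer(c(unname(start), panel$start_bp)),
        end_bp = as.integer(c(unname(start), panel$start_bp) + geneLength - 1L),
        pseudogene = c(pseudo, rep(FALSE, nPanel)),
        row.names = ids)
}

# which receptor class a cell type draws its primary receptor from;
# progenitors (GBC, INP) express none
.receptorClassFor <- function(cellType, nPerClass, matureComp) {
    avail <- names(nPerClass)[nPerClass > 0]
    pickV <- function() {
        w <- matureComp[c("mVSN-V1R", "mVSN-V2R")]
        w[is.na(w)] <- 0
        cand <- c("V1R", "V2R")[c("V1R", "V2R") %in% avail]
        if (!length(cand)) return(sample(avail, 1L))
        if (length(cand) == 1L) return(cand)
        sample(cand, 1L, prob = (w + 1e-9)[c(1, 2)])
    }
    switch(cellType,
        "GBC" = NA_character_, "INP" = NA_character_,
        "mVSN-V1R" = if ("V1R" %in% avail) "V1R" else avail[1],
        "mVSN-V2R" = if ("V2R" %in% avail) "V2R" else avail[1],
        "iVSN" = pickV(),
        "sVSN" = if ("V1R" %in% avail) "V1R" else avail[1],
        "OSN" = if ("OR" %in% avail) "OR" else avail[1],
        avail[1])
}

#' Simulate a synthetic VNO count matrix with cell metadata
#'
#' Each receptor-bearing cell draws one primary receptor within its class
#' with probability proportional to rank^(-alpha); cells whose primary
#' belongs to a planted pair also express the partner with the planted
#' probability (multiplied for immature cells and P14 animals, capped at 1).
#' Primary/partner counts are negative-binomial with means well above the
#' presence threshold; every receptor additionally receives
#' Poisson(ambientRate) stray counts per cell; TF/AG genes wired to the
#' cell's primary receptor are Poisson at their planted means, all other
#' panel genes at the background mean; finally every count is thinned
#' binomially by the capture rate.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nCells number of cells (>= 1).
#' @param annotation optional annotation from [generateAnnotation()]
#'   (regenerated from the truth when omitted).
#' @return a \link[SingleCellExperiment]{SingleCellExperiment}; colData
#'   carries cell_type, age_group, sex, sample_id, prediction_score plus the
#'   generative bookkeeping columns primary_receptor and partner_receptor;
#'   \code{metadata()$truth} stores the truth object.
#' @export
simulateCounts <- function(truth, nCells, annotation = NULL) {
    stopifnot(is(truth, "SyntheticTruth"), nCells >= 1)
    if (is.null(annotation)) annotation <- generateAnnotation(truth)
    comp <- truth@composition
    if (abs(sum(comp) - 1) > 1e-6) stop("composition must sum to 1")
    nPer <- truth@nReceptorsPerClass
    genes <- rownames(annotation)
    recIds <- .allReceptorIds(nPer)
    tfag <- genes[annotation$gene_class %in% c("TF", "AG")]
    nCells <- as.integer(nCells)

    .withSeed(truth@seed + 1L, {
        barcodes <- sprintf("cell_%06d", seq_len(nCells))
        cellType <- sample(names(comp), nCells, replace = TRUE, prob = comp)
        age <- sample(c("P14", "P56"), nCells, replace = TRUE)
        sex <- sample(c("M", "F"), nCells, replace = TRUE)
        sampleId <- paste0(age, "_", sex)
        predScore <- ifelse(stats::runif(nCells) < 0.05,
                            stats::runif(nCells, 0, 0.3),
                            stats::rbeta(nCells, 8, 1.5))

        # primary receptor choice: rank^(-alpha) within the cell's class
        classProb <- lapply(stats::setNames(nm = names(nPer)), function(cl) {
            p <- seq_len(nPer[[cl]])^(-truth@alpha)
            p / sum(p)
        })
        cellClass <- vapply(cellType, .receptorClassFor, character(1),
                            nPerClass = nPer, matureComp = comp)
        primary <- rep(NA_character_, nCells)
        for (cl in names(nPer)) {
            idx <- which(!is.na(cellClass) & cellClass == cl)
            if (!length(idx)) next
            ranks <- sample.int(nPer[[cl]], length(idx), replace = TRUE,
                                prob = classProb[[cl]])
            primary[idx] <- receptorIdsFor(cl, nPer[[cl]])[ranks]
        }

        # planted partner expression, with immature/juvenile multipliers
        pp <- truth@plantedPairs
        partnerOf <- c(stats::setNames(pp$receptor_b, pp$receptor_a),
                       stats::setNames(pp$receptor_a, pp$receptor_b))
        coProbOf <- c(stats::setNames(pp$co_prob, pp$receptor_a),
                      stats::setNames(pp$co_prob, pp$receptor_b))
        partner <- rep(NA_character_, nCells)
        inPair <- !is.na(primary) & primary %in% names(partnerOf)
        if (any(inPair)) {
            pr <- coProbOf[primary[inPair]]
            mult <- ifelse(cellType[inPair] == "iVSN",
                           truth@immatureCoexMultiplier, 1) *
                    ifelse(age[inPair] == "P14",
                           truth@juvenileCoexMultiplier, 1)
            hit <- stats::runif(sum(inPair)) < pmin(1, pr * mult)
            partner[inPair][hit] <- partnerOf[primary[inPair][hit]]
        }

        # receptor counts: ambient everywhere + NB signal on primary/partner
        R <- length(recIds)
        rec <- matrix(if (truth@ambientRate > 0)
                          stats::rpois(R * nCells, truth@ambientRate)
                      else 0L, nrow = R, ncol = nCells,
                      dimnames = list(recIds, barcodes))
        pi <- which(!is.na(primary))
        rec[cbind(match(primary[pi], recIds), pi)] <-
            rec[cbind(match(primary[pi], recIds), pi)] +
            stats::rnbinom(length(pi), mu = truth@primaryMean,
                           size = truth@nbSize)
        qi <- which(!is.na(partner))
        if (length(qi))
            rec[cbind(match(partner[qi], recIds), qi)] <-
                rec[cbind(match(partner[qi], recIds), qi)] +
                stats::rnbinom(length(qi), mu = truth@partnerMean,
                               size = truth@nbSize)

        # panel genes: background Poisson, overwritten by planted programs
        P <- length(tfag)
        pan <- NULL
        if (P) {
            pan <- matrix(stats::rpois(P * nCells, truth@panelBackgroundMean),
                          nrow = P, ncol = nCells,
                          dimnames = list(tfag, barcodes))
            coded <- intersect(unique(primary[!is.na(primary)]),
                               names(truth@codeMap))
            for (r in coded) {
                cols <- which(!is.na(primary) & primary == r)
                prog <- truth@codeMap[[r]]
                means <- c(prog$tf, prog$ag)
                rows <- match(names(means), tfag)
                keep <- !is.na(rows)
                if (!any(keep)) next
                pan[rows[keep], cols] <- stats::rpois(
                    sum(keep) * length(cols), rep(means[keep], length(cols)))
            }
        }

        counts <- rbind(rec, pan)
        if (truth@captureRate < 1) {
            v <- as.integer(counts)
            counts[] <- stats::rbinom(length(v), v, truth@captureRate)
        }
        counts <- counts[match(genes, rownames(counts)), , drop = FALSE]
        rownames(counts) <- genes

        cd <- S4Vectors::DataFrame(
            barcode = barcodes, cell_type = cellType, age_group = age,
            sex = sex, sample_id = sampleId,
            x_px = NA_real_, y_px = NA_real_,
            prediction_score = pmin(1, predScore),
            primary_receptor = primary, partner_receptor = partner,
            row.names = barcodes)
        sce <- SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = methods::as(counts, "CsparseMatrix")),
            rowData = annotation, colData = cd)
        S4Vectors::metadata(sce)$truth <- truth
        sce
    })
}

#' Fraction of the field of view within the marginal zone
#'
#' Grid estimate of the area fraction lying within \code{r1} pixels of the
#' nearest boundary landmark; used by the spatial generator's closed-form
#' enrichment rule and by its recovery tests.
#'
#' @param width,height field of view in pixels.
#' @param landmarks two-column matrix/data.frame of boundary points.
#' @param r1 marginal-zone radius in pixels (default 750).
#' @param gridN grid resolution per axis.
#' @return a fraction in [0, 1].
#' @export
marginalAreaFraction <- function(width, height, landmarks, r1 = 750,
                                 gridN = 201L) {
    landmarks <- as.matrix(landmarks)
    gx <- seq(0, width, length.out = gridN)
    gy <- seq(0, height, length.out = gridN)
    pts <- cbind(rep(gx, times = gridN), rep(gy, each = gridN))
    d <- .nearestLandmarkDistance(pts, landmarks)
    mean(d <= r1)
}

.nearestLandmarkDistance <- function(pts, landmarks) {
    d2 <- outer(pts[, 1], landmarks[, 1], "-")^2 +
          outer(pts[, 2], landmarks[, 2], "-")^2
    sqrt(apply(d2, 1, min))
}

.defaultLandmarks <- function(width) {
    cbind(x = seq(0, width, length.out = 9L), y = 0)
}

#' Place synthetic cells in a tissue field with zone enrichment
#'
#' Cells are positioned uniformly over the field; cell types with a
#' marginal-zone enrichment multiplier e > 1 are instead placed inside the
#' marginal zone (within \code{r1} of the nearest landmark) with probability
#' \code{q = f(e - 1) / (1 - f)} where \code{f} is the marginal area
#' fraction, which multiplies their marginal-zone density by exactly e.
#'
#' @param truth a \linkS4class{SyntheticTruth} (supplies zoneEnrichment and
#'   the seed).
#' @param cells colData-like table with a \code{cell_type} column.
#' @param width,height field of view in pixels (must each be >= 2 * r2).
#' @param landmarks boundary points; default: nine points along the bottom
#'   edge, emulating the neural/non-neuronal boundary of a VNO section.
#' @param r1,r2 marginal and intermediate radii in pixels.
#' @return \code{cells} with \code{x_px}, \code{y_px} filled in.
#' @export
simulateSpatial <- function(truth, cells, width = 6000, height = 3000,
                            landmarks = NULL, r1 = 750, r2 = 1500) {
    stopifnot(is(truth, "SyntheticTruth"))
    if (is.null(landmarks)) landmarks <- .defaultLandmarks(width)
    landmarks <- as.matrix(landmarks)
    if (nrow(landmarks) < 1L) stop("at least one landmark is required")
    if (width < 2 * r2 || height < 2 * r2)
        stop("geometry smaller than 2 * r2: zones would degenerate")
    n <- nrow(cells)
    f <- marginalAreaFraction(width, height, landmarks, r1)
    enr <- truth@zoneEnrichment
    e <- ifelse(cells$cell_type %in% names(enr), enr[cells$cell_type], 1)
    q <- pmin(1, f * (e - 1) / (1 - f))

    .withSeed(truth@seed + 2L, {
        x <- stats::runif(n, 0, width)
        y <- stats::runif(n, 0, height)
        inMarg <- stats::runif(n) < q
        for (i in which(inMarg)) {
            for (tries in seq_len(10000L)) {
                px <- stats::runif(1, 0, width)
                py <- stats::runif(1, 0, height)
                if (.nearestLandmarkDistance(cbind(px, py), landmarks) <= r1) {
                    x[i] <- px; y[i] <- py
                    break
                }
            }
        }
        cells$x_px <- x
        cells$y_px <- y
        cells
    })
}

#' Simulate receptor protein sequences with family structure
#'
#' Draws one random ancestor per family and derives members by point
#' mutation, so within-family percent identity exceeds between-family
#' identity — a planted monotone structure for sequence-similarity
#' experiments.
#'
#' @param receptors character receptor ids (sequence names).
#' @param nFamilies number of families (round-robin membership).
#' @param length sequence length in residues.
#' @param divergence per-site mutation probability within a family.
#' @param seed RNG seed.
#' @return an \link[Biostrings]{AAStringSet} with a \code{family} attribute.
#' @export
simulateReceptorSequences <- function(receptors, nFamilies = 4L,
                                      length = 300L, divergence = 0.05,
                                      seed = 1L) {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    .withSeed(seed, {
        fam <- rep(seq_len(nFamilies), length.out = base::length(receptors))
        anc <- replicate(nFamilies, sample(aa, length, replace = TRUE),
                         simplify = FALSE)
        seqs <- vapply(seq_along(receptors), function(i) {
            s <- anc[[fam[i]]]
            mut <- stats::runif(length) < divergence
            s[mut] <- sample(aa, sum(mut), replace = TRUE)
            paste(s, collapse = "")
        }, character(1))
        out <- Biostrings::AAStringSet(stats::setNames(seqs, receptors))
        attr(out, "family") <- stats::setNames(fam, receptors)
        out
    })
}
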