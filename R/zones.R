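#' Assign cells to marginal / intermediate / main zones
#'
#' The distance of each cell to the nearest boundary landmark partitions
#' the tissue: within \code{r1} pixels (inclusive) is the marginal zone,
#' within \code{r2} (inclusive) the intermediate zone, beyond it the main
#' zone. Cells whose cell-type prediction score falls below
#' \code{scoreMin} are labelled \code{unknown} before zoning; cells flagged
#' in an \code{exclude} column (e.g. non-neuronal region) are labelled
#' \code{excluded}. Cells with missing coordinates get a per-cell error
#' note instead of aborting the run.
#'
#' @param cells table with barcode, x_px, y_px, optional prediction_score
#'   and exclude columns.
#' @param landmarks two-column matrix/data.frame of boundary points.
#' @param r1,r2 zone radii in pixels (defaults 750 and 1500; r1 < r2).
#' @param scoreMin minimal prediction score (default 0.3, inclusive).
#' @return data.frame: barcode, zone (marginal/intermediate/main/unknown/
#'   excluded), distance_px, note.
#' @export
assignZones <- function(cells, landmarks, r1 = 750, r2 = 1500,
                        scoreMin = 0.3) {
    landmarks <- as.matrix(landmarks)
    if (nrow(landmarks) < 1L) stop("at least one landmark is required")
    if (!(r1 < r2)) stop("r1 must be smaller than r2")
    n <- nrow(cells)
    x <- cells$x_px; y <- cells$y_px
    zone <- rep(NA_character_, n)
    note <- rep(NA_character_, n)
    dist <- rep(NA_real_, n)
    bad <- is.na(x) | is.na(y)
    note[bad] <- "missing coordinates"
    ok <- which(!bad)
    if (length(ok))
        dist[ok] <- .nearestLandmarkDistance(cbind(x[ok], y[ok]), landmarks)
    zone[!bad] <- ifelse(dist[!bad] <= r1, "marginal",
                  ifelse(dist[!bad] <= r2, "intermediate", "main"))
    if (!is.null(cells$prediction_score)) {
        low <- !is.na(cells$prediction_score) &
               cells$prediction_score < scoreMin
        zone[low & !bad] <- "unknown"
    }
    if (!is.null(cells$exclude)) {
        ex <- !is.na(cells$exclude) & as.logical(cells$exclude)
        zone[ex] <- "excluded"
    }
    data.frame(
        barcode = if (!is.null(cells$barcode)) cells$barcode
                  else rownames(cells),
        zone = zone, distance_px = dist, note = note, row.names = NULL)
}

#' Cell-type enrichment in the marginal zone
#'
#' For each focus cell type, a one-sided Fisher enrichment test of
#' (focus type vs all other types) x (marginal vs main zone), BH-adjusted
#' across the focus types. The intermediate zone is reported descriptively
#' but does not enter the test; unknown/excluded cells are ignored.
#'
#' @param assignments data.frame from [assignZones()].
#' @param cells table with barcode and cell_type.
#' @param focusTypes cell types to test (default: all types present).
#' @param alpha significance cutoff recorded in the output (default 0.05).
#' @return data.frame per focus type: n_marginal, n_intermediate, n_main,
#'   fraction_marginal, fraction_intermediate, fraction_main, odds_ratio,
#'   p_value, p_adjusted, significant, skipped.
#' @export
zoneEnrichment <- function(assignments, cells, focusTypes = NULL,
                           alpha = 0.05) {
    key <- if (!is.null(cells$barcode)) cells$barcode else rownames(cells)
    type <- cells$cell_type[match(assignments$barcode, key)]
    zone <- assignments$zone
    use <- zone %in% c("marginal", "intermediate", "main") & !is.na(type)
    zone <- zone[use]; type <- type[use]
    if (length(unique(zone)) < 2L)
        stop("need at least 2 populated zones")
    if (is.null(focusTypes)) focusTypes <- sort(unique(type))
    nMargAll <- sum(zone == "marginal")
    nMainAll <- sum(zone == "main")
    rows <- lapply(focusTypes, function(tp) {
        isT <- type == tp
        nm <- sum(isT & zone == "marginal")
        ni <- sum(isT & zone == "intermediate")
        nM <- sum(isT & zone == "main")
        tot <- nm + ni + nM
        skipped <- nMargAll == 0L || nMainAll == 0L
        p <- or <- NA_real_
        if (!skipped) {
            n11 <- nm; n10 <- nM
            n01 <- nMargAll - nm; n00 <- nMainAll - nM
            p <- fisherEnrichmentP(n11, n10, n01, n00)
            or <- .oddsRatio(n11, n10, n01, n00)
        }
        data.frame(cell_type = tp, n_marginal = nm, n_intermediate = ni,
                   n_main = nM,
                   fraction_marginal = if (tot) nm / tot else NA_real_,
                   fraction_intermediate = if (tot) ni / tot else NA_real_,
                   fraction_main = if (tot) nM / tot else NA_real_,
                   odds_ratio = or, p_value = p, skipped = skipped)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- .adjustBH(out$p_value)
    out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
    out
}
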