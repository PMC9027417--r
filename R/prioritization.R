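#' Per-cell group richness and the composite index
#'
#' For every cell, counts the species of each conservation group, converts
#' each count to the ratio of the group total (\eqn{r_{gc} = S_{gc}/N_g})
#' and sums the five ratios into the composite richness index \eqn{R_c}.
#' A group with no members contributes 0 everywhere, with a warning.
#'
#' @param incidence an [IncidenceMatrix-class].
#' @param catalog a [SpeciesCatalog-class] covering all incidence species.
#' @return a [RichnessPattern-class].
#' @export
groupRichness <- function(incidence, catalog) {
    stopifnot(is(incidence, "IncidenceMatrix"), is(catalog, "SpeciesCatalog"))
    if (nrow(incidence@mat) == 0L || sum(incidence@mat) == 0)
        stop("empty incidence matrix")
    miss <- setdiff(speciesIds(incidence), speciesIds(catalog))
    if (length(miss))
        stop("incidence species missing from catalog: ",
             paste(utils::head(miss, 5), collapse = ", "))
    m <- groupMembership(catalog)[speciesIds(incidence), , drop = FALSE]
    totals <- groupTotals(catalog)
    counts <- t(as.matrix(Matrix::crossprod(incidence@mat,
                                            Matrix::Matrix(m, sparse = TRUE))))
    counts <- matrix(as.integer(counts), nrow = nrow(counts),
                     dimnames = list(CONSERVATION_GROUPS, NULL))
    if (any(totals == 0L))
        warning("empty group(s) contribute 0 to the composite index: ",
                paste(names(totals)[totals == 0L], collapse = ", "))
    denom <- ifelse(totals == 0L, 1L, totals)
    ratios <- counts / denom
    ratios[totals == 0L, ] <- 0
    new("RichnessPattern", counts = counts, ratios = ratios,
        composite = colSums(ratios), totals = totals,
        grid = incidence@grid)
}

# order candidate indices by score desc, then smaller cell id; keep the
# top k with tie extension at the k-th score
rankWithTies <- function(cellIds, scores, k) {
    ord <- order(-scores, cellIds)
    cellIds <- cellIds[ord]; scores <- scores[ord]
    if (length(cellIds) <= k)
        return(list(cells = cellIds, scores = scores, tie = FALSE))
    cut <- scores[k]
    keep <- seq_len(max(which(scores >= cut - 1e-12)))
    list(cells = cellIds[keep], scores = scores[keep],
         tie = length(keep) > k)
}

#' Top-richness hotspot ranking
#'
#' Ranks occupied cells by the composite richness index \eqn{R_c} and
#' keeps the top fraction (default 5% of occupied cells, the "top 5%
#' richness algorithm"). All cells tied with the K-th score are retained,
#' so the list can exceed K.
#'
#' @param pattern a [RichnessPattern-class].
#' @param fraction proportion of occupied cells to keep (default 0.05).
#' @param kOverride optional integer fixing K directly (e.g. 150).
#' @return a [HotspotRanking-class].
#' @export
topRichnessHotspots <- function(pattern, fraction = 0.05, kOverride = NULL) {
    stopifnot(is(pattern, "RichnessPattern"))
    if (is.null(kOverride)) {
        if (fraction <= 0 || fraction > 1)
            stop("'fraction' must lie in (0, 1]")
    }
    occ <- which(pattern@composite > 0) - 1L
    if (!length(occ)) stop("no occupied cells to rank")
    k <- if (!is.null(kOverride)) as.integer(kOverride)
         else max(1L, as.integer(roundHalfUp(fraction * length(occ))))
    if (k < 1L) stop("cutoff size must be at least 1")
    r <- rankWithTies(occ, pattern@composite[occ + 1L], k)
    new("HotspotRanking", algorithm = "richness", cellIds = r$cells,
        scores = r$scores, k = k, tieExtended = r$tie)
}

#' Greedy complementarity (set-cover) selection
#'
#' Iteratively selects the cell holding the most not-yet-covered species,
#' removes those species from consideration, and repeats until every
#' species is covered. Each step's complementarity value \eqn{G_c} is the
#' sum over the five conservation groups of (newly covered species of the
#' group) / \eqn{N_g}; over a full solution the gains of each nonempty
#' group sum to 1, so the total gain equals the number of nonempty groups.
#'
#' @param incidence an [IncidenceMatrix-class]; every species must occur
#'   in at least one cell.
#' @param catalog a [SpeciesCatalog-class].
#' @param criterion \code{"all_species"} (default: pick the cell with the
#'   most uncovered species, ties broken by larger composite gain then
#'   smaller cell id) or \code{"composite_gain"} (pick the cell with the
#'   largest composite gain directly).
#' @return a [ComplementaritySolution-class].
#' @export
greedyComplementarity <- function(incidence, catalog,
                                  criterion = c("all_species",
                                                "composite_gain")) {
    stopifnot(is(incidence, "IncidenceMatrix"), is(catalog, "SpeciesCatalog"))
    criterion <- match.arg(criterion)
    mat <- incidence@mat
    sp <- speciesIds(incidence)
    zero <- Matrix::rowSums(mat) == 0
    if (any(zero))
        stop("species with zero occurrences cannot be covered: ",
             paste(utils::head(sp[zero], 5), collapse = ", "))
    m <- groupMembership(catalog)[sp, , drop = FALSE]
    totals <- groupTotals(catalog)
    denom <- ifelse(totals == 0L, Inf, as.numeric(totals))
    w <- as.numeric(m %*% (1 / denom))  # per-species composite weight
    uncovered <- rep(TRUE, length(sp))
    cells <- integer(); gains <- numeric(); covered <- list()
    trace <- integer()
    comps <- matrix(numeric(0), nrow = 5L,
                    dimnames = list(CONSERVATION_GROUPS, NULL))
    while (any(uncovered)) {
        sub <- mat[uncovered, , drop = FALSE]
        cnt <- Matrix::colSums(sub)
        gw <- as.numeric(Matrix::crossprod(sub, w[uncovered]))
        # gains are sums of group-ratio fractions; compare with a small
        # tolerance so exact rational ties are not split by rounding
        cand <- if (criterion == "all_species") {
            best <- which(cnt == max(cnt))
            best[gw[best] >= max(gw[best]) - 1e-9]
        } else which(gw >= max(gw) - 1e-9)
        pick <- cand[which.min(cand)]  # smallest cell id among ties
        newSp <- which(uncovered & mat[, pick])
        uncovered[newSp] <- FALSE
        cells <- c(cells, pick - 1L)
        gains <- c(gains, sum(w[newSp]))
        covered <- c(covered, list(sp[newSp]))
        comps <- cbind(comps, colSums(m[newSp, , drop = FALSE]) / denom)
        trace <- c(trace, sum(uncovered))
    }
    new("ComplementaritySolution", cellIds = cells, gains = gains,
        gainComponents = comps, newlyCovered = covered,
        nUncovered = trace)
}

#' Top-complementarity hotspot ranking
#'
#' Ranks the greedy solution's cells by their complementarity value
#' \eqn{G_c} (descending) and keeps the top \code{k} with tie extension:
#' every cell tied with the k-th value is retained, so 151 cells can come
#' back from a request for 150.
#'
#' @param solution a [ComplementaritySolution-class].
#' @param k integer cutoff (default 150).
#' @return a [HotspotRanking-class].
#' @export
topComplementarityHotspots <- function(solution, k = 150) {
    stopifnot(is(solution, "ComplementaritySolution"))
    if (k < 1) stop("'k' must be at least 1")
    if (!length(solution@cellIds)) stop("empty complementarity solution")
    r <- rankWithTies(solution@cellIds, solution@gains, as.integer(k))
    new("HotspotRanking", algorithm = "complementarity", cellIds = r$cells,
        scores = r$scores, k = as.integer(k), tieExtended = r$tie)
}

#' Integrate the two hotspot rankings into final hotspots
#'
#' Cells present in both rankings become first-class hotspots, ordered by
#' the sum of their two rank orders (1-based positions). Cells present in
#' exactly one ranking fill the remaining slots as second-class hotspots,
#' ordered by their rank among the not-yet-taken cells of their own
#' ranking; at equal order a richness-algorithm cell precedes a
#' complementarity one, so disjoint rankings interleave. If the
#' intersection alone exceeds \code{kTotal} it is truncated and the second
#' class is empty.
#'
#' @param rankR the richness [HotspotRanking-class].
#' @param rankC the complementarity [HotspotRanking-class].
#' @param kTotal integer target total size (default 150).
#' @return a [FinalHotspots-class].
#' @export
integrateHotspots <- function(rankR, rankC, kTotal = 150) {
    stopifnot(is(rankR, "HotspotRanking"), is(rankC, "HotspotRanking"))
    if (kTotal < 1) stop("'kTotal' must be at least 1")
    kTotal <- as.integer(kTotal)
    if (!length(rankR@cellIds) || !length(rankC@cellIds))
        stop("both rankings must be nonempty")
    oR <- structure(seq_along(rankR@cellIds), names = rankR@cellIds)
    oC <- structure(seq_along(rankC@cellIds), names = rankC@cellIds)
    both <- intersect(rankR@cellIds, rankC@cellIds)
    key <- oR[as.character(both)] + oC[as.character(both)]
    ord <- order(key, oR[as.character(both)], both)
    both <- both[ord]; key <- key[ord]
    if (length(both) >= kTotal) {
        both <- both[seq_len(kTotal)]; key <- key[seq_len(kTotal)]
        second <- integer(0); skey <- numeric(0)
    } else {
        onlyR <- setdiff(rankR@cellIds, rankC@cellIds)
        onlyC <- setdiff(rankC@cellIds, rankR@cellIds)
        cand <- data.frame(
            cell = c(onlyR, onlyC),
            order = c(rank(oR[as.character(onlyR)]),
                      rank(oC[as.character(onlyC)])),
            alg = rep(c(1L, 2L), c(length(onlyR), length(onlyC))))
        cand <- cand[order(cand$order, cand$alg, cand$cell), ]
        nSecond <- min(kTotal - length(both), nrow(cand))
        cand <- cand[seq_len(nSecond), , drop = FALSE]
        second <- cand$cell; skey <- cand$order
    }
    tab <- data.frame(
        cell_id = c(both, second),
        class = rep(c("first", "second"), c(length(both), length(second))),
        order_richness = unname(oR[as.character(c(both, second))]),
        order_complementarity = unname(oC[as.character(c(both, second))]),
        sort_key = c(as.numeric(key), as.numeric(skey)))
    new("FinalHotspots", table = tab, kTotal = kTotal)
}

#' Export a hotspot ranking or final hotspots as CSV
#'
#' @param x a [HotspotRanking-class] or [FinalHotspots-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeHotspotsCSV <- function(x, path) {
    df <- if (is(x, "HotspotRanking")) {
        data.frame(cell_id = x@cellIds, order = seq_along(x@cellIds),
                   score = x@scores, class = x@algorithm)
    } else if (is(x, "FinalHotspots")) {
        tab <- x@table
        data.frame(cell_id = tab$cell_id,
                   order = seq_len(nrow(tab)), score = tab$sort_key,
                   class = tab$class)
    } else stop("unsupported object")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
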