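#' Species eligible for distribution modeling
#'
#' Filters a conservation group (threatened species by default) down to
#' those with at least \code{nMin} retained occurrence records; species
#' below the floor are excluded because presence-only models are
#' unreliable for them.
#'
#' @param occ an [OccurrenceTable-class].
#' @param catalog a [SpeciesCatalog-class].
#' @param nMin minimum record count (default 5).
#' @param group conservation group to filter (default
#'   \code{"THREATENED"}).
#' @return character vector of species ids passing the filter.
#' @export
minOccurrenceFilter <- function(occ, catalog, nMin = 5,
                                group = "THREATENED") {
    stopifnot(is(occ, "OccurrenceTable"), is(catalog, "SpeciesCatalog"))
    if (nMin < 1) stop("'nMin' must be at least 1")
    pool <- speciesInGroup(catalog, group)
    n <- table(occ@records$species_id)
    pool[pool %in% names(n)[n >= nMin]]
}

#' Replication plan for an external presence-only model run
#'
#' Species with 5-29 records get a jackknife (leave-one-out) design with
#' as many replicates as records; species with at least
#' \code{cvBreakpoint} records get 10-fold cross-validation with 10
#' replicates. Fewer than 5 records is below the modeling floor and an
#' error.
#'
#' @param nRecords integer record count (vectorised).
#' @param cvBreakpoint first record count handled by cross-validation
#'   (default 30).
#' @return data.frame with columns \code{n_records}, \code{method}
#'   (\code{"jackknife"}/\code{"cross-validation"}) and
#'   \code{replicates}.
#' @examples
#' replicationPlan(7)   # jackknife, 7 replicates
#' replicationPlan(30)  # cross-validation, 10 replicates
#' @export
replicationPlan <- function(nRecords, cvBreakpoint = 30) {
    if (any(nRecords < 5))
        stop("species with fewer than 5 records are not modeled")
    cv <- nRecords >= cvBreakpoint
    data.frame(n_records = as.integer(nRecords),
               method = ifelse(cv, "cross-validation", "jackknife"),
               replicates = as.integer(ifelse(cv, 10L, nRecords)))
}

#' Screen predictors by pairwise correlation
#'
#' Greedy collinearity filter: while any pair of remaining variables has
#' |r| strictly above the cutoff, the member of the worst pair with the
#' larger mean absolute correlation to all remaining variables is
#' removed. The result is a subset whose maximum pairwise |r| is at most
#' the cutoff; a pair at exactly the cutoff is kept.
#'
#' @param table data.frame or matrix of numeric predictor columns
#'   (unique names, equal length, none constant).
#' @param cutoff correlation threshold (default 0.70).
#' @return character vector of retained variable names.
#' @export
screenPredictors <- function(table, cutoff = 0.70) {
    x <- as.matrix(table)
    if (ncol(x) < 2L) stop("need at least 2 variables")
    if (anyDuplicated(colnames(x))) stop("variable names must be unique")
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
        stop("constant variable(s) have undefined correlations: ",
             paste(colnames(x)[sds == 0], collapse = ", "))
    r <- abs(stats::cor(x))
    keep <- colnames(x)
    repeat {
        sub <- r[keep, keep, drop = FALSE]
        diag(sub) <- 0
        # small tolerance so a pair at exactly the cutoff is kept
        if (max(sub) <= cutoff + 1e-9) break
        worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        pair <- keep[worst]
        meanAbs <- rowMeans(sub[pair, , drop = FALSE])
        drop <- pair[which.max(meanAbs)]  # first of the pair on a tie
        keep <- setdiff(keep, drop)
    }
    keep
}

#' Assemble a suitability stack
#'
#' @param values 3-d array (rows x cols x species, species named, row 1 =
#'   southernmost row) of suitability in [0, 1].
#' @param grid the fine-resolution [GridSpec-class].
#' @param scenario scenario label.
#' @param tau retention threshold (default 0.75).
#' @return a [SuitabilityStack-class].
#' @export
suitabilityStack <- function(values, grid, scenario = "current",
                             tau = 0.75) {
    new("SuitabilityStack", scenario = scenario, grid = grid,
        values = values, tau = tau)
}

#' Read a directory of per-species .asc rasters into a stack
#'
#' Expects one \code{<species_id>.asc} per species; all rasters must share
#' one header (geotransform).
#'
#' @param dir directory of .asc files.
#' @param scenario scenario label.
#' @param tau retention threshold.
#' @return a [SuitabilityStack-class].
#' @export
readSuitabilityDir <- function(dir, scenario = "current", tau = 0.75) {
    files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
    if (!length(files)) stop("no .asc rasters in ", dir)
    first <- readAsc(files[1])
    grid <- first$grid
    vals <- array(NA_real_, c(nRows(grid), nCols(grid), length(files)),
                  dimnames = list(NULL, NULL,
                                  sub("\\.asc$", "", basename(files))))
    vals[, , 1] <- first$values
    for (i in seq_along(files)[-1]) {
        a <- readAsc(files[i])
        if (!isTRUE(all.equal(gridToConfig(a$grid), gridToConfig(grid))))
            stop("misaligned geotransform in ", files[i])
        vals[, , i] <- a$values
    }
    suitabilityStack(vals, grid, scenario = scenario, tau = tau)
}

#' Threshold and superpose suitability surfaces
#'
#' Rejects per-species suitability below the stack's threshold tau
#' (values equal to tau are retained) and sums the surviving values per
#' pixel into the community suitability map
#' \eqn{V_x = \sum_s v_{sx} [v_{sx} \ge \tau]}.
#'
#' @param stack a [SuitabilityStack-class].
#' @return numeric matrix \eqn{V} (rows x cols, row 1 = south).
#' @export
thresholdAndSuperpose <- function(stack) {
    stopifnot(is(stack, "SuitabilityStack"))
    v <- stack@values
    v[is.na(v) | v < stack@tau] <- 0
    apply(v, c(1, 2), sum)
}

#' Suitable-habitat-area masks
#'
#' \code{shaMask} returns the community SHA mask (any species at or above
#' tau); \code{stableSha} intersects two scenarios' masks pixelwise to
#' the long-term stable SHA.
#'
#' @param stack a [SuitabilityStack-class].
#' @return logical matrix (rows x cols).
#' @export
shaMask <- function(stack) {
    thresholdAndSuperpose(stack) > 0
}

#' @rdname shaMask
#' @param current,future logical SHA masks of identical dimension.
#' @export
stableSha <- function(current, future) {
    if (!identical(dim(current), dim(future)))
        stop("misaligned masks")
    current & future
}

#' Classify coarse cells against a fine SHA mask
#'
#' Each coarse cell decomposes into \code{factor^2} fine sub-cells (36
#' for 0.5 degrees over 5 arc-minutes). A cell is \code{complete} when
#' all sub-cells are SHA-positive, \code{partial} when at least one is,
#' and \code{none} otherwise. With \code{minFraction} set, \code{complete}
#' instead requires at least that fraction of positive sub-cells.
#'
#' @param cellIds integer 0-based coarse cell ids (e.g. hotspot cells).
#' @param mask logical fine-resolution matrix (row 1 = south).
#' @param grid the coarse [GridSpec-class].
#' @param fineGrid the fine [GridSpec-class] of the mask; its resolution
#'   must divide the coarse resolution evenly.
#' @param minFraction optional fraction of sub-cells required for
#'   \code{complete} (default 1 = all).
#' @return data.frame with columns \code{cell_id}, \code{n_subcells},
#'   \code{n_positive}, \code{class}.
#' @export
shaOverlapClasses <- function(cellIds, mask, grid, fineGrid,
                              minFraction = 1) {
    stopifnot(is(grid, "GridSpec"), is(fineGrid, "GridSpec"))
    factor <- grid@resolution / fineGrid@resolution
    if (abs(factor - round(factor)) > 1e-9)
        stop("fine resolution must divide the coarse resolution evenly")
    factor <- as.integer(round(factor))
    if (!identical(dim(mask),
                   c(nRows(fineGrid), nCols(fineGrid))))
        stop("mask dimensions do not match the fine grid")
    rc <- cellRowCol(cellIds, grid)
    nPos <- vapply(seq_along(cellIds), function(i) {
        rows <- rc[i, "row"] * factor + seq_len(factor)
        cols <- rc[i, "col"] * factor + seq_len(factor)
        sum(mask[rows, cols])
    }, 0)
    nSub <- factor^2
    cls <- ifelse(nPos >= ceiling(minFraction * nSub), "complete",
           ifelse(nPos > 0, "partial", "none"))
    data.frame(cell_id = as.integer(cellIds), n_subcells = nSub,
               n_positive = as.integer(nPos), class = cls)
}

#' Overlap of hotspots with suitable habitat areas per scenario
#'
#' Classifies every hotspot cell as completely, partially or not covered
#' by the SHA of each scenario, and flags cells lying entirely in the
#' long-term stable SHA (the pixelwise intersection of the scenarios).
#'
#' @param hotspots a [FinalHotspots-class] or integer cell ids.
#' @param currentMask,futureMask logical fine SHA masks.
#' @param grid coarse [GridSpec-class].
#' @param fineGrid fine [GridSpec-class].
#' @param minFraction see [shaOverlapClasses()].
#' @return data.frame with one row per hotspot cell: overlap class under
#'   each scenario and a logical \code{stable} column (complete coverage
#'   by the stable mask).
#' @export
hotspotShaOverlap <- function(hotspots, currentMask, futureMask, grid,
                              fineGrid, minFraction = 1) {
    cells <- if (is(hotspots, "FinalHotspots")) hotspotCells(hotspots)
             else as.integer(hotspots)
    cur <- shaOverlapClasses(cells, currentMask, grid, fineGrid,
                             minFraction)
    fut <- shaOverlapClasses(cells, futureMask, grid, fineGrid,
                             minFraction)
    stab <- shaOverlapClasses(cells, stableSha(currentMask, futureMask),
                              grid, fineGrid, minFraction)
    data.frame(cell_id = cells,
               class_current = cur$class, class_future = fut$class,
               stable = stab$class == "complete")
}

#' Summarise an SHA overlap classification
#'
#' Counts and percentages (via [formatPercent()]) of hotspot cells
#' completely/partially/not covered per scenario, and of cells in stable
#' SHA.
#'
#' @param overlap data.frame from [hotspotShaOverlap()].
#' @return data.frame with columns \code{measure}, \code{count},
#'   \code{percent}.
#' @export
shaOverlapSummary <- function(overlap) {
    n <- nrow(overlap)
    rows <- list(
        c("current_complete", sum(overlap$class_current == "complete")),
        c("current_partial", sum(overlap$class_current == "partial")),
        c("current_none", sum(overlap$class_current == "none")),
        c("future_complete", sum(overlap$class_future == "complete")),
        c("future_partial", sum(overlap$class_future == "partial")),
        c("future_none", sum(overlap$class_future == "none")),
        c("stable", sum(overlap$stable)))
    data.frame(measure = vapply(rows, `[`, "", 1),
               count = as.integer(vapply(rows, `[`, "", 2)),
               percent = percentOf(as.integer(vapply(rows, `[`, "", 2)),
                                   n))
}
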