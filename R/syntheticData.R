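#' Configure the synthetic study generator
#'
#' Builds a [SimConfig-class] with the package's default study
#' conditions: 2000 species whose group membership rates mirror the
#' motivating flora (endemic 32.9%, threatened 6.4%, CITES 3.5%,
#' nationally protected 0.8%), a 10 x 10 degree demo extent gridded at
#' 0.5 degrees, 10 planted high-diversity cells with a 10-fold sampling
#' boost, log-uniform record counts between 8 and 600 per species
#' (herbarium-like skew), a 1-degree median range spread (log-normal
#' across species), a 2-degree
#' northward habitat shift under the future scenario, and reserve
#' rectangles targeting 30% coverage.
#'
#' @param seed integer master seed.
#' @param nSpecies number of species.
#' @param groupProps named membership probabilities (\code{endemic},
#'   \code{threatened}, \code{cites}, \code{national_protected}).
#' @param extent numeric (lonMin, latMin, lonMax, latMax).
#' @param resolution coarse grid resolution, degrees.
#' @param nPlantedHotspots number of planted high-diversity cells.
#' @param hotspotBoost sampling weight of one planted cell relative to one
#'   ordinary cell.
#' @param recordsRange log-uniform bounds on records per species.
#' @param rangeSd record spread around a species' centre, degrees.
#' @param futureShiftNorth northward niche shift, degrees.
#' @param reserveCoverageFraction target reserve-union coverage of the
#'   extent.
#' @param fineFactor suitability sub-cells per coarse cell side.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, nSpecies = 2000L,
                      groupProps = c(endemic = 0.329, threatened = 0.064,
                                     cites = 0.035,
                                     national_protected = 0.008),
                      extent = c(100, 20, 110, 30), resolution = 0.5,
                      nPlantedHotspots = 10L, hotspotBoost = 10,
                      recordsRange = c(8, 600), rangeSd = 1.0,
                      futureShiftNorth = 2.0,
                      reserveCoverageFraction = 0.3, fineFactor = 6L) {
    new("SimConfig", seed = as.integer(seed),
        nSpecies = as.integer(nSpecies), groupProps = groupProps,
        extent = as.numeric(extent), resolution = resolution,
        nPlantedHotspots = as.integer(nPlantedHotspots),
        hotspotBoost = hotspotBoost,
        recordsRange = as.numeric(recordsRange), rangeSd = rangeSd,
        futureShiftNorth = futureShiftNorth,
        reserveCoverageFraction = reserveCoverageFraction,
        fineFactor = as.integer(fineFactor))
}

#' Generate a synthetic species catalog
#'
#' Draws each group membership independently at the configured rate;
#' threatened species receive a VU/EN/CR category uniformly at random.
#'
#' @param config a [SimConfig-class].
#' @return a [SpeciesCatalog-class].
#' @export
genCatalog <- function(config) {
    stopifnot(is(config, "SimConfig"))
    seeds <- stageSeeds(config@seed)
    withSeed(seeds[1], {
        n <- config@nSpecies
        p <- config@groupProps
        threatened <- stats::runif(n) < p[["threatened"]]
        cat <- rep("none", n)
        cat[threatened] <- sample(THREAT_CATEGORIES, sum(threatened),
                                  replace = TRUE)
        speciesCatalog(sprintf("sp%05d", seq_len(n)),
                       endemic = stats::runif(n) < p[["endemic"]],
                       threatened = threatened, threat_category = cat,
                       cites = stats::runif(n) < p[["cites"]],
                       national_protected =
                           stats::runif(n) < p[["national_protected"]])
    })
}

#' Generate clustered occurrences with planted hotspot cells
#'
#' Every species gets a range centre: with probability proportional to
#' the hotspot boost (each planted cell carries weight
#' \code{hotspotBoost}, each ordinary cell weight 1) the centre is a
#' planted cell's centroid, otherwise it is uniform over the extent.
#' Records are drawn from an isotropic normal around the centre (sd =
#' \code{rangeSd}) and clipped to the extent; record counts per species
#' are log-uniform, mimicking herbarium skew.
#'
#' @param catalog a [SpeciesCatalog-class] (usually from [genCatalog()]).
#' @param config a [SimConfig-class].
#' @return list with \code{occurrences} (an [OccurrenceTable-class]),
#'   \code{grid} (the coarse [GridSpec-class]) and \code{truth} (planted
#'   cell ids, per-species centres and counts).
#' @export
genOccurrences <- function(catalog, config) {
    stopifnot(is(catalog, "SpeciesCatalog"), is(config, "SimConfig"))
    grid <- makeGrid(config@extent, config@resolution)
    nP <- config@nPlantedHotspots
    if (nP == 0L && config@hotspotBoost > 1)
        stop("hotspotBoost > 1 requires at least one planted hotspot")
    seeds <- stageSeeds(config@seed)
    withSeed(seeds[2], {
        sp <- speciesIds(catalog)
        n <- length(sp)
        # keep planted cells >= 2 * rangeSd from the boundary so edge
        # truncation of background ranges cannot confound them
        margin <- min(ceiling(2 * config@rangeSd / config@resolution),
                      (min(grid@nRows, grid@nCols) - 1L) %/% 2)
        rows <- margin:(grid@nRows - 1L - margin)
        cols <- margin:(grid@nCols - 1L - margin)
        interior <- as.vector(outer(cols, rows * grid@nCols, `+`))
        planted <- if (nP > 0L)
            sort(sample(interior, min(nP, length(interior))))
        else integer(0)
        pHot <- if (nP > 0L)
            nP * config@hotspotBoost /
                (nP * config@hotspotBoost + nCells(grid) - nP) else 0
        isHot <- stats::runif(n) < pHot
        ctr <- cbind(lon = stats::runif(n, grid@lonMin, grid@lonMax),
                     lat = stats::runif(n, grid@latMin, grid@latMax))
        if (any(isHot)) {
            pick <- sample(seq_len(max(nP, 1L)), sum(isHot), replace = TRUE)
            ctr[isHot, ] <- cellCentroid(planted[pick], grid)
        }
        lr <- log(config@recordsRange)
        nRec <- pmax(1L, as.integer(round(exp(
            stats::runif(n, lr[1], lr[2])))))
        # per-species range breadth: log-normal around rangeSd (median),
        # giving the skewed mix of narrow- and wide-ranged species real
        # floras show
        breadth <- stats::rlnorm(n, meanlog = log(config@rangeSd),
                                 sdlog = 0.5)
        idx <- rep(seq_len(n), nRec)
        lon <- stats::rnorm(length(idx), ctr[idx, "lon"], breadth[idx])
        lat <- stats::rnorm(length(idx), ctr[idx, "lat"], breadth[idx])
        # Rejection sampling of record density proportional to
        # normal(centre) x cell weight: a record in a planted cell is
        # always accepted, elsewhere with probability 1/boost (so planted
        # cells carry `hotspotBoost` times the sampling weight of an
        # ordinary cell). Out-of-extent draws are rejected too, which
        # truncates the normal instead of piling records on the boundary.
        plantedFlag <- logical(nCells(grid))
        plantedFlag[planted + 1L] <- TRUE
        accProb <- 1 / max(config@hotspotBoost, 1)
        pending <- seq_along(idx)
        for (it in 1:200) {
            inExt <- lon[pending] >= grid@lonMin &
                     lon[pending] <= grid@lonMax &
                     lat[pending] >= grid@latMin &
                     lat[pending] <= grid@latMax
            acc <- inExt
            acc[inExt] <- plantedFlag[assignCell(lon[pending][inExt],
                                                 lat[pending][inExt],
                                                 grid) + 1L] |
                stats::runif(sum(inExt)) < accProb
            pending <- pending[!acc]
            if (!length(pending)) break
            lon[pending] <- stats::rnorm(length(pending),
                                         ctr[idx[pending], "lon"],
                                         breadth[idx[pending]])
            lat[pending] <- stats::rnorm(length(pending),
                                         ctr[idx[pending], "lat"],
                                         breadth[idx[pending]])
        }
        lon <- pmin(pmax(lon, grid@lonMin), grid@lonMax)
        lat <- pmin(pmax(lat, grid@latMin), grid@latMax)
        occ <- occurrenceTable(data.frame(species_id = sp[idx],
                                          lon = lon, lat = lat,
                                          stringsAsFactors = FALSE))
        list(occurrences = occ, grid = grid,
             truth = list(plantedCells = planted, centers = ctr,
                          breadth = breadth, hotspotAssociated = isHot,
                          nRecords = nRec))
    })
}

# exact union area of axis-aligned rectangles by coordinate compression
rectUnionArea <- function(rects) {
    if (!nrow(rects)) return(0)
    xs <- sort(unique(c(rects[, 1], rects[, 3])))
    total <- 0
    for (i in seq_len(length(xs) - 1L)) {
        w <- xs[i + 1L] - xs[i]
        hit <- rects[, 1] <= xs[i] & rects[, 3] >= xs[i + 1L]
        if (!any(hit)) next
        ys <- rects[hit, c(2, 4), drop = FALSE]
        ys <- ys[order(ys[, 1]), , drop = FALSE]
        cover <- 0; hi <- -Inf; lo <- NA
        for (j in seq_len(nrow(ys))) {
            if (is.na(lo) || ys[j, 1] > hi) {
                if (!is.na(lo)) cover <- cover + hi - lo
                lo <- ys[j, 1]; hi <- ys[j, 2]
            } else hi <- max(hi, ys[j, 2])
        }
        cover <- cover + hi - lo
        total <- total + w * cover
    }
    total
}

#' Generate rectangular nature reserves of a target coverage
#'
#' Adds random rectangles, alternating national and provincial tiers,
#' until their union covers approximately the requested fraction of the
#' extent (exact rectangle-union area, tracked by coordinate
#' compression). A fraction of 0 gives an empty set; 1 gives a single
#' extent-covering national reserve.
#'
#' @param grid a [GridSpec-class].
#' @param config a [SimConfig-class].
#' @return a [ReserveSet-class].
#' @export
genReserves <- function(grid, config) {
    stopifnot(is(grid, "GridSpec"), is(config, "SimConfig"))
    f <- config@reserveCoverageFraction
    if (f <= 0) return(new("ReserveSet", features = list()))
    ext <- c(grid@lonMin, grid@latMin, grid@lonMax, grid@latMax)
    extArea <- (ext[3] - ext[1]) * (ext[4] - ext[2])
    if (f >= 1)
        return(reserveSetFromRects(matrix(ext, 1), "national",
                                   "reserve_all"))
    seeds <- stageSeeds(config@seed)
    withSeed(seeds[3], {
        # each added rectangle covers at most ~4% of the extent, so the
        # final union lands within a few percent above the target
        maxSide <- sqrt(0.04 * extArea)
        minSide <- maxSide / 4
        rects <- matrix(numeric(0), ncol = 4)
        tiers <- character(0)
        iter <- 0L
        while (rectUnionArea(rects) / extArea < f && iter < 10000L) {
            iter <- iter + 1L
            w <- stats::runif(1, minSide, maxSide)
            h <- stats::runif(1, minSide, maxSide)
            cx <- stats::runif(1, ext[1], ext[3])
            cy <- stats::runif(1, ext[2], ext[4])
            r <- c(max(ext[1], cx - w / 2), max(ext[2], cy - h / 2),
                   min(ext[3], cx + w / 2), min(ext[4], cy + h / 2))
            rects <- rbind(rects, r)
            tiers <- c(tiers,
                       if (iter %% 2L) "national" else "provincial")
        }
        reserveSetFromRects(rects, tiers)
    })
}

#' Generate paired current/future suitability stacks
#'
#' Each species' suitability is a Gaussian bump around its niche centre
#' (peak drawn uniformly in [0.8, 1.0], spatial sd = \code{rangeSd});
#' the future surface is identical with the centre displaced north by
#' \code{futureShiftNorth} degrees, emulating a poleward habitat shift.
#'
#' @param species character vector of species ids to model.
#' @param grid the coarse [GridSpec-class] (rasters are generated at
#'   \code{resolution / fineFactor}).
#' @param config a [SimConfig-class].
#' @param centers optional two-column matrix of niche centres, one row
#'   per species (e.g. the range centres from [genOccurrences()]);
#'   drawn uniformly over the extent when absent.
#' @param breadth optional per-species niche breadth (degrees); defaults
#'   to \code{rangeSd} for every species.
#' @return list with \code{current} and \code{future}
#'   [SuitabilityStack-class] objects, \code{fineGrid}, and \code{truth}
#'   (centres and peaks).
#' @export
genSuitability <- function(species, grid, config, centers = NULL,
                           breadth = NULL) {
    stopifnot(is(grid, "GridSpec"), is(config, "SimConfig"))
    fineGrid <- refineGrid(grid, config@fineFactor)
    seeds <- stageSeeds(config@seed)
    withSeed(seeds[4], {
        n <- length(species)
        if (is.null(centers))
            centers <- cbind(lon = stats::runif(n, grid@lonMin,
                                                grid@lonMax),
                             lat = stats::runif(n, grid@latMin,
                                                grid@latMax))
        if (is.null(breadth)) breadth <- rep(config@rangeSd, n)
        peaks <- stats::runif(n, 0.8, 1.0)
        lonC <- fineGrid@lonMin +
            (seq_len(nCols(fineGrid)) - 0.5) * fineGrid@resolution
        latC <- fineGrid@latMin +
            (seq_len(nRows(fineGrid)) - 0.5) * fineGrid@resolution
        bump <- function(cx, cy, peak, sd) {
            g <- outer(exp(-(latC - cy)^2 / (2 * sd^2)),
                       exp(-(lonC - cx)^2 / (2 * sd^2)))
            pmin(pmax(peak * g, 0), 1)
        }
        mk <- function(shift) {
            vals <- array(0, c(nRows(fineGrid), nCols(fineGrid), n),
                          dimnames = list(NULL, NULL, species))
            for (i in seq_len(n))
                vals[, , i] <- bump(centers[i, 1], centers[i, 2] + shift,
                                    peaks[i], breadth[i])
            vals
        }
        shift <- config@futureShiftNorth
        if (n && all(centers[, 2] + shift >
                     grid@latMax + 2 * max(breadth)))
            warning("future shift pushes all suitability mass outside ",
                    "the extent")
        list(current = suitabilityStack(mk(0), fineGrid, "current"),
             future = suitabilityStack(mk(shift), fineGrid, "future"),
             fineGrid = fineGrid,
             truth = list(centers = centers, breadth = breadth,
                          peaks = peaks))
    })
}

#' Generate a complete synthetic study
#'
#' Runs all four generators under one master seed (catalog, occurrences
#' with planted hotspots, reserves, and paired suitability stacks for the
#' threatened species passing the 5-record modeling floor) and optionally
#' writes every external-format input the pipeline reads.
#'
#' @param config a [SimConfig-class].
#' @param dir optional directory; when given, writes \code{catalog.csv},
#'   \code{occurrences.csv}, \code{reserves.geojson} and per-species
#'   \code{suitability/<scenario>/<species>.asc} rasters.
#' @param suitability logical; generate suitability stacks (default TRUE).
#' @return list with \code{config}, \code{grid}, \code{catalog},
#'   \code{occurrences}, \code{reserves}, \code{suitability} (or NULL)
#'   and \code{truth}.
#' @export
simulateStudy <- function(config = simConfig(), dir = NULL,
                          suitability = TRUE) {
    stopifnot(is(config, "SimConfig"))
    catalog <- genCatalog(config)
    occGen <- genOccurrences(catalog, config)
    reserves <- genReserves(occGen$grid, config)
    suit <- NULL
    modeled <- character(0)
    if (suitability) {
        modeled <- minOccurrenceFilter(occGen$occurrences, catalog)
        idx <- match(modeled, speciesIds(catalog))
        suit <- genSuitability(modeled, occGen$grid, config,
                               centers = occGen$truth$centers[idx, ,
                                                              drop = FALSE],
                               breadth = occGen$truth$breadth[idx])
    }
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        writeCatalog(catalog, file.path(dir, "catalog.csv"))
        writeOccurrences(occGen$occurrences,
                         file.path(dir, "occurrences.csv"))
        writeReservesGeoJSON(reserves, file.path(dir, "reserves.geojson"))
        if (!is.null(suit)) {
            for (scen in c("current", "future")) {
                sdir <- file.path(dir, "suitability", scen)
                dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
                stk <- suit[[scen]]
                for (s in speciesIds(stk))
                    writeAsc(stk@values[, , s], stk@grid,
                             file.path(sdir, paste0(s, ".asc")))
            }
        }
    }
    list(config = config, grid = occGen$grid, catalog = catalog,
         occurrences = occGen$occurrences, reserves = reserves,
         suitability = suit,
         truth = c(occGen$truth,
                   list(modeledSpecies = modeled,
                        niche = if (is.null(suit)) NULL else suit$truth)))
}
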