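# --- small planar geometry helpers (axis-aligned grid vs polygons) -------

# shoelace area of a closed ring (matrix, last vertex == first)
ringArea <- function(ring) {
    n <- nrow(ring)
    if (n < 4L) return(0)
    x <- ring[, 1]; y <- ring[, 2]
    abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# Sutherland-Hodgman clip of a ring against rect = c(xmin, ymin, xmax, ymax)
clipRingToRect <- function(ring, rect) {
    pts <- ring[-nrow(ring), , drop = FALSE]
    edges <- list(c(1, rect[1], +1), c(1, rect[3], -1),
                  c(2, rect[2], +1), c(2, rect[4], -1))
    for (e in edges) {
        if (nrow(pts) == 0L) break
        ax <- e[1]; v <- e[2]; sgn <- e[3]
        inside <- sgn * (pts[, ax] - v) >= 0
        n <- nrow(pts)
        out <- matrix(numeric(0), ncol = 2)
        for (i in seq_len(n)) {
            j <- if (i == n) 1L else i + 1L
            p <- pts[i, ]; q <- pts[j, ]
            if (inside[i]) out <- rbind(out, p)
            if (inside[i] != inside[j]) {
                t <- (v - p[ax]) / (q[ax] - p[ax])
                out <- rbind(out, p + t * (q - p))
            }
        }
        pts <- out
    }
    if (nrow(pts) < 3L) return(NULL)
    rbind(pts, pts[1, , drop = FALSE])
}

# even-odd point-in-ring test
pointInRing <- function(pt, ring) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring) - 1L
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
        if ((y[i] > pt[2]) != (y[j] > pt[2]) &&
            pt[1] < (x[j] - x[i]) * (pt[2] - y[i]) / (y[j] - y[i]) + x[i])
            inside <- !inside
        j <- i
    }
    inside
}

# do two closed segments properly intersect (excluding shared endpoints)?
segmentsCross <- function(p1, p2, q1, q2) {
    d <- function(a, b, c)
        (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
    d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

ringSelfIntersects <- function(ring) {
    pts <- ring[-nrow(ring), , drop = FALSE]
    n <- nrow(pts)
    if (n < 4L) return(FALSE)
    for (i in seq_len(n - 2L)) {
        for (j in (i + 2L):n) {
            if (i == 1L && j == n) next  # adjacent around the loop
            if (segmentsCross(pts[i, ], pts[i %% n + 1L, ],
                              pts[j, ], pts[j %% n + 1L, ]))
                return(TRUE)
        }
    }
    FALSE
}

closeRing <- function(ring) {
    if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ],
                          check.attributes = FALSE)))
        ring <- rbind(ring, ring[1, , drop = FALSE])
    ring
}

# ------------------------------------------------------------------ readers

#' Read nature-reserve polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon features, each with
#' a \code{tier} property of \code{national} or \code{provincial}
#' (case-insensitive). Open rings are closed; self-intersecting (bow-tie)
#' rings are rejected with a message naming the offending feature.
#'
#' @param path GeoJSON file.
#' @return a [ReserveSet-class].
#' @export
readReserves <- function(path) {
    gj <- readGeoJSONRaw(path)
    feats <- lapply(seq_along(gj$features), function(i) {
        f <- gj$features[[i]]
        tier <- f$properties$tier
        if (is.null(tier))
            stop("feature ", i, " has no 'tier' property")
        tier <- tolower(tier)
        if (!tier %in% c("national", "provincial"))
            stop("feature ", i, ": unsupported tier '", tier,
                 "' (only national/provincial reserves are analysed)")
        geom <- f$geometry
        polys <- switch(geom$type,
            Polygon = list(geom$coordinates),
            MultiPolygon = geom$coordinates,
            stop("feature ", i, ": geometry must be (Multi)Polygon, got ",
                 geom$type))
        polys <- lapply(polys, function(poly)
            lapply(poly, function(ring) closeRing(ringToMatrix(ring))))
        for (poly in polys) for (ring in poly)
            if (ringSelfIntersects(ring))
                stop("feature ", i,
                     ": self-intersecting ring (bow-tie) rejected; ",
                     "repair the geometry upstream")
        name <- f$properties$name
        list(name = if (is.null(name)) paste0("reserve_", i) else name,
             tier = tier, polygons = polys)
    })
    new("ReserveSet", features = feats)
}

#' Construct a ReserveSet from rectangles
#'
#' Convenience constructor (used by the synthetic generator): one
#' rectangular feature per row of \code{rects}.
#'
#' @param rects numeric matrix with columns lonMin, latMin, lonMax,
#'   latMax.
#' @param tier character vector, \code{"national"}/\code{"provincial"}.
#' @param name optional feature names.
#' @return a [ReserveSet-class].
#' @export
reserveSetFromRects <- function(rects, tier, name = NULL) {
    rects <- matrix(as.numeric(rects), ncol = 4)
    tier <- rep_len(tier, nrow(rects))
    if (is.null(name)) name <- sprintf("reserve_%03d", seq_len(nrow(rects)))
    feats <- lapply(seq_len(nrow(rects)), function(i) {
        r <- rects[i, ]
        ring <- rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]),
                      c(r[1], r[4]), c(r[1], r[2]))
        colnames(ring) <- c("lon", "lat")
        list(name = name[i], tier = tier[i], polygons = list(list(ring)))
    })
    new("ReserveSet", features = feats)
}

# --------------------------------------------------------------- operations

#' Grid cells covered by reserves
#'
#' Under the default \code{"intersects"} rule a cell counts as covered
#' when its box shares positive area with any reserve polygon of the
#' chosen tiers; under \code{"centroid"}, when its centre point lies
#' inside one.
#'
#' @param grid a [GridSpec-class].
#' @param reserves a [ReserveSet-class].
#' @param tiers subset of \code{c("national", "provincial")}.
#' @param rule \code{"intersects"} (default) or \code{"centroid"}.
#' @return integer vector of covered 0-based cell ids (sorted).
#' @export
coveredCells <- function(grid, reserves,
                         tiers = c("national", "provincial"),
                         rule = c("intersects", "centroid")) {
    stopifnot(is(grid, "GridSpec"), is(reserves, "ReserveSet"))
    rule <- match.arg(rule)
    tiers <- match.arg(tiers, several.ok = TRUE)
    feats <- Filter(function(f) f$tier %in% tiers, reserves@features)
    if (!length(feats)) {
        warning("no reserves in the requested tier(s); empty cover")
        return(integer(0))
    }
    covered <- logical(nCells(grid))
    res <- grid@resolution
    for (f in feats) for (poly in f$polygons) {
        bb <- apply(do.call(rbind, poly), 2, range)
        c0 <- max(0L, floor((bb[1, 1] - grid@lonMin) / res))
        c1 <- min(grid@nCols - 1L, floor((bb[2, 1] - grid@lonMin) / res))
        r0 <- max(0L, floor((bb[1, 2] - grid@latMin) / res))
        r1 <- min(grid@nRows - 1L, floor((bb[2, 2] - grid@latMin) / res))
        if (c1 < c0 || r1 < r0) next
        for (row in r0:r1) for (col in c0:c1) {
            cid <- row * grid@nCols + col + 1L
            if (covered[cid]) next
            rect <- c(grid@lonMin + col * res, grid@latMin + row * res,
                      grid@lonMin + (col + 1) * res,
                      grid@latMin + (row + 1) * res)
            if (rule == "centroid") {
                ctr <- c((rect[1] + rect[3]) / 2, (rect[2] + rect[4]) / 2)
                hits <- vapply(poly, function(rg) pointInRing(ctr, rg),
                               NA)
                covered[cid] <- sum(hits) %% 2 == 1  # outer minus holes
            } else {
                area <- 0
                for (k in seq_along(poly)) {
                    cl <- clipRingToRect(poly[[k]], rect)
                    if (!is.null(cl))
                        area <- area + (if (k == 1L) 1 else -1) *
                            ringArea(cl)
                }
                covered[cid] <- area > 1e-9
            }
        }
    }
    which(covered) - 1L
}

#' Partition hotspot cells into protected and gap cells
#'
#' @param hotspots a [FinalHotspots-class] or an integer vector of cell
#'   ids.
#' @param covered integer vector of covered cell ids (from
#'   [coveredCells()]).
#' @return list with \code{protected} and \code{gaps} (integer cell ids);
#'   the two always partition the hotspot set.
#' @export
gapAnalysis <- function(hotspots, covered) {
    cells <- if (is(hotspots, "FinalHotspots")) hotspotCells(hotspots)
             else as.integer(hotspots)
    list(protected = cells[cells %in% covered],
         gaps = cells[!cells %in% covered])
}

#' Species coverage report across area classes
#'
#' The package's twin of the classic effectiveness table: for the whole
#' occupied area, the hotspot set, hotspots covered by national (NNR) /
#' provincial (PNR) reserves and their union, the corresponding
#' conservation gaps, and all grid cells covered by each tier, counts the
#' grid cells and, per conservation group, the species present in at
#' least one member cell with its proportion of the group total.
#'
#' @param incidence an [IncidenceMatrix-class].
#' @param catalog a [SpeciesCatalog-class].
#' @param hotspots a [FinalHotspots-class] or integer cell ids.
#' @param coverNational,coverProvincial integer cell-id vectors from
#'   [coveredCells()] for each tier.
#' @return a [CoverageReport-class].
#' @export
coverageReport <- function(incidence, catalog, hotspots,
                           coverNational, coverProvincial) {
    stopifnot(is(incidence, "IncidenceMatrix"), is(catalog, "SpeciesCatalog"))
    hs <- if (is(hotspots, "FinalHotspots")) hotspotCells(hotspots)
          else as.integer(hotspots)
    occ <- occupiedCells(incidence)
    coverUnion <- union(coverNational, coverProvincial)
    classes <- list(
        china = occ,
        hotspots = hs,
        hotspots_nnr = intersect(hs, coverNational),
        hotspots_pnr = intersect(hs, coverProvincial),
        hotspots_nnr_pnr = intersect(hs, coverUnion),
        gaps_nnr = setdiff(hs, coverNational),
        gaps_pnr = setdiff(hs, coverProvincial),
        gaps_nnr_pnr = setdiff(hs, coverUnion),
        all_cells_nnr = intersect(occ, coverNational),
        all_cells_pnr = intersect(occ, coverProvincial),
        all_cells_nnr_pnr = intersect(occ, coverUnion))
    totals <- groupTotals(catalog)
    m <- groupMembership(catalog)
    counts <- vapply(classes, function(cells) {
        sp <- speciesInCells(incidence, cells)
        as.integer(colSums(m[sp, , drop = FALSE]))
    }, integer(5))
    rownames(counts) <- CONSERVATION_GROUPS
    denom <- ifelse(totals == 0L, 1L, totals)
    new("CoverageReport",
        cellCounts = structure(lengths(classes), names = names(classes)),
        speciesCounts = counts,
        proportions = counts / denom,
        totals = totals)
}

#' Format a coverage report as a count/percent table
#'
#' One row per conservation group plus a bottom row of grid-cell counts;
#' entries are \code{"count/percent"} strings via [formatPercent()], with
#' cell percentages taken of the whole occupied area.
#'
#' @param report a [CoverageReport-class].
#' @return data.frame of character columns, one per area class.
#' @export
coverageTable <- function(report) {
    stopifnot(is(report, "CoverageReport"))
    cnt <- report@speciesCounts
    tot <- report@totals
    body <- matrix(paste0(cnt, "/",
                          formatPercent(cnt, rep(tot, ncol(cnt)))),
                   nrow = nrow(cnt), dimnames = dimnames(cnt))
    nChina <- report@cellCounts[["china"]]
    cells <- paste0(report@cellCounts, "/",
                    formatPercent(report@cellCounts, nChina))
    out <- rbind(as.data.frame(body, stringsAsFactors = FALSE),
                 n_grid_cells = cells)
    out
}

#' @rdname coverageTable
#' @param path output CSV file.
#' @return \code{writeCoverageCSV} returns the path, invisibly.
#' @export
writeCoverageCSV <- function(report, path) {
    utils::write.csv(coverageTable(report), path, quote = FALSE)
    invisible(path)
}

#' Three-way species partition by conservation priority
#'
#' Splits the catalog into threatened species, endemic species excluding
#' the threatened ones, and all remaining species; the three sets always
#' partition the full species list.
#'
#' @param catalog a [SpeciesCatalog-class].
#' @return list with character vectors \code{threatened},
#'   \code{endemic_excl_threatened} and \code{remaining}.
#' @export
compositionPartition <- function(catalog) {
    stopifnot(is(catalog, "SpeciesCatalog"))
    df <- catalog@species
    list(threatened = df$species_id[df$threatened],
         endemic_excl_threatened =
             df$species_id[df$endemic & !df$threatened],
         remaining = df$species_id[!df$threatened & !df$endemic])
}
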