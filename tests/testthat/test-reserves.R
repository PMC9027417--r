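geojsonFeature <- function(coords, tier = "national", name = "r1") {
    list(type = "Feature",
         properties = if (is.null(tier)) list(name = name)
                      else list(name = name, tier = tier),
         geometry = list(type = "Polygon", coordinates = list(coords)))
}

writeFC <- function(features, path) {
    jsonlite::write_json(list(type = "FeatureCollection",
                              features = features),
                         path, auto_unbox = TRUE, digits = NA)
    path
}

rect <- function(x0, y0, x1, y1)
    list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))

test_that("reserve GeoJSON parses tiers and rejects bad geometry", {
    path <- withr::local_tempfile(fileext = ".geojson")
    writeFC(list(geojsonFeature(rect(0, 0, 1, 1), "national"),
                 geojsonFeature(rect(2, 2, 3, 3), "Provincial", "r2")),
            path)
    rs <- readReserves(path)
    expect_length(rs@features, 2)
    expect_equal(reserveTiers(rs), c("national", "provincial"))

    writeFC(list(geojsonFeature(rect(0, 0, 1, 1), tier = NULL)), path)
    expect_error(readReserves(path), "feature 1 has no 'tier'")

    writeFC(list(geojsonFeature(rect(0, 0, 1, 1), "municipal")), path)
    expect_error(readReserves(path), "unsupported tier")

    # bow-tie ring is self-intersecting
    bowtie <- list(c(0, 0), c(1, 1), c(1, 0), c(0, 1), c(0, 0))
    writeFC(list(geojsonFeature(bowtie)), path)
    expect_error(readReserves(path), "self-intersecting")
})

test_that("covered cells follow the positive-area intersection rule", {
    grid <- makeGrid(c(0, 0, 1, 1), 0.5)
    # reserve covering the whole extent -> all cells
    all <- reserveSetFromRects(matrix(c(-1, -1, 2, 2), 1), "national")
    expect_setequal(coveredCells(grid, all), 0:3)
    # empty set warns and returns nothing
    none <- new("ReserveSet", features = list())
    expect_warning(cc <- coveredCells(grid, none), "empty cover")
    expect_length(cc, 0)
    # one polygon overlapping exactly the two western cells
    west <- reserveSetFromRects(matrix(c(0.1, 0.1, 0.4, 0.9), 1),
                                "provincial")
    expect_setequal(coveredCells(grid, west), c(0L, 2L))
    expect_length(coveredCells(grid, west, tiers = "national",
                               rule = "intersects") |>
                      suppressWarnings(), 0)
    # touching along an edge is not positive-area overlap
    touch <- reserveSetFromRects(matrix(c(-1, 0, 0, 1), 1), "national")
    expect_length(coveredCells(grid, touch), 0)
})

test_that("centroid rule only counts cells whose centre is inside", {
    grid <- makeGrid(c(0, 0, 1, 1), 0.5)
    # covers the whole west column but only the SW centroid
    sw <- reserveSetFromRects(matrix(c(0, 0, 0.3, 0.6), 1), "national")
    expect_setequal(coveredCells(grid, sw, rule = "intersects"),
                    c(0L, 2L))
    expect_equal(coveredCells(grid, sw, rule = "centroid"), 0L)
})

test_that("gap analysis partitions hotspot cells", {
    hs <- c(3L, 7L, 9L, 12L)
    ga <- gapAnalysis(hs, covered = c(1L, 7L, 12L))
    expect_equal(ga$protected, c(7L, 12L))
    expect_equal(ga$gaps, c(3L, 9L))
    expect_setequal(c(ga$protected, ga$gaps), hs)
    expect_length(gapAnalysis(hs, covered = hs)$gaps, 0)
    expect_length(gapAnalysis(hs, covered = integer(0))$protected, 0)
})

test_that("coverage report tallies species per area class by hand", {
    grid <- makeGrid(c(0, 0, 1, 1), 0.5)
    cat <- fixtureCatalog(4, endemic = 1:2, threatened = 3, cites = 4,
                          protected = 4)
    byCell <- list(`0` = c("sp01", "sp03"), `1` = c("sp02"),
                   `2` = c("sp02", "sp04"), `3` = c("sp01"))
    inc <- fixtureIncidence(byCell, grid)
    hs <- c(0L, 2L)
    rep <- coverageReport(inc, cat, hs, coverNational = c(0L, 1L),
                          coverProvincial = c(2L))
    expect_equal(unname(rep@cellCounts[c("china", "hotspots",
                                         "hotspots_nnr",
                                         "hotspots_pnr",
                                         "gaps_nnr_pnr")]),
                 c(4L, 2L, 1L, 1L, 0L))
    # hotspots hold sp01, sp03 (cell 0) + sp02, sp04 (cell 2)
    expect_equal(unname(rep@speciesCounts["ALL", "hotspots"]), 4L)
    expect_equal(unname(rep@speciesCounts["THREATENED", "hotspots_nnr"]),
                 1L)       # sp03 via cell 0
    expect_equal(unname(rep@speciesCounts["CITES", "hotspots_nnr"]), 0L)
    expect_equal(unname(rep@speciesCounts["CITES", "hotspots_pnr"]), 1L)
    expect_true(all(rep@proportions >= 0 & rep@proportions <= 1))
    # trivial extremes
    repAll <- coverageReport(inc, cat, occupiedCells(inc),
                             coverNational = 0:3, coverProvincial = 0:3)
    nonGap <- !grepl("^gaps_", colnames(repAll@proportions))
    expect_true(all(repAll@proportions[, nonGap] == 1))
    expect_true(all(repAll@speciesCounts[, !nonGap] == 0))
    repNone <- coverageReport(inc, cat, hs, coverNational = integer(0),
                              coverProvincial = integer(0))
    expect_true(all(repNone@speciesCounts[, "hotspots_nnr"] == 0))
})

test_that("adding a reserve never shrinks coverage", {
    grid <- makeGrid(c(0, 0, 2, 2), 0.5)
    set.seed(13)
    cat <- fixtureCatalog(10, endemic = 1:3, threatened = 4:5)
    byCell <- lapply(0:15, function(i)
        sprintf("sp%02d", sample(1:10, sample(1:4, 1))))
    names(byCell) <- 0:15
    inc <- fixtureIncidence(byCell, grid)
    hs <- sample(0:15, 6)
    r1 <- matrix(c(0.1, 0.1, 0.9, 0.9), 1)
    r2 <- rbind(r1, c(1.1, 1.1, 1.8, 1.6))
    for (tier in c("national", "provincial")) {
        c1 <- coveredCells(grid, reserveSetFromRects(r1, tier),
                           tiers = tier)
        c2 <- coveredCells(grid, reserveSetFromRects(r2, tier),
                           tiers = tier)
        expect_true(all(c1 %in% c2))
    }
    cN1 <- coveredCells(grid, reserveSetFromRects(r1, "national"))
    cN2 <- coveredCells(grid, reserveSetFromRects(r2, "national"))
    repA <- suppressWarnings(coverageReport(inc, cat, hs, cN1, integer(0)))
    repB <- suppressWarnings(coverageReport(inc, cat, hs, cN2, integer(0)))
    expect_true(all(repB@speciesCounts[, "hotspots_nnr"] >=
                    repA@speciesCounts[, "hotspots_nnr"]))
    # union consistency
    expect_true(all(repB@speciesCounts[, "hotspots_nnr_pnr"] >=
                    pmax(repB@speciesCounts[, "hotspots_nnr"],
                         repB@speciesCounts[, "hotspots_pnr"])))
})

test_that("coverage table formats count/percent entries", {
    grid <- makeGrid(c(0, 0, 1, 1), 0.5)
    cat <- fixtureCatalog(4, endemic = 1:2)
    inc <- fixtureIncidence(list(`0` = c("sp01", "sp02"),
                                 `1` = c("sp03", "sp04")), grid)
    rep <- coverageReport(inc, cat, c(0L), coverNational = c(0L, 1L),
                          coverProvincial = integer(0))
    tab <- coverageTable(rep)
    expect_equal(tab["ALL", "china"], "4/100%")
    expect_equal(tab["ALL", "hotspots"], "2/50%")
    expect_equal(tab["ENDEMIC", "hotspots"], "2/100%")
    expect_equal(tab["n_grid_cells", "hotspots"], "1/50%")
})

test_that("composition partition is exhaustive and exclusive", {
    # 3 threatened, 4 endemic of which 2 threatened -> 3 / 2 / 5
    cat <- fixtureCatalog(10, endemic = c(1, 2, 3, 4),
                          threatened = c(3, 4, 5))
    p <- compositionPartition(cat)
    expect_length(p$threatened, 3)
    expect_length(p$endemic_excl_threatened, 2)
    expect_length(p$remaining, 5)
    expect_true("sp03" %in% p$threatened)
    expect_false("sp03" %in% p$endemic_excl_threatened)
    expect_setequal(unlist(p), speciesIds(cat))
    set.seed(8)
    for (i in 1:10) {
        n <- sample(5:50, 1)
        cat2 <- fixtureCatalog(n, endemic = which(runif(n) < 0.4),
                               threatened = which(runif(n) < 0.3))
        p2 <- compositionPartition(cat2)
        expect_equal(sum(lengths(p2)), n)
        expect_false(anyDuplicated(unlist(p2)) > 0)
    }
})

test_that("reserve GeoJSON writing round-trips through the reader", {
    rs <- reserveSetFromRects(matrix(c(0, 0, 1, 1, 2, 2, 3, 4),
                                     2, byrow = TRUE),
                              c("national", "provincial"))
    path <- withr::local_tempfile(fileext = ".geojson")
    writeReservesGeoJSON(rs, path)
    rs2 <- readReserves(path)
    expect_equal(reserveTiers(rs2), c("national", "provincial"))
    expect_equal(rs2@features[[2]]$polygons[[1]][[1]],
                 rs@features[[2]]$polygons[[1]][[1]],
                 ignore_attr = TRUE)
})
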