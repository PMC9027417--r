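#' Run the full prioritization pipeline on external input files
#'
#' Executes the package's workflow end to end: grid the extent, read and
#' validate the catalog and occurrences, build the incidence matrix,
#' compute the composite richness pattern and the greedy complementarity
#' solution, rank and integrate hotspots, correlate the ten distribution
#' patterns, overlay reserves for effectiveness and gaps, and
#' post-process suitability rasters (threshold, superpose, stability,
#' hotspot overlap). Each stage's outputs are written under
#' \code{outDir}, together with a JSON run manifest echoing every
#' parameter and per-stage row counts. The reserve and suitability stages
#' are skipped with a notice when their inputs are absent.
#'
#' @param catalogPath species catalog CSV (see [readCatalog()]).
#' @param occurrencesPath occurrence CSV (see [readOccurrences()]).
#' @param outDir output directory (created if needed).
#' @param extent numeric (lonMin, latMin, lonMax, latMax).
#' @param resolution grid resolution in degrees (default 0.5).
#' @param reservesPath optional reserve GeoJSON.
#' @param suitabilityDir optional directory with \code{current/} and
#'   \code{future/} subdirectories of per-species .asc rasters.
#' @param fraction,kOverride,kTotal,greedyCriterion prioritization
#'   parameters (see [topRichnessHotspots()], [integrateHotspots()],
#'   [greedyComplementarity()]).
#' @param tau,nMin,minFraction suitability parameters (see
#'   [thresholdAndSuperpose()], [minOccurrenceFilter()],
#'   [shaOverlapClasses()]).
#' @param seed optional integer recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return invisibly, a list with all intermediate objects and the
#'   manifest.
#' @export
runPipeline <- function(catalogPath, occurrencesPath, outDir,
                        extent, resolution = 0.5,
                        reservesPath = NULL, suitabilityDir = NULL,
                        fraction = 0.05, kOverride = NULL, kTotal = 150,
                        greedyCriterion = "all_species",
                        tau = 0.75, nMin = 5, minFraction = 1,
                        seed = NULL) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    params <- list(catalog = catalogPath, occurrences = occurrencesPath,
                   reserves = reservesPath,
                   suitability_dir = suitabilityDir, out_dir = outDir,
                   extent = extent, resolution = resolution,
                   fraction = fraction, k_override = kOverride,
                   k_total = kTotal, greedy_criterion = greedyCriterion,
                   tau = tau, n_min = nMin, min_fraction = minFraction,
                   seed = seed)
    stages <- list()
    note <- function(stage, ...) {
        message("[", stage, "] ", ...)
    }
    run <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    grid <- run("grid", makeGrid(extent, resolution))
    stages$grid <- nCells(grid)

    catalog <- run("catalog", readCatalog(catalogPath))
    occ <- run("occurrences",
               readOccurrences(occurrencesPath, catalog, grid))
    inc <- run("incidence", buildIncidence(occ, grid))
    stages$incidence <- length(occupiedCells(inc))
    note("incidence", stages$incidence, " occupied cells, ",
         nrow(inc@mat), " species")

    pattern <- run("richness", groupRichness(inc, catalog))
    rankR <- run("richness",
                 topRichnessHotspots(pattern, fraction, kOverride))
    solution <- run("complementarity",
                    greedyComplementarity(inc, catalog,
                                          criterion = greedyCriterion))
    rankC <- run("complementarity",
                 topComplementarityHotspots(solution, rankR@k))
    final <- run("integration", integrateHotspots(rankR, rankC, kTotal))
    stages$hotspots <- nrow(final@table)
    writeHotspotsCSV(rankR, file.path(outDir, "ranking_richness.csv"))
    writeHotspotsCSV(rankC,
                     file.path(outDir, "ranking_complementarity.csv"))
    writeHotspotsCSV(final, file.path(outDir, "final_hotspots.csv"))
    writeCellsGeoJSON(hotspotCells(final), grid,
                      file.path(outDir, "final_hotspots.geojson"),
                      properties = data.frame(class = final@table$class))

    vecs <- run("correlogram",
                standardPatternVectors(pattern, solution, grid))
    # constant patterns (e.g. an empty group) have no defined correlation
    const <- vapply(vecs, function(v) stats::sd(v) == 0, NA)
    if (any(const))
        note("correlogram", "constant pattern(s) dropped: ",
             paste(names(vecs)[const], collapse = ", "))
    corr <- run("correlogram", correlogram(vecs[!const]))
    stages$correlogram <- sum(upper.tri(corr@r))
    writeCorrelogramCSV(corr, file.path(outDir, "correlogram.csv"))

    gaps <- report <- reserves <- NULL
    if (!is.null(reservesPath) && file.exists(reservesPath)) {
        reserves <- run("gaps", readReserves(reservesPath))
        covN <- run("gaps", coveredCells(grid, reserves, "national"))
        covP <- run("gaps", coveredCells(grid, reserves, "provincial"))
        gaps <- run("gaps", gapAnalysis(final, union(covN, covP)))
        report <- run("gaps",
                      coverageReport(inc, catalog, final, covN, covP))
        stages$gaps <- length(gaps$gaps)
        writeCoverageCSV(report, file.path(outDir, "coverage_table.csv"))
        if (length(gaps$gaps))
            writeCellsGeoJSON(gaps$gaps, grid,
                              file.path(outDir, "gap_cells.geojson"))
    } else {
        note("gaps", "no reserve file supplied; gap stage skipped")
    }

    sha <- NULL
    if (!is.null(suitabilityDir) &&
        dir.exists(file.path(suitabilityDir, "current")) &&
        dir.exists(file.path(suitabilityDir, "future"))) {
        cur <- run("sha", readSuitabilityDir(
            file.path(suitabilityDir, "current"), "current", tau))
        fut <- run("sha", readSuitabilityDir(
            file.path(suitabilityDir, "future"), "future", tau))
        sha <- run("sha", hotspotShaOverlap(final, shaMask(cur),
                                            shaMask(fut), grid, cur@grid,
                                            minFraction))
        stages$sha <- nrow(sha)
        utils::write.csv(sha, file.path(outDir, "sha_overlap.csv"),
                         row.names = FALSE, quote = FALSE)
        utils::write.csv(shaOverlapSummary(sha),
                         file.path(outDir, "sha_summary.csv"),
                         row.names = FALSE, quote = FALSE)
        writeAsc(thresholdAndSuperpose(cur), cur@grid,
                 file.path(outDir, "superposed_current.asc"))
        writeAsc(thresholdAndSuperpose(fut), fut@grid,
                 file.path(outDir, "superposed_future.asc"))
    } else {
        note("sha", "no suitability rasters supplied; SHA stage skipped")
    }

    manifest <- list(
        package = "hotspotDiv",
        version = as.character(utils::packageVersion("hotspotDiv")),
        r_version = as.character(getRversion()),
        timestamp = format(Sys.time(), tz = "UTC"),
        parameters = params,
        counters = as.list(occ@counters),
        stages = stages)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(list(grid = grid, catalog = catalog, occurrences = occ,
                   incidence = inc, pattern = pattern, rankR = rankR,
                   solution = solution, rankC = rankC, hotspots = final,
                   correlogram = corr, reserves = reserves, gaps = gaps,
                   coverage = report, sha = sha, manifest = manifest))
}
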