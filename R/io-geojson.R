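#' Export grid cells as a GeoJSON FeatureCollection
#'
#' Writes one Polygon feature per cell with a \code{cell_id} property plus
#' any extra per-cell properties supplied.
#'
#' @param cellIds integer 0-based cell ids to export.
#' @param grid a [GridSpec-class].
#' @param path output file.
#' @param properties optional data.frame of extra properties, one row per
#'   cell in \code{cellIds}.
#' @return the path, invisibly.
#' @export
writeCellsGeoJSON <- function(cellIds, grid, path, properties = NULL) {
    stopifnot(is(grid, "GridSpec"))
    if (!is.null(properties))
        stopifnot(nrow(properties) == length(cellIds))
    b <- cellBounds(cellIds, grid)
    feats <- lapply(seq_along(cellIds), function(i) {
        ring <- list(c(b[i, 1], b[i, 2]), c(b[i, 3], b[i, 2]),
                     c(b[i, 3], b[i, 4]), c(b[i, 1], b[i, 4]),
                     c(b[i, 1], b[i, 2]))
        props <- list(cell_id = cellIds[i])
        if (!is.null(properties))
            props <- c(props, as.list(properties[i, , drop = FALSE]))
        list(type = "Feature", properties = props,
             geometry = list(type = "Polygon", coordinates = list(ring)))
    })
    fc <- list(type = "FeatureCollection", features = feats)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write a ReserveSet as GeoJSON
#'
#' @param reserves a [ReserveSet-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeReservesGeoJSON <- function(reserves, path) {
    stopifnot(is(reserves, "ReserveSet"))
    feats <- lapply(reserves@features, function(f) {
        coords <- lapply(f$polygons, function(poly)
            lapply(poly, function(ring)
                lapply(seq_len(nrow(ring)), function(i)
                    c(ring[i, 1], ring[i, 2]))))
        geom <- if (length(coords) == 1L)
            list(type = "Polygon", coordinates = coords[[1]])
        else list(type = "MultiPolygon", coordinates = coords)
        list(type = "Feature",
             properties = list(name = f$name, tier = f$tier),
             geometry = geom)
    })
    fc <- list(type = "FeatureCollection", features = feats)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

# parse GeoJSON without vector simplification (coordinates stay nested)
readGeoJSONRaw <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(gj$type) || gj$type != "FeatureCollection")
        stop("expected a GeoJSON FeatureCollection in ", path)
    gj
}

ringToMatrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    colnames(m) <- c("lon", "lat")
    m
}
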