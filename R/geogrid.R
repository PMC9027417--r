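#' Build a regular degree grid over an extent
#'
#' Expands the extent outward to whole multiples of \code{resolution} and
#' tiles it exactly with square cells. Cell ids are 0-based and row-major
#' from the southwest corner.
#'
#' @param extent numeric length-4: (lonMin, latMin, lonMax, latMax) in
#'   WGS84 decimal degrees.
#' @param resolution cell side in degrees (default 0.5).
#' @return a [GridSpec-class].
#' @examples
#' makeGrid(c(0, 0, 1.2, 1), 0.5)  # lon expanded to 1.5: 3 x 2 cells
#' @export
makeGrid <- function(extent, resolution = 0.5) {
    stopifnot(length(extent) == 4L, is.numeric(extent))
    if (!is.numeric(resolution) || length(resolution) != 1L ||
        resolution <= 0)
        stop("'resolution' must be a positive scalar")
    if (extent[1] >= extent[3] || extent[2] >= extent[4])
        stop("inverted or empty extent: need lonMin < lonMax and ",
             "latMin < latMax")
    lonMin <- floor(extent[1] / resolution) * resolution
    latMin <- floor(extent[2] / resolution) * resolution
    nc <- as.integer(ceiling((extent[3] - lonMin) / resolution - 1e-9))
    nr <- as.integer(ceiling((extent[4] - latMin) / resolution - 1e-9))
    new("GridSpec", lonMin = lonMin, latMin = latMin,
        lonMax = lonMin + nc * resolution, latMax = latMin + nr * resolution,
        resolution = resolution, nRows = nr, nCols = nc)
}

#' Assign points to grid cells
#'
#' Maps coordinates to 0-based cell ids under the half-open convention:
#' a cell owns \eqn{[lon, lon+res) \times [lat, lat+res)}, except that
#' points exactly on the grid's maximum boundary fall in the last
#' row/column.
#'
#' @param lon,lat numeric vectors of coordinates in degrees.
#' @param grid a [GridSpec-class].
#' @return integer vector of cell ids.
#' @examples
#' g <- makeGrid(c(0, 0, 1, 1), 0.5)
#' assignCell(0.25, 0.25, g)  # 0  (row 0, col 0)
#' assignCell(0.5, 0.5, g)    # 3  (row 1, col 1: half-open rule)
#' assignCell(1, 1, g)        # 3  (max corner closes onto last cell)
#' @export
assignCell <- function(lon, lat, grid) {
    stopifnot(is(grid, "GridSpec"), length(lon) == length(lat))
    out <- lon < grid@lonMin | lon > grid@lonMax |
           lat < grid@latMin | lat > grid@latMax
    if (any(out, na.rm = TRUE) || anyNA(out))
        stop(sum(out | is.na(out)), " point(s) outside the grid extent")
    col <- pmin(as.integer(floor((lon - grid@lonMin) / grid@resolution)),
                grid@nCols - 1L)
    row <- pmin(as.integer(floor((lat - grid@latMin) / grid@resolution)),
                grid@nRows - 1L)
    row * grid@nCols + col
}

#' Cell geometry lookups
#'
#' \code{cellRowCol} converts 0-based cell ids to (row, col);
#' \code{cellBounds} returns each cell's bounding box and
#' \code{cellCentroid} its centre.
#'
#' @param cellId integer vector of 0-based cell ids.
#' @param grid a [GridSpec-class].
#' @return \code{cellRowCol}: a two-column integer matrix;
#'   \code{cellBounds}: a four-column matrix (lonMin, latMin, lonMax,
#'   latMax); \code{cellCentroid}: a two-column matrix (lon, lat).
#' @export
cellRowCol <- function(cellId, grid) {
    stopifnot(is(grid, "GridSpec"))
    cellId <- as.integer(cellId)
    if (any(cellId < 0L | cellId >= nCells(grid)))
        stop("cell id out of range")
    cbind(row = cellId %/% grid@nCols, col = cellId %% grid@nCols)
}

#' @rdname cellRowCol
#' @export
cellBounds <- function(cellId, grid) {
    rc <- cellRowCol(cellId, grid)
    lon <- grid@lonMin + rc[, "col"] * grid@resolution
    lat <- grid@latMin + rc[, "row"] * grid@resolution
    cbind(lonMin = lon, latMin = lat,
          lonMax = lon + grid@resolution, latMax = lat + grid@resolution)
}

#' @rdname cellRowCol
#' @export
cellCentroid <- function(cellId, grid) {
    b <- cellBounds(cellId, grid)
    cbind(lon = (b[, "lonMin"] + b[, "lonMax"]) / 2,
          lat = (b[, "latMin"] + b[, "latMax"]) / 2)
}

#' Nominal cell area in km^2
#'
#' The flat-earth nominal area of one grid cell,
#' \eqn{(res \cdot kmPerDegree)^2}. The default 110 km/degree convention
#' makes a 0.5-degree cell 55 km x 55 km = 3025 km^2, the round figure
#' used in coarse-grid conservation atlases.
#'
#' @param grid a [GridSpec-class].
#' @param kmPerDegree km per degree (default 110).
#' @return numeric scalar, km^2.
#' @examples
#' nominalCellArea(makeGrid(c(0, 0, 1, 1), 0.5))  # 3025
#' @export
nominalCellArea <- function(grid, kmPerDegree = 110) {
    stopifnot(is(grid, "GridSpec"))
    if (!is.numeric(kmPerDegree) || kmPerDegree <= 0)
        stop("'kmPerDegree' must be positive")
    (grid@resolution * kmPerDegree)^2
}

#' Refine a grid to a finer resolution
#'
#' Splits every cell into \code{factor} x \code{factor} sub-cells; used to
#' put suitability rasters (5 arc-minutes) under a 0.5-degree analysis
#' grid.
#'
#' @param grid a [GridSpec-class].
#' @param factor integer sub-cells per side (default 6).
#' @return a finer [GridSpec-class] with the same extent.
#' @export
refineGrid <- function(grid, factor = 6L) {
    stopifnot(is(grid, "GridSpec"))
    factor <- as.integer(factor)
    if (factor < 1L) stop("'factor' must be a positive integer")
    new("GridSpec", lonMin = grid@lonMin, latMin = grid@latMin,
        lonMax = grid@lonMax, latMax = grid@latMax,
        resolution = grid@resolution / factor,
        nRows = grid@nRows * factor, nCols = grid@nCols * factor)
}

#' Serialize a grid to (and from) a key=value config block
#'
#' @param grid a [GridSpec-class].
#' @param text character vector of \code{key=value} lines.
#' @return \code{gridToConfig}: character vector; \code{gridFromConfig}:
#'   a [GridSpec-class].
#' @export
gridToConfig <- function(grid) {
    stopifnot(is(grid, "GridSpec"))
    c(paste0("lon_min=", grid@lonMin), paste0("lat_min=", grid@latMin),
      paste0("lon_max=", grid@lonMax), paste0("lat_max=", grid@latMax),
      paste0("resolution=", grid@resolution))
}

#' @rdname gridToConfig
#' @export
gridFromConfig <- function(text) {
    kv <- parseKeyValue(text)
    need <- c("lon_min", "lat_min", "lon_max", "lat_max", "resolution")
    if (!all(need %in% names(kv)))
        stop("grid config lacks keys: ",
             paste(setdiff(need, names(kv)), collapse = ", "))
    makeGrid(as.numeric(kv[c("lon_min", "lat_min", "lon_max", "lat_max")]),
             as.numeric(kv[["resolution"]]))
}

parseKeyValue <- function(text) {
    text <- trimws(text)
    text <- text[nzchar(text) & !startsWith(text, "#")]
    parts <- regmatches(text, regexpr("=", text), invert = TRUE)
    vals <- vapply(parts, function(p) trimws(p[2]), "")
    names(vals) <- vapply(parts, function(p) trimws(p[1]), "")
    vals
}
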