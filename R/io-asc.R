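#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text raster exchange format used for suitability surfaces: a
#' six-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by rows of values from the northernmost row
#' down. In-package matrices are stored with row 1 as the southernmost
#' grid row (matching [GridSpec-class] row order), so rows are flipped on
#' the way in and out.
#'
#' @param path file path.
#' @param nodata value written for NA cells (default -9999).
#' @return \code{readAsc}: a list with \code{values} (numeric matrix, row
#'   1 = south) and \code{grid} (a [GridSpec-class]).
#' @export
readAsc <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    hdr <- list()
    i <- 1L
    while (i <= length(lines) &&
           grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
        tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
        i <- i + 1L
    }
    need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
    if (!all(need %in% names(hdr)))
        stop("malformed .asc header in ", path)
    nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
    vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
                 quiet = TRUE)
    if (length(vals) != nr * nc)
        stop("expected ", nr * nc, " values, found ", length(vals))
    if (!is.null(hdr$nodata_value))
        vals[vals == hdr$nodata_value] <- NA_real_
    m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
    m <- m[nr:1, , drop = FALSE]  # asc lists north first; store south first
    grid <- new("GridSpec", lonMin = hdr$xllcorner, latMin = hdr$yllcorner,
                lonMax = hdr$xllcorner + nc * hdr$cellsize,
                latMax = hdr$yllcorner + nr * hdr$cellsize,
                resolution = hdr$cellsize, nRows = nr, nCols = nc)
    list(values = m, grid = grid)
}

#' @rdname readAsc
#' @param values numeric matrix with row 1 as the southernmost row.
#' @param grid the matching [GridSpec-class].
#' @export
writeAsc <- function(values, grid, path, nodata = -9999) {
    stopifnot(is(grid, "GridSpec"),
              nrow(values) == nRows(grid), ncol(values) == nCols(grid))
    hdr <- c(paste("ncols", nCols(grid)), paste("nrows", nRows(grid)),
             paste("xllcorner", grid@lonMin),
             paste("yllcorner", grid@latMin),
             paste("cellsize", grid@resolution),
             paste("NODATA_value", nodata))
    m <- values[nrow(values):1, , drop = FALSE]
    m[is.na(m)] <- nodata
    body <- apply(m, 1, paste, collapse = " ")
    writeLines(c(hdr, body), path)
    invisible(path)
}
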