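#' Construct a species catalog from vectors
#'
#' Programmatic constructor used by [readCatalog()] and the synthetic
#' generator.
#'
#' @param species_id character, unique species identifiers.
#' @param endemic,threatened,cites,national_protected logical membership
#'   flags (recycled scalars allowed).
#' @param threat_category character, one of \code{"VU"}, \code{"EN"},
#'   \code{"CR"} for threatened species and \code{"none"} otherwise.
#' @return a [SpeciesCatalog-class].
#' @export
speciesCatalog <- function(species_id, endemic = FALSE, threatened = FALSE,
                           threat_category = "none", cites = FALSE,
                           national_protected = FALSE) {
    n <- length(species_id)
    df <- data.frame(species_id = as.character(species_id),
                     endemic = rep_len(as.logical(endemic), n),
                     threatened = rep_len(as.logical(threatened), n),
                     threat_category = rep_len(as.character(threat_category),
                                               n),
                     cites = rep_len(as.logical(cites), n),
                     national_protected =
                         rep_len(as.logical(national_protected), n),
                     stringsAsFactors = FALSE)
    new("SpeciesCatalog", species = df)
}

#' Read a species catalog CSV
#'
#' The catalog lists one species per row with 0/1 (or true/false) flags
#' for each conservation-group membership and a threat category that must
#' be VU, EN or CR exactly when the threatened flag is set.
#'
#' @param path CSV with header columns \code{species_id}, \code{endemic},
#'   \code{threatened}, \code{threat_category}, \code{cites},
#'   \code{national_protected}.
#' @return a [SpeciesCatalog-class].
#' @export
readCatalog <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("species_id", "endemic", "threatened", "threat_category",
              "cites", "national_protected")
    if (!all(need %in% names(df)))
        stop("catalog lacks columns: ",
             paste(setdiff(need, names(df)), collapse = ", "))
    parseFlag <- function(x, col) {
        v <- rep(NA, length(x))
        v[tolower(x) %in% c("1", "true")] <- TRUE
        v[tolower(x) %in% c("0", "false")] <- FALSE
        if (anyNA(v))
            stop("unparseable boolean in column '", col, "': ",
                 paste(utils::head(unique(x[is.na(v)]), 3), collapse = ", "))
        v
    }
    cat <- df$threat_category
    cat[cat == "" | is.na(cat)] <- "none"
    bad <- !cat %in% c(THREAT_CATEGORIES, "none")
    if (any(bad))
        stop("unknown threat_category: ",
             paste(unique(cat[bad]), collapse = ", "))
    speciesCatalog(df$species_id,
                   endemic = parseFlag(df$endemic, "endemic"),
                   threatened = parseFlag(df$threatened, "threatened"),
                   threat_category = cat,
                   cites = parseFlag(df$cites, "cites"),
                   national_protected = parseFlag(df$national_protected,
                                                  "national_protected"))
}

#' Write a catalog back to CSV
#' @param catalog a [SpeciesCatalog-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
    stopifnot(is(catalog, "SpeciesCatalog"))
    df <- catalog@species
    for (col in c("endemic", "threatened", "cites", "national_protected"))
        df[[col]] <- as.integer(df[[col]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

# logical membership matrix, species x the five conservation groups
groupMembership <- function(catalog) {
    df <- catalog@species
    m <- cbind(ALL = rep(TRUE, nrow(df)), ENDEMIC = df$endemic,
               THREATENED = df$threatened, CITES = df$cites,
               NATIONAL_PROTECTED = df$national_protected)
    rownames(m) <- df$species_id
    m
}

#' Group denominators N_g
#'
#' Number of catalog species in each of the five conservation groups;
#' these are the denominators of all richness ratios and coverage
#' proportions.
#'
#' @param x a [SpeciesCatalog-class].
#' @return named integer vector over
#'   \code{ALL, ENDEMIC, THREATENED, CITES, NATIONAL_PROTECTED}.
#' @rdname groupTotals
#' @export
setMethod("groupTotals", "SpeciesCatalog", function(x) {
    m <- groupMembership(x)
    structure(as.integer(colSums(m)), names = colnames(m))
})

#' Species belonging to one conservation group
#'
#' @param catalog a [SpeciesCatalog-class].
#' @param group one of \code{CONSERVATION_GROUPS}.
#' @return character vector of species ids.
#' @export
speciesInGroup <- function(catalog, group) {
    stopifnot(is(catalog, "SpeciesCatalog"))
    group <- match.arg(group, CONSERVATION_GROUPS)
    m <- groupMembership(catalog)
    rownames(m)[m[, group]]
}

#' Construct an occurrence table from records
#'
#' @param records data.frame with columns \code{species_id}, \code{lon},
#'   \code{lat}.
#' @param counters optional named integer provenance counters; defaults to
#'   treating all records as read and retained.
#' @return an [OccurrenceTable-class].
#' @export
occurrenceTable <- function(records, counters = NULL) {
    records <- as.data.frame(records)[c("species_id", "lon", "lat")]
    if (is.null(counters))
        counters <- c(read = nrow(records), retained = nrow(records),
                      dropped_no_coordinates = 0L,
                      dropped_unknown_species = 0L,
                      dropped_out_of_extent = 0L)
    new("OccurrenceTable", records = records,
        counters = structure(as.integer(counters), names = names(counters)))
}

#' Read and validate occurrence records
#'
#' Drops records lacking parseable coordinates (the operational reading of
#' "no detailed locality information"), records of species absent from
#' the catalog, and records outside the grid extent (with a warning);
#' every drop is counted.
#'
#' @param path CSV with header columns \code{species_id},
#'   \code{decimal_longitude}, \code{decimal_latitude}; extra columns are
#'   ignored.
#' @param catalog a [SpeciesCatalog-class].
#' @param grid a [GridSpec-class] defining the accepted extent.
#' @return an [OccurrenceTable-class] with provenance counters.
#' @export
readOccurrences <- function(path, catalog, grid) {
    stopifnot(is(catalog, "SpeciesCatalog"), is(grid, "GridSpec"))
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("species_id", "decimal_longitude", "decimal_latitude")
    if (!all(need %in% names(df)))
        stop("occurrence file lacks columns: ",
             paste(setdiff(need, names(df)), collapse = ", "))
    nRead <- nrow(df)
    lon <- suppressWarnings(as.numeric(df$decimal_longitude))
    lat <- suppressWarnings(as.numeric(df$decimal_latitude))
    badCoord <- !is.finite(lon) | !is.finite(lat) |
        lon < -180 | lon > 180 | lat < -90 | lat > 90
    unknown <- !badCoord & !df$species_id %in% speciesIds(catalog)
    outExt <- !badCoord & !unknown &
        (lon < grid@lonMin | lon > grid@lonMax |
         lat < grid@latMin | lat > grid@latMax)
    if (any(outExt))
        warning(sum(outExt), " record(s) outside the grid extent dropped")
    keep <- !badCoord & !unknown & !outExt
    occurrenceTable(
        data.frame(species_id = df$species_id[keep], lon = lon[keep],
                   lat = lat[keep], stringsAsFactors = FALSE),
        counters = c(read = nRead, retained = sum(keep),
                     dropped_no_coordinates = sum(badCoord),
                     dropped_unknown_species = sum(unknown),
                     dropped_out_of_extent = sum(outExt)))
}

#' Write occurrences to the package's CSV dialect
#' @param occ an [OccurrenceTable-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeOccurrences <- function(occ, path) {
    stopifnot(is(occ, "OccurrenceTable"))
    df <- occ@records
    names(df) <- c("species_id", "decimal_longitude", "decimal_latitude")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Build the species-by-cell incidence matrix
#'
#' Marks (species, cell) present when at least one record maps into the
#' cell via [assignCell()]; duplicate records collapse, so incidence is
#' invariant to record order and duplication.
#'
#' @param occ an [OccurrenceTable-class] (all records inside the extent).
#' @param grid a [GridSpec-class].
#' @param species optional character vector fixing the row universe
#'   (e.g. all catalog species); defaults to the species present in
#'   \code{occ}.
#' @return an [IncidenceMatrix-class].
#' @export
buildIncidence <- function(occ, grid, species = NULL) {
    stopifnot(is(occ, "OccurrenceTable"), is(grid, "GridSpec"))
    rec <- occ@records
    if (is.null(species)) species <- sort(unique(rec$species_id))
    sp <- match(rec$species_id, species)
    if (anyNA(sp))
        stop("records contain species outside the supplied universe")
    cells <- assignCell(rec$lon, rec$lat, grid)
    mat <- Matrix::sparseMatrix(i = sp, j = cells + 1L, x = TRUE,
                                dims = c(length(species), nCells(grid)),
                                dimnames = list(species, NULL))
    new("IncidenceMatrix", mat = methods::as(mat, "lMatrix"), grid = grid)
}

#' Range size of a species
#'
#' Number of grid cells a species occupies, and the corresponding nominal
#' area (cells x [nominalCellArea()]); e.g. 20 cells on a 0.5-degree grid
#' is 60500 km^2 under the 110 km/degree convention.
#'
#' @param incidence an [IncidenceMatrix-class].
#' @param species_id character, species to measure (default: all).
#' @param kmPerDegree km per degree for the nominal area.
#' @return data.frame with columns \code{species_id}, \code{n_cells},
#'   \code{area_km2}.
#' @export
rangeSize <- function(incidence, species_id = NULL, kmPerDegree = 110) {
    stopifnot(is(incidence, "IncidenceMatrix"))
    if (is.null(species_id)) species_id <- speciesIds(incidence)
    miss <- setdiff(species_id, speciesIds(incidence))
    if (length(miss))
        stop("unknown species: ", paste(utils::head(miss, 5),
                                        collapse = ", "))
    n <- Matrix::rowSums(incidence@mat[species_id, , drop = FALSE])
    data.frame(species_id = species_id, n_cells = as.integer(n),
               area_km2 = n * nominalCellArea(incidence@grid, kmPerDegree),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cell species lists
#'
#' @param incidence an [IncidenceMatrix-class].
#' @param cellIds integer 0-based cell ids (default: occupied cells).
#' @return named list (by cell id) of character vectors of species ids.
#' @export
cellSpecies <- function(incidence, cellIds = NULL) {
    stopifnot(is(incidence, "IncidenceMatrix"))
    if (is.null(cellIds)) cellIds <- occupiedCells(incidence)
    sp <- speciesIds(incidence)
    out <- lapply(cellIds, function(cid) sp[incidence@mat[, cid + 1L]])
    names(out) <- as.character(cellIds)
    out
}

#' Species present in a set of cells
#'
#' Union of the species occupying at least one of the given cells.
#'
#' @param incidence an [IncidenceMatrix-class].
#' @param cellIds integer 0-based cell ids.
#' @return character vector of species ids.
#' @export
speciesInCells <- function(incidence, cellIds) {
    stopifnot(is(incidence, "IncidenceMatrix"))
    if (!length(cellIds)) return(character())
    sub <- incidence@mat[, cellIds + 1L, drop = FALSE]
    speciesIds(incidence)[Matrix::rowSums(sub) > 0]
}

#' Export incidence as sparse triplets
#' @param incidence an [IncidenceMatrix-class].
#' @param path output CSV (\code{species_id}, \code{cell_id}).
#' @return the path, invisibly.
#' @export
writeIncidenceCSV <- function(incidence, path) {
    stopifnot(is(incidence, "IncidenceMatrix"))
    tm <- methods::as(methods::as(incidence@mat, "TsparseMatrix"),
                      "lMatrix")
    ord <- order(tm@i, tm@j)
    utils::write.csv(data.frame(species_id = rownames(tm)[tm@i[ord] + 1L],
                                cell_id = tm@j[ord]),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
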