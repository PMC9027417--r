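#' Conservation groups used throughout the package
#'
#' The five analysis groups: every species belongs to \code{ALL}; the other
#' four memberships (endemic, threatened, CITES-listed, nationally
#' protected) come from the species catalog and may overlap.
#'
#' @format character vector of length 5.
#' @export
CONSERVATION_GROUPS <- c("ALL", "ENDEMIC", "THREATENED", "CITES",
                         "NATIONAL_PROTECTED")

#' Threat categories recognised in the catalog
#' @format character vector: Vulnerable, Endangered, Critically Endangered.
#' @export
THREAT_CATEGORIES <- c("VU", "EN", "CR")

# ---------------------------------------------------------------- GridSpec

#' GridSpec: a regular analysis grid in decimal degrees
#'
#' A rectangular grid of square cells in WGS84 decimal degrees. Cells are
#' half-open boxes \eqn{[lon, lon+res) \times [lat, lat+res)}, closed on
#' the grid's outermost north/east edge, with 0-based row-major cell ids
#' counted from the southwest corner (row 0 = southernmost).
#'
#' @slot lonMin,latMin,lonMax,latMax numeric, grid extent in degrees.
#' @slot resolution numeric, cell side in degrees.
#' @slot nRows,nCols integer, grid dimensions.
#' @seealso [makeGrid()], [assignCell()], [cellBounds()]
#' @export
setClass("GridSpec",
    representation(lonMin = "numeric", latMin = "numeric",
                   lonMax = "numeric", latMax = "numeric",
                   resolution = "numeric",
                   nRows = "integer", nCols = "integer"),
    validity = function(object) {
        msg <- NULL
        if (length(object@resolution) != 1L || object@resolution <= 0)
            msg <- c(msg, "'resolution' must be a positive scalar")
        if (object@lonMin >= object@lonMax || object@latMin >= object@latMax)
            msg <- c(msg, "extent bounds are inverted or empty")
        if (object@nRows < 1L || object@nCols < 1L)
            msg <- c(msg, "grid must span at least one cell")
        ok <- isTRUE(all.equal(object@lonMin +
                               object@nCols * object@resolution,
                               object@lonMax)) &&
              isTRUE(all.equal(object@latMin +
                               object@nRows * object@resolution,
                               object@latMax))
        if (is.null(msg) && !ok)
            msg <- c(msg, "extent is not an exact tiling of resolution")
        if (is.null(msg)) TRUE else msg
    })

setMethod("show", "GridSpec", function(object) {
    cat("GridSpec:", object@nRows, "x", object@nCols, "cells (",
        nCells(object), "total ) at", object@resolution, "deg\n")
    cat("  extent: lon [", object@lonMin, ",", object@lonMax,
        "]  lat [", object@latMin, ",", object@latMax, "]\n")
})

#' @rdname grid-accessors
#' @export
setMethod("nRows", "GridSpec", function(x) x@nRows)
#' @rdname grid-accessors
#' @export
setMethod("nCols", "GridSpec", function(x) x@nCols)
#' @rdname grid-accessors
#' @export
setMethod("nCells", "GridSpec", function(x) x@nRows * x@nCols)
#' @rdname grid-accessors
#' @export
setMethod("gridResolution", "GridSpec", function(x) x@resolution)

# ----------------------------------------------------------- SpeciesCatalog

#' SpeciesCatalog: species and their conservation-group memberships
#'
#' One row per species with logical membership flags for the endemic,
#' threatened, CITES-listed and nationally protected groups, plus the
#' red-list threat category (VU/EN/CR) for threatened species. Every
#' species implicitly belongs to the ALL group.
#'
#' @slot species data.frame with columns \code{species_id},
#'   \code{endemic}, \code{threatened}, \code{threat_category},
#'   \code{cites}, \code{national_protected}.
#' @seealso [readCatalog()], [groupTotals()], [speciesInGroup()]
#' @export
setClass("SpeciesCatalog",
    representation(species = "data.frame"),
    validity = function(object) {
        df <- object@species
        need <- c("species_id", "endemic", "threatened", "threat_category",
                  "cites", "national_protected")
        if (!all(need %in% names(df)))
            return(paste("catalog lacks columns:",
                         paste(setdiff(need, names(df)), collapse = ", ")))
        if (anyDuplicated(df$species_id))
            return("duplicate species_id in catalog")
        bad <- xor(df$threatened, df$threat_category %in% THREAT_CATEGORIES)
        if (any(bad))
            return(paste0("threat_category inconsistent with threatened ",
                          "flag for: ",
                          paste(utils::head(df$species_id[bad], 5),
                                collapse = ", ")))
        TRUE
    })

setMethod("show", "SpeciesCatalog", function(object) {
    tot <- groupTotals(object)
    cat("SpeciesCatalog:", tot[["ALL"]], "species\n")
    for (g in CONSERVATION_GROUPS[-1])
        cat(sprintf("  %-19s %5d (%s)\n", g, tot[[g]],
                    formatPercent(tot[[g]], tot[["ALL"]], digits = 1)))
})

#' @rdname speciesIds
#' @export
setMethod("speciesIds", "SpeciesCatalog",
          function(x) x@species$species_id)

# ---------------------------------------------------------- OccurrenceTable

#' OccurrenceTable: validated occurrence records with provenance counters
#'
#' Retained records (species id plus decimal-degree coordinates) together
#' with counts of what was read and why records were dropped.
#'
#' @slot records data.frame with columns \code{species_id}, \code{lon},
#'   \code{lat}.
#' @slot counters named integer vector: \code{read}, \code{retained},
#'   \code{dropped_no_coordinates}, \code{dropped_unknown_species},
#'   \code{dropped_out_of_extent}.
#' @seealso [readOccurrences()], [buildIncidence()]
#' @export
setClass("OccurrenceTable",
    representation(records = "data.frame", counters = "integer"),
    validity = function(object) {
        need <- c("read", "retained", "dropped_no_coordinates",
                  "dropped_unknown_species", "dropped_out_of_extent")
        if (!all(need %in% names(object@counters)))
            return("missing provenance counters")
        k <- object@counters
        if (k[["read"]] != k[["retained"]] +
                sum(k[need[-(1:2)]]))
            return("counters do not sum to records read")
        if (nrow(object@records) != k[["retained"]])
            return("retained counter disagrees with record count")
        TRUE
    })

setMethod("show", "OccurrenceTable", function(object) {
    k <- object@counters
    cat("OccurrenceTable:", k[["retained"]], "records retained of",
        k[["read"]], "read\n")
    cat("  dropped: no-coordinates", k[["dropped_no_coordinates"]],
        "| unknown-species", k[["dropped_unknown_species"]],
        "| out-of-extent", k[["dropped_out_of_extent"]], "\n")
})

# ---------------------------------------------------------- IncidenceMatrix

#' IncidenceMatrix: boolean species-by-cell occupancy
#'
#' Sparse logical matrix of species (rows) by grid cells (columns, one per
#' cell id of the grid). Built from occurrence records; duplicate records
#' in a cell collapse to a single presence.
#'
#' @slot mat a sparse logical \code{Matrix} (species x cells).
#' @slot grid the [GridSpec-class] the columns index.
#' @seealso [buildIncidence()], [rangeSize()], [occupiedCells()]
#' @export
setClass("IncidenceMatrix",
    representation(mat = "Matrix", grid = "GridSpec"),
    validity = function(object) {
        if (ncol(object@mat) != nCells(object@grid))
            return("matrix columns do not match grid cell count")
        if (is.null(rownames(object@mat)))
            return("matrix must carry species ids as rownames")
        TRUE
    })

setMethod("show", "IncidenceMatrix", function(object) {
    cat("IncidenceMatrix:", nrow(object@mat), "species x",
        ncol(object@mat), "cells;", length(occupiedCells(object)),
        "cells occupied\n")
})

#' @rdname speciesIds
#' @export
setMethod("speciesIds", "IncidenceMatrix", function(x) rownames(x@mat))

#' Occupied cells of an incidence matrix
#'
#' @param x an \code{IncidenceMatrix}.
#' @return integer vector of 0-based cell ids holding at least one species.
#' @rdname occupiedCells
#' @export
setMethod("occupiedCells", "IncidenceMatrix", function(x) {
    which(Matrix::colSums(x@mat) > 0) - 1L
})

# ---------------------------------------------------------- RichnessPattern

#' RichnessPattern: per-cell group richness and the composite index
#'
#' For every grid cell and conservation group g, the species count
#' \eqn{S_{gc}}, the ratio \eqn{r_{gc} = S_{gc}/N_g}, and the composite
#' richness index \eqn{R_c = \sum_g r_{gc}} summed over the five groups
#' (so \eqn{0 \le R_c \le 5}).
#'
#' @slot counts integer matrix, groups x cells.
#' @slot ratios numeric matrix, groups x cells.
#' @slot composite numeric vector, \eqn{R_c} per cell.
#' @slot totals named integer, group denominators \eqn{N_g}.
#' @slot grid the underlying [GridSpec-class].
#' @seealso [groupRichness()], [topRichnessHotspots()]
#' @export
setClass("RichnessPattern",
    representation(counts = "matrix", ratios = "matrix",
                   composite = "numeric", totals = "integer",
                   grid = "GridSpec"),
    validity = function(object) {
        if (!identical(rownames(object@counts), CONSERVATION_GROUPS))
            return("count rows must be the five conservation groups")
        if (length(object@composite) != nCells(object@grid))
            return("composite length must equal total cell count")
        if (any(object@composite < 0 | object@composite > 5 + 1e-12))
            return("composite index outside [0, 5]")
        TRUE
    })

setMethod("show", "RichnessPattern", function(object) {
    occ <- sum(object@composite > 0)
    cat("RichnessPattern over", nCells(object@grid), "cells (",
        occ, "occupied ); composite index max",
        round(max(object@composite), 3), "\n")
})

# --------------------------------------------------- ComplementaritySolution

#' ComplementaritySolution: the greedy set-cover selection trace
#'
#' Ordered cells picked by the greedy complementarity rule: at each step
#' the cell holding the most not-yet-covered species is selected and its
#' species are removed from consideration, until every species is covered.
#' Each step records the newly covered species and the cell's
#' complementarity value \eqn{G_c}, the sum over groups of (newly covered
#' species of the group) / \eqn{N_g}.
#'
#' @slot cellIds integer, selected cells in selection order (0-based ids).
#' @slot gains numeric, \eqn{G_c} per step.
#' @slot gainComponents numeric matrix, groups x steps (per-group parts of
#'   each gain).
#' @slot newlyCovered list of character vectors, species first covered at
#'   each step.
#' @slot nUncovered integer, species still uncovered after each step.
#' @seealso [greedyComplementarity()], [topComplementarityHotspots()]
#' @export
setClass("ComplementaritySolution",
    representation(cellIds = "integer", gains = "numeric",
                   gainComponents = "matrix", newlyCovered = "list",
                   nUncovered = "integer"),
    validity = function(object) {
        n <- length(object@cellIds)
        if (length(object@gains) != n || length(object@newlyCovered) != n ||
            length(object@nUncovered) != n)
            return("trace slots must have one entry per step")
        if (n && object@nUncovered[n] != 0L)
            return("solution does not cover all species")
        if (any(object@gains <= 0))
            return("every selected cell must have positive gain")
        sp <- unlist(object@newlyCovered)
        if (anyDuplicated(sp))
            return("newly covered sets must be pairwise disjoint")
        TRUE
    })

setMethod("show", "ComplementaritySolution", function(object) {
    cat("ComplementaritySolution:", length(object@cellIds),
        "cells cover", length(unlist(object@newlyCovered)),
        "species; total gain", round(sum(object@gains), 4), "\n")
})

# ----------------------------------------------------------- HotspotRanking

#' HotspotRanking: an ordered hotspot cell list with scores
#'
#' Cells ranked by a diversity score (composite richness \eqn{R_c} or
#' complementarity gain \eqn{G_c}), cut at a target size K with tie
#' extension: every cell tied with the K-th score is kept.
#'
#' @slot algorithm \code{"richness"} or \code{"complementarity"}.
#' @slot cellIds integer, cells in rank order (0-based ids).
#' @slot scores numeric, non-increasing along the order.
#' @slot k integer, the nominal cutoff size.
#' @slot tieExtended logical, whether ties pushed the list past K.
#' @seealso [topRichnessHotspots()], [topComplementarityHotspots()],
#'   [integrateHotspots()]
#' @export
setClass("HotspotRanking",
    representation(algorithm = "character", cellIds = "integer",
                   scores = "numeric", k = "integer",
                   tieExtended = "logical"),
    validity = function(object) {
        if (!object@algorithm %in% c("richness", "complementarity"))
            return("algorithm must be 'richness' or 'complementarity'")
        if (length(object@cellIds) != length(object@scores))
            return("cellIds and scores lengths differ")
        if (is.unsorted(rev(object@scores)))
            return("scores must be non-increasing along the order")
        if (anyDuplicated(object@cellIds))
            return("duplicate cells in ranking")
        TRUE
    })

setMethod("show", "HotspotRanking", function(object) {
    cat("HotspotRanking (", object@algorithm, "): ",
        length(object@cellIds), " cells (K = ", object@k,
        if (object@tieExtended) ", tie-extended" else "", ")\n", sep = "")
})

#' @rdname hotspotCells
#' @export
setMethod("hotspotCells", "HotspotRanking", function(x) x@cellIds)

# ------------------------------------------------------------ FinalHotspots

#' FinalHotspots: first- and second-class hotspots from rank integration
#'
#' Integration of the two algorithms' rankings: cells found by both are
#' first-class hotspots ordered by the sum of their two rank orders; cells
#' found by exactly one fill the remaining slots (second class) ordered by
#' their single rank order, up to a total of \code{kTotal} cells.
#'
#' @slot table data.frame with columns \code{cell_id}, \code{class}
#'   (\code{"first"}/\code{"second"}), \code{order_richness},
#'   \code{order_complementarity} (NA where absent), \code{sort_key}.
#' @slot kTotal integer, the target total size.
#' @seealso [integrateHotspots()], [gapAnalysis()], [coverageReport()]
#' @export
setClass("FinalHotspots",
    representation(table = "data.frame", kTotal = "integer"),
    validity = function(object) {
        df <- object@table
        need <- c("cell_id", "class", "order_richness",
                  "order_complementarity", "sort_key")
        if (!all(need %in% names(df)))
            return("hotspot table lacks required columns")
        if (anyDuplicated(df$cell_id))
            return("first and second class hotspots must be disjoint")
        if (!all(df$class %in% c("first", "second")))
            return("unknown hotspot class")
        TRUE
    })

setMethod("show", "FinalHotspots", function(object) {
    cat("FinalHotspots:", sum(object@table$class == "first"),
        "first-class +", sum(object@table$class == "second"),
        "second-class cells (target", object@kTotal, ")\n")
})

#' Hotspot cell ids
#'
#' @param x a \code{HotspotRanking} or \code{FinalHotspots} object.
#' @return integer vector of 0-based cell ids (both classes combined for
#'   \code{FinalHotspots}, in integration order).
#' @rdname hotspotCells
#' @export
setMethod("hotspotCells", "FinalHotspots", function(x) x@table$cell_id)

#' First/second-class hotspot accessors
#'
#' @param x a [FinalHotspots-class] object.
#' @return integer vector of 0-based cell ids.
#' @export
firstClass <- function(x) {
    stopifnot(is(x, "FinalHotspots"))
    x@table$cell_id[x@table$class == "first"]
}

#' @rdname firstClass
#' @export
secondClass <- function(x) {
    stopifnot(is(x, "FinalHotspots"))
    x@table$cell_id[x@table$class == "second"]
}

# -------------------------------------------------------- CorrelationReport

#' CorrelationReport: pairwise Pearson correlations with class labels
#'
#' Symmetric matrix of Pearson r over distribution-pattern vectors, the
#' two-sided p-values, and the seven-class qualitative label for each
#' pair (perfect / very strong / strong / moderate / weak / very weak /
#' no correlation, on |r|).
#'
#' @slot r,p numeric matrices; \code{r} symmetric with unit diagonal.
#' @slot classes character matrix of class labels.
#' @seealso [correlogram()], [classifyR()]
#' @export
setClass("CorrelationReport",
    representation(r = "matrix", p = "matrix", classes = "matrix"),
    validity = function(object) {
        r <- object@r
        if (nrow(r) != ncol(r)) return("r must be square")
        if (max(abs(r - t(r))) > 1e-12) return("r must be symmetric")
        if (max(abs(diag(r) - 1)) > 1e-12) return("diagonal r must be 1")
        if (any(abs(r) > 1 + 1e-12)) return("|r| exceeds 1")
        TRUE
    })

setMethod("show", "CorrelationReport", function(object) {
    cat("CorrelationReport:", nrow(object@r), "patterns;",
        sum(upper.tri(object@r)), "pairs\n")
    print(round(object@r, 2))
})

# ---------------------------------------------------------------- ReserveSet

#' ReserveSet: nature-reserve polygons with a tier attribute
#'
#' Reserve features read from GeoJSON. Each feature is one (multi)polygon
#' with a \code{tier} of \code{"national"} or \code{"provincial"} and a
#' name. Rings are closed and checked for self-intersection.
#'
#' @slot features list; each element has \code{name}, \code{tier} and
#'   \code{polygons} (a list of polygons, each a list of rings: the first
#'   ring is the outer boundary, later rings are holes; a ring is a
#'   two-column lon/lat matrix whose last vertex repeats the first).
#' @seealso [readReserves()], [coveredCells()], [genReserves()]
#' @export
setClass("ReserveSet",
    representation(features = "list"),
    validity = function(object) {
        for (f in object@features) {
            if (!all(c("name", "tier", "polygons") %in% names(f)))
                return("feature lacks name/tier/polygons")
            if (!f$tier %in% c("national", "provincial"))
                return(paste("unsupported reserve tier:", f$tier))
        }
        TRUE
    })

setMethod("show", "ReserveSet", function(object) {
    tiers <- vapply(object@features, `[[`, "", "tier")
    cat("ReserveSet:", length(object@features), "features (",
        sum(tiers == "national"), "national,",
        sum(tiers == "provincial"), "provincial )\n")
})

#' Reserve tiers
#' @param x a [ReserveSet-class].
#' @return character vector of tiers, one per feature.
#' @export
reserveTiers <- function(x) {
    stopifnot(is(x, "ReserveSet"))
    vapply(x@features, `[[`, "", "tier")
}

# ------------------------------------------------------------ CoverageReport

#' CoverageReport: species coverage per area class (Table-1 style)
#'
#' For each area class (whole study area, hotspot set, hotspots covered by
#' each reserve tier, the corresponding conservation gaps, and all grid
#' cells covered by each tier) the number of grid cells, and per
#' conservation group the number of species present in at least one member
#' cell with its proportion of the group total.
#'
#' @slot cellCounts named integer, grid cells per area class.
#' @slot speciesCounts integer matrix, groups x area classes.
#' @slot proportions numeric matrix, groups x area classes (of \eqn{N_g}).
#' @slot totals named integer, group denominators.
#' @seealso [coverageReport()], [coverageTable()]
#' @export
setClass("CoverageReport",
    representation(cellCounts = "integer", speciesCounts = "matrix",
                   proportions = "matrix", totals = "integer"))

setMethod("show", "CoverageReport", function(object) {
    cat("CoverageReport over", ncol(object@speciesCounts),
        "area classes\n")
    print(coverageTable(object))
})

# ----------------------------------------------------------- SuitabilityStack

#' SuitabilityStack: per-species habitat-suitability rasters
#'
#' One continuous suitability surface in [0, 1] per species on a shared
#' fine grid (default 5 arc-minutes), for one climate scenario. Values
#' below the retention threshold tau are rejected before any use: the
#' suitable-habitat-area (SHA) mask of a species is \eqn{v \ge \tau}, and
#' the superposed community map is \eqn{V_x = \sum_s v_{sx}[v_{sx} \ge
#' \tau]}.
#'
#' @slot scenario character, e.g. \code{"current"} or \code{"future"}.
#' @slot grid the fine-resolution [GridSpec-class]; raster row 1 is the
#'   southernmost grid row.
#' @slot values 3-d numeric array (rows x cols x species), species named.
#' @slot tau numeric retention threshold (default 0.75; values less than
#'   tau are rejected, tau itself is retained).
#' @seealso [suitabilityStack()], [thresholdAndSuperpose()], [shaMask()]
#' @export
setClass("SuitabilityStack",
    representation(scenario = "character", grid = "GridSpec",
                   values = "array", tau = "numeric"),
    validity = function(object) {
        d <- dim(object@values)
        if (length(d) != 3L)
            return("values must be a rows x cols x species array")
        if (d[1] != nRows(object@grid) || d[2] != nCols(object@grid))
            return("raster dimensions do not match the grid")
        if (is.null(dimnames(object@values)[[3]]))
            return("species dimension must be named")
        v <- object@values
        if (any(v < 0 | v > 1, na.rm = TRUE))
            return("suitability values outside [0, 1]")
        if (object@tau < 0 || object@tau > 1)
            return("tau must lie in [0, 1]")
        TRUE
    })

setMethod("show", "SuitabilityStack", function(object) {
    d <- dim(object@values)
    cat("SuitabilityStack (", object@scenario, "): ", d[3],
        " species on ", d[1], "x", d[2], " cells, tau = ",
        object@tau, "\n", sep = "")
})

#' @rdname speciesIds
#' @export
setMethod("speciesIds", "SuitabilityStack",
          function(x) dimnames(x@values)[[3]])

#' Species ids held by an object
#'
#' @param x a \code{SpeciesCatalog}, \code{IncidenceMatrix} or
#'   \code{SuitabilityStack}.
#' @return character vector of species identifiers.
#' @rdname speciesIds
#' @name speciesIds
NULL

# ------------------------------------------------------------------ SimConfig

#' SimConfig: parameters of the synthetic study generator
#'
#' Bundles every knob of the synthetic data generator. Group membership
#' rates default to the composition of the Chinese medicinal flora that
#' motivates the package (endemic 32.9%, threatened 6.4%, CITES-listed
#' 3.5%, nationally protected 0.8%). A single seed drives independent
#' random sub-streams per generator stage, so outputs are reproducible
#' bit-for-bit and changing one stage does not perturb the others.
#'
#' @slot seed integer master seed.
#' @slot nSpecies integer number of species.
#' @slot groupProps named numeric membership probabilities
#'   (\code{endemic}, \code{threatened}, \code{cites},
#'   \code{national_protected}).
#' @slot extent numeric length-4 (lonMin, latMin, lonMax, latMax).
#' @slot resolution numeric coarse grid resolution in degrees.
#' @slot nPlantedHotspots integer number of planted high-diversity cells.
#' @slot hotspotBoost numeric relative sampling weight of a planted cell
#'   against a single ordinary cell.
#' @slot recordsRange numeric length-2; records per species are drawn
#'   log-uniformly between these bounds.
#' @slot rangeSd numeric isotropic spread (degrees) of a species' records
#'   around its range centre.
#' @slot futureShiftNorth numeric northward displacement (degrees) of
#'   every species' niche centre under the future climate scenario.
#' @slot reserveCoverageFraction numeric target fraction of the extent
#'   covered by the generated reserve union.
#' @slot fineFactor integer sub-cells per coarse cell side for suitability
#'   rasters (6 gives 5 arc-minutes under a 0.5-degree grid).
#' @seealso [simConfig()], [simulateStudy()]
#' @export
setClass("SimConfig",
    representation(seed = "integer", nSpecies = "integer",
                   groupProps = "numeric", extent = "numeric",
                   resolution = "numeric", nPlantedHotspots = "integer",
                   hotspotBoost = "numeric", recordsRange = "numeric",
                   rangeSd = "numeric", futureShiftNorth = "numeric",
                   reserveCoverageFraction = "numeric",
                   fineFactor = "integer"),
    validity = function(object) {
        p <- object@groupProps
        need <- c("endemic", "threatened", "cites", "national_protected")
        if (!all(need %in% names(p)))
            return("groupProps must name all four memberships")
        if (any(p < 0 | p > 1))
            return("group proportions must lie in [0, 1]")
        if (object@nSpecies < 10L)
            return("nSpecies must be at least 10")
        if (length(object@extent) != 4L)
            return("extent must be (lonMin, latMin, lonMax, latMax)")
        if (object@reserveCoverageFraction < 0 ||
            object@reserveCoverageFraction > 1)
            return("reserveCoverageFraction must lie in [0, 1]")
        if (object@recordsRange[1] < 1 ||
            object@recordsRange[2] < object@recordsRange[1])
            return("recordsRange must be increasing and >= 1")
        TRUE
    })

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: seed", object@seed, "|", object@nSpecies,
        "species |", object@nPlantedHotspots, "planted hotspots (boost",
        object@hotspotBoost, ")\n")
})
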