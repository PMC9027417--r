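#' @import methods
NULL

#' Grid accessors
#'
#' Accessors for [GridSpec-class] objects: number of rows/columns, total
#' cell count and the grid resolution in decimal degrees.
#'
#' @param x a \code{GridSpec}.
#' @return \code{nRows}, \code{nCols} and \code{nCells} return integers;
#'   \code{gridResolution} returns a numeric scalar (degrees).
#' @name grid-accessors
#' @aliases nRows nCols nCells gridResolution
#' @examples
#' g <- makeGrid(c(0, 0, 1, 1), 0.5)
#' nCells(g)  # 4
NULL

#' @rdname grid-accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname grid-accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' @rdname grid-accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname grid-accessors
#' @export
setGeneric("gridResolution", function(x) standardGeneric("gridResolution"))

#' @rdname speciesIds
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname groupTotals
#' @export
setGeneric("groupTotals", function(x) standardGeneric("groupTotals"))

#' @rdname occupiedCells
#' @export
setGeneric("occupiedCells", function(x) standardGeneric("occupiedCells"))

#' @rdname hotspotCells
#' @export
setGeneric("hotspotCells", function(x) standardGeneric("hotspotCells"))
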