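#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: \code{frames}
#' extracts the intensity array, \code{pixelSize} and \code{frameInterval} the
#' spatial/temporal calibration, \code{maskMatrix} the logical mask,
#' \code{puncta} the punctum table, \code{pixelSets} the per-punctum pixel
#' sets, \code{distances} the nearest-neighbour distances,
#' \code{colocFraction} the colocalized fraction, \code{pValue} the null-model
#' p-value, \code{nullCurve} the mean cumulative distance curve and
#' \code{tracks} the trajectory table.
#'
#' @param x an object of the appropriate class.
#' @return The slot contents (see each method's class documentation).
#' @name accessors
#' @aliases frames pixelSize frameInterval maskMatrix puncta pixelSets
#'   distances colocFraction pValue nullCurve tracks
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("puncta", function(x) standardGeneric("puncta"))

#' @rdname accessors
#' @export
setGeneric("pixelSets", function(x) standardGeneric("pixelSets"))

#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname accessors
#' @export
setGeneric("colocFraction", function(x) standardGeneric("colocFraction"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("nullCurve", function(x) standardGeneric("nullCurve"))

#' @rdname accessors
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))
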