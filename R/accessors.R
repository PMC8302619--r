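#' @describeIn accessors intensity array (Y x X x T) of an ImageStack.
#' @export
setMethod("frames", "ImageStack", function(x) x@data)

#' @describeIn accessors pixel size (nm) of an ImageStack.
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @describeIn accessors pixel size (nm) of a CellMask.
#' @export
setMethod("pixelSize", "CellMask", function(x) x@pixelSize)

#' @describeIn accessors frame interval (s) of an ImageStack.
#' @export
setMethod("frameInterval", "ImageStack", function(x) x@frameInterval)

#' @describeIn accessors frame interval (s) of a TrajectorySet.
#' @export
setMethod("frameInterval", "TrajectorySet", function(x) x@frameInterval)

#' @describeIn accessors logical mask matrix of a CellMask.
#' @export
setMethod("maskMatrix", "CellMask", function(x) x@mask)

#' @describeIn accessors punctum table of a SegmentationResult.
#' @export
setMethod("puncta", "SegmentationResult", function(x) x@puncta)

#' @describeIn accessors per-punctum pixel sets of a SegmentationResult.
#' @export
setMethod("pixelSets", "SegmentationResult", function(x) x@pixelSets)

#' @describeIn accessors nearest-neighbour distances (nm) of a DistanceResult.
#' @export
setMethod("distances", "DistanceResult", function(x) x@distances)

#' @describeIn accessors colocalized fraction of a DistanceResult.
#' @export
setMethod("colocFraction", "DistanceResult", function(x) x@fraction)

#' @describeIn accessors p-value of a RandomizationNull.
#' @export
setMethod("pValue", "RandomizationNull", function(x) x@pValue)

#' @describeIn accessors mean cumulative distance curve of a RandomizationNull.
#' @export
setMethod("nullCurve", "RandomizationNull", function(x) x@curve)

#' @describeIn accessors trajectory table of a TrajectorySet.
#' @export
setMethod("tracks", "TrajectorySet", function(x) x@tracks)

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@data)
    cat(sprintf(
        "ImageStack '%s': %d frame(s), %d x %d px, %.1f nm/px%s\n",
        object@channel, d[3], d[1], d[2], object@pixelSize,
        if (is.na(object@frameInterval)) "" else
            sprintf(", %.3g s/frame", object@frameInterval)
    ))
    invisible(NULL)
})

setMethod("show", "CellMask", function(object) {
    cat(sprintf(
        "CellMask: %d x %d px, %d in-mask pixels, %.1f nm/px\n",
        nrow(object@mask), ncol(object@mask), sum(object@mask),
        object@pixelSize
    ))
    invisible(NULL)
})

setMethod("show", "SegmentationResult", function(object) {
    cat(sprintf(
        "SegmentationResult: %d puncta over %d frame(s)\n",
        nrow(object@puncta), object@nFrames
    ))
    invisible(NULL)
})

setMethod("show", "DistanceResult", function(object) {
    cat(sprintf(
        "DistanceResult: n_A = %d, n_B = %d, %.1f%% colocalized at < %g nm\n",
        object@nA, object@nB, 100 * object@fraction, object@criterion
    ))
    invisible(NULL)
})

setMethod("show", "RandomizationNull", function(object) {
    cat(sprintf(
        "RandomizationNull: %d iterations, null fraction %.4f +/- %.4f, p = %.4g\n",
        object@nIterations, mean(object@fractions),
        stats::sd(object@fractions), object@pValue
    ))
    invisible(NULL)
})

setMethod("show", "TrajectorySet", function(object) {
    n <- length(unique(object@tracks$trajectory))
    cat(sprintf(
        "TrajectorySet: %d trajectories, %d localizations, dt = %g s\n",
        n, nrow(object@tracks), object@frameInterval
    ))
    invisible(NULL)
})
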