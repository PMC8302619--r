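#' @import methods
NULL

#' Calibrated fluorescence image stack
#'
#' A T-frame single-channel fluorescence movie (or single frame) together with
#' its spatial and temporal calibration. The pixel grid is stored as a
#' \code{Y x X x T} numeric array in arbitrary fluorescence units (FU).
#'
#' Coordinate convention used throughout the package: pixel indices are
#' 0-based with x = column and y = row; a pixel's centre sits at its integer
#' index, so the physical position of pixel (y, x) is
#' \code{(y * pixelSize, x * pixelSize)} in nm. Sub-pixel positions (centroids,
#' trajectories) are continuous on the same axes.
#'
#' @slot data numeric array, dim \code{c(Y, X, T)}; finite, non-negative after
#'   background correction.
#' @slot pixelSize numeric(1), physical width of one pixel in nm (> 0).
#' @slot frameInterval numeric(1), time between frames in s (> 0), or
#'   \code{NA_real_} for single frames / uncalibrated stacks.
#' @slot channel character(1), free-text channel label.
#'
#' @examples
#' img <- ImageStack(array(runif(64 * 64), c(64, 64, 1)), pixelSize = 100)
#' dim(frames(img))
#' @export
setClass("ImageStack",
    representation(
        data = "array",
        pixelSize = "numeric",
        frameInterval = "numeric",
        channel = "character"
    )
)

setValidity("ImageStack", function(object) {
    d <- object@data
    if (length(dim(d)) != 3L) {
        return("data must be a Y x X x T array")
    }
    if (any(dim(d) < 1L)) {
        return("all of Y, X, T must be >= 1")
    }
    if (!all(is.finite(d))) {
        return("intensities must be finite")
    }
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0) {
        return("pixelSize must be a single positive number (nm)")
    }
    if (length(object@frameInterval) != 1L ||
        (!is.na(object@frameInterval) && object@frameInterval <= 0)) {
        return("frameInterval must be a single positive number (s) or NA")
    }
    TRUE
})

#' Binary cell (or ROI) mask
#'
#' @slot mask logical matrix (Y x X) with at least one \code{TRUE} pixel.
#' @slot pixelSize numeric(1), nm per pixel.
#'
#' @export
setClass("CellMask",
    representation(mask = "matrix", pixelSize = "numeric")
)

setValidity("CellMask", function(object) {
    if (!is.logical(object@mask)) {
        return("mask must be logical")
    }
    if (!any(object@mask)) {
        return("mask must contain at least one TRUE pixel")
    }
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0) {
        return("pixelSize must be a single positive number (nm)")
    }
    TRUE
})

#' Peripheral/central partition of a cell mask
#'
#' The peripheral region is an annulus extending a fixed depth inward from the
#' cell boundary (Euclidean distance transform); the remaining core is the
#' central region. The two regions are disjoint and together tile the mask.
#'
#' @slot peripheral logical matrix.
#' @slot central logical matrix.
#' @slot annulusDepth integer(1), annulus depth in pixels.
#'
#' @export
setClass("RegionPartition",
    representation(
        peripheral = "matrix",
        central = "matrix",
        annulusDepth = "integer"
    )
)

setValidity("RegionPartition", function(object) {
    if (any(object@peripheral & object@central)) {
        return("peripheral and central regions must be disjoint")
    }
    if (object@annulusDepth < 1L) {
        return("annulusDepth must be >= 1")
    }
    TRUE
})

#' Result of spot segmentation
#'
#' Holds one row per segmented punctum (sub-pixel intensity-weighted centroid
#' in nm, pixel count, integrated/peak intensity, border threshold) together
#' with the pixel sets and the parameters used. Pixel sets of distinct puncta
#' within a frame are disjoint.
#'
#' @slot puncta data.frame with columns \code{frame, id, x_nm, y_nm,
#'   n_pixels, integrated_FU, peak_FU, border_FU}.
#' @slot pixelSets list of integer matrices (columns y, x; 0-based) parallel
#'   to the rows of \code{puncta}.
#' @slot nFrames integer(1).
#' @slot parameters list of segmentation parameters used.
#'
#' @export
setClass("SegmentationResult",
    representation(
        puncta = "data.frame",
        pixelSets = "list",
        nFrames = "integer",
        parameters = "list"
    )
)

setValidity("SegmentationResult", function(object) {
    if (nrow(object@puncta) != length(object@pixelSets)) {
        return("one pixel set per punctum required")
    }
    if (object@nFrames < 1L) {
        return("nFrames must be >= 1")
    }
    TRUE
})

#' Nearest-neighbour centre-to-centre distance result
#'
#' One distance per channel-A punctum (to the nearest channel-B punctum) plus
#' the fraction colocalized at a distance criterion (strict \code{<}).
#'
#' @slot distances numeric, nm, one per A punctum.
#' @slot criterion numeric(1), colocalization criterion in nm.
#' @slot fraction numeric(1), fraction of A puncta with distance < criterion.
#' @slot nA,nB integer(1), numbers of A and B puncta.
#'
#' @export
setClass("DistanceResult",
    representation(
        distances = "numeric",
        criterion = "numeric",
        fraction = "numeric",
        nA = "integer",
        nB = "integer"
    )
)

setValidity("DistanceResult", function(object) {
    if (any(object@distances < 0)) {
        return("distances must be >= 0")
    }
    if (object@fraction < 0 || object@fraction > 1) {
        return("fraction must lie in [0, 1]")
    }
    TRUE
})

#' Object-randomization null model for colocalization
#'
#' Per-iteration colocalized fractions obtained after randomly relocating the
#' B objects within the cell mask, the mean cumulative distance curve with a
#' pointwise 95% band, and the empirical (add-one) p-value for the observed
#' fraction.
#'
#' @slot nIterations integer(1).
#' @slot fractions numeric, one colocalized fraction per iteration.
#' @slot curve data.frame with columns \code{r_nm, mean, lo, hi}: mean
#'   cumulative distance distribution with pointwise 2.5/97.5 percentiles.
#' @slot pValue numeric(1), (1 + #\{fraction_i >= observed\}) / (n + 1).
#' @slot observed numeric(1), the observed colocalized fraction.
#'
#' @export
setClass("RandomizationNull",
    representation(
        nIterations = "integer",
        fractions = "numeric",
        curve = "data.frame",
        pValue = "numeric",
        observed = "numeric"
    )
)

setValidity("RandomizationNull", function(object) {
    if (object@nIterations < 1L) {
        return("nIterations must be >= 1")
    }
    if (object@pValue <= 0 || object@pValue > 1) {
        return("pValue must lie in (0, 1]")
    }
    if (object@pValue < 1 / (object@nIterations + 1) - 1e-12) {
        return("pValue cannot be smaller than 1/(nIterations + 1)")
    }
    TRUE
})

#' A set of linked single-particle trajectories
#'
#' @slot tracks data.frame with columns \code{trajectory, frame, x_nm, y_nm}
#'   (frame indices 0-based, strictly increasing within a trajectory; gaps
#'   allowed).
#' @slot frameInterval numeric(1), s.
#' @slot maxSpeed numeric(1), the linking displacement threshold in um/s.
#'
#' @export
setClass("TrajectorySet",
    representation(
        tracks = "data.frame",
        frameInterval = "numeric",
        maxSpeed = "numeric"
    )
)

setValidity("TrajectorySet", function(object) {
    need <- c("trajectory", "frame", "x_nm", "y_nm")
    if (!all(need %in% names(object@tracks))) {
        return(paste("tracks needs columns", paste(need, collapse = ", ")))
    }
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0) {
        return("frameInterval must be a single positive number (s)")
    }
    TRUE
})
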