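#' Construct an ImageStack
#'
#' @param data numeric matrix (one frame) or Y x X x T array.
#' @param pixelSize pixel width in nm.
#' @param frameInterval time between frames in s (NA for single frames).
#' @param channel free-text channel label.
#' @return An \linkS4class{ImageStack}.
#' @examples
#' ImageStack(matrix(0, 32, 32), pixelSize = 100)
#' @export
ImageStack <- function(data, pixelSize, frameInterval = NA_real_,
                       channel = "") {
    if (is.matrix(data)) {
        data <- array(data, c(dim(data), 1L))
    }
    new("ImageStack",
        data = data, pixelSize = as.numeric(pixelSize),
        frameInterval = as.numeric(frameInterval), channel = channel
    )
}

#' Construct a CellMask
#'
#' @param mask logical or numeric (non-zero = inside) matrix.
#' @param pixelSize pixel width in nm.
#' @return A \linkS4class{CellMask}.
#' @export
CellMask <- function(mask, pixelSize) {
    if (!is.logical(mask)) {
        mask <- mask != 0
    }
    new("CellMask", mask = mask, pixelSize = as.numeric(pixelSize))
}

#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into an
#' \linkS4class{ImageStack}, with page order taken as frame order. Sample
#' values are rescaled from the [0, 1] convention of \pkg{tiff} back to
#' integer counts (FU) according to the stored bit depth, so that a stack
#' written by \code{\link{writeStack}} round-trips bit-exactly.
#'
#' @param path path to a readable TIFF file.
#' @param pixelSize pixel width in nm.
#' @param frameInterval frame interval in s (NA for single frames).
#' @param channel channel label.
#' @return An \linkS4class{ImageStack}.
#' @seealso \code{\link{writeStack}}
#' @export
readStack <- function(path, pixelSize, frameInterval = NA_real_,
                      channel = "") {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    fr <- lapply(pages, function(p) {
        if (length(dim(p)) == 3L) {
            stop("multi-sample pages unsupported (expected grayscale TIFF)")
        }
        bits <- attr(p, "bits.per.sample")
        if (is.null(bits)) bits <- 16L
        round(p * (2^bits - 1))
    })
    d <- dim(fr[[1L]])
    ImageStack(
        array(unlist(fr), c(d[1L], d[2L], length(fr))),
        pixelSize = pixelSize, frameInterval = frameInterval,
        channel = channel
    )
}

#' Write an ImageStack as a 16-bit multi-page TIFF
#'
#' Intensities are clamped to [0, 65535] and rounded; one page per frame.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
    d <- frames(stack)
    pages <- lapply(seq_len(dim(d)[3L]), function(t) {
        pmin(pmax(round(d[, , t]), 0), 65535) / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    invisible(path)
}

#' Read a binary mask from TIFF
#'
#' Any non-zero pixel is taken as inside the mask.
#'
#' @inheritParams readStack
#' @return A \linkS4class{CellMask}.
#' @export
readMask <- function(path, pixelSize) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) {
        stop("multi-sample pages unsupported (expected grayscale TIFF)")
    }
    CellMask(m > 0, pixelSize = pixelSize)
}

#' Background-correct an image stack
#'
#' Subtracts, frame by frame, the mean intensity of a background region
#' recorded outside the cell; negative results are clamped to 0 so that
#' downstream segmentation sees non-negative intensities. Correction is
#' per-frame, so slow drifts in the background level are removed.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param bgRegion a \linkS4class{CellMask} marking the background region
#'   (must be non-empty; should be disjoint from the analysis mask).
#' @return A corrected \linkS4class{ImageStack}.
#' @examples
#' img <- ImageStack(matrix(50, 16, 16), pixelSize = 100)
#' bg <- CellMask(matrix(TRUE, 16, 16), pixelSize = 100)
#' range(frames(backgroundCorrect(img, bg)))
#' @export
backgroundCorrect <- function(stack, bgRegion) {
    m <- maskMatrix(bgRegion)
    if (!any(m)) {
        stop("background region is empty")
    }
    d <- frames(stack)
    for (t in seq_len(dim(d)[3L])) {
        fr <- d[, , t]
        d[, , t] <- pmax(fr - mean(fr[m]), 0)
    }
    initialize(stack, data = d)
}

#' Partition a cell mask into peripheral annulus and central core
#'
#' The peripheral region consists of mask pixels whose Euclidean distance to
#' the mask boundary is at most \code{annulusDepth} pixels (e.g. 15 px = 2.4
#' um at 160 nm pixels); the remaining core is the central region.
#'
#' @param mask a \linkS4class{CellMask}.
#' @param annulusDepth annulus depth in pixels (>= 1; default 15).
#' @return A \linkS4class{RegionPartition}.
#' @export
partitionRegions <- function(mask, annulusDepth = 15L) {
    annulusDepth <- as.integer(annulusDepth)
    if (annulusDepth < 1L) {
        stop("annulusDepth must be >= 1")
    }
    m <- maskMatrix(mask)
    if (!any(m)) {
        stop("mask is empty")
    }
    # distance (px) from each in-mask pixel to the nearest outside pixel;
    # pad so the image border counts as boundary
    pad <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
    pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    dm <- EBImage::distmap(pad)[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]
    peripheral <- m & dm <= annulusDepth
    central <- m & !peripheral
    new("RegionPartition",
        peripheral = peripheral, central = central,
        annulusDepth = annulusDepth
    )
}

#' Variance of a product of two independent variables
#'
#' For independent X and Y,
#' \deqn{Var(XY) = Var(X)Var(Y) + Var(X)E[Y]^2 + Var(Y)E[X]^2.}
#'
#' @param meanX,varX mean and variance of X.
#' @param meanY,varY mean and variance of Y.
#' @return The variance of the product XY.
#' @examples
#' varianceOfProduct(2, 1, 3, 4) # 29
#' @export
varianceOfProduct <- function(meanX, varX, meanY, varY) {
    if (any(c(varX, varY) < 0)) {
        stop("variances must be >= 0")
    }
    varX * varY + varX * meanY^2 + varY * meanX^2
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (is.null(seed)) {
        return(expr)
    }
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(
        if (is.null(old)) {
            rm(".Random.seed", envir = globalenv())
        } else {
            assign(".Random.seed", old, envir = globalenv())
        }
    )
    set.seed(seed)
    expr
}
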