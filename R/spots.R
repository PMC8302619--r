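#' Find local intensity maxima above a seed threshold
#'
#' Returns pixels strictly greater than all 8 neighbours and at least
#' \code{seedThreshold}. Plateaus (flat-topped peaks whose surround is
#' strictly lower) contribute one seed each, the lexicographically lowest
#' (y, x) pixel of the plateau.
#'
#' @param frame numeric matrix (background-corrected).
#' @param seedThreshold minimum seed intensity, FU.
#' @return Integer matrix with columns \code{y, x} (0-based pixel indices),
#'   ordered by decreasing intensity.
#' @export
findLocalMaxima <- function(frame, seedThreshold) {
    ny <- nrow(frame)
    nx <- ncol(frame)
    pad <- matrix(-Inf, ny + 2L, nx + 2L)
    pad[2:(ny + 1L), 2:(nx + 1L)] <- frame
    ctr <- pad[2:(ny + 1L), 2:(nx + 1L)]
    allLess <- matrix(TRUE, ny, nx)
    allLessEq <- matrix(TRUE, ny, nx)
    anyGreater <- matrix(FALSE, ny, nx)
    for (dy in -1:1) {
        for (dx in -1:1) {
            if (dy == 0L && dx == 0L) next
            nb <- pad[2:(ny + 1L) + dy, 2:(nx + 1L) + dx]
            allLess <- allLess & nb < ctr
            allLessEq <- allLessEq & nb <= ctr
            anyGreater <- anyGreater | nb > ctr
        }
    }
    strict <- allLess & ctr >= seedThreshold
    seeds <- which(strict)
    # plateau members: >= all neighbours, tied with at least one, none higher
    plateau <- allLessEq & !allLess & !anyGreater & ctr >= seedThreshold
    if (any(plateau)) {
        # label equal-valued 8-connected plateau components; a component is a
        # maximum only if no member has an equal neighbour outside it that is
        # itself adjacent to something higher (handled by anyGreater above)
        lab <- EBImage::bwlabel(plateau)
        for (l in seq_len(max(lab))) {
            idx <- which(lab == l)
            if (length(unique(ctr[idx])) != 1L) next
            ys <- (idx - 1L) %% ny
            xs <- (idx - 1L) %/% ny
            # a plateau reaching the image border is not a genuine peak
            # (its surround is unobserved)
            if (any(ys == 0L | xs == 0L | ys == ny - 1L | xs == nx - 1L)) {
                next
            }
            # lexicographically lowest (y, x): smallest row, then column
            o <- order(ys, xs)[1L]
            seeds <- c(seeds, idx[o])
        }
    }
    if (length(seeds) == 0L) {
        return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("y", "x"))))
    }
    seeds <- seeds[order(-ctr[seeds])]
    cbind(
        y = as.integer((seeds - 1L) %% ny),
        x = as.integer((seeds - 1L) %/% ny)
    )
}

#' Border intensity threshold from the radial intensity profile
#'
#' Computes mean intensities in concentric 1-pixel-wide rings around a seed
#' out to \code{rMax} pixels (rings truncated at the image edge) and returns
#' the ring mean at the first radius where the profile flattens, i.e. where
#' the relative drop between successive ring means falls below
#' \code{flattenTol}. This is the local background shoulder of the spot. If
#' the profile never flattens, the outermost ring mean is returned.
#'
#' @param frame numeric matrix.
#' @param seed c(y, x) 0-based pixel index of a local maximum.
#' @param rMax maximum ring radius in pixels.
#' @param flattenTol relative-drop tolerance defining "flat".
#' @return The border threshold in FU.
#' @export
radialBorderThreshold <- function(frame, seed, rMax = 10L, flattenTol = 0.05) {
    ny <- nrow(frame)
    nx <- ncol(frame)
    y0 <- seed[1L]
    x0 <- seed[2L]
    ys <- max(0L, y0 - rMax):min(ny - 1L, y0 + rMax)
    xs <- max(0L, x0 - rMax):min(nx - 1L, x0 + rMax)
    d <- sqrt(outer((ys - y0)^2, (xs - x0)^2, "+"))
    ring <- round(d)
    vals <- frame[ys + 1L, xs + 1L]
    keep <- ring <= rMax
    means <- tapply(vals[keep], ring[keep], mean)
    rr <- as.integer(names(means))
    means <- as.numeric(means)[order(rr)]
    if (length(means) < 2L) {
        return(means[length(means)])
    }
    for (i in 2:length(means)) {
        prev <- means[i - 1L]
        if (prev <= 0) {
            return(max(means[i], 0))
        }
        if ((prev - means[i]) / prev < flattenTol) {
            return(means[i])
        }
    }
    means[length(means)]
}

#' Grow a punctum from a seed by monotone radial descent
#'
#' Breadth-first growth from the seed in order of decreasing intensity. A
#' pixel is accepted iff its intensity is above the border threshold, at most
#' the intensity of the already-accepted 4-neighbour through which it is
#' reached (monotone descent), and it is 4-adjacent to an accepted pixel.
#' The centroid is the intensity-weighted mean of the accepted pixel
#' positions with border-subtracted weights.
#'
#' @param frame numeric matrix.
#' @param seed c(y, x) 0-based local maximum with intensity above the border
#'   threshold.
#' @param borderThreshold border intensity, FU.
#' @param pixelSize nm per pixel (for the centroid in nm).
#' @param claimed optional logical matrix of pixels already owned by other
#'   puncta; grown pixels are marked in place semantics by the caller via the
#'   returned pixel set.
#' @return list(pixels = integer matrix (y, x) 0-based, centroid_x_nm,
#'   centroid_y_nm, integrated, peak).
#' @export
growSpot <- function(frame, seed, borderThreshold, pixelSize = 1,
                     claimed = NULL) {
    ny <- nrow(frame)
    nx <- ncol(frame)
    if (is.null(claimed)) {
        claimed <- matrix(FALSE, ny, nx)
    }
    sI <- frame[seed[1L] + 1L, seed[2L] + 1L]
    stopifnot(sI > borderThreshold)
    accY <- integer(0)
    accX <- integer(0)
    seen <- matrix(FALSE, ny, nx)
    frY <- seed[1L]
    frX <- seed[2L]
    frI <- sI
    seen[seed[1L] + 1L, seed[2L] + 1L] <- TRUE
    dys <- c(-1L, 1L, 0L, 0L)
    dxs <- c(0L, 0L, -1L, 1L)
    while (length(frY) > 0L) {
        j <- which.max(frI)
        y <- frY[j]
        x <- frX[j]
        qI <- frI[j]
        frY <- frY[-j]
        frX <- frX[-j]
        frI <- frI[-j]
        accY <- c(accY, y)
        accX <- c(accX, x)
        for (k in 1:4) {
            yn <- y + dys[k]
            xn <- x + dxs[k]
            if (yn < 0L || xn < 0L || yn >= ny || xn >= nx) next
            if (claimed[yn + 1L, xn + 1L] || seen[yn + 1L, xn + 1L]) next
            v <- frame[yn + 1L, xn + 1L]
            if (v > borderThreshold && v <= qI) {
                seen[yn + 1L, xn + 1L] <- TRUE
                frY <- c(frY, yn)
                frX <- c(frX, xn)
                frI <- c(frI, v)
            }
        }
    }
    ints <- frame[cbind(accY + 1L, accX + 1L)]
    w <- ints - borderThreshold
    list(
        pixels = cbind(y = accY, x = accX),
        centroid_x_nm = sum(w * accX) / sum(w) * pixelSize,
        centroid_y_nm = sum(w * accY) / sum(w) * pixelSize,
        integrated = sum(ints),
        peak = sI
    )
}

#' Segment puncta in every frame of a stack
#'
#' Per frame: local maxima above the seed threshold are found, a border
#' intensity threshold is derived from the radial profile around each seed,
#' and spots are grown by monotone radial descent. Seeds are processed in
#' decreasing intensity order and earlier spots keep contested pixels, so
#' pixel sets within a frame are disjoint.
#'
#' If \code{seedThreshold} is NULL it is set per frame to
#' \code{median + k * mad} of the frame intensities (a robust background
#' mean + k SD rule); thresholds are image-specific configuration, as in
#' per-image spot-detection practice. For noisy data a light Gaussian
#' pre-filter (\code{smoothSigmaPx}, the same noise-removal filtering used
#' on raw microscopy frames) suppresses single-pixel noise maxima without
#' moving spot centroids (a Gaussian blurred by a Gaussian keeps its
#' centre).
#'
#' @param stack a background-corrected \linkS4class{ImageStack}.
#' @param seedThreshold absolute seed threshold, FU, or NULL for automatic.
#' @param k robust-threshold multiplier for the automatic rule.
#' @param flattenTol,rMax radial-profile parameters
#'   (\code{\link{radialBorderThreshold}}).
#' @param minPixels discard puncta smaller than this many pixels.
#' @param smoothSigmaPx Gaussian pre-filter sigma in pixels (0 = none).
#' @return A \linkS4class{SegmentationResult}; frames are 0-based in the
#'   punctum table.
#' @export
segmentSpots <- function(stack, seedThreshold = NULL, k = 5,
                         flattenTol = 0.05, rMax = 10L, minPixels = 1L,
                         smoothSigmaPx = 0) {
    d <- frames(stack)
    px <- pixelSize(stack)
    nT <- dim(d)[3L]
    rows <- list()
    sets <- list()
    nOut <- 0L
    for (t in seq_len(nT)) {
        fr <- d[, , t]
        if (smoothSigmaPx > 0) {
            fr <- EBImage::gblur(fr, sigma = smoothSigmaPx)
        }
        thr <- if (is.null(seedThreshold)) {
            stats::median(fr) + k * stats::mad(fr)
        } else {
            seedThreshold
        }
        seeds <- findLocalMaxima(fr, thr)
        claimed <- matrix(FALSE, nrow(fr), ncol(fr))
        id <- 0L
        for (s in seq_len(nrow(seeds))) {
            sy <- seeds[s, 1L]
            sx <- seeds[s, 2L]
            if (claimed[sy + 1L, sx + 1L]) next
            border <- radialBorderThreshold(fr, c(sy, sx), rMax, flattenTol)
            if (fr[sy + 1L, sx + 1L] <= border) next
            sp <- growSpot(fr, c(sy, sx), border, px, claimed)
            if (nrow(sp$pixels) < minPixels) next
            claimed[cbind(sp$pixels[, 1L] + 1L, sp$pixels[, 2L] + 1L)] <- TRUE
            id <- id + 1L
            nOut <- nOut + 1L
            rows[[nOut]] <- data.frame(
                frame = t - 1L, id = id,
                x_nm = sp$centroid_x_nm, y_nm = sp$centroid_y_nm,
                n_pixels = nrow(sp$pixels),
                integrated_FU = sp$integrated, peak_FU = sp$peak,
                border_FU = border
            )
            sets[[nOut]] <- sp$pixels
        }
    }
    tab <- if (nOut) {
        do.call(rbind, rows)
    } else {
        data.frame(
            frame = integer(0), id = integer(0), x_nm = numeric(0),
            y_nm = numeric(0), n_pixels = integer(0),
            integrated_FU = numeric(0), peak_FU = numeric(0),
            border_FU = numeric(0)
        )
    }
    new("SegmentationResult",
        puncta = tab, pixelSets = sets, nFrames = nT,
        parameters = list(
            seedThreshold = seedThreshold, k = k,
            flattenTol = flattenTol, rMax = rMax, minPixels = minPixels,
            smoothSigmaPx = smoothSigmaPx
        )
    )
}

#' Fraction of whole-cell fluorescence attributed to puncta
#'
#' Per frame, the sum of punctum integrated intensities divided by the total
#' intensity within the cell mask - the consistency check used to validate
#' per-image detection thresholds.
#'
#' @param seg a \linkS4class{SegmentationResult} derived from \code{stack}.
#' @param stack the segmented \linkS4class{ImageStack}.
#' @param mask a \linkS4class{CellMask}.
#' @return Numeric vector, one fraction in [0, 1] per frame.
#' @export
punctaFluorescenceFraction <- function(seg, stack, mask) {
    d <- frames(stack)
    m <- maskMatrix(mask)
    tab <- puncta(seg)
    vapply(seq_len(dim(d)[3L]), function(t) {
        tot <- sum(d[, , t][m])
        if (tot <= 0) {
            stop("zero whole-cell fluorescence in frame ", t - 1L)
        }
        min(sum(tab$integrated_FU[tab$frame == t - 1L]) / tot, 1)
    }, numeric(1))
}
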