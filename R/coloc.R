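# Coerce puncta input (data.frame with x_nm/y_nm, matrix, or
# SegmentationResult) to an n x 2 matrix of centroids in nm.
asXY <- function(p) {
    if (is(p, "SegmentationResult")) {
        p <- puncta(p)
    }
    if (is.data.frame(p)) {
        return(cbind(p$x_nm, p$y_nm))
    }
    if (is.matrix(p) && ncol(p) >= 2L) {
        return(p[, 1:2, drop = FALSE])
    }
    stop("cannot interpret puncta input")
}

#' Nearest-neighbour centre-to-centre distances
#'
#' For each channel-A punctum, the Euclidean distance (nm) to the nearest
#' channel-B punctum, plus the fraction colocalized at the criterion
#' (strict \code{<}).
#'
#' @param A,B puncta: data.frames with \code{x_nm, y_nm} columns, two-column
#'   matrices, or \linkS4class{SegmentationResult}s.
#' @param criterionNm colocalization criterion in nm (default 160; use 130
#'   for super-resolution data at 65 nm pixels).
#' @return A \linkS4class{DistanceResult}.
#' @examples
#' a <- data.frame(x_nm = 0, y_nm = 0)
#' b <- data.frame(x_nm = c(300, 1000), y_nm = c(400, 0))
#' distances(nearestNeighbourDistances(a, b)) # 500
#' @export
nearestNeighbourDistances <- function(A, B, criterionNm = 160) {
    a <- asXY(A)
    b <- asXY(B)
    if (nrow(a) < 1L || nrow(b) < 1L) {
        stop("both point sets must be non-empty")
    }
    # row-wise minimum over the full cross-distance matrix, chunked to bound
    # memory on large inputs
    nA <- nrow(a)
    d <- numeric(nA)
    chunk <- max(1L, floor(4e6 / nrow(b)))
    for (s in seq(1L, nA, by = chunk)) {
        i <- s:min(s + chunk - 1L, nA)
        dx <- outer(a[i, 1L], b[, 1L], "-")
        dy <- outer(a[i, 2L], b[, 2L], "-")
        d[i] <- sqrt(apply(dx * dx + dy * dy, 1L, min))
    }
    new("DistanceResult",
        distances = d, criterion = as.numeric(criterionNm),
        fraction = mean(d < criterionNm),
        nA = nA, nB = nrow(b)
    )
}

#' Colocalized fraction at a distance criterion
#'
#' Fraction of distances strictly below the criterion; monotone
#' non-decreasing in the criterion.
#'
#' @param result a \linkS4class{DistanceResult} or a numeric vector of
#'   distances (nm).
#' @param criterionNm criterion in nm (> 0).
#' @return The fraction in [0, 1].
#' @export
colocalizedFraction <- function(result, criterionNm = 160) {
    if (criterionNm <= 0 && criterionNm != 0) {
        stop("criterion must be > 0")
    }
    d <- if (is(result, "DistanceResult")) distances(result) else result
    mean(d < criterionNm)
}

#' Randomization null model for object-based colocalization
#'
#' Repeatedly relocates the channel-B objects to uniformly random in-mask
#' positions and recomputes the nearest-neighbour distances against the fixed
#' A centroids. In \code{"object"} mode every B punctum's segmented pixel set
#' is moved rigidly (shape preserved, whole set inside the mask, no overlap
#' between relocated objects, bounded retries); \code{"point"} mode relocates
#' centroids only and is much faster. The p-value uses the add-one
#' permutation estimator \code{(1 + #\{null fraction >= observed\}) / (n + 1)}
#' and is therefore never exactly 0.
#'
#' @param A fixed puncta (see \code{\link{nearestNeighbourDistances}}).
#' @param B puncta to randomize; a \linkS4class{SegmentationResult} is
#'   required for \code{mode = "object"}.
#' @param mask a \linkS4class{CellMask}.
#' @param nIterations number of randomizations (default 100).
#' @param criterionNm colocalization criterion, nm.
#' @param mode "object" (rigid pixel-set relocation) or "point".
#' @param seed RNG seed.
#' @param curveMaxNm,curveStepNm grid for the cumulative distance curve.
#' @return A \linkS4class{RandomizationNull}.
#' @export
randomizeNull <- function(A, B, mask, nIterations = 100L, criterionNm = 160,
                          mode = c("object", "point"), seed = NULL,
                          curveMaxNm = 2000, curveStepNm = 20) {
    mode <- match.arg(mode)
    nIterations <- as.integer(nIterations)
    stopifnot(nIterations >= 1L)
    m <- maskMatrix(mask)
    if (!any(m)) {
        stop("mask is empty")
    }
    px <- pixelSize(mask)
    a <- asXY(A)
    bxy <- asXY(B)
    observed <- colocalizedFraction(
        nearestNeighbourDistances(a, bxy, criterionNm), criterionNm
    )
    if (mode == "object") {
        if (!is(B, "SegmentationResult")) {
            stop("object-mode randomization needs a SegmentationResult for B")
        }
        sets <- pixelSets(B)
    }
    inPix <- which(m)
    ys <- (inPix - 1L) %% nrow(m)
    xs <- (inPix - 1L) %/% nrow(m)
    grid <- seq(0, curveMaxNm, by = curveStepNm)
    fracs <- numeric(nIterations)
    curves <- matrix(NA_real_, nIterations, length(grid))
    withSeed(seed, {
        for (it in seq_len(nIterations)) {
            if (mode == "point") {
                j <- sample(length(inPix), nrow(bxy), replace = TRUE)
                nb <- cbind(
                    (xs[j] + stats::runif(nrow(bxy), -0.5, 0.5)) * px,
                    (ys[j] + stats::runif(nrow(bxy), -0.5, 0.5)) * px
                )
            } else {
                claimed <- matrix(FALSE, nrow(m), ncol(m))
                nb <- matrix(NA_real_, nrow(bxy), 2L)
                for (i in seq_len(nrow(bxy))) {
                    set <- sets[[i]]
                    cy <- round(bxy[i, 2L] / px)
                    cx <- round(bxy[i, 1L] / px)
                    placed <- FALSE
                    for (try in seq_len(200L)) {
                        j <- sample(length(inPix), 1L)
                        dyx <- c(ys[j] - cy, xs[j] - cx)
                        py <- set[, 1L] + dyx[1L]
                        pxl <- set[, 2L] + dyx[2L]
                        if (any(py < 0L | pxl < 0L | py >= nrow(m) |
                            pxl >= ncol(m))) {
                            next
                        }
                        idx <- cbind(py + 1L, pxl + 1L)
                        if (!all(m[idx]) || any(claimed[idx])) next
                        claimed[idx] <- TRUE
                        nb[i, ] <- c(
                            bxy[i, 1L] + dyx[2L] * px,
                            bxy[i, 2L] + dyx[1L] * px
                        )
                        placed <- TRUE
                        break
                    }
                    if (!placed) {
                        stop("placement infeasible during randomization")
                    }
                }
            }
            dr <- nearestNeighbourDistances(a, nb, criterionNm)
            fracs[it] <- colocFraction(dr)
            dd <- distances(dr)
            curves[it, ] <- vapply(grid, function(r) mean(dd <= r), numeric(1))
        }
    })
    curve <- data.frame(
        r_nm = grid,
        mean = colMeans(curves),
        lo = apply(curves, 2L, stats::quantile, probs = 0.025),
        hi = apply(curves, 2L, stats::quantile, probs = 0.975)
    )
    new("RandomizationNull",
        nIterations = nIterations, fractions = fracs, curve = curve,
        pValue = (1 + sum(fracs >= observed)) / (nIterations + 1),
        observed = observed
    )
}

#' Manders split coefficient against a reference mask
#'
#' The fraction of a channel's intensity (within the analysis mask) that
#' falls inside a reference mask, e.g. the fraction of receptor fluorescence
#' on actin filaments.
#'
#' @param channelFrame numeric matrix (one background-corrected frame).
#' @param referenceMask logical matrix (e.g. a filament mask).
#' @param analysisMask a \linkS4class{CellMask} or logical matrix.
#' @return The coefficient M in [0, 1].
#' @export
mandersSplit <- function(channelFrame, referenceMask, analysisMask) {
    am <- if (is(analysisMask, "CellMask")) {
        maskMatrix(analysisMask)
    } else {
        analysisMask
    }
    denom <- sum(channelFrame[am])
    if (denom <= 0) {
        stop("zero channel intensity inside the analysis mask")
    }
    sum(channelFrame[am & referenceMask]) / denom
}

#' Binary filament mask from a filament-channel image
#'
#' Gaussian-filters the frame (default sigma 0.5 px, removing uneven
#' background) and thresholds it - by Otsu's method on the filtered image by
#' default, or at an absolute intensity if \code{maskThreshold} is given.
#'
#' @param frame numeric matrix (filament channel, e.g. actin).
#' @param gaussianSigmaPx Gaussian filter sigma in pixels (default 0.5).
#' @param maskThreshold absolute threshold in FU, or NULL for Otsu.
#' @return Logical matrix.
#' @export
makeFilamentMask <- function(frame, gaussianSigmaPx = 0.5,
                             maskThreshold = NULL) {
    f <- EBImage::gblur(frame, sigma = gaussianSigmaPx)
    if (!is.null(maskThreshold)) {
        return(f > maskThreshold)
    }
    rng <- range(f)
    if (diff(rng) == 0) {
        return(matrix(FALSE, nrow(f), ncol(f)))
    }
    fn <- (f - rng[1L]) / diff(rng)
    matrix(fn > EBImage::otsu(fn, range = c(0, 1)), nrow(f), ncol(f))
}

#' Per-region colocalization
#'
#' Assigns each punctum to a region by its centroid pixel (first matching
#' mask in \code{masks}; anything unassigned goes to \code{"outside"}) and
#' computes a \linkS4class{DistanceResult} per region, with the B candidates
#' restricted to the same region.
#'
#' @param A,B puncta (see \code{\link{nearestNeighbourDistances}}).
#' @param masks named list of logical matrices (e.g. on/off filament, or the
#'   peripheral/central partition).
#' @param criterionNm colocalization criterion, nm.
#' @param pixelSizeNm nm per pixel of the mask grids.
#' @return Named list of \linkS4class{DistanceResult}s (NULL where a region
#'   has no A or no B puncta), plus an \code{"outside"} element when any
#'   punctum falls outside all masks.
#' @export
colocByRegion <- function(A, B, masks, criterionNm = 160, pixelSizeNm) {
    a <- asXY(A)
    b <- asXY(B)
    assign1 <- function(p) {
        iy <- round(p[, 2L] / pixelSizeNm) + 1L
        ix <- round(p[, 1L] / pixelSizeNm) + 1L
        reg <- rep("outside", nrow(p))
        for (nm in rev(names(masks))) {
            mm <- masks[[nm]]
            ok <- iy >= 1L & ix >= 1L & iy <= nrow(mm) & ix <= ncol(mm)
            idx <- cbind(
                pmin(pmax(iy, 1L), nrow(mm)),
                pmin(pmax(ix, 1L), ncol(mm))
            )
            inR <- ok & mm[idx]
            reg[inR] <- nm
        }
        reg
    }
    regA <- assign1(a)
    regB <- assign1(b)
    regions <- unique(c(names(masks), if ("outside" %in% c(regA, regB)) "outside"))
    out <- stats::setNames(vector("list", length(regions)), regions)
    for (r in regions) {
        ia <- regA == r
        ib <- regB == r
        if (any(ia) && any(ib)) {
            out[[r]] <- nearestNeighbourDistances(
                a[ia, , drop = FALSE], b[ib, , drop = FALSE], criterionNm
            )
        }
    }
    out
}
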