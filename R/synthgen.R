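#' Render diffraction-limited spots into an image
#'
#' Adds isotropic 2-D Gaussians (the PSF approximation) at continuous 0-based
#' pixel positions. The integrated intensity of an isolated spot is
#' \code{amplitude * 2 * pi * sigma^2} (sigma in pixels).
#'
#' @param dims c(Y, X) image size in pixels.
#' @param yPx,xPx numeric vectors of spot centres (0-based pixel units).
#' @param amplitude peak amplitude(s), FU; recycled.
#' @param sigmaPx PSF sigma in pixels.
#' @param img optional existing matrix to add into.
#' @return A Y x X numeric matrix.
#' @export
renderSpots <- function(dims, yPx, xPx, amplitude, sigmaPx, img = NULL) {
    if (is.null(img)) {
        img <- matrix(0, dims[1L], dims[2L])
    }
    if (length(yPx) == 0L) {
        return(img)
    }
    amplitude <- rep_len(amplitude, length(yPx))
    w <- ceiling(5 * sigmaPx)
    for (i in seq_along(yPx)) {
        y0 <- yPx[i]
        x0 <- xPx[i]
        ys <- max(0L, floor(y0 - w)):min(dims[1L] - 1L, ceiling(y0 + w))
        xs <- max(0L, floor(x0 - w)):min(dims[2L] - 1L, ceiling(x0 + w))
        if (length(ys) == 0L || length(xs) == 0L) next
        gy <- exp(-(ys - y0)^2 / (2 * sigmaPx^2))
        gx <- exp(-(xs - x0)^2 / (2 * sigmaPx^2))
        img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] +
            amplitude[i] * outer(gy, gx)
    }
    img
}

# Poisson shot noise plus Gaussian read noise (sCMOS/EMCCD approximation).
addCameraNoise <- function(img, readSd, shotNoise = TRUE) {
    d <- dim(img)
    v <- as.numeric(img)
    if (shotNoise) {
        v <- stats::rpois(length(v), pmax(v, 0))
    }
    if (readSd > 0) {
        v <- v + stats::rnorm(length(v), 0, readSd)
    }
    matrix(pmax(v, 0), d[1L], d[2L])
}

#' Square cell mask helper
#'
#' @param sideUm side length in um.
#' @param pixelSize pixel size in nm.
#' @return A \linkS4class{CellMask} covering the full square field.
#' @export
squareMask <- function(sideUm = 20, pixelSize = 100) {
    n <- round(sideUm * 1000 / pixelSize)
    CellMask(matrix(TRUE, n, n), pixelSize = pixelSize)
}

# Draw n points uniformly over the mask area (continuous, nm), honouring a
# minimum spacing to `avoid` (matrix x_nm, y_nm) and among themselves.
placeUniform <- function(mask, n, minSpacingNm = 0, avoid = NULL,
                         maxTries = 200L) {
    m <- maskMatrix(mask)
    px <- pixelSize(mask)
    inPix <- which(m)
    ys <- (inPix - 1L) %% nrow(m)
    xs <- (inPix - 1L) %/% nrow(m)
    accX <- if (is.null(avoid)) numeric(0) else avoid[, 1L]
    accY <- if (is.null(avoid)) numeric(0) else avoid[, 2L]
    nAvoid <- length(accX)
    out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("x_nm", "y_nm")))
    for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(maxTries)) {
            j <- sample(length(inPix), 1L)
            x <- (xs[j] + stats::runif(1, -0.5, 0.5)) * px
            y <- (ys[j] + stats::runif(1, -0.5, 0.5)) * px
            if (minSpacingNm <= 0 || length(accX) == 0L ||
                min((accX - x)^2 + (accY - y)^2) >= minSpacingNm^2) {
                ok <- TRUE
                break
            }
        }
        if (!ok) {
            stop("placement infeasible: could not honour minimum spacing")
        }
        accX <- c(accX, x)
        accY <- c(accY, y)
        out[i, ] <- c(x, y)
    }
    out
}

#' Generate a two-channel field of puncta with known colocalization
#'
#' Channel-B centroids are placed uniformly at random within the mask;
#' \code{floor(colocFraction * nA)} channel-A centroids are placed uniformly
#' within a disc of \code{offsetRadiusNm} around distinct B centroids (so
#' every flagged pair passes the 160 nm criterion with margin) and the
#' remaining A centroids are placed uniformly within the mask. A minimum
#' spacing (default 4 sigma) is kept within each channel, and - by default -
#' between unpaired A centroids and all B centroids, so that the returned
#' colocalization flags coincide exactly with the distance criterion applied
#' to the true centroids. Both channels are rendered as sums of Gaussian PSF
#' spots on a constant baseline with Poisson shot noise plus Gaussian read
#' noise.
#'
#' The read-noise SD is chosen so that the peak signal-to-background-noise
#' ratio equals \code{snr}: \code{sd_total = amplitude / snr} with the Poisson
#' contribution of the baseline included.
#'
#' @param mask a \linkS4class{CellMask}.
#' @param nA,nB numbers of A and B puncta.
#' @param colocFraction fraction of A puncta constructed colocalized, [0, 1].
#' @param offsetRadiusNm radius of the colocalization offset disc (nm).
#' @param psfSigmaNm PSF sigma (nm).
#' @param amplitude peak spot amplitude above baseline (FU).
#' @param baseline constant background level (FU).
#' @param snr peak amplitude / background noise SD; ignored if
#'   \code{noise = FALSE}.
#' @param minSpacingNm minimum centre spacing (default \code{4 * psfSigmaNm}).
#' @param crossChannelExclusion keep unpaired A at least \code{minSpacingNm}
#'   from every B centroid (criterion-proof ground truth). Set \code{FALSE}
#'   for plain CSR placement of the unpaired remainder.
#' @param noise add camera noise (default TRUE).
#' @param seed RNG seed (NULL = use current RNG state).
#' @return A list with \code{stackA}, \code{stackB} (ImageStacks) and
#'   \code{truth}: \code{punctaA} (x_nm, y_nm, colocalized), \code{punctaB}
#'   (x_nm, y_nm).
#' @export
makePunctaField <- function(mask, nA, nB, colocFraction,
                            offsetRadiusNm = 80, psfSigmaNm = 150,
                            amplitude = 100, baseline = 100, snr = 5,
                            minSpacingNm = 4 * psfSigmaNm,
                            crossChannelExclusion = TRUE,
                            noise = TRUE, seed = NULL) {
    stopifnot(nA >= 0, nB >= 0, colocFraction >= 0, colocFraction <= 1)
    withSeed(seed, {
        m <- maskMatrix(mask)
        px <- pixelSize(mask)
        B <- placeUniform(mask, nB, minSpacingNm)
        nColoc <- floor(colocFraction * nA)
        if (nColoc > nB) {
            stop("not enough B puncta to host the colocalized A puncta")
        }
        hosts <- if (nColoc > 0) sample(nB, nColoc) else integer(0)
        A <- matrix(NA_real_, nA, 2L,
            dimnames = list(NULL, c("x_nm", "y_nm"))
        )
        for (i in seq_len(nColoc)) {
            for (try in seq_len(200L)) {
                r <- offsetRadiusNm * sqrt(stats::runif(1))
                th <- stats::runif(1, 0, 2 * pi)
                x <- B[hosts[i], 1L] + r * cos(th)
                y <- B[hosts[i], 2L] + r * sin(th)
                iy <- round(y / px)
                ix <- round(x / px)
                if (iy >= 0 && ix >= 0 && iy < nrow(m) && ix < ncol(m) &&
                    m[iy + 1L, ix + 1L]) {
                    A[i, ] <- c(x, y)
                    break
                }
            }
            if (is.na(A[i, 1L])) {
                stop("placement infeasible: colocalized A punctum")
            }
        }
        nFree <- nA - nColoc
        if (nFree > 0) {
            avoid <- rbind(if (crossChannelExclusion) B else NULL,
                A[seq_len(nColoc), , drop = FALSE])
            A[nColoc + seq_len(nFree), ] <-
                placeUniform(mask, nFree, minSpacingNm, avoid = avoid)
        }
        sigmaPx <- psfSigmaNm / px
        readSd <- sqrt(max((amplitude / snr)^2 - baseline, 0))
        render <- function(P) {
            img <- renderSpots(dim(m), P[, 2L] / px, P[, 1L] / px,
                amplitude, sigmaPx
            ) + baseline
            if (noise) img <- addCameraNoise(img, readSd)
            ImageStack(img, pixelSize = px)
        }
        list(
            stackA = render(A), stackB = render(B),
            truth = list(
                punctaA = data.frame(
                    x_nm = A[, 1L], y_nm = A[, 2L],
                    colocalized = seq_len(nA) <= nColoc
                ),
                punctaB = data.frame(x_nm = B[, 1L], y_nm = B[, 2L])
            )
        )
    })
}

#' Generate a synthetic filament (actin-like) image
#'
#' Smooth random curves (cubic splines through random waypoints) rendered
#' with a Gaussian cross-section, plus a binary ground-truth mask of pixels
#' within 2 sigma of a filament centreline.
#'
#' @param mask a \linkS4class{CellMask}.
#' @param nFilaments number of filaments (>= 1).
#' @param psfSigmaNm cross-section sigma (nm).
#' @param amplitude stamp amplitude (FU); the ridge intensity is
#'   approximately \code{amplitude * sqrt(2*pi) * sigmaPx / step}.
#' @param baseline background level (FU).
#' @param noise add camera noise.
#' @param snr ridge amplitude / background noise SD when \code{noise}.
#' @param seed RNG seed.
#' @return list(stack = ImageStack, truthMask = logical matrix).
#' @export
makeFilamentImage <- function(mask, nFilaments = 5, psfSigmaNm = 150,
                              amplitude = 20, baseline = 50, noise = FALSE,
                              snr = 10, seed = NULL) {
    stopifnot(nFilaments >= 1)
    withSeed(seed, {
        m <- maskMatrix(mask)
        px <- pixelSize(mask)
        sigmaPx <- psfSigmaNm / px
        step <- 0.25
        img <- matrix(0, nrow(m), ncol(m))
        centreY <- numeric(0)
        centreX <- numeric(0)
        for (f in seq_len(nFilaments)) {
            nW <- sample(3:5, 1L)
            W <- placeUniform(mask, nW) / px # waypoints, px units
            tt <- seq(0, 1, length.out = nW)
            tDense <- seq(0, 1, length.out = 2000L)
            dx <- stats::spline(tt, W[, 1L], xout = tDense)$y
            dy <- stats::spline(tt, W[, 2L], xout = tDense)$y
            # resample at uniform arc length so the stamp spacing (and hence
            # the ridge intensity A * sqrt(2 pi) * sigma / step) is exact
            arc <- c(0, cumsum(sqrt(diff(dx)^2 + diff(dy)^2)))
            sAt <- seq(0, arc[length(arc)], by = step)
            cx <- stats::approx(arc, dx, xout = sAt)$y
            cy <- stats::approx(arc, dy, xout = sAt)$y
            keep <- cy >= 0 & cx >= 0 & cy <= nrow(m) - 1 & cx <= ncol(m) - 1
            centreY <- c(centreY, cy[keep])
            centreX <- c(centreX, cx[keep])
            img <- renderSpots(dim(m), cy[keep], cx[keep], amplitude,
                sigmaPx,
                img = img
            )
        }
        # truth: the FWHM footprint - pixels within sqrt(2 ln 2) sigma of a
        # centreline point, i.e. where the cross-section exceeds half-ridge
        truth <- matrix(FALSE, nrow(m), ncol(m))
        rHalf <- sqrt(2 * log(2)) * sigmaPx
        r2 <- rHalf^2
        w <- ceiling(rHalf)
        for (i in seq_along(centreY)) {
            ys <- max(0L, floor(centreY[i] - w)):
                min(nrow(m) - 1L, ceiling(centreY[i] + w))
            xs <- max(0L, floor(centreX[i] - w)):
                min(ncol(m) - 1L, ceiling(centreX[i] + w))
            d2 <- outer((ys - centreY[i])^2, (xs - centreX[i])^2, "+")
            truth[ys + 1L, xs + 1L] <- truth[ys + 1L, xs + 1L] | d2 <= r2
        }
        img <- img + baseline
        if (noise) {
            ridge <- amplitude * sqrt(2 * pi) * sigmaPx / step
            img <- addCameraNoise(img, sqrt(max((ridge / snr)^2 - baseline, 0)))
        }
        list(stack = ImageStack(img, pixelSize = px), truthMask = truth)
    })
}

#' Generate ground-truth single-particle trajectories
#'
#' Immobile particles hold a fixed position plus isotropic Gaussian
#' localization noise; diffusive particles take 2-D Brownian steps with
#' per-axis variance \code{2 * D * dt}; directed particles move at constant
#' speed \code{v} in a random direction (plus localization noise). Particles
#' start well inside the mask bounding box and are reflected at its edges.
#'
#' @param mask a \linkS4class{CellMask}.
#' @param n number of particles.
#' @param classMix named proportions over c(immobile, diffusive, directed);
#'   must sum to 1.
#' @param D diffusion coefficient, um^2/s.
#' @param v directed speed, um/s.
#' @param locNoiseNm localization noise SD per axis, nm.
#' @param nFrames number of frames.
#' @param dt frame interval, s.
#' @param seed RNG seed.
#' @return data.frame(trajectory, frame, x_nm, y_nm, class) with 0-based
#'   frames.
#' @export
makeTrajectories <- function(mask, n,
                             classMix = c(
                                 immobile = 0.3, diffusive = 0.7,
                                 directed = 0
                             ),
                             D = 0.01, v = 0.5, locNoiseNm = 20,
                             nFrames = 300, dt = 0.1, seed = NULL) {
    stopifnot(abs(sum(classMix) - 1) < 1e-9, nFrames >= 2)
    withSeed(seed, {
        px <- pixelSize(mask)
        m <- maskMatrix(mask)
        counts <- floor(classMix * n)
        rem <- n - sum(counts)
        if (rem > 0) {
            counts[which.max(classMix)] <- counts[which.max(classMix)] + rem
        }
        classes <- rep(names(counts), counts)
        start <- placeUniform(mask, n)
        xmax <- ncol(m) * px
        ymax <- nrow(m) * px
        reflect <- function(z, hi) {
            z <- z %% (2 * hi)
            ifelse(z > hi, 2 * hi - z, z)
        }
        out <- vector("list", n)
        for (i in seq_len(n)) {
            cls <- classes[i]
            if (cls == "immobile") {
                x <- rep(start[i, 1L], nFrames)
                y <- rep(start[i, 2L], nFrames)
            } else if (cls == "diffusive") {
                sd_nm <- sqrt(2 * D * dt) * 1000
                x <- start[i, 1L] + cumsum(c(0, stats::rnorm(nFrames - 1, 0, sd_nm)))
                y <- start[i, 2L] + cumsum(c(0, stats::rnorm(nFrames - 1, 0, sd_nm)))
            } else {
                th <- stats::runif(1, 0, 2 * pi)
                s <- v * dt * 1000 * (seq_len(nFrames) - 1)
                x <- start[i, 1L] + s * cos(th)
                y <- start[i, 2L] + s * sin(th)
            }
            if (locNoiseNm > 0) {
                x <- x + stats::rnorm(nFrames, 0, locNoiseNm)
                y <- y + stats::rnorm(nFrames, 0, locNoiseNm)
            }
            out[[i]] <- data.frame(
                trajectory = i, frame = seq_len(nFrames) - 1L,
                x_nm = reflect(x, xmax), y_nm = reflect(y, ymax),
                class = cls
            )
        }
        do.call(rbind, out)
    })
}

#' Generate a movie of mixed mobile/immobile particles
#'
#' Trajectories from \code{\link{makeTrajectories}} rendered per frame as
#' Gaussian PSF spots on a noisy baseline.
#'
#' @inheritParams makeTrajectories
#' @inheritParams makePunctaField
#' @return list(stack = ImageStack, truth = trajectory data.frame).
#' @export
makeMotionMovie <- function(mask, n, classMix = c(
                                immobile = 0.3,
                                diffusive = 0.7, directed = 0
                            ),
                            D = 0.01, v = 0.5, locNoiseNm = 0,
                            nFrames = 60, dt = 0.1,
                            psfSigmaNm = 150, amplitude = 200,
                            baseline = 100, snr = 10, noise = TRUE,
                            seed = NULL) {
    withSeed(seed, {
        truth <- makeTrajectories(mask, n, classMix, D, v, locNoiseNm,
            nFrames, dt,
            seed = NULL
        )
        m <- maskMatrix(mask)
        px <- pixelSize(mask)
        sigmaPx <- psfSigmaNm / px
        readSd <- sqrt(max((amplitude / snr)^2 - baseline, 0))
        arr <- array(0, c(nrow(m), ncol(m), nFrames))
        for (t in seq_len(nFrames)) {
            fr <- truth[truth$frame == t - 1L, ]
            img <- renderSpots(
                dim(m), fr$y_nm / px, fr$x_nm / px,
                amplitude, sigmaPx
            ) + baseline
            arr[, , t] <- if (noise) addCameraNoise(img, readSd) else img
        }
        list(
            stack = ImageStack(arr,
                pixelSize = px,
                frameInterval = dt
            ),
            truth = truth
        )
    })
}

#' Generate a synthetic FRAP recovery curve
#'
#' Pre-bleach frames at \code{fPre}; from the bleach onward
#' \deqn{F(t) = F_{post} + M_f (F_{pre} - F_{post}) (1 - e^{-t/\tau})}
#' plus Gaussian noise.
#'
#' @param fPre,fPost pre-bleach and immediately-post-bleach levels
#'   (\code{fPost < fPre}).
#' @param mobileFraction true mobile fraction in [0, 1].
#' @param tauS recovery time constant, s.
#' @param nPre number of pre-bleach frames.
#' @param tMaxS duration of the post-bleach record, s.
#' @param dtS sampling interval, s.
#' @param noiseSd additive noise SD (same units as F).
#' @param seed RNG seed.
#' @return data.frame(t_s, F) with attribute \code{bleachFrame} (1-based
#'   index of the first post-bleach sample) and attribute \code{truth}
#'   (list with mobileFraction, tauS, fPre, fPost).
#' @export
makeFrapCurve <- function(fPre = 1, fPost = 0.2, mobileFraction = 0.5,
                          tauS = 10, nPre = 5, tMaxS = 60, dtS = 0.5,
                          noiseSd = 0.02, seed = NULL) {
    stopifnot(
        mobileFraction >= 0, mobileFraction <= 1, fPost < fPre,
        tauS > 0
    )
    withSeed(seed, {
        tPost <- seq(0, tMaxS, by = dtS)
        f <- c(
            rep(fPre, nPre),
            fPost + mobileFraction * (fPre - fPost) * (1 - exp(-tPost / tauS))
        )
        t_s <- c(seq(-nPre, -1) * dtS, tPost)
        if (noiseSd > 0) {
            f <- f + stats::rnorm(length(f), 0, noiseSd)
        }
        out <- data.frame(t_s = t_s, F = f)
        attr(out, "bleachFrame") <- nPre + 1L
        attr(out, "truth") <- list(
            mobileFraction = mobileFraction,
            tauS = tauS, fPre = fPre, fPost = fPost
        )
        out
    })
}

#' Generate a movie of local Ca2+-release events (puffs)
#'
#' Each event multiplies the local baseline by \code{1 + dff(t) * g(r)} where
#' \code{dff(t)} rises linearly over \code{riseFrames} to \code{peakDff} and
#' decays exponentially with time constant \code{decayFrames}, and
#' \code{g(r)} is a spatial Gaussian of SD \code{spatialSigmaNm}. Noise is
#' Gaussian with SD chosen so the true peak dF/F0 divided by the per-pixel
#' dF/F0 noise SD equals \code{snr} (an event-referenced SNR).
#'
#' @param mask a \linkS4class{CellMask}.
#' @param sites data.frame(x_nm, y_nm) of puff-site positions (inside mask).
#' @param eventsPerSite events scheduled per site (integer, recycled).
#' @param peakDff true peak dF/F0 per event (recycled over events).
#' @param riseFrames linear rise time, frames.
#' @param decayFrames exponential decay time constant, frames.
#' @param spatialSigmaNm spatial Gaussian SD, nm.
#' @param baseline baseline fluorescence, FU.
#' @param snr event peak dF/F0 over dF/F0 noise SD; Inf for noiseless.
#' @param nFrames total frames.
#' @param baselineFrames frames before the first event can start (the
#'   pre-stimulus baseline window, e.g. 50 frames = 2.5 s at 20 fps).
#' @param dt frame interval, s (default 0.05 = 20 frames/s).
#' @param seed RNG seed.
#' @return list(stack = ImageStack, truth = data.frame(site, x_nm, y_nm,
#'   t_start_frame, duration_frames, peak_dff)) with 0-based start frames.
#' @export
makePuffMovie <- function(mask, sites, eventsPerSite = 2, peakDff = 1,
                          riseFrames = 2, decayFrames = 8,
                          spatialSigmaNm = 600, baseline = 200, snr = 5,
                          nFrames = 200, baselineFrames = 50, dt = 0.05,
                          seed = NULL) {
    withSeed(seed, {
        m <- maskMatrix(mask)
        px <- pixelSize(mask)
        sigmaPx <- spatialSigmaNm / px
        nS <- nrow(sites)
        eventsPerSite <- rep_len(eventsPerSite, nS)
        eventLen <- riseFrames + ceiling(3 * decayFrames)
        ev <- list()
        for (s in seq_len(nS)) {
            nE <- eventsPerSite[s]
            if (nE == 0L) next
            # non-overlapping starts: one jittered event per equal time slot
            spacing <- (nFrames - baselineFrames) %/% nE
            if (spacing < eventLen + 1L) {
                stop("movie too short for the requested events")
            }
            slots <- baselineFrames + (seq_len(nE) - 1L) * spacing +
                sample.int(spacing - eventLen, nE, replace = TRUE) - 1L
            ev[[s]] <- data.frame(
                site = s, x_nm = sites$x_nm[s], y_nm = sites$y_nm[s],
                t_start_frame = slots, duration_frames = eventLen,
                peak_dff = rep_len(peakDff, nE)
            )
        }
        truth <- do.call(rbind, ev)
        arr <- array(baseline, c(nrow(m), ncol(m), nFrames))
        if (!is.null(truth)) {
            for (e in seq_len(nrow(truth))) {
                prof <- c(
                    seq_len(riseFrames) / riseFrames,
                    exp(-(seq_len(eventLen - riseFrames)) / decayFrames)
                ) * truth$peak_dff[e]
                spot <- renderSpots(
                    dim(m), truth$y_nm[e] / px,
                    truth$x_nm[e] / px, 1, sigmaPx
                )
                for (k in seq_along(prof)) {
                    t <- truth$t_start_frame[e] + k # 0-based start -> 1-based
                    arr[, , t] <- arr[, , t] + baseline * prof[k] * spot
                }
            }
        }
        if (is.finite(snr)) {
            noiseSd <- max(peakDff) * baseline / snr
            arr <- arr + array(
                stats::rnorm(length(arr), 0, noiseSd),
                dim(arr)
            )
            arr[arr < 0] <- 0
        }
        list(
            stack = ImageStack(arr, pixelSize = px, frameInterval = dt),
            truth = truth
        )
    })
}
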