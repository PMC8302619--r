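#' Pixelwise dF/F0 (or dF/Fmax) stack
#'
#' Baseline F0 is the per-pixel temporal mean over the pre-stimulus
#' \code{baselineFrames}; each frame then becomes \code{(F - F0) / F0}.
#' Pixels with non-positive baseline are masked out (set to 0, with a
#' warning reporting their number). If \code{fMax} is supplied (the
#' Ca2+-saturated indicator level, scalar or per-pixel matrix), the
#' companion normalization \code{(F - F0) / Fmax} is returned instead.
#'
#' @param stack an \linkS4class{ImageStack} movie.
#' @param baselineFrames number of initial frames forming the baseline
#'   (e.g. 50 frames = 2.5 s at 20 frames/s).
#' @param fMax optional saturated-indicator level for dF/Fmax mode.
#' @return An \linkS4class{ImageStack} of dF/F0 (or dF/Fmax) values.
#' @export
computeDFF <- function(stack, baselineFrames, fMax = NULL) {
    d <- frames(stack)
    stopifnot(baselineFrames >= 1L, baselineFrames <= dim(d)[3L])
    f0 <- apply(d[, , seq_len(baselineFrames), drop = FALSE], c(1L, 2L), mean)
    bad <- f0 <= 0
    if (any(bad)) {
        warning(sum(bad), " pixel(s) with non-positive baseline masked out")
        f0[bad] <- 1
    }
    denom <- if (is.null(fMax)) f0 else fMax
    for (t in seq_len(dim(d)[3L])) {
        fr <- (d[, , t] - f0) / denom
        fr[bad] <- 0
        d[, , t] <- fr
    }
    initialize(stack, data = d)
}

# 26-connected components over a logical (Y, X, T) array; returns an integer
# vector of component labels parallel to which(supra).
cc3d26 <- function(supra) {
    dims <- dim(supra)
    idx <- which(supra)
    n <- length(idx)
    if (n == 0L) {
        return(list(idx = idx, labels = integer(0)))
    }
    rank <- integer(prod(dims))
    rank[idx] <- seq_len(n)
    coord <- arrayInd(idx, dims)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    offs <- expand.grid(dy = -1:1, dx = -1:1, dz = 0:1)
    offs <- offs[offs$dz > 0L | offs$dx > 0L |
        (offs$dx == 0L & offs$dy > 0L), ]
    for (o in seq_len(nrow(offs))) {
        ny <- coord[, 1L] + offs$dy[o]
        nx <- coord[, 2L] + offs$dx[o]
        nz <- coord[, 3L] + offs$dz[o]
        ok <- ny >= 1L & nx >= 1L & nz >= 1L &
            ny <= dims[1L] & nx <= dims[2L] & nz <= dims[3L]
        lin <- ny[ok] + (nx[ok] - 1L) * dims[1L] +
            (nz[ok] - 1L) * dims[1L] * dims[2L]
        j <- rank[lin]
        ii <- which(ok)[j > 0L]
        jj <- j[j > 0L]
        for (k in seq_along(ii)) {
            a <- find(ii[k])
            b <- find(jj[k])
            if (a != b) parent[a] <- b
        }
    }
    labs <- vapply(seq_len(n), find, integer(1))
    list(idx = idx, labels = match(labs, unique(labs)))
}

#' Detect transient local Ca2+-release events (puffs)
#'
#' Each frame of the dF/F0 stack is Gaussian-smoothed, thresholded at
#' \code{ampThreshold}, and supra-threshold voxels are connected over
#' space-time (26-connectivity). Events spanning at least
#' \code{minDurationFrames} frames are kept. Per event: the peak amplitude
#' is the maximum smoothed dF/F0, and the centroid is the amplitude-weighted
#' spatial centroid at the peak frame. Noise can briefly push an event's
#' decaying tail below threshold, splitting one release event into
#' fragments; co-located detections separated by at most
#' \code{mergeGapFrames} are therefore merged back (within
#' \code{mergeRadiusPx}), keeping the earliest start and the largest peak.
#' Event counts are monotone non-increasing in both thresholds, which is the
#' basis of threshold-sensitivity controls.
#'
#' @param dffStack an \linkS4class{ImageStack} of dF/F0 values.
#' @param ampThreshold detection threshold on smoothed dF/F0 (default 0.3).
#' @param minDurationFrames minimum event duration in frames (default 2).
#' @param spatialSigmaPx smoothing sigma in pixels (default 1).
#' @param mergeGapFrames temporal gap closed when merging fragments.
#' @param mergeRadiusPx spatial radius for fragment merging, px.
#' @return data.frame(id, x_nm, y_nm, t_start_frame, duration_frames,
#'   peak_dff) with 0-based start frames; zero rows if nothing detected.
#' @export
detectPuffs <- function(dffStack, ampThreshold = 0.3,
                        minDurationFrames = 2L, spatialSigmaPx = 1,
                        mergeGapFrames = 2L, mergeRadiusPx = 5) {
    stopifnot(ampThreshold > 0, minDurationFrames >= 1L)
    d <- frames(dffStack)
    px <- pixelSize(dffStack)
    sm <- d
    for (t in seq_len(dim(d)[3L])) {
        sm[, , t] <- EBImage::gblur(d[, , t], sigma = spatialSigmaPx)
    }
    cc <- cc3d26(sm > ampThreshold)
    empty <- data.frame(
        id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
        t_start_frame = integer(0), duration_frames = integer(0),
        peak_dff = numeric(0)
    )
    if (length(cc$idx) == 0L) {
        return(empty)
    }
    coord <- arrayInd(cc$idx, dim(d))
    vals <- sm[cc$idx]
    out <- list()
    id <- 0L
    for (l in seq_len(max(cc$labels))) {
        sel <- cc$labels == l
        fr <- coord[sel, 3L]
        dur <- max(fr) - min(fr) + 1L
        v <- vals[sel]
        peak <- which.max(v)
        pkFrame <- fr[peak]
        inPk <- fr == pkFrame
        w <- v[inPk]
        ys <- coord[sel, 1L][inPk] - 1L
        xs <- coord[sel, 2L][inPk] - 1L
        id <- id + 1L
        out[[id]] <- data.frame(
            id = id,
            x_nm = sum(w * xs) / sum(w) * px,
            y_nm = sum(w * ys) / sum(w) * px,
            t_start_frame = min(fr) - 1L,
            duration_frames = dur,
            peak_dff = max(v)
        )
    }
    if (id == 0L) {
        return(empty)
    }
    ev <- do.call(rbind, out)
    # merge co-located fragments separated by a short sub-threshold dip
    ev <- ev[order(ev$t_start_frame), ]
    i <- 1L
    while (i < nrow(ev)) {
        endI <- ev$t_start_frame[i] + ev$duration_frames[i] - 1L
        j <- which(
            seq_len(nrow(ev)) > i &
                ev$t_start_frame <= endI + 1L + mergeGapFrames &
                sqrt((ev$x_nm - ev$x_nm[i])^2 + (ev$y_nm - ev$y_nm[i])^2) <=
                    mergeRadiusPx * px
        )
        if (length(j)) {
            j <- j[1L]
            endJ <- ev$t_start_frame[j] + ev$duration_frames[j] - 1L
            if (ev$peak_dff[j] > ev$peak_dff[i]) {
                ev$x_nm[i] <- ev$x_nm[j]
                ev$y_nm[i] <- ev$y_nm[j]
                ev$peak_dff[i] <- ev$peak_dff[j]
            }
            ev$duration_frames[i] <- max(endI, endJ) - ev$t_start_frame[i] + 1L
            ev <- ev[-j, ]
        } else {
            i <- i + 1L
        }
    }
    ev <- ev[ev$duration_frames >= minDurationFrames, ]
    ev$id <- seq_len(nrow(ev))
    rownames(ev) <- NULL
    ev
}

#' Group puff events into release sites
#'
#' Single-linkage spatial clustering of event centroids with cutoff
#' \code{siteRadiusNm}; events exactly at the cutoff are merged. The site
#' centroid is the mean of its member event centroids.
#'
#' @param events data.frame from \code{\link{detectPuffs}}.
#' @param siteRadiusNm clustering cutoff, nm (default 500, the scale of
#'   within-site centroid wander of successive puffs).
#' @return list(sites = data.frame(site_id, x_nm, y_nm, n_events),
#'   events = the input with a \code{site_id} column).
#' @export
assignSites <- function(events, siteRadiusNm = 500) {
    if (nrow(events) == 0L) {
        return(list(
            sites = data.frame(
                site_id = integer(0), x_nm = numeric(0),
                y_nm = numeric(0), n_events = integer(0)
            ),
            events = cbind(events, site_id = integer(0))
        ))
    }
    if (nrow(events) == 1L) {
        events$site_id <- 1L
        return(list(
            sites = data.frame(
                site_id = 1L, x_nm = events$x_nm,
                y_nm = events$y_nm, n_events = 1L
            ),
            events = events
        ))
    }
    hc <- stats::hclust(
        stats::dist(cbind(events$x_nm, events$y_nm)),
        method = "single"
    )
    events$site_id <- stats::cutree(hc, h = siteRadiusNm)
    sites <- do.call(rbind, lapply(
        sort(unique(events$site_id)),
        function(s) {
            e <- events[events$site_id == s, ]
            data.frame(
                site_id = s, x_nm = mean(e$x_nm), y_nm = mean(e$y_nm),
                n_events = nrow(e)
            )
        }
    ))
    list(sites = sites, events = events)
}

#' Distances from puff events to (immobile) puncta
#'
#' Nearest-neighbour distance from each event centroid to the punctum set.
#'
#' @param events data.frame with \code{x_nm, y_nm}.
#' @param punctaTab puncta (see \code{\link{nearestNeighbourDistances}}).
#' @return Numeric vector of distances, nm.
#' @export
eventToPunctaDistances <- function(events, punctaTab) {
    distances(nearestNeighbourDistances(events, punctaTab))
}

#' Calibrate fluorescence to cytosolic calcium concentration
#'
#' \deqn{[Ca^{2+}]_c = K_D (F - F_{min}) / (F_{max} - F)} in nM, using the
#' indicator's dissociation constant (389 nM for Fluo-8) and the minimal and
#' maximal fluorescence signals.
#'
#' @param F fluorescence value(s), FU.
#' @param KdNM indicator Kd, nM (default 389, Fluo-8).
#' @param fMin,fMax minimal/maximal fluorescence (fMin < fMax).
#' @return Calcium concentration(s) in nM; monotone increasing in F.
#' @examples
#' calibrateCa(600, 389, 100, 1100) # == Kd at the midpoint
#' @export
calibrateCa <- function(F, KdNM = 389, fMin, fMax) {
    stopifnot(fMax > fMin, KdNM > 0)
    if (any(F >= fMax)) {
        stop("indicator saturated: F >= Fmax")
    }
    if (any(F < fMin)) {
        stop("F below Fmin")
    }
    KdNM * (F - fMin) / (fMax - F)
}

#' Inverse calcium calibration
#'
#' Returns the fluorescence corresponding to a calcium concentration:
#' \code{F = (Fmax * ca + Kd * Fmin) / (ca + Kd)}. Round-trips with
#' \code{\link{calibrateCa}} to machine precision.
#'
#' @param caNM calcium concentration(s), nM.
#' @inheritParams calibrateCa
#' @return Fluorescence value(s), FU.
#' @export
calibrateCaInverse <- function(caNM, KdNM = 389, fMin, fMax) {
    stopifnot(fMax > fMin, KdNM > 0)
    (fMax * caNM + KdNM * fMin) / (caNM + KdNM)
}
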