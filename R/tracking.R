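# Exact min-cost rectangular assignment (Jonker-Volgenant style shortest
# augmenting paths). `cost` is n x m with n <= m, finite entries. Returns the
# assigned column for each row.
solveAssignment <- function(cost) {
    n <- nrow(cost)
    m <- ncol(cost)
    stopifnot(n <= m, all(is.finite(cost)))
    u <- numeric(n + 1L)
    v <- numeric(m + 1L)
    p <- integer(m + 1L) # p[j+1] = row assigned to column j (0 = none)
    way <- integer(m + 1L)
    for (i in seq_len(n)) {
        p[1L] <- i
        j0 <- 0L
        minv <- rep(Inf, m + 1L)
        used <- rep(FALSE, m + 1L)
        repeat {
            used[j0 + 1L] <- TRUE
            i0 <- p[j0 + 1L]
            delta <- Inf
            j1 <- 0L
            for (j in seq_len(m)) {
                if (!used[j + 1L]) {
                    cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
                    if (cur < minv[j + 1L]) {
                        minv[j + 1L] <- cur
                        way[j + 1L] <- j0
                    }
                    if (minv[j + 1L] < delta) {
                        delta <- minv[j + 1L]
                        j1 <- j
                    }
                }
            }
            for (j in 0:m) {
                if (used[j + 1L]) {
                    u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
                    v[j + 1L] <- v[j + 1L] - delta
                } else {
                    minv[j + 1L] <- minv[j + 1L] - delta
                }
            }
            j0 <- j1
            if (p[j0 + 1L] == 0L) break
        }
        repeat {
            j1 <- way[j0 + 1L]
            p[j0 + 1L] <- p[j1 + 1L]
            j0 <- j1
            if (j0 == 0L) break
        }
    }
    ans <- integer(n)
    for (j in seq_len(m)) {
        if (p[j + 1L] > 0L) {
            ans[p[j + 1L]] <- j
        }
    }
    ans
}

# Max-cardinality, min-total-distance matching between two point sets with a
# hard distance gate. Returns an integer vector: for each row of P the index
# of the matched row of Q, or NA. Implemented by padding the gated distance
# matrix with per-row dummy columns whose cost exceeds any admissible
# distance, so extra matches are always preferred.
gatedMatch <- function(dP, dQ, gate) {
    np <- nrow(dP)
    nq <- nrow(dQ)
    if (np == 0L || nq == 0L) {
        return(rep(NA_integer_, np))
    }
    d <- sqrt(outer(dP[, 1L], dQ[, 1L], "-")^2 +
        outer(dP[, 2L], dQ[, 2L], "-")^2)
    P <- gate * (np + nq + 1)
    BIG <- P * (np + nq + 1) * 10
    cost <- matrix(BIG, np, nq + np)
    cost[, seq_len(nq)] <- ifelse(d <= gate, d, BIG)
    cost[, nq + seq_len(np)] <- P
    asg <- solveAssignment(cost)
    out <- ifelse(asg <= nq, asg, NA_integer_)
    # defensive: a BIG assignment means the pair was not admissible
    out[!is.na(out) & d[cbind(seq_len(np), pmax(out, 1L))] > gate] <- NA_integer_
    out
}

#' Link per-frame puncta into trajectories
#'
#' Frame-to-frame particle linking by exact minimum-total-distance bipartite
#' matching restricted to candidate pairs within the displacement gate
#' \code{maxSpeed * dt} (maximum match count first, then minimum distance;
#' deterministic and order-independent), followed by gap closing: track ends
#' are joined to later track starts across at most \code{maxGapFrames}
#' missing frames when the implied speed over the gap does not exceed
#' \code{maxSpeed}.
#'
#' @param seg a \linkS4class{SegmentationResult} or a data.frame with
#'   \code{frame} (0-based), \code{x_nm}, \code{y_nm}.
#' @param frameIntervalS frame interval, s.
#' @param maxSpeedUmS displacement threshold, um/s (default 1.5).
#' @param maxGapFrames maximum number of missed frames closed (default 2).
#' @return A \linkS4class{TrajectorySet}.
#' @export
linkPuncta <- function(seg, frameIntervalS, maxSpeedUmS = 1.5,
                       maxGapFrames = 2L) {
    tab <- if (is(seg, "SegmentationResult")) puncta(seg) else seg
    if (nrow(tab) == 0L) {
        return(new("TrajectorySet",
            tracks = data.frame(
                trajectory = integer(0), frame = integer(0),
                x_nm = numeric(0), y_nm = numeric(0)
            ),
            frameInterval = frameIntervalS, maxSpeed = maxSpeedUmS
        ))
    }
    gate1 <- maxSpeedUmS * 1000 * frameIntervalS
    frames <- sort(unique(tab$frame))
    tab$track <- NA_integer_
    nextId <- 0L
    prevIdx <- which(tab$frame == frames[1L])
    tab$track[prevIdx] <- seq_along(prevIdx)
    nextId <- length(prevIdx)
    for (fi in seq_along(frames)[-1L]) {
        curIdx <- which(tab$frame == frames[fi])
        gap <- frames[fi] - frames[fi - 1L]
        mt <- if (gap == 1L) {
            gatedMatch(
                cbind(tab$x_nm[prevIdx], tab$y_nm[prevIdx]),
                cbind(tab$x_nm[curIdx], tab$y_nm[curIdx]), gate1
            )
        } else {
            rep(NA_integer_, length(prevIdx))
        }
        for (k in seq_along(prevIdx)) {
            if (!is.na(mt[k])) {
                tab$track[curIdx[mt[k]]] <- tab$track[prevIdx[k]]
            }
        }
        newIdx <- curIdx[is.na(tab$track[curIdx])]
        if (length(newIdx)) {
            tab$track[newIdx] <- nextId + seq_along(newIdx)
            nextId <- nextId + length(newIdx)
        }
        prevIdx <- curIdx
    }
    # gap closing between segment ends and later segment starts
    ids <- sort(unique(tab$track))
    ends <- do.call(rbind, lapply(ids, function(id) {
        rowsI <- which(tab$track == id)
        e <- rowsI[which.max(tab$frame[rowsI])]
        s <- rowsI[which.min(tab$frame[rowsI])]
        data.frame(
            id = id,
            endFrame = tab$frame[e], endX = tab$x_nm[e], endY = tab$y_nm[e],
            startFrame = tab$frame[s], startX = tab$x_nm[s],
            startY = tab$y_nm[s]
        )
    }))
    repeat {
        joined <- FALSE
        for (ai in seq_len(nrow(ends))) {
            a <- ends[ai, ]
            cand <- which(ends$startFrame > a$endFrame + 1L &
                ends$startFrame <= a$endFrame + 1L + maxGapFrames &
                ends$id != a$id)
            if (!length(cand)) next
            dg <- sqrt((ends$startX[cand] - a$endX)^2 +
                (ends$startY[cand] - a$endY)^2)
            dtg <- (ends$startFrame[cand] - a$endFrame) * frameIntervalS
            ok <- dg / dtg <= maxSpeedUmS * 1000
            if (!any(ok)) next
            b <- cand[ok][which.min(dg[ok])]
            # merge track b into a
            tab$track[tab$track == ends$id[b]] <- a$id
            ends$endFrame[ai] <- ends$endFrame[b]
            ends$endX[ai] <- ends$endX[b]
            ends$endY[ai] <- ends$endY[b]
            ends <- ends[-b, ]
            joined <- TRUE
            break
        }
        if (!joined) break
    }
    tab <- tab[order(tab$track, tab$frame), ]
    tab$trajectory <- match(tab$track, sort(unique(tab$track)))
    new("TrajectorySet",
        tracks = data.frame(
            trajectory = tab$trajectory, frame = tab$frame,
            x_nm = tab$x_nm, y_nm = tab$y_nm
        ),
        frameInterval = frameIntervalS, maxSpeed = maxSpeedUmS
    )
}

#' Time-averaged mean squared displacement of one trajectory
#'
#' MSD at lag \eqn{\ell} is averaged over all in-trajectory frame pairs
#' \eqn{(f, f+\ell)}; lags with fewer than 2 pairs are dropped.
#'
#' @param traj data.frame with \code{frame, x_nm, y_nm} for one trajectory.
#' @param frameIntervalS frame interval, s.
#' @param maxLag largest lag (frames) computed; NULL for all lags.
#' @return list(lag_s, msd_um2, n_pairs).
#' @export
computeMSD <- function(traj, frameIntervalS, maxLag = NULL) {
    stopifnot(nrow(traj) >= 2L)
    f <- traj$frame
    span <- max(f) - min(f)
    maxLag <- if (is.null(maxLag)) span else min(maxLag, span)
    pos <- matrix(NA_real_, span + 1L, 2L)
    pos[f - min(f) + 1L, ] <- cbind(traj$x_nm, traj$y_nm)
    lag <- integer(0)
    msd <- numeric(0)
    np <- integer(0)
    for (l in seq_len(maxLag)) {
        i <- seq_len(span + 1L - l)
        d2 <- (pos[i + l, 1L] - pos[i, 1L])^2 + (pos[i + l, 2L] - pos[i, 2L])^2
        d2 <- d2[!is.na(d2)]
        if (length(d2) >= 2L) {
            lag <- c(lag, l)
            msd <- c(msd, mean(d2) / 1e6) # nm^2 -> um^2
            np <- c(np, length(d2))
        }
    }
    list(lag_s = lag * frameIntervalS, msd_um2 = msd, n_pairs = np)
}

#' Fit the anomalous-diffusion exponent to an MSD curve
#'
#' Least-squares line on (log t, log MSD) over the first \code{nFitLags}
#' lags, under the anomalous-diffusion model \eqn{MSD = 4 D t^\alpha}:
#' alpha is the slope and \code{D = exp(intercept) / 4}. Degenerate
#' trajectories whose MSD is (numerically) zero get \code{alpha = 0, D = 0}
#' (immobile) rather than a fit failure.
#'
#' @param msdCurve result of \code{\link{computeMSD}}.
#' @param nFitLags number of initial lags used (default 10).
#' @return list(D_um2_s, alpha).
#' @export
fitAnomalousExponent <- function(msdCurve, nFitLags = 10L) {
    n <- min(nFitLags, length(msdCurve$lag_s))
    t <- msdCurve$lag_s[seq_len(n)]
    y <- msdCurve$msd_um2[seq_len(n)]
    pos <- y > 0
    if (sum(pos) < 3L) {
        return(list(D_um2_s = 0, alpha = 0))
    }
    fit <- stats::lm.fit(cbind(1, log(t[pos])), log(y[pos]))
    list(
        D_um2_s = exp(fit$coefficients[[1L]]) / 4,
        alpha = fit$coefficients[[2L]]
    )
}

#' Classify a trajectory's mobility from its MSD exponent
#'
#' \code{immobile} if \code{alpha < alphaImmobile} (default 0.1);
#' \code{subdiffusive} up to the lower diffusive band edge (default 0.8);
#' \code{diffusive} up to the directed edge (default 1.2); \code{directed}
#' above. Trajectories shorter than \code{minLengthFrames} (default 45) are
#' excluded (\code{NA}).
#'
#' @param alpha fitted MSD exponent.
#' @param lengthFrames trajectory length in frames.
#' @param alphaImmobile immobile threshold on alpha.
#' @param bands c(subdiffusive/diffusive edge, diffusive/directed edge).
#' @param minLengthFrames minimum trajectory length for classification.
#' @return Character class or \code{NA_character_} if excluded.
#' @export
classifyMobility <- function(alpha, lengthFrames, alphaImmobile = 0.1,
                             bands = c(0.8, 1.2), minLengthFrames = 45L) {
    if (lengthFrames < minLengthFrames) {
        return(NA_character_)
    }
    if (alpha < alphaImmobile) {
        "immobile"
    } else if (alpha < bands[1L]) {
        "subdiffusive"
    } else if (alpha < bands[2L]) {
        "diffusive"
    } else {
        "directed"
    }
}

#' MSD fit and mobility class for every trajectory in a set
#'
#' @param trajSet a \linkS4class{TrajectorySet} or a data.frame with
#'   \code{trajectory, frame, x_nm, y_nm}.
#' @param frameIntervalS frame interval, s (taken from the TrajectorySet if
#'   omitted).
#' @inheritParams fitAnomalousExponent
#' @inheritParams classifyMobility
#' @return data.frame(trajectory, n_frames, D_um2_s, alpha, class).
#' @export
fitTrajectories <- function(trajSet, frameIntervalS = NULL, nFitLags = 10L,
                            alphaImmobile = 0.1, bands = c(0.8, 1.2),
                            minLengthFrames = 45L) {
    if (is(trajSet, "TrajectorySet")) {
        if (is.null(frameIntervalS)) {
            frameIntervalS <- frameInterval(trajSet)
        }
        tab <- tracks(trajSet)
    } else {
        tab <- trajSet
    }
    stopifnot(!is.null(frameIntervalS))
    ids <- sort(unique(tab$trajectory))
    out <- lapply(ids, function(id) {
        tr <- tab[tab$trajectory == id, ]
        if (nrow(tr) < 2L) {
            return(data.frame(
                trajectory = id, n_frames = nrow(tr),
                D_um2_s = NA_real_, alpha = NA_real_,
                class = NA_character_
            ))
        }
        fit <- fitAnomalousExponent(
            computeMSD(tr, frameIntervalS, maxLag = nFitLags), nFitLags
        )
        data.frame(
            trajectory = id, n_frames = nrow(tr),
            D_um2_s = fit$D_um2_s, alpha = fit$alpha,
            class = classifyMobility(
                fit$alpha, nrow(tr), alphaImmobile, bands,
                minLengthFrames
            )
        )
    })
    do.call(rbind, out)
}

#' Count immobile puncta
#'
#' @param fits output of \code{\link{fitTrajectories}}.
#' @return Number of trajectories classified immobile.
#' @export
countImmobile <- function(fits) {
    sum(fits$class == "immobile", na.rm = TRUE)
}

#' Two-colour temporal overlay
#'
#' Overlays the frame at \code{t0} (green) with the frame \code{intervalS}
#' later (magenta) as an RGB composite: immobile structures appear white,
#' mobile ones colour-separate.
#'
#' @param stack an \linkS4class{ImageStack} movie.
#' @param intervalS overlay interval, s (default 30).
#' @param t0 time of the first frame, s (default 0).
#' @return Y x X x 3 numeric array (RGB in [0, 1]).
#' @export
temporalOverlay <- function(stack, intervalS = 30, t0 = 0) {
    dt <- frameInterval(stack)
    if (is.na(dt)) {
        stop("stack has no frame interval")
    }
    d <- frames(stack)
    f0 <- round(t0 / dt) + 1L
    f1 <- f0 + round(intervalS / dt)
    if (f1 > dim(d)[3L]) {
        stop("overlay interval exceeds movie duration")
    }
    g <- d[, , f0]
    m <- d[, , f1]
    top <- max(g, m, 1e-12)
    rgb <- array(0, c(dim(d)[1L], dim(d)[2L], 3L))
    rgb[, , 1L] <- m / top
    rgb[, , 2L] <- g / top
    rgb[, , 3L] <- m / top
    rgb
}
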