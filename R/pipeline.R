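#' Imaging-modality presets
#'
#' Pixel size and matched colocalization criterion per modality: TIRF at
#' 100 nm pixels and confocal at 160 nm pixels both use the 160 nm
#' criterion; super-resolution confocal at 65 nm pixels uses 130 nm.
#'
#' @param modality one of "TIRF-100nm", "confocal-160nm", "superres-65nm".
#' @return list(pixelSizeNm, criterionNm).
#' @export
modalityPreset <- function(modality = c(
                               "TIRF-100nm", "confocal-160nm",
                               "superres-65nm"
                           )) {
    switch(match.arg(modality),
        "TIRF-100nm" = list(pixelSizeNm = 100, criterionNm = 160),
        "confocal-160nm" = list(pixelSizeNm = 160, criterionNm = 160),
        "superres-65nm" = list(pixelSizeNm = 65, criterionNm = 130)
    )
}

#' Two-channel colocalization workflow
#'
#' Segments both channels, measures nearest-neighbour centre-to-centre
#' distances and the colocalized fraction at the criterion, and evaluates an
#' object-randomization null. Pure function of its inputs and seed: the same
#' call yields an identical report.
#'
#' @param stackA,stackB background-corrected \linkS4class{ImageStack}s.
#' @param mask a \linkS4class{CellMask}.
#' @param criterionNm colocalization criterion, nm.
#' @param nIterations randomization iterations (default 100).
#' @param nullMode "object" or "point" (see \code{\link{randomizeNull}}).
#' @param seed RNG seed for the randomization.
#' @param bgRegion optional background \linkS4class{CellMask}; when given,
#'   both stacks are background-corrected first.
#' @param segParams list of arguments passed to \code{\link{segmentSpots}}.
#' @return list report: counts, observed fraction, null summary (mean, sd,
#'   2.5/97.5 percentiles, p value), distances, and the resolved config.
#' @export
runColocWorkflow <- function(stackA, stackB, mask, criterionNm = 160,
                             nIterations = 100L,
                             nullMode = c("object", "point"), seed = 1L,
                             bgRegion = NULL, segParams = list()) {
    nullMode <- match.arg(nullMode)
    if (!is.null(bgRegion)) {
        stackA <- backgroundCorrect(stackA, bgRegion)
        stackB <- backgroundCorrect(stackB, bgRegion)
    }
    segA <- do.call(segmentSpots, c(list(stackA), segParams))
    segB <- do.call(segmentSpots, c(list(stackB), segParams))
    message(sprintf(
        "coloc: segmented %d A and %d B puncta",
        nrow(puncta(segA)), nrow(puncta(segB))
    ))
    dr <- nearestNeighbourDistances(segA, segB, criterionNm)
    null <- randomizeNull(segA, segB, mask,
        nIterations = nIterations,
        criterionNm = criterionNm, mode = nullMode, seed = seed
    )
    list(
        n_A = dr@nA, n_B = dr@nB,
        observed_fraction = colocFraction(dr),
        distances_nm = distances(dr),
        null_mean = mean(null@fractions),
        null_sd = stats::sd(null@fractions),
        null_ci = as.numeric(
            stats::quantile(null@fractions, c(0.025, 0.975))
        ),
        p_value = pValue(null),
        null_curve = nullCurve(null),
        config = list(
            criterion_nm = criterionNm, n_iterations = nIterations,
            null_mode = nullMode, seed = seed, seg = segParams,
            schema = "punctaflow/coloc/1"
        )
    )
}

#' Mobility (immobile-puncta) workflow
#'
#' Segments every frame, links puncta into trajectories (displacement gate,
#' gap closing), fits the anomalous-diffusion exponent per trajectory and
#' classifies mobility; also builds the 30-s two-colour temporal overlay
#' when the movie is long enough.
#'
#' @param stack a background-corrected \linkS4class{ImageStack} movie.
#' @param maxSpeedUmS displacement threshold, um/s (default 1.5).
#' @param maxGapFrames gap-closing limit, frames.
#' @param minLengthFrames minimum trajectory length for classification
#'   (default 45).
#' @param nFitLags MSD lags used in the fit.
#' @param overlayIntervalS temporal-overlay interval, s (default 30; NULL
#'   to skip).
#' @param segParams list of arguments for \code{\link{segmentSpots}}.
#' @return list report: trajectory fits, class counts, immobile count,
#'   overlay (or NULL), and the resolved config.
#' @export
runMobilityWorkflow <- function(stack, maxSpeedUmS = 1.5, maxGapFrames = 2L,
                                minLengthFrames = 45L, nFitLags = 10L,
                                overlayIntervalS = 30, segParams = list()) {
    dt <- frameInterval(stack)
    if (is.na(dt)) {
        stop("movie frame interval required")
    }
    seg <- do.call(segmentSpots, c(list(stack), segParams))
    message(sprintf("mobility: %d puncta detected", nrow(puncta(seg))))
    trajs <- linkPuncta(seg, dt, maxSpeedUmS, maxGapFrames)
    nT <- length(unique(tracks(trajs)$trajectory))
    message(sprintf("mobility: %d trajectories linked", nT))
    nFrames <- dim(frames(stack))[3L]
    if (nFrames < minLengthFrames) {
        warning("movie shorter than the minimum trajectory length; ",
            "no trajectories classified")
    }
    fits <- if (nT > 0) {
        fitTrajectories(trajs,
            nFitLags = nFitLags,
            minLengthFrames = minLengthFrames
        )
    } else {
        data.frame(
            trajectory = integer(0), n_frames = integer(0),
            D_um2_s = numeric(0), alpha = numeric(0),
            class = character(0)
        )
    }
    overlay <- NULL
    if (!is.null(overlayIntervalS) &&
        (nFrames - 1L) * dt >= overlayIntervalS) {
        overlay <- temporalOverlay(stack, overlayIntervalS)
    }
    list(
        n_puncta = nrow(puncta(seg)),
        n_trajectories = nT,
        fits = fits,
        class_counts = table(fits$class, useNA = "ifany"),
        n_immobile = countImmobile(fits),
        overlay = overlay,
        config = list(
            max_speed_um_s = maxSpeedUmS, max_gap_frames = maxGapFrames,
            min_length_frames = minLengthFrames, n_fit_lags = nFitLags,
            overlay_interval_s = overlayIntervalS, seg = segParams,
            frame_interval_s = dt, schema = "punctaflow/mobility/1"
        )
    )
}

#' Ca2+-puff workflow
#'
#' Computes dF/F0, detects puff events, groups them into sites and (when a
#' punctum table is supplied) measures event-to-punctum nearest-neighbour
#' distances.
#'
#' @param stack raw fluorescence \linkS4class{ImageStack} movie.
#' @param baselineFrames pre-stimulus baseline window, frames (default 50).
#' @param ampThreshold detection threshold on smoothed dF/F0.
#' @param minDurationFrames minimum event duration, frames.
#' @param spatialSigmaPx detector smoothing sigma, px.
#' @param siteRadiusNm site-clustering cutoff, nm.
#' @param punctaTab optional puncta (e.g. immobile puncta) for distances.
#' @return list report: events, sites, counts, amplitude stats, distances
#'   (or NULL), and the resolved config.
#' @export
runPuffWorkflow <- function(stack, baselineFrames = 50L, ampThreshold = 0.3,
                            minDurationFrames = 2L, spatialSigmaPx = 1,
                            siteRadiusNm = 500, punctaTab = NULL) {
    dff <- computeDFF(stack, baselineFrames)
    events <- detectPuffs(dff, ampThreshold, minDurationFrames,
        spatialSigmaPx
    )
    message(sprintf("puffs: %d events detected", nrow(events)))
    st <- assignSites(events, siteRadiusNm)
    dists <- NULL
    if (!is.null(punctaTab) && nrow(events) > 0L) {
        dists <- eventToPunctaDistances(st$events, punctaTab)
    }
    list(
        events = st$events,
        sites = st$sites,
        n_events = nrow(events),
        n_sites = nrow(st$sites),
        amplitude_mean = if (nrow(events)) mean(events$peak_dff) else NA_real_,
        amplitude_sd = if (nrow(events) > 1L) {
            stats::sd(events$peak_dff)
        } else {
            NA_real_
        },
        event_to_punctum_nm = dists,
        config = list(
            baseline_frames = baselineFrames, amp_threshold = ampThreshold,
            min_duration_frames = minDurationFrames,
            spatial_sigma_px = spatialSigmaPx,
            site_radius_nm = siteRadiusNm,
            schema = "punctaflow/puffs/1"
        )
    )
}
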