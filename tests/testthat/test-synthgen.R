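mask10 <- squareMask(10, 100)

test_that("generators are reproducible under a fixed seed", {
    a <- makePunctaField(mask10, 40, 40, 0.3, seed = 11)
    b <- makePunctaField(mask10, 40, 40, 0.3, seed = 11)
    expect_identical(a$truth, b$truth)
    expect_identical(frames(a$stackA), frames(b$stackA))

    t1 <- makeTrajectories(mask10, 10, seed = 3)
    t2 <- makeTrajectories(mask10, 10, seed = 3)
    expect_identical(t1, t2)
    expect_false(identical(
        t1,
        makeTrajectories(mask10, 10, seed = 4)
    ))
})

test_that("puncta-field ground truth satisfies its colocalization flags", {
    pf <- makePunctaField(mask10, 50, 60, 0.3, noise = FALSE, seed = 5)
    tr <- pf$truth
    expect_equal(sum(tr$punctaA$colocalized), floor(0.3 * 50))

    b <- cbind(tr$punctaB$x_nm, tr$punctaB$y_nm)
    nn <- nnOracle(cbind(tr$punctaA$x_nm, tr$punctaA$y_nm), b)
    # flagged A lie within the offset disc (and hence inside the criterion)
    expect_true(all(nn[tr$punctaA$colocalized] <= 80))
    # with cross-channel exclusion, unpaired A keep the full min spacing
    expect_true(all(nn[!tr$punctaA$colocalized] >= 4 * 150))

    none <- makePunctaField(mask10, 30, 30, 0, noise = FALSE, seed = 6)
    expect_equal(sum(none$truth$punctaA$colocalized), 0L)

    all80 <- makePunctaField(mask10, 20, 30, 1,
        offsetRadiusNm = 80,
        noise = FALSE, seed = 7
    )
    nnAll <- nnOracle(
        cbind(all80$truth$punctaA$x_nm, all80$truth$punctaA$y_nm),
        cbind(all80$truth$punctaB$x_nm, all80$truth$punctaB$y_nm)
    )
    expect_true(all(nnAll < 160))
})

test_that("a rendered isolated spot integrates to amplitude * 2 pi sigma^2", {
    img <- renderSpots(c(61, 61), 30, 30, amplitude = 100, sigmaPx = 2)
    expect_equal(sum(img), 100 * 2 * pi * 4, tolerance = 0.01)
    # sub-pixel position conserves the integral too
    img2 <- renderSpots(c(61, 61), 30.37, 29.64, 100, 2)
    expect_equal(sum(img2), 100 * 2 * pi * 4, tolerance = 0.01)
})

test_that("motion classes have the stated displacement statistics", {
    tr <- makeTrajectories(mask10, 40,
        classMix = c(immobile = 0, diffusive = 1, directed = 0),
        D = 0.01, locNoiseNm = 0, nFrames = 200, dt = 0.1, seed = 9
    )
    steps <- do.call(c, lapply(split(tr, tr$trajectory), function(d) {
        diff(d$x_nm)
    }))
    expect_equal(sd(steps), sqrt(2 * 0.01 * 0.1) * 1000, tolerance = 0.03)

    dir <- makeTrajectories(mask10, 20,
        classMix = c(immobile = 0, diffusive = 0, directed = 1),
        v = 0.5, locNoiseNm = 0, nFrames = 50, dt = 0.1, seed = 10
    )
    disp <- do.call(c, lapply(split(dir, dir$trajectory), function(d) {
        sqrt(diff(d$x_nm)^2 + diff(d$y_nm)^2)
    }))
    # reflection at the field boundary shortens the rare folded step, so
    # the median (not the mean) is the exact closed-form displacement
    expect_equal(median(disp), 0.5 * 0.1 * 1000, tolerance = 1e-9)
    expect_equal(mean(disp), 0.5 * 0.1 * 1000, tolerance = 0.01)

    still <- makeMotionMovie(mask10, 5,
        classMix = c(immobile = 1, diffusive = 0, directed = 0),
        locNoiseNm = 0, nFrames = 5, noise = FALSE, seed = 11
    )
    d <- frames(still$stack)
    for (t in 2:5) expect_equal(d[, , t], d[, , 1])
})

test_that("FRAP curves follow the recovery model", {
    full <- makeFrapCurve(
        mobileFraction = 1, tMaxS = 200, noiseSd = 0,
        seed = 1
    )
    expect_equal(tail(full$F, 1), 1, tolerance = 1e-6)

    none <- makeFrapCurve(mobileFraction = 0, noiseSd = 0, seed = 1)
    post <- none$F[attr(none, "bleachFrame"):nrow(none)]
    expect_true(all(abs(post - 0.2) < 1e-12))

    mid <- makeFrapCurve(
        fPre = 1, fPost = 0.2, mobileFraction = 0.6,
        tauS = 10, tMaxS = 200, noiseSd = 0, seed = 1
    )
    expect_equal(tail(mid$F, 1), 0.68, tolerance = 1e-3)

    expect_error(makeFrapCurve(fPre = 1, fPost = 1.5, mobileFraction = 0.5))
})

test_that("puff movies encode events as local multiplicative dF/F transients", {
    mask <- squareMask(10, 160)
    sites <- data.frame(x_nm = 5000, y_nm = 5000)

    quiet <- makePuffMovie(mask, sites,
        eventsPerSite = 0, nFrames = 60,
        snr = Inf, seed = 1
    )
    d <- frames(quiet$stack)
    expect_true(all(apply(d, c(1, 2), sd) == 0))

    one <- makePuffMovie(mask, sites,
        eventsPerSite = 1, peakDff = 1,
        nFrames = 100, snr = Inf, seed = 2
    )
    dff <- frames(computeDFF(one$stack, 50))
    expect_equal(max(dff), 1, tolerance = 0.01)
    pk <- arrayInd(which.max(dff), dim(dff))
    expect_lt(
        sqrt(((pk[1] - 1) * 160 - 5000)^2 + ((pk[2] - 1) * 160 - 5000)^2),
        160
    )
    expect_true(all(one$truth$t_start_frame >= 50))
})
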