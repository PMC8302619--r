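test_that("a stationary punctum links into one full-length trajectory", {
    det <- data.frame(
        frame = 0:29, x_nm = 5000 + rnorm(30, 0, 5),
        y_nm = 4000 + rnorm(30, 0, 5)
    )
    ts <- linkPuncta(det, frameIntervalS = 0.1)
    tab <- tracks(ts)
    expect_equal(length(unique(tab$trajectory)), 1L)
    expect_equal(nrow(tab), 30L)
})

test_that("frame-pair linking equals the exhaustive min-cost matching oracle", {
    set.seed(71)
    for (rep in 1:100) {
        np <- sample(1:6, 1)
        nq <- sample(1:6, 1)
        P <- matrix(runif(np * 2, 0, 2000), np)
        Q <- matrix(runif(nq * 2, 0, 2000), nq)
        gate <- runif(1, 300, 1200)
        mine <- punctaflow:::gatedMatch(P, Q, gate)
        orc <- oracleMatch(P, Q, gate)
        d <- sqrt(outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2)
        got <- which(!is.na(mine))
        expect_equal(length(got), orc$card)
        if (length(got)) {
            expect_equal(sum(d[cbind(got, mine[got])]), orc$cost)
            expect_true(all(d[cbind(got, mine[got])] <= gate))
        }
    }
})

test_that("linking respects the speed gate and closes gaps", {
    # a particle missing from one frame is bridged by gap closing
    det <- data.frame(
        frame = c(0:4, 6:10),
        x_nm = 1000 + c(0:4, 6:10) * 50, y_nm = 2000
    )
    ts <- linkPuncta(det, frameIntervalS = 0.1, maxGapFrames = 2L)
    expect_equal(length(unique(tracks(ts)$trajectory)), 1L)

    # beyond the gap limit the segments stay apart
    det2 <- data.frame(
        frame = c(0:4, 9:13),
        x_nm = 1000, y_nm = 2000
    )
    ts2 <- linkPuncta(det2, frameIntervalS = 0.1, maxGapFrames = 2L)
    expect_equal(length(unique(tracks(ts2)$trajectory)), 2L)

    # no linked step exceeds max speed
    mask <- squareMask(10, 100)
    tr <- makeTrajectories(mask, 20,
        c(immobile = 0.5, diffusive = 0.5, directed = 0),
        nFrames = 50, dt = 0.1, locNoiseNm = 20, seed = 72
    )
    det3 <- data.frame(frame = tr$frame, x_nm = tr$x_nm, y_nm = tr$y_nm)
    ts3 <- linkPuncta(det3, frameIntervalS = 0.1, maxSpeedUmS = 1.5)
    for (tt in split(tracks(ts3), tracks(ts3)$trajectory)) {
        if (nrow(tt) < 2) next
        sp <- sqrt(diff(tt$x_nm)^2 + diff(tt$y_nm)^2) /
            (diff(tt$frame) * 0.1)
        expect_true(all(sp <= 1.5 * 1000 + 1e-9))
    }
})

test_that("MSD follows closed forms for stationary, ballistic and Brownian motion", {
    still <- data.frame(frame = 0:49, x_nm = 1000, y_nm = 1000)
    ms <- computeMSD(still, 0.1)
    expect_true(all(ms$msd_um2 == 0))

    v <- 0.5 # um/s
    line <- data.frame(
        frame = 0:49,
        x_nm = (0:49) * v * 0.1 * 1000, y_nm = 0
    )
    ml <- computeMSD(line, 0.1)
    expect_equal(ml$msd_um2, v^2 * ml$lag_s^2, tolerance = 1e-12)

    set.seed(73)
    D <- 0.01
    dt <- 0.1
    msds <- matrix(0, 100, 10)
    for (i in 1:100) {
        stp <- sqrt(2 * D * dt) * 1000
        tr <- data.frame(
            frame = 0:299,
            x_nm = cumsum(c(0, rnorm(299, 0, stp))),
            y_nm = cumsum(c(0, rnorm(299, 0, stp)))
        )
        msds[i, ] <- computeMSD(tr, dt, maxLag = 10)$msd_um2
    }
    ens <- colMeans(msds)
    expect_equal(ens, 4 * D * (1:10) * dt, tolerance = 0.1)
})

test_that("the anomalous-exponent fit is exact on power-law MSDs", {
    t <- (1:10) * 0.1
    fit1 <- fitAnomalousExponent(list(lag_s = t, msd_um2 = 4 * 0.01 * t))
    expect_equal(fit1$alpha, 1, tolerance = 1e-7)
    expect_equal(fit1$D_um2_s, 0.01, tolerance = 1e-7)

    fit2 <- fitAnomalousExponent(list(lag_s = t, msd_um2 = 4 * 0.01 * t^2))
    expect_equal(fit2$alpha, 2, tolerance = 1e-7)

    flat <- fitAnomalousExponent(list(lag_s = t, msd_um2 = rep(0.002, 10)))
    expect_lt(abs(flat$alpha), 1e-7)

    zero <- fitAnomalousExponent(list(lag_s = t, msd_um2 = rep(0, 10)))
    expect_equal(zero$alpha, 0)
    expect_equal(zero$D_um2_s, 0)
})

test_that("mobility classes follow the alpha bands and length gate", {
    expect_equal(classifyMobility(0.05, 100), "immobile")
    expect_equal(classifyMobility(0.5, 100), "subdiffusive")
    expect_equal(classifyMobility(1.0, 100), "diffusive")
    expect_equal(classifyMobility(1.7, 100), "directed")
    expect_true(is.na(classifyMobility(1.0, 44))) # below 45 frames

    mask <- squareMask(20, 100)
    imm <- makeTrajectories(mask, 50,
        c(immobile = 1, diffusive = 0, directed = 0),
        locNoiseNm = 20, nFrames = 300, dt = 0.1, seed = 74
    )
    fi <- fitTrajectories(imm, frameIntervalS = 0.1)
    expect_gte(mean(fi$class == "immobile"), 0.9)

    dif <- makeTrajectories(mask, 50,
        c(immobile = 0, diffusive = 1, directed = 0),
        D = 0.01, locNoiseNm = 0, nFrames = 300, dt = 0.1, seed = 75
    )
    fd <- fitTrajectories(dif, frameIntervalS = 0.1)
    expect_gte(mean(fd$class == "diffusive"), 0.9)
    expect_lte(mean(fd$class == "immobile"), 0.02)
    expect_equal(countImmobile(fi), sum(fi$class == "immobile"))
})

test_that("classification is invariant to translation of the field", {
    mask <- squareMask(10, 100)
    tr <- makeTrajectories(mask, 20,
        c(immobile = 0.5, diffusive = 0.5, directed = 0),
        locNoiseNm = 20, nFrames = 100, dt = 0.1, seed = 76
    )
    f1 <- fitTrajectories(tr, frameIntervalS = 0.1)
    tr2 <- tr
    tr2$x_nm <- tr2$x_nm + 12345
    tr2$y_nm <- tr2$y_nm - 999
    f2 <- fitTrajectories(tr2, frameIntervalS = 0.1)
    expect_equal(f1$class, f2$class)
    expect_equal(f1$alpha, f2$alpha)
})

test_that("temporal overlays show immobile structures as white", {
    mask <- squareMask(8, 100)
    mm <- makeMotionMovie(mask, 6,
        classMix = c(immobile = 1, diffusive = 0, directed = 0),
        locNoiseNm = 0, nFrames = 301, dt = 0.1, noise = FALSE, seed = 77
    )
    ov <- temporalOverlay(mm$stack, intervalS = 30)
    expect_equal(dim(ov)[3], 3L)
    expect_equal(ov[, , 1], ov[, , 2]) # magenta equals green -> grayscale
    expect_error(temporalOverlay(mm$stack, intervalS = 60), "duration")

    # a mobile spot separates into colour channels
    mv <- makeMotionMovie(mask, 1,
        classMix = c(immobile = 0, diffusive = 0, directed = 1),
        v = 0.2, locNoiseNm = 0, nFrames = 301, dt = 0.1, noise = FALSE,
        seed = 78
    )
    ov2 <- temporalOverlay(mv$stack, intervalS = 30)
    expect_gt(max(abs(ov2[, , 1] - ov2[, , 2])), 0.2)
})
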