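test_that("local maxima detection matches an exhaustive neighbourhood check", {
    expect_equal(nrow(findLocalMaxima(matrix(5, 20, 20), 1)), 0L)

    one <- gaussFrame(c(40, 40), 20, 25, A = 100, sigma = 1.5)
    s <- findLocalMaxima(one, 50)
    expect_identical(s, cbind(y = 20L, x = 25L))

    two <- gaussFrame(c(40, 40), 10, 10) + gaussFrame(c(40, 40), 10, 20)
    expect_equal(nrow(findLocalMaxima(two, 50)), 2L)

    # exhaustive brute force on noisy frames (continuous values, no plateaus)
    set.seed(21)
    for (rep in 1:5) {
        fr <- matrix(rnorm(30 * 30), 30, 30)
        got <- findLocalMaxima(fr, -1)
        brute <- NULL
        for (y in 0:29) {
            for (x in 0:29) {
                nb <- c()
                for (dy in -1:1) {
                    for (dx in -1:1) {
                        if (dy == 0 && dx == 0) next
                        yy <- y + dy
                        xx <- x + dx
                        if (yy >= 0 && xx >= 0 && yy < 30 && xx < 30) {
                            nb <- c(nb, fr[yy + 1, xx + 1])
                        }
                    }
                }
                if (all(nb < fr[y + 1, x + 1])) brute <- rbind(brute, c(y, x))
            }
        }
        expect_equal(
            got[order(got[, 1], got[, 2]), , drop = FALSE],
            brute[order(brute[, 1], brute[, 2]), , drop = FALSE],
            ignore_attr = TRUE
        )
    }
})

test_that("radial border threshold finds the local background shoulder", {
    onZero <- gaussFrame(c(41, 41), 20, 20, A = 100, sigma = 1.5)
    expect_lte(radialBorderThreshold(onZero, c(20, 20)), 5)

    onPed <- gaussFrame(c(41, 41), 20, 20, A = 100, sigma = 1.5, pedestal = 20)
    expect_equal(radialBorderThreshold(onPed, c(20, 20)), 20, tolerance = 0.1)

    hot <- matrix(10, 21, 21)
    hot[11, 11] <- 200
    expect_equal(radialBorderThreshold(hot, c(10, 10)), 10)
})

test_that("spot growth produces accurate sub-pixel centroids and disjoint sets", {
    fr <- gaussFrame(c(40, 60), 10.3, 20.7, A = 100, sigma = 1.5)
    seed <- findLocalMaxima(fr, 50)[1, ]
    sp <- growSpot(fr, seed, radialBorderThreshold(fr, seed), pixelSize = 1)
    expect_lt(abs(sp$centroid_x_nm - 20.7), 0.1)
    expect_lt(abs(sp$centroid_y_nm - 10.3), 0.1)

    # two equal spots: disjoint pixel sets, no pixel claimed twice
    both <- gaussFrame(c(40, 60), 20, 20) + gaussFrame(c(40, 60), 20, 30)
    seg <- segmentSpots(ImageStack(both, 100), seedThreshold = 50)
    expect_equal(nrow(puncta(seg)), 2L)
    keys <- unlist(lapply(pixelSets(seg), function(p) p[, 1] * 1e4 + p[, 2]))
    expect_equal(anyDuplicated(keys), 0L)

    # isolated single hot pixel is a one-pixel punctum at that pixel
    hot <- matrix(0, 21, 21)
    hot[11, 6] <- 200
    sp1 <- growSpot(hot, c(10, 5), 10, pixelSize = 100)
    expect_equal(nrow(sp1$pixels), 1L)
    expect_equal(c(sp1$centroid_y_nm, sp1$centroid_x_nm), c(1000, 500))
})

test_that("segmentation recovers a synthetic SNR-5 field and is deterministic", {
    mask <- squareMask(12, 100)
    pf <- makePunctaField(mask, 80, 80, 0.25, seed = 31)
    seg <- segmentSpots(pf$stackA, smoothSigmaPx = 1)
    m <- matchPoints(
        cbind(pf$truth$punctaA$x_nm, pf$truth$punctaA$y_nm),
        cbind(puncta(seg)$x_nm, puncta(seg)$y_nm), 200
    )
    expect_gte(m$recall, 0.95)
    expect_gte(m$precision, 0.95)

    again <- segmentSpots(pf$stackA, smoothSigmaPx = 1)
    expect_identical(puncta(seg), puncta(again))

    empty <- segmentSpots(ImageStack(matrix(0, 50, 50), 100))
    expect_equal(nrow(puncta(empty)), 0L)
})

test_that("raising the seed threshold never increases the punctum count", {
    mask <- squareMask(8, 100)
    pf <- makePunctaField(mask, 40, 40, 0, seed = 32)
    counts <- vapply(
        c(120, 140, 160, 180, 220),
        function(thr) {
            nrow(puncta(segmentSpots(pf$stackA,
                seedThreshold = thr,
                smoothSigmaPx = 1
            )))
        },
        numeric(1)
    )
    expect_true(all(diff(counts) <= 0))
})

test_that("centroid localization is sub-0.1 px noiseless and sub-pixel at SNR 5", {
    # noiseless grid of isolated spots at irrational sub-pixel offsets
    set.seed(33)
    offs <- matrix(runif(2 * 25, -0.45, 0.45), ncol = 2)
    ctr <- expand.grid(y = seq(10, 50, by = 10), x = seq(10, 50, by = 10))
    fr <- matrix(0, 61, 61)
    for (i in seq_len(25)) {
        fr <- renderSpots(
            c(61, 61), ctr$y[i] + offs[i, 1], ctr$x[i] + offs[i, 2],
            100, 1.5,
            img = fr
        )
    }
    seg <- segmentSpots(ImageStack(fr, 100), seedThreshold = 30)
    m <- matchPoints(
        cbind((ctr$x + offs[, 2]) * 100, (ctr$y + offs[, 1]) * 100),
        cbind(puncta(seg)$x_nm, puncta(seg)$y_nm), 100
    )
    expect_equal(m$recall, 1)
    expect_lt(sqrt(mean(m$matchedErr^2)) / 100, 0.1)

    # SNR 5: weighted-centroid precision stays sub-pixel (~0.4 px RMS)
    mask <- squareMask(15, 100)
    errs <- c()
    for (sd in 1:2) {
        pf <- makePunctaField(mask, 120, 120, 0, seed = 40 + sd)
        seg <- segmentSpots(pf$stackA, smoothSigmaPx = 1)
        mm <- matchPoints(
            cbind(pf$truth$punctaA$x_nm, pf$truth$punctaA$y_nm),
            cbind(puncta(seg)$x_nm, puncta(seg)$y_nm), 200
        )
        errs <- c(errs, mm$matchedErr)
    }
    expect_gte(length(errs), 100)
    expect_lt(sqrt(mean(errs^2)) / 100, 0.5)
})

test_that("puncta fluorescence fraction does photon bookkeeping", {
    mask <- squareMask(10, 100)
    # all fluorescence inside punctum pixel sets
    fr <- matrix(0, 100, 100)
    fr[45:55, 45:55] <- gaussFrame(c(11, 11), 5, 5, A = 500, sigma = 1.5)
    st <- ImageStack(fr, 100)
    seg <- segmentSpots(st, seedThreshold = 50)
    expect_equal(
        punctaFluorescenceFraction(seg, st, mask), 1,
        tolerance = 0.02
    )

    # no puncta -> 0
    flat <- ImageStack(matrix(1, 100, 100), 100)
    segE <- segmentSpots(flat, seedThreshold = 50)
    expect_equal(punctaFluorescenceFraction(segE, flat, mask), 0)

    # spots carry 60% of photons, a broad dim blob (below seed threshold)
    # in the opposite corner carries the other 40%
    grid <- expand.grid(y = c(15, 27, 39, 51), x = c(15, 27, 39, 51))
    img <- renderSpots(c(100, 100), grid$y, grid$x, 100, 1.5)
    spotPhotons <- sum(img)
    blobAmp <- spotPhotons * (0.4 / 0.6) / (2 * pi * 8^2)
    img <- renderSpots(c(100, 100), 80, 80, blobAmp, 8, img = img)
    st2 <- ImageStack(img, 100)
    seg2 <- segmentSpots(st2, seedThreshold = 60)
    expect_equal(
        punctaFluorescenceFraction(seg2, st2, mask), 0.6,
        tolerance = 0.03
    )

    # per frame the punctum sum can never exceed the whole-frame total
    expect_lte(
        sum(puncta(seg2)$integrated_FU),
        sum(frames(st2))
    )
})
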