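test_that("nearest-neighbour distances match hand geometry and the loop oracle", {
    a <- data.frame(x_nm = 0, y_nm = 0)
    b <- data.frame(x_nm = c(300, 1000), y_nm = c(400, 0))
    dr <- nearestNeighbourDistances(a, b)
    expect_equal(distances(dr), 500)

    same <- data.frame(x_nm = runif(20, 0, 5000), y_nm = runif(20, 0, 5000))
    drs <- nearestNeighbourDistances(same, same)
    expect_true(all(distances(drs) == 0))
    expect_equal(colocFraction(drs), 1)

    set.seed(51)
    for (rep in 1:20) {
        n <- sample(5:400, 1)
        m <- sample(5:400, 1)
        A <- cbind(runif(n, 0, 2e4), runif(n, 0, 2e4))
        B <- cbind(runif(m, 0, 2e4), runif(m, 0, 2e4))
        expect_equal(
            distances(nearestNeighbourDistances(A, B)),
            nnOracle(A, B)
        )
    }
    expect_error(nearestNeighbourDistances(a[0, ], b), "non-empty")
})

test_that("colocalized fraction is strict, monotone, and rigid-motion invariant", {
    expect_equal(colocalizedFraction(c(500, 1000), 600), 0.5)
    expect_equal(colocalizedFraction(c(160, 200), 160), 0) # strict <
    expect_equal(colocalizedFraction(c(0, 10), 1e-9), 0.5) # exact coincidence

    set.seed(52)
    A <- cbind(runif(100, 0, 1e4), runif(100, 0, 1e4))
    B <- cbind(runif(100, 0, 1e4), runif(100, 0, 1e4))
    crit <- c(50, 100, 200, 400, 800)
    fr <- vapply(crit, function(cc) {
        colocalizedFraction(distances(nearestNeighbourDistances(A, B)), cc)
    }, numeric(1))
    expect_true(all(diff(fr) >= 0))

    th <- 0.73
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shift <- c(12345, -678)
    A2 <- sweep(A %*% R, 2, shift, "+")
    B2 <- sweep(B %*% R, 2, shift, "+")
    expect_equal(
        distances(nearestNeighbourDistances(A2, B2)),
        distances(nearestNeighbourDistances(A, B))
    )
})

test_that("randomization null p-values behave like a permutation test", {
    mask <- squareMask(10, 100)
    set.seed(53)
    B <- data.frame(x_nm = runif(80, 500, 9500), y_nm = runif(80, 500, 9500))
    # A constructed colocalized with B: observed fraction 1.0
    A <- data.frame(x_nm = B$x_nm + 30, y_nm = B$y_nm - 20)
    null <- randomizeNull(A, B, mask,
        nIterations = 100, mode = "point",
        seed = 54
    )
    expect_equal(pValue(null), 1 / 101)
    expect_equal(null@observed, 1)
    expect_equal(length(null@fractions), 100L)
    # cumulative curve is a well-formed, monotone band on [0, 1]
    cv <- nullCurve(null)
    expect_true(all(cv$lo <= cv$hi))
    expect_true(all(diff(cv$mean) >= 0))
    expect_true(all(cv$mean >= 0 & cv$mean <= 1))

    # CSR data: null mean near the analytic value, p not extreme
    Bc <- data.frame(x_nm = runif(200, 0, 1e4), y_nm = runif(200, 0, 1e4))
    Ac <- data.frame(x_nm = runif(200, 1000, 9000), y_nm = runif(200, 1000, 9000))
    nullC <- randomizeNull(Ac, Bc, mask,
        nIterations = 100, mode = "point",
        seed = 55
    )
    analytic <- 1 - exp(-(200 / 100) * pi * 0.16^2)
    se <- sd(nullC@fractions) / 10
    expect_lt(abs(mean(nullC@fractions) - analytic), 4 * se)
    expect_gte(pValue(nullC), 1 / 101)
})

test_that("object-mode randomization preserves object shapes inside the mask", {
    mask <- squareMask(8, 100)
    pf <- makePunctaField(mask, 25, 25, 0.5, seed = 56)
    segA <- segmentSpots(pf$stackA, smoothSigmaPx = 1)
    segB <- segmentSpots(pf$stackB, smoothSigmaPx = 1)
    null <- randomizeNull(segA, segB, mask,
        nIterations = 20,
        mode = "object", seed = 57
    )
    expect_equal(null@nIterations, 20L)
    expect_equal(length(null@fractions), 20L)
    # constructed colocalization should beat the null comfortably
    expect_gt(null@observed, mean(null@fractions))
    expect_lte(pValue(null), 0.1)
})

test_that("Manders split coefficient sums intensities over masks", {
    cellM <- CellMask(matrix(TRUE, 10, 10), 100)
    fr <- matrix(1, 10, 10)
    expect_equal(mandersSplit(fr, matrix(TRUE, 10, 10), cellM), 1)

    ref <- matrix(FALSE, 10, 10)
    ref[1:5, ] <- TRUE
    zeroIn <- matrix(1, 10, 10)
    zeroIn[1:5, ] <- 0
    expect_equal(mandersSplit(zeroIn, ref, cellM), 0)

    fr2 <- matrix(0, 10, 10)
    fr2[1, 1] <- 10
    fr2[9, 9] <- 30
    ref2 <- matrix(FALSE, 10, 10)
    ref2[1, 1] <- TRUE
    expect_equal(mandersSplit(fr2, ref2, cellM), 0.25)
    expect_error(mandersSplit(matrix(0, 10, 10), ref2, cellM), "zero")
})

test_that("filament masks recover the generator's truth footprint", {
    mask <- squareMask(15, 150)
    fi <- makeFilamentImage(mask,
        nFilaments = 4, amplitude = 20,
        baseline = 50, seed = 58
    )
    fr <- frames(fi$stack)[, , 1]
    ridge <- 20 * sqrt(2 * pi) * 1 / 0.25
    fm <- makeFilamentMask(fr, 0.5, maskThreshold = 50 + ridge / 2)
    jac <- sum(fm & fi$truthMask) / sum(fm | fi$truthMask)
    expect_gte(jac, 0.8)

    # Otsu default at least covers the truth ridge on a noiseless image
    fmO <- makeFilamentMask(fr, 0.5)
    expect_gte(sum(fmO & fi$truthMask) / sum(fi$truthMask), 0.8)

    expect_equal(sum(makeFilamentMask(matrix(0, 20, 20))), 0L)

    # single filament truth is one connected component
    one <- makeFilamentImage(mask, nFilaments = 1, seed = 59)
    expect_equal(max(EBImage::bwlabel(one$truthMask)), 1)
})

test_that("per-region colocalization respects region assignment", {
    mask <- squareMask(10, 100)
    onM <- matrix(FALSE, 100, 100)
    onM[, 1:50] <- TRUE
    masks <- list(on = onM, off = !onM)

    set.seed(60)
    A <- data.frame(x_nm = runif(30, 0, 4800), y_nm = runif(30, 0, 9900))
    B <- data.frame(
        x_nm = c(A$x_nm + 20, runif(20, 5200, 9900)),
        y_nm = c(A$y_nm, runif(20, 0, 9900))
    )
    res <- colocByRegion(A, B, masks, 160, 100)
    expect_equal(res$on@nA, 30L)
    expect_equal(colocFraction(res$on), 1)
    expect_null(res$off) # no A puncta in the off region

    # with the peripheral/central partition as regions
    disc <- discMask(40, pad = 4, pixelSize = 100)
    part <- partitionRegions(disc, 15)
    pmasks <- list(
        peripheral = part@peripheral,
        central = part@central
    )
    set.seed(61)
    ctr <- which(part@central, arr.ind = TRUE)
    pick <- ctr[sample(nrow(ctr), 25), ]
    Ac <- data.frame(x_nm = (pick[, 2] - 1) * 100, y_nm = (pick[, 1] - 1) * 100)
    res2 <- colocByRegion(Ac, Ac, pmasks, 160, 100)
    expect_equal(res2$central@nA, 25L)
    expect_null(res2$peripheral)
})
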