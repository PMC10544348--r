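test_that("saturation rejection flags exactly the planted pixels", {
    scene <- flatScene(rep(0.5, 155), tilePx = 6)
    cap <- simulateCapture(scene, flatIlluminant(), makeFilterBank(),
                           makeLensletGeometry(pitch = 0), noiselessSensor())
    expect_true(all(rejectSaturated(cap)))
    cap@sample[3, 4, 10] <- 4095L
    v <- rejectSaturated(cap)
    expect_false(v[3, 4])
    expect_equal(sum(!v), 1L)
})

test_that("fractional saturation threshold matches an exhaustive scan", {
    scene <- flatScene(rep(0.5, 155), tilePx = 6)
    cap <- simulateCapture(scene, flatIlluminant(), makeFilterBank(),
                           makeLensletGeometry(pitch = 0), noiselessSensor())
    ## plant a DN ramp in one lenslet
    cap@sample[, , 5] <- matrix(as.integer(seq(3500, 4095, length.out = 36)),
                                6, 6)
    frac <- 0.98
    v <- rejectSaturated(cap, frac)
    thr <- frac * 4095
    brute <- matrix(TRUE, 6, 6)
    for (r in 1:6) for (cc in 1:6) for (i in 1:66)
        if (cap@sample[r, cc, i] >= thr) brute[r, cc] <- FALSE
    expect_identical(v, brute)
})

test_that("ROI extraction equals the brute-force per-pixel oracle", {
    set.seed(2)
    arr <- array(stats::runif(10 * 8 * 12), c(10, 8, 12))
    cube <- new("Hypercube", values = arr,
                wavelengths = makeWavelengthGrid(400, 700, 12),
                provenance = list())
    mask <- matrix(sample(0:3, 80, replace = TRUE), 10, 8)
    valid <- matrix(sample(c(TRUE, TRUE, TRUE, FALSE), 80, replace = TRUE),
                    10, 8)
    tab <- extractRoiSpectra(cube, mask, valid)
    oracle <- oracleRoiStats(arr, mask, valid)
    for (j in seq_len(nrow(roiStats(tab)))) {
        lab <- as.character(roiStats(tab)$label[j])
        expect_equal(roiStats(tab)$nValid[j], oracle[[lab]]$n)
        expect_equal(unname(roiMeans(tab)[j, ]), oracle[[lab]]$mean,
                     tolerance = 1e-12)
        expect_equal(unname(roiSds(tab)[j, ]), oracle[[lab]]$sd,
                     tolerance = 1e-12)
    }
})

test_that("constant and two-point regions give exact means and stds", {
    wl <- makeWavelengthGrid(400, 700, 4)
    arr <- array(0, c(2, 2, 4))
    a <- c(0.1, 0.2, 0.3, 0.4); b <- c(0.5, 0.6, 0.7, 0.8)
    arr[1, 1, ] <- a; arr[1, 2, ] <- a
    arr[2, 1, ] <- a; arr[2, 2, ] <- b
    cube <- new("Hypercube", values = arr, wavelengths = wl,
                provenance = list())
    mConst <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
    t1 <- extractRoiSpectra(cube, mConst)
    expect_equal(unname(roiMeans(t1)[1, ]), a)
    expect_equal(unname(roiSds(t1)[1, ]), rep(0, 4))
    mHalf <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
    t2 <- extractRoiSpectra(cube, mHalf)
    expect_equal(unname(roiMeans(t2)[1, ]), (a + b) / 2)
    ## zero valid pixels reported, not dropped
    t3 <- extractRoiSpectra(cube, mConst, valid = matrix(FALSE, 2, 2))
    expect_equal(roiStats(t3)$nValid, 0L)
    expect_true(all(is.na(roiMeans(t3))))
    expect_error(extractRoiSpectra(cube, matrix(0L, 3, 3)), "dimensions")
})

test_that("L1 normalization sums to one, is idempotent and scale-free", {
    expect_equal(l1Normalize(c(2, 2, 4)), c(0.25, 0.25, 0.5))
    v <- c(0.25, 0.25, 0.5)
    expect_equal(l1Normalize(v), v)
    set.seed(3)
    for (i in 1:1000) {
        s <- stats::runif(20, 0, 2)
        n <- l1Normalize(s)
        expect_lt(abs(sum(n) - 1), 1e-12)
        expect_equal(n, l1Normalize(5.7 * s), tolerance = 1e-12)
    }
    expect_error(l1Normalize(rep(0, 5)), "all-zero")
    expect_error(l1Normalize(c(1, -0.1)), "non-negative")
})

test_that("tile-center shrinking keeps the centered fraction of each box", {
    mask <- matrix(0L, 20, 20)
    mask[3:18, 3:18] <- 1L
    keep <- tileCenterRegions(mask, 0.5)
    expect_equal(sum(keep == 1L), 64L)              # 8 x 8 core
    expect_true(all(keep[7:14, 7:14] == 1L))
    expect_identical(tileCenterRegions(mask, 1), mask)

    ## irregular region: brute-force box intersection
    set.seed(9)
    irr <- matrix(0L, 15, 15)
    irr[cbind(sample(3:12, 30, TRUE), sample(4:13, 30, TRUE))] <- 2L
    out <- tileCenterRegions(irr, 0.6)
    idx <- which(irr == 2L, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    kh <- max(1, round(0.6 * (r1 - r0 + 1)))
    kw <- max(1, round(0.6 * (c1 - c0 + 1)))
    rs <- r0 + (r1 - r0 + 1 - kh) %/% 2
    cs <- c0 + (c1 - c0 + 1 - kw) %/% 2
    brute <- matrix(0L, 15, 15)
    for (k in seq_len(nrow(idx))) {
        r <- idx[k, 1]; cc <- idx[k, 2]
        if (r >= rs && r < rs + kh && cc >= cs && cc < cs + kw)
            brute[r, cc] <- 2L
    }
    expect_identical(out, brute)
})

test_that("delta-E validation composes the stage oracles with verdict bands", {
    wl <- grid155
    ## exact match -> all zeros, imperceptible
    pal <- makeTilePalette(3, 1, seed = 2)
    scene <- renderCheckerScene(pal, 2, 2, tilePx = 8)
    tab <- extractRoiSpectra(scene, truthMask(scene))
    ref <- scenePalette(scene); attr(ref, "wavelengths") <- wl
    rep0 <- validateAgainstReference(tab, ref)
    expect_true(all(deltaETable(rep0)$deltaE < 1e-9))
    expect_true(all(deltaETable(rep0)$verdict == "imperceptible"))

    ## flat 0.5 vs flat 0.55 equals the independent two-gray computation
    ref2 <- matrix(0.55, 4, 155)
    rownames(ref2) <- rownames(pal); attr(ref2, "wavelengths") <- wl
    scene2 <- renderCheckerScene({
        p <- matrix(0.5, 4, 155); rownames(p) <- rownames(pal)
        attr(p, "wavelengths") <- wl; p }, 2, 2, tilePx = 8)
    tab2 <- extractRoiSpectra(scene2, truthMask(scene2))
    rep2 <- validateAgainstReference(tab2, ref2)
    direct <- ciede2000(xyzToLab(spectrumToXYZ(rep(0.5, 155), wl)),
                        xyzToLab(spectrumToXYZ(rep(0.55, 155), wl)))
    expect_equal(deltaETable(rep2)$deltaE, rep(direct, 4), tolerance = 1e-12)

    ## missing reference errors by name
    refMissing <- ref2[1:2, ]
    attr(refMissing, "wavelengths") <- wl
    expect_error(validateAgainstReference(tab, refMissing), "label")
})

test_that("verdict bins are half-open at 2 and 6", {
    mkReport <- function(de) new("DeltaEReport",
        table = data.frame(label = 1L, name = "t", deltaE = de,
            verdict = ifelse(de < 2, "imperceptible",
                      ifelse(de < 6, "acceptable", "unacceptable"))),
        summary = list(maxDeltaE = de, meanDeltaE = de))
    expect_equal(deltaETable(mkReport(1.99))$verdict, "imperceptible")
    expect_equal(deltaETable(mkReport(2.0))$verdict, "acceptable")
    expect_equal(deltaETable(mkReport(6.0))$verdict, "unacceptable")
    ## class validity enforces the binning
    expect_error(new("DeltaEReport",
        table = data.frame(label = 1L, name = "t", deltaE = 3,
                           verdict = "imperceptible"),
        summary = list(maxDeltaE = 3, meanDeltaE = 3)), "verdict")
})

test_that("blood tint red-shifts L1-normalized spectra monotonically", {
    wl <- grid155
    pal <- tissuePalette(wl)
    red <- wl >= 620 & wl <= 700
    green <- wl >= 500 & wl <= 580
    ratios <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(f) {
        scene <- renderTissueScene(pal, blobCount = 4, bloodFraction = f,
                                   seed = 5, size = c(48, 48))
        tab <- l1Normalize(extractRoiSpectra(scene, truthMask(scene)))
        mu <- roiMeans(tab)["1", ]    # contaminated cortex class
        sum(mu[red]) / sum(mu[green])
    }, numeric(1))
    expect_true(all(diff(ratios) > 0))
})
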