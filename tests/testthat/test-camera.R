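test_that("Gaussian filter curves peak at 1 with the nominal FWHM", {
    g <- makeWavelengthGrid(600, 700, 1001)   # 0.1 nm grid
    tr <- gaussianFilterCurve(650, 10, g)
    expect_equal(tr[g == 650], 1.0)
    expect_equal(tr[g == 645], 0.5, tolerance = 1e-12)
    expect_equal(tr[g == 655], 0.5, tolerance = 1e-12)
    expect_error(gaussianFilterCurve(500, 10, g), "within")
})

test_that("every default filter measures FWHM 10 nm by half-max crossings", {
    bank <- makeFilterBank()
    expect_length(bank@centers, 66)
    w <- measureFWHM(bank, step = 0.1)
    expect_length(w, 66)
    expect_true(all(abs(w - 10) <= 0.1))
    expect_true(all(round(w) == 10))
})

test_that("xenon SPD is smooth without ripple and rippled only in 750-900 nm", {
    g <- grid155
    il0 <- xenonSPD(g, rippleAmplitude = 0, seed = 1)
    expect_true(all(il0@spd > 0))
    expect_lt(max(abs(diff(il0@spd, differences = 2))), 5e-3 * max(il0@spd))

    il <- xenonSPD(g, rippleAmplitude = 0.5, seed = 1)
    rel <- il@spd / il0@spd - 1
    outside <- g < 750 | g > 900
    expect_true(all(abs(rel[outside]) < 1e-12))
    expect_gt(max(rel[!outside]), 0.1)

    expect_identical(xenonSPD(g, 0.5, seed = 9)@spd,
                     xenonSPD(g, 0.5, seed = 9)@spd)
    expect_error(xenonSPD(g, rippleAmplitude = 1.2), "rippleAmplitude")
})

test_that("capture DN respond linearly to gain and stay in range", {
    scene <- flatScene(0.2 + 0.3 * exp(-0.5 * ((grid155 - 650) / 60)^2))
    bank <- makeFilterBank(); geom <- makeLensletGeometry()
    il <- flatIlluminant()
    c1 <- simulateCapture(scene, il, bank, geom, noiselessSensor(gain = 2))
    c2 <- simulateCapture(scene, il, bank, geom, noiselessSensor(gain = 4))
    expect_true(all(abs(c2@sample - 2 * c1@sample) <= 2))  # rounding slack
    expect_true(all(c1@sample >= 0 & c1@sample <= 4095))
    expect_true(all(c2@white >= 0 & c2@white <= 4095))
})

test_that("a zero-reflectance scene produces DN identical to dark", {
    scene <- flatScene(rep(0, 155))
    scene@cube[] <- 0
    cap <- simulateCapture(scene, flatIlluminant(), makeFilterBank(),
                           makeLensletGeometry(), noiselessSensor())
    expect_identical(cap@sample, cap@dark)
})

test_that("captures are bit-identical for identical configuration and seed", {
    scene <- flatScene(0.1 + 0.6 * exp(-0.5 * ((grid155 - 550) / 80)^2))
    args <- list(scene, xenonSPD(), makeFilterBank(), makeLensletGeometry(),
                 makeSensorConfig(seed = 42))
    a <- do.call(simulateCapture, args)
    b <- do.call(simulateCapture, args)
    expect_identical(a@sample, b@sample)
    expect_identical(a@white, b@white)
    expect_identical(a@dark, b@dark)
})

test_that("raising reflectance at a filter center never lowers its DN", {
    bank <- makeFilterBank()
    geom <- makeLensletGeometry(pitch = 0)   # no parallax
    il <- flatIlluminant()
    i <- 30L   # an interior lenslet
    base <- rep(0.3, 155)
    bump <- base
    k <- which.min(abs(grid155 - bank@centers[i]))
    bump[k + (-2:2)] <- 0.6
    dnFor <- function(spec) {
        cap <- simulateCapture(flatScene(spec, tilePx = 4), il, bank, geom,
                               noiselessSensor(gain = 3))
        cap@sample[2, 2, i]
    }
    expect_gte(dnFor(bump), dnFor(base))
})

test_that("2x2 binning averages disjoint blocks", {
    expect_identical(bin2x2(matrix(c(0, 4, 2, 6), 2, 2)), matrix(3, 1, 1))
    const <- matrix(7, 6, 8)
    expect_true(all(bin2x2(const) == 7))
    expect_equal(dim(bin2x2(const)), c(3, 4))
    ## brute-force block means on a ramp
    ramp <- matrix(seq_len(16), 4, 4)
    out <- bin2x2(ramp)
    for (r in 1:2) for (cc in 1:2) {
        blk <- ramp[(2 * r - 1):(2 * r), (2 * cc - 1):(2 * cc)]
        expect_equal(out[r, cc], round(mean(blk)))
    }
    expect_error(bin2x2(matrix(0, 3, 4)), "even")
})

test_that("frame memory and Brewster angle compute the device constants", {
    expect_equal(frameMemoryBytes(7920, 6008, 12), 71375040)
    expect_equal(round(frameMemoryBytes(7920, 6008, 12) / 2^20), 68)
    expect_equal(frameMemoryBytes(1, 1, 8), 1)
    expect_equal(frameMemoryBytes(100, 100, 12), 15000)
    expect_error(frameMemoryBytes(10, 10, 10), "multiple of 4")

    expect_equal(brewsterAngle(1), 45)
    expect_equal(round(brewsterAngle(1.5)), 56)
    expect_equal(brewsterAngle(sqrt(3)), 60, tolerance = 1e-12)
    expect_error(brewsterAngle(0), "positive")
})

test_that("imaging a white-reflector scene corrects to unity reflectance", {
    rho <- 0.95
    scene <- flatScene(rep(rho, 155))
    cap <- simulateCapture(scene, xenonSPD(), makeFilterBank(),
                           makeLensletGeometry(), noiselessSensor(),
                           whiteReflectance = rho)
    corr <- correctReferences(cap)
    expect_true(all(abs(values(corr) - 1) < 2e-3))
})
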