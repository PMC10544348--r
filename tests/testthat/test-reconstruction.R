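test_that("reference correction follows (S - D) / (W - D)", {
    d <- c(4, 4, 3)
    W <- array(1000L, d); D <- array(100L, d)
    corr <- correctReferences(W, W, D)
    expect_true(all(values(corr) == 1))
    corr0 <- correctReferences(D, W, D)
    expect_true(all(values(corr0) == 0))
    mid <- array(550L, d)   # (W + D) / 2
    corrMid <- correctReferences(mid, W, D)
    expect_true(all(values(corrMid) == 0.5))
    expect_error(correctReferences(W, W, array(0L, c(2, 2, 3))), "shape")
})

test_that("dead reference pixels are flagged invalid", {
    d <- c(3, 3, 2)
    W <- array(500L, d); D <- array(100L, d)
    W[1, 1, 1] <- 100L   # no reference contrast
    corr <- correctReferences(array(300L, d), W, D, epsilon = 1)
    expect_false(corr@valid[1, 1, 1])
    expect_true(all(corr@valid[-1]))
})

test_that("known-geometry registration inverts the applied parallax", {
    ## zero baselines: registration is the identity
    scene <- flatScene(0.2 + 0.5 * exp(-0.5 * ((grid155 - 600) / 50)^2),
                       tilePx = 12)
    cap0 <- simulateCapture(scene, flatIlluminant(), makeFilterBank(),
                            makeLensletGeometry(pitch = 0), noiselessSensor())
    corr0 <- correctReferences(cap0)
    al0 <- registerKnown(corr0)
    expect_identical(values(al0), values(corr0))
    expect_true(all(al0@residualDisparity == 0))

    ## step-edge scene: post-registration edge positions agree within 0.5 px
    pal <- matrix(c(rep(0.15, 155), rep(0.75, 155)), 2, byrow = TRUE)
    rownames(pal) <- c("1", "2")
    attr(pal, "wavelengths") <- grid155
    edge <- renderCheckerScene(pal, 1, 2, tilePx = 16)
    cap <- simulateCapture(edge, flatIlluminant(), makeFilterBank(),
                           makeLensletGeometry(), noiselessSensor())
    al <- registerKnown(correctReferences(cap))
    edgePos <- apply(values(al), 3, function(img) {
        prof <- colMeans(img)
        ## subpixel crossing of the half level along the edge normal
        half <- (max(prof) + min(prof)) / 2
        i <- which(prof >= half)[1]
        i - 1 + (half - prof[i - 1]) / (prof[i] - prof[i - 1])
    })
    expect_lt(max(edgePos) - min(edgePos), 0.5)
})

test_that("cross-correlation registration recovers planted shifts", {
    ## textured windows cut from one larger random field
    set.seed(4)
    base <- matrix(stats::runif(20 * 20), 20, 20)
    v <- array(0, c(10, 10, 3))
    v[, , 1] <- base[5:14, 5:14]
    v[, , 2] <- base[7:16, 5:14]               # content shifted by (-2, 0)
    v[, , 3] <- base[5:14, 7:16]               # content shifted by (0, -2)
    stack <- new("CorrectedStack", values = v,
                 valid = array(TRUE, dim(v)),
                 geometry = makeLensletGeometry(1, 3, 0),
                 disparity = matrix(numeric(0), 0, 2), provenance = list())
    al <- registerEstimate(stack, referenceLenslet = 1, maxShift = 3)
    est <- al@provenance$estimatedDisparity
    expect_equal(est[2, ], c(-2, 0))
    expect_equal(est[3, ], c(0, -2))
    expect_equal(est[1, ], c(0, 0))

    ## already aligned stack: all shifts zero
    v2 <- array(rep(base[1:10, 1:10], 3), c(10, 10, 3))
    stack2 <- new("CorrectedStack", values = v2, valid = array(TRUE, dim(v2)),
                  geometry = makeLensletGeometry(1, 3, 0),
                  disparity = matrix(numeric(0), 0, 2), provenance = list())
    al2 <- registerEstimate(stack2, referenceLenslet = 1, maxShift = 3)
    expect_true(all(al2@provenance$estimatedDisparity == 0))

    ## constant stack: zero shifts with a warning
    stack3 <- new("CorrectedStack", values = array(0.5, c(8, 8, 2)),
                  valid = array(TRUE, c(8, 8, 2)),
                  geometry = makeLensletGeometry(1, 2, 0),
                  disparity = matrix(numeric(0), 0, 2), provenance = list())
    expect_warning(al3 <- registerEstimate(stack3, referenceLenslet = 1),
                   "texture")
    expect_true(all(al3@provenance$estimatedDisparity == 0))
})

test_that("system matrix is row-normalized with full band support", {
    bank <- makeFilterBank()
    A <- buildSystemMatrix(bank)
    expect_equal(dim(A@entries), c(66, 155))
    expect_equal(unname(A@entries %*% rep(1, 155)), matrix(1, 66, 1))
    expect_true(all(colSums(A@entries) > 0))
    ## delta spectrum at filter-i center peaks in row i
    for (i in c(1, 20, 66)) {
        r <- numeric(155)
        r[which.min(abs(grid155 - bank@centers[i]))] <- 1
        m <- A@entries %*% r
        expect_equal(which.max(m), i)
    }
    ## a sparse bank leaves unsupported bands -> error naming them
    sparse <- makeFilterBank(4, range = c(400, 900), fwhm = 10)
    expect_error(buildSystemMatrix(sparse, makeWavelengthGrid(350, 1000, 155)),
                 "without filter support")
})

test_that("inversion recovers flat and smooth spectra from 66 measurements", {
    bank <- makeFilterBank()
    A <- buildSystemMatrix(bank)
    mkAligned <- function(spec) {
        m <- as.vector(A@entries %*% spec)
        v <- array(rep(m, each = 4), c(2, 2, 66))
        new("AlignedStack", values = v,
            residualDisparity = matrix(0, 66, 2), provenance = list())
    }
    flat <- invertSpectra(mkAligned(rep(0.5, 155)), A)
    expect_lt(max(abs(values(flat) - 0.5)), 1e-3)
    expect_equal(nBands(flat), 155)

    spec <- 0.2 + 0.5 * exp(-0.5 * ((grid155 - 620) / 20)^2)
    rec <- invertSpectra(mkAligned(spec), A)
    expect_lt(max(abs(sweep(values(rec), 3, spec))), 0.02)

    expect_error(invertSpectra(mkAligned(spec), A, ridge = 0), "ridge")
})

test_that("full reconstruction round-trips a noiseless checker", {
    cfg <- defaultConfig()
    cfg$scene$tilePx <- 12L
    res <- runCheckerExperiment(seed = 1, noise = FALSE, config = cfg)
    pal <- scenePalette(res$scene)
    mu <- roiMeans(res$table)
    expect_equal(dim(mu), dim(pal))
    expect_lt(max(abs(mu - pal)), 0.02)
    ## determinism of the full chain
    res2 <- runCheckerExperiment(seed = 1, noise = FALSE, config = cfg)
    expect_identical(values(res$cube), values(res2$cube))
})

test_that("white referencing cancels illuminant ripple in recovered spectra", {
    spec <- 0.2 + 0.5 * exp(-0.5 * ((grid155 - 700) / 30)^2)
    scene <- flatScene(spec)
    run <- function(il) {
        cap <- simulateCapture(scene, il, makeFilterBank(),
                               makeLensletGeometry(), noiselessSensor())
        values(reconstruct(cap))
    }
    smooth <- run(xenonSPD(grid155, 0, seed = 1))
    rippled <- run(xenonSPD(grid155, 0.5, seed = 2))
    nir <- grid155 >= 750 & grid155 <= 900
    expect_lt(max(abs(smooth[, , nir] - rippled[, , nir])), 0.01)
})

test_that("two illuminants with matched whites reconstruct the same cube", {
    spec <- 0.15 + 0.45 * exp(-0.5 * ((grid155 - 550) / 60)^2)
    scene <- flatScene(spec)
    run <- function(il) {
        cap <- simulateCapture(scene, il, makeFilterBank(),
                               makeLensletGeometry(), noiselessSensor())
        values(reconstruct(cap))
    }
    a <- run(flatIlluminant())
    b <- run(xenonSPD())
    expect_lt(max(abs(a - b)), 0.02)
})

test_that("reconstruction RMSE is non-decreasing in read noise", {
    spec <- 0.2 + 0.4 * exp(-0.5 * ((grid155 - 600) / 50)^2)
    scene <- flatScene(spec, tilePx = 8)
    rmseFor <- function(sigma, seed) {
        sens <- makeSensorConfig(shotNoise = FALSE, readNoiseSigma = sigma,
                                 seed = seed)
        cap <- simulateCapture(scene, flatIlluminant(), makeFilterBank(),
                               makeLensletGeometry(), sens)
        rec <- values(reconstruct(cap))
        sqrt(mean(sweep(rec, 3, spec)^2))
    }
    seeds <- 1:20
    r0 <- mean(vapply(seeds, function(s) rmseFor(0, s), numeric(1)))
    r2 <- mean(vapply(seeds, function(s) rmseFor(2, s), numeric(1)))
    r8 <- mean(vapply(seeds, function(s) rmseFor(8, s), numeric(1)))
    expect_lte(r0, r2 + 1e-12)
    expect_lte(r2, r8 + 1e-12)
})
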