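## camera model: illuminant, lenslet filter bank, parallax, 12-bit sensor.

#' Gaussian band-pass transmission curve
#'
#' Transmission of a single lenslet filter: a Gaussian with peak 1 at the
#' centre wavelength and sigma = fwhm / (2 sqrt(2 ln 2)).
#'
#' @param center centre wavelength (nm); must lie within \code{wl}.
#' @param fwhm full width at half maximum (nm).
#' @param wl wavelength grid (nm).
#' @return transmission vector on \code{wl}, peak-normalised to 1.
#' @examples
#' g <- makeWavelengthGrid(600, 700, 1001)
#' t <- gaussianFilterCurve(650, 10, g)
#' t[g == 650]  # 1
#' t[g == 645]  # 0.5
#' @export
gaussianFilterCurve <- function(center, fwhm, wl) {
    if (center < min(wl) || center > max(wl))
        stop("filter 'center' must lie within the wavelength grid")
    if (fwhm <= 0) stop("'fwhm' must be positive")
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-0.5 * ((wl - center) / sigma)^2)
}

#' Build the lenslet filter bank
#'
#' The default bank mirrors a 66-lenslet snapshot camera: centre wavelengths
#' evenly spaced across 350--1000 nm, FWHM 10 nm each. The exact commercial
#' filter responses are proprietary; equal spacing with Gaussian shapes is an
#' explicit modelling assumption.
#'
#' @param nLenslets number of lenslets/filters (default 66).
#' @param range length-2 spectral range (nm) of the centre wavelengths.
#' @param fwhm full width at half maximum (nm) of every filter.
#' @param wl reference grid on which transmissions are tabulated.
#' @return a [FilterBank-class].
#' @export
makeFilterBank <- function(nLenslets = 66, range = c(350, 1000), fwhm = 10,
                           wl = defaultBandGrid()) {
    assertWavelengthGrid(wl)
    centers <- seq(range[1L], range[2L], length.out = nLenslets)
    tr <- t(vapply(centers, gaussianFilterCurve, numeric(length(wl)),
                   fwhm = fwhm, wl = wl))
    new("FilterBank", centers = centers, fwhm = fwhm, wavelengths = wl,
        transmission = tr)
}

#' Numerically measure filter FWHM by half-maximum crossings
#'
#' Samples each filter curve analytically on a fine grid and locates the two
#' half-maximum crossings by linear interpolation.
#'
#' @param bank a [FilterBank-class].
#' @param step fine-grid step in nm (default 0.1).
#' @return numeric vector of measured widths (nm), one per filter.
#' @export
measureFWHM <- function(bank, step = 0.1) {
    vapply(seq_along(bank@centers), function(i) {
        c0 <- bank@centers[i]
        wl <- seq(c0 - 2 * bank@fwhm, c0 + 2 * bank@fwhm, by = step)
        y <- gaussianFilterCurve(c0, bank@fwhm, wl)
        half <- max(y) / 2
        above <- which(y >= half)
        i1 <- above[1L]; i2 <- above[length(above)]
        crossLeft <- if (i1 == 1L) wl[1L] else
            wl[i1 - 1L] + (half - y[i1 - 1L]) / (y[i1] - y[i1 - 1L]) * step
        crossRight <- if (i2 == length(y)) wl[length(wl)] else
            wl[i2] + (half - y[i2]) / (y[i2 + 1L] - y[i2]) * step
        crossRight - crossLeft
    }, numeric(1))
}

#' Xenon-like illuminant spectral power distribution
#'
#' A broad smooth hump across 350--1000 nm, strictly positive everywhere,
#' with narrow additive emission peaks confined to 750--900 nm whose relative
#' amplitude is \code{rippleAmplitude} --- the characteristic behaviour of
#' xenon light sources, which are smooth in the visible and become less
#' smooth in the higher wavelength ranges.
#'
#' @param wl wavelength grid (nm).
#' @param rippleAmplitude fraction in [0, 1): peak amplitude relative to the
#'   smooth baseline; 0 disables the ripple.
#' @param seed RNG seed controlling peak positions/widths.
#' @return an [Illuminant-class].
#' @export
xenonSPD <- function(wl = defaultBandGrid(), rippleAmplitude = 0.3, seed = 1) {
    assertWavelengthGrid(wl)
    if (rippleAmplitude < 0 || rippleAmplitude >= 1)
        stop("'rippleAmplitude' must lie in [0, 1)")
    base <- 0.25 + 0.9 * exp(-0.5 * ((wl - 580) / 230)^2)
    spd <- base
    band <- c(750, 900)
    if (rippleAmplitude > 0) {
        peaks <- withSeed(seed, {
            p <- numeric(length(wl))
            centers <- stats::runif(6, 765, 885)
            widths <- stats::runif(6, 2.5, 5)
            amps <- stats::runif(6, 0.4, 1)
            for (k in seq_along(centers))
                p <- p + amps[k] * exp(-0.5 * ((wl - centers[k]) / widths[k])^2)
            p
        })
        ## hard-window so the ripple is exactly confined to the stated band
        peaks[wl < band[1L] | wl > band[2L]] <- 0
        spd <- base * (1 + rippleAmplitude * peaks)
    }
    new("Illuminant", wavelengths = wl, spd = spd,
        rippleAmplitude = rippleAmplitude, rippleBand = band)
}

#' Lenslet geometry with a centred baseline lattice
#'
#' Lenslets are laid out row-major on a gridRows x gridCols lattice with the
#' given pitch; baselines are measured from the optical centre so they sum to
#' zero. The disparity scale defaults to the value that makes the largest
#' lenslet disparity equal \code{maxDisparityPx} at \code{refDepth}.
#'
#' @param gridRows,gridCols lattice layout (default 6 x 11 = 66 lenslets).
#' @param pitch lenslet pitch in mm.
#' @param disparityScale px * cm / mm; \code{NULL} selects the default above.
#' @param maxDisparityPx,refDepth calibration point for the default scale.
#' @return a [LensletGeometry-class].
#' @export
makeLensletGeometry <- function(gridRows = 6, gridCols = 11, pitch = 1,
                                disparityScale = NULL, maxDisparityPx = 3,
                                refDepth = 25) {
    ry <- (seq_len(gridRows) - (gridRows + 1) / 2) * pitch
    cx <- (seq_len(gridCols) - (gridCols + 1) / 2) * pitch
    b <- cbind(rep(ry, each = gridCols), rep(cx, times = gridRows))
    if (is.null(disparityScale)) {
        maxB <- max(sqrt(rowSums(b^2)))
        disparityScale <- if (maxB > 0) maxDisparityPx * refDepth / maxB else 0
    }
    new("LensletGeometry", gridRows = as.integer(gridRows),
        gridCols = as.integer(gridCols), baselines = b,
        disparityScale = disparityScale)
}

#' Sensor configuration
#'
#' @param bitDepth bits per pixel (default 12; full scale 4095).
#' @param exposureGain DN per unit band radiance; \code{NA} (default) selects
#'   auto-exposure placing the brightest white-reference lenslet at 80% of
#'   full scale.
#' @param shotNoise enable Poisson shot noise on the expected DN.
#' @param readNoiseSigma Gaussian read noise sigma in DN (default 2).
#' @param seed RNG seed for the capture noise.
#' @return a [SensorConfig-class].
#' @export
makeSensorConfig <- function(bitDepth = 12, exposureGain = NA_real_,
                             shotNoise = TRUE, readNoiseSigma = 2, seed = 1) {
    new("SensorConfig", bitDepth = as.integer(bitDepth),
        fullScaleDN = as.integer(2^bitDepth - 1),
        exposureGain = as.numeric(exposureGain),
        shotNoise = isTRUE(shotNoise),
        readNoiseSigma = as.numeric(readNoiseSigma), seed = as.integer(seed))
}

## per-lenslet disparity (px): disparityScale * baseline / depth
lensletDisparity <- function(geometry, depth) {
    geometry@disparityScale * geometry@baselines / depth
}

#' Forward-simulate a lightfield capture
#'
#' For each lenslet i the scene is viewed with a parallax shift
#' delta_i = disparityScale * b_i / Z (bilinear resampling), then integrated
#' against the illuminant and filter i's transmission:
#' m_i(x) = sum_lambda L(lambda) F_i(lambda) r(x, lambda) dlambda. Digital
#' numbers are DN = clip(round(gain * m_i + noise), 0, fullScale). The white
#' stack images a uniform reflector (reflectance \code{whiteReflectance}) at
#' the same depth; the dark stack is pure read noise.
#'
#' @param scene a [ReflectanceScene-class] whose grid covers the bank support.
#' @param illuminant an [Illuminant-class] on the scene grid.
#' @param bank a [FilterBank-class].
#' @param geometry a [LensletGeometry-class].
#' @param sensor a [SensorConfig-class].
#' @param whiteReflectance reflectance of the white reference tile
#'   (default 0.95, a typical calibrated tile).
#' @return a [CaptureSet-class]; the parallax actually applied and the
#'   resolved exposure gain are recorded for downstream registration.
#' @export
simulateCapture <- function(scene, illuminant, bank, geometry,
                            sensor = makeSensorConfig(),
                            whiteReflectance = 0.95) {
    wl <- scene@wavelengths
    if (min(bank@centers) < min(wl) || max(bank@centers) > max(wl))
        stop("filter bank support lies outside the scene wavelength grid")
    L <- interpSpectrum(illuminant@wavelengths, illuminant@spd, wl)
    dl <- gridStep(wl)
    H <- dim(scene@cube)[1L]; W <- dim(scene@cube)[2L]
    n <- length(bank@centers)
    ## per-lenslet spectral weights on the scene grid
    Tm <- t(vapply(bank@centers, gaussianFilterCurve, numeric(length(wl)),
                   fwhm = bank@fwhm, wl = wl))        # n x L
    Wt <- Tm * matrix(L * dl, n, length(wl), byrow = TRUE)
    flat <- flattenCube(scene@cube)                   # (H W) x L
    bandImgs <- flat %*% t(Wt)                        # (H W) x n
    depth <- mean(scene@depthMap)
    disp <- lensletDisparity(geometry, depth)
    full <- sensor@fullScaleDN
    whiteLevel <- whiteReflectance * rowSums(Wt)      # per-lenslet radiance
    gain <- sensor@exposureGain
    if (is.na(gain)) gain <- 0.8 * full / max(whiteLevel)
    expectedSample <- array(0, c(H, W, n))
    for (i in seq_len(n)) {
        img <- matrix(bandImgs[, i], H, W)
        expectedSample[, , i] <- gain * shiftImage(img, disp[i, 1L], disp[i, 2L])
    }
    expectedWhite <- array(rep(gain * whiteLevel, each = H * W), c(H, W, n))
    digitize <- function(expected) {
        v <- as.vector(expected)
        if (sensor@shotNoise) v <- stats::rpois(length(v), v)
        if (sensor@readNoiseSigma > 0)
            v <- v + stats::rnorm(length(v), 0, sensor@readNoiseSigma)
        a <- array(as.integer(pmin(pmax(round(v), 0), full)), dim(expected))
        a
    }
    stacks <- withSeed(sensor@seed, {
        list(sample = digitize(expectedSample),
             white = digitize(expectedWhite),
             dark = digitize(array(0, c(H, W, n))))
    })
    resolved <- sensor
    resolved@exposureGain <- gain
    new("CaptureSet", sample = stacks$sample, white = stacks$white,
        dark = stacks$dark, bank = bank, geometry = geometry,
        sensor = resolved, depth = depth,
        whiteReflectance = whiteReflectance, disparity = disp,
        provenance = list(gain = gain, seed = sensor@seed,
                          depth = depth, whiteReflectance = whiteReflectance))
}

#' 2 x 2 pixel binning
#'
#' Averages disjoint 2 x 2 blocks (rounded to integer DN), halving both frame
#' dimensions --- the spatial compression used by a camera viewfinder mode.
#'
#' @param frame 2-D numeric/integer matrix with even dimensions.
#' @return matrix of half the size; each entry the rounded block mean.
#' @export
bin2x2 <- function(frame) {
    if (!is.matrix(frame)) stop("'frame' must be a matrix")
    H <- nrow(frame); W <- ncol(frame)
    if (H %% 2L != 0L || W %% 2L != 0L)
        stop("frame dimensions must be even for 2x2 binning")
    m <- frame[seq(1, H, 2), seq(1, W, 2), drop = FALSE] +
         frame[seq(2, H, 2), seq(1, W, 2), drop = FALSE] +
         frame[seq(1, H, 2), seq(2, W, 2), drop = FALSE] +
         frame[seq(2, H, 2), seq(2, W, 2), drop = FALSE]
    round(m / 4)
}

#' Memory footprint of a packed frame
#'
#' Bytes occupied by a tightly packed frame: width * height * bitDepth / 8.
#' A full-resolution 7,920 x 6,008 mono12 frame computes to 71,375,040 bytes,
#' i.e. 68 MiB.
#'
#' @param width,height frame dimensions in pixels.
#' @param bitDepth bits per pixel; must be a multiple of 4 so rows pack.
#' @return number of bytes.
#' @examples
#' frameMemoryBytes(7920, 6008, 12) / 2^20  # ~68 MiB
#' @export
frameMemoryBytes <- function(width, height, bitDepth) {
    if (width <= 0 || height <= 0 || bitDepth <= 0)
        stop("all arguments must be positive")
    if (bitDepth %% 4 != 0)
        stop("'bitDepth' must be a multiple of 4")
    width * height * bitDepth / 8
}

#' Brewster's angle
#'
#' Incidence angle at which p-polarised reflection off a dielectric interface
#' vanishes: arctan of the relative refractive index. Mounting an optical
#' window at this angle suppresses internal reflections off a sterile drape
#' film (n ~ 1.5 gives ~56 degrees).
#'
#' @param relativeIndex refractive index ratio n2/n1 (> 0).
#' @return angle in degrees.
#' @export
brewsterAngle <- function(relativeIndex) {
    if (!isScalarNumber(relativeIndex) || relativeIndex <= 0)
        stop("'relativeIndex' must be a single positive number")
    atan(relativeIndex) * 180 / pi
}
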