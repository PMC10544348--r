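## phantom scenes: synthetic reflectance targets with known ground truth.

#' Generate a synthetic colour-checker tile palette
#'
#' Produces reflectance spectra for a board of chromatic and neutral tiles, a
#' parametric stand-in for a physical colour checker whose reference spectra
#' are not redistributable. Chromatic tiles are smooth mixtures of 1--3
#' Gaussian bumps clipped to [0.02, 0.95]; neutral tiles are spectrally flat
#' at evenly spaced gray levels (1:n)/(n+1).
#'
#' @param nChromatic number of chromatic tiles (>= 0).
#' @param nNeutral number of neutral (gray) tiles (>= 0).
#' @param seed RNG seed; the palette is deterministic for a fixed seed.
#' @param wl wavelength grid (nm), default [defaultBandGrid()].
#' @return numeric matrix (nChromatic + nNeutral) x length(wl), rownames
#'   "1", "2", ... in tile order (chromatic first).
#' @examples
#' pal <- makeTilePalette(18, 6, seed = 7)
#' range(pal)  # within [0.02, 0.95]
#' @export
makeTilePalette <- function(nChromatic, nNeutral, seed = 1,
                            wl = defaultBandGrid()) {
    if (nChromatic < 0 || nNeutral < 0)
        stop("tile counts must be non-negative")
    assertWavelengthGrid(wl)
    n <- nChromatic + nNeutral
    pal <- matrix(0, n, length(wl))
    if (nChromatic > 0) {
        pal[seq_len(nChromatic), ] <- withSeed(seed, {
            t(vapply(seq_len(nChromatic), function(i) {
                base <- stats::runif(1, 0.05, 0.20)
                nb <- sample(1:3, 1)
                r <- rep(base, length(wl))
                for (k in seq_len(nb)) {
                    a <- stats::runif(1, 0.15, 0.70)
                    mu <- stats::runif(1, 380, 950)
                    s <- stats::runif(1, 25, 80)
                    r <- r + a * exp(-0.5 * ((wl - mu) / s)^2)
                }
                r
            }, numeric(length(wl))))
        })
    }
    if (nNeutral > 0) {
        levels <- seq_len(nNeutral) / (nNeutral + 1)
        pal[nChromatic + seq_len(nNeutral), ] <-
            matrix(levels, nNeutral, length(wl))
    }
    pal <- pmin(pmax(pal, 0.02), 0.95)
    rownames(pal) <- as.character(seq_len(n))
    attr(pal, "wavelengths") <- wl
    pal
}

#' Lay a tile palette out as a checker scene
#'
#' Tiles the palette row-major into a rows x cols board of constant-spectrum
#' square tiles at a constant working distance, with ground-truth labels
#' 1..rows*cols.
#'
#' @param palette labels x bands reflectance matrix with a "wavelengths"
#'   attribute (see [makeTilePalette()]).
#' @param rows,cols board layout; rows*cols must equal the palette size.
#' @param tilePx tile side length in pixels (>= 4).
#' @param depth working distance in cm (default 25, a typical handheld
#'   acquisition distance).
#' @return a [ReflectanceScene-class] of size (rows*tilePx) x (cols*tilePx).
#' @export
renderCheckerScene <- function(palette, rows, cols, tilePx, depth = 25) {
    wl <- attr(palette, "wavelengths")
    if (is.null(wl)) stop("'palette' must carry a 'wavelengths' attribute")
    if (rows * cols != nrow(palette))
        stop(sprintf("palette has %d entries but layout needs %d",
                     nrow(palette), rows * cols))
    if (tilePx < 4) stop("'tilePx' must be at least 4")
    H <- rows * tilePx; W <- cols * tilePx
    mask <- matrix(0L, H, W)
    cube <- array(0, c(H, W, length(wl)))
    for (r in seq_len(rows)) for (cc in seq_len(cols)) {
        lab <- (r - 1L) * cols + cc
        ri <- (r - 1L) * tilePx + seq_len(tilePx)
        ci <- (cc - 1L) * tilePx + seq_len(tilePx)
        mask[ri, ci] <- lab
        cube[ri, ci, ] <- rep(palette[lab, ], each = tilePx * tilePx)
    }
    legend <- stats::setNames(paste0("tile", seq_len(rows * cols)),
                              as.character(seq_len(rows * cols)))
    new("ReflectanceScene", cube = cube, wavelengths = wl,
        depthMap = matrix(depth, H, W), truthMask = mask,
        palette = stripAttr(palette), legend = legend)
}

#' Illustrative blood-like reflectance spectrum
#'
#' A fixed piecewise-smooth curve with low reflectance between 400 and 600 nm
#' and high reflectance beyond 620 nm, used to emulate blood-tint
#' contamination of tissue surfaces. Illustrative, not physiological.
#'
#' @param wl wavelength grid (nm).
#' @return reflectance vector on \code{wl}, in [0, 1].
#' @export
bloodSpectrum <- function(wl = defaultBandGrid()) {
    0.04 + 0.66 / (1 + exp(-(wl - 612) / 6))
}

#' Illustrative two-class tissue palette
#'
#' Smooth cortex-like and vessel-like reflectance curves: both show reduced
#' reflectance in the green (haemoglobin-like absorption) and a rise into the
#' red/NIR, the vessel class darker and redder. Illustrative shapes for
#' phantom scenes, not measured tissue optics.
#'
#' @param wl wavelength grid (nm).
#' @return 2 x bands matrix with rownames "1" (cortex), "2" (vessel) and a
#'   "wavelengths" attribute.
#' @export
tissuePalette <- function(wl = defaultBandGrid()) {
    cortex <- 0.30 - 0.14 * exp(-0.5 * ((wl - 555) / 45)^2) +
        0.25 / (1 + exp(-(wl - 640) / 25))
    vessel <- 0.10 - 0.05 * exp(-0.5 * ((wl - 545) / 40)^2) +
        0.38 / (1 + exp(-(wl - 650) / 20))
    pal <- rbind(cortex, vessel)
    pal <- pmin(pmax(pal, 0.01), 0.95)
    rownames(pal) <- c("1", "2")
    attr(pal, "wavelengths") <- wl
    pal
}

#' Render a tissue-like phantom scene
#'
#' A background of class 1 with randomly placed elliptical blobs of the other
#' classes, optionally contaminated by a blood-like tint: every pixel
#' spectrum becomes (1 - f) r + f r_blood. The stored palette holds the same
#' mixed spectra so ground truth stays consistent with the cube.
#'
#' @param classSpectra classes x bands reflectance matrix with a
#'   "wavelengths" attribute and >= 2 rows (see [tissuePalette()]).
#' @param blobCount number of elliptical blobs to place.
#' @param bloodFraction mixing fraction f in [0, 1].
#' @param seed RNG seed controlling blob placement.
#' @param size c(H, W) scene size in pixels.
#' @param depth working distance (cm).
#' @return a [ReflectanceScene-class].
#' @export
renderTissueScene <- function(classSpectra, blobCount = 6, bloodFraction = 0,
                              seed = 1, size = c(96, 96), depth = 25) {
    wl <- attr(classSpectra, "wavelengths")
    if (is.null(wl)) stop("'classSpectra' must carry a 'wavelengths' attribute")
    if (nrow(classSpectra) < 2) stop("at least 2 tissue classes are required")
    if (!isScalarNumber(bloodFraction) || bloodFraction < 0 || bloodFraction > 1)
        stop("'bloodFraction' must lie in [0, 1]")
    H <- size[1L]; W <- size[2L]
    k <- nrow(classSpectra)
    mask <- withSeed(seed, {
        m <- matrix(1L, H, W)
        rr <- matrix(rep(seq_len(H), W), H, W)
        cc <- matrix(rep(seq_len(W), each = H), H, W)
        for (b in seq_len(blobCount)) {
            cls <- if (k == 2L) 2L else sample(2:k, 1L)
            cy <- stats::runif(1, 0.15 * H, 0.85 * H)
            cx <- stats::runif(1, 0.15 * W, 0.85 * W)
            ay <- stats::runif(1, 0.05, 0.18) * H
            ax <- stats::runif(1, 0.05, 0.18) * W
            th <- stats::runif(1, 0, pi)
            dy <- rr - cy; dx <- cc - cx
            u <- cos(th) * dy + sin(th) * dx
            v <- -sin(th) * dy + cos(th) * dx
            m[(u / ay)^2 + (v / ax)^2 <= 1] <- cls
        }
        m
    })
    f <- bloodFraction
    rb <- bloodSpectrum(wl)
    mixed <- (1 - f) * classSpectra + f * matrix(rb, k, length(wl), byrow = TRUE)
    cube <- array(0, c(H, W, length(wl)))
    flat <- flattenCube(cube)
    flat[] <- mixed[as.vector(mask), ]
    cube <- unflattenCube(flat, H, W)
    nm <- rownames(classSpectra)
    if (is.null(nm)) nm <- as.character(seq_len(k))
    legend <- stats::setNames(paste0("class", nm), nm)
    pal <- stripAttr(mixed)
    rownames(pal) <- nm
    new("ReflectanceScene", cube = cube, wavelengths = wl,
        depthMap = matrix(depth, H, W), truthMask = mask,
        palette = pal, legend = legend)
}

stripAttr <- function(m) {
    attr(m, "wavelengths") <- NULL
    m
}
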