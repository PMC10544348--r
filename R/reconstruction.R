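## reconstruction: reference correction, parallax registration, spectral
## inversion from 66 lenslet measurements to a 155-band hypercube.

#' White/dark reference correction
#'
#' Converts raw digital numbers to reflectance-normalised fractions per pixel
#' and lenslet: R = (S - D) / max(W - D, epsilon). White references taken
#' under the acquisition lighting divide out the illuminant spectrum and the
#' per-lenslet sensitivity; the dark frame removes the sensor offset.
#' Pixels whose reference contrast W - D falls below \code{epsilon} are
#' flagged invalid.
#'
#' @param sample a [CaptureSet-class], or a raw H x W x lenslets sample stack.
#' @param white,dark reference stacks matching \code{sample} (ignored when a
#'   CaptureSet is given).
#' @param epsilon guard level in DN for dead reference pixels (default 1).
#' @return a [CorrectedStack-class] with a validity array alongside.
#' @export
correctReferences <- function(sample, white = NULL, dark = NULL, epsilon = 1) {
    geometry <- NULL; disparity <- matrix(numeric(0), 0, 2); prov <- list()
    if (is(sample, "CaptureSet")) {
        cap <- sample
        sample <- cap@sample; white <- cap@white; dark <- cap@dark
        geometry <- cap@geometry; disparity <- cap@disparity
        prov <- cap@provenance
    }
    if (is.null(white) || is.null(dark))
        stop("'white' and 'dark' stacks are required")
    if (!all(dim(sample) == dim(white)) || !all(dim(sample) == dim(dark)))
        stop("sample/white/dark stacks must share one shape")
    denom <- white - dark
    valid <- denom >= epsilon
    R <- (sample - dark) / pmax(denom, epsilon)
    if (is.null(geometry)) geometry <- makeLensletGeometry(1, dim(sample)[3L], 0)
    new("CorrectedStack", values = R, valid = valid, geometry = geometry,
        disparity = disparity,
        provenance = c(prov, list(epsilon = epsilon,
                                  invalidReference = sum(!valid))))
}

#' Parallax compensation with known geometry
#'
#' Shifts each lenslet image back by the disparity recorded at capture time
#' (subpixel bilinear resampling), putting every lenslet on the central
#' pixel frame. Accurate parallax correction is a precondition for per-pixel
#' spectral inversion; this is the planar-scene path used when the true
#' geometry is available.
#'
#' @param stack a [CorrectedStack-class] carrying the applied disparity.
#' @return an [AlignedStack-class] with residual disparity ~ 0.
#' @export
registerKnown <- function(stack) {
    if (nrow(stack@disparity) != dim(stack@values)[3L])
        stop("stack carries no capture geometry; use registerEstimate()")
    n <- dim(stack@values)[3L]
    out <- stack@values
    for (i in seq_len(n)) {
        d <- stack@disparity[i, ]
        if (any(d != 0))
            out[, , i] <- shiftImage(stack@values[, , i], -d[1L], -d[2L])
    }
    new("AlignedStack", values = out,
        residualDisparity = matrix(0, n, 2),
        provenance = c(stack@provenance,
                       list(registration = "known",
                            appliedShift = -stack@disparity)))
}

#' Parallax compensation by cross-correlation
#'
#' Estimates a global integer shift per lenslet by maximising the zero-mean
#' normalised cross-correlation against a reference lenslet within
#' +/- \code{maxShift} pixels; ties break toward zero shift. Texture-free
#' (constant) lenslet images fall back to zero shift with a warning.
#'
#' @param stack a [CorrectedStack-class].
#' @param referenceLenslet index of the reference view; default the lenslet
#'   with the smallest baseline (the optical centre).
#' @param maxShift search radius in pixels (>= 1).
#' @return an [AlignedStack-class]; estimated shifts are recorded in
#'   provenance.
#' @export
registerEstimate <- function(stack, referenceLenslet = NULL, maxShift = 4) {
    if (maxShift < 1) stop("'maxShift' must be at least 1")
    v <- stack@values
    n <- dim(v)[3L]
    if (is.null(referenceLenslet)) {
        referenceLenslet <- if (nrow(stack@geometry@baselines) == n)
            which.min(rowSums(stack@geometry@baselines^2)) else 1L
    }
    ref <- v[, , referenceLenslet]
    shifts <- matrix(0, n, 2)
    degenerate <- FALSE
    for (i in seq_len(n)) {
        if (i == referenceLenslet) next
        est <- nccShift(v[, , i], ref, maxShift)
        if (is.null(est)) degenerate <- TRUE else shifts[i, ] <- est
    }
    if (degenerate)
        warning("texture-free lenslet image(s); falling back to zero shift")
    out <- v
    for (i in seq_len(n)) {
        d <- shifts[i, ]
        if (any(d != 0)) out[, , i] <- shiftImage(v[, , i], -d[1L], -d[2L])
    }
    new("AlignedStack", values = out,
        residualDisparity = matrix(0, n, 2),
        provenance = c(stack@provenance,
                       list(registration = "estimate",
                            estimatedDisparity = shifts,
                            referenceLenslet = referenceLenslet)))
}

## integer content shift of img relative to ref maximising zero-mean NCC;
## NULL when either overlap is texture-free everywhere.
nccShift <- function(img, ref, maxShift) {
    H <- nrow(img); W <- ncol(img)
    best <- NULL; bestScore <- -Inf; bestDist <- Inf
    anyTexture <- FALSE
    for (dy in -maxShift:maxShift) for (dx in -maxShift:maxShift) {
        ## img(r, c) ~ ref(r - dy, c - dx): overlap windows
        r1 <- max(1, 1 + dy):min(H, H + dy)
        c1 <- max(1, 1 + dx):min(W, W + dx)
        a <- img[r1, c1]
        b <- ref[r1 - dy, c1 - dx]
        a <- a - mean(a); b <- b - mean(b)
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na < 1e-12 || nb < 1e-12) next
        anyTexture <- TRUE
        score <- sum(a * b) / (na * nb)
        dist <- abs(dy) + abs(dx)
        if (score > bestScore + 1e-12 ||
            (abs(score - bestScore) <= 1e-12 && dist < bestDist)) {
            bestScore <- score; best <- c(dy, dx); bestDist <- dist
        }
    }
    if (!anyTexture) return(NULL)
    best
}

#' Build the lenslet-to-band system matrix
#'
#' A[i, k] = F_i(lambda_k) * dlambda, rows normalised so that a flat unit
#' reflectance maps to measurement 1 in every lenslet. The 66-filter bank on
#' the 155-band default grid oversamples: every output band receives support
#' from at least one filter, which the constructor verifies.
#'
#' @param bank a [FilterBank-class].
#' @param outputGrid output band grid (nm), default [defaultBandGrid()].
#' @return a [SystemMatrix-class].
#' @export
buildSystemMatrix <- function(bank, outputGrid = defaultBandGrid()) {
    assertWavelengthGrid(outputGrid, "outputGrid")
    if (min(bank@centers) < min(outputGrid) - bank@fwhm ||
        max(bank@centers) > max(outputGrid) + bank@fwhm)
        stop("output grid lies outside the filter bank support")
    A <- t(vapply(bank@centers, gaussianFilterCurve,
                  numeric(length(outputGrid)),
                  fwhm = bank@fwhm, wl = outputGrid))
    ## transmissions beyond ~7 sigma are physically zero; truncating them
    ## makes the band-support check meaningful
    A[A < 1e-10] <- 0
    A <- A / rowSums(A)
    dead <- which(colSums(A) <= 0)
    if (length(dead))
        stop(sprintf("output band(s) without filter support: %s nm",
                     paste(round(outputGrid[dead], 1), collapse = ", ")))
    new("SystemMatrix", entries = A, outputGrid = outputGrid)
}

#' Invert lenslet measurements to a reflectance spectrum per pixel
#'
#' Solves, for every pixel, the Tikhonov-regularised least-squares problem
#' min ||A r - m||^2 + ridge ||D r||^2 with D the order-\code{smoothOrder}
#' finite-difference operator (second differences by default). Recovering
#' 155 bands from 66 measurements is underdetermined, so the smoothness
#' prior is what makes the inversion well posed: at \code{ridge = 0} the
#' normal equations are singular and the solver refuses.
#'
#' @param aligned an [AlignedStack-class] (lenslet axis = system-matrix rows).
#' @param A a [SystemMatrix-class].
#' @param ridge regularisation weight (default 1e-3).
#' @param smoothOrder difference order of the penalty (default 2).
#' @param nonneg clip negative reflectance to zero after solving.
#' @return a [Hypercube-class] on \code{A}'s output grid, clipped to
#'   [0, 1.5] with clip events counted in provenance.
#' @export
invertSpectra <- function(aligned, A, ridge = 1e-3, smoothOrder = 2,
                          nonneg = FALSE) {
    v <- aligned@values
    if (dim(v)[3L] != nrow(A@entries))
        stop("aligned stack depth must equal the system-matrix row count")
    B <- ncol(A@entries)
    if (ridge <= 0)
        stop("the 66->155 band inversion is underdetermined; ",
             "a positive 'ridge' (smoothness prior) is required")
    D <- diff(diag(B), differences = as.integer(smoothOrder))
    M <- crossprod(A@entries) + ridge * crossprod(D)
    solveOp <- solve(M, t(A@entries))          # B x n_lenslets
    meas <- t(flattenCube(v))                  # n_lenslets x (H W)
    rec <- solveOp %*% meas                    # B x (H W)
    if (nonneg) rec[rec < 0] <- 0
    nClip <- sum(rec < 0 | rec > 1.5)
    rec[rec < 0] <- 0
    rec[rec > 1.5] <- 1.5
    H <- dim(v)[1L]; W <- dim(v)[2L]
    cube <- unflattenCube(t(rec), H, W)
    new("Hypercube", values = cube, wavelengths = A@outputGrid,
        provenance = c(aligned@provenance,
                       list(ridge = ridge, smoothOrder = smoothOrder,
                            nonneg = nonneg, clipCount = nClip)))
}

#' Reconstruct a hypercube from a capture set
#'
#' The full calibration chain: white/dark reference correction, rescaling by
#' the white-reflector reflectance so output is absolute reflectance,
#' parallax registration (known geometry when recorded, cross-correlation
#' otherwise), and regularised spectral inversion onto the output band grid
#' (155 bands over 350--1000 nm by default).
#'
#' @param capture a [CaptureSet-class].
#' @param config optional list overriding pipeline defaults: epsilon, ridge,
#'   smoothOrder, nonneg, outputGrid, register ("known", "estimate" or
#'   "none"), maxShift.
#' @return a [Hypercube-class] with full provenance.
#' @examples
#' pal <- makeTilePalette(4, 2, seed = 3)
#' scene <- renderCheckerScene(pal, 2, 3, tilePx = 8)
#' cap <- simulateCapture(scene, xenonSPD(), makeFilterBank(),
#'                        makeLensletGeometry(),
#'                        makeSensorConfig(shotNoise = FALSE,
#'                                         readNoiseSigma = 0))
#' cube <- reconstruct(cap)
#' nBands(cube)  # 155
#' @export
reconstruct <- function(capture, config = list()) {
    cfg <- utils::modifyList(list(epsilon = 1, ridge = 1e-3, smoothOrder = 2,
                                  nonneg = FALSE,
                                  outputGrid = defaultBandGrid(),
                                  register = "known", maxShift = 4), config)
    corrected <- correctReferences(capture, epsilon = cfg$epsilon)
    ## restore absolute reflectance: the white tile reflects whiteReflectance,
    ## so (S-D)/(W-D) measures r / whiteReflectance
    corrected@values <- corrected@values * capture@whiteReflectance
    aligned <- switch(cfg$register,
        known = registerKnown(corrected),
        estimate = registerEstimate(corrected, maxShift = cfg$maxShift),
        none = new("AlignedStack", values = corrected@values,
                   residualDisparity = matrix(0, dim(corrected@values)[3L], 2),
                   provenance = corrected@provenance),
        stop("unknown 'register' mode: ", cfg$register))
    A <- buildSystemMatrix(capture@bank, cfg$outputGrid)
    cube <- invertSpectra(aligned, A, ridge = cfg$ridge,
                          smoothOrder = cfg$smoothOrder, nonneg = cfg$nonneg)
    cube@provenance$config <- cfg[setdiff(names(cfg), "outputGrid")]
    cube@provenance$seed <- capture@sensor@seed
    cube
}
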