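## colorimetry: spectra -> CIEXYZ -> sRGB / CIELAB, CIEDE2000.

.pkgCache <- new.env(parent = emptyenv())

D65White <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

## IEC 61966-2-1 XYZ (D65) -> linear sRGB
.M_XYZ2RGB <- matrix(c(3.2406255, -1.5372080, -0.4986286,
                       -0.9689307, 1.8757561, 0.0415175,
                       0.0557101, -0.2040211, 1.0569959),
                     3, 3, byrow = TRUE)

## Bradford cone-response matrix
.M_BFD <- matrix(c(0.8951, 0.2664, -0.1614,
                   -0.7502, 1.7135, 0.0367,
                   0.0389, -0.0685, 1.0296),
                 3, 3, byrow = TRUE)

#' Colour-matching functions of the 1931 2-degree standard observer
#'
#' Loads the package's CMF fixture: xbar, ybar, zbar tabulated at 5 nm over
#' 360--830 nm. The table is generated from a published multi-lobe Gaussian
#' analytic fit to the CIE 1931 observer (a close, self-consistent stand-in
#' for the official tabulation, shipped so no download is needed).
#'
#' @return list with elements wavelengths, xbar, ybar, zbar.
#' @export
cieCMF <- function() {
    if (is.null(.pkgCache$cmf)) {
        path <- system.file("extdata", "cie1931_cmf_5nm.csv",
                            package = "lightfieldHSI", mustWork = TRUE)
        tab <- utils::read.csv(path)
        .pkgCache$cmf <- list(wavelengths = tab$wavelength_nm,
                              xbar = tab$xbar, ybar = tab$ybar,
                              zbar = tab$zbar)
    }
    .pkgCache$cmf
}

## Bradford chromatic adaptation matrix from the CMF's own equal-energy
## white (XYZ of a flat unit reflectance) to D65. Applied inside
## spectrumToXYZ so that the perfect reflector maps exactly to the D65 white
## point, grays stay neutral, and flat r = 1 renders as display white.
adaptationMatrix <- function(cmf = cieCMF()) {
    key <- "adapt"
    if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
    N <- sum(cmf$ybar)
    src <- c(sum(cmf$xbar), sum(cmf$ybar), sum(cmf$zbar)) / N
    coneS <- as.vector(.M_BFD %*% src)
    coneD <- as.vector(.M_BFD %*% D65White)
    M <- solve(.M_BFD) %*% diag(coneD / coneS) %*% .M_BFD
    .pkgCache[[key]] <- M
    M
}

## 3 x B operator taking reflectance sampled on `wl` straight to
## (adapted) XYZ: interpolation onto the CMF grid, CMF integration and the
## normalisation sum(ybar * dl) baked into one matrix.
xyzOperator <- function(wl, cmf = cieCMF(), whiteAdapt = TRUE) {
    P <- interpMatrix(wl, cmf$wavelengths)        # cmf-grid x B
    N <- sum(cmf$ybar)
    M <- rbind(cmf$xbar, cmf$ybar, cmf$zbar) %*% P / N
    if (whiteAdapt) M <- adaptationMatrix(cmf) %*% M
    M
}

#' Reflectance spectrum to CIE XYZ
#'
#' Integrates the reflectance against the 1931 2-degree colour-matching
#' functions (linear interpolation onto the CMF grid; zero contribution
#' outside the spectrum's support), normalised so a perfect reflector has
#' Y = 1. White-balanced reflectance carries no illuminant, so integration
#' is under equal energy followed by a fixed Bradford adaptation to D65
#' (disable with \code{whiteAdapt = FALSE}); a flat unit spectrum maps
#' exactly to the D65 white point.
#'
#' @param reflectance reflectance vector, or a pixels x bands matrix.
#' @param wl wavelength grid (nm) of the spectrum.
#' @param cmf colour-matching functions, default [cieCMF()].
#' @param whiteAdapt apply the equal-energy -> D65 Bradford adaptation.
#' @return named XYZ vector, or an n x 3 matrix for matrix input.
#' @export
spectrumToXYZ <- function(reflectance, wl, cmf = cieCMF(), whiteAdapt = TRUE) {
    if (max(wl) < min(cmf$wavelengths) || min(wl) > max(cmf$wavelengths))
        stop("spectrum has no overlap with the CMF support (360-830 nm)")
    M <- xyzOperator(wl, cmf, whiteAdapt)
    if (is.matrix(reflectance)) {
        out <- reflectance %*% t(M)
        colnames(out) <- c("X", "Y", "Z")
        out
    } else {
        stats::setNames(as.vector(M %*% reflectance), c("X", "Y", "Z"))
    }
}

#' CIE XYZ to sRGB
#'
#' Multiplies by the IEC 61966-2-1 matrix and applies the piecewise sRGB
#' gamma (linear slope 12.92 below 0.0031308, else 1.055 v^(1/2.4) - 0.055).
#' Out-of-gamut channels are clipped to [0, 1]; the returned value carries a
#' logical "clipped" attribute flagging affected colours.
#'
#' @param xyz XYZ vector, or an n x 3 matrix.
#' @return RGB in [0, 1] (same shape), with attribute "clipped".
#' @export
xyzToSRGB <- function(xyz) {
    vec <- !is.matrix(xyz)
    m <- if (vec) matrix(xyz, 1, 3) else xyz
    lin <- m %*% t(.M_XYZ2RGB)
    clipped <- lin < 0 | lin > 1
    lin <- pmin(pmax(lin, 0), 1)
    srgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                   1.055 * lin^(1 / 2.4) - 0.055)
    srgb <- pmin(pmax(srgb, 0), 1)
    flag <- apply(clipped, 1, any)
    if (vec) {
        out <- stats::setNames(as.vector(srgb), c("R", "G", "B"))
        attr(out, "clipped") <- flag[1L]
    } else {
        out <- srgb
        colnames(out) <- c("R", "G", "B")
        attr(out, "clipped") <- flag
    }
    out
}

#' CIE XYZ to CIELAB
#'
#' Standard L*a*b* with the cube-root compression and its linear low-ratio
#' segment (t <= (6/29)^3).
#'
#' @param xyz XYZ vector or n x 3 matrix.
#' @param white reference white XYZ (default D65).
#' @return Lab vector or n x 3 matrix.
#' @export
xyzToLab <- function(xyz, white = D65White) {
    if (any(white <= 0)) stop("reference white must have positive components")
    vec <- !is.matrix(xyz)
    m <- if (vec) matrix(xyz, 1, 3) else xyz
    t <- sweep(m, 2, white, "/")
    delta3 <- (6 / 29)^3
    f <- ifelse(t > delta3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
    L <- 116 * f[, 2L] - 16
    a <- 500 * (f[, 1L] - f[, 2L])
    b <- 200 * (f[, 2L] - f[, 3L])
    out <- cbind(L = L, a = a, b = b)
    if (vec) stats::setNames(as.vector(out), c("L", "a", "b")) else out
}

#' CIEDE2000 colour difference
#'
#' The full CIEDE2000 formula: chroma-dependent G rescaling of a*, weighting
#' functions S_L, S_C, S_H, and the rotation term R_T coupling the chroma and
#' hue differences. Symmetric, non-negative, zero iff the inputs are equal.
#'
#' @param lab1,lab2 Lab vectors, or n x 3 matrices of Lab rows.
#' @param kL,kC,kH parametric weighting factors (default 1).
#' @return numeric vector of colour differences.
#' @export
ciede2000 <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
    m1 <- if (is.matrix(lab1)) lab1 else matrix(lab1, ncol = 3)
    m2 <- if (is.matrix(lab2)) lab2 else matrix(lab2, ncol = 3)
    L1 <- m1[, 1L]; a1 <- m1[, 2L]; b1 <- m1[, 3L]
    L2 <- m2[, 1L]; a2 <- m2[, 2L]; b2 <- m2[, 3L]
    C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
    Cbar <- (C1 + C2) / 2
    G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
    a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
    C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
    h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) * 180 / pi) %% 360)
    h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) * 180 / pi) %% 360)
    dLp <- L2 - L1
    dCp <- C2p - C1p
    dh <- h2p - h1p
    dh <- ifelse(abs(dh) <= 180, dh, dh - sign(dh) * 360)
    dh <- ifelse(C1p * C2p == 0, 0, dh)
    dHp <- 2 * sqrt(C1p * C2p) * sin(dh / 2 * pi / 180)
    Lbp <- (L1 + L2) / 2
    Cbp <- (C1p + C2p) / 2
    hsum <- h1p + h2p
    hbp <- ifelse(C1p * C2p == 0, hsum,
           ifelse(abs(h1p - h2p) <= 180, hsum / 2,
           ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))
    cosd <- function(x) cos(x * pi / 180)
    Tt <- 1 - 0.17 * cosd(hbp - 30) + 0.24 * cosd(2 * hbp) +
        0.32 * cosd(3 * hbp + 6) - 0.20 * cosd(4 * hbp - 63)
    dTheta <- 30 * exp(-(((hbp - 275) / 25)^2))
    RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
    SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
    SC <- 1 + 0.045 * Cbp
    SH <- 1 + 0.015 * Cbp * Tt
    RT <- -sin(2 * dTheta * pi / 180) * RC
    sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
         RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

#' Render a hypercube as an sRGB image
#'
#' Per-pixel spectrum -> XYZ -> sRGB, vectorised through a single 3 x B
#' operator, emitting an 8-bit image array.
#'
#' @param cube a [Hypercube-class] (or [ReflectanceScene-class]).
#' @param cmf colour-matching functions, default [cieCMF()].
#' @return integer array H x W x 3 with values 0--255.
#' @export
srgbRender <- function(cube, cmf = cieCMF()) {
    if (is(cube, "ReflectanceScene")) {
        arr <- cube@cube; wl <- cube@wavelengths
    } else {
        arr <- cube@values; wl <- cube@wavelengths
    }
    if (max(wl) < min(cmf$wavelengths) || min(wl) > max(cmf$wavelengths))
        stop("cube wavelengths have no overlap with the CMF support")
    H <- dim(arr)[1L]; W <- dim(arr)[2L]
    xyz <- spectrumToXYZ(flattenCube(arr), wl, cmf)
    srgb <- xyzToSRGB(xyz)
    img <- array(0L, c(H, W, 3L))
    img[] <- as.integer(round(255 * as.vector(srgb)))
    img
}

#' Write an 8-bit sRGB render to PNG
#'
#' @param img integer H x W x 3 array from [srgbRender()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSRGB <- function(img, path) {
    png::writePNG(img / 255, target = path)
    invisible(path)
}
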