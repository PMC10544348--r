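## spectra analysis: ROI extraction, L1 normalisation, saturation rejection,
## CIEDE2000 validation reporting.

#' Specular/saturation pixel rejection
#'
#' Specular highlights saturate the sensor and corrupt reflectance spectra.
#' A pixel is invalid when any raw lenslet DN reaches
#' \code{saturationFraction * fullScaleDN} (when the raw capture is
#' available) or, as a fallback on reconstructed cubes, when any band
#' reaches \code{saturationFraction} times the 1.5 reflectance clip ceiling.
#'
#' @param x a [CaptureSet-class] or [Hypercube-class].
#' @param saturationFraction fraction in (0, 1] of the ceiling (default 1).
#' @return logical H x W matrix, TRUE for valid pixels.
#' @export
rejectSaturated <- function(x, saturationFraction = 1.0) {
    if (saturationFraction <= 0 || saturationFraction > 1)
        stop("'saturationFraction' must lie in (0, 1]")
    if (is(x, "CaptureSet")) {
        thr <- saturationFraction * x@sensor@fullScaleDN
        bad <- apply(x@sample >= thr, c(1, 2), any)
    } else if (is(x, "Hypercube")) {
        thr <- saturationFraction * 1.5
        bad <- apply(x@values >= thr, c(1, 2), any)
    } else stop("'x' must be a CaptureSet or Hypercube")
    !bad
}

#' Extract per-structure mean spectra through a label mask
#'
#' For every label present in the mask, computes the number of annotated
#' pixels, the number that survive the validity mask, and the band-wise mean
#' and population standard deviation over the valid pixels. Labels with no
#' valid pixel are reported with nValid = 0 and NA spectra.
#'
#' @param cube a [Hypercube-class] (or [ReflectanceScene-class]).
#' @param mask a [LabelMask-class] (or integer matrix) matching the cube's
#'   spatial dimensions.
#' @param valid optional logical H x W validity matrix, e.g. from
#'   [rejectSaturated()]; default all valid.
#' @return a [RoiSpectraTable-class].
#' @export
extractRoiSpectra <- function(cube, mask, valid = NULL) {
    if (is(cube, "ReflectanceScene")) {
        arr <- cube@cube; wl <- cube@wavelengths
    } else {
        arr <- cube@values; wl <- cube@wavelengths
    }
    legend <- character()
    if (is(mask, "LabelMask")) {
        legend <- mask@legend
        mask <- mask@labels
    }
    d <- dim(arr)
    if (!all(dim(mask) == d[1:2]))
        stop("mask dimensions must equal the cube's spatial dimensions")
    if (is.null(valid)) valid <- matrix(TRUE, d[1L], d[2L])
    if (!all(dim(valid) == d[1:2]))
        stop("validity mask dimensions must equal the cube's")
    labs <- setdiff(sort(unique(as.vector(mask))), 0L)
    B <- d[3L]
    flat <- flattenCube(arr)
    mu <- matrix(NA_real_, length(labs), B)
    sd <- matrix(NA_real_, length(labs), B)
    nTotal <- integer(length(labs)); nValid <- integer(length(labs))
    for (j in seq_along(labs)) {
        inLab <- as.vector(mask == labs[j])
        nTotal[j] <- sum(inLab)
        sel <- inLab & as.vector(valid)
        nValid[j] <- sum(sel)
        if (nValid[j] > 0L) {
            px <- flat[sel, , drop = FALSE]
            m <- colMeans(px)
            mu[j, ] <- m
            ## population standard deviation; clamp tiny negative variances
            ## from catastrophic cancellation on constant regions
            sd[j, ] <- sqrt(pmax(colMeans(px^2) - m^2, 0))
        }
    }
    nm <- if (length(legend)) unname(legend[as.character(labs)])
          else paste0("label", labs)
    nm[is.na(nm)] <- paste0("label", labs[is.na(nm)])
    rownames(mu) <- rownames(sd) <- as.character(labs)
    new("RoiSpectraTable",
        stats = data.frame(label = labs, name = nm, nTotal = nTotal,
                           nValid = nValid, stringsAsFactors = FALSE),
        mean = mu, sd = sd, wavelengths = wl, normalized = FALSE)
}

#' L1 normalisation of spectra
#'
#' Rescales a spectrum so its values sum to 1, removing overall intensity
#' while preserving spectral shape. For a [RoiSpectraTable-class] every mean
#' spectrum row is normalised (and its standard-deviation row scaled by the
#' same factor).
#'
#' @param x non-negative numeric vector with at least one positive value, a
#'   rows-of-spectra matrix, or a [RoiSpectraTable-class].
#' @return the normalised object, same shape as the input.
#' @examples
#' l1Normalize(c(2, 2, 4))  # 0.25 0.25 0.50
#' @export
l1Normalize <- function(x) {
    if (is(x, "RoiSpectraTable")) {
        ok <- !is.na(x@mean[, 1L])
        if (any(ok)) {
            s <- rowSums(x@mean[ok, , drop = FALSE])
            if (any(s <= 0)) stop("cannot L1-normalize an all-zero spectrum")
            x@mean[ok, ] <- x@mean[ok, , drop = FALSE] / s
            x@sd[ok, ] <- x@sd[ok, , drop = FALSE] / s
        }
        x@normalized <- TRUE
        return(x)
    }
    if (is.matrix(x)) return(t(apply(x, 1, l1Normalize)))
    if (any(is.na(x)) || any(x < 0))
        stop("spectrum must be non-negative with no missing values")
    s <- sum(x)
    if (s <= 0) stop("cannot L1-normalize an all-zero spectrum")
    x / s
}

#' Shrink mask regions to their central core
#'
#' Replaces every labelled region by its intersection with the centred
#' axis-aligned box covering \code{centerFraction} of the region's
#' bounding-box side lengths --- the "central square of pixels per tile"
#' sampling used when validating against a colour checker, which avoids tile
#' edges and registration artefacts.
#'
#' @param mask a [LabelMask-class] or integer matrix.
#' @param centerFraction fraction in (0, 1] of each side to keep.
#' @return object of the same class as \code{mask}.
#' @export
tileCenterRegions <- function(mask, centerFraction = 0.5) {
    if (centerFraction <= 0 || centerFraction > 1)
        stop("'centerFraction' must lie in (0, 1]")
    legend <- NULL
    labels <- mask
    if (is(mask, "LabelMask")) {
        legend <- mask@legend
        labels <- mask@labels
    }
    out <- matrix(0L, nrow(labels), ncol(labels))
    for (lab in setdiff(sort(unique(as.vector(labels))), 0L)) {
        idx <- which(labels == lab, arr.ind = TRUE)
        r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
        c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
        kh <- max(1L, round(centerFraction * (r1 - r0 + 1L)))
        kw <- max(1L, round(centerFraction * (c1 - c0 + 1L)))
        rs <- r0 + (r1 - r0 + 1L - kh) %/% 2L
        cs <- c0 + (c1 - c0 + 1L - kw) %/% 2L
        keep <- idx[, 1L] >= rs & idx[, 1L] < rs + kh &
                idx[, 2L] >= cs & idx[, 2L] < cs + kw
        out[idx[keep, , drop = FALSE]] <- lab
    }
    if (!is.null(legend)) new("LabelMask", labels = out, legend = legend)
    else out
}

#' Validate measured spectra against references with CIEDE2000
#'
#' Converts each structure's mean spectrum and its reference spectrum to
#' CIELAB (via CIEXYZ) and computes the CIEDE2000 difference, with the
#' standard verdict bands: differences below 2 are imperceptible to the eye,
#' below 6 acceptable in most commercial colour reproduction.
#'
#' @param table a [RoiSpectraTable-class] of measured mean spectra.
#' @param reference labels x bands reflectance matrix with label rownames;
#'   either carrying a "wavelengths" attribute or accompanied by
#'   \code{refWavelengths}.
#' @param refWavelengths wavelength grid of the reference spectra (nm).
#' @param cmf colour-matching functions, default [cieCMF()].
#' @return a [DeltaEReport-class].
#' @export
validateAgainstReference <- function(table, reference, refWavelengths = NULL,
                                     cmf = cieCMF()) {
    if (is.null(refWavelengths)) refWavelengths <- attr(reference, "wavelengths")
    if (is.null(refWavelengths))
        stop("reference spectra need a wavelength grid")
    labs <- table@stats$label
    missing <- setdiff(as.character(labs), rownames(reference))
    if (length(missing))
        stop("no reference spectrum for label(s): ",
             paste(missing, collapse = ", "))
    de <- rep(NA_real_, length(labs))
    for (j in seq_along(labs)) {
        if (table@stats$nValid[j] == 0L) next
        labMeas <- xyzToLab(spectrumToXYZ(table@mean[j, ],
                                          table@wavelengths, cmf))
        labRef <- xyzToLab(spectrumToXYZ(reference[as.character(labs[j]), ],
                                         refWavelengths, cmf))
        de[j] <- ciede2000(labMeas, labRef)
    }
    verdict <- ifelse(is.na(de), NA_character_,
               ifelse(de < 2, "imperceptible",
               ifelse(de < 6, "acceptable", "unacceptable")))
    new("DeltaEReport",
        table = data.frame(label = labs, name = table@stats$name,
                           deltaE = de, verdict = verdict,
                           stringsAsFactors = FALSE),
        summary = list(maxDeltaE = if (all(is.na(de))) NA_real_
                                   else max(de, na.rm = TRUE),
                       meanDeltaE = if (all(is.na(de))) NA_real_
                                    else mean(de, na.rm = TRUE)))
}
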