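#' @import methods
NULL

#' FilterBank: the per-lenslet band-pass filter set
#'
#' Describes the spectral filtering of a lenslet-array snapshot camera: one
#' Gaussian band-pass filter per lenslet, peak transmission 1 at the centre
#' wavelength. The default bank mimics a 66-lenslet device whose centre
#' wavelengths span 350--1000 nm with a full width at half maximum of 10 nm.
#'
#' @slot centers numeric vector of centre wavelengths (nm), one per lenslet.
#' @slot fwhm single numeric, full width at half maximum (nm) shared by all
#'   filters.
#' @slot wavelengths reference wavelength grid (nm) on which
#'   \code{transmission} is tabulated.
#' @slot transmission numeric matrix, lenslets x wavelengths, each row the
#'   filter transmission sampled on \code{wavelengths}.
#' @seealso [makeFilterBank()], [gaussianFilterCurve()]
#' @exportClass FilterBank
setClass("FilterBank",
    representation(centers = "numeric", fwhm = "numeric",
                   wavelengths = "numeric", transmission = "matrix"))

setValidity("FilterBank", function(object) {
    msg <- character()
    if (length(object@fwhm) != 1L || object@fwhm <= 0)
        msg <- c(msg, "'fwhm' must be a single positive number")
    if (nrow(object@transmission) != length(object@centers))
        msg <- c(msg, "one transmission row per lenslet required")
    if (ncol(object@transmission) != length(object@wavelengths))
        msg <- c(msg, "transmission columns must match the wavelength grid")
    if (any(object@centers < min(object@wavelengths)) ||
        any(object@centers > max(object@wavelengths)))
        msg <- c(msg, "all filter centers must lie within the wavelength grid")
    ## FWHM measured by half-max crossings on a fine analytic resampling must
    ## agree with the nominal value within 2%.
    if (length(msg) == 0L && length(object@centers)) {
        w <- measureFWHM(object, step = 0.5)
        if (any(abs(w - object@fwhm) > 0.02 * object@fwhm))
            msg <- c(msg, "measured FWHM deviates from nominal by more than 2%")
    }
    if (length(msg)) msg else TRUE
})

#' LensletGeometry: lenslet layout and parallax model
#'
#' Lenslets sit on a regular centred lattice; each views the scene from a
#' slightly different baseline, so a scene point at depth Z appears displaced
#' by a per-lenslet disparity delta_i = disparityScale * b_i / Z (pixels, with
#' baselines in mm and depth in cm).
#'
#' @slot gridRows,gridCols integers; gridRows*gridCols lenslets.
#' @slot baselines numeric matrix (lenslets x 2), (y, x) offsets in mm from
#'   the optical centre; symmetric about zero.
#' @slot disparityScale single numeric, px * cm / mm.
#' @exportClass LensletGeometry
setClass("LensletGeometry",
    representation(gridRows = "integer", gridCols = "integer",
                   baselines = "matrix", disparityScale = "numeric"))

setValidity("LensletGeometry", function(object) {
    msg <- character()
    n <- object@gridRows * object@gridCols
    if (nrow(object@baselines) != n || ncol(object@baselines) != 2L)
        msg <- c(msg, "'baselines' must be an (gridRows*gridCols) x 2 matrix")
    else if (any(abs(colMeans(object@baselines)) > 1e-9))
        msg <- c(msg, "'baselines' must be symmetric about the optical centre")
    if (length(object@disparityScale) != 1L || object@disparityScale < 0)
        msg <- c(msg, "'disparityScale' must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' SensorConfig: 12-bit sensor and noise model
#'
#' @slot bitDepth integer, bits per pixel (default 12).
#' @slot fullScaleDN integer, saturation level; must equal 2^bitDepth - 1.
#' @slot exposureGain numeric, digital numbers per unit band radiance;
#'   \code{NA} requests auto-exposure (white reference placed at 80% of full
#'   scale).
#' @slot shotNoise logical, Poisson shot noise on the expected DN.
#' @slot readNoiseSigma numeric, Gaussian read noise sigma in DN.
#' @slot seed integer RNG seed for the capture.
#' @exportClass SensorConfig
setClass("SensorConfig",
    representation(bitDepth = "integer", fullScaleDN = "integer",
                   exposureGain = "numeric", shotNoise = "logical",
                   readNoiseSigma = "numeric", seed = "integer"))

setValidity("SensorConfig", function(object) {
    msg <- character()
    if (object@fullScaleDN != 2L^object@bitDepth - 1L)
        msg <- c(msg, "fullScaleDN must equal 2^bitDepth - 1")
    if (object@readNoiseSigma < 0)
        msg <- c(msg, "readNoiseSigma must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Illuminant: relative spectral power distribution of the light source
#'
#' @slot wavelengths wavelength grid (nm).
#' @slot spd non-negative relative spectral power on the grid.
#' @slot rippleAmplitude fraction in [0, 1): relative amplitude of the narrow
#'   emission-peak structure characteristic of xenon sources above ~700 nm.
#' @slot rippleBand length-2 numeric (nm): window containing the ripple.
#' @exportClass Illuminant
setClass("Illuminant",
    representation(wavelengths = "numeric", spd = "numeric",
                   rippleAmplitude = "numeric", rippleBand = "numeric"))

setValidity("Illuminant", function(object) {
    msg <- character()
    if (length(object@spd) != length(object@wavelengths))
        msg <- c(msg, "spd length must match the wavelength grid")
    if (any(object@spd < 0))
        msg <- c(msg, "spd must be non-negative")
    if (length(object@rippleBand) != 2L)
        msg <- c(msg, "rippleBand must have two elements")
    if (length(msg)) msg else TRUE
})

#' ReflectanceScene: ground-truth spatial--spectral phantom
#'
#' A synthetic scene with known per-pixel diffuse reflectance spectra, a depth
#' map and an integer ground-truth label mask, standing in for physical
#' imaging targets (colour-checker boards, tissue phantoms).
#'
#' @slot cube numeric array H x W x L of reflectance fractions in [0, 1].
#' @slot wavelengths length-L wavelength grid (nm).
#' @slot depthMap H x W matrix of working distances (cm), strictly positive.
#' @slot truthMask H x W integer matrix of labels (0 = background/unlabelled).
#' @slot palette numeric matrix (labels x L) of the pure per-label spectra;
#'   rownames are the label integers.
#' @slot legend named character vector mapping label to structure name.
#' @seealso [renderCheckerScene()], [renderTissueScene()]
#' @exportClass ReflectanceScene
setClass("ReflectanceScene",
    representation(cube = "array", wavelengths = "numeric",
                   depthMap = "matrix", truthMask = "matrix",
                   palette = "matrix", legend = "character"))

setValidity("ReflectanceScene", function(object) {
    msg <- character()
    d <- dim(object@cube)
    if (length(d) != 3L)
        msg <- c(msg, "cube must be a 3-D array")
    else {
        if (d[3L] != length(object@wavelengths))
            msg <- c(msg, "cube band count must match the wavelength grid")
        if (!all(dim(object@depthMap) == d[1:2]))
            msg <- c(msg, "depthMap dimensions must match the cube")
        if (!all(dim(object@truthMask) == d[1:2]))
            msg <- c(msg, "truthMask dimensions must match the cube")
    }
    if (any(object@cube < 0) || any(object@cube > 1))
        msg <- c(msg, "reflectance values must lie in [0, 1]")
    if (any(object@depthMap <= 0))
        msg <- c(msg, "depths must be strictly positive")
    labs <- setdiff(sort(unique(as.vector(object@truthMask))), 0L)
    if (length(labs) && !all(as.character(labs) %in% rownames(object@palette)))
        msg <- c(msg, "every nonzero truth label needs a palette entry")
    if (length(msg)) msg else TRUE
})

#' CaptureSet: raw simulated lenslet acquisition
#'
#' Sample, white-reference and dark-reference lenslet stacks of 12-bit digital
#' numbers, plus the camera configuration and the parallax actually applied,
#' as produced by [simulateCapture()].
#'
#' @slot sample,white,dark integer arrays H x W x lenslets of digital numbers
#'   in [0, fullScaleDN].
#' @slot bank the [FilterBank-class] used.
#' @slot geometry the [LensletGeometry-class] used.
#' @slot sensor the [SensorConfig-class] used (with the resolved gain).
#' @slot depth scene working distance (cm) assumed planar.
#' @slot whiteReflectance reflectance of the white reference tile.
#' @slot disparity lenslets x 2 matrix of (dy, dx) pixel shifts applied.
#' @slot provenance list of run metadata.
#' @exportClass CaptureSet
setClass("CaptureSet",
    representation(sample = "array", white = "array", dark = "array",
                   bank = "FilterBank", geometry = "LensletGeometry",
                   sensor = "SensorConfig", depth = "numeric",
                   whiteReflectance = "numeric", disparity = "matrix",
                   provenance = "list"))

setValidity("CaptureSet", function(object) {
    msg <- character()
    d <- dim(object@sample)
    if (!all(dim(object@white) == d) || !all(dim(object@dark) == d))
        msg <- c(msg, "sample/white/dark stacks must share one shape")
    full <- object@sensor@fullScaleDN
    for (nm in c("sample", "white", "dark")) {
        v <- slot(object, nm)
        if (any(v < 0) || any(v > full)) {
            msg <- c(msg, sprintf("%s DN outside [0, %d]", nm, full))
            break
        }
    }
    if (length(d) == 3L && d[3L] != length(object@bank@centers))
        msg <- c(msg, "stack depth must equal the number of lenslets")
    if (length(msg)) msg else TRUE
})

## Reference-corrected lenslet stack: values are reflectance-normalised
## fractions, typically in [0, ~1.2] (super-unity allowed where the sample
## outshines the reference).
#' @exportClass CorrectedStack
setClass("CorrectedStack",
    representation(values = "array", valid = "array",
                   geometry = "LensletGeometry", disparity = "matrix",
                   provenance = "list"))

setValidity("CorrectedStack", function(object) {
    if (!all(is.finite(object@values))) "corrected values must be finite"
    else TRUE
})

## Lenslet stack resampled onto the reference lenslet's pixel frame.
#' @exportClass AlignedStack
setClass("AlignedStack",
    representation(values = "array", residualDisparity = "matrix",
                   provenance = "list"))

#' SystemMatrix: lenslet-to-band forward operator
#'
#' Row i holds filter i's transmission sampled on the output band grid and
#' normalised so a flat unit reflectance maps to measurement 1 in every
#' lenslet; spectral inversion solves this underdetermined system (66 rows,
#' 155 bands by default) with a smoothness prior.
#'
#' @slot entries lenslets x bands non-negative matrix.
#' @slot outputGrid output wavelength grid (nm).
#' @exportClass SystemMatrix
setClass("SystemMatrix",
    representation(entries = "matrix", outputGrid = "numeric"))

setValidity("SystemMatrix", function(object) {
    msg <- character()
    if (ncol(object@entries) != length(object@outputGrid))
        msg <- c(msg, "entry columns must match the output grid")
    if (any(object@entries < 0))
        msg <- c(msg, "entries must be non-negative")
    if (any(rowSums(object@entries) <= 0))
        msg <- c(msg, "every row must have positive sum")
    if (any(colSums(object@entries) <= 0))
        msg <- c(msg, "every output band must receive filter support")
    if (length(msg)) msg else TRUE
})

#' Hypercube: reconstructed reflectance cube
#'
#' H x W spatial pixels by B spectral bands of reflectance fractions, with an
#' explicit wavelength vector (default 155 bands spanning 350--1000 nm).
#' Values are clipped to [0, 1.5]; super-unity reflectance is kept visible for
#' specular diagnostics and clip events are counted in \code{provenance}.
#'
#' @slot values numeric array H x W x B.
#' @slot wavelengths length-B wavelength grid (nm).
#' @slot provenance list: configuration, seed, clip counts, residual
#'   disparities and stage log of the run that produced the cube.
#' @seealso [reconstruct()], [readENVI()], [writeENVI()]
#' @exportClass Hypercube
setClass("Hypercube",
    representation(values = "array", wavelengths = "numeric",
                   provenance = "list"))

setValidity("Hypercube", function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(d) != 3L || d[3L] != length(object@wavelengths))
        msg <- c(msg, "band count must equal the wavelength vector length")
    if (any(object@values < 0 - 1e-12) || any(object@values > 1.5 + 1e-12))
        msg <- c(msg, "values must be clipped to [0, 1.5]")
    if (length(msg)) msg else TRUE
})

#' LabelMask: integer annotation mask
#'
#' @slot labels H x W integer matrix; 0 marks unannotated pixels, positive
#'   integers annotated structures.
#' @slot legend named character vector mapping label to structure name.
#' @exportClass LabelMask
setClass("LabelMask",
    representation(labels = "matrix", legend = "character"))

setValidity("LabelMask", function(object) {
    if (any(object@labels < 0)) "labels must be non-negative" else TRUE
})

#' RoiSpectraTable: per-structure mean spectra
#'
#' One row per label present in the mask: pixel counts (total and valid after
#' saturation rejection), the mean spectrum and the population standard
#' deviation spectrum, optionally L1-normalised so each mean sums to 1.
#'
#' @slot stats data.frame with columns label, name, nTotal, nValid.
#' @slot mean,sd numeric matrices (labels x bands).
#' @slot wavelengths band grid (nm).
#' @slot normalized logical: TRUE after [l1Normalize()].
#' @seealso [extractRoiSpectra()]
#' @exportClass RoiSpectraTable
setClass("RoiSpectraTable",
    representation(stats = "data.frame", mean = "matrix", sd = "matrix",
                   wavelengths = "numeric", normalized = "logical"))

setValidity("RoiSpectraTable", function(object) {
    msg <- character()
    if (any(object@stats$nValid > object@stats$nTotal))
        msg <- c(msg, "nValid cannot exceed nTotal")
    if (ncol(object@mean) != length(object@wavelengths) ||
        ncol(object@sd) != length(object@wavelengths))
        msg <- c(msg, "spectra length must match the wavelength grid")
    if (length(msg)) msg else TRUE
})

#' DeltaEReport: CIEDE2000 validation verdicts
#'
#' Per-target CIEDE2000 colour differences with the standard verdict bands:
#' below 2 differences are imperceptible to the eye, below 6 acceptable in
#' most commercial colour reproduction, otherwise unacceptable.
#'
#' @slot table data.frame with columns label, name, deltaE, verdict.
#' @slot summary list with elements maxDeltaE and meanDeltaE.
#' @seealso [validateAgainstReference()]
#' @exportClass DeltaEReport
setClass("DeltaEReport",
    representation(table = "data.frame", summary = "list"))

setValidity("DeltaEReport", function(object) {
    de <- object@table$deltaE
    v <- object@table$verdict
    ok <- is.na(de) |
        (de < 2 & v == "imperceptible") |
        (de >= 2 & de < 6 & v == "acceptable") |
        (de >= 6 & v == "unacceptable")
    if (!all(ok)) "verdicts inconsistent with the <2 / <6 bands" else TRUE
})
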