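#' Wavelength grid of an object
#'
#' @param x a package object carrying a spectral axis.
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Hypercube", function(x) x@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "ReflectanceScene", function(x) x@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "FilterBank", function(x) x@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Illuminant", function(x) x@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SystemMatrix", function(x) x@outputGrid)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "RoiSpectraTable", function(x) x@wavelengths)

#' Number of spectral bands
#'
#' @param x a [Hypercube-class] or [ReflectanceScene-class].
#' @return integer band count.
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname nBands
#' @export
setMethod("nBands", "Hypercube", function(x) dim(x@values)[3L])
#' @rdname nBands
#' @export
setMethod("nBands", "ReflectanceScene", function(x) dim(x@cube)[3L])

#' Raw array values of a container
#'
#' @param x a package container object.
#' @return the underlying numeric/integer array.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "Hypercube", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "ReflectanceScene", function(x) x@cube)
#' @rdname values
#' @export
setMethod("values", "CorrectedStack", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "AlignedStack", function(x) x@values)

#' Provenance record of a derived object
#'
#' @param x a [Hypercube-class] or [CaptureSet-class].
#' @return list of configuration, seeds and stage records.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "Hypercube", function(x) x@provenance)
#' @rdname provenance
#' @export
setMethod("provenance", "CaptureSet", function(x) x@provenance)

#' Ground-truth label mask of a scene
#'
#' @param x a [ReflectanceScene-class].
#' @return a [LabelMask-class].
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))

#' @rdname truthMask
#' @export
setMethod("truthMask", "ReflectanceScene", function(x)
    new("LabelMask", labels = x@truthMask, legend = x@legend))

#' Pure per-label spectra of a scene
#'
#' @param x a [ReflectanceScene-class].
#' @return labels x bands reflectance matrix with label rownames.
#' @export
setGeneric("scenePalette", function(x) standardGeneric("scenePalette"))

#' @rdname scenePalette
#' @export
setMethod("scenePalette", "ReflectanceScene", function(x) x@palette)

#' Per-label summary of an ROI spectra table
#'
#' @param x a [RoiSpectraTable-class].
#' @return data.frame with label, name, nTotal, nValid.
#' @export
setGeneric("roiStats", function(x) standardGeneric("roiStats"))

#' @rdname roiStats
#' @export
setMethod("roiStats", "RoiSpectraTable", function(x) x@stats)

#' Mean / standard-deviation spectra of an ROI table
#'
#' @param x a [RoiSpectraTable-class].
#' @return labels x bands matrix.
#' @export
setGeneric("roiMeans", function(x) standardGeneric("roiMeans"))

#' @rdname roiMeans
#' @export
setMethod("roiMeans", "RoiSpectraTable", function(x) x@mean)

#' @rdname roiMeans
#' @export
setGeneric("roiSds", function(x) standardGeneric("roiSds"))

#' @rdname roiMeans
#' @export
setMethod("roiSds", "RoiSpectraTable", function(x) x@sd)

#' Verdict table of a CIEDE2000 report
#'
#' @param x a [DeltaEReport-class].
#' @return data.frame with label, name, deltaE, verdict.
#' @export
setGeneric("deltaETable", function(x) standardGeneric("deltaETable"))

#' @rdname deltaETable
#' @export
setMethod("deltaETable", "DeltaEReport", function(x) x@table)

#' @describeIn deltaETable the maximum CIEDE2000 in the report.
#' @export
setGeneric("maxDeltaE", function(x) standardGeneric("maxDeltaE"))

#' @rdname deltaETable
#' @export
setMethod("maxDeltaE", "DeltaEReport", function(x) x@summary$maxDeltaE)

setMethod("show", "FilterBank", function(object) {
    cat(sprintf("FilterBank: %d lenslets, centers %.0f-%.0f nm, FWHM %g nm\n",
        length(object@centers), min(object@centers), max(object@centers),
        object@fwhm))
})

setMethod("show", "ReflectanceScene", function(object) {
    d <- dim(object@cube)
    cat(sprintf("ReflectanceScene: %d x %d px, %d bands (%.0f-%.0f nm), %d labels\n",
        d[1L], d[2L], d[3L], min(object@wavelengths), max(object@wavelengths),
        nrow(object@palette)))
})

setMethod("show", "CaptureSet", function(object) {
    d <- dim(object@sample)
    cat(sprintf(
        "CaptureSet: %d lenslets of %d x %d px, %d-bit DN, depth %.1f cm\n",
        d[3L], d[1L], d[2L], object@sensor@bitDepth, object@depth))
})

setMethod("show", "Hypercube", function(object) {
    d <- dim(object@values)
    cat(sprintf("Hypercube: %d x %d px, %d bands (%.1f-%.1f nm)\n",
        d[1L], d[2L], d[3L], min(object@wavelengths), max(object@wavelengths)))
    nc <- object@provenance$clipCount
    if (!is.null(nc)) cat(sprintf("  clipped values: %d\n", nc))
})

setMethod("show", "RoiSpectraTable", function(object) {
    cat(sprintf("RoiSpectraTable: %d structures, %d bands%s\n",
        nrow(object@stats), length(object@wavelengths),
        if (isTRUE(object@normalized)) " (L1-normalized)" else ""))
    print(object@stats)
})

setMethod("show", "DeltaEReport", function(object) {
    cat(sprintf("DeltaEReport: max dE00 = %.3f, mean = %.3f\n",
        object@summary$maxDeltaE, object@summary$meanDeltaE))
    print(object@table, digits = 4)
})
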