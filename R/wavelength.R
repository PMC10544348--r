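#' Construct a uniform wavelength grid
#'
#' Builds the spectral axis used throughout the package: a strictly
#' increasing, uniformly spaced vector of wavelengths in nanometres.
#'
#' @param start first wavelength (nm).
#' @param stop last wavelength (nm); must exceed \code{start}.
#' @param count number of grid points (>= 2).
#' @return numeric vector of length \code{count} with first element
#'   \code{start} and last element \code{stop}.
#' @examples
#' g <- makeWavelengthGrid(350, 1000, 155)
#' diff(g)[1]  # ~4.2208 nm
#' @export
makeWavelengthGrid <- function(start, stop, count) {
    if (!isScalarNumber(start) || !isScalarNumber(stop) ||
        !isScalarNumber(count))
        stop("'start', 'stop' and 'count' must be single numbers")
    if (count < 2)
        stop("'count' must be at least 2")
    if (stop <= start)
        stop("'stop' must be strictly greater than 'start'")
    if (start < 300 || stop > 1100)
        stop("wavelength grid must lie within [300, 1100] nm")
    seq(start, stop, length.out = as.integer(count))
}

#' Default 155-band grid spanning 350--1000 nm
#'
#' The output spectral axis of the default reconstruction: 155 uniformly
#' spaced bands across the visible and near-infrared range.
#'
#' @return numeric vector of 155 wavelengths (nm).
#' @export
defaultBandGrid <- function() makeWavelengthGrid(350, 1000, 155)

assertWavelengthGrid <- function(wl, what = "wavelengths") {
    if (length(wl) < 2L || any(diff(wl) <= 0))
        stop(sprintf("'%s' must be strictly increasing with >= 2 points", what))
    step <- diff(wl)
    if (max(step) - min(step) > 1e-9)
        stop(sprintf("'%s' must be uniformly spaced", what))
    invisible(wl)
}

gridStep <- function(wl) (wl[length(wl)] - wl[1L]) / (length(wl) - 1L)
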