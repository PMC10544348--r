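## CSV/PNG/YAML I/O: masks, legends, palettes, capture sets, pipeline config.

#' Read / write label masks
#'
#' Masks are stored as plain CSV (one row per image row, integer labels) or
#' PNG. PNG masks are read at 8 or 16 bit (labels recovered from the
#' intensity scaling); PNG writing uses 8 bit and therefore requires at most
#' 255 labels --- CSV has no such limit and round-trips exactly.
#'
#' @param path file path; format chosen by extension (.csv or .png).
#' @param legend optional named character vector (label -> structure name).
#' @return \code{readMask}: a [LabelMask-class].
#' @export
readMask <- function(path, legend = character()) {
    ext <- tolower(tools::file_ext(path))
    labels <- if (ext == "png") {
        img <- png::readPNG(path, info = TRUE)
        depth <- attr(img, "info")$bit.depth
        if (is.null(depth)) depth <- 8L
        if (length(dim(img)) == 3L) img <- img[, , 1L]
        ## readPNG normalises to [0,1]; undo the bit-depth scaling
        m <- round(img * (2^depth - 1))
        attributes(m) <- list(dim = dim(m))
        storage.mode(m) <- "integer"
        m
    } else {
        as.matrix(utils::read.csv(path, header = FALSE))
    }
    labels <- unname(labels)
    storage.mode(labels) <- "integer"
    new("LabelMask", labels = labels, legend = legend)
}

#' @rdname readMask
#' @param mask a [LabelMask-class] or integer matrix.
#' @export
writeMask <- function(mask, path) {
    labels <- if (is(mask, "LabelMask")) mask@labels else mask
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        if (max(labels) > 255)
            stop("PNG mask output supports at most 255 labels; use CSV")
        png::writePNG(labels / 255, target = path)
    } else {
        utils::write.table(labels, path, sep = ",", row.names = FALSE,
                           col.names = FALSE)
    }
    invisible(path)
}

#' Read / write mask legends
#'
#' Two-column CSV (label, name).
#'
#' @param path CSV path.
#' @return \code{readLegend}: named character vector.
#' @export
readLegend <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' @rdname readLegend
#' @param legend named character vector (names = labels).
#' @export
writeLegend <- function(legend, path) {
    utils::write.csv(data.frame(label = names(legend),
                                name = unname(legend)),
                     path, row.names = FALSE)
    invisible(path)
}

#' Read / write reference-spectra palettes
#'
#' Long-format CSV with columns label, wavelength_nm, reflectance --- the
#' interchange format for user-supplied reference tile spectra.
#'
#' @param path CSV path.
#' @return \code{readPaletteCSV}: labels x bands matrix with label rownames
#'   and a "wavelengths" attribute.
#' @export
readPaletteCSV <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "wavelength_nm", "reflectance")
    if (!all(need %in% names(tab)))
        stop("palette CSV needs columns: ", paste(need, collapse = ", "))
    labs <- unique(tab$label)
    wl <- sort(unique(tab$wavelength_nm))
    m <- matrix(NA_real_, length(labs), length(wl),
                dimnames = list(as.character(labs), NULL))
    for (l in labs) {
        sub <- tab[tab$label == l, ]
        sub <- sub[order(sub$wavelength_nm), ]
        m[as.character(l), ] <- sub$reflectance
    }
    attr(m, "wavelengths") <- wl
    m
}

#' @rdname readPaletteCSV
#' @param palette labels x bands matrix with a "wavelengths" attribute.
#' @export
writePaletteCSV <- function(palette, path) {
    wl <- attr(palette, "wavelengths")
    if (is.null(wl)) stop("'palette' must carry a 'wavelengths' attribute")
    labs <- rownames(palette)
    tab <- data.frame(
        label = rep(labs, each = length(wl)),
        wavelength_nm = rep(wl, times = nrow(palette)),
        reflectance = as.vector(t(palette)))
    utils::write.csv(tab, path, row.names = FALSE)
    invisible(path)
}

#' Write / read a capture set on disk
#'
#' One ENVI cube per stack (sample/white/dark; lenslet index as the band
#' axis, 16-bit unsigned DN), a per-lenslet sidecar CSV (filter centers,
#' FWHM, baselines, applied disparity) and a YAML sidecar with the scalar
#' camera configuration.
#'
#' @param capture a [CaptureSet-class].
#' @param dir output directory (created if needed).
#' @return \code{writeCaptureSet}: the directory, invisibly;
#'   \code{readCaptureSet}: a [CaptureSet-class].
#' @export
writeCaptureSet <- function(capture, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    idx <- seq_along(capture@bank@centers)
    for (nm in c("sample", "white", "dark"))
        writeENVI(list(values = slot(capture, nm), wavelengths = idx),
                  file.path(dir, nm), dataType = 12L)
    utils::write.csv(data.frame(
        lenslet = idx,
        center_nm = capture@bank@centers,
        fwhm_nm = capture@bank@fwhm,
        baseline_y_mm = capture@geometry@baselines[, 1L],
        baseline_x_mm = capture@geometry@baselines[, 2L],
        disparity_y_px = capture@disparity[, 1L],
        disparity_x_px = capture@disparity[, 2L]),
        file.path(dir, "lenslets.csv"), row.names = FALSE)
    yaml::write_yaml(list(
        gridRows = capture@geometry@gridRows,
        gridCols = capture@geometry@gridCols,
        disparityScale = capture@geometry@disparityScale,
        bitDepth = capture@sensor@bitDepth,
        exposureGain = capture@sensor@exposureGain,
        shotNoise = capture@sensor@shotNoise,
        readNoiseSigma = capture@sensor@readNoiseSigma,
        seed = capture@sensor@seed,
        depth = capture@depth,
        whiteReflectance = capture@whiteReflectance,
        bankRange = range(capture@bank@centers),
        bankGrid = list(start = min(capture@bank@wavelengths),
                        stop = max(capture@bank@wavelengths),
                        count = length(capture@bank@wavelengths))),
        file.path(dir, "capture.yaml"))
    invisible(dir)
}

#' @rdname writeCaptureSet
#' @export
readCaptureSet <- function(dir) {
    meta <- yaml::read_yaml(file.path(dir, "capture.yaml"))
    lens <- utils::read.csv(file.path(dir, "lenslets.csv"))
    stacks <- lapply(c("sample", "white", "dark"), function(nm)
        readENVI(file.path(dir, paste0(nm, ".hdr")), raw = TRUE)$values)
    grid <- makeWavelengthGrid(meta$bankGrid$start, meta$bankGrid$stop,
                               meta$bankGrid$count)
    bank <- makeFilterBank(nrow(lens), range = range(lens$center_nm),
                           fwhm = lens$fwhm_nm[1L], wl = grid)
    geometry <- new("LensletGeometry",
                    gridRows = as.integer(meta$gridRows),
                    gridCols = as.integer(meta$gridCols),
                    baselines = cbind(lens$baseline_y_mm, lens$baseline_x_mm),
                    disparityScale = meta$disparityScale)
    sensor <- makeSensorConfig(bitDepth = meta$bitDepth,
                               exposureGain = meta$exposureGain,
                               shotNoise = meta$shotNoise,
                               readNoiseSigma = meta$readNoiseSigma,
                               seed = meta$seed)
    toInt <- function(a) { storage.mode(a) <- "integer"; a }
    new("CaptureSet", sample = toInt(stacks[[1L]]),
        white = toInt(stacks[[2L]]), dark = toInt(stacks[[3L]]),
        bank = bank, geometry = geometry, sensor = sensor,
        depth = meta$depth, whiteReflectance = meta$whiteReflectance,
        disparity = cbind(lens$disparity_y_px, lens$disparity_x_px),
        provenance = list(source = dir))
}

#' Default pipeline configuration
#'
#' The full set of tunable parameters of the simulate -> reconstruct ->
#' validate chain as one nested, YAML-serialisable list: scene layout,
#' illuminant ripple, filter bank, lenslet geometry, sensor noise,
#' reconstruction regularisation and colorimetry options.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
    list(
        scene = list(rows = 4L, cols = 6L, tilePx = 24L, nChromatic = 18L,
                     nNeutral = 6L, paletteSeed = 7L, depth = 25),
        illuminant = list(rippleAmplitude = 0.3, seed = 1L),
        bank = list(nLenslets = 66L, start = 350, stop = 1000, fwhm = 10),
        geometry = list(gridRows = 6L, gridCols = 11L, pitch = 1,
                        maxDisparityPx = 3, refDepth = 25),
        sensor = list(bitDepth = 12L, shotNoise = TRUE, readNoiseSigma = 2,
                      seed = 0L),
        reconstruction = list(epsilon = 1, ridge = 1e-3, smoothOrder = 2L,
                              nonneg = FALSE, register = "known",
                              bands = 155L),
        colorimetry = list(centerFraction = 0.5, saturationFraction = 1.0),
        whiteReflectance = 0.95)
}

#' Read / write pipeline configuration
#'
#' YAML round trip of the [defaultConfig()] structure; values present in the
#' file override defaults, so partial configs are valid.
#'
#' @param path YAML file path.
#' @return \code{readConfig}: nested named list.
#' @export
readConfig <- function(path) {
    utils::modifyList(defaultConfig(), yaml::read_yaml(path))
}

#' @rdname readConfig
#' @param config nested list as from [defaultConfig()].
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Write an ROI spectra table as CSV
#'
#' Long format: label, name, nTotal, nValid, wavelength_nm, mean, sd.
#'
#' @param table a [RoiSpectraTable-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeRoiCSV <- function(table, path) {
    st <- table@stats
    B <- length(table@wavelengths)
    tab <- data.frame(
        label = rep(st$label, each = B),
        name = rep(st$name, each = B),
        nTotal = rep(st$nTotal, each = B),
        nValid = rep(st$nValid, each = B),
        wavelength_nm = rep(table@wavelengths, times = nrow(st)),
        mean = as.vector(t(table@mean)),
        sd = as.vector(t(table@sd)))
    utils::write.csv(tab, path, row.names = FALSE)
    invisible(path)
}

#' Write a CIEDE2000 report as CSV
#'
#' @param report a [DeltaEReport-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeDeltaECSV <- function(report, path) {
    utils::write.csv(report@table, path, row.names = FALSE)
    invisible(path)
}
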