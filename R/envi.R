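## ENVI header + flat-binary cube I/O, the de facto HSI container.

.enviTypes <- data.frame(
    code = c(1L, 2L, 3L, 4L, 5L, 12L),
    what = c("integer", "integer", "integer", "double", "double", "integer"),
    size = c(1L, 2L, 4L, 4L, 8L, 2L),
    signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))

#' Read an ENVI hypercube
#'
#' Parses a plain-text ENVI header (samples/lines/bands, data type,
#' interleave, byte order, optional wavelength list) and reads the raw cube.
#' BSQ, BIL and BIP interleaves are all accepted. A missing wavelength list
#' produces an index-valued grid with a warning; a size mismatch between
#' header and data file is an error naming both byte counts.
#'
#' @param headerPath path to the .hdr file.
#' @param dataPath path to the binary cube; default: \code{headerPath}
#'   without its .hdr extension, or with .raw/.img appended.
#' @param raw return a bare \code{list(values, wavelengths)} without the
#'   reflectance clipping contract --- used for lenslet DN stacks, whose
#'   "band" axis is the lenslet index.
#' @return a [Hypercube-class], or a list when \code{raw = TRUE}.
#' @export
readENVI <- function(headerPath, dataPath = NULL, raw = FALSE) {
    if (!file.exists(headerPath)) stop("header not found: ", headerPath)
    hdr <- parseEnviHeader(headerPath)
    if (is.null(dataPath)) {
        base <- sub("\\.hdr$", "", headerPath)
        cand <- c(base, paste0(base, ".raw"), paste0(base, ".img"))
        dataPath <- cand[file.exists(cand)][1L]
        if (is.na(dataPath)) stop("no data file found next to ", headerPath)
    }
    S <- hdr$samples; L <- hdr$lines; B <- hdr$bands
    ti <- .enviTypes[.enviTypes$code == hdr$`data type`, ]
    if (nrow(ti) != 1L) stop("unsupported ENVI data type: ", hdr$`data type`)
    offset <- if (is.null(hdr$`header offset`)) 0L else hdr$`header offset`
    expected <- offset + S * L * B * ti$size
    actual <- file.info(dataPath)$size
    if (actual != expected)
        stop(sprintf("ENVI data size mismatch: expected %d bytes, found %d",
                     expected, actual))
    endian <- if (!is.null(hdr$`byte order`) && hdr$`byte order` == 1)
        "big" else "little"
    con <- file(dataPath, "rb")
    on.exit(close(con))
    if (offset > 0) readBin(con, "raw", offset)
    v <- readBin(con, ti$what, n = S * L * B, size = ti$size,
                 signed = ti$signed, endian = endian)
    interleave <- tolower(if (is.null(hdr$interleave)) "bsq" else hdr$interleave)
    cube <- switch(interleave,
        bsq = aperm(array(v, c(S, L, B)), c(2, 1, 3)),
        bil = aperm(array(v, c(S, B, L)), c(3, 1, 2)),
        bip = aperm(array(v, c(B, S, L)), c(3, 2, 1)),
        stop("unsupported interleave: ", interleave))
    wl <- hdr$wavelength
    if (is.null(wl)) {
        warning("no wavelength list in header; using band indices")
        wl <- seq_len(B)
    }
    if (raw) return(list(values = cube, wavelengths = wl))
    new("Hypercube", values = pmin(pmax(cube, 0), 1.5), wavelengths = wl,
        provenance = list(source = dataPath, header = headerPath,
                          rawRange = range(cube)))
}

#' Write a hypercube as ENVI
#'
#' Writes \code{<path>.hdr} (with the wavelength list in nm) and
#' \code{<path>.raw}. Defaults: BSQ interleave, 32-bit float, little endian.
#'
#' @param cube a [Hypercube-class], or a \code{list(values, wavelengths)}
#'   for raw lenslet stacks (band axis = lenslet index).
#' @param path output path without extension (a trailing .hdr is stripped).
#' @param interleave "bsq", "bil" or "bip".
#' @param dataType ENVI data type code: 4 (float32, default), 5 (float64),
#'   12 (uint16), 2/3 (int16/32), 1 (byte).
#' @return invisibly, c(header = , data = ) paths.
#' @export
writeENVI <- function(cube, path, interleave = "bsq", dataType = 4L) {
    if (is(cube, "Hypercube")) {
        arr <- cube@values; wl <- cube@wavelengths
    } else {
        arr <- cube$values; wl <- cube$wavelengths
    }
    d <- dim(arr)
    if (d[3L] < 1L) stop("cannot write a cube with zero bands")
    ti <- .enviTypes[.enviTypes$code == dataType, ]
    if (nrow(ti) != 1L) stop("unsupported ENVI data type: ", dataType)
    base <- sub("\\.hdr$", "", path)
    headerPath <- paste0(base, ".hdr")
    dataPath <- paste0(base, ".raw")
    interleave <- tolower(interleave)
    perm <- switch(interleave,
        bsq = c(2, 1, 3), bil = c(2, 3, 1), bip = c(3, 2, 1),
        stop("unsupported interleave: ", interleave))
    v <- as.vector(aperm(arr, perm))
    if (ti$what == "integer") v <- as.integer(round(v))
    hdr <- c("ENVI",
        "description = { lightfieldHSI hypercube }",
        sprintf("samples = %d", d[2L]),
        sprintf("lines = %d", d[1L]),
        sprintf("bands = %d", d[3L]),
        "header offset = 0",
        "file type = ENVI Standard",
        sprintf("data type = %d", dataType),
        sprintf("interleave = %s", interleave),
        "byte order = 0",
        "wavelength units = Nanometers",
        paste0("wavelength = { ",
               paste(sprintf("%.17g", wl), collapse = " , "), " }"))
    writeLines(hdr, headerPath)
    con <- file(dataPath, "wb")
    on.exit(close(con))
    if (ti$what == "integer" && ti$size %in% c(1L, 2L))
        writeBin(v, con, size = ti$size, endian = "little", useBytes = TRUE)
    else
        writeBin(v, con, size = ti$size, endian = "little")
    invisible(c(header = headerPath, data = dataPath))
}

parseEnviHeader <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^ENVI", lines[1L]))
        stop("not an ENVI header: ", path)
    txt <- paste(lines[-1L], collapse = "\n")
    ## join { ... } blocks onto single logical entries
    out <- list()
    entries <- strsplit(txt, "\n")[[1L]]
    i <- 1L
    while (i <= length(entries)) {
        line <- entries[i]
        if (grepl("\\{", line) && !grepl("\\}", line)) {
            while (i < length(entries) && !grepl("\\}", entries[i])) {
                i <- i + 1L
                line <- paste(line, entries[i])
            }
        }
        i <- i + 1L
        if (!grepl("=", line)) next
        key <- tolower(trimws(sub("=.*", "", line)))
        val <- trimws(sub("^[^=]*=", "", line))
        if (grepl("^\\{", val)) {
            val <- gsub("[{}]", "", val)
            nums <- suppressWarnings(as.numeric(strsplit(val, ",")[[1L]]))
            out[[key]] <- if (all(is.na(nums))) trimws(val) else nums
        } else {
            num <- suppressWarnings(as.numeric(val))
            out[[key]] <- if (is.na(num)) val else num
        }
    }
    out
}
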