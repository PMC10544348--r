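## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic package operations route through this so identical
## (parameters, seed) pairs are bit-reproducible without clobbering the
## user's random stream.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single non-missing number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

## Shift image content by (dy, dx) pixels: output(r, c) = img(r - dy, c - dx),
## bilinear interpolation, replicate-edge padding. Separable weights keep this
## a handful of vectorised matrix ops.
shiftImage <- function(img, dy, dx) {
    stopifnot(is.matrix(img))
    if (dy == 0 && dx == 0) return(img)
    H <- nrow(img); W <- ncol(img)
    r <- seq_len(H) - dy
    cc <- seq_len(W) - dx
    r0 <- floor(r); fr <- r - r0
    c0 <- floor(cc); fc <- cc - c0
    cl <- function(i, n) pmin(pmax(i, 1), n)
    ra <- cl(r0, H); rb <- cl(r0 + 1, H)
    ca <- cl(c0, W); cb <- cl(c0 + 1, W)
    img[ra, ca, drop = FALSE] * ((1 - fr) %o% (1 - fc)) +
        img[rb, ca, drop = FALSE] * (fr %o% (1 - fc)) +
        img[ra, cb, drop = FALSE] * ((1 - fr) %o% fc) +
        img[rb, cb, drop = FALSE] * (fr %o% fc)
}

## Flatten an H x W x K array to (H*W) x K, and back.
flattenCube <- function(a) {
    d <- dim(a)
    dim(a) <- c(d[1L] * d[2L], d[3L])
    a
}

unflattenCube <- function(m, H, W) {
    dim(m) <- c(H, W, ncol(m))
    m
}

## Linear interpolation of a spectrum onto a new grid; zero outside support.
interpSpectrum <- function(wl, values, newWl) {
    out <- stats::approx(wl, values, xout = newWl, rule = 1)$y
    out[is.na(out)] <- 0
    out
}

## Sparse-free linear-interpolation operator: rows index `newWl`, columns
## index `wl`; P %*% v == approx(wl, v, newWl) with zeros outside support.
interpMatrix <- function(wl, newWl) {
    n <- length(wl)
    P <- matrix(0, length(newWl), n)
    for (j in seq_along(newWl)) {
        x <- newWl[j]
        if (x < wl[1L] || x > wl[n]) next
        i <- findInterval(x, wl)
        if (i == n) { P[j, n] <- 1; next }
        t <- (x - wl[i]) / (wl[i + 1L] - wl[i])
        P[j, i] <- 1 - t
        P[j, i + 1L] <- t
    }
    P
}

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
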