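## Shared fixtures and independent oracles, built in code at test time.

grid155 <- defaultBandGrid()

## single-tile scene with one spectrum everywhere
flatScene <- function(spec, tilePx = 8, wl = grid155, depth = 25) {
    pal <- matrix(spec, 1)
    rownames(pal) <- "1"
    attr(pal, "wavelengths") <- wl
    renderCheckerScene(pal, 1, 1, tilePx = tilePx, depth = depth)
}

noiselessSensor <- function(seed = 1, gain = NA_real_)
    makeSensorConfig(exposureGain = gain, shotNoise = FALSE,
                     readNoiseSigma = 0, seed = seed)

flatIlluminant <- function(wl = grid155)
    new("Illuminant", wavelengths = wl, spd = rep(1, length(wl)),
        rippleAmplitude = 0, rippleBand = c(750, 900))

## ---------------------------------------------------------------------------
## Independent CIEDE2000 oracle: scalar, written straight from the published
## formula steps, kept deliberately separate from the package implementation.
oracleCiede2000 <- function(ref, sam) {
    L1 <- ref[1]; a1 <- ref[2]; b1 <- ref[3]
    L2 <- sam[1]; a2 <- sam[2]; b2 <- sam[3]
    rad <- pi / 180
    ## step 1: C', h'
    Cab1 <- sqrt(a1^2 + b1^2)
    Cab2 <- sqrt(a2^2 + b2^2)
    CabM <- (Cab1 + Cab2) / 2
    G <- 0.5 * (1 - sqrt(CabM^7 / (CabM^7 + 25^7)))
    ap1 <- (1 + G) * a1
    ap2 <- (1 + G) * a2
    Cp1 <- sqrt(ap1^2 + b1^2)
    Cp2 <- sqrt(ap2^2 + b2^2)
    hp1 <- if (Cp1 == 0) 0 else { h <- atan2(b1, ap1) / rad; if (h < 0) h + 360 else h }
    hp2 <- if (Cp2 == 0) 0 else { h <- atan2(b2, ap2) / rad; if (h < 0) h + 360 else h }
    ## step 2: differences
    dL <- L2 - L1
    dC <- Cp2 - Cp1
    dhp <- 0
    if (Cp1 * Cp2 != 0) {
        dhp <- hp2 - hp1
        if (dhp > 180) dhp <- dhp - 360
        if (dhp < -180) dhp <- dhp + 360
    }
    dH <- 2 * sqrt(Cp1 * Cp2) * sin(dhp * rad / 2)
    ## step 3: averages and weights
    Lm <- (L1 + L2) / 2
    Cm <- (Cp1 + Cp2) / 2
    if (Cp1 * Cp2 == 0) {
        hm <- hp1 + hp2
    } else {
        hm <- (hp1 + hp2) / 2
        if (abs(hp1 - hp2) > 180) {
            hm <- if (hp1 + hp2 < 360) hm + 180 else hm - 180
        }
    }
    Tf <- 1 - 0.17 * cos((hm - 30) * rad) + 0.24 * cos(2 * hm * rad) +
        0.32 * cos((3 * hm + 6) * rad) - 0.20 * cos((4 * hm - 63) * rad)
    dTheta <- 30 * exp(-((hm - 275) / 25)^2)
    Rc <- 2 * sqrt(Cm^7 / (Cm^7 + 25^7))
    Sl <- 1 + 0.015 * (Lm - 50)^2 / sqrt(20 + (Lm - 50)^2)
    Sc <- 1 + 0.045 * Cm
    Sh <- 1 + 0.015 * Cm * Tf
    Rt <- -sin(2 * dTheta * rad) * Rc
    sqrt((dL / Sl)^2 + (dC / Sc)^2 + (dH / Sh)^2 +
         Rt * (dC / Sc) * (dH / Sh))
}

## brute-force per-pixel ROI statistics oracle
oracleRoiStats <- function(arr, mask, valid) {
    labs <- setdiff(sort(unique(as.vector(mask))), 0L)
    B <- dim(arr)[3]
    out <- list()
    for (lab in labs) {
        mu <- numeric(B); s2 <- numeric(B); n <- 0L
        for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
            if (mask[r, cc] == lab && valid[r, cc]) {
                n <- n + 1L
                mu <- mu + arr[r, cc, ]
            }
        }
        if (n > 0) mu <- mu / n
        for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
            if (mask[r, cc] == lab && valid[r, cc])
                s2 <- s2 + (arr[r, cc, ] - mu)^2
        }
        out[[as.character(lab)]] <- list(n = n, mean = mu,
                                         sd = if (n > 0) sqrt(s2 / n) else mu * NA)
    }
    out
}
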