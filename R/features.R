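# Separable Gaussian blur with reflect padding; kernel truncated at
# radius ceiling(4*sigma). sigma = 0 returns the input unchanged.
.gaussianBlur <- function(img, sigma) {
    if (sigma < 0) stop("blurSigma must be >= 0")
    if (sigma == 0) return(img)
    r <- as.integer(ceiling(4 * sigma))
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k <- k / sum(k)
    reflectIdx <- function(n) {
        # indices for reflect padding ("symmetric": edge pixel not repeated-over)
        i <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
        pmin(pmax(i, 1L), n)
    }
    conv1 <- function(m) {  # convolve along rows (dim 1)
        n <- nrow(m)
        pm <- m[reflectIdx(n), , drop = FALSE]
        out <- matrix(0, n, ncol(m))
        for (j in seq_along(k))
            out <- out + k[j] * pm[(seq_len(n)) + (j - 1L), , drop = FALSE]
        out
    }
    t(conv1(t(conv1(img))))
}

#' Spectral fingerprint of one cell
#'
#' Applies a Gaussian blur (sigma `blurSigma`, reflect padding, kernel
#' truncated at 4 sigma) to every full channel image, then averages the
#' blurred intensities over the cell's mask pixels. With `blurSigma = 0` this
#' is the plain masked mean.
#'
#' @param stack a normalized [HyperspectralStack-class].
#' @param mask a [CellMask-class].
#' @param blurSigma Gaussian sigma in pixels (default 1).
#' @return numeric vector of per-channel means, named `mean_ch01`...
#' @export
cellSpectrum <- function(stack, mask, blurSigma = 1) {
    stopifnot(is(stack, "HyperspectralStack"), is(mask, "CellMask"))
    nch <- dim(stack@pixels)[1L]
    idx <- mask@pixels
    out <- vapply(seq_len(nch), function(i) {
        mean(.gaussianBlur(stack@pixels[i, , ], blurSigma)[idx])
    }, numeric(1L))
    names(out) <- sprintf("mean_ch%02d", stack@channels@channel)
    out
}

#' Morphology of a cell mask
#'
#' Area is the pixel count (converted to square micrometres when a pixel
#' size is given). Length `y` and width `x` are the larger and smaller
#' extents of the pixel-centre cloud projected on its two principal axes
#' (max minus min plus one pixel), and eccentricity is `y/x - 1`, so a round
#' cell scores 0. With `axes = "bbox"` the axis-aligned bounding-box extents
#' are used instead.
#'
#' @param mask a [CellMask-class].
#' @param pixelSize micrometres per pixel side, or `NA` to skip the area
#'   conversion.
#' @param axes `"principal"` (default) or `"bbox"`.
#' @return named list: `area_px`, `area_um2`, `eccentricity`.
#' @export
cellMorphology <- function(mask, pixelSize = NA_real_,
                           axes = c("principal", "bbox")) {
    stopifnot(is(mask, "CellMask"))
    axes <- match.arg(axes)
    px <- mask@pixels
    areaPx <- nrow(px)
    if (axes == "bbox" || areaPx == 1L) {
        ext <- c(mask@bbox[3L] - mask@bbox[1L] + 1, mask@bbox[4L] - mask@bbox[2L] + 1)
    } else {
        xy <- sweep(px, 2L, colMeans(px))
        ev <- eigen(stats::cov(xy), symmetric = TRUE)$vectors
        proj <- xy %*% ev
        ext <- apply(proj, 2L, function(v) max(v) - min(v)) + 1
    }
    y <- max(ext); x <- min(ext)
    list(area_px = areaPx,
         area_um2 = if (is.na(pixelSize)) NA_real_ else areaPx * pixelSize^2,
         eccentricity = y / x - 1)
}

#' Ratio of two channels of a spectral fingerprint
#'
#' Default pair (4, 2): channel 4 sits near the free NAD(P)H spectral peak
#' and channel 2 in the blue-shifted band of the protein-bound form, so the
#' ratio tracks the bound/free balance.
#'
#' @param spectrum named per-channel mean vector as from [cellSpectrum()].
#' @param a,b channel ids of numerator and denominator.
#' @return `spectrum[a] / spectrum[b]`, or `NA` with a warning when the
#'   denominator is zero.
#' @export
intensityRatio <- function(spectrum, a = 4L, b = 2L) {
    nm <- sprintf("mean_ch%02d", c(a, b))
    if (!all(nm %in% names(spectrum))) stop("channel not present in spectrum")
    den <- unname(spectrum[nm[2L]])
    if (den <= 0) {
        warning(sprintf("zero denominator intensity in channel %d; ratio undefined", b))
        return(NA_real_)
    }
    unname(spectrum[nm[1L]]) / den
}

#' Classify a cell as ringed or unringed
#'
#' Computes the log2 fold change between the mean intensity of the border
#' annulus and the adjacent inner annulus (each `thickness` pixels, default
#' 10) in one channel (default 13). Cells with a log2 fold change strictly
#' greater than `threshold` (default 0.4) are called "ringed", others
#' "unringed". Cells whose inner annulus is empty, or where either annulus
#' mean is zero, are "undefined" and never silently dropped.
#'
#' @param stack a normalized [HyperspectralStack-class].
#' @param mask a [CellMask-class].
#' @param channel channel id used for the ring contrast.
#' @param thickness annulus thickness in pixels.
#' @param threshold log2 fold-change call threshold (equality is unringed).
#' @param metric distance metric passed to [cellAnnuli()].
#' @return list with `ring_log2fc` and `ring_call` (factor level `ringed`,
#'   `unringed` or `undefined`).
#' @export
classifyRing <- function(stack, mask, channel = 13L, thickness = 10,
                         threshold = 0.4, metric = "euclidean") {
    img <- channelImage(stack, channel)
    ann <- cellAnnuli(mask, thickness = thickness, metric = metric)
    lev <- c("ringed", "unringed", "undefined")
    if (innerEmpty(ann))
        return(list(ring_log2fc = NA_real_,
                    ring_call = factor("undefined", levels = lev)))
    mb <- mean(img[ann@borderPixels])
    mi <- mean(img[ann@innerPixels])
    if (mb <= 0 || mi <= 0)
        return(list(ring_log2fc = NA_real_,
                    ring_call = factor("undefined", levels = lev)))
    lfc <- log2(mb / mi)
    list(ring_log2fc = lfc,
         ring_call = factor(if (lfc > threshold) "ringed" else "unringed",
                            levels = lev))
}

#' Per-cell feature table for a field of view
#'
#' Combines spectral fingerprints, morphology, the default channel ratio and
#' the ring classification into one data frame with a row per cell, in the
#' column order `mean_ch01..mean_chNN, area_px, area_um2, eccentricity,
#' ratio_ch04_ch02, ring_log2fc, ring_call`.
#'
#' @param stack a normalized [HyperspectralStack-class].
#' @param labelImage integer label mask, or a list of [CellMask-class].
#' @param blurSigma Gaussian blur sigma for the fingerprints.
#' @param ringChannel,ringThickness,ringThreshold ring-classifier settings.
#' @param ratioPair channel ids (numerator, denominator) for the reported
#'   intensity ratio.
#' @return data.frame keyed by `cell_id`.
#' @export
cellFeatureTable <- function(stack, labelImage, blurSigma = 1,
                             ringChannel = 13L, ringThickness = 10,
                             ringThreshold = 0.4, ratioPair = c(4L, 2L)) {
    stopifnot(is(stack, "HyperspectralStack"))
    masks <- if (is.list(labelImage)) labelImage else extractCells(labelImage)
    nch <- dim(stack@pixels)[1L]
    # blur each channel once, then take masked means per cell
    blurred <- lapply(seq_len(nch), function(i)
        .gaussianBlur(stack@pixels[i, , ], blurSigma))
    rows <- lapply(masks, function(m) {
        spec <- vapply(blurred, function(b) mean(b[m@pixels]), numeric(1L))
        names(spec) <- sprintf("mean_ch%02d", stack@channels@channel)
        mor <- cellMorphology(m, pixelSize = stack@pixelSize)
        ring <- classifyRing(stack, m, channel = ringChannel,
                             thickness = ringThickness, threshold = ringThreshold)
        cbind(data.frame(cell_id = m@cellId), as.data.frame(t(spec)),
              data.frame(area_px = mor$area_px, area_um2 = mor$area_um2,
                         eccentricity = mor$eccentricity,
                         ratio = intensityRatio(spec, ratioPair[1L], ratioPair[2L]),
                         ring_log2fc = ring$ring_log2fc,
                         ring_call = ring$ring_call))
    })
    out <- do.call(rbind, rows)
    names(out)[names(out) == "ratio"] <-
        sprintf("ratio_ch%02d_ch%02d", ratioPair[1L], ratioPair[2L])
    rownames(out) <- NULL
    out
}

#' Integer-truncated percentage
#'
#' Reporting convention for cell-count percentages: `floor(100 * num / den)`,
#' so 114 of 174 prints as 65.
#'
#' @param num,den counts.
#' @return integer percentage.
#' @export
pctFloor <- function(num, den) {
    stopifnot(den > 0)
    as.integer(floor(100 * num / den))
}
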