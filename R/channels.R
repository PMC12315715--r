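#' Construct a ChannelTable
#'
#' @param channel integer channel ids, contiguous 1..N.
#' @param lambdaEx,lambdaEm excitation / emission wavelengths (nm).
#' @return a [ChannelTable-class].
#' @examples
#' channelTable(1:2, c(340, 370), c(450, 414))
#' @export
channelTable <- function(channel, lambdaEx, lambdaEm) {
    new("ChannelTable", channel = as.integer(channel),
        lambdaEx = as.numeric(lambdaEx), lambdaEm = as.numeric(lambdaEm))
}

#' Default 15-channel excitation/emission layout
#'
#' A representative layout of a 15-band autofluorescence imaging system.
#' Channels 3 (370/414 nm), 4 (343/451 nm) and 13 (431/594 nm) are the
#' instrument coordinates used by the ring classifier and the NAD(P)H proxy
#' analyses; the remaining entries span the blue-to-red excitation/emission
#' plane (including the 575 nm emission band) in a monotone grid.
#'
#' @return a [ChannelTable-class] with 15 entries.
#' @export
defaultChannelTable <- function() {
    channelTable(1:15,
        lambdaEx = c(320, 320, 370, 343, 355, 390, 390, 405, 405, 415,
                     431, 431, 431, 458, 458),
        lambdaEm = c(400, 430, 414, 451, 500, 470, 520, 450, 530, 575,
                     470, 530, 594, 575, 610))
}

#' Read / write a channel metadata table
#'
#' TSV with header `channel  lambda_ex_nm  lambda_em_nm`.
#'
#' @param path file path.
#' @return `readChannelTable` returns a [ChannelTable-class].
#' @export
readChannelTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    need <- c("channel", "lambda_ex_nm", "lambda_em_nm")
    if (!all(need %in% names(df)))
        stop("channel table must have columns: ", paste(need, collapse = ", "))
    df <- df[order(df$channel), , drop = FALSE]
    channelTable(df$channel, df$lambda_ex_nm, df$lambda_em_nm)
}

#' @rdname readChannelTable
#' @param channels a [ChannelTable-class].
#' @export
writeChannelTable <- function(channels, path) {
    stopifnot(is(channels, "ChannelTable"))
    utils::write.table(
        data.frame(channel = channels@channel,
                   lambda_ex_nm = channels@lambdaEx,
                   lambda_em_nm = channels@lambdaEm),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @export
#' @describeIn channelTable number of channels
setMethod("length", "ChannelTable", function(x) length(x@channel))

setMethod("show", "ChannelTable", function(object) {
    cat(sprintf("ChannelTable with %d channels (ex %g-%g nm, em %g-%g nm)\n",
        length(object@channel), min(object@lambdaEx), max(object@lambdaEx),
        min(object@lambdaEm), max(object@lambdaEm)))
})

setMethod("show", "HyperspectralStack", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("HyperspectralStack: %d channels, %d x %d px, %s%s\n",
        d[1L], d[2L], d[3L],
        if (object@normalized) "background-normalized" else "raw",
        if (is.na(object@pixelSize)) "" else
            sprintf(", %.3g um/px", object@pixelSize)))
})

#' Construct a HyperspectralStack from a pixel array
#'
#' @param pixels 3-D array `[channel, row, col]` of non-negative intensities.
#' @param channels a [ChannelTable-class] matching the channel axis.
#' @param normalized whether per-channel background normalization was applied.
#' @param pixelSize optional physical pixel size (micrometres per pixel side).
#' @return a [HyperspectralStack-class].
#' @export
hyperspectralStack <- function(pixels, channels = defaultChannelTable(),
                               normalized = FALSE, pixelSize = NA_real_) {
    new("HyperspectralStack", pixels = pixels, channels = channels,
        normalized = normalized, pixelSize = as.numeric(pixelSize))
}

#' Pixel data and channel table accessors
#'
#' @param x a [HyperspectralStack-class].
#' @return `stackPixels`: the `[channel, row, col]` array; `stackChannels`:
#'   the [ChannelTable-class]; `channelImage`: one channel as a matrix.
#' @export
stackPixels <- function(x) { stopifnot(is(x, "HyperspectralStack")); x@pixels }

#' @rdname stackPixels
#' @export
stackChannels <- function(x) { stopifnot(is(x, "HyperspectralStack")); x@channels }

#' @rdname stackPixels
#' @param channel channel id.
#' @export
channelImage <- function(x, channel) {
    stopifnot(is(x, "HyperspectralStack"))
    ch <- match(as.integer(channel), x@channels@channel)
    if (is.na(ch)) stop("no such channel: ", channel)
    x@pixels[ch, , ]
}

#' Read a hyperspectral stack from TIFF
#'
#' Accepts either a multi-page TIFF (one page per channel, page order =
#' channel order) or a directory of single-page per-channel images whose file
#' names contain the channel number (e.g. `ch01.tif` .. `ch15.tif`).
#' Integer-typed TIFF data are read as raw camera counts.
#'
#' @param path file or directory path.
#' @param channels a [ChannelTable-class]; page count must match.
#' @return a [HyperspectralStack-class] with `normalized = FALSE`.
#' @export
readStack <- function(path, channels = defaultChannelTable()) {
    nch <- length(channels@channel)
    if (dir.exists(path)) {
        files <- list.files(path, pattern = "\\.tiff?$", full.names = TRUE)
        num <- as.integer(sub("^.*?(\\d+)\\.tiff?$", "\\1", files))
        if (anyNA(num) || anyDuplicated(num))
            stop("cannot extract unique channel numbers from file names in ", path)
        files <- files[order(num)]
        if (!identical(sort(num), channels@channel))
            stop(sprintf("found channels {%s} but table has 1..%d",
                         paste(sort(num), collapse = ","), nch))
        pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
    } else {
        pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
        if (!is.list(pages)) pages <- list(pages)
    }
    if (length(pages) != nch)
        stop(sprintf("page count (%d) does not match channel count (%d)",
                     length(pages), nch))
    dm <- dim(pages[[1L]])
    if (length(dm) != 2L) stop("each page must be a single-plane grayscale image")
    if (!all(vapply(pages, function(p) identical(dim(p), dm), logical(1L))))
        stop("all pages must share the same dimensions")
    px <- array(0, dim = c(nch, dm[1L], dm[2L]))
    for (i in seq_len(nch)) {
        p <- pages[[i]]
        if (!is.numeric(p)) stop("non-numeric pixel data in page ", i)
        px[i, , ] <- p
    }
    hyperspectralStack(px, channels, normalized = FALSE)
}

#' Write a hyperspectral stack as a multi-page TIFF
#'
#' Integer-valued stacks with a maximum below 2^16 are written as 16-bit
#' integer pages (bit-identical on a read round trip); anything else is
#' written as 32-bit float.
#'
#' @param stack a [HyperspectralStack-class].
#' @param path output file path.
#' @export
writeStack <- function(stack, path) {
    stopifnot(is(stack, "HyperspectralStack"))
    px <- stack@pixels
    nch <- dim(px)[1L]
    pages <- lapply(seq_len(nch), function(i) px[i, , ])
    asInt <- all(px == round(px)) && max(px) < 65536
    if (asInt) {
        tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                        bits.per.sample = 16L)
    } else {
        tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    }
    invisible(path)
}

# modal intensity of one channel: round to nearest integer, tabulate, and on
# ties keep the smallest intensity
.channelMode <- function(v) {
    r <- round(v)
    tb <- table(r)
    vals <- as.numeric(names(tb))
    vals[order(-as.integer(tb), vals)][1L]
}

#' Background-normalize a stack by its per-channel modal intensity
#'
#' The most frequent (integer-rounded) intensity in each channel is taken as
#' that channel's background level; the channel is divided by it and rescaled
#' by `scale` (default 30, a typical background count), independently per
#' channel. Ties among modal bins are broken toward the smallest intensity.
#'
#' @param stack a [HyperspectralStack-class].
#' @param scale target background level after normalization.
#' @return a normalized [HyperspectralStack-class].
#' @export
normalizeStack <- function(stack, scale = 30) {
    stopifnot(is(stack, "HyperspectralStack"))
    px <- stack@pixels
    for (i in seq_len(dim(px)[1L])) {
        m <- .channelMode(px[i, , ])
        if (m <= 0)
            stop(sprintf("degenerate background: modal intensity is %g in channel %d",
                         m, stack@channels@channel[i]))
        px[i, , ] <- px[i, , ] / m * scale
    }
    hyperspectralStack(px, stack@channels, normalized = TRUE,
                       pixelSize = stack@pixelSize)
}

#' Pseudo-RGB composite of three channels
#'
#' Maps three channels (default 1, 6 and 13) to the R, G and B planes. Each
#' plane is clipped at `clipMax` (default its 99.5th percentile) and linearly
#' rescaled to `[0, 1]`.
#'
#' @param stack a normalized [HyperspectralStack-class].
#' @param channels integer triple of channel ids for (R, G, B).
#' @param clipMax scalar or length-3 clip ceiling; `NULL` for the per-plane
#'   99.5th percentile.
#' @return array `[row, col, 3]` with values in `[0, 1]`.
#' @export
pseudoRGB <- function(stack, channels = c(1L, 6L, 13L), clipMax = NULL) {
    stopifnot(is(stack, "HyperspectralStack"))
    if (!stack@normalized)
        warning("stack is not background-normalized; composite uses raw counts")
    if (length(channels) != 3L) stop("channels must be a triple")
    planes <- lapply(channels, function(ch) channelImage(stack, ch))
    if (!is.null(clipMax)) clipMax <- rep_len(clipMax, 3L)
    out <- array(0, dim = c(dim(planes[[1L]]), 3L))
    for (i in 1:3) {
        p <- planes[[i]]
        cm <- if (is.null(clipMax)) stats::quantile(p, 0.995, names = FALSE)
              else clipMax[i]
        p <- pmin(p, cm)
        out[, , i] <- if (cm > 0) p / cm else p
    }
    out
}
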