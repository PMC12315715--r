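#' Read a fluorophore spectrum table
#'
#' TSV with header `wavelength_nm  intensity`, wavelengths strictly
#' increasing, intensities non-negative.
#'
#' @param path file path.
#' @return data.frame with columns `wavelength_nm`, `intensity`.
#' @export
readSpectrum <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    need <- c("wavelength_nm", "intensity")
    if (!all(need %in% names(df)))
        stop("spectrum must have columns: ", paste(need, collapse = ", "))
    .checkSpectrum(df[need])
}

.checkSpectrum <- function(df) {
    if (any(diff(df$wavelength_nm) <= 0))
        stop("wavelengths must be strictly increasing")
    if (any(df$intensity < 0)) stop("intensities must be >= 0")
    df
}

# wavelength of the spectral maximum; ties broken toward the smallest
# wavelength
.peakWavelength <- function(df) {
    df$wavelength_nm[which.max(df$intensity)]
}

# linear interpolation within support only
.interpSpectrum <- function(df, lambda) {
    rng <- range(df$wavelength_nm)
    if (any(lambda < rng[1L] | lambda > rng[2L]))
        stop(sprintf("wavelength outside the spectrum's support [%g, %g] nm; no extrapolation",
                     rng[1L], rng[2L]))
    stats::approx(df$wavelength_nm, df$intensity, xout = lambda)$y
}

#' Build an excitation x emission spectra matrix
#'
#' Normalized fluorophore intensity on a wavelength grid:
#' `I(ex, em) = (I_ex(ex) / I_ex(Ex0)) * (I_em(em) / I_em(Em0))`, where Ex0
#' and Em0 are the excitation and emission wavelengths of maximum intensity.
#' The surface is the rank-1 outer product of the two peak-normalized
#' spectra; it is invariant to rescaling either input spectrum, and its
#' maximum is 1 at (Ex0, Em0). Tabulated spectra are linearly interpolated;
#' grid points outside a spectrum's support raise an error.
#'
#' @param excitation,emission spectra as two-column data.frames
#'   (`wavelength_nm`, `intensity`) or paths to TSV files.
#' @param exGrid,emGrid wavelength grids (nm); default the tabulated
#'   wavelengths themselves.
#' @param name fluorophore name.
#' @return a [SpectraMatrix-class].
#' @export
buildSpectraMatrix <- function(excitation, emission, exGrid = NULL,
                               emGrid = NULL, name = "fluorophore") {
    if (is.character(excitation)) excitation <- readSpectrum(excitation)
    if (is.character(emission)) emission <- readSpectrum(emission)
    excitation <- .checkSpectrum(excitation)
    emission <- .checkSpectrum(emission)
    if (is.null(exGrid)) exGrid <- excitation$wavelength_nm
    if (is.null(emGrid)) emGrid <- emission$wavelength_nm
    ex0 <- .peakWavelength(excitation)
    em0 <- .peakWavelength(emission)
    exN <- .interpSpectrum(excitation, exGrid) / max(excitation$intensity)
    emN <- .interpSpectrum(emission, emGrid) / max(emission$intensity)
    new("SpectraMatrix", exGrid = as.numeric(exGrid),
        emGrid = as.numeric(emGrid), intensity = outer(exN, emN),
        peak = c(ex = ex0, em = em0), name = name)
}

setMethod("show", "SpectraMatrix", function(object) {
    cat(sprintf("SpectraMatrix '%s': %d x %d grid, peak at (%g, %g) nm\n",
        object@name, length(object@exGrid), length(object@emGrid),
        object@peak[["ex"]], object@peak[["em"]]))
})

# bilinear interpolation of the spectra matrix at (ex, em); NA outside grid
.bilinear <- function(sm, ex, em) {
    gx <- sm@exGrid; gy <- sm@emGrid
    if (ex < gx[1L] || ex > gx[length(gx)] || em < gy[1L] || em > gy[length(gy)])
        return(NA_real_)
    i <- findInterval(ex, gx, all.inside = TRUE)
    j <- findInterval(em, gy, all.inside = TRUE)
    tx <- if (gx[i + 1L] > gx[i]) (ex - gx[i]) / (gx[i + 1L] - gx[i]) else 0
    ty <- if (gy[j + 1L] > gy[j]) (em - gy[j]) / (gy[j + 1L] - gy[j]) else 0
    z <- sm@intensity
    (1 - tx) * (1 - ty) * z[i, j] + tx * (1 - ty) * z[i + 1L, j] +
        (1 - tx) * ty * z[i, j + 1L] + tx * ty * z[i + 1L, j + 1L]
}

#' Rank instrument channels on a spectra matrix
#'
#' Evaluates the normalized fluorophore intensity at each channel's
#' (excitation, emission) coordinate by bilinear interpolation and ranks
#' channels by descending intensity; the top-ranked channel is the proposed
#' proxy for that fluorophore. Channels outside the grid support are flagged
#' (`in_support = FALSE`) with missing intensity and rank last.
#'
#' @param sm a [SpectraMatrix-class].
#' @param channels a [ChannelTable-class].
#' @return data.frame ordered by rank: `channel`, `lambda_ex`, `lambda_em`,
#'   `intensity`, `in_support`, `rank`.
#' @export
overlayChannels <- function(sm, channels = defaultChannelTable()) {
    stopifnot(is(sm, "SpectraMatrix"), is(channels, "ChannelTable"))
    I <- vapply(seq_along(channels@channel), function(i)
        .bilinear(sm, channels@lambdaEx[i], channels@lambdaEm[i]), numeric(1L))
    df <- data.frame(channel = channels@channel,
                     lambda_ex = channels@lambdaEx,
                     lambda_em = channels@lambdaEm,
                     intensity = I, in_support = !is.na(I))
    df <- df[order(-ifelse(is.na(df$intensity), -Inf, df$intensity),
                   df$channel), ]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    df
}

#' Synthetic Gaussian-shaped fluorophore spectra
#'
#' Stand-in excitation/emission curves for NAD(P)H-like fluorophores, shaped
#' as Gaussians with stated peak and width. These are synthetic surrogates
#' for literature spectra (which are not redistributed here): the free
#' NAD(P)H form peaks near (340, 460) nm and the protein-bound form is
#' blue-shifted in emission, near (330, 440) nm.
#'
#' @param form `"free"` or `"bound"`, or supply explicit peaks/widths.
#' @param exPeak,emPeak peak wavelengths (nm).
#' @param exWidth,emWidth Gaussian sigma (nm).
#' @param step grid spacing (nm).
#' @return list with `excitation` and `emission` spectrum data.frames.
#' @export
syntheticNADHSpectrum <- function(form = c("free", "bound"), exPeak = NULL,
                                  emPeak = NULL, exWidth = 30, emWidth = 35,
                                  step = 2) {
    form <- match.arg(form)
    if (is.null(exPeak)) exPeak <- switch(form, free = 340, bound = 330)
    if (is.null(emPeak)) emPeak <- switch(form, free = 460, bound = 440)
    g <- function(peak, width) {
        wl <- seq(peak - 4 * width, peak + 4 * width, by = step)
        data.frame(wavelength_nm = wl,
                   intensity = 100 * exp(-(wl - peak)^2 / (2 * width^2)))
    }
    list(excitation = g(exPeak, exWidth), emission = g(emPeak, emWidth))
}

#' Write a spectra matrix as CSV (excitation rows, emission columns)
#'
#' @param sm a [SpectraMatrix-class].
#' @param path output file.
#' @export
writeSpectraMatrix <- function(sm, path) {
    stopifnot(is(sm, "SpectraMatrix"))
    m <- sm@intensity
    dimnames(m) <- list(sm@exGrid, sm@emGrid)
    utils::write.csv(m, path)
    invisible(path)
}
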