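#' @import methods
NULL

#' ChannelTable: excitation/emission layout of a hyperspectral imaging system
#'
#' Holds one row per imaging channel: a channel id (contiguous 1..N), the
#' excitation wavelength and the emission wavelength in nanometres. Every
#' channel must satisfy the Stokes shift (emission red of excitation).
#'
#' @slot channel integer vector of channel ids, contiguous 1..N.
#' @slot lambdaEx numeric vector, excitation wavelength (nm).
#' @slot lambdaEm numeric vector, emission wavelength (nm).
#' @aliases ChannelTable-class
#' @exportClass ChannelTable
setClass("ChannelTable",
    representation(channel = "integer", lambdaEx = "numeric", lambdaEm = "numeric"))

setValidity("ChannelTable", function(object) {
    n <- length(object@channel)
    if (length(object@lambdaEx) != n || length(object@lambdaEm) != n)
        return("channel, lambdaEx and lambdaEm must have equal length")
    if (n == 0L) return("channel table is empty")
    if (!identical(object@channel, seq_len(n)))
        return("channel ids must be unique and contiguous 1..N")
    if (any(!is.finite(object@lambdaEx)) || any(!is.finite(object@lambdaEm)))
        return("wavelengths must be finite")
    if (any(object@lambdaEm <= object@lambdaEx))
        return("lambdaEm must exceed lambdaEx for every channel (Stokes shift)")
    TRUE
})

#' HyperspectralStack: one multi-band field of view
#'
#' A 3-D pixel array indexed `[channel, row, col]` together with its
#' [ChannelTable-class], a flag recording whether per-channel background
#' (modal-intensity) normalization has been applied, and optional physical
#' pixel size. All intensities are finite and non-negative.
#'
#' @slot pixels 3-D numeric array `[channel, row, col]`.
#' @slot channels a [ChannelTable-class]; its size must match the channel axis.
#' @slot normalized logical flag.
#' @slot pixelSize micrometres per pixel side, or `NA_real_` when unknown.
#' @aliases HyperspectralStack-class
#' @exportClass HyperspectralStack
setClass("HyperspectralStack",
    representation(pixels = "array", channels = "ChannelTable",
                   normalized = "logical", pixelSize = "numeric"))

setValidity("HyperspectralStack", function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L) return("pixels must be a 3-D array [channel, row, col]")
    if (d[1L] != length(object@channels@channel))
        return(sprintf("channel axis length (%d) differs from channel table size (%d)",
                       d[1L], length(object@channels@channel)))
    if (any(!is.finite(object@pixels))) return("all intensities must be finite")
    if (any(object@pixels < 0)) return("all intensities must be >= 0")
    if (length(object@normalized) != 1L) return("normalized must be a single flag")
    if (length(object@pixelSize) != 1L) return("pixelSize must be a single value")
    TRUE
})

#' CellMask: the pixel set of one segmented cell
#'
#' @slot cellId positive integer label of the cell in the source label image.
#' @slot pixels integer matrix with columns `row`, `col` (1-based pixel
#'   coordinates of the cell's pixel set).
#' @slot imageDim integer of length 2, dimensions of the source image.
#' @slot bbox integer of length 4 `(row0, col0, row1, col1)`, the tight
#'   bounding box (closed, 1-based).
#' @aliases CellMask-class
#' @exportClass CellMask
setClass("CellMask",
    representation(cellId = "integer", pixels = "matrix",
                   imageDim = "integer", bbox = "integer"))

setValidity("CellMask", function(object) {
    px <- object@pixels
    if (nrow(px) < 1L) return("cell pixel set is empty")
    if (ncol(px) != 2L) return("pixels must have two columns (row, col)")
    if (object@cellId < 1L) return("cellId must be positive")
    bb <- object@bbox
    if (length(bb) != 4L) return("bbox must have 4 entries")
    if (bb[1L] != min(px[, 1L]) || bb[2L] != min(px[, 2L]) ||
        bb[3L] != max(px[, 1L]) || bb[4L] != max(px[, 2L]))
        return("bbox does not tightly contain the pixel set")
    if (min(px) < 1L || any(px[, 1L] > object@imageDim[1L]) ||
        any(px[, 2L] > object@imageDim[2L]))
        return("pixels outside image bounds")
    TRUE
})

#' AnnulusPair: border and adjacent inner ring of a cell
#'
#' Pixel sets at Euclidean distance-to-background `<= thickness` (border) and
#' in `(thickness, 2*thickness]` (inner), both subsets of the cell mask. The
#' inner set may be empty for thin cells; downstream ring classification then
#' reports "undefined".
#'
#' @slot borderPixels integer matrix (row, col) of border-ring pixels.
#' @slot innerPixels integer matrix (row, col) of inner-ring pixels.
#' @slot thickness ring thickness in pixels.
#' @aliases AnnulusPair-class
#' @exportClass AnnulusPair
setClass("AnnulusPair",
    representation(borderPixels = "matrix", innerPixels = "matrix",
                   thickness = "numeric"))

#' SpectralPCA: principal components of cell spectral fingerprints
#'
#' @slot scores cells x K score matrix.
#' @slot loadings channels x K loading matrix (orthonormal columns; the
#'   largest-magnitude entry of each column is positive).
#' @slot explainedVarianceRatio length-K vector summing to 1.
#' @slot center per-channel means removed before the SVD.
#' @slot scale per-channel scale factors (all 1 unless standardized).
#' @slot nSelected number of components retained by the successive-gap rule.
#' @aliases SpectralPCA-class
#' @exportClass SpectralPCA
setClass("SpectralPCA",
    representation(scores = "matrix", loadings = "matrix",
                   explainedVarianceRatio = "numeric",
                   center = "numeric", scale = "numeric", nSelected = "integer"))

setValidity("SpectralPCA", function(object) {
    K <- ncol(object@loadings)
    if (ncol(object@scores) != K) return("scores and loadings disagree on K")
    if (length(object@explainedVarianceRatio) != K)
        return("explainedVarianceRatio length must equal K")
    if (abs(sum(object@explainedVarianceRatio) - 1) > 1e-6)
        return("explainedVarianceRatio must sum to 1")
    if (any(diff(object@explainedVarianceRatio) > 1e-8))
        return("explainedVarianceRatio must be non-increasing")
    TRUE
})

#' SpectraMatrix: excitation x emission grid of normalized fluorophore intensity
#'
#' Rank-1 intensity surface I(ex, em) = (I_ex(ex)/I_ex(Ex0)) x
#' (I_em(em)/I_em(Em0)), the outer product of the peak-normalized excitation
#' and emission spectra; its maximum is 1, attained at the spectral peak
#' (Ex0, Em0).
#'
#' @slot exGrid excitation wavelengths (nm), rows of `intensity`.
#' @slot emGrid emission wavelengths (nm), columns of `intensity`.
#' @slot intensity matrix of normalized intensities in `[0, 1]`.
#' @slot peak named numeric `(ex, em)`: wavelengths of the spectral maximum.
#' @slot name fluorophore name.
#' @aliases SpectraMatrix-class
#' @exportClass SpectraMatrix
setClass("SpectraMatrix",
    representation(exGrid = "numeric", emGrid = "numeric", intensity = "matrix",
                   peak = "numeric", name = "character"))

setValidity("SpectraMatrix", function(object) {
    if (nrow(object@intensity) != length(object@exGrid) ||
        ncol(object@intensity) != length(object@emGrid))
        return("intensity dimensions must match the wavelength grids")
    if (any(object@intensity < -1e-12) || any(object@intensity > 1 + 1e-9))
        return("intensities must lie in [0, 1]")
    TRUE
})
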