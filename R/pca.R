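#' PCA of cell spectral fingerprints
#'
#' SVD-based principal component analysis of a cells x channels matrix of
#' mean intensities. Columns are mean-centred; variance scaling is off by
#' default (the fingerprints share units). The sign of each loading column
#' is fixed so that its largest-magnitude entry is positive, making scores
#' reproducible across linear-algebra backends.
#'
#' @param features numeric matrix (cells x channels) or a data.frame whose
#'   `mean_ch*` columns are used.
#' @param standardize also scale columns to unit variance.
#' @return a [SpectralPCA-class].
#' @export
fitSpectralPCA <- function(features, standardize = FALSE) {
    if (is.data.frame(features)) {
        cols <- grep("^mean_ch", names(features), value = TRUE)
        if (length(cols)) features <- as.matrix(features[, cols])
        else features <- as.matrix(features)
    }
    if (nrow(features) < 3L) stop("need at least 3 cells")
    if (anyNA(features)) stop("missing values in feature matrix")
    if (standardize && any(apply(features, 2L, stats::sd) == 0))
        stop("zero-variance column; cannot standardize")
    pc <- stats::prcomp(features, center = TRUE, scale. = standardize)
    evr <- pc$sdev^2 / sum(pc$sdev^2)
    rot <- pc$rotation
    sco <- pc$x
    for (j in seq_len(ncol(rot))) {
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
    }
    obj <- new("SpectralPCA", scores = sco, loadings = rot,
               explainedVarianceRatio = evr,
               center = pc$center,
               scale = if (standardize) pc$scale else rep(1, ncol(features)),
               nSelected = 1L)
    obj@nSelected <- selectComponents(obj)
    obj
}

setMethod("show", "SpectralPCA", function(object) {
    cat(sprintf("SpectralPCA: %d cells x %d components; EVR1 = %.3f, EVR2 = %.3f; %d selected\n",
        nrow(object@scores), ncol(object@scores),
        object@explainedVarianceRatio[1L],
        if (length(object@explainedVarianceRatio) > 1L)
            object@explainedVarianceRatio[2L] else NA_real_,
        object@nSelected))
})

#' @describeIn fitSpectralPCA PCA scores (cells x K)
#' @param pca a [SpectralPCA-class].
#' @export
pcaScores <- function(pca) { stopifnot(is(pca, "SpectralPCA")); pca@scores }

#' @describeIn fitSpectralPCA loadings (channels x K)
#' @export
pcaLoadings <- function(pca) { stopifnot(is(pca, "SpectralPCA")); pca@loadings }

#' @describeIn fitSpectralPCA explained-variance ratios
#' @export
explainedVariance <- function(pca) {
    stopifnot(is(pca, "SpectralPCA")); pca@explainedVarianceRatio
}

#' Squared channel loadings of one component
#'
#' The elementwise square of loading column `k`; by orthonormality it sums
#' to 1 and attributes the component's variance to channels.
#'
#' @param pca a [SpectralPCA-class].
#' @param k component index.
#' @return numeric vector over channels, summing to 1.
#' @export
squaredLoadings <- function(pca, k) {
    stopifnot(is(pca, "SpectralPCA"), k >= 1L, k <= ncol(pca@loadings))
    pca@loadings[, k]^2
}

#' Number of components to keep by the spectral-gap rule
#'
#' Scans the non-increasing explained-variance ratios for the largest
#' relative gap between successive components, `ratio[j] / ratio[j+1]`, and
#' keeps components `1..j`. A trailing zero ratio ends the scan (the gap
#' before it is infinite). For a variance profile like (0.6, 0.3, 0.05, ...)
#' this keeps two components: the drop from the second to the third
#' component is six-fold, against two-fold from first to second.
#'
#' @param pca a [SpectralPCA-class].
#' @return integer number of components.
#' @export
selectComponents <- function(pca) {
    r <- pca@explainedVarianceRatio
    r <- r[r > 1e-10 * r[1L]]  # drop rank-truncation zeros: not a real gap
    if (length(r) < 2L) return(1L)
    gaps <- r[-length(r)] / r[-1L]
    as.integer(which.max(gaps))
}

#' Gate PCA scores into spectral groups by a 2-D KDE level set
#'
#' Fits a Gaussian-product kernel density estimate on (PC1, PC2), evaluates
#' it on a 256 x 256 grid spanning the scores plus a 5% margin, thresholds
#' it at `level`, and partitions the super-level set into 8-connected
#' components. The two largest components define the spectral groups; group
#' 1 is the component containing (or nearest to) the cell with the smallest
#' PC1 score. Cells falling outside both regions are assigned to the nearer
#' component centroid in score space.
#'
#' @param scores cells x 2 matrix of (PC1, PC2) scores, or a
#'   [SpectralPCA-class] (first two score columns are used).
#' @param level density threshold. The default 0.18 is a density value in
#'   the fitted KDE's own units, so its meaning depends on the score scale;
#'   set `relative = TRUE` to interpret `level` as a fraction of the peak
#'   density instead.
#' @param bandwidth `"scott"` (per-axis `sd * n^(-1/6)`) or a positive
#'   scalar used for both axes.
#' @param relative interpret `level` as a fraction of the maximum density.
#' @param gridSize evaluation grid resolution per axis.
#' @return list with `group` (integer 1/2 per cell), `level` (absolute
#'   density level used), `bandwidth` (per-axis), `nComponents` (number of
#'   super-level components found), `density` (grid matrix) and the grid
#'   coordinates `xGrid`, `yGrid`.
#' @export
kdeGate <- function(scores, level = 0.18, bandwidth = "scott",
                    relative = FALSE, gridSize = 256L) {
    if (is(scores, "SpectralPCA")) scores <- scores@scores[, 1:2, drop = FALSE]
    scores <- as.matrix(scores)
    stopifnot(ncol(scores) == 2L)
    n <- nrow(scores)
    if (n < 10L) stop("need at least 10 cells to gate")
    x <- scores[, 1L]; y <- scores[, 2L]
    if (identical(bandwidth, "scott")) {
        h <- c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
    } else {
        h <- rep_len(as.numeric(bandwidth), 2L)
    }
    if (any(h <= 0)) stop("degenerate bandwidth; scores have zero spread")
    pad <- 0.05
    rx <- range(x); ry <- range(y)
    gx <- seq(rx[1L] - pad * diff(rx) - h[1L], rx[2L] + pad * diff(rx) + h[1L],
              length.out = gridSize)
    gy <- seq(ry[1L] - pad * diff(ry) - h[2L], ry[2L] + pad * diff(ry) + h[2L],
              length.out = gridSize)
    # product kernel: density = (Kx %*% t(Ky)) / n, separable per axis
    Kx <- outer(gx, x, function(g, xi) stats::dnorm(g, xi, h[1L]))
    Ky <- outer(gy, y, function(g, yi) stats::dnorm(g, yi, h[2L]))
    dens <- (Kx %*% t(Ky)) / n
    lev <- if (relative) level * max(dens) else level
    fg <- dens >= lev
    if (!any(fg))
        stop(sprintf("super-level set at density %.4g is empty; lower the level", lev))
    comp <- .labelComponents(fg)
    sizes <- tabulate(comp[comp > 0L])
    keep <- order(sizes, decreasing = TRUE)[seq_len(min(2L, length(sizes)))]
    if (length(keep) == 1L)
        warning("single density component; all cells assigned to group 1")
    # map each cell to its grid cell
    ix <- findInterval(x, gx, all.inside = TRUE)
    iy <- findInterval(y, gy, all.inside = TRUE)
    cellComp <- comp[cbind(ix, iy)]
    cellComp[!(cellComp %in% keep)] <- 0L
    # centroids of kept components in score units
    cents <- vapply(keep, function(k) {
        px <- which(comp == k, arr.ind = TRUE)
        c(mean(gx[px[, 1L]]), mean(gy[px[, 2L]]))
    }, numeric(2L))
    for (i in which(cellComp == 0L)) {
        d2 <- (gx[ix[i]] - cents[1L, ])^2 + (gy[iy[i]] - cents[2L, ])^2
        cellComp[i] <- keep[which.min(d2)]
    }
    # group 1 anchored at the cell with the smallest PC1 score
    anchor <- cellComp[which.min(x)]
    grp <- ifelse(cellComp == anchor, 1L, 2L)
    list(group = as.integer(grp), level = lev, bandwidth = h,
         nComponents = length(keep), density = dens, xGrid = gx, yGrid = gy)
}
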