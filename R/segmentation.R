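#' Extract per-cell masks from an integer label image
#'
#' @param labelImage matrix of non-negative integer labels (0 = background).
#' @return list of [CellMask-class], one per distinct nonzero label, in
#'   ascending label order. An empty label image yields an empty list with a
#'   warning.
#' @export
extractCells <- function(labelImage) {
    stopifnot(is.matrix(labelImage))
    labs <- sort(unique(labelImage[labelImage > 0]))
    if (length(labs) == 0L) {
        warning("label image contains no cells")
        return(list())
    }
    lapply(labs, function(l) {
        px <- which(labelImage == l, arr.ind = TRUE)
        dimnames(px) <- NULL
        storage.mode(px) <- "integer"
        new("CellMask", cellId = as.integer(l), pixels = px,
            imageDim = as.integer(dim(labelImage)),
            bbox = as.integer(c(min(px[, 1L]), min(px[, 2L]),
                                max(px[, 1L]), max(px[, 2L]))))
    })
}

#' @describeIn extractCells pixel count (area) of a mask
#' @param mask a [CellMask-class].
#' @export
maskArea <- function(mask) { stopifnot(is(mask, "CellMask")); nrow(mask@pixels) }

setMethod("show", "CellMask", function(object) {
    cat(sprintf("CellMask %d: %d px, bbox [%d:%d, %d:%d]\n", object@cellId,
        nrow(object@pixels), object@bbox[1L], object@bbox[3L],
        object@bbox[2L], object@bbox[4L]))
})

# Euclidean distance-to-background for one cell, computed on a padded window.
# The window is the bounding box grown by `pad`; a one-pixel zero ring is
# always present, so pixels beyond the image edge count as background.
# Returns list(window dist matrix, offset) where offset maps window coords to
# image coords.
.cellDistance <- function(mask, pad) {
    bb <- mask@bbox
    r0 <- bb[1L] - pad; c0 <- bb[2L] - pad
    nr <- bb[3L] - bb[1L] + 1L + 2L * pad
    nc <- bb[4L] - bb[2L] + 1L + 2L * pad
    w <- matrix(0, nr, nc)
    w[cbind(mask@pixels[, 1L] - r0 + 1L, mask@pixels[, 2L] - c0 + 1L)] <- 1
    d <- EBImage::distmap(w, metric = "euclidean")@.Data
    list(dist = d, r0 = r0, c0 = c0)
}

#' Border and inner annuli of a cell mask
#'
#' Splits a cell into a border ring (Euclidean distance to the nearest
#' background pixel centre `<= thickness`) and the adjacent inner ring
#' (distance in `(thickness, 2*thickness]`). Background is the complement of
#' the cell's own pixel set; pixels beyond the image edge also count as
#' background. For cells thinner than `thickness` the inner ring is empty and
#' the pair is flagged so that ring classification reports "undefined".
#'
#' @param mask a [CellMask-class].
#' @param thickness ring thickness in pixels (default 10).
#' @param metric `"euclidean"` (exact Euclidean distance transform, default)
#'   or `"chebyshev"` (erosion-count distance).
#' @return an [AnnulusPair-class].
#' @export
cellAnnuli <- function(mask, thickness = 10, metric = c("euclidean", "chebyshev")) {
    stopifnot(is(mask, "CellMask"), thickness > 0)
    metric <- match.arg(metric)
    pad <- as.integer(ceiling(thickness)) + 1L
    if (metric == "euclidean") {
        cd <- .cellDistance(mask, pad)
        d <- cd$dist
        wr <- mask@pixels[, 1L] - cd$r0 + 1L
        wc <- mask@pixels[, 2L] - cd$c0 + 1L
        dv <- d[cbind(wr, wc)]
    } else {
        dv <- .chebyshevDistance(mask, pad)
    }
    isBorder <- dv <= thickness
    isInner <- dv > thickness & dv <= 2 * thickness
    new("AnnulusPair",
        borderPixels = mask@pixels[isBorder, , drop = FALSE],
        innerPixels = mask@pixels[isInner, , drop = FALSE],
        thickness = thickness)
}

# Chebyshev (chessboard) distance-to-background via iterated 8-neighbour
# erosion on the padded window.
.chebyshevDistance <- function(mask, pad) {
    bb <- mask@bbox
    r0 <- bb[1L] - pad; c0 <- bb[2L] - pad
    nr <- bb[3L] - bb[1L] + 1L + 2L * pad
    nc <- bb[4L] - bb[2L] + 1L + 2L * pad
    w <- matrix(FALSE, nr, nc)
    w[cbind(mask@pixels[, 1L] - r0 + 1L, mask@pixels[, 2L] - c0 + 1L)] <- TRUE
    d <- matrix(0L, nr, nc)
    cur <- w
    k <- 0L
    while (any(cur)) {
        k <- k + 1L
        d[cur] <- k
        # erode: keep pixels whose full 8-neighbourhood is inside `cur`
        p <- matrix(FALSE, nr + 2L, nc + 2L)
        p[2:(nr + 1L), 2:(nc + 1L)] <- cur
        nxt <- cur
        for (dr in -1:1) for (dc in -1:1)
            nxt <- nxt & p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
        cur <- nxt
    }
    d[cbind(mask@pixels[, 1L] - r0 + 1L, mask@pixels[, 2L] - c0 + 1L)]
}

#' @describeIn cellAnnuli whether the inner annulus is empty (cell too thin)
#' @param annuli an [AnnulusPair-class].
#' @export
innerEmpty <- function(annuli) {
    stopifnot(is(annuli, "AnnulusPair"))
    nrow(annuli@innerPixels) == 0L
}

setMethod("show", "AnnulusPair", function(object) {
    cat(sprintf("AnnulusPair: %d border px, %d inner px (thickness %g)\n",
        nrow(object@borderPixels), nrow(object@innerPixels), object@thickness))
})

# 8-connected component labeling by iterative min-label propagation.
# Components are numbered 1..K by the raster-scan (row-major) position of
# each component's first (top-left) pixel.
.labelComponents <- function(fg) {
    nr <- nrow(fg); nc <- ncol(fg)
    lab <- matrix(0L, nr, nc)
    if (!any(fg)) return(lab)
    lab[fg] <- which(fg)  # seed with linear index
    repeat {
        p <- matrix(.Machine$integer.max, nr + 2L, nc + 2L)
        p[2:(nr + 1L), 2:(nc + 1L)][fg] <- lab[fg]
        m <- lab
        for (dr in -1:1) for (dc in -1:1) {
            sh <- p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
            m <- pmin(m, sh)
        }
        m[!fg] <- 0L
        if (identical(m, lab)) break
        lab <- m
    }
    ids <- unique(lab[lab > 0])
    # row-major rank of each component's first pixel
    firstRM <- vapply(ids, function(id) {
        px <- which(lab == id, arr.ind = TRUE)
        min((px[, 1L] - 1L) * nc + px[, 2L])
    }, numeric(1L))
    lab[lab > 0] <- match(lab[lab > 0], ids[order(firstRM)])
    storage.mode(lab) <- "integer"
    lab
}

#' Fallback threshold segmentation for synthetic fields
#'
#' Otsu-thresholds the mean of the named channels, labels 8-connected
#' foreground components, and keeps components with at least `minArea`
#' pixels. This is a deliberately simple segmenter for simulated,
#' non-touching cells; real data are expected to arrive with curated label
#' masks.
#'
#' @param stack a normalized [HyperspectralStack-class].
#' @param channels channel ids averaged before thresholding.
#' @param minArea minimum component area in pixels.
#' @return integer label image (labels 1..K in raster order of each
#'   component's first pixel); all-zero with a warning when nothing passes.
#' @export
thresholdSegment <- function(stack, channels = c(1L, 6L, 13L), minArea = 50L) {
    stopifnot(is(stack, "HyperspectralStack"))
    img <- Reduce(`+`, lapply(channels, function(ch) channelImage(stack, ch))) /
        length(channels)
    rng <- range(img)
    if (rng[2L] <= rng[1L]) {
        warning("flat image; no components found")
        return(matrix(0L, nrow(img), ncol(img)))
    }
    x01 <- (img - rng[1L]) / (rng[2L] - rng[1L])
    th <- EBImage::otsu(EBImage::Image(x01), range = c(0, 1))
    fg <- x01 > th
    lab <- .labelComponents(fg)
    if (max(lab) > 0L) {
        sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
        keep <- which(sizes >= minArea)
        lab[] <- ifelse(lab > 0L & lab %in% keep, lab, 0L)
        if (length(keep)) {
            lab[lab > 0L] <- match(lab[lab > 0L], sort(keep))
        }
    }
    if (max(lab) == 0L) warning("no component reaches minArea = ", minArea)
    storage.mode(lab) <- "integer"
    lab
}
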