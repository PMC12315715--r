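test_that("extractCells returns one mask per label with brute-force disk areas", {
    img <- matrix(0L, 12, 12); img[3:4, 5] <- 1L; img[9, 9:10] <- 2L
    cells <- extractCells(img)
    expect_length(cells, 2L)
    expect_equal(vapply(cells, function(m) m@cellId, integer(1L)), c(1L, 2L))
    img5 <- matrix(0L, 6, 6); img5[2:3, 2:3] <- 5L
    cells5 <- extractCells(img5)
    expect_length(cells5, 1L)
    expect_equal(cells5[[1L]]@cellId, 5L)
    expect_equal(cells5[[1L]]@bbox, c(2L, 2L, 3L, 3L))
    expect_warning(extractCells(matrix(0L, 4, 4)), "no cells")
    # disk areas equal exhaustive pixel enumeration
    lab <- diskLabelImage(c(64, 64), rbind(c(20, 20), c(45, 45)), c(10, 15))
    cells <- extractCells(lab)
    for (i in 1:2) {
        R <- c(10, 15)[i]; ctr <- rbind(c(20, 20), c(45, 45))[i, ]
        enum <- sum(outer((1:64 - ctr[1])^2, (1:64 - ctr[2])^2, `+`) <= R^2)
        expect_equal(maskArea(cells[[i]]), enum)
    }
})

test_that("annuli agree exactly with the O(N^2) distance-transform oracle", {
    shapes <- list(
        disk = diskLabelImage(c(64, 64), rbind(c(32, 32)), 25),
        offdisk = diskLabelImage(c(50, 60), rbind(c(18, 40)), 14),
        rect = { m <- matrix(0L, 40, 40); m[8:33, 12:26] <- 1L; m },
        blob = { m <- diskLabelImage(c(48, 48), rbind(c(20, 20)), 12)
                 m[20:36, 20:30] <- 1L; m })
    for (nm in names(shapes)) {
        lab <- shapes[[nm]]
        mask <- extractCells(lab)[[1L]]
        for (th in c(4, 10)) {
            ann <- cellAnnuli(mask, thickness = th)
            oracle <- bruteAnnuli(lab == 1L, th)
            sortPx <- function(px) px[order(px[, 1L], px[, 2L]), , drop = FALSE]
            expect_equal(unname(sortPx(ann@borderPixels)),
                         unname(sortPx(oracle$border)), info = paste(nm, th))
            expect_equal(unname(sortPx(ann@innerPixels)),
                         unname(sortPx(oracle$inner)), info = paste(nm, th))
        }
    }
})

test_that("annuli are disjoint subsets of the mask and thin cells are flagged", {
    lab <- diskLabelImage(c(64, 64), rbind(c(32, 32)), 25)
    mask <- extractCells(lab)[[1L]]
    ann <- cellAnnuli(mask, 10)
    key <- function(px) paste(px[, 1L], px[, 2L])
    expect_length(intersect(key(ann@borderPixels), key(ann@innerPixels)), 0L)
    expect_true(all(key(ann@borderPixels) %in% key(mask@pixels)))
    expect_true(all(key(ann@innerPixels) %in% key(mask@pixels)))
    # disk of radius 8 is entirely within one 10-px thickness of background
    thin <- extractCells(diskLabelImage(c(30, 30), rbind(c(15, 15)), 8))[[1L]]
    expect_true(innerEmpty(cellAnnuli(thin, 10)))
    expect_false(innerEmpty(cellAnnuli(thin, 3)))
})

test_that("annuli are equivariant under translation and 90-degree rotation", {
    base <- matrix(0L, 40, 48)
    base[10:26, 8:20] <- 1L
    base[12:30, 14:28] <- 1L
    ann0 <- cellAnnuli(extractCells(base)[[1L]], 5)
    # translate by (+4, +7)
    tr <- matrix(0L, 40, 48)
    tr[cbind(which(base == 1L, arr.ind = TRUE)[, 1L] + 4L,
             which(base == 1L, arr.ind = TRUE)[, 2L] + 7L)] <- 1L
    annT <- cellAnnuli(extractCells(tr)[[1L]], 5)
    shift <- function(px, dr, dc) { px[, 1L] <- px[, 1L] + dr; px[, 2L] <- px[, 2L] + dc; px }
    sortPx <- function(px) px[order(px[, 1L], px[, 2L]), , drop = FALSE]
    expect_equal(sortPx(annT@borderPixels), sortPx(shift(ann0@borderPixels, 4L, 7L)))
    # rotate 90 degrees: (r, c) -> (c, nr + 1 - r)
    nr <- nrow(base)
    rot <- matrix(0L, ncol(base), nr)
    px <- which(base == 1L, arr.ind = TRUE)
    rot[cbind(px[, 2L], nr + 1L - px[, 1L])] <- 1L
    annR <- cellAnnuli(extractCells(rot)[[1L]], 5)
    mapRot <- function(p) cbind(p[, 2L], nr + 1L - p[, 1L])
    expect_equal(unname(sortPx(annR@borderPixels)),
                 unname(sortPx(mapRot(ann0@borderPixels))))
    expect_equal(unname(sortPx(annR@innerPixels)),
                 unname(sortPx(mapRot(ann0@innerPixels))))
})

test_that("chebyshev annuli use the erosion-count distance", {
    # 21x21 square: chebyshev distance to background is min(dist to sides)
    lab <- matrix(0L, 31, 31); lab[6:26, 6:26] <- 1L
    mask <- extractCells(lab)[[1L]]
    ann <- cellAnnuli(mask, 5, metric = "chebyshev")
    px <- which(lab == 1L, arr.ind = TRUE)
    cheb <- pmin(px[, 1L] - 5L, 27L - px[, 1L], px[, 2L] - 5L, 27L - px[, 2L])
    expect_equal(nrow(ann@borderPixels), sum(cheb <= 5))
    expect_equal(nrow(ann@innerPixels), sum(cheb > 5 & cheb <= 10))
})

test_that("fallback Otsu segmentation recovers simulated disks", {
    sim <- simulateField(imageSimSpec(fieldSize = 200L, nCells = 3L,
                                      noiseSigma = 0.5, seed = 9L))
    ns <- normalizeStack(sim$stack)
    lab <- thresholdSegment(ns, minArea = 50L)
    expect_equal(max(lab), 3L)
    # each truth cell maps onto exactly one segmented label
    hits <- mapply(function(r, c) lab[round(r), round(c)],
                   sim$truth$row, sim$truth$col)
    expect_setequal(hits, 1:3)
    # blank field: zero labels with a warning
    blank <- flatStack(rep(30, 15), dim = c(64L, 64L))
    expect_warning(lab0 <- thresholdSegment(blank, minArea = 10L), "component|flat")
    expect_equal(max(lab0), 0L)
    # a cell below minArea is dropped
    lab2 <- diskLabelImage(c(80, 80), rbind(c(20, 20), c(60, 60)), c(12, 3))
    px <- array(30, dim = c(15, 80, 80))
    for (ch in 1:15) { p <- px[ch, , ]; p[lab2 > 0] <- 90; px[ch, , ] <- p }
    st <- hyperspectralStack(px, defaultChannelTable(), normalized = TRUE)
    labS <- thresholdSegment(st, minArea = 50L)
    expect_equal(max(labS), 1L)
    expect_true(labS[20, 20] == 1L && labS[60, 60] == 0L)
})

test_that("8-connected labeling joins diagonal pixels in raster order", {
    fg <- matrix(FALSE, 6, 6)
    fg[1, 1] <- TRUE; fg[2, 2] <- TRUE          # diagonal pair: one component
    fg[5, 5:6] <- TRUE                          # separate component
    lab <- spectroCell:::.labelComponents(fg)
    expect_equal(lab[1, 1], lab[2, 2])
    expect_equal(lab[1, 1], 1L)
    expect_equal(lab[5, 5], 2L)
})
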