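test_that("cell spectra equal masked means, matching the dense convolution oracle under blur", {
    ct <- defaultChannelTable()
    # blur of a constant channel is that constant for any mask
    st <- flatStack(seq(10, 150, by = 10), dim = c(32L, 32L))
    lab <- diskLabelImage(c(32, 32), rbind(c(16, 16)), 6)
    mask <- extractCells(lab)[[1L]]
    expect_equal(unname(cellSpectrum(st, mask, blurSigma = 1)), seq(10, 150, by = 10))
    # blurSigma = 0 is the plain masked mean
    px <- array(0, dim = c(15, 8, 8)); px[, 3, 3] <- 10; px[, 3, 4] <- 20
    st2 <- hyperspectralStack(px, ct, normalized = TRUE)
    img2 <- matrix(0L, 8, 8); img2[3, 3:4] <- 1L
    m2 <- extractCells(img2)[[1L]]
    expect_equal(unname(cellSpectrum(st2, m2, blurSigma = 0)), rep(15, 15))
    # sigma = 1 against the brute-force reflect-padded convolution
    set.seed(5)
    rimg <- matrix(runif(32 * 32, 0, 100), 32, 32)
    px3 <- array(0, dim = c(15, 32, 32))
    for (i in 1:15) px3[i, , ] <- rimg
    st3 <- hyperspectralStack(px3, ct, normalized = TRUE)
    mpx <- rbind(c(5, 5), c(5, 6), c(6, 5), c(20, 20), c(30, 31))
    img3 <- matrix(0L, 32, 32); img3[mpx] <- 1L
    m3 <- extractCells(img3)[[1L]]
    oracle <- mean(bruteGaussianBlur(rimg, 1)[m3@pixels])
    expect_equal(unname(cellSpectrum(st3, m3, blurSigma = 1)[1L]), oracle,
                 tolerance = 1e-9)
    expect_error(cellSpectrum(st3, m3, blurSigma = -1), ">= 0")
})

test_that("morphology: pixel-count areas, principal-axis eccentricity, unit conversion", {
    one <- matrix(0L, 5, 5); one[3, 3] <- 1L
    m1 <- extractCells(one)[[1L]]
    mo <- cellMorphology(m1, pixelSize = 1)
    expect_equal(mo$area_px, 1L)
    expect_equal(mo$area_um2, 1)
    expect_equal(mo$eccentricity, 0)
    # 20x10 axis-aligned rectangle: principal axes are its sides, ecc = 20/10 - 1
    rect <- matrix(0L, 30, 30); rect[6:25, 11:20] <- 1L
    mr <- extractCells(rect)[[1L]]
    expect_equal(cellMorphology(mr)$eccentricity, 1.0)
    expect_equal(cellMorphology(mr)$area_px, 200L)
    # 3x4 rectangle at 0.5 um/px: 12 * 0.25 = 3 um^2
    r34 <- matrix(0L, 10, 10); r34[2:4, 3:6] <- 1L
    expect_equal(cellMorphology(extractCells(r34)[[1L]], pixelSize = 0.5)$area_um2, 3.0)
    # eccentricity is invariant under translation and 90-degree rotation
    rectT <- matrix(0L, 30, 30); rectT[3:22, 15:24] <- 1L
    rect90 <- matrix(0L, 30, 30); rect90[11:20, 6:25] <- 1L
    expect_equal(cellMorphology(extractCells(rectT)[[1L]])$eccentricity, 1.0)
    expect_equal(cellMorphology(extractCells(rect90)[[1L]])$eccentricity, 1.0)
    # area is invariant under any lattice rigid motion (same pixel count)
    expect_equal(cellMorphology(extractCells(rect90)[[1L]])$area_px, 200L)
})

test_that("intensity ratios divide the named channel means", {
    spec <- setNames(rep(30, 15), sprintf("mean_ch%02d", 1:15))
    expect_equal(intensityRatio(spec), 1.0)
    spec["mean_ch04"] <- 60; spec["mean_ch02"] <- 30
    expect_equal(intensityRatio(spec, 4, 2), 2.0)
    spec["mean_ch02"] <- 0
    expect_warning(r <- intensityRatio(spec, 4, 2), "undefined")
    expect_true(is.na(r))
    expect_error(intensityRatio(spec[1:3], 4, 2), "not present")
})

test_that("ring classification thresholds the border/inner log2 fold change", {
    ct <- defaultChannelTable()
    lab <- diskLabelImage(c(64, 64), rbind(c(32, 32)), 25)
    mask <- extractCells(lab)[[1L]]
    mkStack <- function(borderVal, innerVal) {
        d <- bruteDistanceToBackground(lab == 1L)
        img <- matrix(10, 64, 64)
        img[!is.na(d) & d <= 10] <- borderVal
        img[!is.na(d) & d > 10] <- innerVal
        px <- array(10, dim = c(15, 64, 64)); px[13, , ] <- img
        hyperspectralStack(px, ct, normalized = TRUE)
    }
    # equal means: log2fc = 0, unringed
    r0 <- classifyRing(mkStack(40, 40), mask)
    expect_equal(r0$ring_log2fc, 0)
    expect_equal(as.character(r0$ring_call), "unringed")
    # border twice inner: log2fc = 1 > 0.4, ringed
    r1 <- classifyRing(mkStack(80, 40), mask)
    expect_equal(r1$ring_log2fc, 1.0)
    expect_equal(as.character(r1$ring_call), "ringed")
    # equality with the threshold is unringed (strict inequality for ringed):
    # border = 2 x inner gives log2fc exactly 1, tested at threshold 1
    rEq <- classifyRing(mkStack(80, 40), mask, threshold = 1.0)
    expect_equal(rEq$ring_log2fc, 1.0)
    expect_equal(as.character(rEq$ring_call), "unringed")
    # scaling the channel leaves the log fold change unchanged
    stA <- mkStack(77, 41)
    stB <- stA; stB@pixels[13, , ] <- stB@pixels[13, , ] * 5.3
    expect_equal(classifyRing(stB, mask)$ring_log2fc,
                 classifyRing(stA, mask)$ring_log2fc)
    # thin cell: undefined, never dropped
    thin <- extractCells(diskLabelImage(c(30, 30), rbind(c(15, 15)), 8))[[1L]]
    rt <- classifyRing(mkStack(80, 40), thin)
    expect_equal(as.character(rt$ring_call), "undefined")
    expect_true(is.na(rt$ring_log2fc))
})

test_that("feature table assembles fingerprints, morphology, ratio and ring call per cell", {
    sim <- simulateField(imageSimSpec(fieldSize = 200L, nCells = 4L, seed = 21L))
    ns <- normalizeStack(sim$stack)
    ft <- cellFeatureTable(ns, sim$labels)
    expect_equal(nrow(ft), 4L)
    expect_named(ft, c("cell_id", sprintf("mean_ch%02d", 1:15), "area_px",
                       "area_um2", "eccentricity", "ratio_ch04_ch02",
                       "ring_log2fc", "ring_call"))
    expect_true(all(ft$area_px >= 1))
    expect_true(all(as.matrix(ft[, sprintf("mean_ch%02d", 1:15)]) >= 0))
    expect_equal(ft$ring_call == "ringed", sim$truth$ringed)
})

test_that("percentage reporting truncates toward zero", {
    expect_identical(pctFloor(114, 174), 65L)
    expect_identical(pctFloor(60, 174), 34L)
    expect_identical(pctFloor(55, 93), 59L)
    expect_identical(pctFloor(0, 10), 0L)
})
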