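test_that("QC metrics compute totals, detection and prefix fractions", {
    m <- matrix(c(26, 74, 0,
                  0, 50, 50,
                  10, 0, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("MT-CO1", "GAPDH", "RPS6"),
                                c("c1", "c2", "c3")))
    qc <- qcMetrics(m)
    expect_equal(qc$total_reads, c(36, 124, 50))
    expect_equal(qc$n_genes_detected, c(2L, 2L, 1L))
    expect_equal(qc$mt_fraction, c(26 / 36, 74 / 124, 0))
    expect_equal(qc$ribo_fraction, c(10 / 36, 0, 0))
    # a cell with 26% mitochondrial reads is MT-high at the 25% threshold
    m2 <- matrix(c(26, 74), 2, 1, dimnames = list(c("MT-CO1", "GAPDH"), "c1"))
    expect_equal(as.character(qcMetrics(m2)$mt_class), "MT-high")
    expect_equal(qcMetrics(m2)$mt_fraction, 0.26)
    # no MT- genes at all: fraction 0, MT-low
    m3 <- matrix(5, 1, 1, dimnames = list("ACTB", "c1"))
    expect_equal(as.character(qcMetrics(m3)$mt_class), "MT-low")
    expect_warning(qcMetrics(cbind(m, c4 = c(0, 0, 0))), "zero total")
})

test_that("gene filtering keeps genes detected in >= minCells cells", {
    set.seed(4)
    m <- matrix(rbinom(200 * 40, 1, 0.2) * rpois(200 * 40, 5), 200, 40,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:40)))
    kept <- filterGenes(m, 10L)
    # brute-force nonzero scan
    expect_setequal(rownames(kept), rownames(m)[rowSums(m > 0) >= 10])
    # boundary: 9 expressing cells dropped, 10 kept
    mb <- rbind(nine = c(rep(1, 9), rep(0, 11)), ten = c(rep(1, 10), rep(0, 10)))
    expect_equal(rownames(filterGenes(mb, 10L)), "ten")
    # minCells = 1 drops only all-zero genes
    expect_equal(nrow(filterGenes(mb, 1L)), 2L)
    mz <- rbind(mb, zero = rep(0, 20))
    expect_equal(rownames(filterGenes(mz, 1L)), c("nine", "ten"))
})

test_that("CPM columns sum to one million and scale counts per cell", {
    m <- matrix(c(1, 3, 2, 2), 2, 2, dimnames = list(c("a", "b"), c("c1", "c2")))
    cpm <- cpmNormalize(m)
    expect_equal(cpm[, "c1"], c(a = 250000, b = 750000))
    expect_equal(unname(colSums(cpm)), rep(1e6, 2))
    set.seed(6)
    mr <- matrix(rpois(300, 4) + 1, 30, 10)
    expect_equal(unname(colSums(cpmNormalize(mr))), rep(1e6, 10))
    expect_warning(cpmNormalize(cbind(m, c3 = c(0, 0))), "zero-total")
})

test_that("signed KS statistics carry the direction of the group difference", {
    cpm <- rbind(flat = rep(5, 12),
                 up = c(rep(10, 6), rep(2, 6)),
                 gene3 = c(1, 2, 3, 1, 2, 3, 4, 5, 6, 4, 5, 6))
    colnames(cpm) <- sprintf("c%02d", 1:12)
    de <- signedKsDE(cpm, 1:6, 7:12, medianFilter = FALSE)
    # identical distributions: D = 0, signed 0, p = 1
    expect_equal(de$signed_ks[1L], 0)
    expect_equal(de$p[1L], 1)
    # group A larger: positive sign, D = 1
    expect_equal(de$signed_ks[2L], 1)
    expect_equal(de$log2_fc[2L], log2(11 / 3))
    # spec example {1,2,3} vs {4,5,6}: D = 1, negative sign, exact p = 2/20
    deX <- signedKsDE(rbind(g = c(1, 2, 3, 4, 5, 6)),
                      1:3, 4:6, medianFilter = FALSE)
    expect_equal(deX$signed_ks, -1)
    expect_equal(deX$p, 0.10)
    expect_error(signedKsDE(cpm, 1:2, 3:12), ">= 3 cells")
    expect_error(signedKsDE(cpm, 1:6, 5:12), "disjoint")
})

test_that("exact KS p-values match the exhaustive permutation oracle", {
    set.seed(13)
    for (sizes in list(c(3, 3), c(4, 5), c(5, 5), c(4, 4))) {
        for (rep in 1:3) {
            a <- round(rexp(sizes[1L], 0.2))          # ties likely
            b <- round(rexp(sizes[2L], 0.1))
            D <- spectroCell:::.ksStat(a, b)
            expect_equal(spectroCell:::.ksPvalue(a, b, D),
                         bruteKsPermutationP(a, b),
                         tolerance = 1e-12,
                         info = paste(sizes, collapse = "x"))
        }
    }
})

test_that("the zero-median filter removes genes from testing and BH correction", {
    set.seed(14)
    cpm <- rbind(good = rpois(20, 20) + 1,
                 sparse = c(rep(0, 8), rpois(12, 3)))
    colnames(cpm) <- sprintf("c%02d", 1:20)
    de <- signedKsDE(cpm, 1:10, 11:20)
    expect_false(de$filtered[1L])
    expect_true(de$filtered[2L])      # median 0 in group A
    expect_true(is.na(de$p[2L]) && is.na(de$q[2L]))
    expect_match(de$filter_reason[2L], "median")
})

test_that("BH adjustment reproduces hand step-up values and is monotone in discoveries", {
    expect_equal(bhAdjust(0.04), 0.04)
    # hand step-up: 0.03*3/3, 0.02*3/2, 0.01*3/1, then cumulative min
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(15)
    for (i in 1:20) {
        p <- runif(30)
        expect_equal(bhAdjust(p), bruteBH(p))
        # shrinking one p-value never loses discoveries
        p2 <- p; j <- sample(30, 1); p2[j] <- p2[j] / 2
        expect_gte(sum(bhAdjust(p2) <= 0.1), sum(bhAdjust(p) <= 0.1))
    }
})

test_that("exon usage fractions are per-gene conditional frequencies", {
    m <- rbind("GA:1" = c(2, 0, 5),
               "GA:2" = c(6, 0, 5),
               "SOLO:1" = c(3, 7, 0))
    colnames(m) <- c("c1", "c2", "c3")
    u <- exonUsage(m)
    expect_equal(u["GA:1", "c1"], 0.25)
    expect_equal(u["GA:2", "c1"], 0.75)
    expect_true(all(is.na(u[c("GA:1", "GA:2"), "c2"])))
    expect_equal(u["SOLO:1", "c1"], 1.0)   # single-exon gene: usage 1
    expect_true(is.na(u["SOLO:1", "c3"]))
    # conservation: per gene per expressing cell the fractions sum to 1
    set.seed(16)
    keys <- paste0(rep(sprintf("g%02d", 1:8), times = rep(c(2, 3, 4, 1), 2)),
                   ":", unlist(lapply(rep(c(2, 3, 4, 1), 2), seq_len)))
    mr <- matrix(rpois(length(keys) * 12, 3), length(keys), 12,
                 dimnames = list(keys, sprintf("c%02d", 1:12)))
    ur <- exonUsage(mr)
    genes <- sub(":[0-9]+$", "", keys)
    for (g in unique(genes)) {
        s <- colSums(ur[genes == g, , drop = FALSE])
        expect_true(all(is.na(s) | abs(s - 1) < 1e-12))
    }
    expect_error(exonUsage(rbind(badkey = c(1, 2))), "malformed|rownames")
    expect_error(exonUsage(rbind("g:x" = c(1, 2))), "positive integer")
})
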