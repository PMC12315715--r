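# Accept a plain matrix or a SummarizedExperiment (first assay).
.countsMatrix <- function(counts) {
    if (is(counts, "SummarizedExperiment")) {
        if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
            stop("the SummarizedExperiment package is needed for this input type")
        counts <- SummarizedExperiment::assay(counts)
    }
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    counts
}

#' Per-cell quality-control metrics
#'
#' Computes, for every cell (column), the total read count, the number of
#' detected genes (count > 0), and the fractions of reads in mitochondrial
#' and ribosomal genes (matched by gene-symbol prefix; human defaults
#' `MT-` and `RPS`/`RPL`). Cells whose mitochondrial fraction exceeds
#' `mtThreshold` (default 0.25) are classed `MT-high`, a low-viability
#' indicator; the rest are `MT-low`. Zero-total cells are flagged and their
#' fractions left undefined.
#'
#' @param counts gene x cell count matrix (or SummarizedExperiment), rows
#'   named by gene symbol.
#' @param mtPrefix,riboPrefixes gene-symbol prefixes; pass explicit gene
#'   name vectors via `mtGenes`/`riboGenes` for other organisms.
#' @param mtThreshold mitochondrial-fraction cutoff for `MT-high`.
#' @param mtGenes,riboGenes optional explicit gene sets overriding the
#'   prefixes.
#' @return data.frame with one row per cell: `cell_id`, `total_reads`,
#'   `n_genes_detected`, `mt_fraction`, `ribo_fraction`, `mt_class`.
#' @export
qcMetrics <- function(counts, mtPrefix = "MT-", riboPrefixes = c("RPS", "RPL"),
                      mtThreshold = 0.25, mtGenes = NULL, riboGenes = NULL) {
    m <- .countsMatrix(counts)
    g <- rownames(m)
    if (is.null(g)) stop("count matrix must have gene-symbol rownames")
    isMT <- if (is.null(mtGenes)) startsWith(g, mtPrefix) else g %in% mtGenes
    isRibo <- if (is.null(riboGenes))
        Reduce(`|`, lapply(riboPrefixes, function(p) startsWith(g, p)))
    else g %in% riboGenes
    tot <- colSums(m)
    mtFrac <- ifelse(tot > 0, colSums(m[isMT, , drop = FALSE]) / tot, NA_real_)
    riboFrac <- ifelse(tot > 0, colSums(m[isRibo, , drop = FALSE]) / tot, NA_real_)
    if (any(tot == 0)) warning(sum(tot == 0), " cell(s) with zero total reads")
    data.frame(
        cell_id = colnames(m) %||% as.character(seq_len(ncol(m))),
        total_reads = tot,
        n_genes_detected = colSums(m > 0),
        mt_fraction = mtFrac,
        ribo_fraction = riboFrac,
        mt_class = factor(ifelse(is.na(mtFrac), NA,
                                 ifelse(mtFrac > mtThreshold, "MT-high", "MT-low")),
                          levels = c("MT-low", "MT-high")),
        row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop genes detected in too few cells
#'
#' Keeps features with a positive count in at least `minCells` cells
#' (default 10): genes expressed in fewer than 10 cells are excluded.
#'
#' @param counts feature x cell count matrix (or SummarizedExperiment).
#' @param minCells minimum number of expressing cells.
#' @return the filtered matrix.
#' @export
filterGenes <- function(counts, minCells = 10L) {
    m <- .countsMatrix(counts)
    m[rowSums(m > 0) >= minCells, , drop = FALSE]
}

#' Counts-per-million normalization
#'
#' Divides each cell's counts by its total and multiplies by 1,000,000, so
#' every column of the result sums to 1e6. Zero-total cells are dropped with
#' a warning.
#'
#' @param counts feature x cell count matrix (or SummarizedExperiment).
#' @return numeric CPM matrix.
#' @export
cpmNormalize <- function(counts) {
    m <- .countsMatrix(counts)
    tot <- colSums(m)
    if (any(tot == 0)) {
        warning(sum(tot == 0), " zero-total cell(s) excluded from CPM")
        m <- m[, tot > 0, drop = FALSE]
        tot <- tot[tot > 0]
    }
    sweep(m, 2L, tot, `/`) * 1e6
}

# two-sample KS statistic D = sup |ECDF_a - ECDF_b| (tie-aware)
.ksStat <- function(a, b) {
    z <- sort(unique(c(a, b)))
    Fa <- stats::ecdf(a)(z)
    Fb <- stats::ecdf(b)(z)
    max(abs(Fa - Fb))
}

# asymptotic two-sided two-sample KS p-value (Kolmogorov series)
.ksAsymptoticP <- function(D, n, m) {
    lambda <- sqrt(n * m / (n + m)) * D
    if (lambda == 0) return(1)
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    min(max(p, 0), 1)
}

# two-sided p-value: permutation-exact (tie-aware, via psmirnov) for small
# groups, asymptotic otherwise
.ksPvalue <- function(a, b, D, exactMax = 8L) {
    n <- length(a); m <- length(b)
    if (min(n, m) <= exactMax) {
        p <- stats::psmirnov(D - 1e-12, sizes = c(n, m), z = c(a, b),
                             two.sided = TRUE, lower.tail = FALSE)
        min(max(p, 0), 1)
    } else {
        .ksAsymptoticP(D, n, m)
    }
}

#' Signed Kolmogorov-Smirnov differential expression
#'
#' For every gene, compares CPM values between two disjoint cell groups with
#' a two-sided two-sample KS test. The signed statistic is the KS `D` given
#' the sign of `mean(group A) - mean(group B)` (a directional effect axis
#' for volcano-style plots); the fold change is
#' `log2((mean_A + pseudocount) / (mean_B + pseudocount))`. Genes whose
#' median CPM is zero in either group are marked filtered and excluded from
#' testing and from the BH correction (the paper's volcano filter).
#' P-values are permutation-exact for `min(nA, nB) <= 8` and use the
#' asymptotic Kolmogorov distribution otherwise.
#'
#' @param cpm CPM matrix (features x cells) as from [cpmNormalize()].
#' @param groupA,groupB disjoint cell id (column name) or index vectors,
#'   each of at least 3 cells.
#' @param medianFilter apply the zero-median filter.
#' @param fcPseudocount pseudocount in the fold-change estimator.
#' @param signBy `"mean"` (default) or `"median"`: which location difference
#'   sets the sign of the signed statistic.
#' @return data.frame per gene: `gene`, `log2_fc`, `signed_ks`, `p`, `q`
#'   (BH over unfiltered genes), `filtered`, `filter_reason`.
#' @export
signedKsDE <- function(cpm, groupA, groupB, medianFilter = TRUE,
                       fcPseudocount = 1, signBy = c("mean", "median")) {
    signBy <- match.arg(signBy)
    cpm <- as.matrix(cpm)
    idx <- function(g) if (is.character(g)) match(g, colnames(cpm)) else as.integer(g)
    ia <- idx(groupA); ib <- idx(groupB)
    if (anyNA(ia) || anyNA(ib)) stop("unknown cell ids in group definition")
    if (length(ia) < 3L || length(ib) < 3L) stop("both groups need >= 3 cells")
    if (length(intersect(ia, ib))) stop("groups must be disjoint")
    A <- cpm[, ia, drop = FALSE]; B <- cpm[, ib, drop = FALSE]
    ng <- nrow(cpm)
    res <- data.frame(
        gene = rownames(cpm) %||% as.character(seq_len(ng)),
        log2_fc = NA_real_, signed_ks = NA_real_, p = NA_real_, q = NA_real_,
        filtered = FALSE, filter_reason = "", row.names = NULL)
    for (i in seq_len(ng)) {
        a <- A[i, ]; b <- B[i, ]
        ma <- mean(a); mb <- mean(b)
        res$log2_fc[i] <- log2((ma + fcPseudocount) / (mb + fcPseudocount))
        if (medianFilter && (stats::median(a) == 0 || stats::median(b) == 0)) {
            res$filtered[i] <- TRUE
            res$filter_reason[i] <- "zero median in a group"
            next
        }
        D <- .ksStat(a, b)
        loc <- if (signBy == "mean") ma - mb else stats::median(a) - stats::median(b)
        res$signed_ks[i] <- D * sign(loc)
        res$p[i] <- .ksPvalue(a, b, D)
    }
    keep <- !res$filtered
    res$q[keep] <- bhAdjust(res$p[keep])
    res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement
#' (delegates to [stats::p.adjust()]); input p-values are validated to lie
#' in `[0, 1]`.
#'
#' @param p numeric vector of p-values.
#' @return vector of q-values in `[0, 1]`.
#' @export
bhAdjust <- function(p) {
    if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

# split "geneID:exonIndex" keys; errors name the offending row
.parseExonKeys <- function(keys) {
    pos <- regexpr(":[^:]*$", keys)
    bad <- which(pos < 1L)
    if (length(bad))
        stop("malformed exon key (expected geneID:exonIndex) in row: ", keys[bad[1L]])
    gene <- substr(keys, 1L, pos - 1L)
    exon <- suppressWarnings(as.integer(substring(keys, pos + 1L)))
    bad <- which(is.na(exon) | exon < 1L)
    if (length(bad))
        stop("exon index must be a positive integer in row: ", keys[bad[1L]])
    data.frame(gene = gene, exon = exon)
}

#' Per-exon usage fractions
#'
#' For flattened exon counts keyed `geneID:exonIndex`, computes within each
#' gene and cell the fraction of the gene's reads assigned to each exon.
#' Fractions are `NA` for cells where the gene's total is zero; over
#' expressing (gene, cell) pairs they sum to 1 across the gene's exons.
#'
#' @param exonCounts exon x cell count matrix (or SummarizedExperiment) with
#'   `geneID:exonIndex` rownames.
#' @return numeric matrix of the same shape with usage fractions.
#' @export
exonUsage <- function(exonCounts) {
    m <- .countsMatrix(exonCounts)
    keys <- rownames(m)
    if (is.null(keys)) stop("exon count matrix must have geneID:exonIndex rownames")
    info <- .parseExonKeys(keys)
    out <- m * NA_real_
    for (g in unique(info$gene)) {
        rows <- which(info$gene == g)
        tot <- colSums(m[rows, , drop = FALSE])
        frac <- sweep(m[rows, , drop = FALSE], 2L, tot, `/`)
        frac[, tot == 0] <- NA_real_
        out[rows, ] <- frac
    }
    out
}
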