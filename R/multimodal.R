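# Spearman rho with average ranks plus the two-sided t-approximation p-value
.spearman <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
        return(c(rho = NA_real_, p = NA_real_, n = n))
    rho <- stats::cor(rank(x), rank(y))
    if (abs(rho) >= 1) {
        p <- 0
    } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    c(rho = rho, p = p, n = n)
}

#' Correlate an imaging feature with gene expression
#'
#' Spearman correlation (average ranks; two-sided p by the t-approximation)
#' between one per-cell feature and every gene's CPM, restricted to a chosen
#' cell subset — by default the analysis runs on viable (MT-low) cells only,
#' passed via `cells`. Genes expressed (CPM > 0) in fewer than `minCells` of
#' the selected cells are excluded; a constant feature yields missing rho.
#'
#' @param feature named numeric vector of per-cell feature values (e.g. cell
#'   area or a channel intensity).
#' @param cpm CPM matrix (genes x cells).
#' @param cells cell ids/indices to use; `NULL` for all cells in `feature`.
#' @param minCells minimum number of expressing cells per gene (default 10).
#' @return data.frame per retained gene: `gene`, `rho`, `p`, `n`.
#' @export
featureExpressionCorrelation <- function(feature, cpm, cells = NULL,
                                         minCells = 10L) {
    cpm <- as.matrix(cpm)
    if (is.null(cells)) cells <- names(feature) %||% seq_along(feature)
    f <- feature[cells]   # name lookup for character ids, positional otherwise
    m <- cpm[, cells, drop = FALSE]
    if (anyNA(f)) stop("feature undefined for some selected cells")
    keep <- rowSums(m > 0) >= minCells
    m <- m[keep, , drop = FALSE]
    res <- t(apply(m, 1L, function(expr) .spearman(f, expr)))
    data.frame(gene = rownames(m) %||% as.character(which(keep)),
               rho = res[, "rho"], p = res[, "p"], n = as.integer(res[, "n"]),
               row.names = NULL)
}

#' Order cells by a feature and cut into fixed-size bins
#'
#' Cells are sorted ascending by feature value (ties broken by cell id) and
#' grouped into consecutive bins of `binSize` (default 15); the last bin
#' holds the remainder. 117 cells thus give seven bins of 15 and a final
#' bin of 12 — the layout used for expression-versus-size box plots.
#'
#' @param feature named (or plain) numeric vector of per-cell values.
#' @param binSize cells per bin.
#' @return list with `order` (cell ids in ascending feature order), `bin`
#'   (bin index per ordered cell) and `sizes` (bin sizes).
#' @export
binCells <- function(feature, binSize = 15L) {
    if (binSize < 1L) stop("binSize must be >= 1")
    n <- length(feature)
    ids <- names(feature) %||% as.character(seq_len(n))
    o <- order(feature, ids)
    bin <- ceiling(seq_len(n) / binSize)
    list(order = ids[o], bin = as.integer(bin),
         sizes = as.integer(tabulate(bin)))
}

#' Per-bin summaries of expression along a feature
#'
#' Convenience export for box-plot style displays: bins cells with
#' [binCells()] and reports per-bin median and quartiles of a gene's values.
#'
#' @param values named per-cell numeric vector (e.g. one gene's CPM).
#' @param feature named per-cell feature used for ordering.
#' @param binSize cells per bin.
#' @return data.frame: `bin`, `n`, `q1`, `median`, `q3`.
#' @export
binSummary <- function(values, feature, binSize = 15L) {
    bs <- binCells(feature, binSize)
    v <- values[bs$order]
    agg <- tapply(v, bs$bin, function(x)
        stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE))
    data.frame(bin = as.integer(names(agg)),
               n = bs$sizes,
               q1 = vapply(agg, `[`, numeric(1L), 1L),
               median = vapply(agg, `[`, numeric(1L), 2L),
               q3 = vapply(agg, `[`, numeric(1L), 3L),
               row.names = NULL)
}

#' Extreme exon-usage correlations per gene
#'
#' For every gene, correlates each exon's usage fraction with a per-cell
#' feature (Spearman) over the cells expressing the gene, and reports the
#' minimum and maximum coefficient and the exons attaining them. Genes
#' expressed in fewer than `minCells` cells, and exons with constant usage
#' (e.g. the single exon of a one-exon gene), are excluded.
#'
#' @param usage exon-usage fraction matrix from [exonUsage()] (rows
#'   `geneID:exonIndex`).
#' @param feature named per-cell numeric vector.
#' @param cells cell ids/indices to use; `NULL` for all.
#' @param minCells minimum number of expressing cells per gene.
#' @return data.frame per gene: `gene`, `min_rho`, `max_rho`, `argmin_exon`,
#'   `argmax_exon`, `n_exons_tested`.
#' @export
exonCorrelationExtremes <- function(usage, feature, cells = NULL,
                                    minCells = 10L) {
    usage <- as.matrix(usage)
    if (is.null(cells)) cells <- colnames(usage) %||% seq_len(ncol(usage))
    u <- usage[, cells, drop = FALSE]
    f <- feature[cells]
    info <- .parseExonKeys(rownames(u))
    out <- list()
    for (g in unique(info$gene)) {
        rows <- which(info$gene == g)
        expressed <- !is.na(u[rows[1L], ])
        if (sum(expressed) < minCells) next
        rhos <- vapply(rows, function(r)
            .spearman(f[expressed], u[r, expressed])[["rho"]], numeric(1L))
        ok <- !is.na(rhos)
        if (!any(ok)) next
        rhos <- rhos[ok]; ex <- info$exon[rows][ok]
        out[[g]] <- data.frame(
            gene = g, min_rho = min(rhos), max_rho = max(rhos),
            argmin_exon = ex[which.min(rhos)], argmax_exon = ex[which.max(rhos)],
            n_exons_tested = length(rhos))
    }
    if (!length(out))
        return(data.frame(gene = character(), min_rho = numeric(),
                          max_rho = numeric(), argmin_exon = integer(),
                          argmax_exon = integer(), n_exons_tested = integer()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Label-shuffle permutation test
#'
#' Tests whether a per-cell value (by default its absolute group-mean
#' difference, the statistic used for the mitochondrial-fraction check
#' between ringed and unringed cells) differs between two labelled groups,
#' against `nPerm` random shuffles of the labels. Reports the raw number of
#' shuffles strictly exceeding the observed statistic alongside the
#' add-one-corrected empirical p-value `(exceed + 1) / (nPerm + 1)`. With a
#' fixed `seed` the shuffle sequence, and hence the result, is reproducible
#' bit for bit.
#'
#' @param values per-cell numeric vector.
#' @param labels two-level factor/vector aligned with `values`.
#' @param statistic function of `(values, labels)` returning a scalar;
#'   default absolute difference of group means.
#' @param nPerm number of shuffles (default 1000).
#' @param seed optional RNG seed (the global RNG state is restored on exit).
#' @return list: `observed`, `exceed_count`, `empirical_p`, `n_perm`.
#' @export
permutationTest <- function(values, labels, statistic = NULL, nPerm = 1000L,
                            seed = NULL) {
    if (nPerm < 1L) stop("nPerm must be >= 1")
    labels <- factor(labels)
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    if (any(table(labels) == 0L)) stop("both groups must be nonempty")
    if (is.null(statistic))
        statistic <- function(v, l) {
            mm <- tapply(v, l, mean)
            abs(mm[[1L]] - mm[[2L]])
        }
    obs <- statistic(values, labels)
    if (obs == 0) warning("observed statistic is 0; test is degenerate")
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        } else {
            on.exit(rm(".Random.seed", envir = globalenv()))
        }
        set.seed(seed)
    }
    perm <- vapply(seq_len(nPerm), function(i)
        statistic(values, sample(labels)), numeric(1L))
    exceed <- sum(perm > obs)
    list(observed = unname(obs), exceed_count = exceed,
         empirical_p = (exceed + 1) / (nPerm + 1), n_perm = as.integer(nPerm))
}
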