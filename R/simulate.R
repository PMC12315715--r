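# All simulator randomness flows from one spec-level seed; named substreams
# (placement, brightness, noise, counts, ...) get fixed offsets so partial
# re-runs are stable.
.withSubstream <- function(seed, offset, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed((seed + offset) %% .Machine$integer.max)
    force(expr)
}

#' Specification of a simulated hyperspectral field
#'
#' Defaults emulate the imaged study conditions: a 15-channel field of
#' disk-shaped cells on a noisy background whose modal count is 30, two
#' spectrally distinct cell populations (blue-weighted and red-weighted
#' fingerprints, separated by several within-population standard
#' deviations), and a sub-population carrying a bright plasma-membrane ring
#' in channel 13 with a planted border/inner log2 fold change of 1.
#'
#' @param fieldSize field side length in pixels.
#' @param nCells number of cells to place (non-overlapping, >= 2 px from the
#'   field edge).
#' @param radiusRange inclusive integer range of disk radii (px); the lower
#'   bound keeps cells thick enough that a 10 px border annulus still leaves
#'   a nonempty inner annulus.
#' @param ringFraction fraction of cells carrying a membrane ring (default
#'   0.34, the ringed share reported for the imaged cells).
#' @param ringChannel channel carrying the ring (default 13).
#' @param ringLog2fc planted border/inner log2 fold change.
#' @param ringThickness ring depth from the cell boundary (px).
#' @param background background intensity level (camera counts).
#' @param noiseSigma Gaussian pixel noise sigma.
#' @param popBrightness list of per-channel brightness vectors (one per
#'   population, added on top of the background inside cells).
#' @param popFractions population mixing fractions.
#' @param brightnessJitter per-cell multiplicative brightness sd.
#' @param seed integer seed driving all substreams.
#' @return an `ImageSimSpec` list.
#' @export
imageSimSpec <- function(fieldSize = 256L, nCells = 12L, radiusRange = c(14L, 20L),
                         ringFraction = 0.34, ringChannel = 13L, ringLog2fc = 1,
                         ringThickness = 10, background = 30, noiseSigma = 0.5,
                         popBrightness = NULL, popFractions = c(0.5, 0.5),
                         brightnessJitter = 0.05, seed = 1L) {
    if (is.null(popBrightness)) {
        # blue-weighted and red-weighted fingerprints; the ~40-count contrast
        # against a ~2-count per-cell jitter gives well-separated populations
        popBrightness <- list(
            c(rep(60, 8), rep(20, 7)),
            c(rep(20, 8), rep(60, 7)))
    }
    stopifnot(ringFraction >= 0, ringFraction <= 1,
              length(popFractions) == length(popBrightness),
              abs(sum(popFractions) - 1) < 1e-9)
    structure(list(fieldSize = as.integer(fieldSize), nCells = as.integer(nCells),
                   radiusRange = as.integer(radiusRange),
                   ringFraction = ringFraction, ringChannel = as.integer(ringChannel),
                   ringLog2fc = ringLog2fc, ringThickness = ringThickness,
                   background = background, noiseSigma = noiseSigma,
                   popBrightness = popBrightness, popFractions = popFractions,
                   brightnessJitter = brightnessJitter, seed = as.integer(seed)),
              class = "ImageSimSpec")
}

#' Simulate a hyperspectral field with planted ground truth
#'
#' Places non-overlapping disk cells (radii drawn from `radiusRange`,
#' centres at least 2 px plus one radius from the field edge), assigns each
#' a population brightness vector with per-cell multiplicative jitter, and
#' for ringed cells multiplies the ring-channel intensity of pixels within
#' `ringThickness` of the disk boundary by `2^ringLog2fc`. Gaussian noise is
#' added and intensities are clamped at zero. The same seed reproduces the
#' stack bit for bit.
#'
#' @param spec an [imageSimSpec()] list.
#' @param channels a [ChannelTable-class] (its size sets the channel count).
#' @return list: `stack` (raw [HyperspectralStack-class]), `labels` (truth
#'   label image), `truth` (data.frame: `cell_id`, `population`, `ringed`,
#'   `radius`, `row`, `col`).
#' @export
simulateField <- function(spec = imageSimSpec(), channels = defaultChannelTable()) {
    stopifnot(inherits(spec, "ImageSimSpec"))
    nch <- length(channels@channel)
    stopifnot(all(vapply(spec$popBrightness, length, integer(1L)) == nch))
    fs <- spec$fieldSize

    placement <- .withSubstream(spec$seed, 101L, {
        radii <- sample(seq(spec$radiusRange[1L], spec$radiusRange[2L]),
                        spec$nCells, replace = TRUE)
        centers <- matrix(NA_real_, spec$nCells, 2L)
        for (i in seq_len(spec$nCells)) {
            placed <- FALSE
            for (try in seq_len(2000L)) {
                margin <- radii[i] + 2L
                cand <- stats::runif(2L, margin + 1L, fs - margin)
                if (i == 1L || all(sqrt(rowSums(sweep(centers[seq_len(i - 1L), ,
                        drop = FALSE], 2L, cand)^2)) >
                        radii[seq_len(i - 1L)] + radii[i] + 3L)) {
                    centers[i, ] <- cand
                    placed <- TRUE
                    break
                }
            }
            if (!placed)
                stop("could not place ", spec$nCells, " non-overlapping cells; ",
                     "reduce nCells or enlarge fieldSize")
        }
        nRing <- round(spec$ringFraction * spec$nCells)
        ringed <- seq_len(spec$nCells) %in% sample(spec$nCells, nRing)
        pop <- sample(length(spec$popBrightness), spec$nCells, replace = TRUE,
                      prob = spec$popFractions)
        list(radii = radii, centers = centers, ringed = ringed, pop = pop)
    })

    jitter <- .withSubstream(spec$seed, 202L,
        stats::rnorm(spec$nCells, 1, spec$brightnessJitter))

    px <- array(spec$background, dim = c(nch, fs, fs))
    labels <- matrix(0L, fs, fs)
    rr <- matrix(rep(seq_len(fs), fs), fs, fs)
    cc <- t(rr)
    for (i in seq_len(spec$nCells)) {
        d2 <- (rr - placement$centers[i, 1L])^2 + (cc - placement$centers[i, 2L])^2
        inside <- d2 <= placement$radii[i]^2
        labels[inside] <- i
        bright <- spec$popBrightness[[placement$pop[i]]] * max(jitter[i], 0.2)
        idx <- which(inside)
        for (ch in seq_len(nch)) {
            plane <- px[ch, , ]
            plane[idx] <- plane[idx] + bright[ch]
            if (placement$ringed[i] && ch == spec$ringChannel) {
                ring <- inside & d2 > (placement$radii[i] - spec$ringThickness)^2
                plane[which(ring)] <- plane[which(ring)] * 2^spec$ringLog2fc
            }
            px[ch, , ] <- plane
        }
    }

    noise <- .withSubstream(spec$seed, 303L,
        array(stats::rnorm(length(px), 0, spec$noiseSigma), dim = dim(px)))
    px <- pmax(px + noise, 0)

    truth <- data.frame(cell_id = seq_len(spec$nCells),
                        population = placement$pop,
                        ringed = placement$ringed,
                        radius = placement$radii,
                        row = placement$centers[, 1L],
                        col = placement$centers[, 2L])
    list(stack = hyperspectralStack(px, channels, normalized = FALSE),
         labels = labels, truth = truth)
}

#' Specification of a simulated count matrix
#'
#' Defaults emulate the sequenced study conditions: 117 viable (MT-low)
#' cells, negative-binomial gene counts, a handful of mitochondrial genes
#' tuned to each cell's drawn mitochondrial fraction, genes whose expression
#' rank is coupled to a per-cell feature through a Gaussian copula at stated
#' Spearman targets, optional group-shift (differentially expressed) genes,
#' and exon tables with planted usage gradients along the feature.
#'
#' @param nCells number of cells (default 117).
#' @param nNullGenes number of undifferentiated background genes.
#' @param plantedRho named numeric vector of Spearman targets in (-1, 1);
#'   names become gene ids (default: none).
#' @param muRange log-uniform range of NB means for background genes.
#' @param plantedMuRange NB-mean range for planted-correlation genes
#'   (moderately expressed, so rank ties at zero stay rare).
#' @param dispersion NB size parameter (constant per gene, drawn uniformly
#'   from this range).
#' @param nMtGenes number of `MT-` genes.
#' @param mtBeta Beta(a, b) parameters of the per-cell mitochondrial
#'   fraction (default c(2, 8), mean 0.2 — a mostly viable population).
#' @param deGenes named numeric vector of log2 fold changes planted between
#'   two cell groups (applied to cells in `deGroup`).
#' @param exonGradients data.frame(`gene`, `nExons`, `upExon`, `downExon`)
#'   of planted exon-usage gradients; `NULL` for the default two demo genes.
#' @param nNullExonGenes extra exon-level genes with feature-independent
#'   usage.
#' @param seed integer seed.
#' @return a `CountsSimSpec` list.
#' @export
countsSimSpec <- function(nCells = 117L, nNullGenes = 200L, plantedRho = NULL,
                          muRange = c(5, 500), plantedMuRange = c(50, 200),
                          dispersion = c(0.5, 2), nMtGenes = 5L,
                          mtBeta = c(2, 8), deGenes = NULL,
                          exonGradients = NULL, nNullExonGenes = 10L,
                          seed = 1L) {
    if (!is.null(plantedRho)) {
        stopifnot(all(abs(plantedRho) < 1))
        if (is.null(names(plantedRho)))
            names(plantedRho) <- sprintf("CORR%03d", seq_along(plantedRho))
    }
    if (is.null(exonGradients))
        exonGradients <- data.frame(gene = c("GRAD1", "GRAD2"),
                                    nExons = c(3L, 4L),
                                    upExon = c(1L, 2L), downExon = c(3L, 4L))
    structure(list(nCells = as.integer(nCells), nNullGenes = as.integer(nNullGenes),
                   plantedRho = plantedRho, muRange = muRange,
                   plantedMuRange = plantedMuRange, dispersion = dispersion,
                   nMtGenes = as.integer(nMtGenes), mtBeta = mtBeta,
                   deGenes = deGenes, exonGradients = exonGradients,
                   nNullExonGenes = as.integer(nNullExonGenes),
                   seed = as.integer(seed)),
              class = "CountsSimSpec")
}

# NB draw whose rank is coupled to the latent standard normal z at Pearson
# latent correlation r (Gaussian copula): count = F_NB^{-1}(Phi(latent))
.copulaNB <- function(z, r, mu, size) {
    eps <- stats::rnorm(length(z))
    latent <- r * z + sqrt(1 - r^2) * eps
    stats::qnbinom(stats::pnorm(latent), size = size, mu = mu)
}

#' Simulate gene- and exon-level counts with planted ground truth
#'
#' Background genes are independent negative binomials. For each planted
#' gene with Spearman target `rho_s`, the latent-normal correlation is
#' `2 sin(pi rho_s / 6)` against the normal score of the feature's rank, and
#' counts are the NB quantile transform of the coupled latent — marginally
#' NB, rank-correlated with the feature at the target. Mitochondrial gene
#' means are set per cell so the expected mitochondrial fraction matches a
#' Beta draw. Optional DE genes multiply the NB mean by `2^lfc` for cells in
#' `deGroup`. Exon counts are multinomial within each gene; planted
#' gradient genes shift usage probability linearly (by +/- 0.4) along the
#' feature percentile for their up/down exons.
#'
#' @param spec a [countsSimSpec()] list.
#' @param feature per-cell numeric vector (length `nCells`) the copula and
#'   exon gradients are tied to; default a log-normal cell-size surrogate.
#' @param deGroup logical vector marking the cells carrying the planted DE
#'   shift (required when `spec$deGenes` is set).
#' @return list: `genes` (count matrix), `exons` (count matrix keyed
#'   `gene:exon`), `truth` (per-gene data.frame), `exonTruth`, `feature`,
#'   `mtFraction` (per-cell drawn target).
#' @export
simulateCounts <- function(spec = countsSimSpec(), feature = NULL,
                           deGroup = NULL) {
    stopifnot(inherits(spec, "CountsSimSpec"))
    n <- spec$nCells
    if (is.null(feature))
        feature <- .withSubstream(spec$seed, 11L, stats::rlnorm(n, 5, 0.4))
    stopifnot(length(feature) == n)
    if (!is.null(spec$deGenes)) stopifnot(length(deGroup) == n)
    cellIds <- sprintf("cell%03d", seq_len(n))
    zf <- stats::qnorm((rank(feature, ties.method = "average") - 0.5) / n)

    .withSubstream(spec$seed, 22L, {
        geneRows <- list()
        truth <- list()
        addGene <- function(name, counts, type, targetRho = NA_real_,
                            lfc = NA_real_, mu, size) {
            geneRows[[name]] <<- counts
            truth[[name]] <<- data.frame(gene = name, type = type,
                                         target_rho = targetRho, log2fc = lfc,
                                         mu = mu, size = size)
        }
        for (i in seq_len(spec$nNullGenes)) {
            mu <- exp(stats::runif(1, log(spec$muRange[1L]), log(spec$muRange[2L])))
            size <- stats::runif(1, spec$dispersion[1L], spec$dispersion[2L])
            addGene(sprintf("GENE%04d", i),
                    stats::rnbinom(n, size = size, mu = mu), "null",
                    mu = mu, size = size)
        }
        if (!is.null(spec$plantedRho)) {
            for (g in names(spec$plantedRho)) {
                rho <- spec$plantedRho[[g]]
                r <- 2 * sin(pi * rho / 6)
                mu <- stats::runif(1, spec$plantedMuRange[1L], spec$plantedMuRange[2L])
                size <- stats::runif(1, spec$dispersion[1L], spec$dispersion[2L])
                addGene(g, .copulaNB(zf, r, mu, size), "correlated",
                        targetRho = rho, mu = mu, size = size)
            }
        }
        if (!is.null(spec$deGenes)) {
            for (g in names(spec$deGenes)) {
                lfc <- spec$deGenes[[g]]
                mu <- stats::runif(1, spec$plantedMuRange[1L], spec$plantedMuRange[2L])
                size <- stats::runif(1, spec$dispersion[1L], spec$dispersion[2L])
                muCell <- mu * 2^(lfc * deGroup)
                addGene(g, stats::rnbinom(n, size = size, mu = muCell), "de",
                        lfc = lfc, mu = mu, size = size)
            }
        }
        # mitochondrial genes: per-cell means chosen so the expected MT share
        # of total reads equals the drawn fraction f: mu_MT = f/(1-f) * T_c
        mtFraction <- stats::rbeta(n, spec$mtBeta[1L], spec$mtBeta[2L])
        baseTotal <- colSums(do.call(rbind, geneRows))
        if (spec$nMtGenes > 0L) {
            mtTot <- mtFraction / (1 - mtFraction) * baseTotal
            for (i in seq_len(spec$nMtGenes)) {
                muCell <- mtTot / spec$nMtGenes
                addGene(sprintf("MT-SIM%d", i),
                        stats::rnbinom(n, size = 5, mu = muCell), "mt",
                        mu = mean(muCell), size = 5)
            }
        }
        genes <- do.call(rbind, geneRows)
        colnames(genes) <- cellIds

        # exon-level tables: multinomial split of an NB gene total
        exonRows <- list()
        exonTruth <- list()
        pct <- (rank(feature, ties.method = "average") - 0.5) / n
        simExonGene <- function(name, nEx, probsPerCell) {
            tot <- stats::rnbinom(n, size = 2, mu = 80)
            cnt <- vapply(seq_len(n), function(c)
                as.numeric(stats::rmultinom(1, tot[c], probsPerCell[, c])),
                numeric(nEx))
            if (nEx == 1L) cnt <- matrix(cnt, nrow = 1L)
            rownames(cnt) <- sprintf("%s:%d", name, seq_len(nEx))
            exonRows[[name]] <<- cnt
        }
        for (k in seq_len(nrow(spec$exonGradients))) {
            gi <- spec$exonGradients[k, ]
            nEx <- gi$nExons
            base <- rep(1 / nEx, nEx)
            probs <- vapply(pct, function(t) {
                p <- base
                p[gi$upExon] <- p[gi$upExon] + 0.4 * (t - 0.5)
                p[gi$downExon] <- p[gi$downExon] - 0.4 * (t - 0.5)
                p <- pmax(p, 0.02)
                p / sum(p)
            }, numeric(nEx))
            simExonGene(gi$gene, nEx, probs)
            exonTruth[[gi$gene]] <- data.frame(gene = gi$gene, nExons = nEx,
                                               upExon = gi$upExon,
                                               downExon = gi$downExon)
        }
        for (i in seq_len(spec$nNullExonGenes)) {
            nEx <- sample(1:5, 1L)
            p <- stats::runif(nEx, 0.5, 1.5)
            simExonGene(sprintf("EXNULL%02d", i),
                        nEx, matrix(p / sum(p), nEx, n))
        }
        exons <- do.call(rbind, exonRows)
        colnames(exons) <- cellIds

        names(feature) <- cellIds
        list(genes = genes, exons = exons,
             truth = { t <- do.call(rbind, truth); rownames(t) <- NULL; t },
             exonTruth = if (length(exonTruth)) do.call(rbind, exonTruth)
                         else NULL,
             feature = feature, mtFraction = mtFraction)
    })
}
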