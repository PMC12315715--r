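# Independent brute-force oracles used to pin down the fast implementations.

# O(N^2) Euclidean distance transform: for every foreground pixel, scan all
# background pixels (complement of the mask within the image, plus the
# out-of-image ring) for the nearest centre.
bruteDistanceToBackground <- function(maskLogical) {
    nr <- nrow(maskLogical); nc <- ncol(maskLogical)
    # pad with one background ring so "outside the image is background"
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- maskLogical
    bg <- which(!p, arr.ind = TRUE)
    fg <- which(p, arr.ind = TRUE)
    d <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nrow(fg))) {
        d[fg[i, 1L] - 1L, fg[i, 2L] - 1L] <-
            sqrt(min((bg[, 1L] - fg[i, 1L])^2 + (bg[, 2L] - fg[i, 2L])^2))
    }
    d
}

# brute-force annuli from the oracle distance transform
bruteAnnuli <- function(maskLogical, thickness) {
    d <- bruteDistanceToBackground(maskLogical)
    list(border = which(!is.na(d) & d <= thickness, arr.ind = TRUE),
         inner = which(!is.na(d) & d > thickness & d <= 2 * thickness,
                       arr.ind = TRUE))
}

# dense 2-D Gaussian convolution with symmetric-reflect padding, truncated
# at radius ceiling(4*sigma); direct double loop over the kernel
bruteGaussianBlur <- function(img, sigma) {
    r <- as.integer(ceiling(4 * sigma))
    off <- seq(-r, r)
    k1 <- exp(-off^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
    k2 <- outer(k1, k1)
    nr <- nrow(img); nc <- ncol(img)
    refl <- function(i, n) { # symmetric reflection, edge not doubled-over
        i[i < 1L] <- 2L - i[i < 1L]
        i[i > n] <- 2L * n - i[i > n]
        pmin(pmax(i, 1L), n)
    }
    out <- matrix(0, nr, nc)
    for (a in seq_along(off)) for (b in seq_along(off)) {
        out <- out + k2[a, b] *
            img[refl(seq_len(nr) + off[a], nr), refl(seq_len(nc) + off[b], nc)]
    }
    out
}

# exhaustive two-sample KS permutation p-value: enumerate all C(n+m, n)
# group assignments of the pooled values
bruteKsPermutationP <- function(a, b) {
    pool <- c(a, b)
    n <- length(a); m <- length(b)
    ksD <- function(x, y) {
        z <- sort(unique(c(x, y)))
        max(abs(ecdf(x)(z) - ecdf(y)(z)))
    }
    obs <- ksD(a, b)
    combs <- combn(n + m, n)
    ds <- apply(combs, 2L, function(ix) ksD(pool[ix], pool[-ix]))
    mean(ds >= obs - 1e-12)
}

# hand step-up Benjamini-Hochberg: sort, scale by n/rank, cumulative min
bruteBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
}

# disk mask by pixel enumeration: (r - r0)^2 + (c - c0)^2 <= R^2
diskLabelImage <- function(dim, centers, radii, labels = seq_len(nrow(centers))) {
    img <- matrix(0L, dim[1L], dim[2L])
    rr <- matrix(rep(seq_len(dim[1L]), dim[2L]), dim[1L], dim[2L])
    cc <- t(matrix(rep(seq_len(dim[2L]), dim[1L]), dim[2L], dim[1L]))
    for (i in seq_len(nrow(centers))) {
        ins <- (rr - centers[i, 1L])^2 + (cc - centers[i, 2L])^2 <= radii[i]^2
        img[ins] <- labels[i]
    }
    img
}

# uniform flat stack with a given per-channel value
flatStack <- function(values, dim = c(32L, 32L), channels = defaultChannelTable()) {
    px <- array(0, dim = c(length(values), dim))
    for (i in seq_along(values)) px[i, , ] <- values[i]
    hyperspectralStack(px, channels, normalized = TRUE)
}
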