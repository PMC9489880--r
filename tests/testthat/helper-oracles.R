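# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle follows the defining formula directly and stays
# independent of the package's implementation path.

# ARI by explicit enumeration of all observation pairs.
pairEnumerationARI <- function(a, b) {
    n <- length(a)
    same_a <- outer(a, a, "==")[upper.tri(diag(n))]
    same_b <- outer(b, b, "==")[upper.tri(diag(n))]
    n11 <- sum(same_a & same_b)
    n00 <- sum(!same_a & !same_b)
    n10 <- sum(same_a & !same_b)
    n01 <- sum(!same_a & same_b)
    total <- n * (n - 1) / 2
    expected <- (n11 + n10) * (n11 + n01) / total
    maxi <- ((n11 + n10) + (n11 + n01)) / 2
    if (maxi == expected) return(ifelse(n11 == expected, 1, 0))
    (n11 - expected) / (maxi - expected)
}

# Spatial covariance by a double loop over pixel pairs.
bruteSpatialCovariance <- function(grid, models, transform = NULL,
                                   jitter = 1e-8) {
    coords <- pixelCoords(grid)
    if (!is.null(transform)) coords <- applyAnisotropy(coords, transform)
    labels <- gridLabels(grid)
    n <- nrow(coords)
    S <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (labels[i] != labels[j]) next
        h <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        S[i, j] <- sphericalCov(h, models[[labels[i]]])
    }
    diag(S) <- diag(S) + jitter
    S
}

# Calinski-Harabasz straight from its definition.
bruteCH <- function(X, labels) {
    X <- as.matrix(X)
    n <- nrow(X); cl <- unique(labels); k <- length(cl)
    overall <- colMeans(X)
    ssb <- sum(sapply(cl, function(c) {
        idx <- labels == c
        sum(idx) * sum((colMeans(X[idx, , drop = FALSE]) - overall)^2)
    }))
    ssw <- sum(sapply(cl, function(c) {
        idx <- labels == c
        sum(sweep(X[idx, , drop = FALSE], 2,
                  colMeans(X[idx, , drop = FALSE]))^2)
    }))
    (ssb / (k - 1)) / (ssw / (n - k))
}

# Davies-Bouldin straight from its definition.
bruteDBI <- function(X, labels) {
    X <- as.matrix(X)
    cl <- sort(unique(labels)); k <- length(cl)
    cent <- t(sapply(cl, function(c) colMeans(X[labels == c, , drop = FALSE])))
    s <- sapply(seq_len(k), function(i)
        mean(sqrt(rowSums(sweep(X[labels == cl[i], , drop = FALSE], 2,
                                cent[i, ])^2))))
    mean(sapply(seq_len(k), function(i) {
        max(sapply(setdiff(seq_len(k), i), function(j)
            (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))))
    }))
}

# Per-bin scan oracle for binAndPick on a single spectrum: for every bin,
# scan all strict-local-max points (plateau leftmost, endpoints excluded)
# falling inside and take the max intensity.
bruteBinPickSpectrum <- function(mz, int, lo, hi, width) {
    n_bins <- ceiling((hi - lo) / width)
    out <- numeric(n_bins)
    n <- length(mz)
    is_max <- rep(FALSE, n)
    for (i in seq_len(n)) {
        if (i == 1 || i == n) next
        # walk left over a plateau
        l <- i - 1
        while (l >= 1 && int[l] == int[i]) l <- l - 1
        r <- i + 1
        while (r <= n && int[r] == int[i]) r <- r + 1
        if (l >= 1 && r <= n && int[i] > int[l] && int[i] > int[r] &&
            (i == 1 || int[i - 1] < int[i]))  # leftmost of plateau
            is_max[i] <- TRUE
    }
    for (b in seq_len(n_bins)) {
        blo <- lo + (b - 1) * width; bhi <- blo + width
        cand <- which(is_max & mz >= blo & mz < bhi)
        if (length(cand)) out[b] <- max(int[cand])
    }
    out
}

# Two isotropic Gaussian blobs with known labels.
makeBlobs <- function(n_per = 100, p = 2, centers = c(-5, 5), sd = 0.5,
                      seed = 1) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(n_per * p, centers[1], sd), n_per),
               matrix(rnorm(n_per * p, centers[2], sd), n_per))
    list(X = X, labels = rep(1:2, each = n_per))
}

# A random profile-spectrum fixture on a small pixel grid.
makeSpectrumFixture <- function(seed = 1, nx = 4, ny = 3, n_points = 40,
                                lo = 400, hi = 402) {
    set.seed(seed)
    coords <- as.matrix(expand.grid(x = 1:nx, y = 1:ny))
    spectra <- lapply(seq_len(nx * ny), function(i) {
        mz <- sort(runif(n_points, lo, hi))
        cbind(mz = mz, intensity = abs(rnorm(n_points, 5, 3)))
    })
    SpectrumSet(spectra, coords, c(lo, hi))
}

# A small simulated cube (shared scenario defaults, reduced grid).
smallCube <- function(seed = 1, spatial_type = 1, mean_mod = "VarMod_0",
                      dist = "normal", grid = c(16, 16), n_clusters = 2) {
    simulateScenario(scenarioSpec(
        spatial_type = spatial_type,
        distribution = distributionSpec(dist),
        mean_mod = mean_mod, n_clusters = n_clusters,
        grid_dim = grid, seed = seed))
}
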