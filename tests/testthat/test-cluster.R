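test_that("k-means handles degenerate k and recovers separated blobs", {
    blobs <- makeBlobs(n_per = 100, seed = 2)
    r1 <- kmeansCluster(blobs$X, 1, seed = 1)
    expect_equal(length(unique(clusterLabels(r1))), 1L)
    for (d in c("euclidean", "correlation")) {
        res <- kmeansCluster(cbind(blobs$X, blobs$X[, 1] * 0.5),
                             2, d, seed = 3)
        expect_equal(adjustedRandIndex(clusterLabels(res), blobs$labels), 1)
    }
    expect_error(kmeansCluster(blobs$X, 500, seed = 1), "k")
})

test_that("correlation distance is invariant to per-row scale and offset", {
    set.seed(4)
    x <- rnorm(20)
    X <- rbind(x, 2 * x + 3, -x + 1, rnorm(20))
    res <- kmeansCluster(X, 2, "correlation", seed = 1)
    lab <- clusterLabels(res)
    expect_equal(lab[1], lab[2])  # y = 2x + 3 has distance 0 from x
    expect_error(kmeansCluster(rbind(x, rep(1, 20)), 2, "correlation"),
                 "constant row")
})

test_that("correlation k-means objective is monotone and restarts keep the best", {
    set.seed(7)
    X <- rbind(matrix(rnorm(300, 0), 30), matrix(rnorm(300, 1.5), 30)) +
        matrix(rnorm(600, sd = 0.3), 60)
    res <- kmeansCluster(X, 3, "correlation", n_init = 8, seed = 2)
    tr <- resultExtras(res)$trace
    expect_true(all(diff(tr) <= 1e-10))
    # single-restart objectives can only be >= the multi-restart winner
    singles <- sapply(1:5, function(s)
        kmeansCluster(X, 3, "correlation", n_init = 1, seed = 2)@objective)
    expect_true(all(res@objective <= singles + 1e-10))
})

test_that("Euclidean k-means agrees with the stats::kmeans objective on blobs", {
    blobs <- makeBlobs(n_per = 50, p = 5, seed = 9)
    res <- kmeansCluster(blobs$X, 2, "euclidean", n_init = 5, seed = 1)
    set.seed(99)
    ref <- kmeans(blobs$X, 2, nstart = 5)
    expect_equal(res@objective, ref$tot.withinss, tolerance = 1e-8)
    expect_equal(adjustedRandIndex(clusterLabels(res), ref$cluster), 1)
})

test_that("GMM log-likelihood is non-decreasing and recovers two Gaussians", {
    blobs <- makeBlobs(n_per = 200, p = 2, centers = c(-4, 4), sd = 1,
                       seed = 12)
    for (s in c("spherical", "diagonal", "full")) {
        res <- gmmEM(blobs$X, 2, s, seed = 5)
        tr <- resultExtras(res)$loglik_trace
        expect_true(all(diff(tr) >= -1e-6))
        expect_gte(adjustedRandIndex(clusterLabels(res), blobs$labels), 0.99)
    }
    # k = 1: single label, fitted mean = sample mean
    r1 <- gmmEM(blobs$X, 1, "diagonal", seed = 1)
    expect_equal(length(unique(clusterLabels(r1))), 1L)
    expect_equal(as.numeric(resultExtras(r1)$means),
                 as.numeric(colMeans(blobs$X)), tolerance = 1e-6)
})

test_that("GMM agrees with mclust on well-separated components", {
    skip_if_not_installed("mclust")
    suppressMessages(library(mclust))  # Mclust needs its namespace attached
    blobs <- makeBlobs(n_per = 150, p = 3, centers = c(-3, 3), sd = 1,
                       seed = 20)
    res <- gmmEM(blobs$X, 2, "diagonal", seed = 2)
    ref <- mclust::Mclust(blobs$X, G = 2, modelNames = "VVI",
                          verbose = FALSE)
    expect_equal(adjustedRandIndex(clusterLabels(res),
                                   ref$classification), 1)
})

test_that("BIC auto-selection picks the best structure", {
    # strongly correlated two-feature components: full must win the BIC
    set.seed(31)
    z <- rnorm(300)
    X <- rbind(cbind(z[1:150], z[1:150] * 0.95 + rnorm(150, sd = 0.1)),
               cbind(z[151:300] + 5, -z[151:300] * 0.95 + rnorm(150, sd = 0.1)))
    res <- gmmEM(X, 2, "auto", seed = 4)
    expect_equal(resultExtras(res)$structure, "full")
})

test_that("sasa with radius 0 reduces exactly to Euclidean k-means", {
    cube <- smallCube(seed = 14, mean_mod = "VarMod_10_10")
    r0 <- sasa(cube, 2, radius = 0, seed = 6, n_init = 3)
    rk <- kmeansCluster(intensityMatrix(cube), 2, "euclidean", seed = 6,
                        n_init = 3)
    expect_identical(clusterLabels(r0), clusterLabels(rk))
    expect_equal(r0@objective, rk@objective)
})

test_that("sasa neighborhood features are Gaussian-weighted copies on a uniform image", {
    # all pixels identical: every weighted block is the same spectrum
    X <- matrix(rep(c(1, 2, 3), each = 25), 25, 3)
    coords <- as.matrix(expand.grid(x = 1:5, y = 1:5))
    F0 <- sasaFeatures(X, coords, radius = 1, sigma = 1, adaptive = FALSE)
    off <- expand.grid(dx = -1:1, dy = -1:1)
    off <- off[off$dx^2 + off$dy^2 <= 1, ]
    w <- exp(-(off$dx^2 + off$dy^2) / 2)
    w <- w / sum(w)
    expected <- do.call(cbind, lapply(w, function(wi)
        matrix(rep(c(1, 2, 3) * wi, each = 25), 25, 3)))
    expect_equal(F0, expected, tolerance = 1e-12)
    expect_error(sasaFeatures(X, coords, radius = 10), "grid extent")
})

test_that("spatial smoothing helps sasa on noisy piecewise-constant images", {
    set.seed(40)
    deltas <- replicate(10, {
        nx <- 20; ny <- 20
        coords <- as.matrix(expand.grid(x = 1:nx, y = 1:ny))
        truth <- ifelse(coords[, 2] <= ny / 2, 1L, 2L)
        mu <- rbind(rep(0, 8), rep(1, 8))
        X <- mu[truth, ] + matrix(rnorm(nx * ny * 8, sd = 0.6), nx * ny)
        spike <- runif(nx * ny) < 0.1  # salt-and-pepper spectral noise
        X[spike, ] <- X[spike, ] + matrix(rnorm(sum(spike) * 8, sd = 4),
                                          sum(spike))
        s <- sample.int(1e6, 1)
        a_sasa <- adjustedRandIndex(
            clusterLabels(sasa(list(data = X, coords = coords), 2,
                               radius = 2, seed = s, n_init = 4)), truth)
        a_km <- adjustedRandIndex(
            clusterLabels(kmeansCluster(X, 2, seed = s, n_init = 4)), truth)
        a_sasa - a_km
    })
    expect_gte(median(deltas), 0)
})

test_that("cluster results are invariant to label renumbering in ARI", {
    cube <- smallCube(seed = 15)
    res <- kmeansCluster(intensityMatrix(cube), 2, seed = 2)
    lab <- clusterLabels(res)
    expect_equal(adjustedRandIndex(lab, lab), 1)
    expect_equal(adjustedRandIndex(lab, 3 - lab), 1)
})
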