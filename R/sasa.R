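# Spatially-aware (structurally adapted) k-means: pixels are represented
# by Gaussian-weighted concatenations of their neighborhood spectra, with
# an optional edge-stopping adaptation, then clustered with Euclidean
# k-means. A documented simplification of the full structurally-adaptive
# scheme.

# Reflect an index into [1, n] (mirror boundary).
reflectIndex <- function(i, n) {
    i <- ifelse(i < 1L, 2L - i, i)
    ifelse(i > n, 2L * n - i, i)
}

# Gradient magnitude of an image (matrix) by central differences, mirrored
# at the edges.
imageGradientMagnitude <- function(img) {
    nx <- nrow(img); ny <- ncol(img)
    gx <- (img[reflectIndex(seq_len(nx) + 1L, nx), , drop = FALSE] -
           img[reflectIndex(seq_len(nx) - 1L, nx), , drop = FALSE]) / 2
    gy <- (img[, reflectIndex(seq_len(ny) + 1L, ny), drop = FALSE] -
           img[, reflectIndex(seq_len(ny) - 1L, ny), drop = FALSE]) / 2
    sqrt(gx^2 + gy^2)
}

#' Build the spatially augmented feature matrix
#'
#' For every pixel, concatenates the spectra of all neighbors within
#' Euclidean offset \code{radius}, each scaled by a Gaussian weight
#' w(offset) = exp(-||offset||^2 / (2 sigma^2)); per-pixel weights are
#' normalized to sum 1. With \code{adaptive = TRUE}, each neighbor's weight
#' is further multiplied by an edge-stopping factor exp(-(g/lambda)^2)
#' evaluated at the neighbor, where g is the gradient magnitude of the
#' first principal-component score image and lambda its median positive
#' value. Out-of-grid neighbors are mirrored.
#'
#' @param X numeric matrix, pixels x features.
#' @param coords integer pixel coordinates on a full rectangular grid.
#' @param radius neighborhood radius in pixels (>= 0).
#' @param sigma Gaussian weight scale (pixels).
#' @param adaptive logical; apply the edge-stopping adaptation
#'   (default FALSE, matching the common toolkit default of plain Gaussian
#'   weights; the edge factor preserves isolated spike pixels, which can
#'   hurt centroid-based clustering under salt-and-pepper noise).
#' @return numeric matrix, pixels x (n_offsets * features).
#' @export
sasaFeatures <- function(X, coords, radius = 2, sigma = 1,
                         adaptive = FALSE) {
    X <- as.matrix(X)
    coords <- as.matrix(coords)
    nx <- max(coords[, 1]); ny <- max(coords[, 2])
    if (radius < 0)
        stop("'radius' must be >= 0")
    if (radius >= nx || radius >= ny)
        stop("'radius' exceeds the grid extent")
    if (nrow(X) != nx * ny)
        stop("a full rectangular grid is required")
    # pixel-index lookup by coordinate
    M <- matrix(NA_integer_, nx, ny)
    M[cbind(coords[, 1], coords[, 2])] <- seq_len(nrow(X))
    off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
    off <- off[off$dx^2 + off$dy^2 <= radius^2, , drop = FALSE]
    w0 <- exp(-(off$dx^2 + off$dy^2) / (2 * sigma^2))
    edge <- NULL
    if (adaptive && radius > 0) {
        s1 <- reducedScores(pcaReduce(X, 1))[, 1]
        img <- matrix(NA_real_, nx, ny)
        img[cbind(coords[, 1], coords[, 2])] <- s1
        g <- imageGradientMagnitude(img)
        lambda <- median(g[g > 0])
        edge <- if (is.finite(lambda) && lambda > 0)
            exp(-(g / lambda)^2) else NULL
    }
    blocks <- vector("list", nrow(off))
    W <- matrix(0, nrow(X), nrow(off))
    nb_idx <- matrix(0L, nrow(X), nrow(off))
    for (o in seq_len(nrow(off))) {
        xi <- reflectIndex(coords[, 1] + off$dx[o], nx)
        yi <- reflectIndex(coords[, 2] + off$dy[o], ny)
        nb <- M[cbind(xi, yi)]
        nb_idx[, o] <- nb
        w <- rep(w0[o], nrow(X))
        # the edge-stopping factor damps neighbors, never the pixel itself,
        # so the normalized weights stay well defined at strong edges
        if (!is.null(edge) && !(off$dx[o] == 0 && off$dy[o] == 0))
            w <- w * edge[cbind(xi, yi)]
        W[, o] <- w
    }
    W <- W / rowSums(W)
    for (o in seq_len(nrow(off)))
        blocks[[o]] <- X[nb_idx[, o], , drop = FALSE] * W[, o]
    do.call(cbind, blocks)
}

#' Spatially-aware structurally-adapted k-means
#'
#' Runs Euclidean k-means (same engine as
#' \code{\link{kmeansCluster}}) on the neighborhood-augmented features of
#' \code{\link{sasaFeatures}}. With \code{radius = 0} the augmentation is
#' the identity and the result equals plain Euclidean k-means with the
#' same seed.
#'
#' @param cube an \linkS4class{MsiSimCube}, or a list with elements
#'   \code{data} (pixels x features) and \code{coords}.
#' @param k number of clusters.
#' @param radius neighborhood radius in pixels (default 2).
#' @param sigma Gaussian weight scale (default 1).
#' @param adaptive logical; gradient-modulated weights (default FALSE; see
#'   \code{\link{sasaFeatures}}).
#' @param seed integer RNG seed.
#' @param n_init k-means restarts (default 10).
#' @return A \linkS4class{ClusterResult} (method "sasa").
#' @export
sasa <- function(cube, k, radius = 2, sigma = 1, adaptive = FALSE,
                 seed = 1L, n_init = 10) {
    if (is(cube, "MsiSimCube")) {
        X <- intensityMatrix(cube)
        coords <- pixelCoords(cube)
    } else {
        X <- as.matrix(cube$data)
        coords <- as.matrix(cube$coords)
    }
    F <- sasaFeatures(X, coords, radius = radius, sigma = sigma,
                      adaptive = adaptive)
    res <- kmeansCluster(F, k, distance = "euclidean", seed = seed,
                         n_init = n_init)
    new("ClusterResult", labels = res@labels, method = "sasa",
        k = res@k, objective = res@objective, seed = res@seed,
        n_iter = res@n_iter,
        extras = list(radius = radius, sigma = sigma, adaptive = adaptive))
}
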