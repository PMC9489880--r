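# Dimension-reduction front-ends: PCA, spatial PCA (Moran-weighted
# eigenanalysis), minimum noise fraction, and a t-SNE adapter (tsne.R).
# PCA / sPCA / MNF are deterministic; only t-SNE is seeded.

resolveDataCoords <- function(x) {
    if (is(x, "MsiSimCube"))
        list(X = intensityMatrix(x), coords = pixelCoords(x))
    else if (is.list(x) && !is.null(x$data))
        list(X = as.matrix(x$data), coords = as.matrix(x$coords))
    else
        list(X = as.matrix(x), coords = NULL)
}

#' Principal component analysis
#'
#' Column-mean-centered SVD; scores are projections onto the leading
#' components, ordered by decreasing variance.
#'
#' @param X numeric matrix (observations x features), an
#'   \linkS4class{MsiSimCube}, or a list with \code{data}.
#' @param n_components number of components (default 4).
#' @return A \linkS4class{ReducedData}; \code{resultExtras()} holds
#'   \code{explained_variance_ratio} and \code{sdev}.
#' @examples
#' r <- pcaReduce(matrix(rnorm(200), 50), 2)
#' resultExtras(r)$explained_variance_ratio
#' @export
pcaReduce <- function(X, n_components = 4) {
    X <- resolveDataCoords(X)$X
    if (n_components > min(dim(X)))
        stop("'n_components' exceeds min(observations, features)")
    fit <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
    evr <- fit$sdev^2 / sum(fit$sdev^2)
    new("ReducedData", scores = fit$x[, seq_len(n_components), drop = FALSE],
        method = "pca", n_components = as.integer(n_components),
        extras = list(explained_variance_ratio = evr[seq_len(n_components)],
                      sdev = fit$sdev,
                      rotation = fit$rotation))
}

# Sparse binary within-lag spatial weight matrix, row-standardized.
# Requires a full rectangular grid; isolated pixels (lag < 1) get a
# self-weight with a warning.
spatialWeightMatrix <- function(coords, lag) {
    stopifnot(lag > 0)
    nx <- max(coords[, 1]); ny <- max(coords[, 2])
    n <- nrow(coords)
    if (n != nx * ny)
        stop("a full rectangular grid is required for the spatial weight matrix")
    M <- matrix(NA_integer_, nx, ny)
    M[cbind(coords[, 1], coords[, 2])] <- seq_len(n)
    r <- floor(lag)
    off <- expand.grid(dx = -r:r, dy = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= lag^2 &
               !(off$dx == 0 & off$dy == 0), , drop = FALSE]
    ii <- integer(); jj <- integer()
    for (o in seq_len(nrow(off))) {
        xi <- coords[, 1] + off$dx[o]
        yi <- coords[, 2] + off$dy[o]
        ok <- xi >= 1L & xi <= nx & yi >= 1L & yi <= ny
        ii <- c(ii, which(ok))
        jj <- c(jj, M[cbind(xi[ok], yi[ok])])
    }
    W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
    rs <- Matrix::rowSums(W)
    if (any(rs == 0)) {
        warning("isolated pixel(s) with no neighbor at the requested lag; using self-weight")
        iso <- which(rs == 0)
        W <- W + Matrix::sparseMatrix(i = iso, j = iso, x = 1,
                                      dims = c(n, n))
        rs <- Matrix::rowSums(W)
    }
    Matrix::Diagonal(x = 1 / rs) %*% W
}

#' Moran's I spatial autocorrelation of a pixel field
#'
#' @param values numeric per-pixel field.
#' @param W spatial weight matrix (e.g. from the sPCA lag-neighborhood).
#' @return Moran's I statistic.
#' @export
moranI <- function(values, W) {
    z <- values - mean(values)
    n <- length(z)
    s0 <- sum(W)
    as.numeric((n / s0) * (t(z) %*% (W %*% z)) / sum(z^2))
}

#' Spatial principal component analysis
#'
#' Eigen-decomposition of (1/(2n)) X' (W + W') X on column-centered X,
#' where W is the row-standardized binary connection matrix of pixels
#' within Euclidean distance \code{lag}. The leading (positive-eigenvalue,
#' "global") components maximize the product of variance and spatial
#' autocorrelation; negative-eigenvalue (local) components are not
#' returned.
#'
#' @param x an \linkS4class{MsiSimCube} or a list with \code{data} and
#'   \code{coords}.
#' @param n_components number of components (default 4).
#' @param lag neighborhood distance for the spatial weight matrix
#'   (default 5 pixels).
#' @return A \linkS4class{ReducedData}; \code{resultExtras()} holds all
#'   eigenvalues (variance x Moran products).
#' @export
spcaReduce <- function(x, n_components = 4, lag = 5) {
    dd <- resolveDataCoords(x)
    if (is.null(dd$coords))
        stop("pixel coordinates are required for sPCA")
    Xc <- scale(dd$X, center = TRUE, scale = FALSE)
    n <- nrow(Xc)
    W <- spatialWeightMatrix(dd$coords, lag)
    A <- as.matrix(W %*% Xc)
    B <- crossprod(Xc, A)
    M <- (B + t(B)) / (2 * n)
    e <- eigen(M, symmetric = TRUE)
    if (n_components > ncol(Xc))
        stop("'n_components' exceeds the feature count")
    V <- e$vectors[, seq_len(n_components), drop = FALSE]
    new("ReducedData", scores = Xc %*% V, method = "spca",
        n_components = as.integer(n_components),
        extras = list(eigenvalues = e$values, lag = lag,
                      n_positive = sum(e$values > 0)))
}

#' Minimum noise fraction transform from explicit covariances
#'
#' Solves the generalized eigenproblem Sigma v = lambda Sigma_N v through
#' Cholesky whitening of the noise covariance; eigenvalues order components
#' by decreasing signal-to-noise.
#'
#' @param sigma signal-plus-noise (data) covariance, p x p.
#' @param sigma_n noise covariance, p x p, positive definite.
#' @param n_components number of components to keep.
#' @return list with \code{vectors} (p x n_components) and \code{values}
#'   (all p eigenvalues, decreasing).
#' @export
mnfTransformFromCov <- function(sigma, sigma_n, n_components) {
    p <- ncol(sigma)
    R <- tryCatch(chol(sigma_n), error = function(e)
        stop("noise covariance is singular even after regularization; reduce the dimension first"))
    Rinv <- backsolve(R, diag(p))
    A <- t(Rinv) %*% sigma %*% Rinv
    A <- (A + t(A)) / 2
    e <- eigen(A, symmetric = TRUE)
    V <- Rinv %*% e$vectors[, seq_len(n_components), drop = FALSE]
    list(vectors = V, values = e$values)
}

#' Minimum noise fraction transform
#'
#' The noise covariance is estimated by the shift-difference estimator:
#' half the covariance of differences between horizontally adjacent
#' pixels, averaged with the vertical analogue, plus a 1e-8 * trace/p
#' ridge. Components solve Sigma v = lambda Sigma_N v and are ordered by
#' decreasing signal-to-noise ratio lambda.
#'
#' @param x an \linkS4class{MsiSimCube} or a list with \code{data} and
#'   \code{coords}; the grid must be at least 2 pixels wide in one
#'   direction.
#' @param n_components number of components (default 6).
#' @param max_features refuse feature counts above this cap (default 500):
#'   the noise-covariance estimate becomes unreliable and the transform is
#'   unsupported in very high dimensions.
#' @return A \linkS4class{ReducedData}; \code{resultExtras()} holds the
#'   signal-to-noise eigenvalues.
#' @export
mnfReduce <- function(x, n_components = 6, max_features = 500) {
    dd <- resolveDataCoords(x)
    if (is.null(dd$coords))
        stop("pixel coordinates are required for MNF")
    X <- dd$X
    p <- ncol(X)
    if (p > max_features)
        stop(sprintf("MNF is unsupported for %d features (cap %d): reduce the dimension first",
                     p, max_features))
    coords <- dd$coords
    nx <- max(coords[, 1]); ny <- max(coords[, 2])
    if (nx < 2 && ny < 2)
        stop("the grid must be at least 2 pixels wide in one direction")
    M <- matrix(NA_integer_, nx, ny)
    M[cbind(coords[, 1], coords[, 2])] <- seq_len(nrow(X))
    diffCov <- function(dx, dy) {
        xi <- coords[, 1] + dx; yi <- coords[, 2] + dy
        ok <- xi >= 1L & xi <= nx & yi >= 1L & yi <= ny
        if (!any(ok)) return(NULL)
        D <- X[which(ok), , drop = FALSE] -
            X[M[cbind(xi[ok], yi[ok])], , drop = FALSE]
        crossprod(D) / (2 * nrow(D))
    }
    parts <- Filter(Negate(is.null), list(diffCov(1L, 0L), diffCov(0L, 1L)))
    sigma_n <- Reduce(`+`, parts) / length(parts)
    diag(sigma_n) <- diag(sigma_n) + 1e-8 * sum(diag(sigma_n)) / p
    Xc <- scale(X, center = TRUE, scale = FALSE)
    sigma <- crossprod(Xc) / (nrow(Xc) - 1)
    tr <- mnfTransformFromCov(sigma, sigma_n, n_components)
    new("ReducedData", scores = Xc %*% tr$vectors, method = "mnf",
        n_components = as.integer(n_components),
        extras = list(snr_eigenvalues = tr$values))
}
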