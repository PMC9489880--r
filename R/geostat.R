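# Geostatistical primitives: spherical covariance, variograms, anisotropy,
# and the block spatial covariance matrix used by the simulator.

#' Spherical covariance function
#'
#' C(h) = b (1 - 3/2 (h/a) + 1/2 (h/a)^3) for 0 <= h <= a, 0 beyond the
#' range; the nugget contributes at h = 0 only.
#'
#' @param h numeric vector of non-negative lag distances (pixel units).
#' @param model a \linkS4class{SphericalModel}.
#' @return numeric vector of covariance values.
#' @examples
#' sphericalCov(c(0, 10, 25), sphericalModel(20, 1))
#' @export
sphericalCov <- function(h, model) {
    stopifnot(is(model, "SphericalModel"))
    if (any(!is.finite(h)) || any(h < 0))
        stop("lag distances 'h' must be finite and non-negative")
    a <- model@range_a; b <- model@sill_b
    r <- h / a
    out <- ifelse(h <= a, b * (1 - 1.5 * r + 0.5 * r^3), 0)
    out[h == 0] <- b + model@nugget
    out
}

#' Model semivariance from the covariance relation
#'
#' r(h) = C(0) - C(h) under a spherical model.
#'
#' @inheritParams sphericalCov
#' @return numeric vector of semivariances.
#' @examples
#' variogramFromCov(10, sphericalModel(20, 1))  # 0.6875
#' @export
variogramFromCov <- function(h, model) {
    stopifnot(is(model, "SphericalModel"))
    if (any(!is.finite(h)) || any(h < 0))
        stop("lag distances 'h' must be finite and non-negative")
    sphericalCov(0, model) - sphericalCov(h, model)
}

#' Apply a geometric anisotropy transform to coordinates
#'
#' Each coordinate row-vector c is mapped to c* = c (R T)^-1 with
#' R = [[cos t, sin t], [-sin t, cos t]] (t in radians from the transform's
#' degrees) and T = diag(a_max, a_min). Distances computed in the
#' transformed space are direction-dependent.
#'
#' @param coords numeric matrix of (x, y) positions, one row per point.
#' @param transform an \linkS4class{AnisotropyTransform}.
#' @return numeric matrix of transformed positions.
#' @examples
#' applyAnisotropy(rbind(c(1, 0)), anisotropyTransform(45, 1, 0.5))
#' @export
applyAnisotropy <- function(coords, transform) {
    stopifnot(is(transform, "AnisotropyTransform"))
    if (transform@a_min == 0)
        stop("singular transform: 'a_min' must be nonzero")
    coords <- as.matrix(coords)
    th <- transform@theta * pi / 180
    R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    Tm <- diag(c(transform@a_max, transform@a_min))
    coords %*% solve(R %*% Tm)
}

#' Empirical (experimental) variogram
#'
#' Bins all unordered pixel pairs by Euclidean lag distance and computes
#' r(h) = 1/(2 N(h)) * sum (Z(x_i) - Z(x_i + h))^2 per bin. Bins with no
#' pairs are omitted.
#'
#' @param values numeric per-pixel scalar field.
#' @param grid a \linkS4class{PixelGrid}, or a numeric coordinate matrix
#'   (possibly already anisotropy-transformed).
#' @param bins increasing numeric vector of lag-bin edges. Default: unit
#'   width bins from 0 up to half the grid diagonal.
#' @return A \linkS4class{VariogramEstimate}.
#' @examples
#' g <- pixelGrid(6, 6, 1)
#' v <- empiricalVariogram(rnorm(36), g)
#' as.data.frame(v)
#' @export
empiricalVariogram <- function(values, grid, bins = NULL) {
    coords <- if (is(grid, "PixelGrid")) grid@coords else as.matrix(grid)
    n <- nrow(coords)
    if (n < 2L)
        stop("at least 2 pixels are required")
    if (length(values) != n || any(!is.finite(values)))
        stop("'values' must be finite, one per pixel")
    d <- dist(coords)
    if (is.null(bins)) {
        half_diag <- sqrt(sum((apply(coords, 2, function(z)
            diff(range(z))))^2)) / 2
        bins <- seq(0, ceiling(half_diag) + 1, by = 1)
    }
    if (is.unsorted(bins, strictly = TRUE))
        stop("'bins' must be strictly increasing lag-bin edges")
    dv <- as.vector(d)
    sq <- as.vector(dist(matrix(values, ncol = 1)))^2
    idx <- findInterval(dv, bins, rightmost.closed = TRUE,
                        left.open = FALSE)
    keep <- idx >= 1L & idx < length(bins)
    idx <- idx[keep]; dv <- dv[keep]; sq <- sq[keep]
    if (!length(idx))
        stop("no pixel pair falls inside the requested bins")
    counts <- tapply(sq, idx, length)
    gamma <- tapply(sq, idx, sum) / (2 * counts)
    centers <- tapply(dv, idx, mean)
    ord <- order(centers)
    new("VariogramEstimate",
        lag = as.numeric(centers[ord]),
        semivariance = as.numeric(gamma[ord]),
        pair_counts = as.integer(counts[ord]))
}

#' Fit a spherical model to an empirical variogram
#'
#' Weighted least squares over (range, sill) with pair counts as weights;
#' nugget fixed at 0. Only as much machinery as parameter-recovery checks
#' need.
#'
#' @param ve a \linkS4class{VariogramEstimate}.
#' @param init optional named numeric of starting values (range_a, sill_b).
#' @return A \linkS4class{SphericalModel} with fitted range and sill.
#' @export
fitSphericalVariogram <- function(ve, init = NULL) {
    stopifnot(is(ve, "VariogramEstimate"))
    if (is.null(init))
        init <- c(range_a = max(ve@lag) / 2,
                  sill_b = max(mean(ve@semivariance), 1e-6))
    obj <- function(p) {
        m <- sphericalModel(max(p[1], 1e-6), max(p[2], 1e-9))
        sum(ve@pair_counts * (ve@semivariance - variogramFromCov(ve@lag, m))^2)
    }
    fit <- optim(init, obj, method = "L-BFGS-B",
                 lower = c(1e-3, 1e-8),
                 upper = c(4 * max(ve@lag), 10 * max(ve@semivariance)))
    sphericalModel(fit$par[1], fit$par[2])
}

#' Block spatial covariance matrix for a labeled grid
#'
#' Entry (i, j) is the spherical covariance of the shared cluster's model at
#' the anisotropy-transformed distance between pixels i and j; pixels in
#' different clusters get exactly zero (block structure). A small jitter is
#' added to the diagonal for Cholesky stability.
#'
#' @param grid a \linkS4class{PixelGrid}.
#' @param models list of \linkS4class{SphericalModel}, one per cluster label.
#' @param transform an \linkS4class{AnisotropyTransform} applied to the
#'   coordinates before any distance is computed. \code{NULL} for isotropy.
#' @param jitter non-negative variance added to the diagonal
#'   (default 1e-8).
#' @return symmetric positive-definite matrix, n_pixels x n_pixels,
#'   ordered like the grid's pixels.
#' @examples
#' g <- pixelGrid(4, 4, 2)
#' S <- buildSpatialCovariance(g, list(sphericalModel(3, 0.1),
#'                                     sphericalModel(3, 0.3)))
#' @export
buildSpatialCovariance <- function(grid, models, transform = NULL,
                                   jitter = 1e-8) {
    stopifnot(is(grid, "PixelGrid"), jitter >= 0)
    k <- max(grid@labels)
    if (length(models) != k)
        stop("one SphericalModel per cluster label is required")
    n <- nrow(grid@coords)
    coords <- grid@coords
    if (!is.null(transform))
        coords <- applyAnisotropy(coords, transform)
    S <- matrix(0, n, n)
    for (cl in seq_len(k)) {
        idx <- which(grid@labels == cl)
        S[idx, idx] <- clusterCovarianceBlock(coords[idx, , drop = FALSE],
                                              models[[cl]])
    }
    diag(S) <- diag(S) + jitter
    ch <- tryCatch(chol(S), error = function(e) e)
    if (inherits(ch, "error")) {
        lam_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
        stop(sprintf(
            "spatial covariance is not positive definite after jitter (min eigenvalue %.3e)",
            lam_min))
    }
    S
}

# Dense within-cluster covariance block at (already transformed) coords.
clusterCovarianceBlock <- function(coords, model) {
    D <- as.matrix(dist(coords))
    B <- matrix(sphericalCov(as.vector(D), model), nrow(D), nrow(D))
    B
}

#' Export a variogram estimate as CSV
#'
#' Long format: lag, semivariance, count.
#'
#' @param ve a \linkS4class{VariogramEstimate}.
#' @param file path of the CSV file to write.
#' @return the file path, invisibly.
#' @export
writeVariogramCSV <- function(ve, file) {
    write.csv(as.data.frame(ve), file, row.names = FALSE)
    invisible(file)
}
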