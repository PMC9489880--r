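# Synthetic MSI-like data generation: non-normal marginals, cluster-wise
# spectral correlation (Cholesky induction), spatial autocorrelation
# (block spatial covariance, Cholesky induction) and scenario
# modifications.

#' Fleishman power-method coefficients
#'
#' Solves the Fleishman moment system for coefficients (alpha, beta, gamma,
#' delta) such that Y = alpha + beta Z + gamma Z^2 + delta Z^3 of a standard
#' normal Z has mean 0, variance 1 and the requested skewness and excess
#' kurtosis. alpha = -gamma by the mean constraint.
#'
#' @param skew target skewness.
#' @param exkurt target excess kurtosis. The pair must be feasible
#'   (approximately \code{exkurt >= skew^2 - 2} plus the method's own
#'   boundary; infeasible pairs raise an error naming the violated bound).
#' @return named numeric (alpha, beta, gamma, delta); the moment-system
#'   residual at the solution is below 1e-8.
#' @examples
#' fleishmanCoefficients(0, 0)        # (0, 1, 0, 0)
#' fleishmanCoefficients(1.5, 3.5)
#' @export
fleishmanCoefficients <- function(skew, exkurt) {
    if (exkurt < skew^2 - 2)
        stop(sprintf(
            "infeasible (skew, exkurt): excess kurtosis %.3f is below the bound skew^2 - 2 = %.3f",
            exkurt, skew^2 - 2))
    if (skew == 0 && exkurt == 0)
        return(c(alpha = 0, beta = 1, gamma = 0, delta = 0))
    sys <- function(p) {
        b <- p[1]; cc <- p[2]; d <- p[3]
        c(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
          2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - skew,
          24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
                d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) - exkurt)
    }
    start <- c(1, 0.15 * skew, 0.05 * sign(exkurt + 1e-12))
    sol <- tryCatch(
        pracma::fsolve(sys, start, tol = 1e-12),
        error = function(e) NULL)
    if (is.null(sol) || max(abs(sys(sol$x))) > 1e-8) {
        # retry from a flatter start before declaring failure
        sol <- tryCatch(pracma::fsolve(sys, c(0.9, 0.1 * skew, 0.1),
                                       tol = 1e-12),
                        error = function(e) NULL)
    }
    if (is.null(sol) || max(abs(sys(sol$x))) > 1e-8)
        stop("Fleishman root-finder did not converge; the (skew, exkurt) pair may sit outside the feasible region")
    p <- sol$x
    c(alpha = -p[2], beta = p[1], gamma = p[2], delta = p[3])
}

#' Distribution specification for base variables
#'
#' @param kind one of "normal", "fleishman", "bimodal", "mixed".
#' @param fleishman_skew,fleishman_exkurt Fleishman targets (defaults 1.5 and
#'   3.5: clearly non-normal and comfortably inside the feasible region).
#' @param bimodal_p1 probability of the first mixture component N(0, 1)
#'   (default 0.2, i.e. about 20\% of draws).
#' @param bimodal_mu2,bimodal_sd2 mean and standard deviation of the second
#'   component (defaults 1 and 0.2).
#' @param mixed_composition integer counts of (normal, bimodal, fleishman)
#'   variables for kind "mixed"; must sum to the variable count when used.
#' @return a list with class "DistributionSpec".
#' @export
distributionSpec <- function(kind = c("normal", "fleishman", "bimodal", "mixed"),
                             fleishman_skew = 1.5, fleishman_exkurt = 3.5,
                             bimodal_p1 = 0.2, bimodal_mu2 = 1,
                             bimodal_sd2 = 0.2,
                             mixed_composition = c(60, 20, 20)) {
    kind <- match.arg(kind)
    if (bimodal_p1 <= 0 || bimodal_p1 >= 1)
        stop("'bimodal_p1' must lie in (0, 1)")
    structure(list(kind = kind, fleishman_skew = fleishman_skew,
                   fleishman_exkurt = fleishman_exkurt,
                   bimodal_p1 = bimodal_p1, bimodal_mu2 = bimodal_mu2,
                   bimodal_sd2 = bimodal_sd2,
                   mixed_composition = as.integer(mixed_composition)),
              class = "DistributionSpec")
}

#' Draw a standardized bimodal variable
#'
#' Mixture p1 * N(0, 1) + (1 - p1) * N(mu2, sd2), standardized by the
#' mixture's theoretical mean and standard deviation so the result has mean
#' 0 and sd 1 by construction. Component provenance is attached as the
#' logical attribute \code{"component1"} (TRUE = drawn from N(0, 1)).
#'
#' @param n number of draws.
#' @param p1 probability of the first component (default 0.2).
#' @param mu2,sd2 mean and sd of the second component (defaults 1 and 0.2).
#' @return numeric vector of standardized draws with attribute
#'   \code{"component1"}.
#' @export
drawBimodal <- function(n, p1 = 0.2, mu2 = 1, sd2 = 0.2) {
    comp1 <- runif(n) < p1
    x <- ifelse(comp1, rnorm(n), rnorm(n, mu2, sd2))
    m <- (1 - p1) * mu2
    v <- p1 * 1 + (1 - p1) * (sd2^2 + mu2^2) - m^2
    out <- (x - m) / sqrt(v)
    attr(out, "component1") <- comp1
    out
}

#' Draw independent standardized base variables
#'
#' Columns are independent with mean 0 and sd 1 by construction of each
#' generator: normal columns are N(0,1); Fleishman columns are cubic
#' polynomials of a standard normal matched to the target moments; bimodal
#' columns mix N(0,1) (probability p1) with N(mu2, sd2) and are standardized
#' by the mixture's theoretical moments. Kind "mixed" lays out
#' \code{mixed_composition} = (normal, bimodal, fleishman) columns in that
#' order.
#'
#' @param n_pixels,n_vars dimensions of the returned matrix.
#' @param dist a \code{\link{distributionSpec}}.
#' @param rng_seed integer seed.
#' @return numeric matrix, n_pixels x n_vars; attribute
#'   \code{"column_kind"} names each column's generator.
#' @export
drawBaseVariables <- function(n_pixels, n_vars, dist = distributionSpec(),
                              rng_seed = 1L) {
    stopifnot(n_pixels >= 1, n_vars >= 1)
    if (!inherits(dist, "DistributionSpec"))
        stop("'dist' must be a distributionSpec()")
    set.seed(as.integer(rng_seed))
    kinds <- switch(dist$kind,
        normal = rep("normal", n_vars),
        fleishman = rep("fleishman", n_vars),
        bimodal = rep("bimodal", n_vars),
        mixed = {
            if (sum(dist$mixed_composition) != n_vars)
                stop("'mixed_composition' must sum to 'n_vars'")
            rep(c("normal", "bimodal", "fleishman"), dist$mixed_composition)
        })
    fl <- if (any(kinds == "fleishman"))
        fleishmanCoefficients(dist$fleishman_skew, dist$fleishman_exkurt)
    else NULL
    X <- matrix(0, n_pixels, n_vars)
    for (j in seq_len(n_vars)) {
        X[, j] <- switch(kinds[j],
            normal = rnorm(n_pixels),
            fleishman = {
                z <- rnorm(n_pixels)
                fl["alpha"] + fl["beta"] * z + fl["gamma"] * z^2 +
                    fl["delta"] * z^3
            },
            bimodal = as.numeric(drawBimodal(n_pixels, dist$bimodal_p1,
                                             dist$bimodal_mu2,
                                             dist$bimodal_sd2)))
    }
    attr(X, "column_kind") <- kinds
    X
}

#' Cluster-wise variable correlation matrix
#'
#' Partitions the variables into random blocks (sizes drawn uniformly from
#' \code{block_range}) of mutually correlated variables; within a block,
#' the common correlation is drawn uniformly from
#' [\code{rho_low}, \code{rho_high}], across blocks it is zero. Such a
#' block (clique) matrix is positive definite by construction, so the
#' delivered correlations genuinely lie in the stated range; a
#' nearest-positive-definite repair (eigenvalue clipping + rescaling to
#' unit diagonal) is still applied as a safety net and is a no-op here.
#' Co-regulated ion families are the natural block structure of spectral
#' correlation in MSI data.
#'
#' @param n_vars number of variables (>= 2).
#' @param rho_low,rho_high bounds of the within-block correlations
#'   (defaults 0.4 and 0.7).
#' @param block_range integer(2), min/max block size (default 5 to 15).
#' @param rng_seed integer seed.
#' @return a positive-definite correlation matrix (unit diagonal, minimum
#'   eigenvalue > 0, maximum absolute off-diagonal <= rho_high up to
#'   repair slack).
#' @export
clusterCorrelationMatrix <- function(n_vars, rho_low = 0.4, rho_high = 0.7,
                                     block_range = c(5L, 15L),
                                     rng_seed = 1L) {
    stopifnot(n_vars >= 2)
    set.seed(as.integer(rng_seed))
    C <- diag(n_vars)
    perm <- sample.int(n_vars)
    i <- 1L
    while (i <= n_vars) {
        m <- min(sample(seq(block_range[1], block_range[2]), 1),
                 n_vars - i + 1L)
        idx <- perm[i:(i + m - 1L)]
        C[idx, idx] <- runif(1, rho_low, rho_high)
        i <- i + m
    }
    diag(C) <- 1
    nearestPDCorrelation(C)
}

# Eigenvalue clipping + rescaling to unit diagonal; always succeeds.
nearestPDCorrelation <- function(C, eps = 1e-4) {
    e <- eigen(C, symmetric = TRUE)
    lam <- pmax(e$values, eps)
    B <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(B))
    B <- B / tcrossprod(d)
    (B + t(B)) / 2
}

#' Induce variable correlation by Cholesky multiplication
#'
#' Output = Z U where U is the upper-triangular Cholesky factor
#' (corr = U' U); columns of independent standardized input acquire the
#' target correlation.
#'
#' @param Z numeric matrix, pixels x variables, independent columns.
#' @param corr positive-definite correlation matrix, dimension =
#'   variable count.
#' @return correlated matrix of the same dimension.
#' @export
induceVariableCorrelation <- function(Z, corr) {
    Z <- as.matrix(Z)
    if (ncol(Z) != nrow(corr))
        stop("'corr' dimension must equal the variable count")
    U <- tryCatch(chol(corr), error = function(e)
        stop("'corr' is not positive definite: Cholesky decomposition failed"))
    Z %*% U
}

#' Induce spatial autocorrelation by Cholesky multiplication
#'
#' Output = L X where sigma_s = L L' (L is the transpose of the upper
#' Cholesky factor), so every variable's per-pixel field has covariance
#' sigma_s across replicate draws.
#'
#' @param X numeric matrix, pixels x variables.
#' @param sigma_s positive-definite spatial covariance, dimension = pixel
#'   count (e.g. from \code{\link{buildSpatialCovariance}}).
#' @return spatially autocorrelated matrix of the same dimension.
#' @export
induceSpatialAutocorrelation <- function(X, sigma_s) {
    X <- as.matrix(X)
    if (nrow(X) != nrow(sigma_s))
        stop("'sigma_s' dimension must equal the pixel count")
    L <- t(chol(sigma_s))
    L %*% X
}

#' Spatial-type variogram parameters
#'
#' Per-cluster (range, sill) pairs of the three simulated spatial
#' structures. Two clusters: type 1 ranges (20, 20), sills (0.1, 0.3);
#' type 2 ranges (20, 10), sills (0.1, 0.1); type 3 ranges (20, 10), sills
#' (0.1, 0.3). Four clusters extend the pattern: ranges (20, 10, 20, 10)
#' and sills (0.1, 0.3, 0.2, 0.15) with per-type modifications mirroring
#' the two-cluster design.
#'
#' @param spatial_type integer 1, 2 or 3.
#' @param n_clusters 2 or 4.
#' @return list of \linkS4class{SphericalModel}, one per cluster.
#' @export
spatialTypeModels <- function(spatial_type, n_clusters = 2) {
    stopifnot(spatial_type %in% 1:3, n_clusters %in% c(2, 4))
    if (n_clusters == 2) {
        par <- switch(spatial_type,
            `1` = list(a = c(20, 20), b = c(0.1, 0.3)),
            `2` = list(a = c(20, 10), b = c(0.1, 0.1)),
            `3` = list(a = c(20, 10), b = c(0.1, 0.3)))
    } else {
        par <- switch(spatial_type,
            `1` = list(a = c(20, 20, 20, 20), b = c(0.1, 0.3, 0.2, 0.15)),
            `2` = list(a = c(20, 10, 20, 10), b = c(0.1, 0.1, 0.1, 0.1)),
            `3` = list(a = c(20, 10, 20, 10), b = c(0.1, 0.3, 0.2, 0.15)))
    }
    mapply(sphericalModel, par$a, par$b, SIMPLIFY = FALSE)
}

#' Scenario specification
#'
#' Bundles everything one simulated dataset needs: spatial structure type,
#' marginal distribution, mean-modification scenario, cluster count, grid
#' size, variable count and seed.
#'
#' @param spatial_type 1, 2 or 3 (see \code{\link{spatialTypeModels}}).
#' @param distribution a \code{\link{distributionSpec}}.
#' @param mean_mod one of "VarMod_0", "VarMod_0_5", "VarMod_0_10",
#'   "VarMod_5_5", "VarMod_10_10", "VarMod_5_5_addnoise",
#'   "VarMod_10_10_addnoise".
#' @param n_clusters 2 or 4.
#' @param grid_dim integer(2) grid extent (default c(80, 80)).
#' @param n_vars number of base variables (default 100).
#' @param seed integer seed.
#' @param transform anisotropy applied before building the spatial
#'   covariance (default 45 degrees, scales 1 and 0.5).
#' @return a list with class "ScenarioSpec".
#' @export
scenarioSpec <- function(spatial_type = 1,
                         distribution = distributionSpec("normal"),
                         mean_mod = "VarMod_0", n_clusters = 2,
                         grid_dim = c(80, 80), n_vars = 100, seed = 1L,
                         transform = anisotropyTransform(45, 1, 0.5)) {
    mean_mod <- match.arg(mean_mod, c("VarMod_0", "VarMod_0_5",
                                      "VarMod_0_10", "VarMod_5_5",
                                      "VarMod_10_10", "VarMod_5_5_addnoise",
                                      "VarMod_10_10_addnoise"))
    stopifnot(spatial_type %in% 1:3, n_clusters %in% c(2, 4))
    structure(list(spatial_type = spatial_type, distribution = distribution,
                   mean_mod = mean_mod, n_clusters = n_clusters,
                   grid_dim = as.integer(grid_dim),
                   n_vars = as.integer(n_vars), seed = as.integer(seed),
                   transform = transform),
              class = "ScenarioSpec")
}

# Designated shifted variables for a mean-mod scenario. Disjoint variable
# sets per cluster in the "both clusters" scenarios so the clusters stay
# distinguishable by mean. Sampled with the scenario RNG.
scenarioShiftPlan <- function(mean_mod, n_vars, n_clusters) {
    m <- switch(mean_mod,
        VarMod_0 = 0L,
        VarMod_0_5 = 5L, VarMod_0_10 = 10L,
        VarMod_5_5 = 5L, VarMod_5_5_addnoise = 5L,
        VarMod_10_10 = 10L, VarMod_10_10_addnoise = 10L,
        stop("unknown mean-modification scenario: ", mean_mod))
    both <- mean_mod %in% c("VarMod_5_5", "VarMod_10_10",
                            "VarMod_5_5_addnoise", "VarMod_10_10_addnoise")
    noise <- grepl("addnoise", mean_mod)
    clusters <- if (m == 0L) integer() else if (both) seq_len(n_clusters) else 1L
    vars <- if (m == 0L) list() else {
        pool <- sample.int(n_vars, m * length(clusters))
        split(pool, rep(seq_along(clusters), each = m))
    }
    list(shift = 0.5, n_shift = m, clusters = clusters, vars = vars,
         add_noise = noise, n_noise = if (noise) 5L else 0L)
}

#' Apply mean-shift / noise-variable scenario modifications
#'
#' \code{VarMod_0}: unchanged. \code{VarMod_0_5} / \code{VarMod_0_10}:
#' +0.5 added to 5 / 10 designated variables on cluster-1 pixels only.
#' \code{VarMod_5_5} / \code{VarMod_10_10}: +0.5 added to designated
#' variables in every cluster, with disjoint variable sets per cluster.
#' \code{*_addnoise} variants additionally append 5 iid standard-normal
#' columns with no spatial structure. Shifts are applied after spatial
#' induction, so the delivered contrast is exactly +0.5.
#'
#' @param cube an \linkS4class{MsiSimCube}.
#' @param mean_mod scenario id (see above).
#' @param rng_seed integer seed used to designate variables and draw noise.
#' @return the modified \linkS4class{MsiSimCube}; \code{modifiedVars()} and
#'   \code{noiseVars()} record the affected variable indices.
#' @export
applyScenarioModifications <- function(cube, mean_mod, rng_seed = 1L) {
    stopifnot(is(cube, "MsiSimCube"))
    X <- intensityMatrix(cube)
    truth <- truthLabels(cube)
    set.seed(as.integer(rng_seed))
    plan <- scenarioShiftPlan(mean_mod, ncol(X), max(truth))
    mod_vars <- integer()
    for (i in seq_along(plan$clusters)) {
        cl <- plan$clusters[i]
        v <- plan$vars[[i]]
        X[truth == cl, v] <- X[truth == cl, v] + plan$shift
        mod_vars <- c(mod_vars, v)
    }
    noise_vars <- integer()
    if (plan$add_noise) {
        N <- matrix(rnorm(nrow(X) * plan$n_noise), nrow(X))
        noise_vars <- ncol(X) + seq_len(plan$n_noise)
        X <- cbind(X, N)
        colnames(X) <- paste0("V", seq_len(ncol(X)))
    }
    sc <- scenarioInfo(cube)
    sc$mean_mod <- mean_mod
    MsiSimCube(X, pixelGridOf(cube), scenario = sc,
               modified_vars = sort(mod_vars), noise_vars = noise_vars)
}

#' Simulate one scenario end to end
#'
#' Pipeline: draw standardized base variables; induce cluster-wise variable
#' correlation (each cluster's Cholesky factor applied to that cluster's
#' pixel rows); build the block spatial covariance (anisotropy 45 degrees,
#' scales 1 / 0.5 by default); induce spatial autocorrelation per cluster
#' block; apply mean-shift / noise modifications. Deterministic given the
#' scenario seed.
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @return an \linkS4class{MsiSimCube} with ground-truth labels (2 clusters:
#'   two nx x ny/2 halves; 4 clusters: four nx x ny/4 bands).
#' @examples
#' spec <- scenarioSpec(grid_dim = c(16, 16), seed = 7)
#' cube <- simulateScenario(spec)
#' dim(intensityMatrix(cube))
#' @export
simulateScenario <- function(spec) {
    stopifnot(inherits(spec, "ScenarioSpec"))
    grid <- pixelGrid(spec$grid_dim[1], spec$grid_dim[2], spec$n_clusters)
    n <- nrow(grid@coords)
    Z <- drawBaseVariables(n, spec$n_vars, spec$distribution,
                           rng_seed = spec$seed)
    models <- spatialTypeModels(spec$spatial_type, spec$n_clusters)
    coords_t <- applyAnisotropy(grid@coords, spec$transform)
    X <- matrix(0, n, spec$n_vars)
    for (cl in seq_len(spec$n_clusters)) {
        idx <- which(grid@labels == cl)
        corr <- clusterCorrelationMatrix(spec$n_vars,
                                         rng_seed = (spec$seed %% 100000L) * 13L + cl)
        Xc <- induceVariableCorrelation(Z[idx, , drop = FALSE], corr)
        Sb <- clusterCovarianceBlock(coords_t[idx, , drop = FALSE],
                                     models[[cl]])
        diag(Sb) <- diag(Sb) + 1e-8
        X[idx, ] <- induceSpatialAutocorrelation(Xc, Sb)
    }
    cube <- MsiSimCube(X, grid, scenario = list(
        spatial_type = spec$spatial_type,
        distribution = spec$distribution$kind,
        mean_mod = spec$mean_mod, n_clusters = spec$n_clusters,
        grid_dim = spec$grid_dim, n_vars = spec$n_vars, seed = spec$seed))
    applyScenarioModifications(cube, spec$mean_mod,
                               rng_seed = spec$seed + 1L)
}
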