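# Clustering methods compared by the benchmark: k-means with Euclidean or
# correlation distance, Gaussian mixture EM, and a spatially-aware k-means
# variant (see sasa.R / gmm.R).

# Row standardization for correlation distance: mean 0, population sd 1.
# 1 - Pearson(x, y) is then a monotone function of the Euclidean distance
# between standardized rows, and cor(x, y) = (xs . ys) / p.
standardizeRows <- function(X) {
    m <- rowMeans(X)
    Xc <- X - m
    s <- sqrt(rowMeans(Xc^2))
    bad <- which(s == 0)
    if (length(bad))
        stop("correlation distance undefined for constant row(s): ",
             paste(head(bad, 5), collapse = ", "))
    Xc / s
}

# k-means++ seeding on a generic squared-dissimilarity function.
# distFun(X, C) must return an n x nrow(C) matrix of dissimilarities.
kmeansPlusPlusCenters <- function(X, k, distFun) {
    n <- nrow(X)
    centers <- matrix(NA_real_, k, ncol(X))
    centers[1, ] <- X[sample.int(n, 1), ]
    if (k > 1) {
        for (j in 2:k) {
            D <- distFun(X, centers[seq_len(j - 1), , drop = FALSE])
            d2 <- apply(D, 1, min)^2
            p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
            centers[j, ] <- X[sample.int(n, 1, prob = p), ]
        }
    }
    centers
}

# One Lloyd run for correlation distance. Returns labels, objective trace.
lloydCorrelation <- function(Xs, k, max_iter) {
    p <- ncol(Xs)
    corDist <- function(A, C) 1 - tcrossprod(A, C) / p
    centers <- kmeansPlusPlusCenters(Xs, k, corDist)
    centers <- standardizeRows(centers)
    labels <- integer(nrow(Xs))
    trace <- numeric()
    for (it in seq_len(max_iter)) {
        D <- corDist(Xs, centers)
        new_labels <- max.col(-D, ties.method = "first")
        # keep every cluster populated: move the worst-fit point into an
        # empty cluster
        for (cl in seq_len(k)) {
            if (!any(new_labels == cl)) {
                far <- which.max(D[cbind(seq_len(nrow(Xs)), new_labels)])
                new_labels[far] <- cl
                D[far, ] <- 0
            }
        }
        trace <- c(trace, sum(D[cbind(seq_len(nrow(Xs)), new_labels)]))
        converged <- it > 1L && all(new_labels == labels)
        labels <- new_labels
        centers <- do.call(rbind, lapply(seq_len(k), function(cl)
            colMeans(Xs[labels == cl, , drop = FALSE])))
        centers <- standardizeRows(centers)
        if (converged) break
    }
    # objective at the final assignment/centroids
    D <- corDist(Xs, centers)
    obj <- sum(D[cbind(seq_len(nrow(Xs)), labels)])
    list(labels = labels, objective = obj, n_iter = it,
         trace = c(trace, obj))
}

#' K-means clustering with Euclidean or correlation distance
#'
#' Euclidean distance delegates to \code{\link[stats]{kmeans}} (Lloyd
#' iterations, \code{n_init} random restarts). Correlation distance
#' d(x, y) = 1 - Pearson(x, y) runs Lloyd iterations with k-means++
#' seeding; centroids are means of row-standardized members,
#' re-standardized after averaging. The best of \code{n_init} restarts by
#' objective is returned.
#'
#' @param X numeric matrix, observations x features.
#' @param k number of clusters (1 <= k <= nrow(X)).
#' @param distance "euclidean" or "correlation". Correlation distance
#'   requires >= 2 features and no constant rows.
#' @param n_init number of restarts (default 10).
#' @param seed integer RNG seed.
#' @param max_iter Lloyd iteration cap (default 300; convergence = no
#'   assignment change).
#' @return A \linkS4class{ClusterResult}; the objective is the total
#'   within-cluster sum of squared distances (Euclidean) or the summed
#'   correlation distance to centroids. For the correlation path the
#'   per-iteration objective trace of the winning restart is in
#'   \code{resultExtras()$trace}.
#' @examples
#' X <- rbind(matrix(rnorm(40, -3), 20), matrix(rnorm(40, 3), 20))
#' clusterLabels(kmeansCluster(X, 2, seed = 1))
#' @export
kmeansCluster <- function(X, k, distance = c("euclidean", "correlation"),
                          n_init = 10, seed = 1L, max_iter = 300) {
    distance <- match.arg(distance)
    X <- as.matrix(X)
    if (k < 1 || k > nrow(X))
        stop("'k' must satisfy 1 <= k <= number of observations")
    set.seed(as.integer(seed))
    if (distance == "euclidean") {
        if (k == nrow(X)) {
            # degenerate: one observation per cluster
            return(new("ClusterResult", labels = seq_len(nrow(X)),
                       method = "kmeans_euclidean", k = as.integer(k),
                       objective = 0, seed = as.integer(seed),
                       n_iter = 1L, extras = list()))
        }
        fit <- suppressWarnings(
            kmeans(X, centers = k, nstart = n_init, iter.max = max_iter,
                   algorithm = "Lloyd"))
        return(new("ClusterResult", labels = as.integer(fit$cluster),
                   method = "kmeans_euclidean", k = as.integer(k),
                   objective = fit$tot.withinss, seed = as.integer(seed),
                   n_iter = max(1L, as.integer(fit$iter)),
                   extras = list(centers = fit$centers)))
    }
    if (ncol(X) < 2)
        stop("correlation distance requires at least 2 features")
    Xs <- standardizeRows(X)
    best <- NULL
    for (r in seq_len(n_init)) {
        run <- lloydCorrelation(Xs, k, max_iter)
        if (is.null(best) || run$objective < best$objective) best <- run
    }
    new("ClusterResult", labels = as.integer(best$labels),
        method = "kmeans_correlation", k = as.integer(k),
        objective = best$objective, seed = as.integer(seed),
        n_iter = as.integer(best$n_iter),
        extras = list(trace = best$trace))
}
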