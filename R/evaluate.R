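# External (ARI) and internal (Calinski-Harabasz, Davies-Bouldin) cluster
# validation, and index-based k selection.

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions,
#' computed from the contingency table:
#' (sum_ij C(n_ij,2) - E) / (0.5 (sum_i C(a_i,2) + sum_j C(b_j,2)) - E)
#' with E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2). Symmetric in its
#' arguments; 1 iff the partitions are identical up to relabeling, about 0
#' for independent partitions.
#'
#' @param labels_a,labels_b partitions of the same observations (any
#'   atomic label type), length >= 2.
#' @return the ARI (dimensionless, <= 1).
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjustedRandIndex <- function(labels_a, labels_b) {
    if (length(labels_a) != length(labels_b))
        stop("partitions must have equal length")
    n <- length(labels_a)
    if (n < 2)
        stop("at least 2 observations are required")
    tab <- table(labels_a, labels_b)
    choose2 <- function(x) x * (x - 1) / 2
    sum_ij <- sum(choose2(tab))
    sum_a <- sum(choose2(rowSums(tab)))
    sum_b <- sum(choose2(colSums(tab)))
    expected <- sum_a * sum_b / choose2(n)
    denom <- (sum_a + sum_b) / 2 - expected
    if (denom == 0) return(ifelse(sum_ij == expected, 1, 0))
    (sum_ij - expected) / denom
}

withinBetweenScatter <- function(X, labels) {
    X <- as.matrix(X)
    cl <- unique(labels)
    overall <- colMeans(X)
    ssw <- 0; ssb <- 0
    cents <- list()
    for (c in cl) {
        idx <- labels == c
        cent <- colMeans(X[idx, , drop = FALSE])
        cents[[as.character(c)]] <- cent
        ssw <- ssw + sum(sweep(X[idx, , drop = FALSE], 2, cent)^2)
        ssb <- ssb + sum(idx) * sum((cent - overall)^2)
    }
    list(ssw = ssw, ssb = ssb, k = length(cl), n = nrow(X),
         centroids = cents)
}

#' Calinski-Harabasz index
#'
#' (between-cluster scatter / (k - 1)) / (within-cluster scatter /
#' (n - k)), from centroid sums of squares. Higher is better. Zero
#' within-cluster scatter (point-mass clusters) yields +Inf.
#'
#' @param X numeric matrix, observations x features.
#' @param labels partition with >= 2 non-empty clusters; n > k required.
#' @return the CH index (>= 0, possibly Inf).
#' @export
calinskiHarabasz <- function(X, labels) {
    s <- withinBetweenScatter(X, labels)
    if (s$k < 2)
        stop("at least 2 non-empty clusters are required")
    if (s$n <= s$k)
        stop("more observations than clusters are required")
    if (s$ssw == 0) return(Inf)
    (s$ssb / (s$k - 1)) / (s$ssw / (s$n - s$k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of max_{j != i} (s_i + s_j) / d_ij, where s is the
#' mean within-cluster distance to the centroid and d the centroid
#' separation. Lower is better. Coincident centroids are guarded: the pair
#' is skipped with a warning.
#'
#' @inheritParams calinskiHarabasz
#' @return the DBI (>= 0).
#' @export
daviesBouldin <- function(X, labels) {
    X <- as.matrix(X)
    cl <- sort(unique(labels))
    k <- length(cl)
    if (k < 2)
        stop("at least 2 non-empty clusters are required")
    cent <- t(vapply(cl, function(c)
        colMeans(X[labels == c, , drop = FALSE]), numeric(ncol(X))))
    s <- vapply(seq_len(k), function(i) {
        idx <- labels == cl[i]
        mean(sqrt(rowSums(sweep(X[idx, , drop = FALSE], 2, cent[i, ])^2)))
    }, numeric(1))
    ratios <- matrix(NA_real_, k, k)
    skipped <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i == j) next
        d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
        if (d == 0) { skipped <- TRUE; next }
        ratios[i, j] <- (s[i] + s[j]) / d
    }
    if (skipped)
        warning("coincident centroids: pair(s) skipped in the DBI")
    mean(apply(ratios, 1, function(r)
        if (all(is.na(r))) 0 else max(r, na.rm = TRUE)))
}

#' Select the number of clusters by internal validity indices
#'
#' Runs \code{clusterer} for each k in \code{k_range} and scores the
#' partitions with the Calinski-Harabasz (maximize) and Davies-Bouldin
#' (minimize) indices. When the two indices disagree, both winners are
#' reported and the CH winner is the default. When the CH optimum is not
#' interior to \code{k_range} (flat or monotone index, e.g. a single
#' blob), a flatness warning is issued and the smallest k is returned.
#'
#' @param X numeric matrix, observations x features.
#' @param clusterer function(X, k) returning a
#'   \linkS4class{ClusterResult} (e.g. a wrapper around
#'   \code{\link{kmeansCluster}}).
#' @param k_range integer vector of candidate k (within 2 .. n - 1).
#' @return list with \code{k} (selected, CH winner), \code{k_ch},
#'   \code{k_dbi}, \code{agreement} (logical) and \code{table}
#'   (data.frame k / ch / dbi, one row per candidate).
#' @export
selectK <- function(X, clusterer, k_range) {
    X <- as.matrix(X)
    if (any(k_range < 2) || any(k_range > nrow(X) - 1))
        stop("'k_range' must lie within 2 .. n - 1")
    tab <- data.frame(k = k_range, ch = NA_real_, dbi = NA_real_)
    for (i in seq_along(k_range)) {
        res <- clusterer(X, k_range[i])
        lab <- clusterLabels(res)
        tab$ch[i] <- calinskiHarabasz(X, lab)
        tab$dbi[i] <- daviesBouldin(X, lab)
    }
    k_ch <- tab$k[which.max(tab$ch)]
    k_dbi <- tab$k[which.min(tab$dbi)]
    selected <- k_ch
    pos <- which.max(tab$ch)
    if (length(k_range) > 2 && (pos == 1L || pos == length(k_range))) {
        # no interior optimum: the index carries no clear structure signal
        warning("no interior CH optimum over 'k_range' (flat or monotone index); returning the smallest k")
        selected <- min(tab$k)
    }
    list(k = selected, k_ch = k_ch, k_dbi = k_dbi,
         agreement = k_ch == k_dbi, table = tab)
}
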