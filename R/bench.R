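# Benchmark driver: scenario grid x clustering methods x dimension
# reductions x replicates, scored by ARI against the ground truth, plus
# median-ARI aggregation.

#' Deterministic per-cell seed
#'
#' seed = ((master \%\% 100000) * 20011 + cell_index * 211 + replicate)
#' \%\% 2147483647, so benchmark tables are replicable across machines
#' without 64-bit arithmetic.
#'
#' @param master_seed integer master seed.
#' @param cell_index integer index of the grid cell (1-based).
#' @param replicate integer replicate number (1-based).
#' @return an integer seed below 2^31.
#' @export
cellSeed <- function(master_seed, cell_index, replicate) {
    as.integer(((master_seed %% 100000) * 20011 +
                cell_index * 211 + replicate) %% 2147483647)
}

applyDimred <- function(cube, dimred, seed) {
    switch(dimred,
        raw = intensityMatrix(cube),
        pca = reducedScores(pcaReduce(cube, 4)),
        spca = reducedScores(spcaReduce(cube, 4, lag = 5)),
        mnf = reducedScores(mnfReduce(cube, 6)),
        tsne = reducedScores(tsneEmbed(cube, 2, perplexity = 10,
                                       pca_predims = 10, seed = seed)),
        stop("unknown dimension reduction: ", dimred))
}

applyClusterer <- function(X, cube, method, k, seed, gmm_cov = "auto") {
    switch(method,
        kmeans_euclidean = kmeansCluster(X, k, "euclidean", seed = seed),
        kmeans_correlation = kmeansCluster(X, k, "correlation",
                                           seed = seed),
        gmm = gmmEM(X, k, cov_structure = gmm_cov, seed = seed),
        sasa = sasa(list(data = X, coords = pixelCoords(cube)), k,
                    seed = seed),
        stop("unknown clustering method: ", method))
}

#' Run a simulation study
#'
#' For every combination of scenario, clustering method, dimension
#' reduction and replicate: simulate the scenario (per-cell seed derived
#' from the master seed by \code{\link{cellSeed}}), optionally reduce the
#' dimension, cluster with k equal to the true cluster count, and score by
#' ARI against the ground truth. k-means with correlation distance is
#' skipped when paired with a dimension reduction (orthogonal bases do not
#' carry a meaningful variable-correlation structure); the skip is
#' recorded in the returned table's \code{note} column. Stage failures are
#' recorded per cell (\code{error} column) and the run continues.
#'
#' @param scenarios list of \code{\link{scenarioSpec}} objects (the seed
#'   inside each spec is replaced by the per-cell seed).
#' @param methods character vector from \{"kmeans_euclidean",
#'   "kmeans_correlation", "gmm", "sasa"\}.
#' @param dimreds character vector from \{"raw", "pca", "spca", "mnf",
#'   "tsne"\}.
#' @param reps replicates per cell (default 10).
#' @param master_seed integer master seed (default 1).
#' @param gmm_cov GMM covariance structure (default "auto" = BIC
#'   selection).
#' @param checkpoint_dir optional directory; each completed cell is saved
#'   as a CSV there and reloaded instead of recomputed on a rerun.
#' @param verbose print per-cell progress (default FALSE).
#' @return long-format data.frame (one record per scenario x method x
#'   dimred x replicate): scenario descriptors, method, dimred, replicate,
#'   seed, ari, runtime_s, note, error.
#' @export
runStudy <- function(scenarios, methods, dimreds = "raw", reps = 10,
                     master_seed = 1L, gmm_cov = "auto",
                     checkpoint_dir = NULL, verbose = FALSE) {
    stopifnot(reps >= 1, length(scenarios) >= 1)
    grid <- expand.grid(scenario = seq_along(scenarios),
                        method = methods, dimred = dimreds,
                        stringsAsFactors = FALSE)
    if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
        dir.create(checkpoint_dir, recursive = TRUE)
    records <- vector("list", nrow(grid) * reps)
    rec_i <- 0L
    for (g in seq_len(nrow(grid))) {
        sc_i <- grid$scenario[g]
        spec <- scenarios[[sc_i]]
        method <- grid$method[g]
        dimred <- grid$dimred[g]
        scenario_id <- sprintf("type%d_%s_%s_k%d", spec$spatial_type,
                               spec$distribution$kind, spec$mean_mod,
                               spec$n_clusters)
        ckpt <- if (!is.null(checkpoint_dir))
            file.path(checkpoint_dir,
                      sprintf("cell_%s_%s_%s.csv", scenario_id, method,
                              dimred))
        else NULL
        if (!is.null(ckpt) && file.exists(ckpt)) {
            cell <- read.csv(ckpt)
            for (r in seq_len(nrow(cell))) {
                rec_i <- rec_i + 1L
                records[[rec_i]] <- cell[r, , drop = FALSE]
            }
            next
        }
        cell_rows <- vector("list", reps)
        for (r in seq_len(reps)) {
            seed <- cellSeed(master_seed, sc_i, r)
            skip_note <- ""
            t0 <- proc.time()[["elapsed"]]
            out <- if (method == "kmeans_correlation" && dimred != "raw") {
                skip_note <- "skipped: correlation distance is not meaningful on orthogonal reduced bases"
                list(ari = NA_real_, error = "")
            } else tryCatch({
                rspec <- spec; rspec$seed <- seed
                cube <- simulateScenario(rspec)
                X <- applyDimred(cube, dimred, seed)
                res <- applyClusterer(X, cube, method, spec$n_clusters,
                                      seed, gmm_cov)
                list(ari = adjustedRandIndex(clusterLabels(res),
                                             truthLabels(cube)),
                     error = "")
            }, error = function(e)
                list(ari = NA_real_, error = conditionMessage(e)))
            rt <- proc.time()[["elapsed"]] - t0
            cell_rows[[r]] <- data.frame(
                scenario = scenario_id, spatial_type = spec$spatial_type,
                distribution = spec$distribution$kind,
                mean_mod = spec$mean_mod, n_clusters = spec$n_clusters,
                method = method, dimred = dimred, replicate = r,
                seed = seed, ari = out$ari, runtime_s = rt,
                note = skip_note, error = out$error,
                stringsAsFactors = FALSE)
        }
        cell <- do.call(rbind, cell_rows)
        if (!is.null(ckpt)) write.csv(cell, ckpt, row.names = FALSE)
        if (verbose)
            message(sprintf("[%d/%d] %s | %s | %s : median ARI %.3f",
                            g, nrow(grid), scenario_id, method, dimred,
                            median(cell$ari)))
        for (r in seq_len(reps)) {
            rec_i <- rec_i + 1L
            records[[rec_i]] <- cell_rows[[r]]
        }
    }
    do.call(rbind, records[seq_len(rec_i)])
}

#' Summarize a benchmark table by median ARI
#'
#' Median over replicates per (scenario, method, dimred) cell, with the
#' replicate count per cell.
#'
#' @param table a long-format benchmark table from \code{\link{runStudy}}.
#' @return data.frame with scenario, method, dimred, median_ari, n_reps.
#' @export
summarizeMedianAri <- function(table) {
    if (is.null(table) || nrow(table) == 0)
        stop("the benchmark table is empty")
    agg <- aggregate(ari ~ scenario + method + dimred, data = table,
                     FUN = function(x) median(x, na.rm = TRUE),
                     na.action = stats::na.pass)
    cnt <- aggregate(ari ~ scenario + method + dimred, data = table,
                     FUN = function(x) sum(is.finite(x)),
                     na.action = stats::na.pass)
    names(agg)[names(agg) == "ari"] <- "median_ari"
    agg$n_reps <- cnt$ari
    agg[order(agg$scenario, agg$method, agg$dimred), ]
}

#' Pivot a median-ARI summary into a heatmap-ready matrix
#'
#' @param summary output of \code{\link{summarizeMedianAri}}.
#' @return numeric matrix, scenarios x (method.dimred) cells.
#' @export
medianAriMatrix <- function(summary) {
    summary$cell <- paste(summary$method, summary$dimred, sep = ".")
    out <- stats::xtabs(median_ari ~ scenario + cell, data = summary,
                        na.action = stats::na.pass)
    m <- matrix(as.numeric(out), nrow(out), ncol(out),
                dimnames = dimnames(out))
    m
}

#' Write cluster labels as a CSV of (x, y, label)
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param coords pixel coordinates matrix.
#' @param file CSV path.
#' @return the file path, invisibly.
#' @export
writeLabelsCSV <- function(result, coords, file) {
    write.csv(data.frame(x = coords[, 1], y = coords[, 2],
                         label = clusterLabels(result)),
              file, row.names = FALSE)
    invisible(file)
}
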