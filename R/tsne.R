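# t-SNE adapter. The embedding itself is delegated to the established
# Barnes-Hut implementation in scikit-learn (driven through the `python`
# interpreter on the PATH); this package contributes only the PCA
# pre-reduction and the benchmark plumbing around it.

#' t-SNE embedding (Barnes-Hut, external implementation)
#'
#' PCA pre-reduction to \code{pca_predims} dimensions in R, then a standard
#' Barnes-Hut t-SNE embedding computed by scikit-learn's \code{TSNE}
#' (fixed \code{random_state}, PCA initialization), making the result
#' deterministic given the seed.
#'
#' @param X numeric matrix, observations x features (or an
#'   \linkS4class{MsiSimCube}).
#' @param n_components embedding dimension, 2 or 3 (default 2).
#' @param perplexity t-SNE perplexity (default 10); must be smaller than
#'   (observations - 1) / 3.
#' @param pca_predims PCA dimensions fed to t-SNE (default 10).
#' @param seed integer seed.
#' @return A \linkS4class{ReducedData} (method "tsne").
#' @export
tsneEmbed <- function(X, n_components = 2, perplexity = 10,
                      pca_predims = 10, seed = 1L) {
    X <- resolveDataCoords(X)$X
    if (!n_components %in% 2:3)
        stop("'n_components' must be 2 or 3")
    if (perplexity >= (nrow(X) - 1) / 3)
        stop("'perplexity' must be smaller than (observations - 1) / 3")
    Xr <- if (ncol(X) > pca_predims)
        reducedScores(pcaReduce(X, pca_predims))
    else scale(X, center = TRUE, scale = FALSE)
    py <- Sys.which("python")
    if (!nzchar(py)) py <- Sys.which("python3")
    if (!nzchar(py))
        stop("no 'python' interpreter found on the PATH for the t-SNE backend")
    fin <- tempfile(fileext = ".csv")
    fout <- tempfile(fileext = ".csv")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    utils::write.table(Xr, fin, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    code <- sprintf(paste0(
        "import numpy as np\n",
        "from sklearn.manifold import TSNE\n",
        "X = np.loadtxt(%s, delimiter=',', ndmin=2)\n",
        "emb = TSNE(n_components=%d, perplexity=%.6f, random_state=%d,\n",
        "           init='pca', learning_rate='auto').fit_transform(X)\n",
        "np.savetxt(%s, emb, delimiter=',')\n"),
        deparse(fin), as.integer(n_components), perplexity,
        as.integer(seed), deparse(fout))
    status <- system2(py, c("-c", shQuote(code)), stdout = FALSE,
                      stderr = "")
    if (status != 0L || !file.exists(fout))
        stop("the t-SNE backend failed (exit status ", status, ")")
    emb <- as.matrix(read.csv(fout, header = FALSE))
    dimnames(emb) <- NULL
    new("ReducedData", scores = emb, method = "tsne",
        n_components = as.integer(n_components),
        extras = list(perplexity = perplexity, pca_predims = pca_predims,
                      seed = as.integer(seed)))
}
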