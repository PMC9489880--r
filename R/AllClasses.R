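#' @import methods
#' @importFrom stats cor cov dist median optim quantile rnorm runif sd var
#'   aggregate kmeans prcomp setNames rbinom
#' @importFrom utils head read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# ---------------------------------------------------------------------------
# Geostatistical model objects
# ---------------------------------------------------------------------------

#' Spherical covariance model
#'
#' Parameterizes the spherical covariance function by its range \code{a}
#' (pixel units; the lag beyond which observations are uncorrelated), its
#' sill \code{b} (the variance reached at the range) and an optional nugget
#' (added at lag zero only).
#'
#' @slot range_a numeric(1), range, must be > 0.
#' @slot sill_b numeric(1), sill, must be > 0.
#' @slot nugget numeric(1), nugget variance, must be >= 0.
#' @export
setClass("SphericalModel",
    representation(range_a = "numeric", sill_b = "numeric", nugget = "numeric"),
    prototype(range_a = 20, sill_b = 0.1, nugget = 0))

setValidity("SphericalModel", function(object) {
    msg <- character()
    if (length(object@range_a) != 1L || !is.finite(object@range_a) ||
        object@range_a <= 0)
        msg <- c(msg, "'range_a' must be a single positive number")
    if (length(object@sill_b) != 1L || !is.finite(object@sill_b) ||
        object@sill_b <= 0)
        msg <- c(msg, "'sill_b' must be a single positive number")
    if (length(object@nugget) != 1L || !is.finite(object@nugget) ||
        object@nugget < 0)
        msg <- c(msg, "'nugget' must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' Construct a spherical covariance model
#'
#' @param range_a range parameter (pixel units), > 0.
#' @param sill_b sill parameter (variance units), > 0.
#' @param nugget nugget variance, >= 0 (default 0; the generator never uses a
#'   nonzero nugget).
#' @return A \linkS4class{SphericalModel}.
#' @examples
#' sphericalModel(20, 0.1)
#' @export
sphericalModel <- function(range_a, sill_b, nugget = 0) {
    new("SphericalModel", range_a = as.numeric(range_a),
        sill_b = as.numeric(sill_b), nugget = as.numeric(nugget))
}

#' Geometric anisotropy transform
#'
#' Rotation angle (degrees) and major/minor range scaling used to map
#' isotropic pixel coordinates into an anisotropic space: row-vectors of
#' coordinates are right-multiplied by (R T)^-1 with R the rotation matrix
#' and T = diag(a_max, a_min).
#'
#' @slot theta numeric(1), rotation angle in degrees.
#' @slot a_max numeric(1), major range scale, >= a_min.
#' @slot a_min numeric(1), minor range scale, > 0.
#' @export
setClass("AnisotropyTransform",
    representation(theta = "numeric", a_max = "numeric", a_min = "numeric"),
    prototype(theta = 45, a_max = 1, a_min = 0.5))

setValidity("AnisotropyTransform", function(object) {
    msg <- character()
    if (length(object@theta) != 1L || !is.finite(object@theta))
        msg <- c(msg, "'theta' must be a single finite number (degrees)")
    if (length(object@a_min) != 1L || !is.finite(object@a_min) ||
        object@a_min <= 0)
        msg <- c(msg, "'a_min' must be > 0")
    if (length(object@a_max) != 1L || !is.finite(object@a_max) ||
        object@a_max < object@a_min)
        msg <- c(msg, "'a_max' must be >= 'a_min'")
    if (length(msg)) msg else TRUE
})

#' Construct an anisotropy transform
#'
#' @param theta rotation angle in degrees.
#' @param a_max major range scale (dimensionless).
#' @param a_min minor range scale (dimensionless), > 0.
#' @return An \linkS4class{AnisotropyTransform}. The default (45 degrees,
#'   1, 0.5) is the anisotropy applied in all simulated scenarios.
#' @examples
#' anisotropyTransform(45, 1, 0.5)
#' @export
anisotropyTransform <- function(theta = 45, a_max = 1, a_min = 0.5) {
    new("AnisotropyTransform", theta = as.numeric(theta),
        a_max = as.numeric(a_max), a_min = as.numeric(a_min))
}

#' Pixel grid with ground-truth cluster labels
#'
#' Integer (x, y) pixel coordinates of a rectangular acquisition together
#' with per-pixel ground-truth cluster labels.
#'
#' @slot coords integer matrix, n_pixels x 2 (columns x, y); rows unique.
#' @slot labels integer vector of cluster ids covering 1..k with no empty
#'   cluster.
#' @export
setClass("PixelGrid",
    representation(coords = "matrix", labels = "integer"))

setValidity("PixelGrid", function(object) {
    msg <- character()
    if (ncol(object@coords) != 2L)
        msg <- c(msg, "'coords' must have two columns (x, y)")
    if (nrow(object@coords) != length(object@labels))
        msg <- c(msg, "one label per coordinate row required")
    if (anyDuplicated(object@coords))
        msg <- c(msg, "pixel coordinates must be unique")
    k <- max(object@labels)
    if (!setequal(unique(object@labels), seq_len(k)))
        msg <- c(msg, "labels must cover 1..k with no empty cluster")
    if (length(msg)) msg else TRUE
})

#' Construct a rectangular pixel grid with banded cluster layout
#'
#' Clusters are laid out as equal bands along the y axis: two clusters on an
#' 80 x 80 grid give two 80 x 40 halves, four clusters give four 80 x 20
#' bands.
#'
#' @param nx,ny grid extent in pixels.
#' @param n_clusters number of cluster bands; must divide \code{ny}.
#' @return A \linkS4class{PixelGrid}.
#' @examples
#' g <- pixelGrid(8, 8, 2)
#' table(gridLabels(g))
#' @export
pixelGrid <- function(nx, ny, n_clusters = 2) {
    nx <- as.integer(nx); ny <- as.integer(ny)
    if (ny %% n_clusters != 0L)
        stop("'n_clusters' must divide 'ny' for a banded layout")
    coords <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny)))
    storage.mode(coords) <- "integer"
    band <- ny %/% n_clusters
    labels <- as.integer(ceiling(coords[, "y"] / band))
    new("PixelGrid", coords = coords, labels = labels)
}

#' @describeIn pixelGrid construct a grid from explicit coordinates/labels.
#' @param coords integer matrix of (x, y) positions.
#' @param labels integer cluster labels, one per row of \code{coords}.
#' @export
pixelGridFromCoords <- function(coords, labels) {
    coords <- as.matrix(coords)
    colnames(coords) <- c("x", "y")
    new("PixelGrid", coords = coords, labels = as.integer(labels))
}

#' Empirical variogram estimate
#'
#' Binned semivariances r(h) with lag-bin centers and pair counts N(h).
#' Only bins with at least one pair are reported.
#'
#' @slot lag numeric, strictly increasing lag-bin centers (pixel units).
#' @slot semivariance numeric, r(h) per bin (intensity^2 units), >= 0.
#' @slot pair_counts integer, N(h) per bin, >= 1.
#' @export
setClass("VariogramEstimate",
    representation(lag = "numeric", semivariance = "numeric",
                   pair_counts = "integer"))

setValidity("VariogramEstimate", function(object) {
    msg <- character()
    n <- length(object@lag)
    if (length(object@semivariance) != n || length(object@pair_counts) != n)
        msg <- c(msg, "slots must have equal length")
    if (any(object@semivariance < 0))
        msg <- c(msg, "semivariance must be non-negative")
    if (any(object@pair_counts < 1L))
        msg <- c(msg, "every reported bin needs at least one pair")
    if (n > 1L && any(diff(object@lag) <= 0))
        msg <- c(msg, "lag bin centers must be strictly increasing")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Simulated data cube
# ---------------------------------------------------------------------------

#' Simulated MSI-like intensity cube
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one assay
#' \code{"intensity"} (variables as rows, pixels as columns), pixel
#' coordinates and ground-truth cluster labels in \code{colData} (columns
#' \code{x}, \code{y}, \code{truth}), and scenario provenance (scenario
#' spec, indices of mean-shifted variables, indices of appended noise
#' variables) in \code{metadata()}.
#'
#' @export
setClass("MsiSimCube", contains = "SummarizedExperiment")

setValidity("MsiSimCube", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("x", "y", "truth") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'x', 'y' and 'truth'")
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    if (length(msg)) msg else TRUE
})

#' Construct an MsiSimCube
#'
#' @param data numeric matrix, pixels x variables.
#' @param grid a \linkS4class{PixelGrid} with one row per data row.
#' @param scenario list of scenario provenance (may be empty).
#' @param modified_vars integer indices of mean-shifted variables.
#' @param noise_vars integer indices of appended non-spatial noise variables.
#' @return An \linkS4class{MsiSimCube}.
#' @export
MsiSimCube <- function(data, grid, scenario = list(),
                       modified_vars = integer(), noise_vars = integer()) {
    data <- as.matrix(data)
    if (nrow(data) != nrow(grid@coords))
        stop("row count of 'data' must equal the grid pixel count")
    if (is.null(colnames(data)))
        colnames(data) <- paste0("V", seq_len(ncol(data)))
    assay <- t(data)
    colnames(assay) <- paste0("px", seq_len(ncol(assay)))
    cd <- S4Vectors::DataFrame(x = grid@coords[, 1], y = grid@coords[, 2],
                               truth = grid@labels,
                               row.names = colnames(assay))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = assay), colData = cd,
        metadata = list(scenario = scenario,
                        modified_vars = as.integer(modified_vars),
                        noise_vars = as.integer(noise_vars)))
    new("MsiSimCube", se)
}

# ---------------------------------------------------------------------------
# Result containers
# ---------------------------------------------------------------------------

#' Clustering result
#'
#' @slot labels integer per-pixel/observation class labels (at most k
#'   distinct values).
#' @slot method character method identifier.
#' @slot k integer requested cluster count.
#' @slot objective numeric final objective (within-cluster sum of
#'   dissimilarities for k-means; log-likelihood for GMM).
#' @slot seed integer RNG seed used.
#' @slot n_iter integer iterations used (>= 1).
#' @slot extras list of method-specific diagnostics (e.g. the per-iteration
#'   log-likelihood trace for GMM, the per-iteration objective trace for
#'   correlation k-means).
#' @export
setClass("ClusterResult",
    representation(labels = "integer", method = "character", k = "integer",
                   objective = "numeric", seed = "integer",
                   n_iter = "integer", extras = "list"))

setValidity("ClusterResult", function(object) {
    msg <- character()
    if (length(unique(object@labels)) > object@k)
        msg <- c(msg, "more distinct labels than requested clusters")
    if (object@n_iter < 1L)
        msg <- c(msg, "'n_iter' must be >= 1")
    if (!is.finite(object@objective))
        msg <- c(msg, "'objective' must be finite")
    if (length(msg)) msg else TRUE
})

#' Dimension-reduction result
#'
#' @slot scores numeric matrix, observations x components.
#' @slot method character identifier ("pca", "spca", "mnf", "tsne").
#' @slot n_components integer component count.
#' @slot extras list of diagnostics (explained-variance ratios, eigenvalues,
#'   signal-to-noise eigenvalues, ...).
#' @export
setClass("ReducedData",
    representation(scores = "matrix", method = "character",
                   n_components = "integer", extras = "list"))

setValidity("ReducedData", function(object) {
    msg <- character()
    if (ncol(object@scores) != object@n_components)
        msg <- c(msg, "'scores' column count must match 'n_components'")
    if (!all(is.finite(object@scores)))
        msg <- c(msg, "scores must be finite")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MSI preprocessing containers
# ---------------------------------------------------------------------------

#' A set of centroided/profile spectra with pixel coordinates
#'
#' @slot spectra list of two-column matrices (mz, intensity), one per pixel;
#'   m/z sorted ascending, intensities non-negative.
#' @slot coords integer matrix of pixel (x, y) positions.
#' @slot mz_range numeric(2) m/z range bounds in Da.
#' @export
setClass("SpectrumSet",
    representation(spectra = "list", coords = "matrix", mz_range = "numeric"))

setValidity("SpectrumSet", function(object) {
    msg <- character()
    if (length(object@spectra) != nrow(object@coords))
        msg <- c(msg, "one spectrum per coordinate row required")
    ok <- vapply(object@spectra, function(s) {
        is.matrix(s) && ncol(s) == 2L &&
            (nrow(s) < 2L || !is.unsorted(s[, 1], strictly = FALSE)) &&
            all(s[, 2] >= 0)
    }, logical(1))
    if (!all(ok))
        msg <- c(msg, "spectra must be 2-column (mz, intensity) matrices, m/z ascending, intensities >= 0")
    if (length(object@mz_range) != 2L || diff(object@mz_range) <= 0)
        msg <- c(msg, "'mz_range' must be increasing bounds")
    if (length(msg)) msg else TRUE
})

#' Construct a SpectrumSet
#'
#' @param spectra list of two-column (mz, intensity) matrices.
#' @param coords integer matrix of pixel positions.
#' @param mz_range numeric(2) m/z bounds (Da).
#' @return A \linkS4class{SpectrumSet}.
#' @export
SpectrumSet <- function(spectra, coords, mz_range) {
    spectra <- lapply(spectra, function(s) {
        s <- as.matrix(s)
        colnames(s) <- c("mz", "intensity")
        s
    })
    coords <- as.matrix(coords)
    colnames(coords) <- c("x", "y")
    new("SpectrumSet", spectra = spectra, coords = coords,
        mz_range = as.numeric(mz_range))
}

#' Binned ion-image cube
#'
#' @slot intensities numeric array, x by y by bins.
#' @slot bin_centers numeric bin centers in Da (from a constant-width bin
#'   grid; gaps appear where the matrix-peak filter removed bins).
#' @slot mask logical matrix (x by y); TRUE = on-tissue.
#' @slot removed_bins integer indices of bins removed by the matrix-peak
#'   filter (relative to the original binning).
#' @export
setClass("IonImageCube",
    representation(intensities = "array", bin_centers = "numeric",
                   mask = "matrix", removed_bins = "integer"))

setValidity("IonImageCube", function(object) {
    msg <- character()
    d <- dim(object@intensities)
    if (length(d) != 3L)
        msg <- c(msg, "'intensities' must be a 3-d array (x, y, bins)")
    else {
        if (d[3] != length(object@bin_centers))
            msg <- c(msg, "bin count mismatch")
        if (!all(dim(object@mask) == d[1:2]))
            msg <- c(msg, "mask dimensions must match the image plane")
    }
    if (length(msg)) msg else TRUE
})
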