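# Accessors and show methods for the S4 containers.

#' Pixel intensity matrix of a cube
#'
#' Returns the pixels x variables intensity matrix (the transpose of the
#' stored assay, which is variables x pixels).
#'
#' @param object an \linkS4class{MsiSimCube}.
#' @return numeric matrix, pixels x variables.
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' @rdname intensityMatrix
#' @export
setMethod("intensityMatrix", "MsiSimCube", function(object) {
    t(SummarizedExperiment::assay(object, "intensity"))
})

#' Pixel coordinates
#' @param object an \linkS4class{MsiSimCube} or \linkS4class{PixelGrid}.
#' @return integer matrix with columns x, y.
#' @export
setGeneric("pixelCoords", function(object) standardGeneric("pixelCoords"))

#' @rdname pixelCoords
#' @export
setMethod("pixelCoords", "MsiSimCube", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cbind(x = cd$x, y = cd$y)
})

#' @rdname pixelCoords
#' @export
setMethod("pixelCoords", "PixelGrid", function(object) object@coords)

#' Ground-truth cluster labels
#' @param object an \linkS4class{MsiSimCube}.
#' @return integer vector of per-pixel labels.
#' @export
setGeneric("truthLabels", function(object) standardGeneric("truthLabels"))

#' @rdname truthLabels
#' @export
setMethod("truthLabels", "MsiSimCube", function(object) {
    as.integer(SummarizedExperiment::colData(object)$truth)
})

#' Grid labels of a PixelGrid
#' @param object a \linkS4class{PixelGrid}.
#' @return integer vector of per-pixel cluster labels.
#' @export
gridLabels <- function(object) object@labels

#' Pixel grid of a cube
#' @param object an \linkS4class{MsiSimCube}.
#' @return the \linkS4class{PixelGrid} of the cube.
#' @export
setGeneric("pixelGridOf", function(object) standardGeneric("pixelGridOf"))

#' @rdname pixelGridOf
#' @export
setMethod("pixelGridOf", "MsiSimCube", function(object) {
    pixelGridFromCoords(pixelCoords(object), truthLabels(object))
})

#' Scenario provenance, shifted and noise variable indices
#' @param object an \linkS4class{MsiSimCube}.
#' @return \code{scenarioInfo}: the scenario provenance list;
#'   \code{modifiedVars} / \code{noiseVars}: integer variable indices.
#' @export
scenarioInfo <- function(object) S4Vectors::metadata(object)$scenario

#' @rdname scenarioInfo
#' @export
modifiedVars <- function(object) S4Vectors::metadata(object)$modified_vars

#' @rdname scenarioInfo
#' @export
noiseVars <- function(object) S4Vectors::metadata(object)$noise_vars

#' Cluster labels of a ClusterResult
#' @param object a \linkS4class{ClusterResult}.
#' @return integer vector of labels.
#' @export
clusterLabels <- function(object) object@labels

#' Scores matrix of a ReducedData
#' @param object a \linkS4class{ReducedData}.
#' @return numeric matrix, observations x components.
#' @export
reducedScores <- function(object) object@scores

#' Diagnostics list of a ReducedData or ClusterResult
#' @param object a \linkS4class{ReducedData} or \linkS4class{ClusterResult}.
#' @return the extras list.
#' @export
resultExtras <- function(object) object@extras

#' Convert a VariogramEstimate to a data.frame
#'
#' Long format (lag, semivariance, count), suitable for CSV export.
#'
#' @param x a \linkS4class{VariogramEstimate}.
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return data.frame with columns lag, semivariance, count.
#' @export
as.data.frame.VariogramEstimate <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
    data.frame(lag = x@lag, semivariance = x@semivariance,
               count = x@pair_counts)
}

setMethod("show", "SphericalModel", function(object) {
    cat("SphericalModel: range =", object@range_a, ", sill =", object@sill_b,
        ", nugget =", object@nugget, "\n")
})

setMethod("show", "AnisotropyTransform", function(object) {
    cat("AnisotropyTransform: theta =", object@theta, "deg, a_max =",
        object@a_max, ", a_min =", object@a_min, "\n")
})

setMethod("show", "PixelGrid", function(object) {
    cat("PixelGrid:", nrow(object@coords), "pixels,",
        max(object@labels), "clusters\n")
})

setMethod("show", "VariogramEstimate", function(object) {
    cat("VariogramEstimate:", length(object@lag), "lag bins, lags",
        round(min(object@lag), 2), "-", round(max(object@lag), 2), "\n")
})

setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult:", object@method, "| k =", object@k,
        "| objective =", signif(object@objective, 6),
        "| iterations =", object@n_iter, "\n")
})

setMethod("show", "ReducedData", function(object) {
    cat("ReducedData:", object@method, "|", nrow(object@scores),
        "observations x", object@n_components, "components\n")
})

setMethod("show", "SpectrumSet", function(object) {
    cat("SpectrumSet:", length(object@spectra), "spectra, m/z",
        object@mz_range[1], "-", object@mz_range[2], "Da\n")
})

setMethod("show", "IonImageCube", function(object) {
    d <- dim(object@intensities)
    cat("IonImageCube:", d[1], "x", d[2], "pixels x", d[3], "bins;",
        sum(object@mask), "on-tissue pixels\n")
})
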