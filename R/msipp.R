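# MSI preprocessing: 0.1 Da binning with local-maxima peak picking,
# off-tissue matrix-peak removal, TIC normalization and per-ion-image
# median filtering. Exercised on synthetic spectrum fixtures; the plain
# CSV spectrum format (pixel_id, mz, intensity) is the supported input.

#' Read spectra from the plain CSV format
#'
#' Columns: pixel_id, x, y, mz, intensity; one row per point.
#'
#' @param file CSV path.
#' @param mz_range numeric(2) m/z bounds (Da); defaults to the data range.
#' @return A \linkS4class{SpectrumSet}.
#' @export
readSpectrumCSV <- function(file, mz_range = NULL) {
    df <- read.csv(file)
    need <- c("pixel_id", "x", "y", "mz", "intensity")
    if (!all(need %in% names(df)))
        stop("CSV must have columns: ", paste(need, collapse = ", "))
    ids <- unique(df$pixel_id)
    spectra <- lapply(ids, function(i) {
        s <- df[df$pixel_id == i, c("mz", "intensity")]
        s <- s[order(s$mz), ]
        as.matrix(s)
    })
    coords <- do.call(rbind, lapply(ids, function(i)
        as.integer(df[match(i, df$pixel_id), c("x", "y")])))
    if (is.null(mz_range))
        mz_range <- range(df$mz)
    SpectrumSet(spectra, coords, mz_range)
}

# Strict local maxima of an intensity sequence; plateaus take the leftmost
# point; endpoints are not candidates.
localMaximaIdx <- function(y) {
    n <- length(y)
    if (n < 3L) return(integer())
    # run-length encode so plateaus act as single points
    r <- rle(y)
    v <- r$values
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    m <- length(v)
    if (m < 3L) return(integer())
    cand <- which(v[2:(m - 1)] > v[1:(m - 2)] &
                  v[2:(m - 1)] > v[3:m]) + 1L
    starts[cand]
}

#' Bin spectra and pick peaks
#'
#' Half-open m/z bins [low, low + width) anchored at the configured range
#' start. Per spectrum and bin, candidate peaks are strict local maxima of
#' the raw point list (plateaus take the leftmost point; endpoints are not
#' candidates); the maximum-intensity candidate is stored. Empty bins are
#' zero.
#'
#' @param spectra a \linkS4class{SpectrumSet} with m/z range bounds set.
#' @param bin_width bin size in Da (default 0.1).
#' @return An \linkS4class{IonImageCube} with an all-TRUE mask.
#' @export
binAndPick <- function(spectra, bin_width = 0.1) {
    stopifnot(is(spectra, "SpectrumSet"), bin_width > 0)
    lo <- spectra@mz_range[1]; hi <- spectra@mz_range[2]
    n_bins <- ceiling((hi - lo) / bin_width)
    centers <- lo + (seq_len(n_bins) - 0.5) * bin_width
    coords <- spectra@coords
    nx <- max(coords[, 1]); ny <- max(coords[, 2])
    cube <- array(0, dim = c(nx, ny, n_bins))
    for (i in seq_along(spectra@spectra)) {
        s <- spectra@spectra[[i]]
        if (nrow(s) && is.unsorted(s[, 1]))
            stop("spectrum ", i, " is not sorted by m/z")
        pk <- localMaximaIdx(s[, 2])
        if (!length(pk)) next
        mz <- s[pk, 1]; int <- s[pk, 2]
        b <- floor((mz - lo) / bin_width) + 1L
        ok <- b >= 1L & b <= n_bins
        b <- b[ok]; int <- int[ok]
        if (!length(b)) next
        best <- tapply(int, b, max)
        cube[coords[i, 1], coords[i, 2], as.integer(names(best))] <- best
    }
    new("IonImageCube", intensities = cube, bin_centers = centers,
        mask = matrix(TRUE, nx, ny), removed_bins = integer())
}

#' Remove matrix-associated peaks using an off-tissue mask
#'
#' A bin is removed when its mean off-tissue intensity exceeds
#' \code{prevalence_ratio} times its mean on-tissue intensity (the matrix
#' peaks are identified from spectra collected outside the tissue).
#'
#' @param cube an \linkS4class{IonImageCube}.
#' @param mask logical matrix, TRUE = on-tissue; both regions must be
#'   non-empty.
#' @param prevalence_ratio removal threshold (default 1.0).
#' @return the filtered \linkS4class{IonImageCube}; the dropped bin
#'   indices are in \code{@removed_bins}.
#' @export
matrixPeakFilter <- function(cube, mask, prevalence_ratio = 1.0) {
    stopifnot(is(cube, "IonImageCube"))
    mask <- as.matrix(mask)
    if (!any(mask) || all(mask))
        stop("the mask must contain both on- and off-tissue pixels")
    n_bins <- dim(cube@intensities)[3]
    on_mean <- vapply(seq_len(n_bins), function(b)
        mean(cube@intensities[, , b][mask]), numeric(1))
    off_mean <- vapply(seq_len(n_bins), function(b)
        mean(cube@intensities[, , b][!mask]), numeric(1))
    drop <- which(off_mean > prevalence_ratio * on_mean)
    keep <- setdiff(seq_len(n_bins), drop)
    new("IonImageCube",
        intensities = cube@intensities[, , keep, drop = FALSE],
        bin_centers = cube@bin_centers[keep], mask = mask,
        removed_bins = as.integer(drop))
}

#' Otsu threshold helper for tissue-mask construction
#'
#' Threshold of a single ion image maximizing the between-class variance;
#' replaces the interactive visual-inspection step with a reproducible
#' one.
#'
#' @param img numeric matrix (one ion image).
#' @param n_breaks histogram resolution (default 256).
#' @return the threshold value; \code{img > threshold} is the tissue mask.
#' @export
otsuThreshold <- function(img, n_breaks = 256) {
    v <- as.vector(img)
    br <- seq(min(v), max(v), length.out = n_breaks + 1)
    h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_breaks)
    p <- h / sum(h)
    omega <- cumsum(p)
    mids <- (br[-1] + br[-length(br)]) / 2
    mu <- cumsum(p * mids)
    mu_t <- mu[length(mu)]
    sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
    sb[!is.finite(sb)] <- 0
    # the maximizing plateau spans any empty gap between the two classes;
    # take its midpoint
    idx <- which(sb == max(sb))
    mean(mids[range(idx)])
}

#' Total ion current normalization
#'
#' Each on-tissue pixel's bin vector is divided by its sum and multiplied
#' by the mean on-tissue total, so per-pixel sums are equal afterwards;
#' within-pixel bin proportions are preserved exactly. Zero-sum pixels are
#' flagged with a warning and left unnormalized.
#'
#' @param cube an \linkS4class{IonImageCube}.
#' @return the normalized \linkS4class{IonImageCube}.
#' @export
ticNormalize <- function(cube) {
    stopifnot(is(cube, "IonImageCube"))
    d <- dim(cube@intensities)
    flat <- matrix(cube@intensities, d[1] * d[2], d[3])
    on <- as.vector(cube@mask)
    tot <- rowSums(flat)
    zero <- on & tot == 0
    if (any(zero))
        warning(sum(zero), " on-tissue pixel(s) with zero total intensity left unnormalized")
    target <- mean(tot[on & !zero])
    scale_idx <- on & !zero
    flat[scale_idx, ] <- flat[scale_idx, ] / tot[scale_idx] * target
    new("IonImageCube", intensities = array(flat, d),
        bin_centers = cube@bin_centers, mask = cube@mask,
        removed_bins = cube@removed_bins)
}

# 2-d median filter with reflected edges.
medianFilter2D <- function(img, window = 3L) {
    if (window %% 2L != 1L)
        stop("'window' must be odd-sized")
    r <- (window - 1L) %/% 2L
    nx <- nrow(img); ny <- ncol(img)
    px <- reflectIndex(seq(1L - r, nx + r), nx)
    py <- reflectIndex(seq(1L - r, ny + r), ny)
    pad <- img[px, py, drop = FALSE]
    stack <- array(NA_real_, c(nx, ny, window^2))
    s <- 0L
    for (dx in 0:(window - 1L)) for (dy in 0:(window - 1L)) {
        s <- s + 1L
        stack[, , s] <- pad[dx + seq_len(nx), dy + seq_len(ny)]
    }
    apply(stack, c(1, 2), median)
}

#' Median filter every ion image
#'
#' Per-bin 2-d median filter over the pixel grid (default 3 x 3 window),
#' edges handled by reflection, each ion image filtered independently.
#'
#' @param cube an \linkS4class{IonImageCube}.
#' @param window odd window size (default 3).
#' @return the filtered \linkS4class{IonImageCube}.
#' @export
medianFilterImages <- function(cube, window = 3L) {
    stopifnot(is(cube, "IonImageCube"))
    out <- cube@intensities
    for (b in seq_len(dim(out)[3]))
        out[, , b] <- medianFilter2D(cube@intensities[, , b], window)
    new("IonImageCube", intensities = out,
        bin_centers = cube@bin_centers, mask = cube@mask,
        removed_bins = cube@removed_bins)
}

#' Run the full MSI preprocessing pipeline
#'
#' Enforces the order: binning + peak picking, matrix-peak removal, TIC
#' normalization, median filtering.
#'
#' @param spectra a \linkS4class{SpectrumSet}.
#' @param mask logical on-tissue mask.
#' @param bin_width bin size in Da (default 0.1).
#' @param prevalence_ratio matrix-peak removal threshold (default 1.0).
#' @param window median-filter window (default 3).
#' @return the preprocessed \linkS4class{IonImageCube}.
#' @export
preprocessMsi <- function(spectra, mask, bin_width = 0.1,
                          prevalence_ratio = 1.0, window = 3L) {
    cube <- binAndPick(spectra, bin_width)
    cube <- matrixPeakFilter(cube, mask, prevalence_ratio)
    cube <- ticNormalize(cube)
    medianFilterImages(cube, window)
}
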