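# Synthetic spectrum fixtures are built in code (helper-oracles.R); no
# binary data.

test_that("binAndPick stores the strongest local maximum per bin", {
    # hand trace: triplet around 400.0; the middle point is the local max
    s <- cbind(mz = c(399.95, 400.00, 400.05), intensity = c(1, 5, 2))
    ss <- SpectrumSet(list(s), rbind(c(1, 1)), c(400.0, 400.2))
    cube <- binAndPick(ss, 0.1)
    expect_equal(cube@intensities[1, 1, 1], 5)   # bin [400.0, 400.1)
    expect_equal(cube@intensities[1, 1, 2], 0)
    # two local maxima inside one bin: the larger one wins
    s2 <- cbind(mz = 400 + c(.01, .02, .03, .05, .06, .07),
                intensity = c(1, 3, 1, 2, 7, 2))
    ss2 <- SpectrumSet(list(s2), rbind(c(1, 1)), c(400.0, 400.1))
    expect_equal(binAndPick(ss2, 0.1)@intensities[1, 1, 1], 7)
    # monotone spectrum: no interior local maxima at all
    s3 <- cbind(mz = 400 + (1:10) / 100, intensity = 1:10)
    ss3 <- SpectrumSet(list(s3), rbind(c(1, 1)), c(400.0, 400.2))
    expect_true(all(binAndPick(ss3, 0.1)@intensities == 0))
})

test_that("binAndPick agrees with a brute-force per-bin scan on random spectra", {
    set.seed(23)
    for (i in 1:12) {
        n <- sample(5:50, 1)
        mz <- sort(runif(n, 400, 401))
        int <- round(abs(rnorm(n, 4, 3)), 1)  # ties make plateaus likely
        ss <- SpectrumSet(list(cbind(mz, int)), rbind(c(1, 1)), c(400, 401))
        got <- as.numeric(binAndPick(ss, 0.1)@intensities[1, 1, ])
        expect_equal(got, bruteBinPickSpectrum(mz, int, 400, 401, 0.1))
    }
})

test_that("matrix-peak filter removes planted off-tissue bins exactly", {
    set.seed(24)
    nx <- 6; ny <- 6; n_bins <- 12
    arr <- array(runif(nx * ny * n_bins, 1, 2), c(nx, ny, n_bins))
    mask <- matrix(FALSE, nx, ny); mask[2:5, 2:5] <- TRUE
    planted <- c(3, 7, 11)
    for (b in planted) {  # 5:1 off- vs on-tissue intensity
        arr[, , b][!mask] <- 5
        arr[, , b][mask] <- 1
    }
    for (b in setdiff(seq_len(n_bins), planted)) {
        arr[, , b][mask] <- arr[, , b][mask] + 3  # clearly tissue-borne
    }
    cube <- new("IonImageCube", intensities = arr,
                bin_centers = 400 + (seq_len(n_bins) - 0.5) / 10,
                mask = matrix(TRUE, nx, ny), removed_bins = integer())
    filt <- matrixPeakFilter(cube, mask, prevalence_ratio = 1.0)
    expect_equal(filt@removed_bins, planted)
    expect_equal(dim(filt@intensities)[3], n_bins - 3)
    expect_error(matrixPeakFilter(cube, matrix(TRUE, nx, ny)), "mask")
})

test_that("TIC normalization equalizes totals and preserves proportions", {
    ss <- makeSpectrumFixture(seed = 25)
    cube <- binAndPick(ss, 0.1)
    norm <- ticNormalize(cube)
    d <- dim(norm@intensities)
    tots <- rowSums(matrix(norm@intensities, d[1] * d[2], d[3]))
    expect_lt(diff(range(tots)) / mean(tots), 1e-10)
    # scaling one pixel's raw spectrum by 10 leaves its normalized bin
    # pattern unchanged (the global target total rescales every pixel
    # equally, so compare up to that common factor)
    cube2 <- cube
    cube2@intensities[2, 2, ] <- cube@intensities[2, 2, ] * 10
    norm2 <- ticNormalize(cube2)
    expect_equal(norm2@intensities[2, 2, ] / sum(norm2@intensities[2, 2, ]),
                 norm@intensities[2, 2, ] / sum(norm@intensities[2, 2, ]),
                 tolerance = 1e-12)
    d2 <- dim(norm2@intensities)
    tots2 <- rowSums(matrix(norm2@intensities, d2[1] * d2[2], d2[3]))
    expect_lt(diff(range(tots2)) / mean(tots2), 1e-10)
    # within-pixel proportions unchanged
    raw_prop <- cube@intensities[1, 1, ] / sum(cube@intensities[1, 1, ])
    new_prop <- norm@intensities[1, 1, ] / sum(norm@intensities[1, 1, ])
    expect_equal(new_prop, raw_prop, tolerance = 1e-12)
})

test_that("median filtering smooths spikes and matches a window oracle", {
    const <- matrix(5, 7, 7)
    cube <- new("IonImageCube",
                intensities = array(const, c(7, 7, 1)),
                bin_centers = 400.05, mask = matrix(TRUE, 7, 7),
                removed_bins = integer())
    expect_equal(medianFilterImages(cube)@intensities[, , 1], const)
    spiked <- const; spiked[4, 4] <- 100
    cube@intensities[, , 1] <- spiked
    expect_equal(medianFilterImages(cube)@intensities[, , 1], const)
    # checkerboard: interior pixels become the 9-neighborhood median
    cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
    cube@intensities <- array(cb[1:6, 1:6], c(6, 6, 1))
    cube@mask <- matrix(TRUE, 6, 6)
    got <- medianFilterImages(cube)@intensities[, , 1]
    for (i in 2:5) for (j in 2:5)
        expect_equal(got[i, j], median(cb[(i - 1):(i + 1), (j - 1):(j + 1)]))
})

test_that("the pipeline runs end to end in the documented order", {
    ss <- makeSpectrumFixture(seed = 26, nx = 6, ny = 6, n_points = 60)
    mask <- matrix(FALSE, 6, 6); mask[2:5, 2:5] <- TRUE
    # tissue pixels carry stronger signal than the bare-slide region
    on_idx <- which(mask[cbind(ss@coords[, 1], ss@coords[, 2])])
    ss@spectra[on_idx] <- lapply(ss@spectra[on_idx], function(s) {
        s[, 2] <- s[, 2] * 4
        s
    })
    out <- preprocessMsi(ss, mask, bin_width = 0.1)
    expect_s4_class(out, "IonImageCube")
    d <- dim(out@intensities)
    flat <- matrix(out@intensities, d[1] * d[2], d[3])
    expect_true(all(is.finite(flat)))
    # an Otsu threshold on a bimodal image separates the two levels
    img <- matrix(c(rep(1, 30), rep(9, 19)) + rnorm(49, sd = 0.1), 7, 7)
    th <- otsuThreshold(img)
    expect_gt(th, 2); expect_lt(th, 9)
})
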