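test_that("spherical covariance matches direct evaluation and handles the range", {
    m <- sphericalModel(20, 0.1)
    expect_equal(sphericalCov(0, m), 0.1)
    expect_equal(sphericalCov(25, m), 0)
    expect_equal(sphericalCov(10, sphericalModel(20, 1)), 0.3125)
    # nugget contributes at h = 0 only
    mn <- sphericalModel(20, 1, nugget = 0.5)
    expect_equal(sphericalCov(0, mn), 1.5)
    expect_equal(sphericalCov(1e-9, mn), sphericalCov(1e-9, sphericalModel(20, 1)))
    expect_error(sphericalCov(-1, m), "non-negative")
})

test_that("covariance and semivariance conserve r(h) = C(0) - C(h)", {
    m <- sphericalModel(20, 1)
    h <- seq(0, 40, by = 0.25)
    expect_lt(max(abs(variogramFromCov(h, m) + sphericalCov(h, m) -
                      sphericalCov(0, m))), 1e-12)
    expect_equal(variogramFromCov(0, m), 0)
    expect_equal(variogramFromCov(c(20, 30), m), c(1, 1))  # sill beyond range
    expect_equal(variogramFromCov(10, m), 0.6875)
    # non-increasing on [0, a], exactly 0 beyond
    cv <- sphericalCov(seq(0, 20, 0.1), m)
    expect_true(all(diff(cv) <= 1e-12))
    expect_true(all(sphericalCov(seq(20.01, 50, 0.7), m) == 0))
})

test_that("anisotropy transform reproduces hand matrix algebra", {
    # identity for theta = 0, unit scales
    id <- anisotropyTransform(0, 1, 1)
    pts <- matrix(rnorm(20), 10)
    expect_equal(applyAnisotropy(pts, id), pts)
    # theta = 45, a_min = 0.5: (1, 0) -> (sqrt(2)/2, -sqrt(2)/2)
    tr <- anisotropyTransform(45, 1, 0.5)
    expect_equal(as.numeric(applyAnisotropy(rbind(c(1, 0)), tr)),
                 c(sqrt(2) / 2, -sqrt(2) / 2), tolerance = 1e-10)
    # hand-inverted (R T)^-1 at several angles
    for (th in c(0, 45, 90)) {
        rad <- th * pi / 180
        R <- rbind(c(cos(rad), sin(rad)), c(-sin(rad), cos(rad)))
        expect_equal(R %*% t(R), diag(2), tolerance = 1e-12)
        Tm <- diag(c(1, 0.5))
        expect_equal(applyAnisotropy(pts, anisotropyTransform(th, 1, 0.5)),
                     pts %*% solve(R %*% Tm), tolerance = 1e-12)
    }
})

test_that("pure rotation preserves pairwise distances; scaling makes them direction-dependent", {
    pts <- matrix(rnorm(30), 15)
    for (th in c(13, 45, 120)) {
        rot <- applyAnisotropy(pts, anisotropyTransform(th, 1, 1))
        expect_equal(as.numeric(dist(rot)), as.numeric(dist(pts)),
                     tolerance = 1e-10)
    }
    # separations along the major axis shrink relative to the minor axis
    tr <- anisotropyTransform(45, 1, 0.5)
    major <- applyAnisotropy(rbind(c(0, 0), c(sqrt(2) / 2, sqrt(2) / 2)), tr)
    minor <- applyAnisotropy(rbind(c(0, 0), c(-sqrt(2) / 2, sqrt(2) / 2)), tr)
    expect_lt(dist(major)[1], dist(minor)[1])
})

test_that("empirical variogram follows the r(h) formula", {
    # constant field: zero semivariance in every bin
    g <- pixelGrid(5, 5, 1)
    ve <- empiricalVariogram(rep(3.2, 25), g)
    expect_true(all(ve@semivariance == 0))
    expect_true(all(ve@pair_counts >= 1L))
    expect_true(all(diff(ve@lag) > 0))
    # two pixels at distance 1, values 0 and 1: r = 0.5, one pair
    g2 <- pixelGridFromCoords(rbind(c(1, 1), c(2, 1)), c(1, 1))
    ve2 <- empiricalVariogram(c(0, 1), g2, bins = c(0.5, 1.5))
    expect_equal(ve2@semivariance, 0.5)
    expect_equal(ve2@pair_counts, 1L)
    # iid unit-variance field: pure nugget, semivariance about 1 everywhere
    set.seed(11)
    g3 <- pixelGrid(30, 30, 1)
    ve3 <- empiricalVariogram(rnorm(900), g3, bins = seq(0.5, 10.5, 1))
    expect_true(all(abs(ve3@semivariance - 1) < 0.12))
    expect_error(empiricalVariogram(1, pixelGridFromCoords(rbind(c(1, 1)), 1)),
                 "2 pixels")
    expect_error(empiricalVariogram(c(NA, 1), g2), "finite")
})

test_that("block spatial covariance equals the brute-force pair loop", {
    models <- list(sphericalModel(3, 0.1), sphericalModel(2, 0.3))
    tr <- anisotropyTransform(45, 1, 0.5)
    for (dims in list(c(6, 6), c(12, 12))) {
        g <- pixelGrid(dims[1], dims[2], 2)
        S <- buildSpatialCovariance(g, models, tr)
        expect_equal(S, bruteSpatialCovariance(g, models, tr),
                     tolerance = 1e-12)
        expect_true(isSymmetric(S))
        expect_silent(chol(S))
    }
})

test_that("block covariance zeros cross-cluster entries and sets the diagonal", {
    g <- pixelGrid(4, 4, 2)
    models <- list(sphericalModel(3, 0.1, nugget = 0.05),
                   sphericalModel(3, 0.3))
    S <- buildSpatialCovariance(g, models, transform = NULL, jitter = 1e-8)
    lab <- gridLabels(g)
    expect_true(all(S[lab == 1, lab == 2] == 0))
    expect_equal(diag(S)[lab == 1], rep(0.1 + 0.05 + 1e-8, 8))
    expect_equal(diag(S)[lab == 2], rep(0.3 + 1e-8, 8))
    # same-cluster pixels beyond the range are uncorrelated
    gfar <- pixelGridFromCoords(rbind(c(1, 1), c(10, 1)), c(1, 1))
    Sfar <- buildSpatialCovariance(gfar, list(sphericalModel(3, 0.2)),
                                   transform = NULL, jitter = 0)
    expect_equal(Sfar[1, 2], 0)
})

test_that("variogram of simulated fields recovers the generating model", {
    g <- pixelGrid(40, 40, 1)
    true_a <- 10; true_b <- 0.2
    S <- buildSpatialCovariance(g, list(sphericalModel(true_a, true_b)),
                                transform = NULL)
    L <- t(chol(S))
    set.seed(99)
    fits <- replicate(8, {
        z <- as.numeric(L %*% rnorm(1600))
        m <- fitSphericalVariogram(
            empiricalVariogram(z, g, bins = seq(0, 20, 1)))
        c(m@range_a, m@sill_b)
    })
    expect_lt(abs(mean(fits[1, ]) - true_a) / true_a, 0.35)
    expect_lt(abs(mean(fits[2, ]) - true_b) / true_b, 0.25)
})
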