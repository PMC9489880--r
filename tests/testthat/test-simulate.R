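test_that("Fleishman coefficients solve the moment system", {
    expect_equal(fleishmanCoefficients(0, 0),
                 c(alpha = 0, beta = 1, gamma = 0, delta = 0))
    expect_error(fleishmanCoefficients(0, -3), "infeasible")
    for (tgt in list(c(1.5, 3.5), c(0.8, 1.0), c(0, 1))) {
        cf <- fleishmanCoefficients(tgt[1], tgt[2])
        # analytic moments of the cubic polynomial of a standard normal
        b <- cf["beta"]; cc <- cf["gamma"]; d <- cf["delta"]
        v <- b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2
        sk <- 2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2)
        ku <- 24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
                    d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2))
        expect_equal(unname(v), 1, tolerance = 1e-8)
        expect_equal(unname(sk), tgt[1], tolerance = 1e-8)
        expect_equal(unname(ku), tgt[2], tolerance = 1e-8)
    }
    # sample moments of polynomial draws match the targets
    cf <- fleishmanCoefficients(1.5, 3.5)
    set.seed(1)
    z <- rnorm(4e5)
    y <- cf["alpha"] + cf["beta"] * z + cf["gamma"] * z^2 + cf["delta"] * z^3
    expect_equal(mean(y), 0, tolerance = 0.01)
    expect_equal(sd(y), 1, tolerance = 0.01)
    expect_equal(mean(y^3) / sd(y)^3, 1.5, tolerance = 0.06)
})

test_that("bimodal generator mixes about 20% component-1 draws and standardizes", {
    set.seed(5)
    y <- drawBimodal(1e5)
    expect_lt(abs(mean(attr(y, "component1")) - 0.2), 0.01)
    expect_equal(mean(y), 0, tolerance = 0.02)
    expect_equal(sd(y), 1, tolerance = 0.02)
})

test_that("base variables are standardized and laid out by composition", {
    X <- drawBaseVariables(6400, 10, distributionSpec("normal"), rng_seed = 2)
    expect_true(all(abs(colMeans(X)) < 0.05))
    expect_true(all(abs(apply(X, 2, sd) - 1) < 0.05))
    # normal column skewness near zero
    xs <- X[, 1]
    expect_lt(abs(mean(xs^3) / sd(xs)^3), 0.09)
    # mixed composition: exact counts in order normal / bimodal / fleishman
    Xm <- drawBaseVariables(200, 100, distributionSpec("mixed"), rng_seed = 3)
    kinds <- attr(Xm, "column_kind")
    expect_equal(as.vector(table(factor(kinds,
        c("normal", "bimodal", "fleishman")))), c(60, 20, 20))
    # non-normal columns are visibly skewed at scale
    Xf <- drawBaseVariables(20000, 1, distributionSpec("fleishman"),
                            rng_seed = 4)
    expect_gt(mean(Xf^3) / sd(Xf)^3, 1)
})

test_that("cluster correlation matrices are valid PD correlations in range", {
    for (s in 1:10) {
        C <- clusterCorrelationMatrix(100, rng_seed = s)
        expect_equal(diag(C), rep(1, 100))
        expect_true(isSymmetric(C))
        expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
        off <- abs(C[upper.tri(C)])
        expect_lte(max(off), 0.72)
        expect_gte(max(off), 0.4)  # delivered correlations reach the range
    }
})

test_that("Cholesky correlation induction reproduces the target correlation", {
    # identity target: output identical to input
    Z <- matrix(rnorm(500), 100)
    expect_equal(induceVariableCorrelation(Z, diag(5)), Z)
    # two variables at rho = 0.6, large sample
    set.seed(10)
    corr2 <- matrix(c(1, 0.6, 0.6, 1), 2)
    Y <- induceVariableCorrelation(matrix(rnorm(2e5), ncol = 2), corr2)
    expect_equal(cor(Y)[1, 2], 0.6, tolerance = 0.01)
    expect_error(
        induceVariableCorrelation(matrix(rnorm(20), ncol = 2),
                                  matrix(c(1, 2, 2, 1), 2)),
        "positive definite")
})

test_that("spatial induction carries the target covariance across replicates", {
    g <- pixelGrid(8, 8, 1)
    S <- buildSpatialCovariance(g, list(sphericalModel(4, 0.5)),
                                transform = NULL)
    expect_equal(induceSpatialAutocorrelation(diag(64), diag(64)), diag(64))
    set.seed(20)
    reps <- sapply(1:300, function(i)
        as.numeric(induceSpatialAutocorrelation(matrix(rnorm(64), 64), S)))
    emp <- tcrossprod(reps - rowMeans(reps)) / (ncol(reps) - 1)
    # SE of a Gaussian sample-covariance entry: (s_ii s_jj + s_ij^2) / n
    se <- sqrt((outer(diag(S), diag(S)) + S^2) / 300)
    expect_lt(max(abs(emp - S) / se), 5)
    expect_lt(mean(abs(emp - S)), 3 * mean(se))
    expect_error(induceSpatialAutocorrelation(matrix(0, 10, 2), S),
                 "pixel count")
})

test_that("scenario modifications shift the designated variables only", {
    cube <- smallCube(seed = 8)
    base <- applyScenarioModifications(cube, "VarMod_0", rng_seed = 9)
    expect_equal(intensityMatrix(base), intensityMatrix(cube))
    expect_length(modifiedVars(base), 0)
    mod <- applyScenarioModifications(cube, "VarMod_0_5", rng_seed = 9)
    mv <- modifiedVars(mod)
    expect_length(mv, 5)
    truth <- truthLabels(cube)
    X0 <- intensityMatrix(cube); X1 <- intensityMatrix(mod)
    expect_equal(X1[truth == 2, ], X0[truth == 2, ])  # cluster 2 untouched
    expect_equal(X1[truth == 1, mv], X0[truth == 1, mv] + 0.5)
    expect_equal(X1[truth == 1, -mv], X0[truth == 1, -mv])
    # both-cluster variant uses disjoint sets; noise adds 5 flat columns
    both <- applyScenarioModifications(cube, "VarMod_5_5_addnoise",
                                       rng_seed = 9)
    expect_equal(ncol(intensityMatrix(both)), 105)
    expect_equal(noiseVars(both), 101:105)
    expect_length(modifiedVars(both), 10)
    expect_error(applyScenarioModifications(cube, "VarMod_99"), "unknown")
})

test_that("appended noise variables carry no spatial structure", {
    cube <- smallCube(seed = 12, mean_mod = "VarMod_5_5_addnoise")
    g <- pixelGridOf(cube)
    nv <- noiseVars(cube)[1]
    ve <- empiricalVariogram(intensityMatrix(cube)[, nv], g,
                             bins = seq(0.5, 8.5, 1))
    # flat (pure nugget) variogram at the field's sample variance
    x <- intensityMatrix(cube)[, nv]
    expect_lt(max(ve@semivariance) - min(ve@semivariance), 0.45)
    expect_equal(mean(ve@semivariance), var(x), tolerance = 0.1)
    expect_equal(var(x), 1, tolerance = 0.3)
})

test_that("simulated cubes have the documented shape, labels and determinism", {
    spec <- scenarioSpec(grid_dim = c(80, 80), seed = 21)
    cube <- simulateScenario(spec)
    expect_s4_class(cube, "MsiSimCube")
    expect_equal(dim(intensityMatrix(cube)), c(6400, 100))
    expect_equal(as.vector(table(truthLabels(cube))), c(3200, 3200))
    # four clusters: four equal bands
    cube4 <- simulateScenario(scenarioSpec(n_clusters = 4,
                                           grid_dim = c(16, 16), seed = 5))
    expect_equal(as.vector(table(truthLabels(cube4))), rep(64, 4))
    # determinism
    c1 <- simulateScenario(scenarioSpec(grid_dim = c(16, 16), seed = 33))
    c2 <- simulateScenario(scenarioSpec(grid_dim = c(16, 16), seed = 33))
    expect_identical(intensityMatrix(c1), intensityMatrix(c2))
})

test_that("spatial induction roughly preserves the variable correlation structure", {
    set.seed(30)
    g <- pixelGrid(20, 20, 1)
    S <- buildSpatialCovariance(g, list(sphericalModel(8, 0.2)),
                                transform = NULL)
    corr <- clusterCorrelationMatrix(20, rng_seed = 31)
    devs <- replicate(10, {
        Z <- matrix(rnorm(400 * 20), 400)
        X <- induceSpatialAutocorrelation(induceVariableCorrelation(Z, corr), S)
        mean(abs((cor(X) - corr)[upper.tri(corr)]))
    })
    expect_lt(mean(devs), 0.15)  # structure only slightly modified
})
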