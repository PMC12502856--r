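test_that("SIRT iterates match the dense linear-algebra reference", {
    fx <- fix_simulation(n = 6L, nInner = 4L, tilts = 0, lMax = 2L, nSeg = 3L)
    basis <- basisSet(fx$phantom$field)
    B <- segmentIntegrals(basis, fx$geometry, fx$segments)
    A <- oracle_full_matrix(fx$geometry, B, 6L, 6L)
    b <- as.numeric(projectionData(fx$stack))
    xDense <- oracle_dense_sirt(A, b, 8L)
    rec <- runSirt(fx$stack, basis, maxIter = 8L)
    expect_lt(max(abs(as.numeric(coefficients4D(rec)) - xDense)), 1e-8)
})

test_that("SIRT recovers a noiseless scalar phantom and is stable", {
    fx <- fix_simulation(n = 16L, nInner = 20L, lMax = 0L, nSeg = 8L,
                         anisotropy = 0, texture = "isotropic")
    rec <- runSirt(fx$stack, SphericalHarmonicsBasis(0), maxIter = 20L)
    truth <- coefficients4D(fx$phantom$field)
    expect_gt(cor(as.numeric(coefficients4D(rec)), as.numeric(truth)), 0.95)
    tr <- provenance(rec)$lossTrace
    expect_true(all(diff(tr) <= 1e-9 * tr[1]))         # non-increasing
    # zero data is a fixed point
    z <- fx$stack
    z@data[] <- 0
    rec0 <- runSirt(z, SphericalHarmonicsBasis(0), maxIter = 3L)
    expect_equal(max(abs(coefficients4D(rec0))), 0)
    # inputs are never modified
    expect_identical(projectionData(fx$stack), projectionData(fx$sim$stack))
})

test_that("MITRA without regularizers or momentum reproduces SIRT", {
    fx <- fix_simulation(n = 8L, nInner = 6L, lMax = 2L, nSeg = 4L)
    basis <- basisSet(fx$phantom$field)
    r1 <- runSirt(fx$stack, basis, maxIter = 6L)
    r2 <- runMitra(fx$stack, basis, maxIter = 6L)
    expect_lt(max(abs(coefficients4D(r1) - coefficients4D(r2))), 1e-12)
})

test_that("MITRA with momentum recovers a harmonic phantom", {
    fx <- fix_simulation(n = 16L, nInner = 20L, lMax = 4L, nSeg = 8L)
    rec <- runMitra(fx$stack, SphericalHarmonicsBasis(4), nesterov = TRUE,
                    maxIter = 20L)
    msk <- array(fx$phantom$support, dim(coefficients4D(rec)))
    expect_gt(cor(coefficients4D(rec)[msk],
                  coefficients4D(fx$phantom$field)[msk]), 0.9)
})

test_that("an l1 penalty shrinks the reconstruction monotonically in mu", {
    # stable small-mu regime of the fixed-step subgradient iteration; very
    # large weights make the nonsmooth step oscillate and abort instead
    fx <- fix_simulation(n = 6L, nInner = 6L, lMax = 2L, nSeg = 4L)
    basis <- basisSet(fx$phantom$field)
    norms <- sapply(c(0, 0.1, 0.3, 1), function(mu) {
        regs <- if (mu > 0) list(list(kind = "l1", weight = mu)) else list()
        rec <- suppressWarnings(
            runMitra(fx$stack, basis, regularizers = regs, maxIter = 10L))
        sum(abs(coefficients4D(rec)))
    })
    expect_true(all(diff(norms) < 0))
})

test_that("SIGTT fits noiseless data essentially exactly", {
    fx <- fix_simulation(n = 8L, nInner = 12L, lMax = 2L, nSeg = 4L)
    rec <- runSigtt(fx$stack, lMax = 2L, laplacianWeight = 0,
                    maxIter = 500L, tol = 1e-12)
    tr <- provenance(rec)$lossTrace
    expect_lt(min(tr), 1e-8 * tr[1])
    # the fitted forward projections match the data closely
    B <- segmentIntegrals(basisSet(rec), fx$geometry, fx$segments)
    model <- forwardModel(coefficients4D(rec), fx$geometry, B,
                          dim(fx$stack@data)[2], dim(fx$stack@data)[3])
    relRms <- sqrt(mean((model - projectionData(fx$stack))^2)) /
        sqrt(mean(projectionData(fx$stack)^2))
    expect_lt(relRms, 0.01)
})

test_that("dominant Laplacian regularization flattens the field", {
    fx <- fix_simulation(n = 6L, nInner = 4L, lMax = 0L, nSeg = 2L)
    rec <- runSigtt(fx$stack, lMax = 0L, laplacianWeight = 1e7,
                    maxIter = 200L, tol = 1e-12)
    co <- coefficients4D(rec)
    expect_lt(sd(co) / max(abs(mean(co)), 1e-12), 0.05)
})

test_that("regularization helps under noise at a suitable weight", {
    # Gaussian noise with sd = 5% of the maximum model intensity; SIGTT run
    # to convergence so the unregularized fit is free to chase the noise
    fx <- fix_simulation(n = 8L, nInner = 8L, lMax = 2L, nSeg = 4L)
    set.seed(33)
    model <- fx$sim$model
    noisy <- pmax(model + array(rnorm(length(model), sd = 0.05 * max(model)),
                                dim(model)), 0)
    st <- fx$stack
    st@data <- noisy
    truth <- coefficients4D(fx$phantom$field)
    err <- sapply(c(0, 0.3, 1), function(mu) {
        rec <- runSigtt(st, lMax = 2L, laplacianWeight = mu,
                        maxIter = 300L, tol = 1e-12)
        sqrt(mean((coefficients4D(rec) - truth)^2))
    })
    expect_lt(min(err[-1]), err[1])
})

test_that("discrete directions reduce to scalar SIRT and collapse under isotropy", {
    fx <- fix_simulation(n = 8L, nInner = 12L, tilts = c(0, 20, 40) * pi / 180,
                         lMax = 0L, nSeg = 8L,
                         anisotropy = 0, texture = "isotropic")
    # a single all-covering direction is exactly scalar SIRT with that basis
    oneDir <- matrix(c(0, 0, 1), 1)
    rdd <- runDd(fx$stack, oneDir, maxIter = 8L)
    rs <- runSirt(fx$stack, NearestNeighborBasis(oneDir), maxIter = 8L)
    expect_identical(coefficients4D(rdd), coefficients4D(rs))
    # isotropic phantom: every channel resembles the scalar reconstruction
    dirs <- fibonacciGrid(6)
    rdd6 <- runDd(fx$stack, dirs, maxIter = 10L)
    scalar <- as.numeric(meanIntensity(runSirt(fx$stack,
                                               SphericalHarmonicsBasis(0),
                                               maxIter = 10L)@field))
    for (m in seq_len(6))
        expect_gt(cor(as.numeric(coefficients4D(rdd6)[, , , m]), scalar), 0.9)
    # permuting the grid permutes the channels
    perm <- c(3, 1, 2, 6, 5, 4)
    rddP <- runDd(fx$stack, dirs[perm, ], maxIter = 10L)
    expect_identical(coefficients4D(rddP), coefficients4D(rdd6)[, , , perm])
})
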