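make_voxel_field <- function(coeffs, basis) {
    TensorField(array(coeffs, c(1, 1, 1, length(coeffs))), basis)
}

# expand an oriented reciprocal-space map W(q) = iso + a * g(q . u) in a basis
# (weighted least squares on a quadrature mesh, as the phantom generator does)
project_rsm <- function(basis, u, iso = 0.2, a = 0.8, width = 0.35,
                        pattern = "equatorial") {
    quad <- sphereQuadrature(2000)
    A <- evaluateBasis(basis, quad$points)
    t <- drop(quad$points %*% u)
    g <- if (pattern == "equatorial") exp(-t^2 / (2 * width^2))
         else exp(-(1 - t^2) / (2 * width^2))
    W <- iso + a * g
    Aw <- A * quad$weights
    drop(solve(crossprod(A, Aw), crossprod(Aw, W)))
}

test_that("mean intensity reduces to the degree-0 coefficient for harmonics", {
    sh <- SphericalHarmonicsBasis(4)
    f <- make_voxel_field(c(sqrt(4 * pi), rnorm(14)), sh)
    expect_equal(as.numeric(meanIntensity(f)), 1, tolerance = 1e-12)
    f0 <- make_voxel_field(numeric(15), sh)
    expect_equal(as.numeric(meanIntensity(f0)), 0)
})

test_that("quadrature mean intensity is mesh-converged for kernels", {
    gk <- GaussianKernelBasis(fibonacciGrid(8), sigma = 0.4)
    set.seed(15)
    f <- make_voxel_field(rnorm(8), gk)
    m1 <- meanIntensity(f, quadratureNodes = 1000)
    m2 <- meanIntensity(f, quadratureNodes = 10000)
    expect_equal(as.numeric(m1), as.numeric(m2), tolerance = 1e-4)
})

test_that("second moment of the constant map is (4pi/3) I", {
    sh <- SphericalHarmonicsBasis(2)
    f <- make_voxel_field(c(sqrt(4 * pi), rep(0, 5)), sh)   # W = 1
    Tm <- matrix(secondMoment(f)[1, 1, 1, , ], 3, 3)
    expect_equal(Tm, diag(3) * 4 * pi / 3, tolerance = 1e-12)
    f0 <- make_voxel_field(numeric(6), sh)
    expect_equal(max(abs(secondMoment(f0))), 0)
})

test_that("closed-form second moment agrees with sphere quadrature", {
    sh <- SphericalHarmonicsBasis(2)
    set.seed(16)
    for (i in 1:5) {
        f <- make_voxel_field(rnorm(6), sh)
        Tc <- secondMoment(f, method = "closed")
        Tq <- secondMoment(f, method = "quadrature", quadratureNodes = 10000)
        expect_lt(max(abs(Tc - Tq)), 1e-6)
    }
})

test_that("fractional anisotropy has the analytic endpoints and known values", {
    expect_equal(fractionalAnisotropy(c(1, 1, 1)), 0)
    expect_equal(fractionalAnisotropy(c(1, 0, 0)), 1)
    expect_equal(fractionalAnisotropy(c(2, 1, 1)), 0.408248290463863,
                 tolerance = 1e-12)
    # scale-free
    set.seed(17)
    ev <- abs(matrix(rnorm(30), 10, 3))
    for (s in c(1e-3, 1, 1e4))
        expect_equal(fractionalAnisotropy(ev * s), fractionalAnisotropy(ev),
                     tolerance = 1e-12)
    expect_true(is.na(fractionalAnisotropy(c(0, 0, 0))))
})

test_that("main orientation picks the extremal eigenvector with fixed sign", {
    expect_equal(mainOrientation(diag(c(3, 1, 1)), "polar_peaks"), c(1, 0, 0),
                 ignore_attr = TRUE)
    expect_equal(mainOrientation(diag(c(3, 3, 1)), "equatorial_band"),
                 c(0, 0, 1), ignore_attr = TRUE)
    set.seed(18)
    for (i in 1:5) {
        Aq <- matrix(rnorm(9), 3, 3)
        Tm <- crossprod(Aq)                        # random PSD
        for (mode in c("polar_peaks", "equatorial_band")) {
            v <- mainOrientation(Tm, mode)
            ev <- eigen(Tm, symmetric = TRUE)$values
            lam <- if (mode == "polar_peaks") ev[1] else ev[3]
            expect_lt(max(abs(Tm %*% v - lam * v)), 1e-10)
        }
    }
    # degenerate pair flagged
    v <- mainOrientation(diag(c(2, 2, 1)), "polar_peaks")
    expect_true(isTRUE(attr(v, "ambiguous")))
    expect_error(mainOrientation(matrix(rnorm(9), 3, 3)), "symmetric")
})

test_that("rotating the map rotates eigenvectors and preserves anisotropy", {
    sh <- SphericalHarmonicsBasis(4)
    u1 <- c(0, 0, 1)
    axis <- c(1, 0, 0)
    Rm <- matrix(c(1, 0, 0, 0, cos(0.7), sin(0.7), 0, -sin(0.7), cos(0.7)), 3, 3)
    u2 <- drop(Rm %*% u1)
    f1 <- make_voxel_field(project_rsm(sh, u1), sh)
    f2 <- make_voxel_field(project_rsm(sh, u2), sh)
    T1 <- matrix(secondMoment(f1)[1, 1, 1, , ], 3, 3)
    T2 <- matrix(secondMoment(f2)[1, 1, 1, , ], 3, 3)
    e1 <- eigen(T1, symmetric = TRUE); e2 <- eigen(T2, symmetric = TRUE)
    expect_equal(e1$values, e2$values, tolerance = 1e-6)
    expect_equal(fractionalAnisotropy(e1$values),
                 fractionalAnisotropy(e2$values), tolerance = 1e-6)
    v1 <- mainOrientation(T1, "equatorial_band")
    v2 <- mainOrientation(T2, "equatorial_band")
    expect_lt(acos(min(1, abs(sum((Rm %*% v1) * v2)))), 1e-5)
})

test_that("second moments of nonnegative maps are positive semi-definite", {
    gk <- GaussianKernelBasis(fibonacciGrid(10), sigma = 0.5)
    set.seed(19)
    for (i in 1:5) {
        f <- make_voxel_field(abs(rnorm(10)), gk)   # W >= 0 everywhere
        Tm <- matrix(secondMoment(f)[1, 1, 1, , ], 3, 3)
        expect_gte(min(eigen(Tm, symmetric = TRUE)$values), -1e-10)
    }
})

test_that("relative anisotropy vanishes for isotropic maps", {
    sh <- SphericalHarmonicsBasis(4)
    f <- make_voxel_field(c(2, rep(0, 14)), sh)
    expect_lt(as.numeric(relativeAnisotropy(f)), 1e-6)
    fa <- make_voxel_field(project_rsm(sh, c(0, 0, 1)), sh)
    expect_gt(as.numeric(relativeAnisotropy(fa)), 0.1)
})

test_that("deriveMaps assembles a consistent eigensystem", {
    sh <- SphericalHarmonicsBasis(2)
    set.seed(20)
    co <- array(rnorm(2 * 2 * 2 * 6), c(2, 2, 2, 6))
    co[, , , 1] <- abs(co[, , , 1]) + 3          # keep maps mostly positive
    rec <- deriveMaps(TensorField(co, sh))
    m <- derivedMaps(rec)
    expect_equal(dim(m$eigenvalues), c(2L, 2L, 2L, 3L))
    expect_true(all(m$eigenvalues[, , , 1] >= m$eigenvalues[, , , 3]))
    expect_true(all(m$fractional_anisotropy >= 0 & m$fractional_anisotropy <= 1))
    # eigenvectors orthonormal per voxel
    V <- matrix(m$eigenvectors[1, 2, 1, , ], 3, 3)
    expect_lt(max(abs(crossprod(V) - diag(3))), 1e-10)
})
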