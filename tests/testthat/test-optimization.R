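test_that("Huber loss has the right branches and a continuous seam", {
    expect_equal(huberValue(0.5, 1), 0.125)
    expect_equal(huberValue(2, 1), 1.5)
    expect_equal(huberValue(1, 1), huberValue(-1, 1))
    expect_equal(huberValue(1, 1), 0.5)                       # both branches
    eps <- 1e-9
    expect_equal(huberValue(1 + eps, 1), huberValue(1 - eps, 1),
                 tolerance = 1e-8)
    expect_equal(huberGrad(1 + eps, 1), huberGrad(1 - eps, 1),
                 tolerance = 1e-8)
    expect_error(huberValue(1, 0), "positive")
})

test_that("regularizer gradients pass finite-difference checks", {
    set.seed(21)
    x <- array(rnorm(5^3 * 2), c(5, 5, 5, 2))
    x <- x + sign(x) * 0.2                  # keep l1 away from the kink
    for (kind in c("laplacian", "total_variation", "l1", "l2", "huber_norm")) {
        fn <- function(z) regularizerValueGrad(z, kind, delta = 0.05)
        expect_lt(fd_gradient_check(fn, x, h = 1e-6), 1e-5)
    }
    expect_error(regularizerValueGrad(x, "nope"))
})

test_that("constant fields are unpenalized by smoothness regularizers", {
    x <- array(3.7, c(4, 4, 4, 2))
    for (kind in c("laplacian", "total_variation")) {
        vg <- regularizerValueGrad(x, kind)
        expect_equal(vg$value, 0)
        expect_equal(max(abs(vg$gradient)), 0)
    }
    # single unit voxel under l1
    y <- array(0, c(3, 3, 3, 1)); y[2, 2, 2, 1] <- 1
    vg <- regularizerValueGrad(y, "l1")
    expect_equal(vg$value, 1)
    expect_equal(vg$gradient, sign(y))
})

test_that("model residuals and gradients are exact and maskable", {
    fx <- fix_simulation(n = 4L, nInner = 3L, tilts = 0, lMax = 2L, nSeg = 4L)
    stack <- fx$stack
    B <- segmentIntegrals(basisSet(fx$phantom$field), geometry(stack),
                          detectorSegments(stack))
    truth <- coefficients4D(fx$phantom$field)
    # the exact solution of noiseless data has zero loss and gradient
    rg <- residualAndGradient(truth, stack, B)
    expect_lt(rg$value, 1e-14 * sum(projectionData(stack)^2))
    expect_lt(max(abs(rg$gradient)), 1e-8)
    # zero field: residuals are minus the weighted data
    rg0 <- residualAndGradient(array(0, dim(truth)), stack, B)
    expect_equal(rg0$residuals, -measurementWeights(stack) * projectionData(stack))
    # masking: a zero-weight measurement never influences loss or gradient
    w <- measurementWeights(stack); w[2, 1, 3, 2] <- 0
    stackM <- new("ProjectionStack", data = projectionData(stack), diode = diodeData(stack),
                  weights = w, geometry = geometry(stack),
                  segments = detectorSegments(stack))
    set.seed(22)
    x <- array(rnorm(length(truth)), dim(truth))
    r1 <- residualAndGradient(x, stackM, B)
    d2 <- projectionData(stack); d2[2, 1, 3, 2] <- d2[2, 1, 3, 2] + 100
    stackM2 <- new("ProjectionStack", data = d2, diode = diodeData(stack),
                   weights = w, geometry = geometry(stack),
                   segments = detectorSegments(stack))
    r2 <- residualAndGradient(x, stackM2, B)
    expect_identical(r1$value, r2$value)
    expect_identical(r1$gradient, r2$gradient)
    expect_equal(r1$residuals[2, 1, 3, 2], 0)
})

test_that("data-term gradients pass finite-difference checks", {
    fx <- fix_simulation(n = 4L, nInner = 3L, tilts = 0, lMax = 2L, nSeg = 3L)
    B <- segmentIntegrals(basisSet(fx$phantom$field), fx$geometry, fx$segments)
    set.seed(23)
    x <- array(rnorm(4^3 * 6), c(4, 4, 4, 6))
    for (loss in c("squared", "huber")) {
        fn <- function(z) residualAndGradient(z, fx$stack, B, loss = loss,
                                              huberDelta = 0.7)
        expect_lt(fd_gradient_check(fn, x, h = 1e-5), 1e-5)
    }
    # combined with a regularizer
    fn <- function(z) residualAndGradient(
        z, fx$stack, B,
        regularizers = list(list(kind = "laplacian", weight = 0.3),
                            list(kind = "l2", weight = 0.1,
                                 dWeights = seq(0.5, 1.5, length.out = 6))))
    expect_lt(fd_gradient_check(fn, x, h = 1e-5), 1e-5)
})

test_that("gradient descent takes the textbook step and converges", {
    fq <- function(x) list(value = sum(x^2), gradient = 2 * x)
    res <- gradientDescent(fq, x0 = 1, step = 0.4, maxIter = 1L)
    expect_equal(res$x, 0.2)
    # convex quadratic: compare with the exact solve
    set.seed(24)
    M <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
    b <- rnorm(5)
    fn <- function(x) list(value = 0.5 * sum(x * (M %*% x)) - sum(b * x),
                           gradient = drop(M %*% x) - b)
    xStar <- drop(solve(M, b))
    res <- gradientDescent(fn, numeric(5), step = 1 / max(eigen(M)$values),
                           maxIter = 5000L)
    expect_lt(max(abs(res$x - xStar)), 1e-6)
})

test_that("Nesterov momentum accelerates an ill-conditioned quadratic", {
    set.seed(25)
    ev <- c(100, 10, 1, 0.1)
    Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    M <- Q %*% diag(ev) %*% t(Q)
    fn <- function(x) list(value = 0.5 * sum(x * (M %*% x)),
                           gradient = drop(M %*% x))
    x0 <- rep(1, 4)
    itersTo <- function(nesterov) {
        r <- gradientDescent(fn, x0, step = 1 / 100, nesterov = nesterov,
                             maxIter = 5000L)
        which(r$trace < 1e-8 * r$trace[1])[1]
    }
    expect_lt(itersTo(TRUE), itersTo(FALSE))
})

test_that("the quasi-Newton wrapper solves standard test problems", {
    set.seed(26)
    M <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
    b <- rnorm(6)
    fn <- function(x) list(value = 0.5 * sum(x * (M %*% x)) - sum(b * x),
                           gradient = drop(M %*% x) - b)
    res <- lbfgsMinimize(fn, numeric(6), maxIter = 200L, tol = 1e-14)
    expect_lt(max(abs(res$x - drop(solve(M, b)))), 1e-6)
    rosen <- function(x) list(
        value = 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2,
        gradient = c(-400 * x[1] * (x[2] - x[1]^2) - 2 * (1 - x[1]),
                     200 * (x[2] - x[1]^2)))
    res <- lbfgsMinimize(rosen, c(-1.2, 1), maxIter = 500L, tol = 1e-15)
    expect_lt(res$value, 1e-6)
})

test_that("l1-type penalties with harmonics trigger the anisotropy warning", {
    fx <- fix_simulation(n = 4L, nInner = 2L, tilts = 0, lMax = 2L, nSeg = 2L)
    B <- segmentIntegrals(basisSet(fx$phantom$field), fx$geometry, fx$segments)
    x <- array(0, c(4, 4, 4, 6))
    expect_warning(
        residualAndGradient(x, fx$stack, B,
                            regularizers = list(list(kind = "l1", weight = 1)),
                            basis = SphericalHarmonicsBasis(2)),
        "rotational")
})
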