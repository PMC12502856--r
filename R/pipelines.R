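# Reconstruction pipelines: SIRT, MITRA, SIGTT, DD.  All are pure functions
# of the input stack (which is never modified), start from a zero field (the
# linear models are convex) and record a loss trace in the provenance.

.weighted_ls_loss <- function(r) 0.5 * sum(r^2)

# Core preconditioned iteration shared by SIRT and MITRA:
#   x <- y - C * [A^T (R * w * (A y - b)) + sum mu grad(reg)]
# which for empty regularizers and no momentum is the classical SIRT update
# x <- x + C A^T R (b - A x) with masking weights w on the residual.
.sirt_engine <- function(data, weights, geometry, response, maxIter,
                         regularizers = list(), nesterov = FALSE,
                         basis = NULL, x0 = NULL) {
    d <- dim(data)
    vs <- geometry@volumeShape
    N <- dim(response)[3L]
    pre <- sirtPreconditioners(geometry, response, J = d[2L], K = d[3L])
    x <- if (is.null(x0)) array(0, c(vs, N)) else x0
    xPrev <- x
    trace <- numeric(0)
    for (t in seq_len(maxIter)) {
        y <- if (nesterov && t > 1L) x + ((t - 1) / (t + 2)) * (x - xPrev) else x
        model <- forwardModel(y, geometry, response, J = d[2L], K = d[3L])
        r <- weights * (model - data)
        loss <- .weighted_ls_loss(r)
        if (length(regularizers)) {
            rv <- .apply_reg(y, regularizers, basis)
            loss <- loss + rv$value
        }
        trace <- c(trace, loss)
        if (t > 1L && loss > 10 * trace[1L] && trace[1L] > 0)
            stop("SIRT-type iteration diverged (loss grew more than 10-fold)")
        g <- adjointModel(pre$R * r, geometry, response)
        if (length(regularizers)) g <- g + rv$gradient
        xPrev <- x
        x <- y - pre$C * g
    }
    list(x = x, trace = trace)
}

.as_stack_pieces <- function(stack) {
    list(data = stack@data, weights = stack@weights,
         geometry = stack@geometry, segments = stack@segments)
}

.make_output <- function(x, basis, pipeline, trace, config) {
    field <- new("TensorField", coefficients = x, basis = basis)
    new("TTReconstruction", field = field, maps = list(),
        provenance = list(pipeline = pipeline, lossTrace = trace,
                          config = config))
}

#' SIRT reconstruction pipeline
#'
#' Classical simultaneous iterative reconstruction technique extended to the
#' tensor system matrix: preconditioned Landweber-type iteration
#' \code{x <- x + C A^T R (b - A x)} with the row/column-sum preconditioners
#' of \code{\link{sirtPreconditioners}}.  Semi-convergence provides implicit
#' regularization via the iteration count.
#'
#' @param stack A \linkS4class{ProjectionStack} (aligned).
#' @param basis A \linkS4class{BasisSet}.
#' @param maxIter Number of iterations (default 20).
#' @param responseMethod Quadrature mode for \code{\link{segmentIntegrals}}.
#' @return A \linkS4class{TTReconstruction}.
#' @export
runSirt <- function(stack, basis, maxIter = 20L,
                    responseMethod = c("adaptive", "midpoint")) {
    responseMethod <- match.arg(responseMethod)
    p <- .as_stack_pieces(stack)
    B <- segmentIntegrals(basis, p$geometry, p$segments, method = responseMethod)
    res <- .sirt_engine(p$data, p$weights, p$geometry, B, maxIter)
    .make_output(res$x, basis, "SIRT", res$trace,
                 list(maxIter = maxIter, responseMethod = responseMethod))
}

#' MITRA reconstruction pipeline
#'
#' Modular iterative tomographic reconstruction: the SIRT-preconditioned
#' gradient descent on the weighted least-squares loss, with arbitrary
#' regularizers and optional Nesterov momentum.  With no regularizers and no
#' momentum the iterates coincide with \code{\link{runSirt}}.
#'
#' @inheritParams runSirt
#' @param regularizers List of \code{list(kind =, weight =, delta =,
#'   dWeights =)} terms, see \code{\link{regularizerValueGrad}}.
#' @param nesterov Enable Nesterov momentum.
#' @return A \linkS4class{TTReconstruction}.
#' @export
runMitra <- function(stack, basis, regularizers = list(), nesterov = FALSE,
                     maxIter = 20L,
                     responseMethod = c("adaptive", "midpoint")) {
    responseMethod <- match.arg(responseMethod)
    p <- .as_stack_pieces(stack)
    B <- segmentIntegrals(basis, p$geometry, p$segments, method = responseMethod)
    res <- .sirt_engine(p$data, p$weights, p$geometry, B, maxIter,
                        regularizers = regularizers, nesterov = nesterov,
                        basis = basis)
    .make_output(res$x, basis, "MITRA", res$trace,
                 list(maxIter = maxIter, nesterov = nesterov,
                      regularizers = regularizers,
                      responseMethod = responseMethod))
}

#' SIGTT reconstruction pipeline
#'
#' Spherical integral geometric tensor tomography: spherical-harmonics basis,
#' squared-difference loss, finite-difference Laplacian regularization, and
#' quasi-Newton (L-BFGS-B) minimization with a relative loss-change stop
#' criterion.  Deterministic from the zero start.
#'
#' @inheritParams runSirt
#' @param lMax Spherical-harmonic band limit (even degrees, Friedel
#'   symmetric).
#' @param laplacianWeight Regularization weight mu (0 disables).
#' @param tol Relative loss-change stopping tolerance.
#' @return A \linkS4class{TTReconstruction}.
#' @export
runSigtt <- function(stack, lMax = 6L, laplacianWeight = 0, maxIter = 20L,
                     tol = 1e-4, responseMethod = c("adaptive", "midpoint")) {
    responseMethod <- match.arg(responseMethod)
    basis <- SphericalHarmonicsBasis(lMax = lMax, friedel = TRUE)
    p <- .as_stack_pieces(stack)
    B <- segmentIntegrals(basis, p$geometry, p$segments, method = responseMethod)
    regs <- if (laplacianWeight > 0)
        list(list(kind = "laplacian", weight = laplacianWeight)) else list()
    x0 <- array(0, c(p$geometry@volumeShape, coefficientCount(basis)))
    fn <- function(x) {
        rg <- residualAndGradient(x, stack, B, loss = "squared",
                                  regularizers = regs, basis = basis)
        list(value = rg$value, gradient = rg$gradient)
    }
    res <- lbfgsMinimize(fn, x0, maxIter = maxIter, tol = tol)
    .make_output(res$x, basis, "SIGTT", res$trace,
                 list(lMax = lMax, laplacianWeight = laplacianWeight,
                      maxIter = maxIter, tol = tol,
                      responseMethod = responseMethod,
                      converged = res$converged))
}

#' Discrete-directions reconstruction pipeline
#'
#' Splits the tensor reconstruction into independent scalar tomography
#' problems, one per orientation-grid direction of a nearest-neighbor basis:
#' the measurements (s, c) whose segment arc maps to direction m (positive
#' nearest-neighbor response) are reconstructed by scalar SIRT with the data
#' weighted by that response, and form channel m of the output.  Channels
#' are independent and permutation-equivariant in the grid.
#'
#' @inheritParams runSirt
#' @param directions M x 3 matrix of unit grid directions (e.g.
#'   \code{\link{fibonacciGrid}} or \code{\link{truncatedIcosahedronGrid}}).
#' @return A \linkS4class{TTReconstruction} with the
#'   \linkS4class{NearestNeighborBasis} field.
#' @export
runDd <- function(stack, directions, maxIter = 20L,
                  responseMethod = c("adaptive", "midpoint")) {
    responseMethod <- match.arg(responseMethod)
    basis <- NearestNeighborBasis(directions)
    p <- .as_stack_pieces(stack)
    B <- segmentIntegrals(basis, p$geometry, p$segments, method = responseMethod)
    M <- coefficientCount(basis)
    vs <- p$geometry@volumeShape
    x <- array(0, c(vs, M))
    traces <- vector("list", M)
    for (m in seq_len(M)) {
        Bm <- B[, , m, drop = FALSE]                  # [S, C, 1]
        selSC <- matrix(Bm[, , 1L] > 0, dim(B)[1L], dim(B)[2L])  # [S, C]
        if (!any(selSC)) {
            warning(sprintf("direction %d has no assigned measurements; channel zeroed", m),
                    call. = FALSE)
            traces[[m]] <- numeric(0)
            next
        }
        wm <- p$weights * aperm(array(selSC, c(dim(selSC),
                                               dim(p$weights)[2:3])),
                                c(1L, 3L, 4L, 2L))
        res <- .sirt_engine(p$data, wm, p$geometry, Bm, maxIter)
        x[, , , m] <- res$x[, , , 1L]
        traces[[m]] <- res$trace
    }
    .make_output(x, basis, "DD", traces,
                 list(maxIter = maxIter, responseMethod = responseMethod,
                      nDirections = M))
}
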