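#' Huber loss
#'
#' Quadratic for |r| <= delta, linear beyond, with continuous value and first
#' derivative: rho(r) = r^2/2 if |r| <= delta, else delta*|r| - delta^2/2.
#'
#' @param r Numeric residuals (any shape).
#' @param delta Positive transition point.
#' @return \code{huberValue}: values like \code{r}; \code{huberGrad}: the
#'   derivative rho'(r).
#' @export
huberValue <- function(r, delta = 1) {
    if (delta <= 0) stop("delta must be positive")
    a <- abs(r)
    ifelse(a <= delta, 0.5 * r^2, delta * a - 0.5 * delta^2)
}

#' @rdname huberValue
#' @export
huberGrad <- function(r, delta = 1) {
    if (delta <= 0) stop("delta must be positive")
    ifelse(abs(r) <= delta, r, delta * sign(r))
}

# ---- regularizers -----------------------------------------------------------

.shift_replicate <- function(x, axis, by) {
    # shift a 4D array along a spatial axis with replicated (Neumann) edges
    d <- dim(x)
    idx <- seq_len(d[axis]) + by
    idx <- pmin(pmax(idx, 1L), d[axis])
    switch(axis,
           x[idx, , , , drop = FALSE],
           x[, idx, , , drop = FALSE],
           x[, , idx, , drop = FALSE])
}

.laplacian4 <- function(x) {
    # 6-neighbor finite-difference Laplacian with reflective boundaries,
    # symmetric as a linear operator (negative graph Laplacian of the grid)
    out <- -6 * x
    for (ax in 1:3) {
        out <- out + .shift_replicate(x, ax, 1L) + .shift_replicate(x, ax, -1L)
    }
    out
}

#' Regularizer value and gradient
#'
#' Spatial and norm penalties on a coefficient field:
#' \describe{
#'   \item{laplacian}{0.5 * ||L c||^2 with the 6-neighbor finite-difference
#'     Laplacian L per channel, reflective boundaries (constant fields are
#'     unpenalized).}
#'   \item{total_variation}{Huber(delta) norm of the forward-difference
#'     spatial gradient, summed over channels; no difference is taken across
#'     the far boundary, so constant fields are unpenalized.}
#'   \item{l2}{0.5 * ||c||^2.}
#'   \item{l1}{||c||_1 with subgradient sign(c).}
#'   \item{huber_norm}{elementwise Huber(delta) of c.}
#' }
#'
#' @param field Numeric array [X, Y, Z, N] of coefficients (a
#'   \linkS4class{TensorField} is accepted).
#' @param kind One of \code{"laplacian"}, \code{"total_variation"},
#'   \code{"l1"}, \code{"l2"}, \code{"huber_norm"}.
#' @param delta Huber transition for \code{total_variation} /
#'   \code{huber_norm}.
#' @return List with \code{value} (scalar) and \code{gradient} (array like
#'   \code{field}).
#' @export
regularizerValueGrad <- function(field,
                                 kind = c("laplacian", "total_variation",
                                          "l1", "l2", "huber_norm"),
                                 delta = 1e-2) {
    kind <- match.arg(kind)
    x <- if (is(field, "TensorField")) field@coefficients else field
    x <- .as_field4(x)
    switch(kind,
        laplacian = {
            lx <- .laplacian4(x)
            list(value = 0.5 * sum(lx^2), gradient = .laplacian4(lx))
        },
        total_variation = {
            d <- dim(x)
            value <- 0
            grad <- array(0, d)
            for (ax in 1:3) {
                n <- d[ax]
                if (n < 2L) next
                fwd <- switch(ax,
                              x[c(2:n, n), , , , drop = FALSE],
                              x[, c(2:n, n), , , drop = FALSE],
                              x[, , c(2:n, n), , drop = FALSE])
                diff <- fwd - x          # zero in the duplicated last slice
                value <- value + sum(huberValue(diff, delta))
                g <- huberGrad(diff, delta)
                grad <- grad - g
                gshift <- switch(ax,
                                 g[c(1L, seq_len(n - 1L)), , , , drop = FALSE],
                                 g[, c(1L, seq_len(n - 1L)), , , drop = FALSE],
                                 g[, , c(1L, seq_len(n - 1L)), , drop = FALSE])
                zero_first <- function(a, ax) {
                    switch(ax,
                           { a[1L, , , ] <- 0; a },
                           { a[, 1L, , ] <- 0; a },
                           { a[, , 1L, ] <- 0; a })
                }
                grad <- grad + zero_first(gshift, ax)
            }
            list(value = value, gradient = grad)
        },
        l2 = list(value = 0.5 * sum(x^2), gradient = x),
        l1 = list(value = sum(abs(x)), gradient = sign(x)),
        huber_norm = list(value = sum(huberValue(x, delta)),
                          gradient = huberGrad(x, delta))
    )
}

.apply_reg <- function(x, regularizers, basis = NULL) {
    value <- 0
    grad <- array(0, dim(x))
    for (rg in regularizers) {
        mu <- rg$weight
        if (is.null(mu) || mu < 0) stop("regularizer weight must be >= 0")
        if (mu == 0) next
        if (!is.null(basis) && is(basis, "SphericalHarmonicsBasis") &&
            rg$kind %in% c("l1", "huber_norm"))
            warning("l1/huber_norm penalties are not rotational invariants ",
                    "with a spherical-harmonics basis and can bias the ",
                    "solution towards certain directions", call. = FALSE)
        xr <- x
        dW <- rg$dWeights
        if (!is.null(dW)) {
            if (length(dW) != dim(x)[4L])
                stop("dWeights must have one entry per coefficient channel")
            xr <- sweep(x, 4L, dW, `*`)
        }
        vg <- regularizerValueGrad(xr, rg$kind,
                                   delta = if (is.null(rg$delta)) 1e-2 else rg$delta)
        g <- vg$gradient
        if (!is.null(dW)) g <- sweep(g, 4L, dW, `*`)
        value <- value + mu * vg$value
        grad <- grad + mu * g
    }
    list(value = value, gradient = grad)
}

# ---- residual and gradient --------------------------------------------------

#' Loss value and gradient of the tensor-tomography model
#'
#' Evaluates the data term of the reconstruction problem for a coefficient
#' field: the model intensities are the basis response applied to the
#' John-transform projections, the residuals are
#' \code{weights * (model - data)} (weight 0 fully excludes a measurement),
#' the loss is the sum of \code{rho(residual)} (squared or Huber) plus any
#' regularization terms, and the gradient is the exact adjoint chain applied
#' to \code{rho'(residuals) * weights} plus regularizer gradients.
#'
#' @param field Numeric array [X, Y, Z, N] or \linkS4class{TensorField}.
#' @param stack A \linkS4class{ProjectionStack}.
#' @param response Segment-response array [S, C, N] from
#'   \code{\link{segmentIntegrals}}.
#' @param loss \code{"squared"} or \code{"huber"}.
#' @param huberDelta Huber transition point for the data term.
#' @param regularizers List of terms, each
#'   \code{list(kind =, weight =, delta =, dWeights =)}; see
#'   \code{\link{regularizerValueGrad}}.  \code{dWeights} is an optional
#'   per-coefficient diagonal weight.
#' @param basis Optional \linkS4class{BasisSet} (enables the anisotropy
#'   warning for l1-type penalties with spherical harmonics).
#' @return List with \code{value}, \code{gradient} (array like the field) and
#'   \code{residuals} (array [S, J, K, C]).
#' @export
residualAndGradient <- function(field, stack, response,
                                loss = c("squared", "huber"), huberDelta = 1,
                                regularizers = list(), basis = NULL) {
    loss <- match.arg(loss)
    x <- if (is(field, "TensorField")) field@coefficients else field
    x <- .as_field4(x)
    if (any(!is.finite(x))) stop("field contains non-finite values")
    geom <- stack@geometry
    d <- dim(stack@data)
    model <- forwardModel(x, geom, response, J = d[2L], K = d[3L])
    r <- stack@weights * (model - stack@data)
    if (loss == "squared") {
        value <- 0.5 * sum(r^2)
        rho1 <- r
    } else {
        value <- sum(huberValue(r, huberDelta))
        rho1 <- huberGrad(r, huberDelta)
    }
    grad <- adjointModel(stack@weights * rho1, geom, response)
    if (length(regularizers)) {
        rv <- .apply_reg(x, regularizers, basis)
        value <- value + rv$value
        grad <- grad + rv$gradient
    }
    if (!is.finite(value)) stop("loss is not finite")
    list(value = value, gradient = grad, residuals = r)
}

# ---- optimizers -------------------------------------------------------------

#' Gradient descent with optional Nesterov momentum
#'
#' Fixed-step gradient descent \code{x <- y - step * grad(f)(y)} with the
#' standard Nesterov extrapolation \code{y = x + t/(t+3) * (x - x_prev)} when
#' \code{nesterov = TRUE}.  Stops at \code{maxIter} iterations or when the
#' relative loss change falls below \code{tol}; returns the best iterate
#' seen.
#'
#' @param fn Function taking the current array and returning
#'   \code{list(value =, gradient =)}.
#' @param x0 Start array.
#' @param step Positive step size.
#' @param nesterov Enable momentum.
#' @param maxIter Iteration cap.
#' @param tol Relative loss-change stopping tolerance.
#' @return List with \code{x} (final iterate), \code{trace} (loss values) and
#'   \code{converged}.
#' @export
gradientDescent <- function(fn, x0, step, nesterov = FALSE, maxIter = 100L,
                            tol = 0) {
    if (step <= 0) stop("step must be positive")
    x <- x0
    xPrev <- x0
    trace <- numeric(0)
    for (t in seq_len(maxIter)) {
        y <- if (nesterov && t > 1L) x + ((t - 1) / (t + 2)) * (x - xPrev) else x
        fg <- fn(y)
        if (!is.finite(fg$value)) stop("loss became non-finite during descent")
        trace <- c(trace, fg$value)
        xPrev <- x
        x <- y - step * fg$gradient
        if (t > 1L && tol > 0) {
            rel <- abs(trace[t] - trace[t - 1L]) /
                max(abs(trace[t - 1L]), .Machine$double.eps)
            if (rel < tol)
                return(list(x = x, trace = trace, converged = TRUE))
        }
    }
    list(x = x, trace = trace, converged = FALSE)
}

#' Quasi-Newton minimization (L-BFGS-B)
#'
#' Thin wrapper around \code{stats::optim(method = "L-BFGS-B")} for functions
#' returning value and gradient together; the relative loss-change stopping
#' rule is mapped onto the optimizer's \code{factr} control.  Deterministic
#' given the start point.
#'
#' @param fn Function: array -> \code{list(value =, gradient =)}.
#' @param x0 Start array.
#' @param maxIter Iteration cap.
#' @param tol Relative loss-change stopping tolerance.
#' @param lower,upper Optional bounds (default unbounded).
#' @return List with \code{x}, \code{value}, \code{trace} (loss at each
#'   evaluation) and \code{converged}.
#' @export
lbfgsMinimize <- function(fn, x0, maxIter = 50L, tol = 1e-4,
                          lower = -Inf, upper = Inf) {
    d <- dim(x0)
    trace <- new.env()
    trace$vals <- numeric(0)
    cache <- new.env()
    evalAt <- function(par) {
        if (!is.null(cache$par) && identical(par, cache$par)) return(cache$fg)
        x <- par
        if (!is.null(d)) dim(x) <- d
        fg <- fn(x)
        cache$par <- par
        cache$fg <- fg
        trace$vals <- c(trace$vals, fg$value)
        fg
    }
    res <- optim(as.numeric(x0),
                 fn = function(par) evalAt(par)$value,
                 gr = function(par) as.numeric(evalAt(par)$gradient),
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = maxIter,
                                factr = max(tol / .Machine$double.eps, 10)))
    x <- res$par
    if (!is.null(d)) dim(x) <- d
    if (res$convergence > 1L)
        warning("L-BFGS-B reported: ", res$message, call. = FALSE)
    list(x = x, value = res$value, trace = trace$vals,
         converged = res$convergence == 0L)
}
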