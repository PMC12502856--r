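#' Basis-set constructors
#'
#' @param lMax Spherical-harmonic band limit.  With \code{friedel = TRUE}
#'   (default) only even degrees are included, matching the inversion
#'   symmetry of scattering intensities and half-circle SAXS detector
#'   coverage; odd degrees are admitted with \code{friedel = FALSE} for full
#'   360-degree WAXS data.
#' @param friedel Antipodal (Friedel) symmetry flag.
#' @return A \linkS4class{SphericalHarmonicsBasis}.
#' @seealso \linkS4class{BasisSet}
#' @export
SphericalHarmonicsBasis <- function(lMax = 6L, friedel = TRUE) {
    new("SphericalHarmonicsBasis", lMax = as.integer(lMax), friedel = friedel)
}

#' @rdname SphericalHarmonicsBasis
#' @param directions M x 3 matrix of unit grid vectors (rows), e.g. from
#'   \code{\link{fibonacciGrid}} or \code{\link{truncatedIcosahedronGrid}}.
#' @export
NearestNeighborBasis <- function(directions, friedel = TRUE) {
    new("NearestNeighborBasis", directions = .as_dirmat(directions),
        friedel = friedel)
}

#' @rdname SphericalHarmonicsBasis
#' @param sigma Gaussian kernel width (radians, geodesic).
#' @export
GaussianKernelBasis <- function(directions, sigma = 0.3, friedel = TRUE) {
    new("GaussianKernelBasis", directions = .as_dirmat(directions),
        sigma = as.numeric(sigma), friedel = friedel)
}

.as_dirmat <- function(directions) {
    d <- as.matrix(directions)
    if (ncol(d) != 3L) stop("directions must be an M x 3 matrix")
    storage.mode(d) <- "double"
    dimnames(d) <- NULL
    d
}

.check_unit_dirs <- function(directions) {
    n <- sqrt(rowSums(directions^2))
    if (any(abs(n - 1) > 1e-7))
        stop("directions must be unit vectors")
    invisible(directions)
}

# ---- coefficient counts -----------------------------------------------------

.sh_degrees <- function(basis) {
    if (basis@friedel) seq(0L, basis@lMax, by = 2L) else seq(0L, basis@lMax)
}

#' @rdname coefficientCount
setMethod("coefficientCount", "SphericalHarmonicsBasis", function(basis) {
    sum(2L * .sh_degrees(basis) + 1L)
})

#' @rdname coefficientCount
setMethod("coefficientCount", "NearestNeighborBasis", function(basis) {
    nrow(basis@directions)
})

#' @rdname coefficientCount
setMethod("coefficientCount", "GaussianKernelBasis", function(basis) {
    nrow(basis@directions)
})

#' Degree/order table of a spherical-harmonic basis
#'
#' Coefficient ordering is degree l ascending (even only under Friedel
#' symmetry), order m from -l to +l within each degree.
#'
#' @param basis A \linkS4class{SphericalHarmonicsBasis}.
#' @return data.frame with columns \code{l} and \code{m}, one row per
#'   coefficient.
#' @export
shIndexTable <- function(basis) {
    ls <- .sh_degrees(basis)
    data.frame(l = rep(ls, 2L * ls + 1L),
               m = unlist(lapply(ls, function(l) seq(-l, l))))
}

# ---- evaluation -------------------------------------------------------------

# Real orthonormal (tesseral) spherical harmonics, Condon-Shortley phase
# cancelled so that e.g. Y_{2,1} = sqrt(15/4pi) * xz.
.sh_evaluate <- function(dirs, degrees) {
    n <- nrow(dirs)
    ct <- pmin(1, pmax(-1, dirs[, 3L]))
    phi <- atan2(dirs[, 2L], dirs[, 1L])
    out <- matrix(0, n, sum(2L * degrees + 1L))
    col <- 1L
    for (l in degrees) {
        if (l == 0L) {
            out[, col] <- 1 / sqrt(4 * pi)
            col <- col + 1L
            next
        }
        P <- pracma::legendre(l, ct)       # (l+1) x n, rows m = 0..l, CS phase
        if (n == 1L) P <- matrix(P, ncol = 1L)
        for (m in seq(-l, l)) {
            am <- abs(m)
            norm <- sqrt((2 * l + 1) / (4 * pi) *
                         exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
            pm <- (-1)^am * P[am + 1L, ]   # cancel Condon-Shortley
            out[, col] <- if (m == 0L) norm * pm
                          else if (m > 0L) sqrt(2) * norm * pm * cos(am * phi)
                          else sqrt(2) * norm * pm * sin(am * phi)
            col <- col + 1L
        }
    }
    out
}

.prep_dirs <- function(directions) {
    if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3L)
    directions <- .as_dirmat(directions)
    .check_unit_dirs(directions)
    directions
}

#' @rdname evaluateBasis
setMethod("evaluateBasis", "SphericalHarmonicsBasis", function(basis, directions) {
    dirs <- .prep_dirs(directions)
    .sh_evaluate(dirs, .sh_degrees(basis))
})

#' @rdname evaluateBasis
setMethod("evaluateBasis", "NearestNeighborBasis", function(basis, directions) {
    dirs <- .prep_dirs(directions)
    dots <- dirs %*% t(basis@directions)
    if (basis@friedel) dots <- abs(dots)
    nearest <- max.col(dots, ties.method = "first")
    out <- matrix(0, nrow(dirs), nrow(basis@directions))
    out[cbind(seq_len(nrow(dirs)), nearest)] <- 1
    out
})

#' @rdname evaluateBasis
setMethod("evaluateBasis", "GaussianKernelBasis", function(basis, directions) {
    dirs <- .prep_dirs(directions)
    dots <- dirs %*% t(basis@directions)
    if (basis@friedel) dots <- abs(dots)
    dots[dots > 1] <- 1
    dots[dots < -1] <- -1
    d <- acos(dots)                        # geodesic angle to nearer center
    exp(-d^2 / (2 * basis@sigma^2))
})

# ---- detector-segment response ----------------------------------------------

# Adaptive Simpson quadrature for a vector-valued integrand (Newton-Cotes
# order 2 with interval halving), absolute tolerance in the max norm.
.adaptive_simpson <- function(f, a, b, tol, maxDepth = 24L) {
    rec <- function(a, b, fa, fm, fb, whole, depth) {
        m <- (a + b) / 2
        fl <- f((a + m) / 2); fr <- f((m + b) / 2)
        left <- (m - a) / 6 * (fa + 4 * fl + fm)
        right <- (b - m) / 6 * (fm + 4 * fr + fb)
        err <- max(abs(left + right - whole))
        if (err < 15 * tol || depth >= maxDepth)
            return(left + right + (left + right - whole) / 15)
        rec(a, m, fa, fl, fm, left, depth + 1L) +
            rec(m, b, fm, fr, fb, right, depth + 1L)
    }
    fa <- f(a); fb <- f(b); fm <- f((a + b) / 2)
    whole <- (b - a) / 6 * (fa + 4 * fm + fb)
    rec(a, b, fa, fm, fb, whole, 0L)
}

#' @rdname segmentIntegrals
setMethod("segmentIntegrals", "BasisSet",
function(basis, geometry, segments, method = c("adaptive", "midpoint"),
         tol = 1e-6) {
    method <- match.arg(method)
    S <- length(geometry@innerAngles)
    bnd <- segments@boundaries
    C <- length(bnd) - 1L
    N <- coefficientCount(basis)
    theta <- segments@scatteringAngle / 2
    q0 <- geometry@detectorDirectionOrigin
    q90 <- geometry@detectorDirectionPositive90
    p <- geometry@pDirection
    out <- array(0, c(S, C, N))
    for (s in seq_len(S)) {
        R <- rotationMatrix(geometry, s)
        dirfun <- function(phi) {
            qlab <- cos(theta) * (cos(phi) * q0 + sin(phi) * q90) -
                sin(theta) * p
            drop(crossprod(R, qlab))
        }
        f <- function(phi) evaluateBasis(basis, dirfun(phi))[1L, ]
        for (cc in seq_len(C)) {
            lo <- bnd[cc]; hi <- bnd[cc + 1L]
            out[s, cc, ] <- if (method == "midpoint") f((lo + hi) / 2)
                            else .adaptive_simpson(f, lo, hi, tol) / (hi - lo)
        }
        if (any(!is.finite(out[s, , ])))
            stop(sprintf("segment integral not finite at projection %d", s))
    }
    out
})

#' Evaluate a reciprocal-space map on a sphere mesh
#'
#' Computes W(q) = sum_i c_i basis_i(q) on each mesh node, the
#' latitude-longitude view of one voxel's 2D reciprocal-space-map shell.
#'
#' @param coefficients Numeric vector of length N.
#' @param basis A \linkS4class{BasisSet}.
#' @param mesh n x 3 matrix of unit vectors.
#' @return Numeric vector of length n.
#' @export
rsmOnGrid <- function(coefficients, basis, mesh) {
    if (length(coefficients) != coefficientCount(basis))
        stop("coefficient length does not match the basis set")
    drop(evaluateBasis(basis, mesh) %*% coefficients)
}

# ---- sphere meshes and quadrature -------------------------------------------

#' Near-uniform direction grids on the sphere
#'
#' \code{fibonacciGrid} returns n directions from the Fibonacci (golden-angle)
#' spiral, restricted to the upper hemisphere when \code{hemisphere = TRUE}
#' (the natural choice for antipodally symmetric bases).
#' \code{truncatedIcosahedronGrid} returns the 32 face-center directions of
#' the truncated icosahedron (12 pentagon centers = icosahedron vertices plus
#' 20 hexagon centers = dodecahedron vertices), or the 16 upper-hemisphere
#' representatives when \code{hemisphere = TRUE}.
#'
#' @param n Number of directions.
#' @param hemisphere Keep only directions with z >= 0 (one representative per
#'   antipodal pair).
#' @return Matrix of unit row vectors.
#' @export
fibonacciGrid <- function(n, hemisphere = TRUE) {
    m <- if (hemisphere) 2L * n else n
    i <- seq_len(m) - 0.5
    z <- 1 - 2 * i / m
    r <- sqrt(pmax(0, 1 - z^2))
    ga <- pi * (3 - sqrt(5))
    pts <- cbind(r * cos(ga * i), r * sin(ga * i), z)
    if (hemisphere) pts <- pts[pts[, 3L] >= 0, , drop = FALSE][seq_len(n), , drop = FALSE]
    pts / sqrt(rowSums(pts^2))
}

#' @rdname fibonacciGrid
#' @export
truncatedIcosahedronGrid <- function(hemisphere = TRUE) {
    gr <- (1 + sqrt(5)) / 2
    cyc <- function(v) rbind(v, v[c(2, 3, 1)], v[c(3, 1, 2)])
    ico <- do.call(rbind, lapply(list(c(0, 1, gr), c(0, 1, -gr),
                                      c(0, -1, gr), c(0, -1, -gr)), cyc))
    dod <- rbind(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
                 do.call(rbind, lapply(list(c(0, 1 / gr, gr), c(0, 1 / gr, -gr),
                                            c(0, -1 / gr, gr), c(0, -1 / gr, -gr)),
                                       cyc)))
    pts <- rbind(ico, dod)
    pts <- pts / sqrt(rowSums(pts^2))
    if (hemisphere) {
        keep <- pts[, 3L] > 1e-12 |
            (abs(pts[, 3L]) <= 1e-12 &
                 (pts[, 2L] > 1e-12 | (abs(pts[, 2L]) <= 1e-12 & pts[, 1L] > 0)))
        pts <- pts[keep, , drop = FALSE]
    }
    dimnames(pts) <- NULL
    pts
}

#' Quadrature rule on the unit sphere
#'
#' Product rule combining Gauss-Legendre nodes in the polar cosine with a
#' uniform (trapezoidal) azimuthal grid; exact for spherical polynomials up
#' to high degree and therefore used for all surface integrals of
#' reciprocal-space maps.
#'
#' @param n Approximate number of nodes (the rule uses about this many).
#' @return List with \code{points} (m x 3 unit vectors) and \code{weights}
#'   (length m, summing to 4*pi).
#' @export
sphereQuadrature <- function(n = 1000L) {
    nt <- max(4L, ceiling(sqrt(n / 2)))
    np <- 2L * nt
    gl <- pracma::gaussLegendre(nt, -1, 1)
    phi <- 2 * pi * (seq_len(np) - 1) / np
    ct <- rep(gl$x, each = np)
    st <- sqrt(pmax(0, 1 - ct^2))
    ph <- rep(phi, nt)
    pts <- cbind(st * cos(ph), st * sin(ph), ct)
    w <- rep(gl$w, each = np) * (2 * pi / np)
    list(points = pts, weights = w)
}
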