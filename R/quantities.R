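#' Mean (isotropic) scattering intensity per voxel
#'
#' The spherical average (1/4pi) of the reciprocal-space map W over the unit
#' sphere.  For spherical harmonics this is computed analytically from the
#' degree-0 coefficient (c00 / sqrt(4*pi)); for grid-based bases by sphere
#' quadrature.
#'
#' @param field A \linkS4class{TensorField}.
#' @param quadratureNodes Number of quadrature nodes for non-analytic bases
#'   (>= 500 recommended).
#' @return Numeric array [X, Y, Z].
#' @export
meanIntensity <- function(field, quadratureNodes = 1000L) {
    co <- field@coefficients
    d <- dim(co)
    basis <- field@basis
    if (is(basis, "SphericalHarmonicsBasis"))
        return(array(co[, , , 1L] / sqrt(4 * pi), d[1:3]))
    quad <- sphereQuadrature(quadratureNodes)
    A <- evaluateBasis(basis, quad$points)
    m <- drop(crossprod(A, quad$weights)) / (4 * pi)      # length N
    array(matrix(co, prod(d[1:3]), d[4L]) %*% m, d[1:3])
}

# Exact second-moment response of the degree-0/2 real spherical harmonics:
# integral of Y_lm(q) q_i q_j over the sphere.  Only l = 0 and l = 2
# contribute for any band limit.
.sh_moment_matrices <- function() {
    c15 <- 2 * sqrt(pi / 15)
    list(
        l0 = diag(3) * (2 * sqrt(pi) / 3),
        m_m2 = matrix(c(0, c15, 0, c15, 0, 0, 0, 0, 0), 3, 3),  # xy
        m_m1 = matrix(c(0, 0, 0, 0, 0, c15, 0, c15, 0), 3, 3),  # yz
        m_0 = diag(c(-1, -1, 2)) * (2 / 3) * sqrt(pi / 5),
        m_p1 = matrix(c(0, 0, c15, 0, 0, 0, c15, 0, 0), 3, 3),  # xz
        m_p2 = diag(c(1, -1, 0)) * c15
    )
}

#' Second-moment tensor per voxel
#'
#' The rank-2 tensor T with elements \code{T[i, j] = integral of
#' W(q) q_i q_j} over the unit sphere.  For spherical harmonics only the
#' degree-0 and degree-2 coefficients contribute and the tensor is obtained
#' in closed form; for other bases (or \code{method = "quadrature"}) it is
#' computed by sphere quadrature.  The tensor is not normalized by the
#' spherical mean; fractional anisotropy and orientation are invariant to
#' that choice.
#'
#' @param field A \linkS4class{TensorField}.
#' @param method \code{"auto"} (closed form when available),
#'   \code{"closed"} or \code{"quadrature"}.
#' @param quadratureNodes Quadrature size for the quadrature path.
#' @return Numeric array [X, Y, Z, 3, 3], symmetric in the last two indices.
#' @export
secondMoment <- function(field, method = c("auto", "closed", "quadrature"),
                         quadratureNodes = 1000L) {
    method <- match.arg(method)
    basis <- field@basis
    co <- field@coefficients
    d <- dim(co)
    nv <- prod(d[1:3])
    cm <- matrix(co, nv, d[4L])
    if (method == "closed" && !is(basis, "SphericalHarmonicsBasis"))
        stop("closed-form second moment is only available for spherical harmonics")
    useClosed <- method == "closed" ||
        (method == "auto" && is(basis, "SphericalHarmonicsBasis"))
    if (useClosed) {
        tab <- shIndexTable(basis)
        M <- .sh_moment_matrices()
        Tm <- array(0, c(nv, 3, 3))
        add <- function(Tm, cvec, mat) {
            for (i in 1:3) for (j in 1:3)
                if (mat[i, j] != 0) Tm[, i, j] <- Tm[, i, j] + cvec * mat[i, j]
            Tm
        }
        Tm <- add(Tm, cm[, 1L], M$l0)
        idx2 <- which(tab$l == 2L)
        if (length(idx2)) {
            mats <- list(M$m_m2, M$m_m1, M$m_0, M$m_p1, M$m_p2)
            for (k in seq_along(idx2))
                Tm <- add(Tm, cm[, idx2[k]], mats[[k]])
        }
    } else {
        quad <- sphereQuadrature(quadratureNodes)
        A <- evaluateBasis(basis, quad$points)
        W <- cm %*% t(A)                                   # nv x m
        q <- quad$points
        Tm <- array(0, c(nv, 3, 3))
        for (i in 1:3) for (j in i:3) {
            g <- W %*% (quad$weights * q[, i] * q[, j])
            Tm[, i, j] <- g
            Tm[, j, i] <- g
        }
    }
    array(Tm, c(d[1:3], 3, 3))
}

#' Fractional anisotropy from eigenvalues
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, the standard
#' scale-free eigenvalue dispersion measure: 0 for perfectly isotropic
#' scattering, 1 when all scattering is concentrated along one eigendirection
#' and vanishes in the orthogonal ones.  For positive semi-definite tensors
#' the value is clipped to [0, 1] (guarding round-off); an all-zero triple is
#' undefined and yields NA.
#'
#' @param eigenvalues Numeric vector of 3 eigenvalues, or an n x 3 matrix of
#'   triples (rows).
#' @return Numeric scalar or vector of FA values in [0, 1] (NA where
#'   undefined).
#' @export
fractionalAnisotropy <- function(eigenvalues) {
    ev <- if (is.null(dim(eigenvalues))) matrix(eigenvalues, ncol = 3L)
          else as.matrix(eigenvalues)
    if (ncol(ev) != 3L) stop("expected 3 eigenvalues per tensor")
    mu <- rowMeans(ev)
    num <- sqrt(rowSums((ev - mu)^2))
    den <- sqrt(rowSums(ev^2))
    fa <- sqrt(3 / 2) * num / den
    fa[den == 0] <- NA_real_
    fa <- pmin(1, pmax(0, fa))
    if (is.null(dim(eigenvalues))) fa[1L] else fa
}

#' Main nanostructure orientation from a second-moment tensor
#'
#' For scattering concentrated at two opposite poles (\code{"polar_peaks"})
#' the main orientation is the eigenvector of the largest eigenvalue; for an
#' equatorial scattering band (\code{"equatorial_band"}, e.g. fiber
#' scattering perpendicular to the fiber axis) it is the eigenvector of the
#' smallest eigenvalue.  The sign is fixed so that the first component of
#' magnitude above 1e-12 is positive.  If the relevant eigenvalue pair is
#' degenerate (gap below 1e-9 of the trace magnitude) the result carries the
#' attribute \code{ambiguous = TRUE} and the tie is broken deterministically
#' by eigenvector index.
#'
#' @param tensor Symmetric 3 x 3 matrix.
#' @param mode \code{"polar_peaks"} or \code{"equatorial_band"}.
#' @return Unit 3-vector (possibly with attribute \code{ambiguous}).
#' @export
mainOrientation <- function(tensor, mode = c("polar_peaks", "equatorial_band")) {
    mode <- match.arg(mode)
    if (max(abs(tensor - t(tensor))) > 1e-8 * max(1, max(abs(tensor))))
        stop("second-moment tensor must be symmetric")
    e <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)  # values descending
    idx <- if (mode == "polar_peaks") 1L else 3L
    gapIdx <- if (mode == "polar_peaks") 1L else 2L
    gap <- e$values[gapIdx] - e$values[gapIdx + 1L]
    v <- e$vectors[, idx]
    v <- .fix_sign(v)
    if (abs(gap) < 1e-9 * max(abs(sum(diag(tensor))), .Machine$double.xmin))
        attr(v, "ambiguous") <- TRUE
    v
}

.fix_sign <- function(v) {
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1L]] < 0) v <- -v
    v
}

#' Relative anisotropy per voxel
#'
#' The spherical standard deviation of the reciprocal-space map normalized by
#' its spherical mean, evaluated on a quadrature mesh.
#'
#' @param field A \linkS4class{TensorField}.
#' @param quadratureNodes Quadrature size.
#' @return Numeric array [X, Y, Z] (NA where the mean vanishes).
#' @export
relativeAnisotropy <- function(field, quadratureNodes = 1000L) {
    co <- field@coefficients
    d <- dim(co)
    quad <- sphereQuadrature(quadratureNodes)
    A <- evaluateBasis(field@basis, quad$points)
    W <- matrix(co, prod(d[1:3]), d[4L]) %*% t(A)
    wn <- quad$weights / sum(quad$weights)
    mu <- drop(W %*% wn)
    m2 <- drop(W^2 %*% wn)
    sdv <- sqrt(pmax(0, m2 - mu^2))
    out <- sdv / mu
    out[mu == 0] <- NA_real_
    array(out, d[1:3])
}

#' Compute all derived maps of a reconstruction
#'
#' Fills the \code{maps} slot of a \linkS4class{TTReconstruction} with the
#' per-voxel mean intensity, second-moment tensor, its eigensystem
#' (eigenvalues descending, orthonormal eigenvectors), fractional anisotropy,
#' main orientation and relative anisotropy.
#'
#' @param rec A \linkS4class{TTReconstruction} (or a
#'   \linkS4class{TensorField}, which is wrapped).
#' @param mode Orientation rule, see \code{\link{mainOrientation}}.
#' @param quadratureNodes Quadrature size for non-analytic bases.
#' @return The reconstruction with populated \code{maps}.
#' @export
deriveMaps <- function(rec, mode = c("polar_peaks", "equatorial_band"),
                       quadratureNodes = 1000L) {
    mode <- match.arg(mode)
    if (is(rec, "TensorField"))
        rec <- new("TTReconstruction", field = rec, maps = list(),
                   provenance = list())
    field <- rec@field
    d <- dim(field@coefficients)
    sm <- secondMoment(field, quadratureNodes = quadratureNodes)
    nv <- prod(d[1:3])
    smFlat <- array(sm, c(nv, 3, 3))
    vals <- matrix(0, nv, 3)
    vecs <- array(0, c(nv, 3, 3))
    orient <- matrix(0, nv, 3)
    pick <- if (mode == "polar_peaks") 1L else 3L
    for (v in seq_len(nv)) {
        e <- eigen(matrix(smFlat[v, , ], 3, 3), symmetric = TRUE)
        vals[v, ] <- e$values
        vecs[v, , ] <- e$vectors
        orient[v, ] <- .fix_sign(e$vectors[, pick])
    }
    rec@maps <- list(
        mean_intensity = meanIntensity(field, quadratureNodes),
        second_moment = sm,
        eigenvalues = array(vals, c(d[1:3], 3)),
        eigenvectors = array(vecs, c(d[1:3], 3, 3)),
        fractional_anisotropy = array(fractionalAnisotropy(vals), d[1:3]),
        main_orientation = array(orient, c(d[1:3], 3)),
        relative_anisotropy = relativeAnisotropy(field, quadratureNodes),
        orientation_mode = mode)
    rec
}
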