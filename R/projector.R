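#' John-transform projector (forward)
#'
#' Computes line integrals of a multi-channel voxel field along the beam for
#' every projection and raster-scan position, using Joseph's method: the ray
#' marches in unit steps along the dominant component of the rotated beam
#' direction and the field is bilinearly interpolated in the transverse
#' plane.  The interpolation weights are the beam-voxel overlap coefficients;
#' each lies in [0, 1] and is zero for voxels the ray does not touch.
#' Per-projection offsets are applied as sub-pixel shifts of the ray origins
#' in the scan plane.  Channels are treated independently.
#'
#' @param field Numeric array [X, Y, Z, N] (a 3D array is promoted to N = 1).
#' @param geometry A \linkS4class{TTGeometry}; its \code{volumeShape} must
#'   match the field.
#' @param J,K Raster-scan dimensions (default: the two transverse volume
#'   dimensions).
#' @return Numeric array [S, J, K, N].
#' @seealso \code{\link{adjointProject}}, the exact transpose.
#' @export
forwardProject <- function(field, geometry, J = NULL, K = NULL) {
    field <- .as_field4(field)
    d <- dim(field)
    if (!identical(d[1:3], as.integer(geometry@volumeShape)))
        stop("field shape does not match geometry volumeShape")
    if (is.null(J)) J <- d[2L]
    if (is.null(K)) K <- d[3L]
    bb <- beamBasis(geometry)
    scale <- geometry@scanStep / geometry@voxelSize
    cpp_forward(field, as.integer(d), as.integer(J), as.integer(K),
                bb$p, bb$j * scale, bb$k * scale,
                geometry@jOffsets, geometry@kOffsets)
}

#' John-transform projector (adjoint)
#'
#' Exact matrix transpose of \code{\link{forwardProject}}: satisfies
#' \code{sum(forwardProject(x) * y) == sum(x * adjointProject(y))} to
#' round-off for all fields x and projection arrays y.
#'
#' @param projections Numeric array [S, J, K, N] (3D promoted to N = 1).
#' @param geometry A \linkS4class{TTGeometry}.
#' @return Numeric array [X, Y, Z, N].
#' @export
adjointProject <- function(projections, geometry) {
    projections <- .as_field4(projections)
    d <- dim(projections)
    S <- length(geometry@innerAngles)
    if (d[1L] != S) stop("projection array does not match geometry (S)")
    bb <- beamBasis(geometry)
    scale <- geometry@scanStep / geometry@voxelSize
    cpp_adjoint(projections, c(as.integer(geometry@volumeShape), d[4L]),
                d[2L], d[3L], bb$p, bb$j * scale, bb$k * scale,
                geometry@jOffsets, geometry@kOffsets)
}

.as_field4 <- function(x) {
    if (is.null(dim(x))) stop("expected an array")
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    if (length(dim(x)) != 4L) stop("expected a 3D or 4D array")
    x
}

#' Full tensor-tomography forward model
#'
#' Combines the spatial projector with the detector-segment response of the
#' basis set: \code{model[s, j, k, c] = sum_i B[s, c, i] *
#' forwardProject(field)[s, j, k, i]}.  \code{adjointModel} is its exact
#' transpose.
#'
#' @param field Numeric array [X, Y, Z, N].
#' @param geometry A \linkS4class{TTGeometry}.
#' @param response Segment-response array [S, C, N] from
#'   \code{\link{segmentIntegrals}}.
#' @param J,K Raster-scan dimensions.
#' @return \code{forwardModel}: array [S, J, K, C]; \code{adjointModel}:
#'   array [X, Y, Z, N].
#' @export
forwardModel <- function(field, geometry, response, J = NULL, K = NULL) {
    proj <- forwardProject(field, geometry, J, K)
    d <- dim(proj)
    S <- d[1L]; C <- dim(response)[2L]; N <- d[4L]
    if (!identical(dim(response), c(S, C, N)))
        stop("response array does not match geometry/basis")
    out <- array(0, c(S, d[2L], d[3L], C))
    jk <- d[2L] * d[3L]
    for (s in seq_len(S)) {
        ps <- matrix(proj[s, , , ], jk, N)
        out[s, , , ] <- ps %*% t(matrix(response[s, , ], C, N))
    }
    out
}

#' @rdname forwardModel
#' @param modelResiduals Numeric array [S, J, K, C] in data space.
#' @export
adjointModel <- function(modelResiduals, geometry, response) {
    d <- dim(modelResiduals)
    S <- d[1L]; C <- d[4L]; N <- dim(response)[3L]
    proj <- array(0, c(S, d[2L], d[3L], N))
    jk <- d[2L] * d[3L]
    for (s in seq_len(S)) {
        rs <- matrix(modelResiduals[s, , , ], jk, C)
        proj[s, , , ] <- rs %*% matrix(response[s, , ], C, N)
    }
    adjointProject(proj, geometry)
}

#' SIRT preconditioners
#'
#' Row- and column-sum preconditioners of the simultaneous iterative
#' reconstruction technique, generalized to the tensor system matrix
#' A = (projector) x (segment response): \code{R = 1/rowSums(|A|)} in data
#' space and \code{C = 1/colSums(|A|)} in coefficient space, computed
#' matrix-free by applying the projector to all-ones arrays and combining
#' with the per-segment absolute response sums.  Sums below
#' \code{1e-12 * max(sum)} are masked to 0 (the corresponding rows/columns
#' are excluded).  Absolute values make the weights well defined for signed
#' (spherical-harmonic) responses; for nonnegative responses they coincide
#' with the plain row/column sums.
#'
#' @param geometry A \linkS4class{TTGeometry}.
#' @param response Segment-response array [S, C, N].
#' @param J,K Raster-scan dimensions.
#' @return List with \code{C} (array [X, Y, Z, N]) and \code{R}
#'   (array [S, J, K, C]).
#' @export
sirtPreconditioners <- function(geometry, response, J = NULL, K = NULL) {
    vs <- geometry@volumeShape
    if (is.null(J)) J <- vs[2L]
    if (is.null(K)) K <- vs[3L]
    S <- length(geometry@innerAngles)
    C <- dim(response)[2L]; N <- dim(response)[3L]
    ones <- array(1, c(vs, 1L))
    raySums <- forwardProject(ones, geometry, J, K)[, , , 1L, drop = FALSE]
    bAbsRow <- apply(abs(response), c(1L, 2L), sum)        # [S, C]
    rowSum <- array(0, c(S, J, K, C))
    for (cc in seq_len(C))
        rowSum[, , , cc] <- raySums[, , , 1L] * bAbsRow[, cc]
    bAbsCol <- apply(abs(response), c(1L, 3L), sum)        # [S, N]
    proj <- array(0, c(S, J, K, N))
    for (n in seq_len(N))
        proj[, , , n] <- array(bAbsCol[, n], c(S, J, K))
    colSum <- adjointProject(proj, geometry)
    inv_masked <- function(x) {
        eps <- 1e-12 * max(x)
        out <- array(0, dim(x))
        ok <- x > eps
        out[ok] <- 1 / x[ok]
        out
    }
    list(C = inv_masked(colSum), R = inv_masked(rowSum))
}
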