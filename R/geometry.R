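#' Construct an experiment geometry
#'
#' The default vectors place the beam along +x, the raster-scan axes along +y
#' (j) and +z (k), the detector azimuth origin along +z with the positive
#' azimuth direction +y, the inner "rotation" axis along +z and the outer
#' "tilt" axis along +y.  All of them are configurable; the only constraints
#' are unit norm and the orthogonality of the two scan axes and of the two
#' detector directions.
#'
#' @param innerAngles,outerAngles Per-projection goniometer angles (radians).
#' @param volumeShape Voxel-grid shape, 3 positive integers (a scalar is
#'   recycled to a cube).
#' @param jOffsets,kOffsets Per-projection offsets in scan-step units
#'   (default 0).
#' @param pDirection,jDirection,kDirection,detectorDirectionOrigin,detectorDirectionPositive90,innerAxis,outerAxis
#'   Geometry unit vectors, see above.
#' @param voxelSize,scanStep Voxel edge a and scan step b (default 1 and 1).
#' @return A \linkS4class{TTGeometry}.
#' @examples
#' g <- TTGeometry(innerAngles = seq(0, pi, length.out = 4),
#'                 outerAngles = rep(0, 4), volumeShape = 16)
#' rotationMatrix(g, 1)
#' @export
TTGeometry <- function(innerAngles, outerAngles = rep(0, length(innerAngles)),
                       volumeShape,
                       jOffsets = rep(0, length(innerAngles)),
                       kOffsets = rep(0, length(innerAngles)),
                       pDirection = c(1, 0, 0),
                       jDirection = c(0, 1, 0),
                       kDirection = c(0, 0, 1),
                       detectorDirectionOrigin = c(0, 0, 1),
                       detectorDirectionPositive90 = c(0, 1, 0),
                       innerAxis = c(0, 0, 1),
                       outerAxis = c(0, 1, 0),
                       voxelSize = 1, scanStep = 1) {
    if (length(volumeShape) == 1L) volumeShape <- rep(volumeShape, 3L)
    new("TTGeometry",
        pDirection = as.numeric(pDirection),
        jDirection = as.numeric(jDirection),
        kDirection = as.numeric(kDirection),
        detectorDirectionOrigin = as.numeric(detectorDirectionOrigin),
        detectorDirectionPositive90 = as.numeric(detectorDirectionPositive90),
        innerAxis = as.numeric(innerAxis),
        outerAxis = as.numeric(outerAxis),
        innerAngles = as.numeric(innerAngles),
        outerAngles = as.numeric(outerAngles),
        jOffsets = as.numeric(jOffsets),
        kOffsets = as.numeric(kOffsets),
        volumeShape = as.integer(volumeShape),
        voxelSize = as.numeric(voxelSize),
        scanStep = as.numeric(scanStep))
}

#' Construct a detector segmentation
#'
#' @param nSegments Number of evenly spaced segments C (ignored when
#'   \code{boundaries} is given).
#' @param coverage \code{"half"} (pi span, the SAXS convention relying on
#'   Friedel symmetry) or \code{"full"} (2*pi, WAXS).
#' @param boundaries Optional explicit strictly increasing C+1 azimuth
#'   boundaries (radians).
#' @param scatteringAngle Scattering angle 2-theta (radians); 0 selects the
#'   small-angle limit in which the probed directions lie in the detector
#'   plane.
#' @return A \linkS4class{DetectorSegments}.
#' @export
DetectorSegments <- function(nSegments = 8L, coverage = c("half", "full"),
                             boundaries = NULL, scatteringAngle = 0) {
    coverage <- match.arg(coverage)
    if (is.null(boundaries)) {
        span <- if (coverage == "full") 2 * pi else pi
        boundaries <- seq(0, span, length.out = nSegments + 1L)
    }
    new("DetectorSegments", boundaries = as.numeric(boundaries),
        coverage = coverage, scatteringAngle = as.numeric(scatteringAngle))
}

#' Rotation about an arbitrary unit axis (Rodrigues formula)
#' @noRd
.axis_rotation <- function(axis, angle) {
    n <- sqrt(sum(axis^2))
    if (abs(n - 1) > .unit_tol) stop("rotation axis must be unit-norm")
    u <- axis
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Goniometer rotation matrix of one projection
#'
#' Returns the full sample rotation at projection \code{s}: the outer tilt
#' carries the inner rotation stage, so R_s = R(beta_s, outer axis) *
#' R(alpha_s, inner axis).  Lab-frame vectors are brought into the sample
#' frame by multiplying with the transpose of this matrix.
#'
#' @param geometry A \linkS4class{TTGeometry}.
#' @param s Projection index (1-based).
#' @return Orthogonal 3 x 3 matrix with determinant +1.
#' @export
rotationMatrix <- function(geometry, s) {
    S <- length(geometry@innerAngles)
    if (s < 1L || s > S) stop(sprintf("projection index %d out of range 1..%d", s, S))
    .axis_rotation(geometry@outerAxis, geometry@outerAngles[s]) %*%
        .axis_rotation(geometry@innerAxis, geometry@innerAngles[s])
}

#' Scattering direction probed by a detector azimuth
#'
#' Gives the sample-frame unit scattering vector measured at azimuth
#' \code{phi} of the detector for projection \code{s}.  In the lab frame the
#' probed direction is cos(theta) (cos(phi) q0 + sin(phi) q90) +
#' \code{tiltSign} sin(theta) p, with theta half the scattering angle stored
#' in \code{segments}; the small-angle limit (2-theta = 0) reduces to the
#' in-plane direction.  The lab vector is rotated into the sample frame with
#' the transpose of \code{\link{rotationMatrix}}.
#'
#' @param geometry A \linkS4class{TTGeometry}.
#' @param segments A \linkS4class{DetectorSegments} (supplies 2-theta and the
#'   admissible azimuth range).
#' @param s Projection index (1-based).
#' @param phi Azimuth angle(s), radians, within the segment coverage.
#' @param tiltSign Sign of the out-of-plane (beam-direction) component; the
#'   default -1 tilts the scattering vector against the beam.
#' @return Matrix length(phi) x 3 of unit vectors (a single phi gives a
#'   3-vector).
#' @export
probedDirection <- function(geometry, segments, s, phi, tiltSign = -1) {
    b <- segments@boundaries
    if (any(phi < b[1L] - .unit_tol | phi > b[length(b)] + .unit_tol))
        stop("phi outside the declared detector coverage")
    theta <- segments@scatteringAngle / 2
    R <- rotationMatrix(geometry, s)
    qlab <- cos(theta) * (outer(cos(phi), geometry@detectorDirectionOrigin) +
                          outer(sin(phi), geometry@detectorDirectionPositive90)) +
        tiltSign * sin(theta) * matrix(geometry@pDirection, length(phi), 3,
                                       byrow = TRUE)
    out <- qlab %*% R  # (R^T q)^T = q^T R
    if (length(phi) == 1L) drop(out) else out
}

#' Sample-frame beam and scan axes for every projection
#'
#' @param geometry A \linkS4class{TTGeometry}.
#' @return List of S x 3 matrices \code{p}, \code{j}, \code{k}: the beam and
#'   raster axes rotated into the sample frame for each projection.
#' @export
beamBasis <- function(geometry) {
    S <- length(geometry@innerAngles)
    p <- j <- k <- matrix(0, S, 3)
    for (s in seq_len(S)) {
        Rt <- t(rotationMatrix(geometry, s))
        p[s, ] <- Rt %*% geometry@pDirection
        j[s, ] <- Rt %*% geometry@jDirection
        k[s, ] <- Rt %*% geometry@kDirection
    }
    list(p = p, j = j, k = k)
}
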