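#' @import methods
#' @importFrom stats fft optim rnorm runif rpois sd
NULL

.unit_tol <- 1e-9

.is_unit <- function(v, tol = .unit_tol) {
    is.numeric(v) && length(v) == 3L && all(is.finite(v)) &&
        abs(sqrt(sum(v^2)) - 1) < tol
}

#' Experimental geometry of a tensor-tomography acquisition
#'
#' Holds the laboratory-frame unit vectors defining the beam, raster-scan and
#' detector axes, the two goniometer rotation axes, and the per-projection
#' rotation angles and alignment offsets.  The laboratory frame coincides with
#' the sample-fixed voxel frame when both goniometer angles are zero.
#'
#' @slot pDirection Beam (projection) direction, unit 3-vector.
#' @slot jDirection,kDirection Orthogonal raster-scan axes, unit 3-vectors.
#' @slot detectorDirectionOrigin,detectorDirectionPositive90 Unit 3-vectors
#'   spanning the detector plane: the azimuth origin and the +90 degree
#'   direction of the azimuthal integration.
#' @slot innerAxis,outerAxis Goniometer rotation axes (inner "rotation" stage
#'   and outer "tilt" stage), unit 3-vectors.
#' @slot innerAngles,outerAngles Per-projection rotation angles (radians),
#'   length S each.
#' @slot jOffsets,kOffsets Per-projection alignment offsets caused by parasitic
#'   sample-stage movement, in units of the scan step, length S each.
#' @slot volumeShape Integer 3-vector, the reconstruction voxel grid.
#' @slot voxelSize,scanStep Voxel edge length a and raster-scan step b (same
#'   length unit); typically a = b = 1.
#' @export
setClass("TTGeometry", representation(
    pDirection = "numeric",
    jDirection = "numeric",
    kDirection = "numeric",
    detectorDirectionOrigin = "numeric",
    detectorDirectionPositive90 = "numeric",
    innerAxis = "numeric",
    outerAxis = "numeric",
    innerAngles = "numeric",
    outerAngles = "numeric",
    jOffsets = "numeric",
    kOffsets = "numeric",
    volumeShape = "integer",
    voxelSize = "numeric",
    scanStep = "numeric"
))

setValidity("TTGeometry", function(object) {
    msg <- character()
    for (nm in c("pDirection", "jDirection", "kDirection",
                 "detectorDirectionOrigin", "detectorDirectionPositive90",
                 "innerAxis", "outerAxis")) {
        if (!.is_unit(slot(object, nm)))
            msg <- c(msg, sprintf("'%s' must be a unit 3-vector (tol 1e-9)", nm))
    }
    if (.is_unit(object@detectorDirectionOrigin) &&
        .is_unit(object@detectorDirectionPositive90) &&
        abs(sum(object@detectorDirectionOrigin *
                object@detectorDirectionPositive90)) > .unit_tol)
        msg <- c(msg, "detector directions must be orthogonal (tol 1e-9)")
    if (.is_unit(object@jDirection) && .is_unit(object@kDirection) &&
        abs(sum(object@jDirection * object@kDirection)) > .unit_tol)
        msg <- c(msg, "jDirection and kDirection must be orthogonal (tol 1e-9)")
    s <- length(object@innerAngles)
    for (nm in c("outerAngles", "jOffsets", "kOffsets"))
        if (length(slot(object, nm)) != s)
            msg <- c(msg, sprintf("'%s' must have length %d (= length(innerAngles))",
                                  nm, s))
    if (length(object@volumeShape) != 3L || any(object@volumeShape < 1L))
        msg <- c(msg, "volumeShape must be 3 positive integers")
    if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
        msg <- c(msg, "voxelSize must be a positive scalar")
    if (length(object@scanStep) != 1L || object@scanStep <= 0)
        msg <- c(msg, "scanStep must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' Azimuthal detector segmentation
#'
#' Describes how the detector has been azimuthally regrouped: C segments with
#' boundaries on either the full circle (WAXS) or a half circle (SAXS, relying
#' on Friedel symmetry), plus the scattering angle 2-theta of the q shell.
#'
#' @slot boundaries Strictly increasing azimuth boundaries, length C+1
#'   (radians); span must equal the declared coverage.
#' @slot coverage Either \code{"full"} (2*pi span) or \code{"half"} (pi span).
#' @slot scatteringAngle The scattering angle 2-theta in radians (0 in the
#'   small-angle limit).
#' @export
setClass("DetectorSegments", representation(
    boundaries = "numeric",
    coverage = "character",
    scatteringAngle = "numeric"
))

setValidity("DetectorSegments", function(object) {
    msg <- character()
    b <- object@boundaries
    if (length(b) < 2L || any(diff(b) <= 0))
        msg <- c(msg, "boundaries must be strictly increasing with length >= 2")
    if (!object@coverage %in% c("full", "half"))
        msg <- c(msg, "coverage must be 'full' or 'half'")
    span <- if (identical(object@coverage, "full")) 2 * pi else pi
    if (length(b) >= 2L && abs((b[length(b)] - b[1L]) - span) > .unit_tol)
        msg <- c(msg, sprintf("boundary span must equal %s (tol 1e-9)",
                              if (span > pi) "2*pi" else "pi"))
    th <- object@scatteringAngle
    if (length(th) != 1L || th < 0 || th >= pi)
        msg <- c(msg, "scatteringAngle (2-theta) must lie in [0, pi)")
    if (length(msg)) msg else TRUE
})

#' Measured projection stack
#'
#' Container for the azimuthally regrouped measurements of one q shell: the
#' 4D intensity array indexed [projection s, scan row j, scan column k,
#' detector segment c], the transmission (diode) images, per-measurement
#' weights (0 masks a measurement), and the geometry and detector segmentation
#' they were acquired with.
#'
#' @slot data Nonnegative array [S, J, K, C].
#' @slot diode Positive array [S, J, K] of transmitted intensities.
#' @slot weights Nonnegative array [S, J, K, C]; 0 excludes a measurement.
#' @slot geometry A \linkS4class{TTGeometry} with per-projection angles/offsets
#'   of length S.
#' @slot segments A \linkS4class{DetectorSegments} with C segments.
#' @export
setClass("ProjectionStack", representation(
    data = "array",
    diode = "array",
    weights = "array",
    geometry = "TTGeometry",
    segments = "DetectorSegments"
))

setValidity("ProjectionStack", function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 4L)
        return("data must be a 4D array [S, J, K, C]")
    if (!identical(dim(object@weights), d))
        msg <- c(msg, "weights must have the same shape as data")
    if (!identical(dim(object@diode), d[1:3]))
        msg <- c(msg, "diode must have shape [S, J, K]")
    if (length(object@geometry@innerAngles) != d[1L])
        msg <- c(msg, "geometry must carry one angle/offset set per projection")
    if (length(object@segments@boundaries) != d[4L] + 1L)
        msg <- c(msg, "segments must define C = dim(data)[4] segments")
    if (any(object@weights < 0))
        msg <- c(msg, "weights must be nonnegative")
    if (d[1L] < 1L)
        msg <- c(msg, "at least one projection required")
    if (length(msg)) msg else TRUE
})

#' Spherical basis sets for reciprocal-space-map expansion
#'
#' \code{BasisSet} is the virtual parent of the three linear basis-set types
#' used to expand the per-voxel 2D reciprocal-space map: real spherical
#' harmonics (\linkS4class{SphericalHarmonicsBasis}), nearest-neighbor
#' indicator functions on an orientation grid
#' (\linkS4class{NearestNeighborBasis}), and spherical Gaussian kernels
#' (\linkS4class{GaussianKernelBasis}).  All honor Friedel symmetry
#' W(q) = W(-q) when their \code{friedel} flag is set.
#'
#' @slot friedel Logical; if TRUE the basis is antipodally symmetric.
#' @aliases BasisSet
#' @export
setClass("BasisSet", representation("VIRTUAL", friedel = "logical"))

#' @rdname BasisSet-class
#' @slot lMax Band limit of the expansion; with \code{friedel = TRUE} only
#'   even degrees are used (the SAXS default).
#' @export
setClass("SphericalHarmonicsBasis", contains = "BasisSet",
         representation(lMax = "integer"))

setValidity("SphericalHarmonicsBasis", function(object) {
    if (length(object@lMax) != 1L || object@lMax < 0L)
        return("lMax must be a single nonnegative integer")
    if (object@friedel && object@lMax %% 2L != 0L)
        return("with Friedel symmetry lMax must be even")
    TRUE
})

#' @rdname BasisSet-class
#' @slot directions M x 3 matrix of unit orientation-grid vectors.
#' @export
setClass("NearestNeighborBasis", contains = "BasisSet",
         representation(directions = "matrix"))

.check_grid <- function(directions) {
    if (!is.numeric(directions) || ncol(directions) != 3L || nrow(directions) < 1L)
        return("directions must be an M x 3 numeric matrix")
    n <- sqrt(rowSums(directions^2))
    if (any(abs(n - 1) > .unit_tol))
        return("grid directions must be unit vectors (tol 1e-9)")
    TRUE
}

setValidity("NearestNeighborBasis", function(object) .check_grid(object@directions))

#' @rdname BasisSet-class
#' @slot sigma Kernel width (radians, geodesic standard deviation).
#' @export
setClass("GaussianKernelBasis", contains = "BasisSet",
         representation(directions = "matrix", sigma = "numeric"))

setValidity("GaussianKernelBasis", function(object) {
    ok <- .check_grid(object@directions)
    if (!isTRUE(ok)) return(ok)
    if (length(object@sigma) != 1L || object@sigma <= 0)
        return("sigma must be a positive scalar")
    TRUE
})

#' Voxel field of basis-set coefficients
#'
#' The reconstruction unknown: one coefficient vector of length N per voxel,
#' stored as a 4D array [X, Y, Z, N] together with the basis set that gives
#' the coefficients meaning.
#'
#' @slot coefficients Array [X, Y, Z, N].
#' @slot basis The \linkS4class{BasisSet} the coefficients refer to.
#' @export
setClass("TensorField", representation(
    coefficients = "array",
    basis = "BasisSet"
))

setValidity("TensorField", function(object) {
    d <- dim(object@coefficients)
    if (length(d) != 4L)
        return("coefficients must be a 4D array [X, Y, Z, N]")
    if (d[4L] != coefficientCount(object@basis))
        return(sprintf("coefficient channels (%d) must match the basis set (%d)",
                       d[4L], coefficientCount(object@basis)))
    TRUE
})

#' Reconstruction result container
#'
#' Bundles the optimized coefficient field with derived per-voxel maps (mean
#' intensity, second-moment tensor eigensystem, fractional anisotropy, main
#' orientation) and provenance (pipeline name, loss trace, configuration).
#'
#' @slot field A \linkS4class{TensorField}.
#' @slot maps Named list of derived maps (possibly empty); see
#'   \code{\link{deriveMaps}}.
#' @slot provenance Named list: pipeline, lossTrace, config.
#' @export
setClass("TTReconstruction", representation(
    field = "TensorField",
    maps = "list",
    provenance = "list"
))

setMethod("show", "TTGeometry", function(object) {
    cat("TTGeometry:", length(object@innerAngles), "projections, volume",
        paste(object@volumeShape, collapse = " x "),
        sprintf("(a = %g, b = %g)\n", object@voxelSize, object@scanStep))
    cat("  beam:", paste(signif(object@pDirection, 3), collapse = " "),
        "| inner axis:", paste(signif(object@innerAxis, 3), collapse = " "),
        "| outer axis:", paste(signif(object@outerAxis, 3), collapse = " "), "\n")
})

setMethod("show", "DetectorSegments", function(object) {
    cat(sprintf("DetectorSegments: %d segments, %s-circle coverage, 2theta = %g rad\n",
                length(object@boundaries) - 1L, object@coverage,
                object@scatteringAngle))
})

setMethod("show", "ProjectionStack", function(object) {
    d <- dim(object@data)
    cat(sprintf("ProjectionStack: S = %d projections of %d x %d scan points, C = %d segments\n",
                d[1], d[2], d[3], d[4]))
    cat(sprintf("  masked measurements: %d of %d\n",
                sum(object@weights == 0), length(object@weights)))
})

setMethod("show", "TensorField", function(object) {
    d <- dim(object@coefficients)
    cat(sprintf("TensorField: %d x %d x %d voxels, N = %d coefficients (%s)\n",
                d[1], d[2], d[3], d[4], class(object@basis)))
})

setMethod("show", "TTReconstruction", function(object) {
    cat("TTReconstruction from pipeline:",
        if (!is.null(object@provenance$pipeline)) object@provenance$pipeline
        else "<unknown>", "\n")
    show(object@field)
    if (length(object@maps))
        cat("  derived maps:", paste(names(object@maps), collapse = ", "), "\n")
})
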