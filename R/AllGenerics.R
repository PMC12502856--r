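#' Number of coefficients of a basis set
#'
#' For spherical harmonics this is the number of (l, m) pairs up to the band
#' limit (even degrees only under Friedel symmetry); for grid-based bases it
#' is the number of grid directions.
#'
#' @param basis A \linkS4class{BasisSet}.
#' @return Integer N.
#' @export
setGeneric("coefficientCount", function(basis) standardGeneric("coefficientCount"))

#' Evaluate basis functions at unit directions
#'
#' @param basis A \linkS4class{BasisSet}.
#' @param directions Numeric n x 3 matrix of unit vectors (a single vector is
#'   accepted).
#' @return Numeric n x N matrix of basis-function values.
#' @export
setGeneric("evaluateBasis", function(basis, directions) standardGeneric("evaluateBasis"))

#' Detector-segment response matrix of a basis set
#'
#' Computes B[s, c, i]: the average of basis function i over the azimuthal arc
#' of detector segment c, probed in the sample frame at goniometer setting s.
#' This is the reciprocal-space half of the tensor-tomography forward model.
#'
#' @param basis A \linkS4class{BasisSet}.
#' @param geometry A \linkS4class{TTGeometry}.
#' @param segments A \linkS4class{DetectorSegments}.
#' @param method \code{"adaptive"} for adaptive Newton-Cotes quadrature (to
#'   absolute tolerance \code{tol}) or \code{"midpoint"} to evaluate at the
#'   central angle of each segment.
#' @param tol Absolute quadrature tolerance (adaptive mode).
#' @return Numeric array [S, C, N].
#' @export
setGeneric("segmentIntegrals",
           function(basis, geometry, segments, method = c("adaptive", "midpoint"),
                    tol = 1e-6)
               standardGeneric("segmentIntegrals"))

# Accessors

#' @rdname accessors
#' @export
setGeneric("projectionData", function(x) standardGeneric("projectionData"))
#' @rdname accessors
#' @export
setGeneric("diodeData", function(x) standardGeneric("diodeData"))
#' @rdname accessors
#' @export
setGeneric("measurementWeights", function(x) standardGeneric("measurementWeights"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("geometry<-", function(x, value) standardGeneric("geometry<-"))
#' @rdname accessors
#' @export
setGeneric("detectorSegments", function(x) standardGeneric("detectorSegments"))
#' @rdname accessors
#' @export
setGeneric("coefficients4D", function(x) standardGeneric("coefficients4D"))
#' @rdname accessors
#' @export
setGeneric("basisSet", function(x) standardGeneric("basisSet"))
#' @rdname accessors
#' @export
setGeneric("derivedMaps", function(x) standardGeneric("derivedMaps"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Accessors for tensor-tomography containers
#'
#' Read-only views of the slots of \linkS4class{ProjectionStack},
#' \linkS4class{TensorField} and \linkS4class{TTReconstruction};
#' \code{geometry<-} replaces the geometry of a stack (e.g. to override
#' offsets after alignment).
#'
#' @param x A container object.
#' @param value Replacement value.
#' @name accessors
NULL
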