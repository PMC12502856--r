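# HDF5 projection-stack format: top-level geometry vectors (p_direction_0,
# j_direction_0, k_direction_0, detector_direction_origin,
# detector_direction_positive_90, inner_axis, outer_axis), volume_shape,
# detector_angles, and a "projections" group of consecutively numbered
# subgroups 0, 1, ... each holding data [J, K, C], diode [J, K],
# inner_angle, outer_angle, j_offset, k_offset and weights.
# Dialect notes: all angles are radians; detector_angles holds the C+1
# segment-boundary azimuths (a file carrying C segment centers is accepted
# with centers = TRUE, boundaries then reconstructed assuming even spacing);
# floats are written as 64-bit and read back bit-exactly.

.geom_fields <- c(p_direction_0 = "pDirection", j_direction_0 = "jDirection",
                  k_direction_0 = "kDirection",
                  detector_direction_origin = "detectorDirectionOrigin",
                  detector_direction_positive_90 = "detectorDirectionPositive90",
                  inner_axis = "innerAxis", outer_axis = "outerAxis")

#' Write a projection stack to an HDF5 file
#'
#' @param stack A \linkS4class{ProjectionStack}.
#' @param path Output file path (overwritten if present).
#' @param degrees Write angles in degrees instead of radians.
#' @return Invisibly, \code{path}.
#' @seealso \code{\link{loadProjectionStack}}
#' @export
saveProjectionStack <- function(stack, path, degrees = FALSE) {
    validObject(stack)
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    g <- stack@geometry
    conv <- if (degrees) 180 / pi else 1
    for (nm in names(.geom_fields))
        rhdf5::h5write(slot(g, .geom_fields[[nm]]), path, nm)
    rhdf5::h5write(as.integer(g@volumeShape), path, "volume_shape")
    rhdf5::h5write(stack@segments@boundaries * conv, path, "detector_angles")
    rhdf5::h5write(stack@segments@coverage, path, "detector_coverage")
    rhdf5::h5write(stack@segments@scatteringAngle * conv, path,
                   "scattering_angle")
    rhdf5::h5createGroup(path, "projections")
    S <- dim(stack@data)[1L]
    for (s in seq_len(S)) {
        grp <- sprintf("projections/%d", s - 1L)
        rhdf5::h5createGroup(path, grp)
        rhdf5::h5write(stack@data[s, , , ], path, file.path(grp, "data"))
        rhdf5::h5write(stack@diode[s, , ], path, file.path(grp, "diode"))
        rhdf5::h5write(stack@weights[s, , , ], path, file.path(grp, "weights"))
        rhdf5::h5write(g@innerAngles[s] * conv, path, file.path(grp, "inner_angle"))
        rhdf5::h5write(g@outerAngles[s] * conv, path, file.path(grp, "outer_angle"))
        rhdf5::h5write(g@jOffsets[s], path, file.path(grp, "j_offset"))
        rhdf5::h5write(g@kOffsets[s], path, file.path(grp, "k_offset"))
    }
    invisible(path)
}

.h5_has <- function(contents, path)
    any(contents == path)

#' Load a projection stack from an HDF5 file
#'
#' Assembles the per-projection datasets in index order 0..S-1 (an error
#' names the first missing index if the numbering has gaps), checks shape
#' consistency, and fills missing optional datasets (weights, diode) with
#' ones.  Geometry fields absent from the file must be supplied via
#' \code{defaults}; fields present in the file win unless listed in
#' \code{override}.
#'
#' @param path HDF5 file path.
#' @param defaults Named list of \linkS4class{TTGeometry} slot values used
#'   for fields absent from the file (e.g. \code{list(innerAxis = c(0, 0,
#'   1))}).
#' @param override Named list of slot values that replace whatever the file
#'   contains (the post-load override mechanism).
#' @param degrees Angles in the file are degrees.
#' @param centers \code{detector_angles} holds C segment centers rather than
#'   C+1 boundaries; boundaries are reconstructed assuming even spacing.
#' @return A \linkS4class{ProjectionStack} (carrying its geometry and
#'   detector segmentation).
#' @export
loadProjectionStack <- function(path, defaults = list(), override = list(),
                                degrees = FALSE, centers = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    ls <- rhdf5::h5ls(path)
    contents <- file.path(ls$group, ls$name)
    contents <- sub("^//", "/", contents)
    conv <- if (degrees) pi / 180 else 1

    if (!.h5_has(contents, "/projections"))
        stop("format error: missing group 'projections'")
    pnames <- ls$name[ls$group == "/projections"]
    if (!length(pnames)) stop("format error: 'projections' group is empty")
    S <- length(pnames)
    wanted <- as.character(seq_len(S) - 1L)
    missing <- setdiff(wanted, pnames)
    if (length(missing))
        stop("format error: missing projection key \"", missing[1L], "\"")

    read1 <- function(grp, nm) rhdf5::h5read(path, file.path(grp, nm))
    data <- diode <- weights <- NULL
    inner <- outer <- joff <- koff <- numeric(S)
    for (s in seq_len(S)) {
        grp <- sprintf("/projections/%d", s - 1L)
        gset <- contents[startsWith(contents, paste0(grp, "/"))]
        if (!file.path(grp, "data") %in% gset)
            stop("format error: missing mandatory dataset ",
                 file.path(grp, "data"))
        d1 <- read1(grp, "data")
        if (length(dim(d1)) != 3L)
            stop("validation error: projection data must be [J, K, C]")
        if (is.null(data)) {
            data <- array(0, c(S, dim(d1)))
            diode <- array(1, c(S, dim(d1)[1:2]))
            weights <- array(1, c(S, dim(d1)))
        }
        if (!identical(dim(d1), dim(data)[-1L]))
            stop(sprintf("validation error: projection %d has shape (%s), expected (%s)",
                         s - 1L, paste(dim(d1), collapse = ","),
                         paste(dim(data)[-1L], collapse = ",")))
        data[s, , , ] <- d1
        if (file.path(grp, "diode") %in% gset) diode[s, , ] <- read1(grp, "diode")
        if (file.path(grp, "weights") %in% gset) {
            w1 <- read1(grp, "weights")
            if (!identical(dim(w1), dim(d1)))
                stop("validation error: weights shape differs from data")
            weights[s, , , ] <- w1
        }
        inner[s] <- as.numeric(read1(grp, "inner_angle")) * conv
        outer[s] <- as.numeric(read1(grp, "outer_angle")) * conv
        joff[s] <- as.numeric(read1(grp, "j_offset"))
        koff[s] <- as.numeric(read1(grp, "k_offset"))
    }

    geomArgs <- list(innerAngles = inner, outerAngles = outer,
                     jOffsets = joff, kOffsets = koff)
    for (nm in names(.geom_fields)) {
        slotName <- .geom_fields[[nm]]
        if (.h5_has(contents, paste0("/", nm)))
            geomArgs[[slotName]] <- as.numeric(rhdf5::h5read(path, nm))
        else if (!is.null(defaults[[slotName]]))
            geomArgs[[slotName]] <- defaults[[slotName]]
    }
    if (.h5_has(contents, "/volume_shape"))
        geomArgs$volumeShape <- as.integer(rhdf5::h5read(path, "volume_shape"))
    else if (!is.null(defaults$volumeShape))
        geomArgs$volumeShape <- defaults$volumeShape
    else stop("format error: missing dataset volume_shape (and no default given)")
    for (nm in names(override)) geomArgs[[nm]] <- override[[nm]]
    geom <- do.call(TTGeometry, geomArgs)

    C <- dim(data)[4L]
    coverage <- if (.h5_has(contents, "/detector_coverage"))
        as.character(rhdf5::h5read(path, "detector_coverage")) else "half"
    twoTheta <- if (.h5_has(contents, "/scattering_angle"))
        as.numeric(rhdf5::h5read(path, "scattering_angle")) * conv else 0
    if (.h5_has(contents, "/detector_angles")) {
        ang <- as.numeric(rhdf5::h5read(path, "detector_angles")) * conv
        if (centers || length(ang) == C) {
            if (length(ang) != C)
                stop("format error: expected ", C, " segment centers")
            half <- if (length(ang) > 1L) diff(ang)[1L] / 2
                    else (if (coverage == "full") pi else pi / 2)
            ang <- c(ang - half, ang[length(ang)] + half)
        }
        if (length(ang) != C + 1L)
            stop("format error: detector_angles must hold C+1 boundaries or C centers")
        segs <- new("DetectorSegments", boundaries = ang, coverage = coverage,
                    scatteringAngle = twoTheta)
    } else {
        segs <- DetectorSegments(nSegments = C, coverage = coverage,
                                 scatteringAngle = twoTheta)
    }

    new("ProjectionStack", data = data, diode = diode, weights = weights,
        geometry = geom, segments = segs)
}

#' Normalize measured intensities by the transmitted intensity
#'
#' Divides every detector-segment intensity by the diode (transmission)
#' value of its scan point, the standard absorption correction.  Scan points
#' with non-positive diode readings are masked: their weights are set to 0
#' and their data left untouched (never used downstream).
#'
#' @param stack A \linkS4class{ProjectionStack}.
#' @return A new \linkS4class{ProjectionStack} with normalized data and with
#'   weights zeroed where the transmission was degenerate (those data values
#'   are left as-is but are never used downstream).
#' @export
normalizeByTransmission <- function(stack) {
    d <- dim(stack@data)
    ok <- stack@diode > 0
    scale <- array(1, d[1:3])
    scale[ok] <- 1 / stack@diode[ok]
    data <- stack@data * array(scale, d)   # [S,J,K] recycled over C
    weights <- stack@weights * array(as.numeric(ok), d)
    new("ProjectionStack", data = data, diode = stack@diode,
        weights = weights, geometry = stack@geometry,
        segments = stack@segments)
}

#' Save a reconstruction (with derived maps) to HDF5
#'
#' Writes the coefficient array, a self-describing basis descriptor, any
#' derived maps, and provenance attributes.  A reconstruction without
#' derived maps is written with \code{has_derived_maps = 0}.
#'
#' @param rec A \linkS4class{TTReconstruction}.
#' @param path Output file path (overwritten).
#' @return Invisibly, \code{path}.
#' @export
saveReconstruction <- function(rec, path) {
    validObject(rec@field)
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    rhdf5::h5write(rec@field@coefficients, path, "coefficients")
    b <- rec@field@basis
    rhdf5::h5createGroup(path, "basis")
    kind <- switch(class(b)[1L],
                   SphericalHarmonicsBasis = "spherical_harmonics",
                   NearestNeighborBasis = "nearest_neighbor",
                   GaussianKernelBasis = "gaussian_kernel",
                   stop("unknown basis class"))
    rhdf5::h5write(kind, path, "basis/kind")
    rhdf5::h5write(as.integer(b@friedel), path, "basis/friedel")
    if (is(b, "SphericalHarmonicsBasis"))
        rhdf5::h5write(b@lMax, path, "basis/l_max")
    else {
        rhdf5::h5write(b@directions, path, "basis/directions")
        if (is(b, "GaussianKernelBasis"))
            rhdf5::h5write(b@sigma, path, "basis/sigma")
    }
    maps <- rec@maps
    rhdf5::h5write(as.integer(length(maps) > 0), path, "has_derived_maps")
    if (length(maps)) {
        for (nm in setdiff(names(maps), "orientation_mode"))
            rhdf5::h5write(maps[[nm]], path, nm)
        if (!is.null(maps$orientation_mode))
            rhdf5::h5write(maps$orientation_mode, path, "orientation_mode")
    }
    pv <- rec@provenance
    if (!is.null(pv$pipeline)) rhdf5::h5write(pv$pipeline, path, "pipeline")
    if (!is.null(pv$lossTrace) && is.numeric(pv$lossTrace))
        rhdf5::h5write(pv$lossTrace, path, "loss_trace")
    invisible(path)
}

#' Load a reconstruction written by \code{\link{saveReconstruction}}
#'
#' @param path HDF5 file path.
#' @return A \linkS4class{TTReconstruction}.
#' @export
loadReconstruction <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    ls <- rhdf5::h5ls(path)
    contents <- sub("^//", "/", file.path(ls$group, ls$name))
    kind <- as.character(rhdf5::h5read(path, "basis/kind"))
    friedel <- as.logical(rhdf5::h5read(path, "basis/friedel"))
    basis <- switch(kind,
        spherical_harmonics = SphericalHarmonicsBasis(
            as.integer(rhdf5::h5read(path, "basis/l_max")), friedel),
        nearest_neighbor = NearestNeighborBasis(
            rhdf5::h5read(path, "basis/directions"), friedel),
        gaussian_kernel = GaussianKernelBasis(
            rhdf5::h5read(path, "basis/directions"),
            as.numeric(rhdf5::h5read(path, "basis/sigma")), friedel),
        stop("unknown basis kind: ", kind))
    co <- rhdf5::h5read(path, "coefficients")
    field <- new("TensorField", coefficients = co, basis = basis)
    maps <- list()
    if (.h5_has(contents, "/has_derived_maps") &&
        as.integer(rhdf5::h5read(path, "has_derived_maps")) > 0L) {
        for (nm in c("mean_intensity", "second_moment", "eigenvalues",
                     "eigenvectors", "fractional_anisotropy",
                     "main_orientation", "relative_anisotropy"))
            if (.h5_has(contents, paste0("/", nm)))
                maps[[nm]] <- rhdf5::h5read(path, nm)
        if (.h5_has(contents, "/orientation_mode"))
            maps$orientation_mode <- as.character(rhdf5::h5read(path, "orientation_mode"))
    }
    pv <- list()
    if (.h5_has(contents, "/pipeline"))
        pv$pipeline <- as.character(rhdf5::h5read(path, "pipeline"))
    if (.h5_has(contents, "/loss_trace"))
        pv$lossTrace <- as.numeric(rhdf5::h5read(path, "loss_trace"))
    new("TTReconstruction", field = field, maps = maps, provenance = pv)
}

# ---- accessors --------------------------------------------------------------

#' @rdname accessors
setMethod("projectionData", "ProjectionStack", function(x) x@data)
#' @rdname accessors
setMethod("diodeData", "ProjectionStack", function(x) x@diode)
#' @rdname accessors
setMethod("measurementWeights", "ProjectionStack", function(x) x@weights)
#' @rdname accessors
setMethod("geometry", "ProjectionStack", function(x) x@geometry)
#' @rdname accessors
setMethod("detectorSegments", "ProjectionStack", function(x) x@segments)
#' @rdname accessors
setMethod("geometry<-", "ProjectionStack", function(x, value) {
    x@geometry <- value
    validObject(x)
    x
})
#' @rdname accessors
setMethod("coefficients4D", "TensorField", function(x) x@coefficients)
#' @rdname accessors
setMethod("basisSet", "TensorField", function(x) x@basis)
#' @rdname accessors
setMethod("coefficients4D", "TTReconstruction", function(x) x@field@coefficients)
#' @rdname accessors
setMethod("basisSet", "TTReconstruction", function(x) x@field@basis)
#' @rdname accessors
setMethod("derivedMaps", "TTReconstruction", function(x) x@maps)
#' @rdname accessors
setMethod("provenance", "TTReconstruction", function(x) x@provenance)
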