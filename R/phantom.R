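# Synthetic tensor-tomography experiments with known ground truth: a voxel
# support carrying a smoothly varying orientation field, per-voxel
# reciprocal-space maps built from an isotropic term plus an oriented
# (polar-cap or equatorial-band) component, expanded in the requested basis
# and forward-projected into the measured-data format.

#' Crossed rotation/tilt angle scheme
#'
#' Full inner rotations crossed with a few outer tilts, mimicking a typical
#' rotation-plus-tilt tensor-tomography acquisition.
#'
#' @param nInner Number of uniform inner-rotation steps over [0, 2*pi).
#' @param tilts Outer tilt angles (radians).
#' @return List with vectors \code{inner} and \code{outer} of length
#'   \code{nInner * length(tilts)}.
#' @export
ttAngleScheme <- function(nInner = 20L, tilts = c(0, 20, 40) * pi / 180) {
    inner <- rep(2 * pi * (seq_len(nInner) - 1L) / nInner, times = length(tilts))
    outer <- rep(tilts, each = nInner)
    list(inner = inner, outer = outer)
}

#' Generate a phantom coefficient field with known orientations
#'
#' Builds a voxel support (a centered sphere, or concentric spherical
#' shells) with a smoothly varying per-voxel orientation axis u, gives every
#' support voxel the reciprocal-space map
#' \code{W(q) = (1 - anisotropy) + anisotropy * g(q . u)} with g either a
#' Gaussian equatorial band (scattering perpendicular to u, the fiber
#' archetype) or Gaussian polar caps (scattering along u), and expands W in
#' the requested basis by weighted least squares on a sphere-quadrature mesh
#' (an orthonormal projection for spherical harmonics).
#'
#' @param volumeShape Voxel grid (scalar = cube).
#' @param texture \code{"uniaxial_fiber"} (smoothly bending axis field),
#'   \code{"isotropic"} (no oriented component) or
#'   \code{"concentric_shells"} (radial axis field on two shells).
#' @param basis \linkS4class{BasisSet} used for the ground-truth expansion.
#' @param anisotropy Oriented fraction in [0, 1]; 0 gives FA = 0 everywhere.
#' @param pattern \code{"equatorial"} band or \code{"polar"} caps; defaults
#'   to equatorial for fibers and polar for shells.
#' @param bandWidth Gaussian width of the oriented component (in q . u).
#' @param quadratureNodes Mesh size for the basis projection.
#' @return List with \code{field} (\linkS4class{TensorField}),
#'   \code{orientation} (array [X, Y, Z, 3] of unit axes, NA outside the
#'   support) and \code{support} (logical array).
#' @export
makePhantom <- function(volumeShape = 16L,
                        texture = c("uniaxial_fiber", "isotropic",
                                    "concentric_shells"),
                        basis = SphericalHarmonicsBasis(4L),
                        anisotropy = 0.8,
                        pattern = NULL,
                        bandWidth = 0.35,
                        quadratureNodes = 800L) {
    texture <- match.arg(texture)
    if (anisotropy < 0 || anisotropy > 1) stop("anisotropy must lie in [0, 1]")
    if (length(volumeShape) == 1L) volumeShape <- rep(volumeShape, 3L)
    vs <- as.integer(volumeShape)
    if (is.null(pattern))
        pattern <- if (texture == "concentric_shells") "polar" else "equatorial"
    pattern <- match.arg(pattern, c("equatorial", "polar"))

    # normalized voxel-center coordinates in [-0.5, 0.5]
    cx <- (seq_len(vs[1L]) - (vs[1L] + 1) / 2) / vs[1L]
    cy <- (seq_len(vs[2L]) - (vs[2L] + 1) / 2) / vs[2L]
    cz <- (seq_len(vs[3L]) - (vs[3L] + 1) / 2) / vs[3L]
    G <- expand.grid(x = cx, y = cy, z = cz)
    r <- sqrt(G$x^2 + G$y^2 + G$z^2)
    support <- switch(texture,
        uniaxial_fiber = r <= 0.42,
        isotropic = r <= 0.42,
        concentric_shells = (r <= 0.42 & r > 0.30) | (r <= 0.20 & r > 0.08))

    nv <- nrow(G)
    U <- matrix(NA_real_, nv, 3)
    if (texture == "concentric_shells") {
        rr <- pmax(r, 1e-6)
        U <- cbind(G$x, G$y, G$z) / rr
    } else {
        # gently bending axis field around +z
        U <- cbind(0.3 * sin(2 * pi * G$y), 0.3 * cos(2 * pi * G$x),
                   rep(1, nv))
        U <- U / sqrt(rowSums(U^2))
    }

    quad <- sphereQuadrature(quadratureNodes)
    A <- evaluateBasis(basis, quad$points)
    Aw <- A * quad$weights
    M <- crossprod(A, Aw)

    aniso <- if (texture == "isotropic") 0 else anisotropy
    idx <- which(support)
    tmat <- quad$points %*% t(U[idx, , drop = FALSE])   # mesh x nsupport
    g <- if (pattern == "equatorial") exp(-tmat^2 / (2 * bandWidth^2))
         else exp(-(1 - tmat^2) / (2 * bandWidth^2))
    W <- (1 - aniso) + aniso * g
    co <- matrix(0, nv, coefficientCount(basis))
    co[idx, ] <- t(solve(M, crossprod(Aw, W)))
    field <- new("TensorField",
                 coefficients = array(co, c(vs, coefficientCount(basis))),
                 basis = basis)
    O <- array(NA_real_, c(nv, 3L))
    O[idx, ] <- U[idx, ]
    list(field = field,
         orientation = array(O, c(vs, 3L)),
         support = array(support, vs))
}

#' Simulate a tensor-tomography experiment from a coefficient field
#'
#' Runs the full forward model (segment response applied to John-transform
#' projections), optionally injecting per-projection alignment shifts (as
#' ray-origin offsets), measurement noise, and a Beer-Lambert transmission
#' signal computed from the field's mean-intensity map as a density proxy.
#' The returned stack records zero offsets: the injected shifts are what an
#' alignment procedure should recover.
#'
#' @param field A \linkS4class{TensorField} (ground truth).
#' @param geometry A \linkS4class{TTGeometry} (its offsets are ignored; the
#'   injected \code{shifts} are used for generation).
#' @param segments A \linkS4class{DetectorSegments}.
#' @param noise \code{"none"}, \code{"gaussian"} (sd = \code{noiseLevel}
#'   times the mean model intensity) or \code{"poisson"} (counts scaled by
#'   \code{noiseLevel}, i.e. larger = less noisy).
#' @param noiseLevel Noise parameter, see \code{noise}.
#' @param shifts Optional S x 2 matrix of injected (Delta-j, Delta-k) offsets
#'   in scan-step units.
#' @param J,K Scan dimensions (default transverse volume dimensions).
#' @param seed Seed fixing all randomness.
#' @param transmission Scale of the attenuation proxy: maximum optical depth
#'   along any ray (0 disables, diode = 1).
#' @return List with \code{stack} (a \linkS4class{ProjectionStack} whose
#'   recorded offsets are zero), \code{shifts} (the injected S x 2 matrix)
#'   and \code{model} (the noiseless data array).
#' @export
simulateExperiment <- function(field, geometry, segments,
                               noise = c("none", "gaussian", "poisson"),
                               noiseLevel = 0.05, shifts = NULL,
                               J = NULL, K = NULL, seed = 1L,
                               transmission = 1) {
    noise <- match.arg(noise)
    S <- length(geometry@innerAngles)
    if (is.null(shifts)) shifts <- matrix(0, S, 2L)
    shifts <- as.matrix(shifts)
    if (!identical(dim(shifts), c(S, 2L)))
        stop("shifts must be an S x 2 matrix")
    gTrue <- geometry
    gTrue@jOffsets <- shifts[, 1L]
    gTrue@kOffsets <- shifts[, 2L]
    B <- segmentIntegrals(field@basis, gTrue, segments, method = "adaptive")
    model <- forwardModel(field@coefficients, gTrue, B, J = J, K = K)
    d <- dim(model)

    set.seed(seed)
    data <- model
    nClipped <- 0L
    if (noise == "gaussian") {
        sdv <- noiseLevel * mean(model)
        data <- model + array(rnorm(length(model), sd = sdv), d)
    } else if (noise == "poisson") {
        scale <- noiseLevel
        if (scale <= 0) stop("poisson noise scale must be positive")
        data <- array(rpois(length(model), lambda = pmax(model, 0) * scale) / scale, d)
    }
    if (any(data < 0)) {
        nClipped <- sum(data < 0)
        data[data < 0] <- 0
        warning(sprintf("%d negative intensities clipped to 0", nClipped),
                call. = FALSE)
    }

    diode <- array(1, d[1:3])
    if (transmission > 0) {
        dens <- meanIntensity(field)
        paths <- forwardProject(array(dens, c(dim(dens), 1L)), gTrue,
                                J = d[2L], K = d[3L])[, , , 1L]
        mx <- max(paths)
        if (mx > 0) diode <- exp(-transmission * paths / mx)
    }

    gOut <- geometry
    gOut@jOffsets <- rep(0, S)
    gOut@kOffsets <- rep(0, S)
    stack <- new("ProjectionStack", data = data, diode = diode,
                 weights = array(1, d), geometry = gOut, segments = segments)
    list(stack = stack, shifts = shifts, model = model)
}
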