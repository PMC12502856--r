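# Shared fixtures: small geometries and simulated experiments built in code.

fix_geometry <- function(n = 8L, S = 5L, seed = 1L, tilts = TRUE) {
    set.seed(seed)
    TTGeometry(innerAngles = runif(S, 0, 2 * pi),
               outerAngles = if (tilts) runif(S, 0, 0.7) else rep(0, S),
               volumeShape = n)
}

fix_scheme_geometry <- function(n, nInner = 20L,
                                tilts = c(0, 20, 40) * pi / 180) {
    ang <- ttAngleScheme(nInner, tilts)
    TTGeometry(innerAngles = ang$inner, outerAngles = ang$outer,
               volumeShape = n)
}

fix_simulation <- function(n = 8L, nInner = 8L, tilts = c(0, 25) * pi / 180,
                           lMax = 2L, nSeg = 4L, anisotropy = 0.8,
                           texture = "uniaxial_fiber", noise = "none",
                           shifts = NULL, seed = 1L) {
    g <- fix_scheme_geometry(n, nInner, tilts)
    seg <- DetectorSegments(nSeg, "half")
    ph <- makePhantom(n, texture, SphericalHarmonicsBasis(lMax),
                      anisotropy = anisotropy)
    sim <- simulateExperiment(ph$field, g, seg, noise = noise,
                              shifts = shifts, seed = seed)
    list(geometry = g, segments = seg, phantom = ph, sim = sim,
         stack = sim$stack)
}

# relative max deviation of analytic vs central finite-difference gradient,
# evaluated on a random subset of entries
fd_gradient_check <- function(fn, x, nProbe = 12L, h = 1e-5, seed = 42L) {
    set.seed(seed)
    g <- fn(x)$gradient
    idx <- sample(length(x), min(nProbe, length(x)))
    worst <- 0
    for (i in idx) {
        xp <- x; xp[i] <- xp[i] + h
        xm <- x; xm[i] <- xm[i] - h
        num <- (fn(xp)$value - fn(xm)$value) / (2 * h)
        scale <- max(abs(num), abs(g[i]), 1e-8)
        worst <- max(worst, abs(num - g[i]) / scale)
    }
    worst
}

angular_error_deg <- function(v1, v2) {
    acos(pmin(1, abs(rowSums(v1 * v2)))) * 180 / pi
}
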