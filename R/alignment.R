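# Iterative phase-matching projection alignment: reconstruct a scalar
# tomogram from an isotropic signal (transmission or azimuthally averaged
# intensity), re-project it, and update the per-projection offsets from the
# sub-pixel cross-correlation between measured and synthetic images.

.fft2 <- function(x) fft(x)
.ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

# Matrix-multiply DFT evaluation of the upsampled inverse FFT in a small
# window (Guizar-Sicairos-style single-step refinement).
.dftups <- function(Fc, nor, noc, usfac, roff, coff) {
    nr <- nrow(Fc); nc <- ncol(Fc)
    fr <- c(0:(floor(nr / 2)), (-ceiling(nr / 2) + 1):-1)[seq_len(nr)]
    fc <- c(0:(floor(nc / 2)), (-ceiling(nc / 2) + 1):-1)[seq_len(nc)]
    kernr <- exp(2i * pi / (nr * usfac) *
                 outer(seq_len(nor) - 1 - roff, fr))
    kernc <- exp(2i * pi / (nc * usfac) *
                 outer(fc, seq_len(noc) - 1 - coff))
    kernr %*% Fc %*% kernc
}

# Sub-pixel shift of image m relative to image s by FFT cross-correlation:
# integer peak, center-of-mass refinement over a (2w+1)^2 window, then
# Fourier-upsampled refinement with factor usfac.
.subpixel_shift <- function(m, s, usfac = 10L, window = 2L) {
    nr <- nrow(m); nc <- ncol(m)
    Fm <- .fft2(m); Fs <- .fft2(s)
    Fc <- Fm * Conj(Fs)
    cc <- Re(.ifft2(Fc))
    pk <- arrayInd(which.max(cc), dim(cc))
    # center of mass over a small window around the peak (circular indexing)
    ri <- (pk[1L] - 1 + (-window:window)) %% nr + 1
    ci <- (pk[2L] - 1 + (-window:window)) %% nc + 1
    wcc <- pmax(cc[ri, ci], 0)
    tot <- sum(wcc)
    com <- if (tot > 0)
        c(sum((-window:window) * rowSums(wcc)), sum((-window:window) * colSums(wcc))) / tot
    else c(0, 0)
    wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
    shift <- c(wrap(pk[1L], nr), wrap(pk[2L], nc)) + com
    if (usfac > 1L) {
        # refine on a usfac-times finer grid in a +-1.5 px neighborhood
        half <- ceiling(1.5 * usfac)
        nup <- 2L * half + 1L
        roff <- half - shift[1L] * usfac
        coff <- half - shift[2L] * usfac
        ccup <- Re(.dftups(Fc, nup, nup, usfac, roff, coff))
        pu <- arrayInd(which.max(ccup), dim(ccup))
        shift <- shift + (c(pu[1L], pu[2L]) - 1 - half) / usfac
    }
    shift
}

#' Remove the object-translation gauge from per-projection offsets
#'
#' A rigid translation t of the reconstructed object changes the offsets of
#' every projection by (j_s . t, k_s . t) with j_s, k_s the sample-frame
#' scan axes, and is therefore unobservable from projection consistency.
#' This projects the best-fitting translation out of an offset set, leaving
#' the minimal-norm gauge representative; alignment results and injected
#' ground-truth shifts should be compared after applying it to both.
#'
#' @param jOffsets,kOffsets Numeric length-S offset vectors.
#' @param geometry A \linkS4class{TTGeometry}.
#' @return List with gauge-fixed \code{jOffsets}, \code{kOffsets} and the
#'   removed \code{translation} (3-vector).
#' @export
removeTranslationGauge <- function(jOffsets, kOffsets, geometry) {
    bb <- beamBasis(geometry)
    A <- rbind(bb$j, bb$k)
    tr <- qr.solve(A, c(jOffsets, kOffsets))
    fit <- drop(A %*% tr)
    S <- length(jOffsets)
    list(jOffsets = jOffsets - fit[seq_len(S)],
         kOffsets = kOffsets - fit[S + seq_len(S)],
         translation = tr)
}

#' Iterative phase-matching alignment of a projection stack
#'
#' Estimates the per-projection offsets Delta-j, Delta-k (in scan-step units,
#' sub-pixel) of an isotropic sinogram by alternating scalar SIRT
#' reconstruction, forward re-projection, and per-projection sub-pixel
#' cross-correlation between measured and synthetic images; offset updates
#' are damped and the object-translation gauge is fixed each iteration with
#' \code{\link{removeTranslationGauge}}.  Initial offsets come from
#' center-of-mass pre-centering of the measured images.
#'
#' @param sinogram Numeric array [S, J, K]: the transmission signal (e.g.
#'   \code{-log(diode)}) or the azimuthally averaged scattering intensity.
#' @param geometry A \linkS4class{TTGeometry}; its offsets are used as the
#'   starting estimate and overridden by the result.
#' @param maxIter Maximum outer iterations (default 20).
#' @param tol Convergence threshold on the maximum offset change per
#'   iteration (pixels; default 0.1).
#' @param damping Update damping factor in (0, 1] (default 0.8).
#' @param sirtIter Inner scalar-SIRT iterations per outer loop.
#' @param upsample Fourier upsampling factor for sub-pixel refinement.
#' @return List with \code{jOffsets}, \code{kOffsets} (length S; intended to
#'   override the offsets stored with the data), \code{trace} (max offset
#'   change per iteration), \code{converged}, and \code{reconstruction} (the
#'   final scalar tomogram).
#' @export
phaseMatchingAlign <- function(sinogram, geometry, maxIter = 20L, tol = 0.1,
                               damping = 0.8, sirtIter = 10L, upsample = 10L) {
    d <- dim(sinogram)
    if (length(d) != 3L) stop("sinogram must be [S, J, K]")
    S <- d[1L]; J <- d[2L]; K <- d[3L]
    if (S < 2L) stop("alignment needs at least two projections")
    if (all(sinogram == 0)) stop("sinogram is identically zero")
    if (length(geometry@innerAngles) != S)
        stop("geometry does not match the sinogram")

    # center-of-mass pre-centering: images positive by construction
    jOff <- geometry@jOffsets
    kOff <- geometry@kOffsets
    jc <- (J + 1) / 2; kc <- (K + 1) / 2
    for (s in seq_len(S)) {
        img <- pmax(sinogram[s, , ], 0)
        tot <- sum(img)
        if (tot > 0) {
            jOff[s] <- sum(rowSums(img) * seq_len(J)) / tot - jc
            kOff[s] <- sum(colSums(img) * seq_len(K)) / tot - kc
        }
    }
    gfix <- removeTranslationGauge(jOff, kOff, geometry)
    jOff <- gfix$jOffsets; kOff <- gfix$kOffsets

    # scalar SIRT with current offsets, then re-project and correlate
    ones <- array(1, c(S, J, K, 1L))
    trace <- numeric(0)
    converged <- FALSE
    recon <- NULL
    for (it in seq_len(maxIter)) {
        g <- geometry
        g@jOffsets <- jOff
        g@kOffsets <- kOff
        pre <- {
            raySums <- forwardProject(array(1, c(g@volumeShape, 1L)), g, J, K)
            colSums_ <- adjointProject(ones, g)
            eps1 <- 1e-12 * max(raySums); eps2 <- 1e-12 * max(colSums_)
            R <- array(0, dim(raySums)); R[raySums > eps1] <- 1 / raySums[raySums > eps1]
            Cw <- array(0, dim(colSums_)); Cw[colSums_ > eps2] <- 1 / colSums_[colSums_ > eps2]
            list(C = Cw, R = R)
        }
        x <- array(0, c(g@volumeShape, 1L))
        b <- array(sinogram, c(S, J, K, 1L))
        for (t in seq_len(sirtIter)) {
            r <- b - forwardProject(x, g, J, K)
            x <- x + pre$C * adjointProject(pre$R * r, g)
        }
        recon <- x
        synth <- forwardProject(x, g, J, K)
        dj <- dk <- numeric(S)
        for (s in seq_len(S)) {
            sh <- .subpixel_shift(sinogram[s, , ], synth[s, , , 1L],
                                  usfac = upsample)
            dj[s] <- sh[1L]; dk[s] <- sh[2L]
        }
        # measured = synthetic shifted by -(Delta_true - Delta_est) in index
        # space, so the correlation peak moves opposite to the offset error
        jNew <- jOff - damping * dj
        kNew <- kOff - damping * dk
        gfix <- removeTranslationGauge(jNew, kNew, geometry)
        jNew <- gfix$jOffsets; kNew <- gfix$kOffsets
        change <- max(abs(c(jNew - jOff, kNew - kOff)))
        trace <- c(trace, change)
        jOff <- jNew; kOff <- kNew
        if (change < tol) { converged <- TRUE; break }
    }
    list(jOffsets = jOff, kOffsets = kOff, trace = trace,
         converged = converged, reconstruction = recon[, , , 1L])
}

#' Sort projections by beam direction
#'
#' Greedy nearest-neighbor ordering of the sample-frame beam directions on
#' the sphere, starting from the first projection, so that neighboring
#' projections in the returned order have beam directions as close as
#' possible (useful for visualizing offset traces).
#'
#' @param geometry A \linkS4class{TTGeometry}.
#' @return Integer permutation of 1..S.
#' @export
sortProjectionsByDirection <- function(geometry) {
    p <- beamBasis(geometry)$p
    S <- nrow(p)
    if (S == 1L) return(1L)
    remaining <- seq_len(S)
    ord <- integer(S)
    ord[1L] <- 1L
    remaining <- remaining[-1L]
    for (i in 2:S) {
        last <- p[ord[i - 1L], ]
        dots <- p[remaining, , drop = FALSE] %*% last
        pick <- which.max(dots)
        ord[i] <- remaining[pick]
        remaining <- remaining[-pick]
    }
    ord
}
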