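# Independent slow reference implementations used as oracles.  The dense ray
# tracer below re-derives the projector's discretization (dominant-axis
# marching with transverse bilinear weights) with plain R loops and explicit
# matrix assembly; it defines correctness for the compiled projector.

oracle_rotation <- function(axis, angle) {
    # Rodrigues formula written out component-wise
    c <- cos(angle); s <- sin(angle); C <- 1 - c
    x <- axis[1]; y <- axis[2]; z <- axis[3]
    matrix(c(x * x * C + c, x * y * C + z * s, x * z * C - y * s,
             x * y * C - z * s, y * y * C + c, y * z * C + x * s,
             x * z * C + y * s, y * z * C - x * s, z * z * C + c),
           3, 3)
}

# Dense spatial system matrix: rows index rays in (s, j, k) order (s fastest),
# columns index voxels in R array order (x fastest).
oracle_dense_matrix <- function(geometry, J, K) {
    vs <- geometry@volumeShape
    S <- length(geometry@innerAngles)
    A <- matrix(0, S * J * K, prod(vs))
    scale <- geometry@scanStep / geometry@voxelSize
    for (s in seq_len(S)) {
        R <- oracle_rotation(geometry@outerAxis, geometry@outerAngles[s]) %*%
            oracle_rotation(geometry@innerAxis, geometry@innerAngles[s])
        p <- drop(t(R) %*% geometry@pDirection)
        jv <- drop(t(R) %*% geometry@jDirection) * scale
        kv <- drop(t(R) %*% geometry@kDirection) * scale
        dom <- which.max(abs(p))
        tr <- setdiff(1:3, dom)
        for (k in seq_len(K)) for (j in seq_len(J)) {
            o <- (j - 1 - (J - 1) / 2 + geometry@jOffsets[s]) * jv +
                 (k - 1 - (K - 1) / 2 + geometry@kOffsets[s]) * kv
            row <- s + S * (j - 1) + S * J * (k - 1)
            for (g in seq_len(vs[dom])) {
                t0 <- ((g - 1 - (vs[dom] - 1) / 2) - o[dom]) / p[dom]
                pt <- o + t0 * p
                vox <- integer(3); vox[dom] <- g
                for (a1 in 0:1) for (a2 in 0:1) {
                    u1 <- pt[tr[1]] + (vs[tr[1]] - 1) / 2
                    u2 <- pt[tr[2]] + (vs[tr[2]] - 1) / 2
                    i1 <- floor(u1) + a1; i2 <- floor(u2) + a2
                    w <- (if (a1 == 0) 1 - (u1 - floor(u1)) else u1 - floor(u1)) *
                         (if (a2 == 0) 1 - (u2 - floor(u2)) else u2 - floor(u2))
                    if (w == 0) next
                    if (i1 < 0 || i1 >= vs[tr[1]] || i2 < 0 || i2 >= vs[tr[2]]) next
                    vox[tr[1]] <- i1 + 1; vox[tr[2]] <- i2 + 1
                    col <- vox[1] + vs[1] * (vox[2] - 1) + vs[1] * vs[2] * (vox[3] - 1)
                    A[row, col] <- A[row, col] + w
                }
            }
        }
    }
    A
}

# Dense full system matrix including the basis response:
# rows (s, j, k, c) with s fastest then j, k, c; columns (voxel, channel).
oracle_full_matrix <- function(geometry, response, J, K) {
    P <- oracle_dense_matrix(geometry, J, K)
    S <- dim(response)[1L]; C <- dim(response)[2L]; N <- dim(response)[3L]
    nRay <- nrow(P); nVox <- ncol(P)
    A <- matrix(0, nRay * C, nVox * N)
    sIdx <- rep(seq_len(S), length.out = nRay)  # s is the fastest ray index
    for (cc in seq_len(C)) for (n in seq_len(N)) {
        rows <- (cc - 1) * nRay + seq_len(nRay)
        cols <- (n - 1) * nVox + seq_len(nVox)
        A[rows, cols] <- P * response[cbind(sIdx, cc, n)]
    }
    A
}

# Dense SIRT reference: x <- x + C A^T R (b - A x) with |A| row/column sums.
oracle_dense_sirt <- function(A, b, nIter) {
    rs <- rowSums(abs(A)); cs <- colSums(abs(A))
    R <- ifelse(rs > 1e-12 * max(rs), 1 / rs, 0)
    Cw <- ifelse(cs > 1e-12 * max(cs), 1 / cs, 0)
    x <- numeric(ncol(A))
    for (i in seq_len(nIter))
        x <- x + Cw * drop(crossprod(A, R * (b - drop(A %*% x))))
    x
}

# Midpoint-rule quadrature oracle for segment responses
oracle_segment_midpoint <- function(basis, geometry, segments, nPoints = 10000L) {
    S <- length(geometry@innerAngles)
    bnd <- segments@boundaries
    C <- length(bnd) - 1L
    N <- coefficientCount(basis)
    out <- array(0, c(S, C, N))
    for (s in seq_len(S)) {
        for (cc in seq_len(C)) {
            phis <- seq(bnd[cc], bnd[cc + 1L], length.out = nPoints + 1L)
            phis <- (phis[-1L] + phis[-length(phis)]) / 2
            dirs <- probedDirection(geometry, segments, s, phis)
            out[s, cc, ] <- colMeans(evaluateBasis(basis, dirs))
        }
    }
    out
}
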