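# Internal helpers shared across modules.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state so
# that no function leaves hidden global state behind.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Shift a matrix by (dr, dc), padding with `fill`.
shiftMatrix <- function(m, dr, dc, fill = 0) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(fill, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
}

# Label 8-connected components of a logical matrix.  Written here because no
# installed package labels with 8-connectivity; label propagation to the
# fixed point (each pixel takes the minimum positive label among itself and
# its 8 neighbours) converges in O(component diameter) sweeps, which is small
# for the blob-like masks this package handles.
labelComponents8 <- function(mask) {
    stopifnot(is.matrix(mask))
    lab <- matrix(0, nrow(mask), ncol(mask))
    idx <- which(mask)
    if (!length(idx)) return(lab)
    lab[idx] <- seq_along(idx)
    offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
    big <- length(idx) + 1
    repeat {
        cur <- lab
        cur[cur == 0] <- big
        mn <- cur
        for (d in offs) {
            s <- shiftMatrix(cur, d[1], d[2], fill = big)
            mn <- pmin(mn, s)
        }
        nxt <- matrix(0, nrow(mask), ncol(mask))
        nxt[mask] <- mn[mask]
        if (identical(nxt, lab)) break
        lab <- nxt
    }
    # relabel to consecutive integers in first-appearance order
    u <- unique(lab[lab > 0])
    lab[lab > 0] <- match(lab[lab > 0], u)
    lab
}

# Indices (row, col matrix) of voxels whose centres lie within a circle of
# `diameter` mm centred at `center` (in-plane voxel coordinates, 1-based),
# given in-plane spacing (mm).  Boundary voxels at exactly the radius are
# included (centre within the radius).
circleIndices <- function(center, diameter, spacingInPlane, dims) {
    r <- diameter / 2
    rr <- ceiling(r / spacingInPlane)
    rows <- seq(floor(center[1] - rr[1]), ceiling(center[1] + rr[1]))
    cols <- seq(floor(center[2] - rr[2]), ceiling(center[2] + rr[2]))
    g <- expand.grid(row = rows, col = cols)
    d2 <- ((g$row - center[1]) * spacingInPlane[1])^2 +
          ((g$col - center[2]) * spacingInPlane[2])^2
    g <- g[d2 <= r^2 + 1e-12, , drop = FALSE]
    as.matrix(g)
}

# Logical in-plane mask of voxels within `radius` voxels (Chebyshev distance)
# of any TRUE voxel of `mask`, excluding `mask` itself.
chebyshevBand <- function(mask, radius) {
    dil <- mask
    for (dr in -radius:radius)
        for (dc in -radius:radius) {
            if (dr == 0 && dc == 0) next
            dil <- dil | shiftMatrix(mask, dr, dc, fill = FALSE)
        }
    dil & !mask
}

# Inverse CDF of a normal truncated at zero from below.
qtruncnorm0 <- function(u, mean, sd) {
    p0 <- stats::pnorm(0, mean, sd)
    stats::qnorm(p0 + u * (1 - p0), mean, sd)
}

# Population standard deviation (divisor n).
popSD <- function(x) sqrt(mean((x - mean(x))^2))

stopIfNot <- function(cond, fmt, ...) {
    if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}
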