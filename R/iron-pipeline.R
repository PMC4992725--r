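#' Two-point R2* map from a dual-echo magnitude pair
#'
#' Voxelwise apparent transverse relaxation rate from two gradient-echo
#' magnitudes: `R2* = ln(S(TE1) / S(TE2)) / (TE2 - TE1)` with echo times
#' converted from ms to seconds, which for two echoes coincides with the
#' log-linear least-squares fit of the mono-exponential decay and is exact on
#' noise-free data.  Voxels with a non-positive signal at either echo are
#' invalidated; voxels where noise drives `S(TE2) >= S(TE1)` (apparent
#' negative rate) are clamped to zero and counted (`clamp = TRUE`, the
#' default, since tissue R2* is non-negative) or invalidated
#' (`clamp = FALSE`).
#'
#' @param vol1,vol2 magnitude [ImageVolume-class]s at TE1 and TE2 (same grid
#'   and spacing).
#' @param te1,te2 echo times in ms, `0 < te1 < te2`.
#' @param clamp clamp apparent negative rates to 0 (default) instead of
#'   invalidating them.
#' @return A [QuantMap-class] of kind `"R2star"` (values in 1/s).
#' @examples
#' ph <- dualEchoPhantom(r2sSN = c(41.17, 41.17), noiseSD = 0)
#' r2 <- fitR2Star(ph$te1Volume, ph$te2Volume, ph$te[1], ph$te[2])
#' mean(mapValues(r2)[ph$masks$left])
#' @export
fitR2Star <- function(vol1, vol2, te1, te2, clamp = TRUE) {
    stopIfNot(identical(dim(vol1@data), dim(vol2@data)) &&
              isTRUE(all.equal(vol1@spacing, vol2@spacing)),
              "echo volumes must share grid and spacing")
    stopIfNot(te1 > 0 && te1 < te2, "echo times must satisfy 0 < TE1 < TE2")
    s1 <- vol1@data; s2 <- vol2@data
    valid <- s1 > 0 & s2 > 0
    dte <- (te2 - te1) / 1000
    r2 <- array(0, dim(s1))
    r2[valid] <- log(s1[valid] / s2[valid]) / dte
    neg <- valid & r2 < 0
    nClamped <- 0L
    if (clamp) {
        r2[neg] <- 0
        nClamped <- sum(neg)
    } else {
        valid <- valid & !neg
    }
    r2[!valid] <- NA_real_
    new("QuantMap", kind = "R2star", data = r2, valid = valid,
        spacing = vol1@spacing, nClamped = as.integer(nClamped))
}

#' Select the consecutive slices where a mask is largest
#'
#' Restricts a 3-D mask to the `n` consecutive slices with the greatest total
#' in-plane area -- the rule used to pick the six central SN slices when the
#' structure is visible on more.  Ties go to the earliest window.
#'
#' @param mask 3-D logical array.
#' @param n number of consecutive slices to keep (default 6).
#' @return The mask with all other slices cleared.
#' @export
selectCentralSlices <- function(mask, n = 6) {
    d <- dim(mask)
    area <- vapply(seq_len(d[3]), function(s) sum(mask[, , s]), numeric(1))
    if (sum(area > 0) <= n) return(mask)
    starts <- seq_len(d[3] - n + 1)
    tot <- vapply(starts, function(s) sum(area[s:(s + n - 1)]), numeric(1))
    s0 <- starts[which.max(tot)]
    keep <- s0:(s0 + n - 1)
    out <- mask
    out[, , setdiff(seq_len(d[3]), keep)] <- FALSE
    out
}

#' Sample a quantitative map over per-side SN ROIs
#'
#' Unweighted mean of the map values under each side's mask, excluding
#' invalid voxels and reporting their fraction.  Masks spanning more than
#' `maxSlices` slices are reduced to the largest-area consecutive window
#' with [selectCentralSlices()] (with a warning).
#'
#' @param map a [QuantMap-class].
#' @param masks named list of per-side 3-D logical arrays
#'   (`list(left =, right =)`).
#' @param maxSlices maximum number of slices a mask may span (default 6).
#' @return data.frame: `side`, `mean`, `voxels` (valid voxels used),
#'   `invalid_fraction`.
#' @examples
#' ph <- susceptibilityPhantom(snPPM = c(0.16, 0.16))
#' sampleSnRois(ph$map, ph$masks)
#' @export
sampleSnRois <- function(map, masks, maxSlices = 6) {
    out <- lapply(names(masks), function(s) {
        m <- masks[[s]]
        stopIfNot(identical(dim(m), dim(map@data)),
                  "mask '%s' does not match the map grid", s)
        stopIfNot(any(m), "mask '%s' is empty", s)
        nsl <- sum(vapply(seq_len(dim(m)[3]), function(z) any(m[, , z]),
                          logical(1)))
        if (nsl > maxSlices) {
            warning(sprintf("mask '%s' spans %d slices; reducing to the %d with largest area",
                            s, nsl, maxSlices))
            m <- selectCentralSlices(m, maxSlices)
        }
        use <- m & map@valid
        stopIfNot(any(use), "mask '%s' contains no valid voxels", s)
        data.frame(side = s, mean = mean(map@data[use]),
                   voxels = sum(use),
                   invalid_fraction = 1 - sum(use) / sum(m))
    })
    do.call(rbind, out)
}

#' Average two measurement repeats
#'
#' Arithmetic mean of two repeated ROI measurements, per side and measure.
#'
#' @param m1,m2 numeric vectors, or data.frames as returned by
#'   [sampleSnRois()] (matched on `side`).
#' @return Same shape as the inputs with values averaged.
#' @examples
#' averageTwoRepeats(c(40, 42), c(42, 44))
#' @export
averageTwoRepeats <- function(m1, m2) {
    if (is.numeric(m1) && is.numeric(m2)) return((m1 + m2) / 2)
    stopIfNot(is.data.frame(m1) && is.data.frame(m2) &&
              identical(m1$side, m2$side),
              "repeat tables must match on side")
    out <- m1
    num <- vapply(m1, is.numeric, logical(1))
    out[num] <- (m1[num] + m2[num]) / 2
    out
}
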