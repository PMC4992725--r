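#' Background region statistics
#'
#' Mean and population SD of the voxels of a circular or mask ROI on one
#' slice.  Circles are rasterised by the voxel-centre rule: a voxel belongs to
#' the circle when its centre lies within the radius, distances measured in mm
#' using the in-plane spacing.
#'
#' @param vol an [ImageVolume-class].
#' @param roi a [RoiSpec-class].
#' @return A [RegionStats-class].
#' @examples
#' vol <- imageVolume(array(c(98, 100, 102), c(3, 1, 1)))
#' regionStats(vol, roiSpec(1, mask = matrix(TRUE, 3, 1)))
#' @export
regionStats <- function(vol, roi) {
    d <- dim(vol@data)
    stopIfNot(roi@slice <= d[3], "ROI slice %d beyond volume (%d slices)",
              roi@slice, d[3])
    plane <- vol@data[, , roi@slice]
    if (roi@shape == "circle") {
        idx <- circleIndices(roi@center, roi@diameter, vol@spacing[1:2], d[1:2])
        stopIfNot(nrow(idx) > 0, "ROI at (%g, %g) slice %d is empty",
                  roi@center[1], roi@center[2], roi@slice)
        stopIfNot(all(idx[, 1] >= 1 & idx[, 1] <= d[1] &
                      idx[, 2] >= 1 & idx[, 2] <= d[2]),
                  "circle ROI at (%g, %g) slice %d extends outside the grid",
                  roi@center[1], roi@center[2], roi@slice)
        x <- plane[idx]
    } else {
        stopIfNot(identical(base::dim(roi@mask), d[1:2]),
                  "mask ROI dimensions do not match the slice")
        stopIfNot(any(roi@mask), "mask ROI on slice %d is empty", roi@slice)
        x <- plane[roi@mask]
    }
    makeRegionStats(mean(x), popSD(x), length(x))
}

#' Threshold binary map for one slice and side
#'
#' Marks the voxels of one slice whose intensity strictly exceeds
#' `mean + k * SD` of the background reference statistics (default k = 3,
#' i.e. the MN_CC + 3 x SD_CC rule), restricted to the requested side of the
#' mid-sagittal plane and, optionally, to a declared mesencephalic search
#' region.
#'
#' @param vol an [ImageVolume-class].
#' @param bg background [RegionStats-class] for that slice and side.
#' @param slice slice index.
#' @param side `"left"`, `"right"` or `NULL` (no side restriction).
#' @param searchMask optional logical in-plane matrix restricting the search.
#' @param k threshold multiplier (default 3).
#' @param midlineRow rows `<= midlineRow` are the left side; default half the
#'   first grid dimension.
#' @return Logical in-plane matrix.
#' @export
binaryMap <- function(vol, bg, slice, side = NULL, searchMask = NULL, k = 3,
                      midlineRow = dim(vol@data)[1] / 2) {
    d <- dim(vol@data)
    thr <- regionMean(bg) + k * regionSD(bg)
    m <- vol@data[, , slice] > thr
    if (!is.null(side)) {
        rows <- seq_len(d[1])
        keep <- if (side == "left") rows <= midlineRow else rows > midlineRow
        m[!keep, ] <- FALSE
    }
    if (!is.null(searchMask)) m <- m & searchMask
    m
}

#' Segment the substantia nigra from per-slice binary maps
#'
#' Per slice, keeps the largest 8-connected in-plane component (ties broken
#' by the component containing the first voxel in array order), then selects
#' the 4-slice consecutive window with the greatest total component area --
#' the operational reading of "the slices in which the SN is visible".  When
#' fewer than `windowSize` slices carry any signal, all non-empty slices are
#' used with a warning; when none do, a flagged missing-side result is
#' returned rather than an error.
#'
#' @param masks named list of logical in-plane matrices, names are slice
#'   indices (as from [binaryMap()] per candidate slice, already
#'   side-restricted).
#' @param spacing voxel spacing (mm, length 3).
#' @param windowSize number of consecutive slices to retain (default 4).
#' @return List: `mask` (named list of per-slice component masks over the
#'   selected window), `slices`, `voxels`, `volume` (mm^3), `perSliceArea`
#'   (voxel counts), `missing` flag.
#' @export
segmentSN <- function(masks, spacing, windowSize = 4) {
    slices <- as.integer(names(masks))
    stopIfNot(length(slices) > 0 && !any(is.na(slices)),
              "masks must be a list named by slice index")
    comp <- lapply(masks, function(m) {
        lab <- labelComponents8(m)
        if (max(lab) == 0) return(m & FALSE)
        sizes <- tabulate(lab[lab > 0])
        lab == which.max(sizes)   # which.max: first (lowest label) wins ties
    })
    area <- vapply(comp, sum, numeric(1))
    if (all(area == 0)) {
        return(list(mask = comp[0], slices = integer(0), voxels = 0L,
                    volume = NA_real_, perSliceArea = area, missing = TRUE))
    }
    ord <- order(slices)
    slices <- slices[ord]; comp <- comp[ord]; area <- area[ord]
    nz <- which(area > 0)
    if (length(nz) < windowSize) {
        warning(sprintf("only %d slice(s) with suprathreshold signal; using all",
                        length(nz)))
        sel <- nz
    } else {
        # best consecutive run of `windowSize` slice positions
        starts <- seq_len(length(slices) - windowSize + 1)
        ok <- vapply(starts, function(s)
            all(diff(slices[s:(s + windowSize - 1)]) == 1), logical(1))
        starts <- starts[ok]
        stopIfNot(length(starts) > 0, "no %d consecutive slices available",
                  windowSize)
        tot <- vapply(starts, function(s) sum(area[s:(s + windowSize - 1)]),
                      numeric(1))
        s0 <- starts[which.max(tot)]
        sel <- s0:(s0 + windowSize - 1)
    }
    nvox <- sum(area[sel])
    list(mask = comp[sel], slices = slices[sel], voxels = as.integer(nvox),
         volume = nvox * prod(spacing), perSliceArea = area[sel],
         missing = FALSE)
}

#' Contrast-to-noise ratio of the segmented SN
#'
#' Per analysed slice, `CNR = (MN_SN - MN_CC) / SD_CC` where MN_SN is the
#' mean intensity over the slice's SN component and MN_CC / SD_CC come from
#' the cerebral-crus reference ROI of that slice and side; the side value is
#' the unweighted mean across the analysed slices.
#'
#' @param vol an [ImageVolume-class].
#' @param sn a segmentation result from [segmentSN()].
#' @param bg a single [RegionStats-class] applied to every slice, or a list
#'   of them named by slice index.
#' @return List: `perSlice` (data.frame slice, mnSN, cnr), `value` (side
#'   average).
#' @export
cnrSN <- function(vol, sn, bg) {
    stopIfNot(!isTRUE(sn$missing), "missing-side segmentation has no CNR")
    getBG <- function(s) if (is(bg, "RegionStats")) bg else bg[[as.character(s)]]
    per <- lapply(seq_along(sn$slices), function(i) {
        s <- sn$slices[i]
        b <- getBG(s)
        stopIfNot(regionSD(b) > 0,
                  "degenerate background (SD = 0) on slice %d", s)
        mn <- mean(vol@data[, , s][sn$mask[[i]]])
        data.frame(slice = s, mnSN = mn,
                   cnr = (mn - regionMean(b)) / regionSD(b))
    })
    per <- do.call(rbind, per)
    list(perSlice = per, value = mean(per$cnr))
}

#' Locate the locus coeruleus on one slice and side
#'
#' Returns the highest-intensity voxel in the adjacency band of the fourth
#' ventricle: all voxels within `bandRadius` in-plane voxels (Chebyshev
#' distance) of the ventricle mask, excluding the mask itself, restricted to
#' the requested side.  Intensity ties are broken by the smallest row, then
#' the smallest column index.
#'
#' @param vol an [ImageVolume-class].
#' @param ventricleMask 3-D logical array marking the fourth ventricle.
#' @param slice slice index.
#' @param side `"left"` or `"right"`.
#' @param bandRadius adjacency radius in voxels (default 2).
#' @param midlineRow side split as in [binaryMap()].
#' @return Integer `c(row, col)` of LC_MAX.
#' @export
locateLC <- function(vol, ventricleMask, slice, side, bandRadius = 2,
                     midlineRow = dim(vol@data)[1] / 2) {
    d <- dim(vol@data)
    vent <- ventricleMask[, , slice]
    band <- chebyshevBand(vent, bandRadius)
    rows <- seq_len(d[1])
    keep <- if (side == "left") rows <= midlineRow else rows > midlineRow
    band[!keep, ] <- FALSE
    stopIfNot(any(band), "empty ventricle adjacency band on slice %d (%s)",
              slice, side)
    plane <- vol@data[, , slice]
    idx <- which(band, arr.ind = TRUE)
    v <- plane[idx]
    best <- idx[v == max(v), , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    c(row = best[1, 1], col = best[1, 2])
}

# Mean of a voxel and its available in-plane 4-neighbours, warning when the
# point sits on the grid edge.
lcIntensity <- function(plane, point) {
    d <- dim(plane)
    nb <- rbind(point, point + c(-1, 0), point + c(1, 0),
                point + c(0, -1), point + c(0, 1))
    inb <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2]
    if (!all(inb))
        warning(sprintf("LC_MAX at (%d, %d) is on the grid edge; using %d of 4 abutting voxels",
                        point[1], point[2], sum(inb) - 1L))
    mean(plane[nb[inb, , drop = FALSE]])
}

#' Contrast-to-noise ratio of the locus coeruleus
#'
#' For each of three consecutive slices: locate LC_MAX with [locateLC()],
#' take the LC intensity as the mean of LC_MAX and its four in-plane abutting
#' voxels, sample a circular pontine-tegmentum reference ROI (default 6 mm
#' diameter), and compute `CNR = (MN_LC - MN_TG) / SD_TG`; the side value is
#' the mean over the slices.  When the tegmentum ROI has zero SD (noise-free
#' images have no intensity scale of their own) the declared `referenceSD`
#' is substituted; with neither available an error is raised.
#'
#' @param vol an [ImageVolume-class].
#' @param ventricleMask 3-D logical array marking the fourth ventricle.
#' @param slices the (three) slice indices to analyse.
#' @param side `"left"` or `"right"`.
#' @param tgCenter in-plane `c(row, col)` of the tegmentum ROI centre
#'   (applied on every slice).
#' @param tgDiameter tegmentum ROI diameter in mm (default 6).
#' @param bandRadius,midlineRow passed to [locateLC()].
#' @param referenceSD nominal intensity SD used when the estimated tegmentum
#'   SD is exactly zero.
#' @return List: `perSlice` (data.frame slice, row, col, mnLC, mnTG, sdTG,
#'   cnr), `value` (side average).
#' @export
cnrLC <- function(vol, ventricleMask, slices, side, tgCenter, tgDiameter = 6,
                  bandRadius = 2, midlineRow = dim(vol@data)[1] / 2,
                  referenceSD = NULL) {
    per <- lapply(slices, function(s) {
        pt <- locateLC(vol, ventricleMask, s, side, bandRadius, midlineRow)
        mnLC <- lcIntensity(vol@data[, , s], pt)
        tg <- regionStats(vol, roiSpec(s, tgCenter, tgDiameter, side))
        sdTG <- regionSD(tg)
        if (sdTG == 0) {
            stopIfNot(!is.null(referenceSD) && referenceSD > 0,
                      "degenerate tegmentum ROI (SD = 0) on slice %d and no referenceSD", s)
            sdTG <- referenceSD
        }
        data.frame(slice = s, row = pt[1], col = pt[2], mnLC = mnLC,
                   mnTG = regionMean(tg), sdTG = sdTG,
                   cnr = (mnLC - regionMean(tg)) / sdTG)
    })
    per <- do.call(rbind, per)
    list(perSlice = per, value = mean(per$cnr))
}

#' Normalise contrast values to the healthy-control median
#'
#' Expresses a CNR as a percentage of the corresponding healthy-control group
#' median, making SN and LC contrast directly comparable.
#'
#' @param values numeric vector of contrast values.
#' @param hcMedian healthy-control median of the same measure (> 0).
#' @return `values / hcMedian * 100`.
#' @examples
#' percentCNR(3.54, 4.89)
#' @export
percentCNR <- function(values, hcMedian) {
    stopIfNot(is.finite(hcMedian) && hcMedian > 0,
              "healthy-control median must be > 0")
    values / hcMedian * 100
}

#' Left-right asymmetry index
#'
#' `AI = |(ipsi - contra) / (ipsi + contra)| * 200`, a 0-200 imbalance score
#' applied identically to putamen and caudate DAT binding, SN volume and SN
#' CNR.  By convention the contralateral side is opposite the clinically
#' worse hemibody; healthy controls take the right side as ipsilateral.
#'
#' @param ipsi,contra non-negative measure values (vectorised).
#' @return Asymmetry indices in `[0, 200]`.
#' @examples
#' asymmetryIndex(2.06, 1.60)
#' @export
asymmetryIndex <- function(ipsi, contra) {
    stopIfNot(all(ipsi >= 0 & contra >= 0, na.rm = TRUE),
              "asymmetry index is defined for non-negative values")
    stopIfNot(all(ipsi + contra != 0, na.rm = TRUE),
              "asymmetry index undefined when both sides are zero")
    abs((ipsi - contra) / (ipsi + contra)) * 200
}

#' Average repeated measurements
#'
#' Mean and sample SD across repeated measurement runs (each run re-places
#' the background ROIs).  The SD here is the sample SD (divisor n - 1): it
#' estimates rater variability from a small number of repeats.
#'
#' @param x numeric vector of repeats, or a matrix / data.frame with one row
#'   per repeat.
#' @return For a vector, `list(mean, sd)`; otherwise a data.frame with one
#'   row per column of `x`.
#' @examples
#' averageRepeats(c(4.0, 4.2, 4.4, 4.6))
#' @export
averageRepeats <- function(x) {
    if (is.numeric(x) && is.null(base::dim(x))) {
        stopIfNot(length(x) >= 2, "need at least 2 repeats")
        return(list(mean = mean(x), sd = stats::sd(x)))
    }
    x <- as.data.frame(x)
    stopIfNot(nrow(x) >= 2, "need at least 2 repeats")
    data.frame(measure = names(x),
               mean = vapply(x, mean, numeric(1)),
               sd = vapply(x, stats::sd, numeric(1)), row.names = NULL)
}

#' Full neuromelanin measurement of one volume
#'
#' Runs the complete NM-MRI chain for both sides: cerebral-crus background
#' statistics per candidate slice, threshold binary maps, largest-component
#' SN segmentation over the best 4-slice window, SN volume and CNR, LC
#' localisation and CNR over the declared pontine slices.  The whole chain is
#' repeated `repeats` times with every reference-ROI centre independently
#' jittered by a uniform +/-1 voxel in-plane shift (emulating intra-rater
#' ROI placement variability), and the mean and sample SD across repeats are
#' reported.
#'
#' When a background ROI lands on a degenerate (zero SD) region -- as in
#' noise-free synthetic images -- the configuration's `referenceSD` is
#' substituted for thresholding and CNR so the measurement remains defined.
#'
#' @param vol an [ImageVolume-class].
#' @param config measurement configuration: `snSlices` (candidate slices),
#'   `searchBox` (per-side `c(row0, row1, col0, col1)`), `crus` (per-side
#'   `c(row, col)` reference centres), `crusDiameter` (mm), `lcSlices`,
#'   `tegmentum` (per-side centres), `tgDiameter`, `ventricleMask`,
#'   `midlineRow`, optional `referenceSD`.  Phantoms from [nmPhantom()]
#'   provide a matching `config` element.
#' @param repeats number of measurement repeats (default 4).
#' @param seed RNG seed driving the ROI jitter.
#' @return List: `summary` (data.frame side, measure, mean, sd across
#'   repeats), `repeats` (data.frame of per-repeat values), `segmentation`
#'   (first repeat's per-side [segmentSN()] results).
#' @export
measureNM <- function(vol, config, repeats = 4, seed = 1) {
    d <- dim(vol@data)
    midline <- config$midlineRow %||% (d[1] / 2)
    refSD <- config$referenceSD
    jitters <- withSeed(seed, lapply(seq_len(repeats), function(i)
        if (i == 1) c(0L, 0L) else
            as.integer(sample(-1:1, 2, replace = TRUE))))
    runs <- list(); seg1 <- list()
    for (r in seq_len(repeats)) {
        jt <- jitters[[r]]
        for (s in c("left", "right")) {
            box <- config$searchBox[[s]]
            search <- matrix(FALSE, d[1], d[2])
            search[box[1]:box[2], box[3]:box[4]] <- TRUE
            bgs <- list(); maps <- list()
            for (sl in config$snSlices) {
                bg <- regionStats(vol, roiSpec(sl, config$crus[[s]] + jt,
                                               config$crusDiameter, s))
                if (regionSD(bg) == 0) {
                    stopIfNot(!is.null(refSD) && refSD > 0,
                              "degenerate crus ROI (SD = 0) on slice %d and no referenceSD", sl)
                    bg <- makeRegionStats(regionMean(bg), refSD, regionN(bg))
                }
                bgs[[as.character(sl)]] <- bg
                maps[[as.character(sl)]] <-
                    binaryMap(vol, bg, sl, s, search, midlineRow = midline)
            }
            seg <- segmentSN(maps, vol@spacing)
            if (r == 1) seg1[[s]] <- seg
            cs <- if (seg$missing) NA_real_ else cnrSN(vol, seg, bgs)$value
            cl <- cnrLC(vol, config$ventricleMask, config$lcSlices, s,
                        config$tegmentum[[s]] + jt, config$tgDiameter,
                        midlineRow = midline, referenceSD = refSD)$value
            runs[[length(runs) + 1]] <- data.frame(
                repeat_ = r, side = s, volume_mm3 = seg$volume,
                cnr_sn = cs, cnr_lc = cl, missing = seg$missing)
        }
    }
    runs <- do.call(rbind, runs)
    summ <- do.call(rbind, lapply(c("left", "right"), function(s) {
        sub <- runs[runs$side == s, c("volume_mm3", "cnr_sn", "cnr_lc")]
        if (repeats >= 2) cbind(side = s, averageRepeats(sub))
        else data.frame(side = s, measure = names(sub),
                        mean = unlist(sub, use.names = FALSE), sd = NA_real_)
    }))
    list(summary = summ, repeats = runs, segmentation = seg1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
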