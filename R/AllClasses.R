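#' @import methods
NULL

#' 3-D image volume with voxel spacing
#'
#' The substrate of every image operation in the package: a 3-D scalar grid
#' together with its voxel spacing in mm.  Slices are always indexed along the
#' third array dimension; the first two dimensions are in-plane (row = left to
#' right axis, column = anterior to posterior axis by the package convention).
#' All voxel indices in the package are 1-based, and a circular ROI contains a
#' voxel when the voxel centre lies within the radius.
#'
#' @slot data 3-D numeric array of intensities; all values must be finite.
#' @slot spacing numeric length-3 voxel spacing in mm, all entries > 0.
#'
#' @seealso [imageVolume()], [readVolume()], [voxelVolume()]
#' @export
setClass("ImageVolume",
    representation(data = "array", spacing = "numeric"))

setValidity("ImageVolume", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, sprintf("data must be a 3-D array, got %d dimension(s)",
                              length(dim(object@data))))
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    if (any(!is.finite(object@data)))
        msg <- c(msg, sprintf("%d non-finite voxel(s) in data",
                              sum(!is.finite(object@data))))
    if (length(msg)) msg else TRUE
})

#' Construct an ImageVolume
#'
#' @param data 3-D numeric array.
#' @param spacing voxel spacing in mm (length 3).
#' @return An [ImageVolume-class] object.
#' @examples
#' vol <- imageVolume(array(0, c(4, 4, 2)), spacing = c(0.5, 0.5, 3))
#' voxelVolume(vol)
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1)) {
    new("ImageVolume", data = data, spacing = as.numeric(spacing))
}

#' @describeIn imageVolume intensity array accessor
#' @param x,object an `ImageVolume`
#' @export
imageData <- function(x) x@data

#' @describeIn imageVolume voxel spacing (mm) accessor
#' @export
spacing <- function(x) x@spacing

#' @describeIn imageVolume volume of one voxel in mm^3
#' @export
voxelVolume <- function(x) prod(x@spacing)

#' @describeIn imageVolume number of slices (third dimension)
#' @export
nSlices <- function(x) dim(x@data)[3L]

setMethod("show", "ImageVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("ImageVolume: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
                d[1], d[2], d[3],
                object@spacing[1], object@spacing[2], object@spacing[3]))
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(object@data), max(object@data)))
})

#' @describeIn imageVolume array dimensions
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

#' Sampling region specification
#'
#' A circular (diameter in mm, rasterised by the voxel-centre rule) or
#' explicit-mask in-plane region on one slice, tagged with the anatomical side
#' it belongs to.
#'
#' @slot shape `"circle"` or `"mask"`.
#' @slot slice 1-based slice index.
#' @slot center in-plane voxel coordinates (row, column) of the circle centre.
#' @slot diameter circle diameter in mm.
#' @slot side `"left"` or `"right"`.
#' @slot mask logical in-plane matrix for explicit-mask regions.
#' @export
setClass("RoiSpec",
    representation(shape = "character", slice = "integer", center = "numeric",
                   diameter = "numeric", side = "character", mask = "matrix"))

setValidity("RoiSpec", function(object) {
    msg <- character()
    if (!object@shape %in% c("circle", "mask"))
        msg <- c(msg, "shape must be 'circle' or 'mask'")
    if (object@shape == "circle") {
        if (length(object@center) != 2L || any(!is.finite(object@center)))
            msg <- c(msg, "circle center must be 2 finite in-plane coordinates")
        if (!is.finite(object@diameter) || object@diameter <= 0)
            msg <- c(msg, "circle diameter must be > 0 mm")
    }
    if (length(object@slice) != 1L || object@slice < 1L)
        msg <- c(msg, "slice must be a single index >= 1")
    if (!object@side %in% c("left", "right"))
        msg <- c(msg, "side must be 'left' or 'right'")
    if (length(msg)) msg else TRUE
})

#' Construct a circular or mask ROI
#'
#' @param slice 1-based slice index.
#' @param center in-plane voxel coordinates `c(row, col)` of the centre
#'   (circle ROIs).
#' @param diameter circle diameter in mm.
#' @param side `"left"` or `"right"`.
#' @param mask logical in-plane matrix; supplying it makes an explicit-mask
#'   ROI and `center`/`diameter` are ignored.
#' @return A [RoiSpec-class].
#' @examples
#' roiSpec(slice = 3, center = c(20, 30), diameter = 4, side = "left")
#' @export
roiSpec <- function(slice, center = NULL, diameter = NULL, side = "left",
                    mask = NULL) {
    if (is.null(mask)) {
        new("RoiSpec", shape = "circle", slice = as.integer(slice),
            center = as.numeric(center), diameter = as.numeric(diameter),
            side = side, mask = matrix(logical(0), 0, 0))
    } else {
        new("RoiSpec", shape = "mask", slice = as.integer(slice),
            center = numeric(0), diameter = 0, side = side,
            mask = mask)
    }
}

setMethod("show", "RoiSpec", function(object) {
    if (object@shape == "circle")
        cat(sprintf("RoiSpec: circle d=%g mm at (%g, %g), slice %d, %s\n",
                    object@diameter, object@center[1], object@center[2],
                    object@slice, object@side))
    else
        cat(sprintf("RoiSpec: mask of %d voxels, slice %d, %s\n",
                    sum(object@mask), object@slice, object@side))
})

#' Region summary statistics
#'
#' Mean, standard deviation and voxel count of a sampling region.  The SD is
#' the population SD (divisor n): the threshold rule is a statement about the
#' voxel population of the reference region, not an inference from a sample.
#'
#' @slot mean region mean intensity.
#' @slot sd region population SD.
#' @slot n voxel count.
#' @export
setClass("RegionStats",
    representation(mean = "numeric", sd = "numeric", n = "integer"))

setValidity("RegionStats", function(object) {
    msg <- character()
    if (!is.finite(object@mean)) msg <- c(msg, "mean must be finite")
    if (!is.finite(object@sd) || object@sd < 0)
        msg <- c(msg, "sd must be finite and >= 0")
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct RegionStats directly
#'
#' Normally produced by [regionStats()]; direct construction is useful when a
#' nominal background scale is known (e.g. noise-free synthetic images).
#'
#' @param mean,sd,n region mean, population SD and voxel count.
#' @return A [RegionStats-class].
#' @export
makeRegionStats <- function(mean, sd, n = 1L) {
    new("RegionStats", mean = as.numeric(mean), sd = as.numeric(sd),
        n = as.integer(n))
}

#' @describeIn makeRegionStats region mean accessor
#' @param x a `RegionStats`
#' @export
regionMean <- function(x) x@mean

#' @describeIn makeRegionStats region SD accessor
#' @export
regionSD <- function(x) x@sd

#' @describeIn makeRegionStats region voxel count accessor
#' @export
regionN <- function(x) x@n

setMethod("show", "RegionStats", function(object) {
    cat(sprintf("RegionStats: mean %.4g, SD %.4g (population), n = %d\n",
                object@mean, object@sd, object@n))
})

#' Quantitative parameter map
#'
#' A voxelwise quantitative map (apparent transverse relaxation rate R2* in
#' 1/s, or magnetic susceptibility in ppm) with a validity mask.  Voxels where
#' the input signals were non-positive are invalid; apparent negative R2*
#' (noise pushing the second echo above the first) is clamped to zero by
#' default and counted in `nClamped`.
#'
#' @slot kind `"R2star"` or `"susceptibility"`.
#' @slot data 3-D value grid.
#' @slot valid logical array, same shape.
#' @slot spacing voxel spacing (mm).
#' @slot nClamped number of voxels clamped to zero.
#' @export
setClass("QuantMap",
    representation(kind = "character", data = "array", valid = "array",
                   spacing = "numeric", nClamped = "integer"))

setValidity("QuantMap", function(object) {
    msg <- character()
    if (!object@kind %in% c("R2star", "susceptibility"))
        msg <- c(msg, "kind must be 'R2star' or 'susceptibility'")
    if (!identical(dim(object@data), dim(object@valid)))
        msg <- c(msg, "data and valid must have identical dimensions")
    if (object@kind == "R2star" &&
        any(object@data[object@valid] < 0, na.rm = TRUE))
        msg <- c(msg, "valid R2* values must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn fitR2Star map values accessor (3-D array)
#' @param x a `QuantMap`
#' @export
mapValues <- function(x) x@data

#' @describeIn fitR2Star validity mask accessor (logical array)
#' @export
mapValid <- function(x) x@valid

setMethod("show", "QuantMap", function(object) {
    d <- dim(object@data)
    cat(sprintf("QuantMap (%s): %d x %d x %d voxels, %d invalid, %d clamped\n",
                object@kind, d[1], d[2], d[3], sum(!object@valid),
                object@nClamped))
})

#' ROC analysis result
#'
#' Empirical ROC of one measure for discriminating two groups, with the area
#' under the curve, every candidate cut-off (midpoints between adjacent sorted
#' values) and its sensitivity / specificity / accuracy with exact
#' Clopper-Pearson 95% intervals, and the three named operating points:
#' the cut-off keeping sensitivity at 100% (with maximal specificity), the
#' cut-off keeping specificity at 100% (with maximal sensitivity), and the
#' accuracy-maximising cut-off (ties broken by Youden's J, then the smaller
#' cut-off).
#'
#' @slot auc area under the empirical ROC curve (trapezoid rule).
#' @slot cutoffs data.frame of candidate cut-offs and their operating
#'   characteristics.
#' @slot named list with elements `sens100`, `spec100`, `best`: one-row
#'   data.frames from `cutoffs`.
#' @slot nPositive,nNegative group sizes.
#' @slot direction `"lower"` or `"higher"`: which tail of the measure
#'   indicates the positive class.
#' @slot degenerate TRUE when all values coincide (AUC fixed at 0.5).
#' @seealso [rocAnalysis()]
#' @export
setClass("RocResult",
    representation(auc = "numeric", cutoffs = "data.frame", named = "list",
                   nPositive = "integer", nNegative = "integer",
                   direction = "character", degenerate = "logical"))

setValidity("RocResult", function(object) {
    msg <- character()
    if (object@auc < 0 || object@auc > 1) msg <- c(msg, "AUC must be in [0,1]")
    cf <- object@cutoffs
    if (nrow(cf)) {
        if (any(cf$sensitivity < 0 | cf$sensitivity > 1) ||
            any(cf$specificity < 0 | cf$specificity > 1))
            msg <- c(msg, "sensitivity/specificity must be in [0,1]")
        if (any(cf$sens_lo > cf$sensitivity + 1e-12) ||
            any(cf$sens_hi < cf$sensitivity - 1e-12) ||
            any(cf$spec_lo > cf$specificity + 1e-12) ||
            any(cf$spec_hi < cf$specificity - 1e-12))
            msg <- c(msg, "confidence intervals must contain point estimates")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn rocAnalysis AUC accessor
#' @param x a `RocResult`
#' @export
auc <- function(x) x@auc

#' @describeIn rocAnalysis candidate cut-off table accessor
#' @export
rocCutoffs <- function(x) x@cutoffs

#' @describeIn rocAnalysis one named operating point
#' @param which one of `"sens100"`, `"spec100"`, `"best"`
#' @export
rocNamedCutoff <- function(x, which = c("best", "sens100", "spec100")) {
    x@named[[match.arg(which)]]
}

setMethod("show", "RocResult", function(object) {
    cat(sprintf("RocResult: AUC = %.4f (%d positive vs %d negative, %s tail)\n",
                object@auc, object@nPositive, object@nNegative,
                object@direction))
    if (object@degenerate) cat("  degenerate: all values identical\n")
    for (nm in c("sens100", "spec100", "best")) {
        p <- object@named[[nm]]
        if (is.null(p)) next
        cat(sprintf("  %-8s cut-off %.4g: sens %.1f%% (%.2f-%.2f), spec %.1f%% (%.2f-%.2f), acc %.1f%%\n",
                    nm, p$cutoff, 100 * p$sensitivity, 100 * p$sens_lo,
                    100 * p$sens_hi, 100 * p$specificity, 100 * p$spec_lo,
                    100 * p$spec_hi, 100 * p$accuracy))
    }
})
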