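#' Recompute the validation quantities from scratch
#'
#' Runs the phantom-to-measurement validation battery the package is checked
#' against: threshold segmentation of noise-free NM phantoms built at the
#' study's group-mean SN volumes, noise-free CNR recovery for SN and LC, the
#' two-point R2* round trip, and the ROC operating characteristics of
#' contralateral SN volume on large synthetic cohorts drawn from the two
#' group distributions, classified at the 292 mm^3 cut-off.  Every number is
#' computed at call time by the package's own measurement chain.
#'
#' @param seed RNG seed for the stochastic (cohort) quantities.
#' @param nPerGroup cohort size per group for the ROC quantities.
#' @return Named list; each element is `list(value =, n =)`.
#' @export
acceptanceSummary <- function(seed = 1, nPerGroup = 5000) {
    seed <- as.integer(seed)
    out <- list()

    segVolume <- function(targetVol) {
        ph <- nmPhantom(snVolume = c(targetVol, targetVol), snCNR = c(5, 5),
                        noiseSD = 0, seed = seed)
        cfg <- ph$config
        maps <- list(); bgs <- list()
        for (sl in cfg$snSlices) {
            bg <- regionStats(ph$volume, roiSpec(sl, cfg$crus$left,
                                                 cfg$crusDiameter, "left"))
            if (regionSD(bg) == 0)
                bg <- makeRegionStats(regionMean(bg), cfg$referenceSD,
                                      regionN(bg))
            bgs[[as.character(sl)]] <- bg
            search <- matrix(FALSE, dim(ph$volume)[1], dim(ph$volume)[2])
            box <- cfg$searchBox$left
            search[box[1]:box[2], box[3]:box[4]] <- TRUE
            maps[[as.character(sl)]] <- binaryMap(ph$volume, bg, sl, "left",
                                                  search,
                                                  midlineRow = cfg$midlineRow)
        }
        seg <- segmentSN(maps, spacing(ph$volume))
        list(seg = seg, phantom = ph, bgs = bgs)
    }

    # noise-free SN volume recovery at the two group means
    s1 <- segVolume(236)
    out$t1 <- list(value = s1$seg$volume, n = s1$seg$voxels)
    s2 <- segVolume(344)
    out$t2 <- list(value = s2$seg$volume, n = s2$seg$voxels)

    # noise-free CNR_SN at the PD contralateral contrast
    ph3 <- nmPhantom(snCNR = c(4.28, 4.28), noiseSD = 0, seed = seed)
    cfg <- ph3$config
    maps <- list(); bgs <- list()
    for (sl in cfg$snSlices) {
        bg <- regionStats(ph3$volume, roiSpec(sl, cfg$crus$left,
                                              cfg$crusDiameter, "left"))
        bgs[[as.character(sl)]] <- makeRegionStats(regionMean(bg),
                                                   cfg$referenceSD,
                                                   regionN(bg))
        search <- matrix(FALSE, dim(ph3$volume)[1], dim(ph3$volume)[2])
        box <- cfg$searchBox$left
        search[box[1]:box[2], box[3]:box[4]] <- TRUE
        maps[[as.character(sl)]] <- binaryMap(ph3$volume,
                                              bgs[[as.character(sl)]], sl,
                                              "left", search,
                                              midlineRow = cfg$midlineRow)
    }
    seg3 <- segmentSN(maps, spacing(ph3$volume))
    out$t3 <- list(value = cnrSN(ph3$volume, seg3, bgs)$value,
                   n = seg3$voxels)

    # noise-free CNR_LC at the PD contralateral contrast
    ph4 <- nmPhantom(lcCNR = c(3.54, 3.54), noiseSD = 0, seed = seed)
    lc <- cnrLC(ph4$volume, ph4$config$ventricleMask, ph4$config$lcSlices,
                "left", ph4$config$tegmentum$left, ph4$config$tgDiameter,
                midlineRow = ph4$config$midlineRow,
                referenceSD = ph4$config$referenceSD)
    out$t4 <- list(value = lc$value, n = nrow(lc$perSlice))

    # two-point R2* round trip at the PD contralateral mean
    de <- dualEchoPhantom(r2sSN = c(41.17, 41.17), te = c(9.2, 23),
                          noiseSD = 0, seed = seed)
    r2map <- fitR2Star(de$te1Volume, de$te2Volume, de$te[1], de$te[2])
    r2roi <- sampleSnRois(r2map, de$masks)
    out$t5 <- list(value = r2roi$mean[r2roi$side == "left"],
                   n = r2roi$voxels[r2roi$side == "left"])

    # ROC of contralateral SN volume on large synthetic cohorts
    coh <- simulateCohort(nPD = nPerGroup, nHC = nPerGroup, seed = seed)
    roc <- rocAnalysis(coh, "sn_volume_contra", direction = "lower")
    out$t7 <- list(value = auc(roc), n = 2L * nPerGroup)
    cls <- classifyAtCutoff(coh, "sn_volume_contra", 292,
                            direction = "lower")
    out$t8 <- list(value = cls$sensitivity, n = 2L * nPerGroup)
    out$t9 <- list(value = cls$specificity, n = 2L * nPerGroup)
    out$t10 <- list(value = cls$accuracy, n = 2L * nPerGroup)
    out
}
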