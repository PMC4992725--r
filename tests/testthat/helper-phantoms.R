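# Shared fixtures, all generated in code.

# Noise-free NM phantom at the default study geometry.
quietPhantom <- function(...) nmPhantom(noiseSD = 0, seed = 1, ...)

# Run the threshold-segmentation chain on one side of a phantom and return
# the segmentation plus the per-slice background stats used.
segmentPhantomSide <- function(ph, side = "left") {
    cfg <- ph$config
    d <- dim(ph$volume)
    maps <- list(); bgs <- list()
    for (sl in cfg$snSlices) {
        bg <- regionStats(ph$volume,
                          roiSpec(sl, cfg$crus[[side]], cfg$crusDiameter, side))
        if (regionSD(bg) == 0)
            bg <- makeRegionStats(regionMean(bg), cfg$referenceSD, regionN(bg))
        bgs[[as.character(sl)]] <- bg
        search <- matrix(FALSE, d[1], d[2])
        box <- cfg$searchBox[[side]]
        search[box[1]:box[2], box[3]:box[4]] <- TRUE
        maps[[as.character(sl)]] <- binaryMap(ph$volume, bg, sl, side, search,
                                              midlineRow = cfg$midlineRow)
    }
    list(seg = segmentSN(maps, spacing(ph$volume)), bgs = bgs)
}

# Tiny volume with a rectangular "ventricle" for LC localisation tests.
lcTestVolume <- function(plane, ventRows = 8:12, ventCols = 12:15) {
    d <- dim(plane)
    vol <- imageVolume(array(plane, c(d, 1)))
    vent <- array(FALSE, c(d, 1))
    vent[ventRows, ventCols, 1] <- TRUE
    list(vol = vol, vent = vent)
}
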