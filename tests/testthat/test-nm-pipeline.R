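test_that("region statistics use the population SD", {
    vol <- imageVolume(array(c(98, 100, 102), c(3, 1, 1)))
    st <- regionStats(vol, roiSpec(1, side = "left", mask = matrix(TRUE, 3, 1)))
    expect_equal(regionMean(st), 100)
    expect_equal(regionSD(st), sqrt(8 / 3), tolerance = 1e-12)  # 1.633
    expect_equal(regionN(st), 3L)
    cvol <- imageVolume(array(7, c(4, 4, 1)))
    cst <- regionStats(cvol, roiSpec(1, side = "left",
                                     mask = matrix(TRUE, 4, 4)))
    expect_equal(regionMean(cst), 7); expect_equal(regionSD(cst), 0)
})

test_that("circular crus ROI recovers the nominal background distribution", {
    ph <- nmPhantom(noiseSD = 10, seed = 21)
    st <- regionStats(ph$volume, roiSpec(ph$config$snSlices[2],
                                         ph$config$crus$left,
                                         ph$config$crusDiameter, "left"))
    expect_gte(regionN(st), 45)
    expect_lt(abs(regionMean(st) - 100), 6)
    expect_lt(abs(regionSD(st) - 10), 4)
    # circle fully outside the grid is rejected
    expect_error(regionStats(ph$volume, roiSpec(1, c(2, 2), 4, "left")),
                 "outside")
})

test_that("threshold is MN + 3 SD with a strict inequality", {
    vol <- imageVolume(array(c(130, 130.1, 129.9, 100), c(4, 1, 1)))
    bg <- makeRegionStats(100, 10, 50)
    m <- binaryMap(vol, bg, 1, side = NULL)
    expect_identical(as.vector(m), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("false-positive fraction on pure noise matches the Gaussian tail", {
    set.seed(6)
    n <- 3e5
    vol <- imageVolume(array(rnorm(n, 100, 10), c(500, 600, 1)))
    m <- binaryMap(vol, makeRegionStats(100, 10, 50), 1, side = NULL)
    p <- mean(m)
    expect_lt(abs(p - pnorm(-3)), 4 * sqrt(pnorm(-3) / n))  # ~0.00135
})

test_that("segmentation keeps the largest in-plane 8-connected component", {
    m <- matrix(FALSE, 20, 20)
    m[2:9, 2:6] <- TRUE               # 40 voxels
    m[15 + 0:1, 15] <- TRUE; m[15, 16] <- TRUE  # 3 voxels, diagonal-joined
    expect_warning(seg <- segmentSN(list(`5` = m), spacing = c(0.5, 0.5, 3)),
                   "1 slice")
    expect_equal(seg$voxels, 40L)
    # single isolated voxel has the volume of one voxel
    s1 <- matrix(FALSE, 5, 5); s1[3, 3] <- TRUE
    expect_warning(seg1 <- segmentSN(list(`1` = s1), c(0.5, 0.5, 3)))
    expect_equal(seg1$volume, 0.75)
    # diagonal-only contact is one component (8-connectivity)
    diagm <- matrix(FALSE, 6, 6)
    diagm[cbind(1:4, 1:4)] <- TRUE
    expect_warning(sd_ <- segmentSN(list(`1` = diagm), c(1, 1, 1)))
    expect_equal(sd_$voxels, 4L)
})

test_that("window selection takes the best four consecutive slices and flags empty sides", {
    blob <- function(k) { m <- matrix(FALSE, 12, 12); if (k) m[2:(1 + k), 2] <- TRUE; m }
    masks <- list(`3` = blob(1), `4` = blob(5), `5` = blob(5), `6` = blob(5),
                  `7` = blob(5), `8` = blob(2))
    seg <- segmentSN(masks, c(1, 1, 1))
    expect_equal(seg$slices, 4:7)
    expect_equal(seg$voxels, 20L)
    none <- segmentSN(list(`4` = blob(0), `5` = blob(0)), c(1, 1, 1))
    expect_true(none$missing)
    expect_true(is.na(none$volume))
})

test_that("noise-free phantom recovery is exact for volume and CNR", {
    ph <- quietPhantom(snVolume = c(236, 236), snCNR = c(4.28, 4.28))
    side <- segmentPhantomSide(ph, "left")
    trueMask <- ph$labels == 1L
    expect_lt(abs(side$seg$volume - 236), voxelVolume(ph$volume))
    expect_equal(side$seg$voxels, sum(trueMask))
    cnr <- cnrSN(ph$volume, side$seg, side$bgs)
    expect_equal(cnr$value, 4.28, tolerance = 1e-9)
    # a region at the reference mean has CNR 0
    flat <- cnrSN(imageVolume(array(100, dim(ph$volume)), spacing(ph$volume)),
                  side$seg, makeRegionStats(100, 10, 49))
    expect_equal(flat$value, 0)
})

test_that("segmented volume is monotone non-increasing in the threshold multiplier", {
    ph <- nmPhantom(noiseSD = 10, seed = 31)
    cfg <- ph$config
    bg <- regionStats(ph$volume, roiSpec(cfg$snSlices[2], cfg$crus$left,
                                         cfg$crusDiameter, "left"))
    for (sl in cfg$snSlices) {
        m3 <- binaryMap(ph$volume, bg, sl, "left", k = 3)
        m4 <- binaryMap(ph$volume, bg, sl, "left", k = 4)
        expect_true(all(m3 | !m4))  # m4 subset of m3
    }
})

test_that("CNR of SN and LC is invariant under positive affine rescaling", {
    ph <- nmPhantom(noiseSD = 10, seed = 41)
    a <- 3.7; b <- 120
    ph2 <- ph
    ph2$volume <- imageVolume(a * imageData(ph$volume) + b,
                              spacing(ph$volume))
    for (p in list(ph, ph2)) {
        side <- segmentPhantomSide(p, "left")
        val <- cnrSN(p$volume, side$seg, side$bgs)$value
        if (identical(p, ph)) v1 <- val else v2 <- val
    }
    expect_equal(v1, v2, tolerance = 1e-9)
    l1 <- cnrLC(ph$volume, ph$config$ventricleMask, ph$config$lcSlices,
                "left", ph$config$tegmentum$left)$value
    l2 <- cnrLC(ph2$volume, ph2$config$ventricleMask, ph2$config$lcSlices,
                "left", ph2$config$tegmentum$left)$value
    expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("degenerate background is an error for CNR", {
    ph <- quietPhantom()
    side <- segmentPhantomSide(ph, "left")
    expect_error(cnrSN(ph$volume, side$seg,
                       makeRegionStats(100, 0, 10)), "degenerate")
})

test_that("LC localisation takes the band arg-max with a row-major tie-break", {
    plane <- matrix(100, 20, 20)
    fx <- lcTestVolume(plane)
    # two equal maxima in the band: smaller row wins
    p2 <- plane; p2[6, 13] <- 150; p2[7, 14] <- 150
    fx2 <- lcTestVolume(p2)
    pt <- locateLC(fx2$vol, fx2$vent, 1, "left", midlineRow = 20)
    expect_equal(unname(pt), c(6, 13))
    # a voxel inside the ventricle is never selected
    p3 <- plane; p3[9, 13] <- 500; p3[6, 12] <- 120
    fx3 <- lcTestVolume(p3)
    expect_equal(unname(locateLC(fx3$vol, fx3$vent, 1, "left",
                                 midlineRow = 20)), c(6, 12))
    expect_error(locateLC(fx$vol, array(FALSE, c(20, 20, 1)), 1, "left"),
                 "empty")
})

test_that("LC arg-max is uniform on a noise-only band", {
    plane0 <- matrix(0, 16, 16)
    fx <- lcTestVolume(plane0, ventRows = 6:10, ventCols = 6:10)
    band <- which(nigrascan:::chebyshevBand(fx$vent[, , 1], 2))
    counts <- integer(length(band))
    set.seed(17)
    for (i in 1:1000) {
        vol <- imageVolume(array(rnorm(256), c(16, 16, 1)))
        pt <- locateLC(vol, fx$vent, 1, "left", midlineRow = 16)
        j <- match(pt[1] + 16 * (pt[2] - 1), band)
        counts[j] <- counts[j] + 1L
    }
    expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("noise-free LC contrast is recovered exactly from the 5-voxel cross", {
    ph <- quietPhantom(lcCNR = c(3.54, 3.54))
    lc <- cnrLC(ph$volume, ph$config$ventricleMask, ph$config$lcSlices,
                "left", ph$config$tegmentum$left,
                referenceSD = ph$config$referenceSD)
    expect_equal(lc$value, 3.54, tolerance = 1e-6)
    # LC intensity equal to the tegmentum mean gives CNR 0
    ph0 <- quietPhantom(lcCNR = c(0, 0))
    lc0 <- cnrLC(ph0$volume, ph0$config$ventricleMask, ph0$config$lcSlices,
                 "left", ph0$config$tegmentum$left,
                 referenceSD = ph0$config$referenceSD)
    expect_lt(abs(lc0$value), 1e-6)
})

test_that("an LC_MAX on the grid edge uses the available abutting voxels with a warning", {
    plane <- matrix(0, 6, 10)
    plane[1, 4] <- 10; plane[1, 3] <- 4; plane[1, 5] <- 4; plane[2, 4] <- 4
    expect_warning(v <- nigrascan:::lcIntensity(plane, c(1L, 4L)), "edge")
    expect_equal(v, mean(c(10, 4, 4, 4)))
})

test_that("percent CNR normalises to the healthy-control median", {
    expect_equal(percentCNR(4.89, 4.89), 100)
    expect_equal(percentCNR(3.54, 4.89), 72.392638, tolerance = 1e-6)
    expect_true(percentCNR(3, 4.89) < percentCNR(3.5, 4.89))  # monotone
    expect_error(percentCNR(3, 0), "median")
})

test_that("asymmetry index follows the 0-200 convention", {
    expect_equal(asymmetryIndex(2, 2), 0)
    expect_equal(asymmetryIndex(2.06, 1.60), 25.136612, tolerance = 1e-6)
    expect_equal(asymmetryIndex(3, 0), 200)
    x <- runif(20, 0.1, 5); y <- runif(20, 0.1, 5)
    expect_equal(asymmetryIndex(x, y), asymmetryIndex(y, x))  # side swap
    expect_true(all(asymmetryIndex(x, y) >= 0 & asymmetryIndex(x, y) <= 200))
    expect_error(asymmetryIndex(0, 0), "zero")
    expect_error(asymmetryIndex(-1, 2), "non-negative")
})

test_that("repeat averaging uses the sample SD", {
    r <- averageRepeats(c(4.0, 4.2, 4.4, 4.6))
    expect_equal(r$mean, 4.3)
    expect_equal(r$sd, 0.2581989, tolerance = 1e-6)
    expect_equal(averageRepeats(c(5, 5, 5))$sd, 0)
    expect_error(averageRepeats(4), "repeats")
})

test_that("repeated measurement with ROI jitter is stable on a noisy phantom", {
    ph <- nmPhantom(noiseSD = 10, seed = 51)
    m <- measureNM(ph$volume, ph$config, repeats = 4, seed = 13)
    s <- m$summary
    for (mm in c("volume_mm3", "cnr_sn")) {
        row <- s[s$side == "left" & s$measure == mm, ]
        expect_lt(row$sd / row$mean, 0.05)
    }
    # determinism of the full measurement under a fixed seed
    m2 <- measureNM(ph$volume, ph$config, repeats = 4, seed = 13)
    expect_identical(m$summary, m2$summary)
})
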