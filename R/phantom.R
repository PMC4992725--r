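#' Synthetic neuromelanin-MRI phantom with known ground truth
#'
#' Builds a midbrain/pons slab emulating the anatomy a neuromelanin-sensitive
#' scan is analysed on: two hyperintense substantia nigra (SN) ellipsoids
#' spanning four consecutive slices, a dark rectangular fourth ventricle over
#' three pontine slices flanked by single-voxel-wide locus coeruleus (LC)
#' columns (a 5-voxel in-plane cross per slice), and signal-neutral cerebral
#' crus and pontine tegmentum cylinders that serve as reference-ROI
#' locations.  Structure intensity is `bgMean + CNR * bgSD` plus additive
#' Gaussian noise of SD `noiseSD`; the returned integer label volume is the
#' exact ground truth.
#'
#' The SN voxel set is the `round(volume / voxelVolume)` voxels closest to the
#' structure centre in normalised ellipsoid distance, so the realised volume
#' is within half a voxel of the request.  The LC cross centre is raised by
#' `1e-9 * bgSD` so that the arg-max localisation is unambiguous even in
#' noise-free images (the perturbation is orders of magnitude below any
#' reported precision).
#'
#' @param snVolume length-2 numeric, target SN volume in mm^3 (left, right).
#' @param snCNR length-2 numeric, SN contrast in background-SD units.
#' @param lcCNR length-2 numeric, LC contrast in background-SD units.
#' @param ventricleCNR ventricle contrast (negative: CSF is dark on NM-MRI).
#' @param bgMean,bgSD nominal background mean and SD (arbitrary units); `bgSD`
#'   is the intensity scale contrast is expressed in.
#' @param noiseSD SD of the additive Gaussian noise (default `bgSD`; 0 gives
#'   a noise-free phantom).
#' @param dim grid size in voxels (3 axes).
#' @param spacing voxel spacing in mm; default the anisotropic
#'   0.5 x 0.5 x 3.0 mm NM-MRI grid.
#' @param seed RNG seed; identical spec and seed give bit-identical output.
#' @return A list of class `nmPhantom`: `volume` ([ImageVolume-class]),
#'   `labels` (integer array, codes in `structures$code`), `structures`
#'   (data.frame of id, code, voxel count, realised volume, CNR), `config`
#'   (measurement configuration consumed by [measureNM()]), and the scalar
#'   parameters.
#' @examples
#' ph <- nmPhantom(snVolume = c(236, 236), noiseSD = 0)
#' ph$structures
#' @export
nmPhantom <- function(snVolume = c(236, 236), snCNR = c(4.28, 4.28),
                      lcCNR = c(3.54, 3.54), ventricleCNR = -2,
                      bgMean = 100, bgSD = 10, noiseSD = bgSD,
                      dim = c(96, 96, 12), spacing = c(0.5, 0.5, 3.0),
                      seed = 1) {
    stopIfNot(all(spacing > 0), "voxel spacing must be > 0")
    stopIfNot(all(snVolume > 0), "target SN volumes must be > 0")
    stopIfNot(bgSD > 0, "background SD must be > 0")
    stopIfNot(noiseSD >= 0, "noise SD must be >= 0")
    stopIfNot(all(dim >= c(48, 48, 10)), "grid too small for the geometry")
    d1 <- dim[1]; d2 <- dim[2]; d3 <- dim[3]
    vox <- prod(spacing)

    geom <- nmGeometry(dim)
    labels <- array(0L, dim)
    codes <- c(SN_left = 1L, SN_right = 2L, LC_left = 3L, LC_right = 4L,
               crus_left = 5L, crus_right = 6L, tegmentum_left = 7L,
               tegmentum_right = 8L, fourth_ventricle = 9L)

    paint <- function(idx, id) {
        # idx: matrix (row, col, slice)
        stopIfNot(all(idx[, 1] >= 1 & idx[, 1] <= d1 &
                      idx[, 2] >= 1 & idx[, 2] <= d2 &
                      idx[, 3] >= 1 & idx[, 3] <= d3),
                  "structure '%s' exceeds grid bounds", id)
        lin <- idx[, 1] + d1 * (idx[, 2] - 1) + d1 * d2 * (idx[, 3] - 1)
        hit <- labels[lin] != 0L
        stopIfNot(!any(hit), "structure '%s' overlaps structure '%s'", id,
                  names(codes)[if (any(hit)) labels[lin][hit][1] else 1])
        labels[lin] <<- codes[[id]]
        lin
    }

    # SN ellipsoids: exactly round(volume / voxel) voxels nearest the centre
    snLin <- list()
    for (s in c("left", "right")) {
        i <- if (s == "left") 1L else 2L
        n <- round(snVolume[i] / vox)
        ctr <- geom$snCenter[[s]]
        ax <- geom$snAxes
        cand <- expand.grid(
            row = max(1, floor(ctr[1] - ax[1])):min(d1, ceiling(ctr[1] + ax[1])),
            col = max(1, floor(ctr[2] - ax[2])):min(d2, ceiling(ctr[2] + ax[2])),
            slice = geom$snSlices)
        zc <- mean(range(geom$snSlices))
        dd <- ((cand$row - ctr[1]) / ax[1])^2 + ((cand$col - ctr[2]) / ax[2])^2 +
              ((cand$slice - zc) / ax[3])^2
        ord <- order(dd, cand$slice, cand$row, cand$col)
        stopIfNot(n <= sum(dd <= 1),
                  "structure 'SN_%s' target volume too large for the geometry", s)
        sel <- as.matrix(cand[ord[seq_len(n)], c("row", "col", "slice")])
        snLin[[s]] <- paint(sel, paste0("SN_", s))
    }

    # crus and tegmentum cylinders (contrast 0: reference-ROI locations)
    cylinder <- function(ctr, radius, slices) {
        g <- expand.grid(row = (ctr[1] - radius):(ctr[1] + radius),
                         col = (ctr[2] - radius):(ctr[2] + radius),
                         slice = slices)
        g <- g[(g$row - ctr[1])^2 + (g$col - ctr[2])^2 <= radius^2, ]
        as.matrix(g)
    }
    for (s in c("left", "right")) {
        paint(cylinder(geom$crusCenter[[s]], geom$crusRadius, geom$snSlices),
              paste0("crus_", s))
        paint(cylinder(geom$tgCenter[[s]], geom$tgRadius, geom$lcSlices),
              paste0("tegmentum_", s))
    }

    # fourth ventricle rectangle
    vr <- geom$ventricleRows; vc <- geom$ventricleCols
    vent <- as.matrix(expand.grid(row = vr[1]:vr[2], col = vc[1]:vc[2],
                                  slice = geom$lcSlices))
    paint(vent, "fourth_ventricle")

    # LC crosses (5 voxels per slice); centre kept for the epsilon bump
    lcCenterLin <- list()
    for (s in c("left", "right")) {
        ctr <- geom$lcCenter[[s]]
        cross <- rbind(c(ctr[1], ctr[2]), c(ctr[1] - 1, ctr[2]),
                       c(ctr[1] + 1, ctr[2]), c(ctr[1], ctr[2] - 1),
                       c(ctr[1], ctr[2] + 1))
        idx <- cbind(cross[rep(seq_len(5), length(geom$lcSlices)), ],
                     rep(geom$lcSlices, each = 5))
        paint(idx, paste0("LC_", s))
        lcCenterLin[[s]] <- ctr[1] + d1 * (ctr[2] - 1) +
            d1 * d2 * (geom$lcSlices - 1)
    }

    # intensities
    cnrOf <- c(snCNR[1], snCNR[2], lcCNR[1], lcCNR[2], 0, 0, 0, 0,
               ventricleCNR)
    img <- array(bgMean, dim)
    inside <- labels != 0L
    img[inside] <- bgMean + cnrOf[labels[inside]] * bgSD
    img[unlist(lcCenterLin)] <- img[unlist(lcCenterLin)] + 1e-9 * bgSD
    if (noiseSD > 0)
        img <- img + withSeed(seed, array(stats::rnorm(prod(dim), 0, noiseSD),
                                          dim))

    structures <- data.frame(
        id = names(codes), code = unname(codes),
        voxels = vapply(codes, function(k) sum(labels == k), integer(1)),
        cnr = cnrOf, row.names = NULL)
    structures$volume_mm3 <- structures$voxels * vox

    config <- list(
        snSlices = max(1, geom$snSlices[1] - 1):min(d3, geom$snSlices[4] + 1),
        searchBox = geom$searchBox,
        crus = geom$crusCenter, crusDiameter = 4,
        lcSlices = geom$lcSlices,
        tegmentum = geom$tgCenter, tgDiameter = 6,
        ventricleMask = labels == codes[["fourth_ventricle"]],
        midlineRow = d1 / 2,
        referenceSD = bgSD)

    structure(list(volume = imageVolume(img, spacing), labels = labels,
                   structures = structures, config = config, bgMean = bgMean,
                   bgSD = bgSD, noiseSD = noiseSD, seed = seed),
              class = "nmPhantom")
}

# Fixed phantom geometry, scaled to the grid (voxel coordinates).
nmGeometry <- function(dim) {
    d1 <- dim[1]; d2 <- dim[2]; d3 <- dim[3]
    zc <- round(d3 / 2)
    snSlices <- zc:(zc + 3)
    vr <- c(round(0.458 * d1), round(0.552 * d1))
    vc <- c(round(0.625 * d2), round(0.688 * d2))
    list(
        snSlices = snSlices,
        snCenter = list(left = c(round(0.396 * d1), round(0.5 * d2)),
                        right = c(d1 + 1 - round(0.396 * d1), round(0.5 * d2))),
        snAxes = c(8, 12, 2.6) * dim / c(96, 96, 12),
        crusCenter = list(left = c(round(0.21 * d1), round(0.31 * d2)),
                          right = c(d1 + 1 - round(0.21 * d1), round(0.31 * d2))),
        crusRadius = max(5, round(0.0625 * d1)),
        lcSlices = 2:4,
        tgCenter = list(left = c(round(0.354 * d1), round(0.52 * d2)),
                        right = c(d1 + 1 - round(0.354 * d1), round(0.52 * d2))),
        tgRadius = max(7, round(0.083 * d1)),
        ventricleRows = vr, ventricleCols = vc,
        lcCenter = list(left = c(vr[1] - 2, round(mean(vc))),
                        right = c(vr[2] + 2, round(mean(vc)))),
        searchBox = list(
            left = c(round(0.29 * d1), floor(d1 / 2), round(0.35 * d2),
                     round(0.65 * d2)),
            right = c(floor(d1 / 2) + 1, d1 + 1 - round(0.29 * d1),
                      round(0.35 * d2), round(0.65 * d2))))
}

#' Synthetic dual-echo gradient-echo magnitude pair
#'
#' Generates the two magnitude volumes of a dual-echo gradient-echo
#' acquisition over a slab containing two SN ellipsoids with a prescribed
#' apparent transverse relaxation rate R2*, on a background with its own R2*.
#' Voxel signal is `s0 * exp(-R2* * TE)` (TE in seconds) plus optional
#' additive Gaussian noise, so noise-free voxels satisfy the mono-exponential
#' decay law exactly and the two-point fit of [fitR2Star()] recovers the
#' ground truth to machine precision.
#'
#' @param r2sSN length-2 numeric, true SN R2* in 1/s (left, right).
#' @param r2sBackground background R2* in 1/s.
#' @param s0 baseline signal at TE = 0 (arbitrary units, > 0).
#' @param te echo times TE1 < TE2 in ms.
#' @param noiseSD additive noise SD.
#' @param dim,spacing grid size and voxel spacing (default isotropic 1 mm).
#' @param seed RNG seed.
#' @return List of class `dualEchoPhantom`: `te1Volume`, `te2Volume`
#'   ([ImageVolume-class]), `te` (ms), `labels`, `masks` (per-side logical
#'   arrays), `r2Truth` (array of true rates).
#' @examples
#' ph <- dualEchoPhantom(r2sSN = c(41.17, 41.17), noiseSD = 0)
#' range(ph$r2Truth[ph$masks$left])
#' @export
dualEchoPhantom <- function(r2sSN = c(41.17, 41.17), r2sBackground = 20,
                            s0 = 1000, te = c(9.2, 23), noiseSD = 0,
                            dim = c(64, 64, 16), spacing = c(1, 1, 1),
                            seed = 1) {
    stopIfNot(s0 > 0, "baseline signal s0 must be > 0")
    stopIfNot(length(te) == 2 && te[1] > 0 && te[1] < te[2],
              "echo times must satisfy 0 < TE1 < TE2")
    stopIfNot(all(c(r2sSN, r2sBackground) >= 0), "R2* must be >= 0")
    labels <- ironLabels(dim)
    r2 <- array(r2sBackground, dim)
    r2[labels == 1L] <- r2sSN[1]
    r2[labels == 2L] <- r2sSN[2]
    sig <- function(teMS) s0 * exp(-r2 * teMS / 1000)
    v1 <- sig(te[1]); v2 <- sig(te[2])
    if (noiseSD > 0) {
        noise <- withSeed(seed, array(stats::rnorm(2 * prod(dim), 0, noiseSD),
                                      c(dim, 2)))
        v1 <- v1 + noise[, , , 1]; v2 <- v2 + noise[, , , 2]
    }
    structure(list(te1Volume = imageVolume(v1, spacing),
                   te2Volume = imageVolume(v2, spacing),
                   te = te, labels = labels,
                   masks = list(left = labels == 1L, right = labels == 2L),
                   r2Truth = r2),
              class = "dualEchoPhantom")
}

# SN label geometry shared by the iron-phantom generators:
# two ellipsoids across six slices (1 = left, 2 = right).
ironLabels <- function(dim) {
    d1 <- dim[1]; d2 <- dim[2]; d3 <- dim[3]
    stopIfNot(d3 >= 8, "iron phantom needs >= 8 slices")
    z0 <- max(2, round(d3 / 2) - 3)
    slices <- z0:(z0 + 5)
    labels <- array(0L, dim)
    ax <- c(5, 8, 3.2) * dim / c(64, 64, 16)
    for (s in c("left", "right")) {
        ctr <- c(if (s == "left") round(0.37 * d1) else d1 + 1 - round(0.37 * d1),
                 round(0.5 * d2))
        g <- expand.grid(row = 1:d1, col = 1:d2, slice = slices)
        dd <- ((g$row - ctr[1]) / ax[1])^2 + ((g$col - ctr[2]) / ax[2])^2 +
              ((g$slice - mean(range(slices))) / ax[3])^2
        g <- g[dd <= 1, ]
        labels[cbind(g$row, g$col, g$slice)] <- if (s == "left") 1L else 2L
    }
    labels
}

#' Synthetic magnetic-susceptibility map
#'
#' A stand-in for a quantitative susceptibility map produced by dipole
#' inversion: SN voxels take the prescribed susceptibility (ppm), the
#' background a reference value (default 0 ppm), plus optional Gaussian
#' noise.  Uses the same SN geometry as [dualEchoPhantom()].
#'
#' @param snPPM length-2 numeric, SN susceptibility in ppm (left, right).
#' @param backgroundPPM background susceptibility.
#' @param noiseSD additive noise SD (ppm).
#' @param dim,spacing,seed as in [dualEchoPhantom()].
#' @return List of class `susceptibilityPhantom`: `map` (a
#'   [QuantMap-class] of kind `"susceptibility"`), `labels`, `masks`.
#' @export
susceptibilityPhantom <- function(snPPM = c(0.16, 0.16), backgroundPPM = 0,
                                  noiseSD = 0, dim = c(64, 64, 16),
                                  spacing = c(1, 1, 1), seed = 1) {
    stopIfNot(noiseSD >= 0, "noise SD must be >= 0")
    labels <- ironLabels(dim)
    chi <- array(backgroundPPM, dim)
    chi[labels == 1L] <- snPPM[1]
    chi[labels == 2L] <- snPPM[2]
    if (noiseSD > 0)
        chi <- chi + withSeed(seed, array(stats::rnorm(prod(dim), 0, noiseSD),
                                          dim))
    map <- new("QuantMap", kind = "susceptibility", data = chi,
               valid = array(TRUE, dim), spacing = as.numeric(spacing),
               nClamped = 0L)
    structure(list(map = map, labels = labels,
                   masks = list(left = labels == 1L, right = labels == 2L)),
              class = "susceptibilityPhantom")
}

#' Group distribution parameters for the synthetic cohort
#'
#' Per-measure mean and SD for the Parkinson's disease (PD) and healthy
#' control (HC) groups used as the defaults of [simulateCohort()]: striatal
#' DAT binding (putamen and caudate, contralateral/ipsilateral to the worse
#' hemibody), SN volume (mm^3), CNR of SN and LC, SN R2* (1/s) and SN
#' susceptibility (ppm).
#'
#' @return data.frame with columns `measure`, `pd_mean`, `pd_sd`, `hc_mean`,
#'   `hc_sd`.
#' @export
cohortParameters <- function() {
    data.frame(
        measure = c("putamen_contra", "putamen_ipsi", "caudate_contra",
                    "caudate_ipsi", "sn_volume_contra", "sn_volume_ipsi",
                    "cnr_sn_contra", "cnr_sn_ipsi", "cnr_lc_contra",
                    "cnr_lc_ipsi", "r2star_contra", "r2star_ipsi",
                    "susceptibility_contra", "susceptibility_ipsi"),
        pd_mean = c(1.60, 2.06, 2.97, 3.28, 236, 283, 4.28, 4.42, 3.54, 3.85,
                    41.17, 43.30, 0.16, 0.15),
        pd_sd   = c(0.67, 0.75, 1.02, 0.97, 50, 84, 0.41, 0.45, 0.87, 0.96,
                    10.96, 10.01, 0.05, 0.05),
        hc_mean = c(4.60, 4.65, 4.92, 4.94, 344, 362, 4.91, 4.83, 4.89, 5.07,
                    37.47, 39.09, 0.13, 0.13),
        hc_sd   = c(0.83, 0.83, 0.98, 0.96, 51, 60, 0.38, 0.37, 0.61, 0.47,
                    5.16, 5.74, 0.05, 0.03))
}

#' Simulate a PD / HC cohort of per-subject measurements
#'
#' Draws one row per subject with every imaging and SPECT measure sampled from
#' its group distribution, truncated at zero (volumes, contrasts and binding
#' values are physically non-negative).  Within the PD group, contralateral SN
#' volume and contralateral putamen DAT binding are coupled through a Gaussian
#' copula at a prescribed Spearman rank correlation (the coupling is
#' rank-based because downstream correlation analysis is Spearman); the
#' Pearson parameter of the copula is `2 * sin(pi * rho / 6)`.  Asymmetry
#' indices are derived from the drawn side pairs with [asymmetryIndex()], so
#' the per-side margins are imposed and the AI margins implied.  Clinical
#' covariates (age, disease duration, UPDRS-III, akinetic-rigid subscore) are
#' drawn from rounded normal distributions consistent with the cohort
#' summaries of the study population.
#'
#' @param nPD,nHC group sizes (each >= 2).
#' @param params group distribution table as returned by [cohortParameters()].
#' @param rhoSNvolDAT target Spearman correlation between contralateral SN
#'   volume and contralateral putamen DAT within PD (|rho| <= 1).
#' @param seed RNG seed.
#' @return data.frame with `subject_id`, `group`, `ipsi_side`, one column per
#'   measure, derived `ai_*` columns and clinical covariates.
#' @examples
#' coh <- simulateCohort(nPD = 18, nHC = 18, seed = 7)
#' aggregate(sn_volume_contra ~ group, coh, mean)
#' @export
simulateCohort <- function(nPD = 18, nHC = 18, params = cohortParameters(),
                           rhoSNvolDAT = 0.75, seed = 1) {
    stopIfNot(nPD >= 2 && nHC >= 2, "group sizes must be >= 2")
    stopIfNot(abs(rhoSNvolDAT) <= 1,
              "target rank correlation must be in [-1, 1]")
    stopIfNot(all(params$pd_sd > 0) && all(params$hc_sd > 0),
              "group SDs must be > 0")
    withSeed(seed, {
        rows <- lapply(c("PD", "HC"), function(g) {
            n <- if (g == "PD") nPD else nHC
            mu <- if (g == "PD") params$pd_mean else params$hc_mean
            sg <- if (g == "PD") params$pd_sd else params$hc_sd
            u <- matrix(stats::runif(n * nrow(params)), n)
            colnames(u) <- params$measure
            if (g == "PD") {
                r <- 2 * sin(pi * rhoSNvolDAT / 6)
                z1 <- stats::rnorm(n)
                z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
                u[, "sn_volume_contra"] <- stats::pnorm(z1)
                u[, "putamen_contra"] <- stats::pnorm(z2)
            }
            x <- vapply(seq_len(nrow(params)),
                        function(j) qtruncnorm0(u[, j], mu[j], sg[j]),
                        numeric(n))
            colnames(x) <- params$measure
            df <- as.data.frame(x)
            df$group <- g
            df$ipsi_side <- if (g == "PD")
                sample(c("left", "right"), n, replace = TRUE) else "right"
            df$age <- round(pmin(pmax(stats::rnorm(n, 62, 8), 44), 78))
            df$disease_duration <- if (g == "PD")
                round(pmax(stats::rnorm(n, 7, 3.5), 3)) else NA_real_
            df$updrs3 <- if (g == "PD")
                round(pmin(pmax(stats::rnorm(n, 14, 5), 5), 25)) else NA_real_
            df$updrs_ak <- if (g == "PD")
                round(pmin(pmax(stats::rnorm(n, 5, 2), 1), 8)) else NA_real_
            df
        })
        coh <- do.call(rbind, rows)
        coh$subject_id <- sprintf("S%03d", seq_len(nrow(coh)))
        for (m in c("putamen", "caudate", "sn_volume", "cnr_sn")) {
            coh[[paste0("ai_", m)]] <- asymmetryIndex(
                coh[[paste0(m, "_ipsi")]], coh[[paste0(m, "_contra")]])
        }
        first <- c("subject_id", "group", "ipsi_side")
        coh[, c(first, setdiff(names(coh), first))]
    })
}
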