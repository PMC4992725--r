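#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 file, validates that it is a finite 3-D scalar volume and
#' returns it with the voxel spacing taken from the header.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return An [ImageVolume-class].
#' @export
readVolume <- function(path) {
    stopIfNot(file.exists(path), "file not found: %s", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    stopIfNot(length(d) == 3L,
              "expected a 3-D volume, got %d dimensions in %s",
              length(d), path)
    arr <- structure(as.vector(img), dim = d)
    nBad <- sum(!is.finite(arr))
    stopIfNot(nBad == 0, "%d non-finite voxel(s) in %s", nBad, path)
    imageVolume(arr, RNifti::pixdim(img)[1:3])
}

#' Write an ImageVolume to NIfTI
#'
#' @param vol an [ImageVolume-class] (or integer label array with a
#'   `spacing` attribute supplied via `spacing`).
#' @param path destination `.nii` / `.nii.gz` path.
#' @param spacing voxel spacing override (mm).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, spacing = NULL) {
    if (is(vol, "ImageVolume")) {
        arr <- vol@data
        sp <- spacing %||% vol@spacing
    } else {
        arr <- vol
        sp <- spacing %||% c(1, 1, 1)
    }
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read / write a cohort table
#'
#' Cohort CSVs carry one row per subject with a header row; `subject_id` and
#' `group` columns are required.
#'
#' @param path CSV path.
#' @return data.frame of subject records.
#' @export
readCohort <- function(path) {
    stopIfNot(file.exists(path), "file not found: %s", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("subject_id", "group"), names(d))
    stopIfNot(length(miss) == 0, "cohort CSV %s lacks column(s): %s", path,
              paste(miss, collapse = ", "))
    d
}

#' @rdname readCohort
#' @param data data.frame of subject records.
#' @export
writeCohort <- function(data, path) {
    utils::write.csv(data, path, row.names = FALSE)
    invisible(path)
}

#' Read and validate a pipeline run configuration
#'
#' YAML configuration for [runPipeline()].  Validates that seeds are
#' integers and that every referenced file exists.
#'
#' @param path YAML path.
#' @return Named list (the parsed configuration) with class `runConfig`.
#' @export
readRunConfig <- function(path) {
    stopIfNot(file.exists(path), "config file not found: %s", path)
    cfg <- yaml::read_yaml(path)
    stopIfNot(!is.null(cfg$seed), "config must declare a seed")
    stopIfNot(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
              "seed must be an integer, got '%s'", format(cfg$seed))
    for (sub in cfg$subjects) {
        for (f in c("nm_image", "mag1", "mag2", "susceptibility", "sn_mask",
                    "rois")) {
            p <- sub[[f]]
            if (!is.null(p))
                stopIfNot(file.exists(p), "config references missing file: %s", p)
        }
    }
    cfg$path <- path
    class(cfg) <- c("runConfig", "list")
    cfg
}

#' Run the full measurement and statistics pipeline
#'
#' Drives phantom generation (or image reading), the NM and iron measurement
#' chains per subject, cohort assembly and the statistical layer, writing
#' tidy CSV reports, a JSON ROC report and a manifest.  In `simulate` mode
#' each subject gets an NM phantom, a dual-echo pair and a susceptibility map
#' whose ground truth is drawn from the cohort generator; DAT binding enters
#' as tabular data from the same draw.  All randomness flows from the
#' configuration seed, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config a `runConfig` from [readRunConfig()], or a path to one, or
#'   an equivalent named list.
#' @param outDir output directory (created if needed); overrides the
#'   configuration's `output_dir`.
#' @return Invisibly, a list with the measured cohort, the statistics tables
#'   and the manifest.
#' @export
runPipeline <- function(config, outDir = NULL) {
    if (is.character(config)) config <- readRunConfig(config)
    outDir <- outDir %||% config$output_dir %||% stop("no output directory")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed)

    stopIfNot(!is.null(config$simulate), "only 'simulate' runs are configured here; provide a simulate block")
    sim <- config$simulate
    nPD <- sim$n_pd %||% 18; nHC <- sim$n_hc %||% 18
    noiseSD <- sim$noise_sd %||% 10
    ironNoise <- sim$iron_noise_sd %||% 5
    repeats <- sim$repeats %||% 2

    truth <- simulateCohort(nPD, nHC, seed = seed)
    rows <- list()
    for (i in seq_len(nrow(truth))) {
        tr <- truth[i, ]
        sid <- tr$subject_id
        toSide <- function(base) {
            ipsi <- tr[[paste0(base, "_ipsi")]]
            contra <- tr[[paste0(base, "_contra")]]
            if (tr$ipsi_side == "left") c(ipsi, contra) else c(contra, ipsi)
        }
        fromSide <- function(left, right, base) {
            out <- list()
            out[[paste0(base, "_ipsi")]] <-
                if (tr$ipsi_side == "left") left else right
            out[[paste0(base, "_contra")]] <-
                if (tr$ipsi_side == "left") right else left
            out
        }
        res <- tryCatch({
            ph <- nmPhantom(snVolume = toSide("sn_volume"),
                            snCNR = toSide("cnr_sn"), lcCNR = toSide("cnr_lc"),
                            noiseSD = noiseSD, seed = seed + 101L * i)
            nm <- measureNM(ph$volume, ph$config, repeats = repeats,
                            seed = seed + 101L * i + 1L)
            nm$summary
        }, error = function(e)
            stop(sprintf("nm_pipeline failed for subject %s: %s", sid,
                         conditionMessage(e)), call. = FALSE))
        iron <- tryCatch({
            de <- dualEchoPhantom(r2sSN = toSide("r2star"),
                                  noiseSD = ironNoise, seed = seed + 101L * i + 2L)
            r2map <- fitR2Star(de$te1Volume, de$te2Volume, de$te[1], de$te[2])
            r2a <- sampleSnRois(r2map, de$masks)
            r2b <- sampleSnRois(r2map, lapply(de$masks, jitterMask,
                                              seed = seed + 101L * i + 3L))
            r2 <- averageTwoRepeats(r2a, r2b)
            sp <- susceptibilityPhantom(snPPM = toSide("susceptibility"),
                                        noiseSD = 0.01,
                                        seed = seed + 101L * i + 4L)
            cha <- sampleSnRois(sp$map, sp$masks)
            chb <- sampleSnRois(sp$map, lapply(sp$masks, jitterMask,
                                               seed = seed + 101L * i + 5L))
            chi <- averageTwoRepeats(cha, chb)
            list(r2 = r2, chi = chi)
        }, error = function(e)
            stop(sprintf("iron_pipeline failed for subject %s: %s", sid,
                         conditionMessage(e)), call. = FALSE))
        get_ <- function(df, m, s) df$mean[df$side == s & df$measure == m]
        row <- data.frame(subject_id = sid, group = tr$group,
                          ipsi_side = tr$ipsi_side,
                          putamen_contra = tr$putamen_contra,
                          putamen_ipsi = tr$putamen_ipsi,
                          caudate_contra = tr$caudate_contra,
                          caudate_ipsi = tr$caudate_ipsi)
        for (b in c("sn_volume", "cnr_sn", "cnr_lc")) {
            m <- c(sn_volume = "volume_mm3", cnr_sn = "cnr_sn",
                   cnr_lc = "cnr_lc")[[b]]
            row <- cbind(row, fromSide(get_(res, m, "left"),
                                       get_(res, m, "right"), b))
        }
        row <- cbind(row,
                     fromSide(iron$r2$mean[iron$r2$side == "left"],
                              iron$r2$mean[iron$r2$side == "right"], "r2star"),
                     fromSide(iron$chi$mean[iron$chi$side == "left"],
                              iron$chi$mean[iron$chi$side == "right"],
                              "susceptibility"))
        rows[[i]] <- row
    }
    cohort <- do.call(rbind, rows)
    for (m in c("putamen", "caudate", "sn_volume", "cnr_sn"))
        cohort[[paste0("ai_", m)]] <- asymmetryIndex(
            cohort[[paste0(m, "_ipsi")]], cohort[[paste0(m, "_contra")]])

    gcMeasures <- unlist(config$group_compare) %||%
        c("sn_volume_contra", "cnr_sn_contra", "cnr_lc_contra")
    gc <- do.call(rbind, lapply(gcMeasures, function(m) {
        g <- groupCompare(cohort, m)
        data.frame(measure = m, U = g$U, p = g$p, method = g$method)
    }))
    battery <- config$battery %||% list(
        c("sn_volume_contra", "putamen_contra"),
        c("cnr_sn_contra", "putamen_contra"),
        c("cnr_lc_contra", "putamen_contra"))
    corr <- spearmanBattery(cohort[cohort$group == "PD", ],
                            lapply(battery, unlist))
    rocCfg <- config$roc %||% list(measure = "sn_volume_contra",
                                   direction = "lower")
    roc <- rocAnalysis(cohort, rocCfg$measure,
                       direction = rocCfg$direction %||% "lower")

    paths <- c(cohort = file.path(outDir, "cohort_measured.csv"),
               tests = file.path(outDir, "group_tests.csv"),
               correlations = file.path(outDir, "correlations.csv"),
               roc = file.path(outDir, "roc.json"))
    writeCohort(cohort, paths["cohort"])
    utils::write.csv(gc, paths["tests"], row.names = FALSE)
    utils::write.csv(corr, paths["correlations"], row.names = FALSE)
    jsonlite::write_json(list(auc = roc@auc, named = roc@named,
                              direction = roc@direction),
                         paths["roc"], auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    manifest <- list(
        package = "nigrascan",
        version = as.character(utils::packageVersion("nigrascan")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = seed,
        config_md5 = if (!is.null(config$path))
            unname(tools::md5sum(config$path)) else NA,
        outputs = lapply(paths, function(p)
            list(file = basename(p), md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(cohort = cohort, group_tests = gc, correlations = corr,
                   roc = roc, manifest = manifest))
}

# Shift a 3-D mask by one voxel along a random in-plane axis: a minimal model
# of a rater re-drawing the same ROI.
jitterMask <- function(mask, seed = NULL) {
    withSeed(seed, {
        ax <- sample(1:2, 1); dr <- sample(c(-1L, 1L), 1)
        out <- array(FALSE, dim(mask))
        d <- dim(mask)
        if (ax == 1) {
            rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
            out[rs, , ] <- mask[rs - dr, , ]
        } else {
            cs <- max(1, 1 + dr):min(d[2], d[2] + dr)
            out[, cs, ] <- mask[, cs - dr, ]
        }
        out
    })
}
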