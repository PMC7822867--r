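# End-to-end driver and NIfTI/CSV/YAML plumbing.

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving voxel spacing. `readVolume` errors
#' on non-3D images.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality modality tag for the returned [ImageVolume-class].
#' @return `readVolume`: an [ImageVolume-class].
#' @export
readVolume <- function(path, modality = "t2w") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI at ", path, ", got dims ",
         paste(d, collapse = "x"))
  sp <- RNifti::pixdim(img)[1:3]
  imageVolume(array(as.numeric(img), d), spacing = sp, modality = modality)
}

#' @rdname readVolume
#' @param volume an [ImageVolume-class] (or [VoiMask-class] for
#'   `writeMask`).
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@data)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname readVolume
#' @param mask a [VoiMask-class].
#' @export
writeMask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask@data), dim(mask@data)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname readVolume
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  voiMask(array(as.numeric(img) != 0, dim(img)))
}

#' Read / write the cohort manifest
#'
#' The manifest is a CSV with one row per tumor (patient_id, site_id,
#' tumor_id, grade_group, zone, n_voxels, fat_ref, muscle_ref, and path
#' columns when images are written to disk).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readManifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readManifest
#' @param manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature table CSV in canonical column order
#'
#' Metadata columns first (patient_id, site_id, tumor_id, grade_group,
#' aggressiveness), then the 51 canonical feature columns.
#'
#' @param table feature data.frame.
#' @param path CSV path.
#' @export
writeFeatureTable <- function(table, path) {
  meta <- intersect(c("patient_id", "site_id", "tumor_id", "grade_group",
                      "aggressiveness"), colnames(table))
  feats <- intersect(featureNames(), colnames(table))
  utils::write.csv(table[, c(meta, feats)], path, row.names = FALSE)
  invisible(path)
}

#' Extract the full feature table of a cohort
#'
#' Per tumor: normalizes the T2W volume with its own fat/muscle references
#' ([normalizeDualReference()]), extracts the VOI with 3-sigma outlier
#' exclusion, computes the ADC map from the DW series ([fitAdcMap()],
#' nonzero b-values only) and its VOI values (unnormalized, outlier
#' excluded), then the 11 + 11 histogram features and the 29 T2W texture
#' features.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param nLevels grey levels for texture quantization (default from the
#'   cohort config).
#' @return data.frame, one row per tumor: metadata + 51 features.
#' @export
extractFeatureTable <- function(cohort, nLevels = NULL) {
  cfg <- cohort@config
  if (is.null(nLevels)) nLevels <- cfg$nLevels
  rows <- lapply(cohort@tumors, function(tum) {
    t2n <- normalizeDualReference(tum$t2w, tum$fatRef, tum$muscleRef,
                                  cfg$t2Fat, cfg$t2Muscle)
    voiT2 <- extractVoi(t2n, tum$mask)
    adcMap <- fitAdcMap(tum$dw)
    voiAdc <- extractVoi(adcMap, tum$mask)
    tex <- textureFeatures(voiT2, nLevels = nLevels)
    fx <- c(histogramFeatures(voiValues(voiAdc), prefix = "adc_"),
            histogramFeatures(voiValues(voiT2), prefix = "t2w_"),
            stats::setNames(tex, paste0("t2w_", names(tex))))
    meta <- tum$spec
    cbind(data.frame(patient_id = meta$patient_id, site_id = meta$site_id,
                     tumor_id = meta$tumor_id,
                     grade_group = meta$grade_group,
                     aggressiveness = dichotomize(meta$grade_group),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fx)))
  })
  do.call(rbind, rows)
}

#' Run the whole analysis pipeline
#'
#' Simulate (or accept) a cohort, extract features, run the association
#' statistics and the ANOVA site screen, run the hold-one-institution-out
#' SVM evaluation, and (optionally) write all artifacts: the manifest,
#' feature table, association table, screen table, per-site results, the
#' paired augmentation tests, and a JSON run manifest with the config hash
#' and seeds.
#'
#' @param config a [cohortConfig()] (or a path to a YAML serialization of
#'   one).
#' @param cohortSeed,cvSeed integer seeds for generation and inner CV.
#' @param outDir output directory, or `NULL` to skip writing.
#' @param sets feature sets to evaluate (default [featureSets()]).
#' @param writeImages also write per-tumor NIfTI volumes/masks (slow;
#'   default FALSE).
#' @return list with `cohort`, `features`, `association`, `screen`,
#'   `results`, `summary`, `augmentation`.
#' @export
runPipeline <- function(config = cohortConfig(), cohortSeed = 1, cvSeed = 1,
                        outDir = NULL, sets = featureSets(),
                        writeImages = FALSE) {
  if (is.character(config)) config <- readConfig(config)
  cohort <- generateCohort(config, seed = cohortSeed)
  if (length(unique(cohort@manifest$site_id)) < 2)
    stop("classification stage needs >= 2 sites; the cohort has one")
  features <- extractFeatureTable(cohort)
  association <- associationTable(features)
  screen <- anovaSiteScreen(features)
  results <- holdOneSiteOut(features, sets = sets, seed = cvSeed)
  summary <- summarizeSiteResults(results)
  augmentation <- augmentationTests(results)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeManifest(cohort@manifest, file.path(outDir, "manifest.csv"))
    writeFeatureTable(features, file.path(outDir, "features.csv"))
    utils::write.csv(association, file.path(outDir, "association.csv"),
                     row.names = FALSE)
    utils::write.csv(screen, file.path(outDir, "site_screen.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(outDir, "site_results.csv"),
                     row.names = FALSE)
    utils::write.csv(augmentation, file.path(outDir, "augmentation.csv"),
                     row.names = FALSE)
    cfgPath <- file.path(outDir, "config.yaml")
    writeConfig(config, cfgPath)
    selected <- lapply(results, function(res)
      lapply(res[setdiff(names(res), "site")], function(r)
        r$model$selectedFeatures))
    jsonlite::write_json(
      list(config_hash = unname(tools::md5sum(cfgPath)),
           cohort_seed = cohortSeed, cv_seed = cvSeed,
           c_grid = makeCGrid(), n_tumors = nrow(features),
           selected_features = selected),
      file.path(outDir, "run_manifest.json"), auto_unbox = TRUE,
      pretty = TRUE)
    if (writeImages) {
      for (tum in cohort@tumors) {
        pd <- file.path(outDir, "images", tum$spec$patient_id)
        dir.create(pd, recursive = TRUE, showWarnings = FALSE)
        writeVolume(tum$t2w, file.path(pd,
          paste0(tum$spec$tumor_id, "_t2w.nii.gz")))
        writeMask(tum$mask, file.path(pd,
          paste0(tum$spec$tumor_id, "_mask.nii.gz")))
        for (i in seq_along(bValues(tum$dw)))
          writeVolume(tum$dw@frames[[i]], file.path(pd,
            sprintf("%s_dw_b%04d.nii.gz", tum$spec$tumor_id,
                    bValues(tum$dw)[i])))
        writeLines(as.character(bValues(tum$dw)),
                   file.path(pd, paste0(tum$spec$tumor_id, ".bval")))
      }
    }
  }
  list(cohort = cohort, features = features, association = association,
       screen = screen, results = results, summary = summary,
       augmentation = augmentation)
}

#' Augmentation comparisons across feature sets
#'
#' For every "before/after texture augmentation" pair present in the
#' results (T2W histogram vs T2W histogram + texture; ADC + T2W histogram
#' vs ADC + T2W histogram + texture): per-site DeLong AUC comparisons plus
#' paired t-tests across sites on AUC and balanced accuracy.
#'
#' The DeLong z-test is asymptotic; at test sites with only a couple of
#' tumors in a class its variance estimate collapses and the test is
#' invalid, so per-site comparisons are only computed where both classes
#' have at least `minPerClass` tumors at the held-out site.
#'
#' @param results output of [holdOneSiteOut()].
#' @param minPerClass minimum per-class test-site count for the per-site
#'   DeLong comparison (default 5).
#' @return data.frame with columns pair, site (or `"(all)"` for the paired
#'   tests), test, p, estimate.
#' @export
augmentationTests <- function(results, minPerClass = 5) {
  pairs <- list(
    c("t2w_hist", "t2w_hist_texture"),
    c("adc_t2w_hist", "adc_t2w_hist_texture"))
  rows <- list()
  setsPresent <- setdiff(names(results[[1]]), "site")
  for (pr in pairs) {
    if (!all(pr %in% setsPresent)) next
    aucsA <- aucsB <- accA <- accB <- numeric(0)
    for (res in results) {
      a <- res[[pr[1]]]; b <- res[[pr[2]]]
      if (!a$aucDegenerate && !b$aucDegenerate) {
        aucsA <- c(aucsA, a$auc)
        aucsB <- c(aucsB, b$auc)
        if (min(table(a$labels)) >= minPerClass) {
          dl <- delongCompare(a$scores, b$scores, a$labels)
          rows[[length(rows) + 1L]] <- data.frame(
            pair = paste(pr, collapse = " vs "), site = res$site,
            test = "delong", p = dl$p, estimate = dl$aucB - dl$aucA,
            stringsAsFactors = FALSE)
        }
      }
      accA <- c(accA, a$accuracy)
      accB <- c(accB, b$accuracy)
    }
    if (length(aucsA) >= 3) {
      tt <- pairedSiteTtest(aucsB, aucsA)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(pr, collapse = " vs "), site = "(all)",
        test = "paired_t_auc", p = tt$p, estimate = tt$meanDiff,
        stringsAsFactors = FALSE)
    }
    if (length(accA) >= 3) {
      tt <- pairedSiteTtest(accB, accA)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(pr, collapse = " vs "), site = "(all)",
        test = "paired_t_accuracy", p = tt$p, estimate = tt$meanDiff,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pair = character(), site = character(),
                      test = character(), p = numeric(),
                      estimate = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read / write a cohort configuration as YAML
#'
#' @param path YAML file path.
#' @return `readConfig`: a [cohortConfig()]-shaped list.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  sites <- do.call(rbind, lapply(raw$sites, function(s)
    data.frame(site_id = s$site_id, gain = s$gain, offset = s$offset,
               n_patients = s$n_patients, prop_low = s$prop_low,
               stringsAsFactors = FALSE)))
  args <- raw[setdiff(names(raw), "sites")]
  do.call(cohortConfig, c(list(sites = sites), args))
}

#' @rdname readConfig
#' @param config a [cohortConfig()].
#' @export
writeConfig <- function(config, path) {
  out <- list(effect = config$effect,
              sites = lapply(seq_len(nrow(config$sites)), function(i)
                as.list(config$sites[i, ])),
              secondTumorProb = config$secondTumorProb,
              nVoxelRange = config$nVoxelRange,
              ggWeightsIntHigh = config$ggWeightsIntHigh,
              dwNoiseSd = config$dwNoiseSd, dwNoise = config$dwNoise,
              fatTrue = config$fatTrue, muscleTrue = config$muscleTrue,
              t2Fat = config$t2Fat, t2Muscle = config$t2Muscle,
              nLevels = config$nLevels, bvalues = config$bvalues)
  yaml::write_yaml(out, path)
  invisible(path)
}
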