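# Multi-site synthetic cohort generator. Emulates the statistical structure
# the downstream analysis assumes: two aggressiveness classes that differ in
# textural homogeneity/disorder, T2W intensity level and ADC; per-site
# affine intensity effects; embedded fat/muscle reference regions; an
# imbalanced six-site cohort.

#' Cohort generator configuration
#'
#' Builds the configuration list consumed by [generateCohort()]. The default
#' (`effect = "strong"`) reproduces the layout of a six-institution cohort
#' of 87 patients and ~104 peripheral-zone tumors with a 30/74 low versus
#' intermediate/high class imbalance, with clearly separated class effects
#' on texture and ADC. `effect = "null"` switches every class effect off
#' (all grade groups share texture, intensity and ADC parameters) so that
#' classifier behaviour under the null can be studied.
#'
#' Class effects (per grade group 1..5): texture correlation length 3.0,
#' 2.5, 2.0, 1.5, 1.0 px; texture noise SD 0.3..0.7; T2W tumor level 110
#' down to 70; mean ADC 1.30 down to 0.75 x 10^-3 mm^2/s. Site intensity
#' effects are affine (gain, offset) on raw T2W intensities applied after
#' texture synthesis.
#'
#' @param effect `"strong"` (class effects on) or `"null"` (off).
#' @param sites data.frame with columns `site_id`, `gain`, `offset`,
#'   `n_patients`, `prop_low`; defaults emulate the six-site layout.
#' @param secondTumorProb probability a patient carries a second tumor.
#' @param nVoxelRange admissible tumor sizes in voxels (default 101..1397,
#'   mean ~469).
#' @param ggWeightsIntHigh sampling weights of grade groups 2..5 within the
#'   intermediate/high class.
#' @param dwNoiseSd DW noise SD as a fraction of S0 (default 0.02).
#' @param dwNoise `"gaussian"` or `"rician"`.
#' @param fatTrue,muscleTrue raw-intensity reference tissue anchors before
#'   the site effect.
#' @param t2Fat,t2Muscle pseudo-T2 anchors in ms for normalization.
#' @param nLevels grey levels for downstream quantization.
#' @param bvalues DW b-values in s/mm^2.
#' @return a named list (class `cohortConfig`).
#' @examples
#' cfg <- cohortConfig()
#' sum(cfg$sites$n_patients)  # 87
#' @export
cohortConfig <- function(effect = c("strong", "null"),
                         sites = NULL,
                         secondTumorProb = 0.2,
                         nVoxelRange = c(101, 1397),
                         ggWeightsIntHigh = c(36, 26, 6, 6),
                         dwNoiseSd = 0.02,
                         dwNoise = c("gaussian", "rician"),
                         fatTrue = 180, muscleTrue = 45,
                         t2Fat = 121, t2Muscle = 40,
                         nLevels = 32,
                         bvalues = c(0, 100, 400, 800)) {
  effect <- match.arg(effect)
  dwNoise <- match.arg(dwNoise)
  if (is.null(sites)) {
    sites <- data.frame(
      site_id = LETTERS[1:6],
      gain = c(1.0, 1.3, 0.8, 1.15, 0.9, 1.25),
      offset = c(0, 15, -10, 5, 20, -5),
      n_patients = c(17, 15, 21, 16, 8, 10),
      # Table-1-like low-class proportions per site (tumor level)
      prop_low = c(5 / 19, 1 / 17, 10 / 27, 3 / 20, 6 / 10, 5 / 11),
      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(sites) >= 1, all(sites$gain > 0), all(sites$n_patients >= 1),
            all(sites$prop_low >= 0 & sites$prop_low <= 1))
  if (effect == "strong") {
    pars <- list(
      corrLength = c(3.0, 2.5, 2.0, 1.5, 1.0),
      noiseSd = c(0.3, 0.4, 0.5, 0.6, 0.7),
      t2wLevel = c(110, 100, 90, 80, 70),
      adcMean = c(1.30, 1.05, 0.95, 0.85, 0.75) * 1e-3)
  } else {
    pars <- list(
      corrLength = rep(2.0, 5),
      noiseSd = rep(0.5, 5),
      t2wLevel = rep(90, 5),
      adcMean = rep(1.0e-3, 5))
  }
  structure(list(
    effect = effect, sites = sites, secondTumorProb = secondTumorProb,
    nVoxelRange = nVoxelRange, ggWeightsIntHigh = ggWeightsIntHigh,
    classPars = pars,
    t2wLevelSd = 6, t2wFieldSd = 12, adcJitterSd = 0.08e-3,
    adcVoxelSd = 0.05e-3, backgroundLevel = 85, backgroundAdc = 1.6e-3,
    dwS0 = 400, dwNoiseSd = dwNoiseSd, dwNoise = dwNoise,
    fatTrue = fatTrue, muscleTrue = muscleTrue,
    t2Fat = t2Fat, t2Muscle = t2Muscle, nLevels = nLevels,
    bvalues = bvalues,
    spacing = c(0.625, 0.625, 3.6)),
    class = "cohortConfig")
}

#' Stationary correlated texture field
#'
#' Synthesizes a 2D random field as white Gaussian noise smoothed with an
#' isotropic Gaussian kernel of width `corrLength` (pixels), rescaled to
#' unit variance, plus independent Gaussian noise of SD `noiseSd`. Larger
#' correlation lengths give visually and statistically more homogeneous
#' textures (higher GLCM angular second moment, lower entropy).
#'
#' @param shape integer length-2 (rows, cols).
#' @param corrLength positive smoothing kernel SD in pixels; `Inf` gives a
#'   constant (zero) field.
#' @param noiseSd SD of the added independent noise.
#' @param seed integer seed (deterministic output).
#' @return numeric matrix, approximately zero mean.
#' @export
synthesizeTextureField <- function(shape, corrLength, noiseSd = 0, seed = 1) {
  stopifnot(length(shape) == 2, all(shape >= 1), corrLength > 0)
  withSeed(seed, {
    if (is.infinite(corrLength)) {
      f <- matrix(0, shape[1], shape[2])
    } else {
      half <- max(1L, ceiling(3 * corrLength))
      kx <- stats::dnorm(seq(-half, half), sd = corrLength)
      kx <- kx / sum(kx)
      pad <- half
      w <- matrix(stats::rnorm((shape[1] + 2 * pad) * (shape[2] + 2 * pad)),
                  shape[1] + 2 * pad, shape[2] + 2 * pad)
      sm <- apply(w, 2, function(col) stats::filter(col, kx, sides = 2))
      sm <- t(apply(sm, 1, function(row) stats::filter(row, kx, sides = 2)))
      f <- sm[pad + seq_len(shape[1]), pad + seq_len(shape[2]), drop = FALSE]
      s <- stats::sd(as.vector(f))
      if (is.na(s) || s == 0) s <- 1
      f <- f / s
    }
    if (noiseSd > 0)
      f <- f + matrix(stats::rnorm(length(f), sd = noiseSd),
                      nrow(f), ncol(f))
    f
  })
}

#' Embed reference tissue regions in a volume
#'
#' Writes a fat block and a muscle block into opposite corners of every
#' slice. Block values are constructed so the 90th percentile of the fat
#' region and the 10th percentile of the muscle region equal `fatTrue` and
#' `muscleTrue` exactly (before any site gain/offset).
#'
#' @param volume an [ImageVolume-class].
#' @param mask a [VoiMask-class]; regions must not intersect it.
#' @param fatTrue,muscleTrue target percentile intensities
#'   (`fatTrue > muscleTrue > 0`).
#' @param blockSize edge length of the square corner blocks (default 4).
#' @param seed integer seed for the within-block spread.
#' @return list with `volume` (modified), `fatRef`, `muscleRef` (the exact
#'   percentile values, here equal to the inputs) and the block index
#'   ranges (`fatIdx`, `muscleIdx`).
#' @export
embedReferenceTissues <- function(volume, mask, fatTrue, muscleTrue,
                                  blockSize = 4L, seed = 1) {
  stopifnot(is(volume, "ImageVolume"), fatTrue > muscleTrue, muscleTrue > 0)
  d <- dim(volume@data)
  bs <- min(blockSize, d[1], d[2])
  fatIdx <- list(rows = seq_len(bs), cols = seq_len(bs), slices = seq_len(d[3]))
  muscleIdx <- list(rows = d[1] - bs + seq_len(bs),
                    cols = d[2] - bs + seq_len(bs), slices = seq_len(d[3]))
  if (!is.null(mask)) {
    md <- maskData(mask)
    if (any(md[fatIdx$rows, fatIdx$cols, , drop = FALSE]) ||
        any(md[muscleIdx$rows, muscleIdx$cols, , drop = FALSE]))
      stop("reference regions overlap the tumor mask")
  }
  vol <- volume@data
  fill <- function(target, prob, n) {
    withSeed(seed + round(target), {
      v <- target * (1 + stats::rnorm(n, sd = 0.03))
      # shift so the requested quantile is hit exactly
      v + (target - stats::quantile(v, prob, names = FALSE, type = 7))
    })
  }
  nblk <- bs * bs * d[3]
  vol[fatIdx$rows, fatIdx$cols, ] <- fill(fatTrue, 0.9, nblk)
  vol[muscleIdx$rows, muscleIdx$cols, ] <- fill(muscleTrue, 0.1, nblk)
  list(volume = imageVolume(vol, volume@spacing, volume@modality),
       fatRef = fatTrue, muscleRef = muscleTrue,
       fatIdx = fatIdx, muscleIdx = muscleIdx)
}

# Ellipsoid mask with ~nVoxels in-mask voxels over nz slices, centred in a
# (nr, nc, nzTot) grid, with mild per-tumor shape jitter.
.makeEllipsoidMask <- function(nVoxels, seed) {
  withSeed(seed, {
    nz <- sample(2:5, 1, prob = c(0.2, 0.35, 0.3, 0.15))
    # in-plane radius from target volume of an ellipsoid-ish stack
    perSlice <- nVoxels / nz
    r <- sqrt(perSlice / pi) * (1 + stats::runif(1, -0.1, 0.1))
    ecc <- stats::runif(1, 0.75, 1.3)
    a <- r * ecc; b <- r / ecc
    nr <- 2L * ceiling(a) + 13L
    nc <- 2L * ceiling(b) + 13L
    nzTot <- nz + 2L
    cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
    m <- array(FALSE, c(nr, nc, nzTot))
    zc <- (nz + 1) / 2
    for (k in seq_len(nz)) {
      # slice-wise shrink toward the poles of the ellipsoid
      zfac <- sqrt(pmax(0.25, 1 - ((k - zc) / (nz / 2 + 0.5))^2))
      ii <- matrix(seq_len(nr), nr, nc)
      jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      m[, , k + 1L] <- ((ii - cx) / (a * zfac))^2 +
        ((jj - cy) / (b * zfac))^2 <= 1
    }
    m
  })
}

#' Generate a multi-site synthetic cohort
#'
#' Draws patients per site, assigns each tumor a grade group (low class =
#' grade group 1 with the site's `prop_low`; grade groups 2..5 weighted by
#' `ggWeightsIntHigh` otherwise), synthesizes for each tumor a small
#' tumor-centred T2W volume with class-dependent texture, an aligned
#' multi-b DW series following `S(b) = S0 exp(-b ADC)` with voxelwise ADC,
#' an ellipsoidal VOI mask, and embedded fat/muscle reference regions.
#' The site's affine intensity effect (gain, offset) is applied to the T2W
#' volume after texture synthesis; the returned reference intensities are
#' reported after the site effect so dual-reference normalization can undo
#' it.
#'
#' @param config a [cohortConfig()] list.
#' @param seed integer; the cohort is bit-for-bit reproducible under
#'   the same (config, seed).
#' @return A [SyntheticCohort-class].
#' @examples
#' cfg <- cohortConfig(sites = data.frame(
#'   site_id = c("A", "B"), gain = c(1, 1.2), offset = c(0, 5),
#'   n_patients = c(3, 3), prop_low = c(0.5, 0.5)))
#' coh <- generateCohort(cfg, seed = 1)
#' nrow(cohortManifest(coh))
#' @export
generateCohort <- function(config, seed) {
  stopifnot(inherits(config, "cohortConfig"))
  if (nrow(config$sites) < 1) stop("degenerate cohort: no sites")
  if (any(config$sites$gain <= 0)) stop("non-positive gain")
  seed <- as.integer(seed)

  # ---- draw the cohort layout -------------------------------------------
  layout <- withSeed(childSeed(seed, 0L), {
    rows <- list()
    pid <- 0L
    for (s in seq_len(nrow(config$sites))) {
      st <- config$sites[s, ]
      for (p in seq_len(st$n_patients)) {
        pid <- pid + 1L
        nTum <- 1L + stats::rbinom(1, 1, config$secondTumorProb)
        for (t in seq_len(nTum)) {
          isLow <- stats::runif(1) < st$prop_low
          gg <- if (isLow) 1L else
            sample(2:5, 1, prob = config$ggWeightsIntHigh)
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = sprintf("P%03d", pid), site_id = st$site_id,
            gain = st$gain, offset = st$offset,
            tumor_index = t, grade_group = gg, zone = "peripheral",
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  cls <- ifelse(layout$grade_group == 1, "low", "int_high")
  if (length(unique(cls)) < 2 || min(table(cls)) < 2)
    stop("degenerate cohort: fewer than two tumors in a class")

  # tumor sizes: lognormal around the study's mean VOI size, clipped
  layout$n_voxels <- withSeed(childSeed(seed, 1L), {
    n <- nrow(layout)
    v <- round(stats::rlnorm(n, meanlog = log(420), sdlog = 0.55))
    pmin(pmax(v, config$nVoxelRange[1]), config$nVoxelRange[2])
  })

  # ---- synthesize per-tumor volumes -------------------------------------
  tumors <- vector("list", nrow(layout))
  fatRefs <- muscleRefs <- numeric(nrow(layout))
  for (it in seq_len(nrow(layout))) {
    row <- layout[it, ]
    gg <- row$grade_group
    tseed <- childSeed(seed, 10L + it)
    pars <- config$classPars
    corrLen <- pars$corrLength[gg]
    noiseSd <- pars$noiseSd[gg]

    maskArr <- .makeEllipsoidMask(row$n_voxels, tseed)
    d <- dim(maskArr)
    mask <- voiMask(maskArr, tumorId = sprintf("T%03d", it))

    local <- withSeed(childSeed(tseed, 1L), {
      level <- pars$t2wLevel[gg] + stats::rnorm(1, sd = config$t2wLevelSd)
      vol <- array(config$backgroundLevel +
                     stats::rnorm(prod(d), sd = 2), d)
      for (k in seq_len(d[3])) {
        fld <- synthesizeTextureField(d[1:2], corrLen, noiseSd,
                                      seed = childSeed(tseed, 100L + k))
        sl <- vol[, , k]
        inm <- maskArr[, , k]
        sl[inm] <- level + config$t2wFieldSd * fld[inm]
        vol[, , k] <- sl
      }
      adcTum <- pars$adcMean[gg] + stats::rnorm(1, sd = config$adcJitterSd)
      adcMap <- array(config$backgroundAdc +
                        stats::rnorm(prod(d), sd = 0.02e-3), d)
      adcMap[maskArr] <- adcTum +
        stats::rnorm(sum(maskArr), sd = config$adcVoxelSd)
      adcMap <- pmax(adcMap, 1e-5)
      list(vol = vol, adcMap = adcMap, adcTum = adcTum)
    })

    t2raw <- imageVolume(local$vol, config$spacing, "t2w")
    emb <- embedReferenceTissues(t2raw, mask, config$fatTrue,
                                 config$muscleTrue,
                                 seed = childSeed(tseed, 2L))
    # site affine intensity effect, applied after texture synthesis
    t2site <- imageVolume(row$gain * volumeData(emb$volume) + row$offset,
                          config$spacing, "t2w")
    fatRefs[it] <- row$gain * emb$fatRef + row$offset
    muscleRefs[it] <- row$gain * emb$muscleRef + row$offset

    dw <- withSeed(childSeed(tseed, 3L), {
      frames <- lapply(config$bvalues, function(b) {
        sig <- config$dwS0 * exp(-b * local$adcMap)
        if (config$dwNoiseSd > 0) {
          nsd <- config$dwNoiseSd * config$dwS0
          if (config$dwNoise == "gaussian") {
            sig <- sig + array(stats::rnorm(prod(d), sd = nsd), d)
          } else {
            sig <- sqrt((sig + array(stats::rnorm(prod(d), sd = nsd), d))^2 +
                          array(stats::rnorm(prod(d), sd = nsd), d)^2)
          }
        }
        imageVolume(pmax(sig, 1e-6), config$spacing, "dw")
      })
      dwSeries(frames, config$bvalues)
    })

    tumors[[it]] <- list(
      spec = list(patient_id = row$patient_id, site_id = row$site_id,
                  tumor_id = sprintf("T%03d", it), grade_group = gg,
                  zone = row$zone, n_voxels = sum(maskArr),
                  texture_corr_length = corrLen, noise_sd = noiseSd,
                  adc_mean = local$adcTum),
      t2w = t2site, dw = dw, mask = mask,
      fatRef = fatRefs[it], muscleRef = muscleRefs[it],
      adcTrue = local$adcTum)
  }

  manifest <- data.frame(
    patient_id = layout$patient_id, site_id = layout$site_id,
    tumor_id = vapply(tumors, function(t) t$spec$tumor_id, ""),
    grade_group = layout$grade_group, zone = layout$zone,
    n_voxels = vapply(tumors, function(t) t$spec$n_voxels, 0L),
    fat_ref = fatRefs, muscle_ref = muscleRefs,
    stringsAsFactors = FALSE)

  new("SyntheticCohort", tumors = tumors, manifest = manifest,
      config = unclass(config), seed = seed)
}
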