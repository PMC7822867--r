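#' Dual-reference pseudo-T2 intensity normalization
#'
#' Maps raw T2-weighted intensities to pseudo-T2 values by the unique affine
#' transform sending the fat reference intensity to the literature T2 of fat
#' and the muscle reference intensity to the T2 of muscle at 3T. Because any
#' scanner/site intensity effect that is affine is absorbed into the
#' references, normalizing with references measured on the same volume
#' removes the site effect exactly.
#'
#' @param volume an [ImageVolume-class] (raw T2W intensities).
#' @param fatRef,muscleRef scalar reference intensities measured on this
#'   volume (90th percentile of the fat region, 10th percentile of muscle).
#' @param t2Fat,t2Muscle target T2 values in ms at 3T. The defaults are
#'   typical literature values; both are configurable.
#' @return An [ImageVolume-class] with every voxel mapped through the line.
#' @examples
#' v <- imageVolume(array(c(200, 500, 800), c(3, 1, 1)))
#' volumeData(normalizeDualReference(v, 800, 200, 120, 40))  # 40, 80, 120
#' @export
normalizeDualReference <- function(volume, fatRef, muscleRef,
                                   t2Fat = 121, t2Muscle = 40) {
  stopifnot(is(volume, "ImageVolume"))
  if (fatRef == muscleRef)
    stop("degenerate references: fat and muscle intensities are equal")
  if (t2Fat == t2Muscle)
    stop("degenerate references: target T2 values are equal")
  slope <- (t2Fat - t2Muscle) / (fatRef - muscleRef)
  intercept <- t2Fat - slope * fatRef
  imageVolume(slope * volume@data + intercept,
              spacing = volume@spacing, modality = volume@modality)
}

#' Exclude outlier voxels by the 3-sigma rule
#'
#' Computes the mean and SD of the input values once and keeps values inside
#' `[mu - 3 sigma, mu + 3 sigma]`; a single pass, no re-estimation. A
#' constant input (sigma = 0) is returned unchanged.
#'
#' @param values numeric vector (>= 2 values).
#' @param sdType `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return list with `values` (kept), `nExcluded`, `mu`, `sigma`.
#' @examples
#' excludeOutliers(c(rnorm(100), 50))$nExcluded  # the 50 goes
#' @export
excludeOutliers <- function(values, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  stopifnot(length(values) >= 2L, all(is.finite(values)))
  mu <- mean(values)
  sigma <- stats::sd(values)
  if (sdType == "population")
    sigma <- sigma * sqrt((length(values) - 1) / length(values))
  if (sigma == 0) {
    return(list(values = values, nExcluded = 0L, mu = mu, sigma = sigma))
  }
  keep <- values >= mu - 3 * sigma & values <= mu + 3 * sigma
  list(values = values[keep], nExcluded = sum(!keep), mu = mu, sigma = sigma)
}

#' Extract the masked voxel sample of one tumor
#'
#' Crops every axial slice intersecting the mask, applies [excludeOutliers()]
#' once to the pooled in-mask values of the whole VOI, and propagates the
#' exclusions to the per-slice masks, so downstream texture extraction sees
#' exactly the kept voxels.
#'
#' @param volume an [ImageVolume-class].
#' @param mask a [VoiMask-class] with the same grid shape.
#' @param excludeOutliersFlag logical; apply the 3-sigma rule (default TRUE).
#' @param sdType passed to [excludeOutliers()].
#' @return A [VoiSample-class].
#' @export
extractVoi <- function(volume, mask, excludeOutliersFlag = TRUE,
                       sdType = "sample") {
  stopifnot(is(volume, "ImageVolume"), is(mask, "VoiMask"))
  if (!identical(dim(volume@data), dim(mask@data)))
    stop(sprintf("mask shape (%s) does not match volume shape (%s)",
                 paste(dim(mask@data), collapse = "x"),
                 paste(dim(volume@data), collapse = "x")))
  m <- mask@data
  vals <- volume@data[m]
  if (length(vals) == 0L) stop("empty mask")
  if (excludeOutliersFlag && length(vals) >= 2L) {
    ex <- excludeOutliers(vals, sdType = sdType)
    lo <- ex$mu - 3 * ex$sigma
    hi <- ex$mu + 3 * ex$sigma
    if (ex$sigma > 0) m <- m & volume@data >= lo & volume@data <= hi
  } else {
    ex <- list(values = vals, nExcluded = 0L,
               mu = mean(vals), sigma = if (length(vals) > 1) stats::sd(vals) else 0)
  }
  d <- dim(volume@data)
  sliceHas <- which(apply(mask@data, 3, any))
  slices <- lapply(sliceHas, function(k) {
    mk <- matrix(mask@data[, , k], d[1], d[2])
    vk <- matrix(volume@data[, , k], d[1], d[2])
    ek <- matrix(m[, , k], d[1], d[2])
    rows <- range(which(rowSums(mk) > 0))
    cols <- range(which(colSums(mk) > 0))
    list(values = vk[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
         mask = ek[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE])
  })
  new("VoiSample",
      values = volume@data[m], slices = slices,
      nExcluded = as.integer(sum(mask@data) - sum(m)),
      mu = ex$mu, sigma = ex$sigma, tumorId = mask@tumorId)
}
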