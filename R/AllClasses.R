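#' @import methods
NULL

#' ImageVolume: a 3D scalar image with voxel spacing
#'
#' Container for a single 3D image grid (T2-weighted, a diffusion-weighted
#' frame, or an ADC map). The third array index is the axial slice axis.
#'
#' @slot data numeric 3D array.
#' @slot spacing numeric length-3 voxel spacing (dx, dy, dz) in mm.
#' @slot modality character, one of \code{"t2w"}, \code{"dw"}, \code{"adc"}.
#'
#' @seealso [imageVolume()], [normalizeDualReference()], [fitAdcMap()]
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", modality = "character"))

setValidity("ImageVolume", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values")
  if (!object@modality %in% c("t2w", "dw", "adc"))
    msg <- c(msg, "modality must be one of 't2w', 'dw', 'adc'")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "volume contains non-finite values")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ImageVolume
#'
#' @param data numeric 3D array (axial slices along the third axis).
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param modality one of `"t2w"`, `"dw"`, `"adc"`.
#' @return An [ImageVolume-class] object.
#' @examples
#' vol <- imageVolume(array(1, c(4, 4, 2)), spacing = c(0.6, 0.6, 3.6))
#' dim(volumeData(vol))
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1), modality = "t2w") {
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      modality = modality)
}

#' @describeIn imageVolume Extract the raw 3D array.
#' @param x an `ImageVolume`.
#' @export
volumeData <- function(x) x@data

#' @describeIn imageVolume Voxel spacing in mm.
#' @export
voxelSpacing <- function(x) x@spacing

#' @describeIn imageVolume Modality tag.
#' @export
modality <- function(x) x@modality

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume [%s] %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              object@modality, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

#' VoiMask: a binary tumor volume-of-interest mask
#'
#' @slot data logical 3D array aligned to its [ImageVolume-class].
#' @slot tumorId character label.
#' @export
setClass("VoiMask", representation(data = "array", tumorId = "character"))

setValidity("VoiMask", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L) msg <- c(msg, "mask must be a 3D array")
  if (!is.logical(object@data)) msg <- c(msg, "mask must be logical")
  if (sum(object@data) < 1L) msg <- c(msg, "mask must contain >= 1 voxel")
  if (is.null(msg)) TRUE else msg
})

#' Construct a VoiMask
#' @param data logical 3D array.
#' @param tumorId character label for the tumor.
#' @return A [VoiMask-class] object.
#' @export
voiMask <- function(data, tumorId = "tumor") {
  new("VoiMask", data = (data != 0), tumorId = tumorId)
}

#' @describeIn voiMask Raw logical array.
#' @param x a `VoiMask`.
#' @export
maskData <- function(x) x@data

setMethod("show", "VoiMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoiMask '%s' %d x %d x %d, %d voxels across %d slice(s)\n",
              object@tumorId, d[1], d[2], d[3], sum(object@data),
              sum(apply(object@data, 3, any))))
})

#' DwSeries: a multi-b diffusion-weighted series
#'
#' @slot frames list of [ImageVolume-class] objects sharing geometry.
#' @slot bvalues numeric b-values in s/mm^2, strictly increasing.
#' @export
setClass("DwSeries", representation(frames = "list", bvalues = "numeric"))

setValidity("DwSeries", function(object) {
  msg <- NULL
  if (length(object@frames) != length(object@bvalues))
    msg <- c(msg, "one frame per b-value required")
  if (any(object@bvalues < 0) || any(diff(object@bvalues) <= 0))
    msg <- c(msg, "b-values must be nonnegative and strictly increasing")
  if (sum(object@bvalues > 0) < 2L)
    msg <- c(msg, "need >= 2 nonzero b-values")
  dims <- lapply(object@frames, function(f) dim(f@data))
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "frames must share geometry")
  if (is.null(msg)) TRUE else msg
})

#' Construct a DwSeries
#' @param frames list of [ImageVolume-class] frames (one per b-value).
#' @param bvalues numeric b-values in s/mm^2.
#' @return A [DwSeries-class] object.
#' @export
dwSeries <- function(frames, bvalues) {
  new("DwSeries", frames = frames, bvalues = as.numeric(bvalues))
}

#' @describeIn dwSeries b-values of the series.
#' @param x a `DwSeries`.
#' @export
bValues <- function(x) x@bvalues

setMethod("show", "DwSeries", function(object) {
  cat(sprintf("DwSeries with %d frames, b = {%s} s/mm^2\n",
              length(object@frames),
              paste(object@bvalues, collapse = ", ")))
})

#' VoiSample: the masked, outlier-cleaned voxel sample of one tumor
#'
#' Produced by [extractVoi()]. Holds the flat vector of kept in-mask values,
#' the per-slice 2D crops with aligned masks (outlier voxels removed from the
#' masks), and the pre-exclusion mean/SD used for the 3-sigma rule.
#'
#' @slot values numeric kept in-mask intensities.
#' @slot slices list; each element a list with elements `values` (2D matrix)
#'   and `mask` (2D logical matrix).
#' @slot nExcluded integer count of voxels removed by outlier exclusion.
#' @slot mu,sigma numeric pre-exclusion mean and SD.
#' @slot tumorId character.
#' @export
setClass("VoiSample",
  representation(values = "numeric", slices = "list", nExcluded = "integer",
                 mu = "numeric", sigma = "numeric", tumorId = "character"))

setValidity("VoiSample", function(object) {
  msg <- NULL
  if (length(object@values) < 1L) msg <- c(msg, "values must be nonempty")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn extractVoi Kept in-mask values of a `VoiSample`.
#' @param x a `VoiSample`.
#' @export
voiValues <- function(x) x@values

#' @describeIn extractVoi Per-slice crops of a `VoiSample` (list of
#'   `list(values, mask)`).
#' @export
voiSlices <- function(x) x@slices

#' @describeIn extractVoi Number of voxels excluded by the 3-sigma rule.
#' @export
nExcluded <- function(x) x@nExcluded

setMethod("show", "VoiSample", function(object) {
  cat(sprintf(
    "VoiSample '%s': %d kept voxels (%d excluded), %d slice(s), mu=%.4g sigma=%.4g\n",
    object@tumorId, length(object@values), object@nExcluded,
    length(object@slices), object@mu, object@sigma))
})

#' QuantizedVoi: fixed-bin-number discretized VOI
#'
#' @slot slices list of `list(levels, mask)`; `levels` is an integer matrix
#'   with in-mask entries in 1..nLevels.
#' @slot nLevels integer number of grey levels.
#' @slot binEdges numeric nLevels + 1 strictly increasing edges.
#' @export
setClass("QuantizedVoi",
  representation(slices = "list", nLevels = "integer", binEdges = "numeric"))

setValidity("QuantizedVoi", function(object) {
  msg <- NULL
  if (object@nLevels < 2L) msg <- c(msg, "nLevels must be >= 2")
  if (length(object@binEdges) != object@nLevels + 1L)
    msg <- c(msg, "need nLevels + 1 bin edges")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "QuantizedVoi", function(object) {
  cat(sprintf("QuantizedVoi: %d slice(s), Ng = %d, range [%.4g, %.4g]\n",
              length(object@slices), object@nLevels,
              object@binEdges[1], object@binEdges[length(object@binEdges)]))
})

#' CooccurrenceMatrix: normalized symmetric GLCM for one (slice, direction)
#'
#' @slot p numeric Ng x Ng matrix; sums to 1 when `nPairs > 0`; symmetric.
#' @slot direction numeric angle in degrees (0, 45, 90, 135).
#' @slot distance integer pixel offset (1).
#' @slot nPairs integer symmetric pair count before normalization.
#' @export
setClass("CooccurrenceMatrix",
  representation(p = "matrix", direction = "numeric", distance = "integer",
                 nPairs = "integer"))

setValidity("CooccurrenceMatrix", function(object) {
  msg <- NULL
  if (nrow(object@p) != ncol(object@p)) msg <- c(msg, "p must be square")
  if (object@nPairs > 0L) {
    if (abs(sum(object@p) - 1) > 1e-8) msg <- c(msg, "p must sum to 1")
    if (max(abs(object@p - t(object@p))) > 1e-12)
      msg <- c(msg, "p must be symmetric")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix Ng=%d, theta=%g deg, d=%d, %d pairs\n",
              nrow(object@p), object@direction, object@distance,
              object@nPairs))
})

#' RunLengthMatrix: grey level run length matrix for one (slice, direction)
#'
#' @slot r numeric Ng x Lmax matrix of run counts.
#' @slot direction numeric angle in degrees.
#' @slot nPixels integer in-mask pixels traversed.
#' @slot nRuns integer number of runs.
#' @export
setClass("RunLengthMatrix",
  representation(r = "matrix", direction = "numeric", nPixels = "integer",
                 nRuns = "integer"))

setValidity("RunLengthMatrix", function(object) {
  msg <- NULL
  if (object@nRuns > 0L) {
    lens <- seq_len(ncol(object@r))
    if (abs(sum(object@r %*% lens) - object@nPixels) > 1e-9)
      msg <- c(msg, "run lengths must account for every in-mask pixel")
    if (abs(sum(object@r) - object@nRuns) > 1e-9)
      msg <- c(msg, "sum of counts must equal nRuns")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RunLengthMatrix", function(object) {
  cat(sprintf("RunLengthMatrix Ng=%d, Lmax=%d, theta=%g deg, %d runs over %d pixels\n",
              nrow(object@r), ncol(object@r), object@direction,
              object@nRuns, object@nPixels))
})

#' SyntheticCohort: a generated multi-site tumor cohort
#'
#' @slot tumors list; one element per tumor with components `spec` (list of
#'   tumor metadata), `t2w` ([ImageVolume-class]), `dw` ([DwSeries-class]),
#'   `mask` ([VoiMask-class]), `fatRef`, `muscleRef` (scalars, reported after
#'   the site intensity effect), and `adcTrue` (mean true tumor ADC).
#' @slot manifest data.frame, one row per tumor (patient_id, site_id,
#'   tumor_id, grade_group, zone, n_voxels, fat_ref, muscle_ref).
#' @slot config list, the generating [cohortConfig()].
#' @slot seed integer seed used.
#' @export
setClass("SyntheticCohort",
  representation(tumors = "list", manifest = "data.frame", config = "list",
                 seed = "integer"))

setMethod("show", "SyntheticCohort", function(object) {
  m <- object@manifest
  cat(sprintf("SyntheticCohort: %d tumors / %d patients / %d sites (seed %d)\n",
              nrow(m), length(unique(m$patient_id)),
              length(unique(m$site_id)), object@seed))
  tab <- table(factor(ifelse(m$grade_group == 1, "low", "int_high"),
                      levels = c("low", "int_high")))
  cat(sprintf("  classes: %d low / %d int_high\n", tab["low"], tab["int_high"]))
})

#' @describeIn generateCohort Cohort manifest (one row per tumor).
#' @param x a `SyntheticCohort`.
#' @export
cohortManifest <- function(x) x@manifest

#' @describeIn generateCohort List of per-tumor records.
#' @export
cohortTumors <- function(x) x@tumors
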