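# Grey level texture analysis: fixed-bin-number quantization, per-slice
# directional GLCM/GLRLM, IBSI-style features, 2D-average aggregation.

# direction -> (row, col) pixel offset; 0 deg is along a row (columns),
# rows count downwards so 45/90/135 use a -1 row step.
.dirOffset <- function(direction) {
  switch(as.character(direction),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("direction must be one of 0, 45, 90, 135"))
}

#' The four texture directions
#' @return numeric vector `c(0, 45, 90, 135)` (degrees).
#' @export
textureDirections <- function() c(0, 45, 90, 135)

#' Fixed-bin-number quantization of a VOI
#'
#' Discretizes the kept VOI intensities into `nLevels` equal-width bins
#' spanning the VOI minimum to maximum, computed over the whole 3D VOI so
#' all slices share one grey scale. The maximum maps to level `nLevels`; a
#' constant VOI maps entirely to level 1.
#'
#' @param sample a [VoiSample-class].
#' @param nLevels number of grey levels (default 32).
#' @return A [QuantizedVoi-class].
#' @examples
#' # values 0..3 with 4 bins occupy one level each
#' @export
quantizeFbn <- function(sample, nLevels = 32) {
  stopifnot(is(sample, "VoiSample"), nLevels >= 2)
  nLevels <- as.integer(nLevels)
  lo <- min(sample@values)
  hi <- max(sample@values)
  edges <- seq(lo, hi, length.out = nLevels + 1L)
  if (hi == lo) edges <- lo + seq(0, 1, length.out = nLevels + 1L)
  width <- hi - lo
  slices <- lapply(sample@slices, function(s) {
    lv <- if (width == 0) {
      matrix(1L, nrow(s$values), ncol(s$values))
    } else {
      matrix(pmin(as.integer(floor((s$values - lo) / width * nLevels)) + 1L,
                  nLevels),
             nrow(s$values), ncol(s$values))
    }
    lv[!s$mask] <- NA_integer_
    # voxels outside [lo, hi] can only be outlier-excluded ones, already
    # masked out above
    list(levels = lv, mask = s$mask)
  })
  new("QuantizedVoi", slices = slices, nLevels = nLevels, binEdges = edges)
}

#' Grey level co-occurrence matrix of one slice
#'
#' Counts ordered level pairs at the given direction's one-pixel offset with
#' both endpoints inside the mask, symmetrizes by adding the transpose, and
#' normalizes to a probability matrix. `nPairs` is the symmetric count
#' before normalization; a slice with no valid pair is flagged empty
#' (`nPairs = 0`) and skipped by [aggregate2dAverage()].
#'
#' @param sliceLevels integer matrix of levels (1..Ng; NA outside mask).
#' @param mask logical matrix, same shape.
#' @param direction angle in degrees (0, 45, 90, 135).
#' @param nLevels Ng; defaults to `max(sliceLevels, na.rm = TRUE)`.
#' @param distance pixel offset (1).
#' @return A [CooccurrenceMatrix-class].
#' @export
glcm <- function(sliceLevels, mask, direction, nLevels = NULL, distance = 1L) {
  stopifnot(any(mask))
  if (is.null(nLevels)) nLevels <- max(sliceLevels, na.rm = TRUE)
  nLevels <- as.integer(nLevels)
  off <- .dirOffset(direction) * as.integer(distance)
  nr <- nrow(sliceLevels); nc <- ncol(sliceLevels)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  counts <- matrix(0, nLevels, nLevels)
  if (length(r1) > 0 && length(c1) > 0) {
    a <- sliceLevels[r1, c1, drop = FALSE]
    b <- sliceLevels[r1 + off[1], c1 + off[2], drop = FALSE]
    ma <- mask[r1, c1, drop = FALSE] & mask[r1 + off[1], c1 + off[2], drop = FALSE]
    ok <- ma & !is.na(a) & !is.na(b)
    if (any(ok)) {
      idx <- (a[ok] - 1L) * nLevels + b[ok]
      tab <- tabulate(idx, nbins = nLevels * nLevels)
      counts <- matrix(tab, nLevels, nLevels, byrow = TRUE)
    }
  }
  sym <- counts + t(counts)
  n <- sum(sym)
  p <- if (n > 0) sym / n else sym
  new("CooccurrenceMatrix", p = p, direction = as.numeric(direction),
      distance = as.integer(distance), nPairs = as.integer(n))
}

#' Grey level run length matrix of one slice
#'
#' Maximal runs of equal level along the direction; runs break at mask
#' boundaries (and at excluded voxels). Every in-mask pixel belongs to
#' exactly one run per direction.
#'
#' @inheritParams glcm
#' @return A [RunLengthMatrix-class].
#' @export
glrlm <- function(sliceLevels, mask, direction, nLevels = NULL) {
  stopifnot(any(mask))
  if (is.null(nLevels)) nLevels <- max(sliceLevels, na.rm = TRUE)
  nLevels <- as.integer(nLevels)
  lv <- sliceLevels
  lv[!mask] <- NA_integer_
  lines <- .directionLines(lv, direction)
  runs <- list()
  for (ln in lines) {
    if (all(is.na(ln))) next
    r <- rle(as.vector(ln))
    keep <- !is.na(r$values)
    if (any(keep))
      runs[[length(runs) + 1L]] <- cbind(level = r$values[keep],
                                         len = r$lengths[keep])
  }
  if (length(runs) == 0L) {
    return(new("RunLengthMatrix", r = matrix(0, nLevels, 1),
               direction = as.numeric(direction), nPixels = 0L, nRuns = 0L))
  }
  allRuns <- do.call(rbind, runs)
  lmax <- max(allRuns[, "len"])
  r <- matrix(0, nLevels, lmax)
  for (i in seq_len(nrow(allRuns)))
    r[allRuns[i, "level"], allRuns[i, "len"]] <-
      r[allRuns[i, "level"], allRuns[i, "len"]] + 1
  new("RunLengthMatrix", r = r, direction = as.numeric(direction),
      nPixels = as.integer(sum(!is.na(lv))),
      nRuns = as.integer(nrow(allRuns)))
}

# Decompose a matrix into the scan lines of a direction. NA entries encode
# out-of-mask pixels and break runs naturally under rle.
.directionLines <- function(m, direction) {
  nr <- nrow(m); nc <- ncol(m)
  switch(as.character(direction),
    "0"  = lapply(seq_len(nr), function(i) m[i, ]),
    "90" = lapply(seq_len(nc), function(j) m[, j]),
    "45" = {
      # direction (-1, +1): anti-diagonals, i + j constant
      lapply(seq_len(nr + nc - 1L), function(s) {
        i <- seq(from = min(nr, s), by = -1L,
                 length.out = min(s, nr, nc, nr + nc - s))
        j <- s + 1L - i
        m[cbind(i, j)]
      })
    },
    "135" = {
      # direction (-1, -1): main diagonals, j - i constant
      lapply(seq(-(nr - 1L), nc - 1L), function(d) {
        i <- seq(from = max(1L, 1L - d), length.out =
                   min(nr, nc - d, nr + d, nc))
        j <- i + d
        m[cbind(i, j)]
      })
    },
    stop("direction must be one of 0, 45, 90, 135"))
}

# 0 * log2(0) := 0
.xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)

#' GLCM texture features
#'
#' The 18 co-occurrence features (IBSI definitions, entropies in bits):
#' angular second moment, autocorrelation, cluster prominence, cluster
#' shade, contrast, correlation, difference entropy, difference variance,
#' dissimilarity, entropy, the two information measures of correlation,
#' inverse difference moment, maximum probability, sum average, sum entropy,
#' sum variance and (joint) variance. A degenerate matrix with zero marginal
#' variance (constant slice) yields correlation 1 and IMC1 = IMC2 = 0.
#'
#' @param m a [CooccurrenceMatrix-class] with `nPairs > 0`.
#' @return named numeric vector of length 18.
#' @export
glcmFeatures <- function(m) {
  stopifnot(is(m, "CooccurrenceMatrix"))
  if (m@nPairs <= 0L) stop("empty co-occurrence matrix")
  p <- m@p
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)            # symmetric: mu_x = mu_y
  sx2 <- sum((seq_len(ng) - mu)^2 * px)
  sx <- sqrt(sx2)

  # diagonal and cross-diagonal distributions
  k_sum <- 2:(2 * ng)
  pxy_sum <- vapply(k_sum, function(k) sum(p[i + j == k]), 0)
  k_dif <- 0:(ng - 1)
  pxy_dif <- vapply(k_dif, function(k) sum(p[abs(i - j) == k]), 0)

  asm <- sum(p^2)
  autoc <- sum(i * j * p)
  mu2 <- 2 * mu
  clprom <- sum((i + j - mu2)^4 * p)
  clshade <- sum((i + j - mu2)^3 * p)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sx2 > 0) (sum(i * j * p) - mu^2) / sx2 else 1
  diffent <- -sum(.xlog2(pxy_dif))
  mu_dif <- sum(k_dif * pxy_dif)
  diffvar <- sum((k_dif - mu_dif)^2 * pxy_dif)
  dissim <- sum(abs(i - j) * p)
  entropy <- -sum(.xlog2(p))
  hx <- -sum(.xlog2(px))
  pxpy <- outer(px, px)
  hxy1 <- -sum(ifelse(p > 0 & pxpy > 0, p * log2(pxpy), 0))
  hxy2 <- -sum(.xlog2(pxpy))
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= entropy && (hxy2 - entropy) > 0)
    sqrt(1 - exp(-2 * log(2) * (hxy2 - entropy))) else 0
  idm <- sum(p / (1 + (i - j)^2))
  maxprob <- max(p)
  sumavg <- sum(k_sum * pxy_sum)
  sument <- -sum(.xlog2(pxy_sum))
  sumvar <- sum((k_sum - sumavg)^2 * pxy_sum)
  variance <- sx2

  c(asm = asm, autocorrelation = autoc, cluster_prominence = clprom,
    cluster_shade = clshade, contrast = contrast, correlation = correlation,
    difference_entropy = diffent, difference_variance = diffvar,
    dissimilarity = dissim, entropy = entropy, imc1 = imc1, imc2 = imc2,
    idm = idm, maximum_probability = maxprob, sum_average = sumavg,
    sum_entropy = sument, sum_variance = sumvar, variance = variance)
}

#' GLRLM texture features
#'
#' The 11 run length features (IBSI definitions): grey level non-uniformity,
#' high/low grey level run emphasis, long/short run emphasis, long run
#' high/low grey level emphasis, run length non-uniformity, run percentage,
#' short run high/low grey level emphasis.
#'
#' @param rl a [RunLengthMatrix-class] with `nRuns > 0`.
#' @return named numeric vector of length 11.
#' @export
glrlmFeatures <- function(rl) {
  stopifnot(is(rl, "RunLengthMatrix"))
  if (rl@nRuns <= 0L) stop("empty run length matrix")
  r <- rl@r
  ns <- rl@nRuns
  np <- rl@nPixels
  gi <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))      # grey level index
  lj <- t(matrix(seq_len(ncol(r)), ncol(r), nrow(r)))   # run length index
  ri <- rowSums(r)
  rj <- colSums(r)
  jj <- seq_len(ncol(r))
  ii <- seq_len(nrow(r))

  c(glnu = sum(ri^2) / ns,
    hglre = sum(ii^2 * ri) / ns,
    lglre = sum(ri / ii^2) / ns,
    lre = sum(jj^2 * rj) / ns,
    lrhgle = sum(gi^2 * lj^2 * r) / ns,
    lrlgle = sum(lj^2 / gi^2 * r) / ns,
    rlnu = sum(rj^2) / ns,
    run_percentage = ns / np,
    sre = sum(rj / jj^2) / ns,
    srhgle = sum(gi^2 / lj^2 * r) / ns,
    srlgle = sum(r / (gi^2 * lj^2)) / ns)
}

#' 2D-average aggregation of per-slice per-direction features
#'
#' For each feature: the mean across slices is taken within each direction
#' (skipping empty (slice, direction) cells), then the mean of the
#' directional means. Directions with no valid slice are dropped from the
#' outer mean.
#'
#' @param cells a list of lists: `cells[[direction]][[slice]]` is a named
#'   feature vector or `NULL` for an empty cell.
#' @return named numeric vector.
#' @export
aggregate2dAverage <- function(cells) {
  dirMeans <- list()
  for (d in seq_along(cells)) {
    vecs <- Filter(Negate(is.null), cells[[d]])
    if (length(vecs) > 0)
      dirMeans[[length(dirMeans) + 1L]] <- colMeans(do.call(rbind, vecs))
  }
  if (length(dirMeans) == 0L) stop("VOI too small for texture")
  colMeans(do.call(rbind, dirMeans))
}

#' All texture features of one VOI
#'
#' Convenience wrapper: quantizes the sample ([quantizeFbn()]), builds the
#' per-slice directional GLCMs and GLRLMs at one-pixel distance, computes
#' the 18 + 11 features per matrix, and aggregates by [aggregate2dAverage()].
#'
#' @param sample a [VoiSample-class].
#' @param nLevels grey levels for quantization (default 32).
#' @return named numeric vector of 29 features, names prefixed
#'   `glcm_` / `glrlm_`.
#' @export
textureFeatures <- function(sample, nLevels = 32) {
  q <- quantizeFbn(sample, nLevels = nLevels)
  dirs <- textureDirections()
  cellsC <- lapply(dirs, function(d) {
    lapply(q@slices, function(s) {
      if (!any(s$mask)) return(NULL)
      g <- glcm(s$levels, s$mask, d, nLevels = q@nLevels)
      if (g@nPairs == 0L) NULL else glcmFeatures(g)
    })
  })
  cellsR <- lapply(dirs, function(d) {
    lapply(q@slices, function(s) {
      if (!any(s$mask)) return(NULL)
      r <- glrlm(s$levels, s$mask, d, nLevels = q@nLevels)
      if (r@nRuns == 0L) NULL else glrlmFeatures(r)
    })
  })
  fc <- aggregate2dAverage(cellsC)
  fr <- aggregate2dAverage(cellsR)
  out <- c(fc, fr)
  names(out) <- c(paste0("glcm_", names(fc)), paste0("glrlm_", names(fr)))
  out
}
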