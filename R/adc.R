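#' Voxelwise apparent diffusion coefficient map
#'
#' Fits the monoexponential decay `S(b) = S0 * exp(-b * ADC)` per voxel by
#' ordinary least squares of `log S(b)` on `b`, using the nonzero b-values
#' only. The b = 0 frame, when present, is excluded to avoid perfusion
#' contamination of the estimate. Voxels with any nonpositive intensity at a
#' nonzero b-value get ADC = 0 and are counted in the `qcNonpositive`
#' attribute of the result.
#'
#' @param series a [DwSeries-class] with at least two nonzero b-values.
#' @param method `"loglinear"` (default, OLS on the log signal) or
#'   `"nls"` (nonlinear least squares on the raw signal, per voxel; slow,
#'   intended for small inputs).
#' @return An [ImageVolume-class] with `modality = "adc"`, units mm^2/s. The
#'   attribute `qcNonpositive` on the data array counts zeroed voxels.
#' @examples
#' sig <- function(b) 1000 * exp(-0.0012 * b)
#' frames <- lapply(c(0, 100, 400, 800), function(b)
#'   imageVolume(array(sig(b), c(2, 2, 1)), modality = "dw"))
#' adc <- fitAdcMap(dwSeries(frames, c(0, 100, 400, 800)))
#' volumeData(adc)[1]  # 0.0012
#' @export
fitAdcMap <- function(series, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  stopifnot(is(series, "DwSeries"))
  nz <- which(series@bvalues > 0)
  if (length(nz) < 2L) stop("need >= 2 nonzero b-values")
  b <- series@bvalues[nz]
  dims <- dim(series@frames[[nz[1]]]@data)
  S <- matrix(vapply(nz, function(i) as.vector(series@frames[[i]]@data),
                     numeric(prod(dims))), nrow = prod(dims))
  bad <- rowSums(S <= 0) > 0
  adc <- numeric(nrow(S))
  if (method == "loglinear") {
    # slope of ln S on b, vectorized over voxels
    bc <- b - mean(b)
    denom <- sum(bc^2)
    ok <- !bad
    if (any(ok)) {
      L <- log(S[ok, , drop = FALSE])
      adc[ok] <- -as.vector(L %*% bc) / denom
    }
  } else {
    for (v in which(!bad)) {
      s <- S[v, ]
      bc <- b - mean(b)
      start_adc <- max(-sum(log(s) * bc) / sum(bc^2), 1e-6)
      fit <- try(stats::nls(s ~ s0 * exp(-b * a),
                            start = list(s0 = max(s), a = start_adc),
                            control = stats::nls.control(warnOnly = TRUE)),
                 silent = TRUE)
      adc[v] <- if (inherits(fit, "try-error")) 0 else
        stats::coef(fit)[["a"]]
    }
  }
  out <- array(adc, dims)
  attr(out, "qcNonpositive") <- sum(bad)
  imageVolume(out, spacing = series@frames[[nz[1]]]@spacing, modality = "adc")
}

#' Read an FSL-style b-value sidecar
#'
#' Plain text, whitespace/newline separated, one value per acquired frame.
#'
#' @param path file path.
#' @return numeric vector of b-values.
#' @export
readBvals <- function(path) {
  scan(path, what = numeric(), quiet = TRUE)
}
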