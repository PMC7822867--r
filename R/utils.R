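# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never clobbers user randomness.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a base seed and an index (keeps derived
# seeds well inside 32-bit integer range).
childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483399) + 1L
}

#' Canonical feature name registry
#'
#' Returns the canonical column names of the feature table: 11 first-order
#' histogram features per modality (prefixes `adc_`, `t2w_`), 18 grey level
#' co-occurrence features (`t2w_glcm_*`) and 11 run length features
#' (`t2w_glrlm_*`), 51 columns in total.
#'
#' @param which one of `"all"`, `"adc_hist"`, `"t2w_hist"`, `"t2w_texture"`,
#'   `"hist"`, `"glcm"`, `"glrlm"` (the last three unprefixed).
#' @return character vector of feature names.
#' @examples
#' length(featureNames())      # 51
#' featureNames("glrlm")
#' @export
featureNames <- function(which = "all") {
  hist <- c("kurtosis", "maximum", "mean", "median", "minimum",
            "p10", "p25", "p75", "p90", "skewness", "sd")
  glcm <- c("asm", "autocorrelation", "cluster_prominence", "cluster_shade",
            "contrast", "correlation", "difference_entropy",
            "difference_variance", "dissimilarity", "entropy", "imc1",
            "imc2", "idm", "maximum_probability", "sum_average",
            "sum_entropy", "sum_variance", "variance")
  glrlm <- c("glnu", "hglre", "lglre", "lre", "lrhgle", "lrlgle", "rlnu",
             "run_percentage", "sre", "srhgle", "srlgle")
  switch(which,
    hist = hist,
    glcm = glcm,
    glrlm = glrlm,
    adc_hist = paste0("adc_", hist),
    t2w_hist = paste0("t2w_", hist),
    t2w_texture = c(paste0("t2w_glcm_", glcm), paste0("t2w_glrlm_", glrlm)),
    all = c(paste0("adc_", hist), paste0("t2w_", hist),
            paste0("t2w_glcm_", glcm), paste0("t2w_glrlm_", glrlm)),
    stop("unknown feature group: ", which))
}

#' The six evaluated feature sets
#'
#' Named list of feature-column groups evaluated by the hold-one-site-out
#' analysis: ADC histogram, T2W histogram and T2W texture alone, plus the
#' three combinations studied.
#'
#' @return named list of character vectors of feature names.
#' @export
featureSets <- function() {
  list(
    adc_hist              = featureNames("adc_hist"),
    t2w_hist              = featureNames("t2w_hist"),
    t2w_texture           = featureNames("t2w_texture"),
    t2w_hist_texture      = c(featureNames("t2w_hist"),
                              featureNames("t2w_texture")),
    adc_t2w_hist          = c(featureNames("adc_hist"),
                              featureNames("t2w_hist")),
    adc_t2w_hist_texture  = c(featureNames("adc_hist"),
                              featureNames("t2w_hist"),
                              featureNames("t2w_texture")))
}
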