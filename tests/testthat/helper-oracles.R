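# Independent brute-force oracles and fixture builders. These deliberately
# use naive loop-based computations so they share no code path with the
# package implementation.

# GLCM by explicit enumeration of all ordered pixel pairs at the offset.
oracleGlcm <- function(levels, mask, direction, nLevels) {
  off <- switch(as.character(direction),
                "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                "135" = c(-1, -1))
  counts <- matrix(0, nLevels, nLevels)
  nr <- nrow(levels); nc <- ncol(levels)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
    if (!mask[i, j] || !mask[i2, j2]) next
    a <- levels[i, j]; b <- levels[i2, j2]
    if (is.na(a) || is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1   # symmetrize pair by pair
  }
  counts
}

# GLRLM by stepping along each line pixel by pixel.
oracleGlrlm <- function(levels, mask, direction, nLevels) {
  off <- switch(as.character(direction),
                "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                "135" = c(-1, -1))
  nr <- nrow(levels); nc <- ncol(levels)
  lv <- levels
  lv[!mask] <- NA
  starts <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ip <- i - off[1]; jp <- j - off[2]
    if (ip < 1 || ip > nr || jp < 1 || jp > nc)
      starts[[length(starts) + 1]] <- c(i, j)
  }
  runs <- matrix(0, nLevels, nr * nc)
  for (s in starts) {
    i <- s[1]; j <- s[2]
    cur <- NA; len <- 0
    while (i >= 1 && i <= nr && j >= 1 && j <= nc) {
      v <- lv[i, j]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) runs[cur, len] <- runs[cur, len] + 1
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      i <- i + off[1]; j <- j + off[2]
    }
    if (!is.na(cur)) runs[cur, len] <- runs[cur, len] + 1
  }
  lmax <- max(c(1, which(colSums(runs) > 0)))
  runs[, seq_len(lmax), drop = FALSE]
}

# GLCM features by direct formula evaluation with explicit loops; entropies
# computed in nats and converted, so log handling is independent too.
oracleGlcmFeatures <- function(p) {
  ng <- nrow(p)
  ent0 <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }   # nats
  px <- sapply(seq_len(ng), function(i) sum(p[i, ]))
  py <- sapply(seq_len(ng), function(j) sum(p[, j]))
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  psum <- rep(0, 2 * ng); pdif <- rep(0, ng)
  acc <- 0; contrast <- 0; dissim <- 0; idm <- 0
  clp <- 0; cls <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    acc <- acc + i * j * p[i, j]
    contrast <- contrast + (i - j)^2 * p[i, j]
    dissim <- dissim + abs(i - j) * p[i, j]
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    clp <- clp + (i + j - mux - muy)^4 * p[i, j]
    cls <- cls + (i + j - mux - muy)^3 * p[i, j]
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  ks <- 2:(2 * ng); kd <- 0:(ng - 1)
  psum <- psum[ks - 1]
  hxy <- ent0(p)
  hx <- ent0(px)
  hy <- ent0(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log(q)
      hxy2 <- hxy2 - q * log(q)
    }
  }
  sa <- sum(ks * psum)
  mudif <- sum(kd * pdif)
  list(
    asm = sum(p^2),
    autocorrelation = acc,
    cluster_prominence = clp,
    cluster_shade = cls,
    contrast = contrast,
    correlation = if (sx > 0 && sy > 0) (acc - mux * muy) / (sx * sy) else 1,
    difference_entropy = ent0(pdif) / log(2),
    difference_variance = sum((kd - mudif)^2 * pdif),
    dissimilarity = dissim,
    entropy = hxy / log(2),
    imc1 = if (hx > 0) (hxy - hxy1) / log(2) / (hx / log(2)) else 0,
    imc2 = if (hxy2 > hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0,
    idm = idm,
    maximum_probability = max(p),
    sum_average = sa,
    sum_entropy = ent0(psum) / log(2),
    sum_variance = sum((ks - sa)^2 * psum),
    variance = sx^2)
}

# GLRLM features by direct loops.
oracleGlrlmFeatures <- function(r, nPixels) {
  ns <- sum(r)
  acc <- function(f) {
    tot <- 0
    for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r)))
      tot <- tot + f(i, j) * r[i, j]
    tot / ns
  }
  list(glnu = sum(sapply(seq_len(nrow(r)), function(i) sum(r[i, ]))^2) / ns,
       hglre = acc(function(i, j) i^2),
       lglre = acc(function(i, j) 1 / i^2),
       lre = acc(function(i, j) j^2),
       lrhgle = acc(function(i, j) i^2 * j^2),
       lrlgle = acc(function(i, j) j^2 / i^2),
       rlnu = sum(sapply(seq_len(ncol(r)), function(j) sum(r[, j]))^2) / ns,
       run_percentage = ns / nPixels,
       sre = acc(function(i, j) 1 / j^2),
       srhgle = acc(function(i, j) i^2 / j^2),
       srlgle = acc(function(i, j) 1 / (i^2 * j^2)))
}

# Random masked quantized slice.
randomSlice <- function(n = 8, nLevels = 4, pMask = 0.8, seed = 1) {
  set.seed(seed)
  repeat {
    mask <- matrix(runif(n * n) < pMask, n, n)
    if (sum(mask) >= 2) break
  }
  levels <- matrix(sample.int(nLevels, n * n, replace = TRUE), n, n)
  levels[!mask] <- NA
  list(levels = levels, mask = mask)
}

# Build a VoiSample directly from a full-volume + mask (via extractVoi).
sliceSample <- function(mat, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(mat), ncol(mat))
  vol <- pzgrade::imageVolume(array(mat, c(nrow(mat), ncol(mat), 1)))
  m <- pzgrade::voiMask(array(mask, c(nrow(mat), ncol(mat), 1)))
  pzgrade::extractVoi(vol, m, excludeOutliersFlag = FALSE)
}

# Synthetic multi-site feature table (no images) on canonical feature
# names; classEffect shifts int_high tumors, siteOffsets shift whole sites.
makeFeatureTable <- function(nSites = 6, patientsPerSite = 8, nFeatures = 8,
                             classEffect = 0, siteOffsets = NULL,
                             propLow = 0.4, seed = 1, balanced = FALSE,
                             logScale = FALSE,
                             features = pzgrade::featureNames("adc_hist")[seq_len(nFeatures)]) {
  set.seed(seed)
  rows <- list()
  pid <- 0
  for (s in seq_len(nSites)) {
    for (p in seq_len(patientsPerSite)) {
      pid <- pid + 1
      isLow <- if (balanced) p %% 2 == 0 else runif(1) < propLow
      gg <- if (isLow) 1L else sample(2:5, 1)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("P%03d", pid),
        site_id = LETTERS[s], grade_group = gg,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  X <- matrix(rnorm(n * length(features)), n, length(features))
  isHigh <- tab$grade_group >= 2
  X[isHigh, ] <- X[isHigh, ] + classEffect
  if (!is.null(siteOffsets))
    for (s in seq_len(nSites))
      X[tab$site_id == LETTERS[s], ] <-
        X[tab$site_id == LETTERS[s], ] + siteOffsets[s]
  # log-scale tables are positive with multiplicative effects, the regime
  # the log-transforming ANOVA screen assumes
  if (logScale) X <- exp(X)
  colnames(X) <- features
  cbind(tab, as.data.frame(X))
}

# Small two-site cohort config for fast end-to-end tests.
tinyConfig <- function(...) {
  pzgrade::cohortConfig(sites = data.frame(
    site_id = c("A", "B"), gain = c(1, 1.4), offset = c(0, 12),
    n_patients = c(4, 4), prop_low = c(0.5, 0.5),
    stringsAsFactors = FALSE), ...)
}
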