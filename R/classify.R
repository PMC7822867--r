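# Hold-one-institution-out linear SVM evaluation with patient-grouped
# stratified inner 10-fold cross-validation, concurrent misclassification-
# cost grid search and recursive feature elimination, Youden threshold
# transfer, and DeLong/paired-t inference.

#' The misclassification-cost grid
#'
#' Seven logarithmically spaced values of the SVM cost C between 10^-1 and
#' 10^1 inclusive.
#'
#' @return numeric vector of length 7.
#' @examples
#' makeCGrid()
#' @export
makeCGrid <- function() 10^seq(-1, 1, length.out = 7)

# ---- internal SVM helpers -------------------------------------------------

# class labels are a factor with levels c("low", "int_high"); decision
# scores are oriented so higher = int_high.
.classLevels <- c("low", "int_high")

.classWeights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

# z-scoring parameters from a training matrix; constant columns get sd 1
.scaleParams <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

.applyScale <- function(X, sp) sweep(sweep(X, 2, sp$mu), 2, sp$sd, "/")

.fitLinearSvm <- function(X, y, cost) {
  e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
             class.weights = .classWeights(y))
}

# signed decision scores, oriented so higher = int_high; computed directly
# as x.w - rho (identical to libsvm's decision values for a linear kernel,
# whose positive side is the first training label)
.decisionScores <- function(model, X, w = NULL) {
  if (is.null(w)) w <- .svmWeights(model)
  s <- as.numeric(X %*% w) - model$rho
  if (model$levels[model$labels][1] == "low") -s else s
}

.svmWeights <- function(model) {
  as.numeric(crossprod(model$coefs, model$SV))
}

# balanced (mean per-class) misclassification error of score predictions
.balancedError <- function(pred, truth) {
  errs <- vapply(levels(truth)[table(truth) > 0], function(cl)
    mean(pred[truth == cl] != cl), 0)
  mean(errs)
}

# One RFE elimination path: fits at sizes p, p-1, ..., 1 (eliminating the
# smallest-|weight| feature each step) and records validation scores and
# balanced errors at every size. Returns per-size results indexed by k.
.rfePath <- function(Xtr, ytr, Xva, yva, cost) {
  p <- ncol(Xtr)
  err <- rep(NA_real_, p)
  scores <- vector("list", p)
  active <- seq_len(p)
  while (length(active) >= 1L) {
    fit <- .fitLinearSvm(Xtr[, active, drop = FALSE], ytr, cost)
    w <- .svmWeights(fit)
    sc <- .decisionScores(fit, Xva[, active, drop = FALSE], w = w)
    k <- length(active)
    pred <- factor(ifelse(sc > 0, "int_high", "low"), levels = .classLevels)
    err[k] <- .balancedError(pred, yva)
    scores[[k]] <- sc
    if (k == 1L) break
    active <- active[-which.min(abs(w))]
  }
  list(err = err, scores = scores)
}

# RFE on a full training set with fixed cost: returns the active feature
# index set at size k.
.rfeSelect <- function(X, y, cost, k) {
  active <- seq_len(ncol(X))
  while (length(active) > k) {
    fit <- .fitLinearSvm(X[, active, drop = FALSE], y, cost)
    w <- .svmWeights(fit)
    active <- active[-which.min(abs(w))]
  }
  active
}

# Patient-grouped stratified fold assignment: patients are stratified by
# their class (a patient with any int_high tumor counts int_high) and dealt
# round-robin into nFolds folds in a seeded random order.
.patientFolds <- function(patientId, cls, nFolds, seed) {
  pats <- unique(patientId)
  pcls <- vapply(pats, function(p) {
    if (any(cls[patientId == p] == "int_high")) "int_high" else "low"
  }, "")
  withSeed(seed, {
    fold <- stats::setNames(integer(length(pats)), pats)
    for (cl in unique(pcls)) {
      g <- sample(pats[pcls == cl])
      fold[g] <- (seq_along(g) - 1L) %% nFolds + 1L
    }
    fold
  })
}

#' Inner cross-validated SVM training
#'
#' Stratified patient-level 10-fold cross-validation on the training table,
#' tuning the misclassification cost C (7-point log grid, [makeCGrid()])
#' and the recursive-feature-elimination subset size concurrently: for
#' every (C, subset size k) the mean balanced misclassification error over
#' the validation folds is computed along one elimination path per (C,
#' fold), and the argmin pair is selected (ties: fewer features, then
#' smaller C). The final model refits on all training data with RFE down to
#' the selected size; the Youden threshold is computed from the pooled
#' out-of-fold decision scores of the selected pair. Features are z-scored
#' with training-fold parameters throughout.
#'
#' @param table feature data.frame (rows = tumors) with `patient_id`,
#'   `grade_group` and feature columns.
#' @param features character vector of feature columns to use.
#' @param seed integer seed for the fold assignment.
#' @param nFolds inner folds (default 10).
#' @return list (a model spec) with `C`, `selectedFeatures`, `threshold`,
#'   `model` (e1071 fit on z-scored data), `scaleParams`, `classWeights`,
#'   `cvError`, `foldOf` (per-patient fold).
#' @export
innerCvTrain <- function(table, features, seed, nFolds = 10) {
  cls <- factor(dichotomize(table$grade_group), levels = .classLevels)
  if (length(unique(cls)) < 2) stop("degenerate training set: one class")
  if (length(unique(table$patient_id)) < nFolds)
    stop("need >= ", nFolds, " patients for inner cross-validation")
  X <- as.matrix(table[, features, drop = FALSE])
  grid <- makeCGrid()
  p <- ncol(X)
  foldOf <- .patientFolds(table$patient_id, as.character(cls), nFolds, seed)
  rowFold <- foldOf[table$patient_id]

  errCube <- array(NA_real_, c(length(grid), p, nFolds))
  oofScores <- array(vector("list", 1), c(length(grid), p, nFolds))
  oofIdx <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    va <- which(rowFold == f)
    tr <- which(rowFold != f)
    oofIdx[[f]] <- va
    if (length(va) == 0L || length(unique(cls[tr])) < 2) next
    sp <- .scaleParams(X[tr, , drop = FALSE])
    Xtr <- .applyScale(X[tr, , drop = FALSE], sp)
    Xva <- .applyScale(X[va, , drop = FALSE], sp)
    for (ci in seq_along(grid)) {
      path <- .rfePath(Xtr, cls[tr], Xva, cls[va], grid[ci])
      errCube[ci, , f] <- path$err
      for (k in seq_len(p)) oofScores[[ci, k, f]] <- path$scores[[k]]
    }
  }
  meanErr <- apply(errCube, c(1, 2), mean, na.rm = TRUE)
  best <- which(meanErr == min(meanErr, na.rm = TRUE), arr.ind = TRUE)
  # ties: fewest features, then smallest C
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
  bestC <- grid[best[1]]
  bestK <- best[2]

  # pooled out-of-fold scores of the selected pair -> Youden threshold
  poolScores <- unlist(lapply(seq_len(nFolds), function(f)
    oofScores[[best[1], bestK, f]]))
  poolLabels <- cls[unlist(lapply(seq_len(nFolds), function(f)
    if (is.null(oofScores[[best[1], bestK, f]])) integer(0) else oofIdx[[f]]))]
  thr <- youdenThreshold(poolScores, poolLabels)

  sp <- .scaleParams(X)
  Xs <- .applyScale(X, sp)
  sel <- .rfeSelect(Xs, cls, bestC, bestK)
  finalFit <- .fitLinearSvm(Xs[, sel, drop = FALSE], cls, bestC)

  list(C = bestC, selectedFeatures = features[sel],
       threshold = thr$threshold, model = finalFit, scaleParams = sp,
       featureIdx = sel, classWeights = .classWeights(cls),
       cvError = meanErr[best[1], bestK], foldOf = foldOf)
}

#' Youden-index threshold
#'
#' The decision threshold maximizing sensitivity + specificity - 1 over
#' candidate cuts midway between adjacent sorted unique scores (plus
#' outside cuts). Ties are broken toward higher specificity (the higher
#' threshold).
#'
#' @param scores numeric decision scores (higher = int_high).
#' @param labels factor/character with classes `"low"` and `"int_high"`.
#' @return list with `threshold`, `J` (the Youden index there).
#' @export
youdenThreshold <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = .classLevels)
  stopifnot(length(unique(labels)) == 2)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  pos <- labels == "int_high"
  J <- vapply(cand, function(t) {
    sens <- mean(scores[pos] > t)
    spec <- mean(scores[!pos] <= t)
    sens + spec - 1
  }, 0)
  best <- max(J)
  # ties toward higher specificity = larger threshold
  thr <- max(cand[J >= best - 1e-12])
  list(threshold = thr, J = best)
}

# ---- ROC / AUC / DeLong ---------------------------------------------------

# DeLong structural components: V10 (per positive), V01 (per negative)
.delongComponents <- function(scores, pos) {
  xs <- scores[pos]
  ys <- scores[!pos]
  m <- length(xs); n <- length(ys)
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' ROC AUC with DeLong 95\% confidence interval
#'
#' AUC via the Mann-Whitney identity (midrank ties), identical to the
#' trapezoidal ROC area; the CI uses the DeLong variance, truncated to
#' \[0, 1\].
#'
#' @param scores numeric decision scores (higher = int_high).
#' @param labels classes `"low"`/`"int_high"`.
#' @return list with `auc`, `ci` (length 2), `se`, `degenerate` (TRUE when
#'   only one class is present, in which case auc is NA).
#' @export
rocAucCi <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = .classLevels)
  pos <- labels == "int_high"
  if (all(pos) || all(!pos))
    return(list(auc = NA_real_, ci = c(NA_real_, NA_real_), se = NA_real_,
                degenerate = TRUE))
  dc <- .delongComponents(scores, pos)
  s10 <- if (dc$m > 1) stats::var(dc$v10) else 0
  s01 <- if (dc$n > 1) stats::var(dc$v01) else 0
  se <- sqrt(s10 / dc$m + s01 / dc$n)
  ci <- pmin(pmax(dc$auc + c(-1, 1) * 1.959964 * se, 0), 1)
  list(auc = dc$auc, ci = ci, se = se, degenerate = FALSE)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided p value of the paired AUC difference z-test using DeLong
#' structural components on identical tumors.
#'
#' @param scoresA,scoresB paired decision scores on the same cases.
#' @param labels classes `"low"`/`"int_high"`.
#' @return list with `aucA`, `aucB`, `p`, `degenerate` (TRUE, with p 1,
#'   when the difference variance is zero).
#' @export
delongCompare <- function(scoresA, scoresB, labels) {
  stopifnot(length(scoresA) == length(scoresB))
  labels <- factor(as.character(labels), levels = .classLevels)
  pos <- labels == "int_high"
  stopifnot(any(pos), any(!pos))
  da <- .delongComponents(scoresA, pos)
  db <- .delongComponents(scoresB, pos)
  m <- da$m; n <- da$n
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  if (m < 2) s10 <- matrix(0, 2, 2)
  if (n < 2) s01 <- matrix(0, 2, 2)
  varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
             (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (varDiff <= 0)
    return(list(aucA = da$auc, aucB = db$auc, p = 1, degenerate = TRUE))
  z <- (da$auc - db$auc) / sqrt(varDiff)
  list(aucA = da$auc, aucB = db$auc, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Test-set performance at a fixed threshold
#'
#' Sensitivity on the intermediate/high class, specificity on the low
#' class, and balanced accuracy (their mean). A class missing from the
#' test set leaves the corresponding member NA.
#'
#' @param scores numeric decision scores.
#' @param labels classes `"low"`/`"int_high"`.
#' @param threshold decision threshold (scores > threshold predict
#'   int_high).
#' @return list with `accuracy` (balanced), `sensitivity`, `specificity`.
#' @export
sitePerformance <- function(scores, labels, threshold) {
  labels <- factor(as.character(labels), levels = .classLevels)
  pos <- labels == "int_high"
  sens <- if (any(pos)) mean(scores[pos] > threshold) else NA_real_
  spec <- if (any(!pos)) mean(scores[!pos] <= threshold) else NA_real_
  acc <- mean(c(sens, spec), na.rm = TRUE)
  list(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Paired t-test of a per-site metric between two feature sets
#'
#' @param metricA,metricB numeric per-site values on the same sites
#'   (>= 3 pairs).
#' @return list with `p`, `meanDiff`, `degenerate` (TRUE with p 1 when the
#'   differences have zero variance).
#' @export
pairedSiteTtest <- function(metricA, metricB) {
  stopifnot(length(metricA) == length(metricB), length(metricA) >= 3)
  d <- metricA - metricB
  if (stats::sd(d) == 0)
    return(list(p = 1, meanDiff = mean(d), degenerate = TRUE))
  tt <- stats::t.test(metricA, metricB, paired = TRUE)
  list(p = tt$p.value, meanDiff = mean(d), degenerate = FALSE)
}

#' Hold-one-institution-out evaluation
#'
#' For each site in turn the remaining sites form the training set. Within
#' each split the ANOVA site screen ([anovaSiteScreen()]) is applied to the
#' training data only (leakage-free default; set `screen = "none"` to skip
#' or `"all"` to screen once on the full table beforehand), then each
#' feature set is trained by [innerCvTrain()] and evaluated on the held-out
#' site at tumor level with the training-derived Youden threshold.
#'
#' @param table feature data.frame with `patient_id`, `site_id`,
#'   `grade_group` and feature columns.
#' @param sets named list of feature-name vectors (default [featureSets()]).
#' @param seed integer; per-split inner-CV seeds derive from it.
#' @param screen `"train"` (default), `"all"`, or `"none"`.
#' @param nFolds inner folds (default 10).
#' @return list of per-site results; each element has `site`, and per
#'   feature set a list with `model` (spec from [innerCvTrain()]),
#'   `scores`, `labels`, `auc`, `ci`, `accuracy`, `sensitivity`,
#'   `specificity`, `aucDegenerate`.
#' @export
holdOneSiteOut <- function(table, sets = featureSets(), seed = 1,
                           screen = c("train", "all", "none"), nFolds = 10) {
  screen <- match.arg(screen)
  sites <- sort(unique(table$site_id))
  if (length(sites) < 2) stop("need >= 2 sites for hold-one-site-out")
  cls <- dichotomize(table$grade_group)
  globalKeep <- NULL
  if (screen == "all") {
    scr <- anovaSiteScreen(table)
    globalKeep <- scr$feature[scr$keep]
  }
  results <- vector("list", length(sites))
  names(results) <- sites
  for (si in seq_along(sites)) {
    s <- sites[si]
    test <- table[table$site_id == s, , drop = FALSE]
    train <- table[table$site_id != s, , drop = FALSE]
    if (length(unique(dichotomize(train$grade_group))) < 2)
      stop("degenerate training set for held-out site ", s)
    keep <- switch(screen,
      none = featureNames(),
      all = globalKeep,
      train = tryCatch({
        scr <- anovaSiteScreen(train)
        scr$feature[scr$keep]
      }, error = function(e) {
        # a screen that cannot be estimated (e.g. a training site missing
        # one class) performs no exclusion
        warning("site screen skipped for held-out site ", s, ": ",
                conditionMessage(e))
        featureNames()
      }))
    res <- list(site = s)
    for (nm in names(sets)) {
      feats <- intersect(sets[[nm]], keep)
      if (length(feats) == 0L) feats <- sets[[nm]]  # screen emptied the set
      spec <- innerCvTrain(train, feats, seed = childSeed(seed, si))
      Xte <- .applyScale(as.matrix(test[, feats, drop = FALSE]),
                         spec$scaleParams)
      sc <- .decisionScores(spec$model,
                            Xte[, spec$featureIdx, drop = FALSE])
      lab <- factor(dichotomize(test$grade_group), levels = .classLevels)
      roc <- rocAucCi(sc, lab)
      perf <- sitePerformance(sc, lab, spec$threshold)
      res[[nm]] <- list(model = spec, scores = sc, labels = lab,
                        auc = roc$auc, ci = roc$ci,
                        aucDegenerate = roc$degenerate,
                        accuracy = perf$accuracy,
                        sensitivity = perf$sensitivity,
                        specificity = perf$specificity,
                        trainPatients = unique(train$patient_id),
                        testPatients = unique(test$patient_id))
    }
    results[[si]] <- res
  }
  results
}

#' Summarize hold-one-site-out results
#'
#' @param results output of [holdOneSiteOut()].
#' @return data.frame with one row per (site, feature set): auc, ci bounds,
#'   accuracy, sensitivity, specificity.
#' @export
summarizeSiteResults <- function(results) {
  rows <- list()
  for (res in results) {
    for (nm in setdiff(names(res), "site")) {
      r <- res[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        site = res$site, feature_set = nm, auc = r$auc,
        ci_lo = r$ci[1], ci_hi = r$ci[2], accuracy = r$accuracy,
        sensitivity = r$sensitivity, specificity = r$specificity,
        n_selected = length(r$model$selectedFeatures),
        C = r$model$C, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
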