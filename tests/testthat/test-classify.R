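# Linear SVM evaluation machinery: C grid, Youden threshold, ROC/AUC,
# DeLong, inner CV with RFE, hold-one-site-out, paired tests.

test_that("the C grid is the 7-point log spacing over 0.1..10", {
  g <- makeCGrid()
  expect_length(g, 7)
  expect_equal(g[1], 0.1)
  expect_equal(g[4], 1)
  expect_equal(g[7], 10)
  expect_equal(diff(log10(g)), rep(1 / 3, 6), tolerance = 1e-12)
})

test_that("Youden threshold separates separable scores at the midpoint", {
  r <- youdenThreshold(c(0.1, 0.2, 0.8, 0.9),
                       c("low", "low", "int_high", "int_high"))
  expect_equal(r$J, 1)
  expect_equal(r$threshold, 0.5)
  # anti-separation: best J <= 0
  r2 <- youdenThreshold(c(0.9, 0.8, 0.2, 0.1),
                        c("low", "low", "int_high", "int_high"))
  expect_lte(r2$J, 0)
  # random scores: J near 0
  set.seed(61)
  r3 <- youdenThreshold(rnorm(200), sample(c("low", "int_high"), 200,
                                           replace = TRUE))
  expect_lt(r3$J, 0.35)
})

test_that("AUC equals the Mann-Whitney identity and pROC agrees", {
  set.seed(62)
  for (i in 1:10) {
    sc <- rnorm(40) + rep(c(0, 1), each = 20)
    lab <- rep(c("low", "int_high"), each = 20)
    roc <- rocAucCi(sc, lab)
    mw <- mwuTest(sc[lab == "int_high"], sc[lab == "low"], exactMax = 0)
    expect_equal(roc$auc, mw$U / 400, tolerance = 1e-12)
  }
  # perfect separation and all-tied scores
  expect_equal(rocAucCi(c(1, 2, 3, 4),
                        c("low", "low", "int_high", "int_high"))$auc, 1)
  expect_equal(rocAucCi(rep(1, 10), rep(c("low", "int_high"), 5))$auc, 0.5)
  # one class only: degenerate
  expect_true(rocAucCi(1:3, rep("low", 3))$degenerate)
  skip_if_not_installed("pROC")
  sc <- rnorm(60) + rep(c(0, 0.8), 30)
  lab <- rep(c("low", "int_high"), 30)
  ours <- rocAucCi(sc, lab)
  ref <- pROC::ci.auc(pROC::roc(lab, sc, levels = c("low", "int_high"),
                                direction = "<", quiet = TRUE),
                      method = "delong")
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(ours$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-6)
})

test_that("DeLong comparison is symmetric, degenerate-safe, and matches pROC", {
  set.seed(63)
  lab <- rep(c("low", "int_high"), 30)
  a <- rnorm(60) + (lab == "int_high") * 1
  b <- a * 0.5 + rnorm(60) * 0.5
  d1 <- delongCompare(a, b, lab)
  d2 <- delongCompare(b, a, lab)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
  expect_equal(delongCompare(a, a, lab)$p, 1)
  expect_true(delongCompare(a, a, lab)$degenerate)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(lab, a, levels = c("low", "int_high"), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(lab, b, levels = c("low", "int_high"), direction = "<",
                  quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(d1$p, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong holds its level under the null at adequate sample size", {
  set.seed(66)
  rej <- replicate(200, {
    lab <- rep(c("low", "int_high"), each = 30)
    base <- rnorm(60) + (lab == "int_high") * 0.5
    a <- base + rnorm(60, sd = 0.5)
    b <- base + rnorm(60, sd = 0.5)   # same information, equal true AUC
    delongCompare(a, b, lab)$p < 0.05
  })
  expect_lt(mean(rej), 0.1)
  expect_gt(mean(rej), 0.005)
})

test_that("DeLong has power against an uninformative competitor", {
  set.seed(64)
  hits <- 0
  for (i in 1:50) {
    lab <- rep(c("low", "int_high"), each = 250)
    good <- rnorm(500) + (lab == "int_high") * 1
    noise <- rnorm(500)
    if (delongCompare(good, noise, lab)$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("site performance implements balanced accuracy at a threshold", {
  # perfect classifier
  p <- sitePerformance(c(-1, -1, 1, 1),
                       c("low", "low", "int_high", "int_high"), 0)
  expect_equal(unlist(p), c(accuracy = 1, sensitivity = 1, specificity = 1))
  # all-int_high predictor on a mixed test set
  p2 <- sitePerformance(rep(1, 6), rep(c("low", "int_high"), 3), 0)
  expect_equal(p2$sensitivity, 1)
  expect_equal(p2$specificity, 0)
  expect_equal(p2$accuracy, 0.5)
  # TP=3 FN=1 TN=4 FP=1
  sc <- c(1, 1, 1, -1, -1, -1, -1, -1, 1)
  lb <- c(rep("int_high", 4), rep("low", 5))
  p3 <- sitePerformance(sc, lb, 0)
  expect_equal(p3$sensitivity, 0.75)
  expect_equal(p3$specificity, 0.8)
  expect_equal(p3$accuracy, 0.775)
  # missing class: that member is NA
  p4 <- sitePerformance(c(1, -1), c("int_high", "int_high"), 0)
  expect_true(is.na(p4$specificity))
  expect_equal(p4$sensitivity, 0.5)
})

test_that("paired site t-test handles signal, nulls, and degeneracy", {
  expect_equal(pairedSiteTtest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(65)
  a <- c(0.7, 0.75, 0.8, 0.72, 0.78, 0.74)
  b <- a + 0.1 + rnorm(6, sd = 0.01)
  expect_lt(pairedSiteTtest(b, a)$p, 0.05)
  # sign flip of all differences preserves p
  expect_equal(pairedSiteTtest(a, b)$p, pairedSiteTtest(b, a)$p)
  ref <- t.test(b, a, paired = TRUE)
  expect_equal(pairedSiteTtest(b, a)$p, ref$p.value)
})

test_that("inner CV recovers informative features and groups patients", {
  feats <- featureNames("adc_hist")[1:10]
  recovered <- 0
  for (seed in 1:10) {
    tab <- makeFeatureTable(nSites = 2, patientsPerSite = 20,
                            nFeatures = 10, classEffect = 0, seed = seed)
    isHigh <- tab$grade_group >= 2
    tab[[feats[1]]] <- tab[[feats[1]]] + isHigh * 2.5
    tab[[feats[2]]] <- tab[[feats[2]]] - isHigh * 2.5
    spec <- innerCvTrain(tab, feats, seed = seed)
    if (all(feats[1:2] %in% spec$selectedFeatures)) recovered <- recovered + 1
  }
  expect_gte(recovered / 10, 0.9)
})

test_that("tumors of one patient always share an inner fold", {
  tab <- makeFeatureTable(nSites = 2, patientsPerSite = 10, nFeatures = 4,
                          classEffect = 1, seed = 71)
  tab2 <- rbind(tab, tab)   # duplicate every tumor of every patient
  spec <- innerCvTrain(tab2, featureNames("adc_hist")[1:4], seed = 71)
  rowFold <- spec$foldOf[tab2$patient_id]
  byPatient <- tapply(rowFold, tab2$patient_id, function(f)
    length(unique(f)))
  expect_true(all(byPatient == 1))
  # folds stratify by class: each fold's patients mix classes roughly
  expect_equal(sort(unique(spec$foldOf)), 1:10)
})

test_that("permuted labels give chance-level out-of-fold performance", {
  set.seed(72)
  errs <- sapply(1:10, function(seed) {
    tab <- makeFeatureTable(nSites = 2, patientsPerSite = 15,
                            nFeatures = 6, classEffect = 0,
                            seed = 100 + seed)
    spec <- innerCvTrain(tab, featureNames("adc_hist")[1:6], seed = seed)
    spec$cvError
  })
  expect_gt(mean(errs), 0.3)   # balanced error ~ 0.5 under the null
  expect_lt(abs(mean(errs) - 0.5), 0.12)
})

test_that("degenerate training inputs are rejected", {
  tab <- makeFeatureTable(nSites = 2, patientsPerSite = 10, nFeatures = 4,
                          seed = 73)
  tab$grade_group <- 3
  expect_error(innerCvTrain(tab, featureNames("adc_hist")[1:4], seed = 1),
               "degenerate")
  expect_error(holdOneSiteOut(makeFeatureTable(nSites = 1,
    patientsPerSite = 12, nFeatures = 4, seed = 74),
    sets = list(s = featureNames("adc_hist")[1:4])), ">= 2 sites")
})

test_that("hold-one-site-out partitions sites and never leaks patients", {
  tab <- makeFeatureTable(nSites = 4, patientsPerSite = 12, nFeatures = 6,
                          classEffect = 1.5, seed = 75)
  sets <- list(small = featureNames("adc_hist")[1:6])
  res <- holdOneSiteOut(tab, sets = sets, seed = 75, screen = "none")
  expect_length(res, 4)
  expect_equal(sort(names(res)), sort(unique(tab$site_id)))
  for (r in res) {
    expect_length(intersect(r$small$trainPatients, r$small$testPatients), 0)
    testPats <- unique(tab$patient_id[tab$site_id == r$site])
    expect_setequal(r$small$testPatients, testPats)
    expect_length(r$small$scores, sum(tab$site_id == r$site))
    # AUC-U identity on every split
    mw <- mwuTest(r$small$scores[r$small$labels == "int_high"],
                  r$small$scores[r$small$labels == "low"], exactMax = 0)
    n1 <- sum(r$small$labels == "int_high")
    n0 <- sum(r$small$labels == "low")
    expect_equal(r$small$auc, mw$U / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("hold-one-site-out is deterministic under fixed seeds", {
  tab <- makeFeatureTable(nSites = 3, patientsPerSite = 10, nFeatures = 5,
                          classEffect = 1, seed = 76)
  sets <- list(s = featureNames("adc_hist")[1:5])
  r1 <- summarizeSiteResults(holdOneSiteOut(tab, sets, seed = 7,
                                            screen = "none"))
  r2 <- summarizeSiteResults(holdOneSiteOut(tab, sets, seed = 7,
                                            screen = "none"))
  expect_identical(r1, r2)
})
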