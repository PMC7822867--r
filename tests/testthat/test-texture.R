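# Texture module: quantization, GLCM/GLRLM construction and features.

test_that("fixed-bin-number quantization assigns equal-width bins", {
  s <- sliceSample(matrix(c(0, 1, 2, 3), 1, 4))
  q <- quantizeFbn(s, 4)
  expect_equal(as.vector(q@slices[[1]]$levels), 1:4)
  expect_equal(q@binEdges, seq(0, 3, length.out = 5))

  # uniform values on [0, 32): each integer window maps to its own level
  v <- seq(0, 31.999, length.out = 320)
  q2 <- quantizeFbn(sliceSample(matrix(v, 16, 20)), 32)
  lv <- as.vector(q2@slices[[1]]$levels)
  expect_equal(sort(unique(lv)), 1:32)
  expect_equal(lv, pmin(floor(matrix(v, 16, 20) / 31.999 * 32) + 1, 32),
               ignore_attr = TRUE)

  # constant VOI: single occupied level 1
  qc <- quantizeFbn(sliceSample(matrix(7, 3, 3)), 32)
  expect_true(all(qc@slices[[1]]$levels == 1L))

  # max value goes to level Ng, not Ng + 1
  q3 <- quantizeFbn(sliceSample(matrix(c(0, 10), 1, 2)), 8)
  expect_equal(as.vector(q3@slices[[1]]$levels), c(1L, 8L))
})

test_that("GLCM matches the hand-enumerated 2x3 example", {
  lv <- matrix(c(1, 1, 1, 2, 2, 2), 2, 3)  # rows: [1,1,2] / [1,2,2]
  g <- glcm(lv, matrix(TRUE, 2, 3), 0, nLevels = 2)
  expect_equal(g@nPairs, 8L)
  expect_equal(g@p, matrix(0.25, 2, 2))
  f <- glcmFeatures(g)
  expect_equal(unname(f["asm"]), 0.25)
  expect_equal(unname(f["entropy"]), 2.0)
  expect_equal(unname(f["contrast"]), 0.5)
  expect_equal(unname(f["maximum_probability"]), 0.25)
})

test_that("GLCM is symmetric, normalized, and empty when no pair exists", {
  s <- randomSlice(seed = 11)
  for (d in textureDirections()) {
    g <- glcm(s$levels, s$mask, d, nLevels = 4)
    if (g@nPairs > 0) {
      expect_equal(sum(g@p), 1)
      expect_equal(g@p, t(g@p))
    }
  }
  # single isolated pixel: no pair in any direction
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  lv <- matrix(1L, 3, 3)
  g <- glcm(lv, m, 0, nLevels = 2)
  expect_equal(g@nPairs, 0L)
})

test_that("constant slice yields the degenerate GLCM closed forms", {
  g <- glcm(matrix(1L, 4, 4), matrix(TRUE, 4, 4), 0, nLevels = 32)
  f <- glcmFeatures(g)
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["idm"]), 1)
  expect_equal(unname(f["correlation"]), 1)   # degenerate convention
  expect_equal(unname(f["imc1"]), 0)
  expect_equal(unname(f["imc2"]), 0)
})

test_that("uniform GLCM has entropy 2 log2(Ng) and ASM 1/Ng^2", {
  ng <- 4L
  m <- new("CooccurrenceMatrix", p = matrix(1 / ng^2, ng, ng),
           direction = 0, distance = 1L, nPairs = 16L)
  f <- glcmFeatures(m)
  expect_equal(unname(f["entropy"]), 2 * log2(ng))
  expect_equal(unname(f["asm"]), 1 / ng^2)
})

test_that("GLRLM matches run enumeration and conserves pixels", {
  r <- glrlm(matrix(c(1, 1, 2, 2, 2), 1, 5), matrix(TRUE, 1, 5), 0,
             nLevels = 2)
  expect_equal(r@r[1, 2], 1)
  expect_equal(r@r[2, 3], 1)
  expect_equal(r@nRuns, 2L)
  expect_equal(r@nPixels, 5L)
  f <- glrlmFeatures(r)
  expect_equal(unname(f["sre"]), (1 / 4 + 1 / 9) / 2)
  expect_equal(unname(f["glnu"]), 1)
  expect_equal(unname(f["rlnu"]), 1)
  expect_equal(unname(f["run_percentage"]), 2 / 5)

  # a mask hole splits a run
  m <- matrix(c(TRUE, TRUE, FALSE, TRUE), 1, 4)
  r2 <- glrlm(matrix(1L, 1, 4), m, 0, nLevels = 1)
  expect_equal(r2@nRuns, 2L)
  expect_equal(r2@r[1, 1], 1)   # length-1 run
  expect_equal(r2@r[1, 2], 1)   # length-2 run

  # constant N-pixel row: one run of length N
  r3 <- glrlm(matrix(2L, 1, 7), matrix(TRUE, 1, 7), 0, nLevels = 2)
  expect_equal(r3@nRuns, 1L)
  f3 <- glrlmFeatures(r3)
  expect_equal(unname(f3["lre"]), 49)
  expect_equal(unname(f3["sre"]), 1 / 49)
  expect_equal(unname(f3["run_percentage"]), 1 / 7)
})

test_that("all-singleton runs give SRE = LRE = run percentage = 1", {
  lv <- matrix(c(1L, 2L), 4, 4)  # vertical stripes alternate along rows
  r <- glrlm(lv, matrix(TRUE, 4, 4), 90, nLevels = 2)
  f <- glrlmFeatures(r)
  expect_equal(unname(f["sre"]), 1)
  expect_equal(unname(f["lre"]), 1)
  expect_equal(unname(f["run_percentage"]), 1)
})

test_that("GLRLM pixel conservation holds on random masked slices", {
  for (seed in 1:10) {
    s <- randomSlice(seed = seed)
    for (d in textureDirections()) {
      r <- glrlm(s$levels, s$mask, d, nLevels = 4)
      expect_equal(sum(r@r %*% seq_len(ncol(r@r))), sum(s$mask))
      expect_equal(r@nPixels, sum(s$mask))
    }
  }
})

test_that("pipeline GLCM/GLRLM and features match the brute-force oracle", {
  for (seed in 1:12) {
    s <- randomSlice(n = 8, nLevels = 4, seed = seed)
    for (d in textureDirections()) {
      g <- glcm(s$levels, s$mask, d, nLevels = 4)
      counts <- oracleGlcm(s$levels, s$mask, d, 4)
      expect_equal(g@nPairs, as.integer(sum(counts)))
      if (sum(counts) > 0) {
        expect_equal(g@p, counts / sum(counts))
        fo <- oracleGlcmFeatures(g@p)
        fi <- glcmFeatures(g)
        for (nm in names(fo))
          expect_equal(unname(fi[nm]), fo[[nm]], tolerance = 1e-12,
                       label = paste("glcm", nm, "seed", seed, "dir", d))
      }
      r <- glrlm(s$levels, s$mask, d, nLevels = 4)
      ro <- oracleGlrlm(s$levels, s$mask, d, 4)
      expect_equal(r@r, ro[, seq_len(ncol(r@r)), drop = FALSE],
                   label = paste("glrlm seed", seed, "dir", d))
      fo <- oracleGlrlmFeatures(ro, sum(s$mask))
      fi <- glrlmFeatures(r)
      for (nm in names(fo))
        expect_equal(unname(fi[nm]), fo[[nm]], tolerance = 1e-12)
    }
  }
})

test_that("2D-average aggregation nests slice means inside direction means", {
  fv <- function(x) c(a = x)
  cells <- list(list(fv(1), fv(3)),   # direction 1: slices 1, 3
                list(fv(5)),          # direction 2
                list(NULL),           # direction 3: empty, dropped
                list())               # direction 4: empty, dropped
  expect_equal(aggregate2dAverage(cells), c(a = mean(c(2, 5))))
  # identical vectors in every cell pass through unchanged
  cells2 <- rep(list(rep(list(c(a = 7, b = 2)), 3)), 4)
  expect_equal(aggregate2dAverage(cells2), c(a = 7, b = 2))
  expect_error(aggregate2dAverage(list(list(NULL), list(NULL))),
               "too small")
})

test_that("nested equals flat averaging under equal counts", {
  set.seed(42)
  vols <- array(rnorm(10 * 10 * 3, 100, 15), c(10, 10, 3))
  samp <- extractVoi(imageVolume(vols),
                     voiMask(array(TRUE, c(10, 10, 3))),
                     excludeOutliersFlag = FALSE)
  q <- quantizeFbn(samp, 8)
  dirs <- textureDirections()
  cells <- lapply(dirs, function(d)
    lapply(q@slices, function(s) glcmFeatures(glcm(s$levels, s$mask, d,
                                                   nLevels = 8))))
  nested <- aggregate2dAverage(cells)
  flat <- colMeans(do.call(rbind, unlist(cells, recursive = FALSE)))
  expect_equal(nested, flat, tolerance = 1e-12)
})

test_that("90-degree rotation leaves direction-averaged features unchanged", {
  set.seed(7)
  m <- matrix(rnorm(144, 50, 10), 12, 12)
  rot90 <- function(x) t(x)[, rev(seq_len(nrow(x))), drop = FALSE]
  f1 <- textureFeatures(sliceSample(m), nLevels = 8)
  f2 <- textureFeatures(sliceSample(rot90(m)), nLevels = 8)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("texture features are invariant to intensity shifts", {
  set.seed(8)
  m <- matrix(rnorm(100, 80, 12), 10, 10)
  f1 <- textureFeatures(sliceSample(m), nLevels = 16)
  f2 <- textureFeatures(sliceSample(m + 250), nLevels = 16)
  expect_equal(f1, f2, tolerance = 1e-10)
})
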