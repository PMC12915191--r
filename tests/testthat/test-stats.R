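test_that("KS test closed cases: identical samples and disjoint supports", {
  a <- c(1, 2, 3, 4)
  r <- ksTwoSample(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$pValue, 1)
  r2 <- ksTwoSample(c(0, 0, 0), c(1, 1, 1))
  expect_equal(r2$statistic, 1)
  expect_error(ksTwoSample(numeric(0), a), "nonempty")
})

test_that("KS statistic matches the brute-force ECDF sweep to 1e-12", {
  set.seed(123)
  for (i in 1:200) {
    a <- rnorm(sample(5:60, 1))
    b <- rnorm(sample(5:60, 1), mean = runif(1, -1, 1))
    expect_equal(ksTwoSample(a, b)$statistic, bruteKS(a, b),
                 tolerance = 1e-12)
  }
})

test_that("KS statistic is invariant under strictly monotone transforms", {
  set.seed(9)
  a <- rnorm(40); b <- rnorm(55, 0.5)
  d0 <- ksTwoSample(a, b)$statistic
  expect_equal(ksTwoSample(exp(a), exp(b))$statistic, d0, tolerance = 1e-15)
  expect_equal(ksTwoSample(atan(a), atan(b))$statistic, d0, tolerance = 1e-15)
})

test_that("t-test closed cases and degenerate conventions", {
  a <- c(1, 2, 3, 4, 5)
  r <- tTestUnpaired(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$pValue, 1)
  same <- tTestUnpaired(c(2, 2, 2), c(2, 2, 2))
  expect_true(same$degenerate)
  expect_equal(same$pValue, 1)
  diffc <- tTestUnpaired(c(2, 2, 2), c(3, 3, 3))
  expect_true(diffc$degenerate)
  expect_equal(diffc$pValue, 0)
})

test_that("t-test has power ~1 at d = 1, n = 50 and calibrated type-I error", {
  set.seed(21)
  rej <- replicate(400, tTestUnpaired(rnorm(50), rnorm(50, 1))$pValue < 0.05)
  expect_gte(mean(rej), 0.9)
  set.seed(22)
  t1 <- replicate(2000, tTestUnpaired(rnorm(20), rnorm(20))$pValue < 0.05)
  expect_lt(abs(mean(t1) - 0.05), 0.015)
})

test_that("significance bands map p-values across the band boundaries", {
  expect_equal(significanceBand(0.2), "n.s.")
  expect_equal(significanceBand(0.05), "*")
  expect_equal(significanceBand(0.010), "**")
  expect_equal(significanceBand(0.001), "***")
  expect_equal(significanceBand(1e-5), "****")
  expect_equal(significanceBand(0.050001), "n.s.")
})

test_that("Pearson colocalization closed forms and affine invariance", {
  set.seed(3)
  a <- matrix(runif(400), 20)
  expect_equal(pearsonColoc(a, a), 1)
  expect_equal(pearsonColoc(a, max(a) - a), -1)
  expect_equal(pearsonColoc(a, 3 * a + 2), 1, tolerance = 1e-12)
  b <- matrix(runif(400), 20)
  expect_equal(pearsonColoc(a, b), pearsonColoc(a, 10 * b + 5),
               tolerance = 1e-12)
  expect_error(pearsonColoc(a, matrix(1, 20, 20)), "zero variance")
})

test_that("independent noise channels have |r| < 0.05 in at least 95% of seeds", {
  ok <- sapply(1:40, function(s) {
    set.seed(s)
    abs(pearsonColoc(matrix(rnorm(1e4), 100), matrix(rnorm(1e4), 100))) < 0.05
  })
  expect_gte(mean(ok), 0.95)
})

test_that("per-ROI Pearson reporting returns mean and spread", {
  set.seed(4)
  a <- matrix(runif(900), 30)
  b <- a + matrix(rnorm(900, sd = 0.2), 30)
  rois <- list(row(a) <= 15, row(a) > 15)
  res <- pearsonColocRois(a, b, rois)
  expect_length(res$perRoi, 2)
  expect_equal(res$mean, mean(res$perRoi))
})

test_that("Manders coefficients: nested, half-overlap and disjoint masks", {
  img <- matrix(1, 10, 10)
  maskA <- matrix(FALSE, 10, 10); maskA[3:6, 3:6] <- TRUE
  maskB <- matrix(TRUE, 10, 10)
  expect_equal(mandersColoc(img, img, maskA, maskB)$m1, 1)
  ## exactly half of A's intensity lies inside B's mask
  chanA <- matrix(0, 10, 10); chanA[1:4, 1] <- c(2, 2, 1, 3)
  mA <- chanA > 0
  mB <- matrix(FALSE, 10, 10); mB[1:2, 1] <- TRUE   # covers intensity 4 of 8
  expect_equal(mandersColoc(chanA, img, mA, mB)$m1, 0.5)
  mC <- matrix(FALSE, 10, 10); mC[9:10, 9:10] <- TRUE
  r <- mandersColoc(img, img, maskA, mC)
  expect_equal(r$m1, 0)
  expect_equal(r$m2, 0)
  expect_error(mandersColoc(img, img, matrix(FALSE, 10, 10), maskB), "M1")
})

test_that("M1 and M2 stay in [0,1] and coincide for identical inputs", {
  set.seed(6)
  for (i in 1:20) {
    a <- matrix(runif(100), 10); b <- matrix(runif(100), 10)
    ma <- a > 0.4; mb <- b > 0.6
    if (!any(ma) || !any(mb)) next
    r <- mandersColoc(a, b, ma, mb)
    expect_gte(r$m1, 0); expect_lte(r$m1, 1)
    expect_gte(r$m2, 0); expect_lte(r$m2, 1)
  }
  a <- matrix(runif(100), 10); ma <- a > 0.3
  r <- mandersColoc(a, a, ma, ma)
  expect_equal(r$m1, r$m2)
})

test_that("Otsu segmentation splits a bimodal image at the right count", {
  set.seed(12)
  img <- matrix(c(rnorm(700, 10, 1), rnorm(300, 50, 2)), 50, 20)
  mask <- segmentChannel(img)
  expect_lt(abs(sum(mask) - 300) / 300, 0.01)
  ## fixed threshold honored exactly; idempotent on the binarized image
  expect_true(all(segmentChannel(img, "fixed", level = 0)))
  bin <- matrix(as.numeric(mask), 50, 20)
  expect_identical(segmentChannel(bin, "fixed", level = 0.5), mask)
  expect_error(segmentChannel(matrix(3, 5, 5)), "constant")
})

test_that("identical spot populations compare as indistinguishable", {
  set.seed(14)
  pop <- data.frame(rg = rgamma(80, 5), eccentricity = runif(80, 0, 0.5))
  res <- compareSizeEccentricity(pop, pop)
  expect_equal(res$rgTest$pValue, 1)
  expect_equal(res$eccTest$pValue, 1)
  expect_equal(unname(res$medianShift["rg"]), 0)
})

test_that("random splits of one population give well-calibrated KS p-values", {
  set.seed(15)
  pop <- rnorm(240)
  ps <- replicate(200, {
    idx <- sample(240, 120)
    ksTwoSample(pop[idx], pop[-idx])$pValue
  })
  ## p should be roughly uniform: no excess of small values
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.1)
  expect_gt(mean(ps), 0.35)
})
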