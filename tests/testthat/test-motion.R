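test_that("MSD of a hand-enumerated track and a stationary track", {
  tr <- data.frame(frame = 1:4, x = 0:3, y = 0)
  m <- computeMSD(tr, pixelSize = 1, dt = 1, maxLagFraction = 1)
  expect_equal(m$msd, c(1, 4, 9))
  expect_equal(m$n_pairs, c(3L, 2L, 1L))
  still <- data.frame(frame = 1:10, x = 2, y = 3)
  expect_true(all(computeMSD(still, 1, 1, 1)$msd == 0))
  expect_error(computeMSD(data.frame(frame = 1, x = 0, y = 0), 1, 1), "at least 2")
})

test_that("computeMSD agrees with the brute-force double loop to 1e-9", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    frames <- sort(sample(1:(n * 2), n))
    tr <- data.frame(frame = frames, x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
    a <- computeMSD(tr, pixelSize = 0.117, dt = 0.2, maxLagFraction = 0.5)
    b <- bruteMSD(tr, pixelSize = 0.117, dt = 0.2, maxLagFraction = 0.5)
    expect_equal(a$msd, b$msd, tolerance = 1e-9)
    expect_equal(a$lag, b$lag, tolerance = 1e-12)
    expect_equal(a$n_pairs, b$n_pairs)
  }
})

test_that("ensemble Brownian MSD matches 4 D tau", {
  set.seed(8)
  D <- 0.1; dt <- 0.2
  msum <- 0
  nT <- 300
  for (i in seq_len(nT)) {
    p <- simulateTrajectory(motionModel("normal", D), 200, dt)
    m <- computeMSD(data.frame(frame = 1:200, x = p[, 1], y = p[, 2]), 1, dt)
    msum <- msum + m$msd[1:5]
  }
  expect_true(all(abs(msum / nT - 4 * D * (1:5) * dt) / (4 * D * (1:5) * dt)
                  < 0.05))
})

test_that("alpha fitting recovers exact power laws", {
  lag <- (1:10) * 0.2
  brown <- data.frame(lag = lag, msd = 4 * 0.1 * lag)
  f <- fitAlpha(brown, 10)
  expect_equal(f$alpha, 1, tolerance = 1e-12)
  expect_equal(f$dGen, 0.1, tolerance = 1e-12)
  ballistic <- data.frame(lag = lag, msd = (2 * lag)^2)
  expect_equal(fitAlpha(ballistic, 10)$alpha, 2, tolerance = 1e-12)
  flat <- data.frame(lag = lag, msd = rep(0.5, 10))
  expect_equal(fitAlpha(flat, 10)$alpha, 0, tolerance = 1e-12)
})

test_that("zero MSD points are excluded with a warning; too few points fail softly", {
  msd <- data.frame(lag = (1:5) * 0.1, msd = c(0, 0.2, 0.4, 0.6, 0.8))
  expect_warning(f <- fitAlpha(msd, 5), "zero-valued")
  expect_true(is.finite(f$alpha))
  short <- data.frame(lag = c(0.1, 0.2), msd = c(1, 2))
  f2 <- fitAlpha(short, 2)
  expect_true(is.na(f2$alpha))
  expect_match(f2$reason, "fewer than 3")
})

test_that("MSD is invariant under time reversal and covariant under scaling", {
  set.seed(19)
  p <- simulateTrajectory(motionModel("normal", 0.1), 80, 0.2)
  tr <- data.frame(frame = 1:80, x = p[, 1], y = p[, 2])
  rev <- data.frame(frame = 1:80, x = rev(p[, 1]), y = rev(p[, 2]))
  expect_equal(computeMSD(tr, 1, 0.2)$msd, computeMSD(rev, 1, 0.2)$msd,
               tolerance = 1e-12)
  sc <- tr; sc$x <- 3 * sc$x; sc$y <- 3 * sc$y
  expect_equal(computeMSD(sc, 1, 0.2)$msd, 9 * computeMSD(tr, 1, 0.2)$msd,
               tolerance = 1e-12)
  expect_equal(fitAlpha(computeMSD(sc, 1, 0.2))$alpha,
               fitAlpha(computeMSD(tr, 1, 0.2))$alpha, tolerance = 1e-9)
})

test_that("per-track alpha recovery is unbiased with finite-track spread", {
  mkAlpha <- function(model, seedBase) {
    sapply(1:100, function(s) {
      p <- simulateTrajectory(model, 200, 0.2, seed = seedBase + s)
      fitAlpha(computeMSD(data.frame(frame = 1:200, x = p[, 1], y = p[, 2]),
                          1, 0.2), 10)$alpha
    })
  }
  aN <- mkAlpha(motionModel("normal", 0.1), 100)
  expect_lt(abs(mean(aN) - 1), 0.1)
  expect_gt(var(aN), 0)
  aS <- mkAlpha(motionModel("subdiffusive", 0.05, hurst = 0.25), 200)
  expect_lt(abs(mean(aS) - 0.5), 0.1)
  aD <- mkAlpha(motionModel("directed", 0.02, velocity = 1), 300)
  expect_gte(mean(aD), 1.7)
})

test_that("rule-based segmentation recovers the simulated diffusion mode", {
  windowAcc <- function(model, seedBase, nTracks = 15) {
    hits <- 0; tot <- 0
    for (s in seq_len(nTracks)) {
      p <- simulateTrajectory(model, 200, 0.2, seed = seedBase + s)
      segs <- segmentMotion(data.frame(frame = 1:200, x = p[, 1], y = p[, 2]),
                            window = 30L, stride = 5L, pixelSize = 1, dt = 0.2)
      tot <- tot + sum(segs$n_windows)
      hits <- hits + sum(segs$n_windows[segs$motion_class == attr(model, "lab")])
    }
    hits / tot
  }
  mD <- motionModel("directed", 0.02, velocity = 1); attr(mD, "lab") <- "directed"
  mC <- motionModel("confined", 0.1, confinementRadius = 0.25)
  attr(mC, "lab") <- "confined"
  mN <- motionModel("normal", 0.1); attr(mN, "lab") <- "normal"
  expect_gte(windowAcc(mD, 1000), 0.90)
  expect_gte(windowAcc(mC, 2000), 0.85)
  expect_gte(windowAcc(mN, 3000), 0.80)
})

test_that("dominant class and fractions follow segment frame counts", {
  segs <- data.frame(start_frame = c(1, 61), end_frame = c(60, 100),
                     motion_class = c("confined", "normal"),
                     window_alpha = c(0.2, 1), n_windows = c(5L, 3L))
  cls <- classifyTrack(segs)
  expect_equal(cls$dominant, "confined")
  expect_equal(unname(cls$fractions[c("confined", "normal")]), c(0.6, 0.4))
  expect_equal(sum(cls$fractions), 1)
  one <- data.frame(start_frame = 1, end_frame = 50,
                    motion_class = "subdiffusive", window_alpha = 0.4,
                    n_windows = 4L)
  expect_equal(classifyTrack(one)$dominant, "subdiffusive")
  expect_equal(unname(classifyTrack(one)$fractions["subdiffusive"]), 1)
})

test_that("a mixed population's class fractions are recovered within 0.1", {
  set.seed(55)
  mix <- c(directed = 6, confined = 7, normal = 7)
  doms <- c()
  for (cl in names(mix)) {
    model <- switch(cl,
      directed = motionModel("directed", 0.02, velocity = 1),
      confined = motionModel("confined", 0.1, confinementRadius = 0.25),
      normal = motionModel("normal", 0.1))
    for (i in seq_len(mix[[cl]])) {
      p <- simulateTrajectory(model, 150, 0.2)
      segs <- segmentMotion(data.frame(frame = 1:150, x = p[, 1], y = p[, 2]),
                            window = 30L, stride = 10L, pixelSize = 1, dt = 0.2)
      doms <- c(doms, classifyTrack(segs)$dominant)
    }
  }
  est <- table(factor(doms, levels = c("normal", "directed", "confined",
                                       "subdiffusive"))) / length(doms)
  want <- c(normal = 7, directed = 6, confined = 7, subdiffusive = 0) / 20
  expect_lt(max(abs(est[names(want)] - want)), 0.1)
})
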