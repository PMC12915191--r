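test_that("motion model validity rejects bad parameters", {
  expect_error(motionModel("confined", 0.1), "confinementRadius")
  expect_error(motionModel("subdiffusive", 0.1, hurst = 0.7), "hurst")
  expect_error(motionModel("subdiffusive", 0.1, hurst = 0), "hurst")
  expect_error(motionModel("normal", -1), "diffusionCoefficient")
  expect_error(motionModel("directed", 0.1), "velocity")
  expect_s4_class(motionModel("subdiffusive", 0.1, hurst = 0.5), "MotionModel")
})

test_that("zero-diffusion trajectory never moves and n_steps positions return", {
  xy <- simulateTrajectory(motionModel("normal", 0), 25, 0.2, seed = 5)
  expect_equal(dim(xy), c(25L, 2L))
  expect_true(all(xy == 0))
  expect_equal(nrow(simulateTrajectory(motionModel("normal", 0.1), 1, 0.1)), 1L)
  expect_error(simulateTrajectory(motionModel("normal", 0.1), 0, 0.1), "nSteps")
  expect_error(simulateTrajectory(motionModel("normal", 0.1), 10, -1), "dt")
})

test_that("Brownian mean squared step matches 4 D dt", {
  D <- 0.1; dt <- 0.1
  xy <- simulateTrajectory(motionModel("normal", D), 1e5, dt, seed = 1)
  st <- diff(xy[, 1])^2 + diff(xy[, 2])^2
  se <- sd(st) / sqrt(length(st))
  expect_lt(abs(mean(st) - 4 * D * dt), 3 * se)
})

test_that("fractional Brownian subdiffusion has ensemble log-log slope 2H", {
  set.seed(42)
  H <- 0.25
  msds <- sapply(seq_len(200), function(i) {
    p <- simulateTrajectory(motionModel("subdiffusive", 0.05, hurst = H),
                            200, 0.2)
    m <- computeMSD(data.frame(frame = 1:200, x = p[, 1], y = p[, 2]),
                    pixelSize = 1, dt = 0.2)
    m$msd[1:10]
  })
  em <- rowMeans(msds)
  slope <- coef(lm(log(em) ~ log((1:10) * 0.2)))[2]
  expect_lt(abs(slope - 2 * H), 0.05)
})

test_that("confined trajectories never leave the disk and the MSD plateaus", {
  R <- 0.5
  p <- simulateTrajectory(motionModel("confined", 0.1, confinementRadius = R),
                          5000, 0.2, seed = 3)
  expect_true(all(sqrt(rowSums(p^2)) <= R + 1e-12))
  expect_lte(max(dist(p[seq(1, 5000, by = 10), ])), 2 * R)
  m <- computeMSD(data.frame(frame = 1:5000, x = p[, 1], y = p[, 2]),
                  pixelSize = 1, dt = 0.2, maxLagFraction = 0.5)
  expect_true(all(m$msd <= 4 * R^2))
})

test_that("identical seed reproduces trajectories bit for bit", {
  m <- motionModel("subdiffusive", 0.05, hurst = 0.3)
  expect_identical(simulateTrajectory(m, 100, 0.2, seed = 9),
                   simulateTrajectory(m, 100, 0.2, seed = 9))
  m2 <- motionModel("directed", 0.05, velocity = 1)
  expect_identical(simulateTrajectory(m2, 50, 0.2, seed = 4),
                   simulateTrajectory(m2, 50, 0.2, seed = 4))
})

test_that("cell geometry annulus area matches the analytic value", {
  r <- 100; w <- 4
  geom <- makeCellGeometry(c(428L, 684L), r, w)
  analytic <- pi * (r^2 - (r - w)^2)
  expect_lt(abs(sum(membraneMask(geom)) - analytic) / analytic, 0.05)
  ## membrane within cell; deep interior disjoint from membrane
  expect_true(all(cellMask(geom)[membraneMask(geom)]))
  deep <- makeCellGeometry(c(428L, 684L), r - w, 0)
  expect_false(any(membraneMask(geom) & cellMask(deep)))
})

test_that("zero-width membrane is empty and oversized cells are rejected", {
  geom <- makeCellGeometry(c(64L, 64L), 20, 0)
  expect_equal(sum(membraneMask(geom)), 0L)
  expect_error(makeCellGeometry(c(64L, 64L), 40, 2), "fit")
})

test_that("geometry construction is deterministic", {
  g1 <- makeCellGeometry(c(100L, 120L), 30, 3)
  g2 <- makeCellGeometry(c(100L, 120L), 30, 3)
  expect_identical(cellMask(g1), cellMask(g2))
  expect_identical(membraneMask(g1), membraneMask(g2))
})

test_that("simulation config validity catches bad values", {
  expect_error(simulationConfig(nFrames = 0), "nFrames")
  expect_error(simulationConfig(psfSigma = -1), "psfSigma")
  expect_s4_class(simulationConfig(), "SimulationConfig")
})
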