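## A small geometry for occupancy tests: 64 x 64, cell radius 20,
## membrane width 3.
deliveryGeom <- function() makeCellGeometry(c(64L, 64L), 20, 3)

test_that("occupancy follows the distance transform to the membrane", {
  geom <- deliveryGeom()
  mem <- which(membraneMask(geom), arr.ind = TRUE)
  onPix <- mem[1, ]  # a membrane pixel (row, col)
  tr <- data.frame(frame = 1:3,
                   x = c(onPix[2] - 1, 31.5, 1),
                   y = c(onPix[1] - 1, 31.5, 1))
  occ <- assignOccupancy(tr, geom, dMem = 0)
  expect_equal(as.character(occ$occupancy),
               c("on_membrane", "in_cell", "outside"))
  ## a spot 3 px inward from the inner membrane edge is not on_membrane
  ## at dMem = 2: center (31.5, 31.5), membrane inner radius 17
  tr2 <- data.frame(frame = 1, x = 31.5 + 14, y = 31.5)
  occ2 <- assignOccupancy(tr2, geom, dMem = 2)
  expect_equal(as.character(occ2$occupancy), "in_cell")
  ## the same spot at dMem = 4 is on_membrane
  occ3 <- assignOccupancy(tr2, geom, dMem = 4)
  expect_equal(as.character(occ3$occupancy), "on_membrane")
  expect_error(assignOccupancy(data.frame(frame = 1, x = 100, y = 2), geom),
               "outside")
})

test_that("a scripted membrane-to-interior track reproduces its occupancy script", {
  geom <- deliveryGeom()
  ## walk straight from the membrane ring (radius ~18.5) to the center
  xs <- 31.5 + seq(18.5, 0, length.out = 12)
  tr <- data.frame(frame = 1:12, x = xs, y = 31.5)
  occ <- assignOccupancy(tr, geom, dMem = 2)
  d <- 31.5 + 20 - xs  # depth in px from the outer cell edge
  expect_true(all(as.character(occ$occupancy)[xs >= 31.5 + 15] == "on_membrane"))
  expect_true(all(as.character(occ$occupancy)[xs < 31.5 + 14] == "in_cell"))
})

mkOcc <- function(seq) data.frame(frame = seq_along(seq),
                                  occupancy = factor(seq,
                                    levels = c("on_membrane", "in_cell",
                                               "outside")))

test_that("each delivery-path rule classifies its scripted track exactly", {
  memThenIn <- mkOcc(c(rep("on_membrane", 5), rep("in_cell", 20)))
  expect_equal(classifyPath(memThenIn, alphaPost = 0.9)$label, "fast")
  expect_equal(classifyPath(memThenIn, alphaPost = 0.1)$label, "slow")
  expect_equal(classifyPath(memThenIn, alphaPost = 0.5)$label, "unclassified")
  attached <- mkOcc(rep("on_membrane", 25))
  expect_equal(classifyPath(attached, alphaPost = 0.1)$label, "attached")
  tempFixed <- mkOcc(c(rep("on_membrane", 15), rep("outside", 10)))
  expect_equal(classifyPath(tempFixed, alphaPost = 0.1)$label,
               "temporarily_fixed")
  ## short membrane visit with no entry: unclassified
  brief <- mkOcc(c(rep("on_membrane", 4), rep("outside", 4)))
  expect_equal(classifyPath(brief, alphaPost = 0.2)$label, "unclassified")
  ## boundary jitter of fewer than mMove in_cell frames does not count as
  ## moving into the cell
  jitterOcc <- mkOcc(c(rep("on_membrane", 12), "in_cell", "in_cell",
                       rep("on_membrane", 11)))
  expect_equal(classifyPath(jitterOcc, alphaPost = 0.9)$label,
               "temporarily_fixed")
})

test_that("residence is counted on the longest consecutive membrane run", {
  occ <- mkOcc(c(rep("on_membrane", 8), "outside",
                 rep("on_membrane", 12), rep("outside", 4)))
  cls <- classifyPath(occ, alphaPost = 0.5)
  expect_equal(cls$membraneResidence, 12)
  expect_equal(cls$label, "temporarily_fixed")
})

test_that("every track receives exactly one of the five labels", {
  set.seed(77)
  labels <- c("fast", "slow", "attached", "temporarily_fixed", "unclassified")
  for (i in 1:60) {
    occ <- mkOcc(sample(c("on_membrane", "in_cell", "outside"), 30,
                        replace = TRUE))
    out <- classifyPath(occ, alphaPost = runif(1, -0.2, 2.2))
    expect_true(out$label %in% labels)
    expect_length(out$label, 1L)
  }
})

test_that("raising the fast cut or lowering the slow cut shrinks those counts", {
  set.seed(88)
  occ <- mkOcc(c(rep("on_membrane", 5), rep("in_cell", 25)))
  alphas <- runif(200, 0, 2)
  countFast <- function(cut) sum(sapply(alphas, function(a)
    classifyPath(occ, a, alphaFast = cut)$label == "fast"))
  countSlow <- function(cut) sum(sapply(alphas, function(a)
    classifyPath(occ, a, alphaSlow = cut)$label == "slow"))
  expect_true(all(diff(sapply(c(0.5, 0.8, 1.2, 1.6), countFast)) <= 0))
  expect_true(all(diff(sapply(c(0.6, 0.3, 0.15, 0.05), countSlow)) <= 0))
})

test_that("payload counts separate a 5x-density condition at n = 3 replicates", {
  set.seed(5)
  render1 <- function(nEmit, seed) {
    cfg <- simulationConfig(nFrames = 1L, imageShape = c(214L, 342L),
                            seed = seed)
    pts <- cbind(runif(nEmit, 10, 330), runif(nEmit, 10, 200))
    truth <- data.frame(particle_id = seq_len(nEmit),
                        frame = rep(1L, nEmit),
                        x_px = pts[, 1], y_px = pts[, 2],
                        multiplicity = rep(1L, nEmit))
    r <- renderStack(truth, cfg)
    nrow(detectSpots(getFrame(r$stack, 1), 1.3, 700))
  }
  withAb <- sapply(1:3, function(i) render1(50, 100 + i))
  without <- sapply(1:3, function(i) render1(10, 200 + i))
  res <- countPayloads(list(with_antibody = withAb, without_antibody = without))
  expect_equal(res$summary$n_replicates, c(3L, 3L))
  expect_lt(res$tests$p_value, 0.05)
  ## control with no payloads at all: zero false positives on pure noise
  ctrl <- sapply(1:3, function(i) render1(0, 300 + i))
  expect_equal(unname(ctrl), c(0L, 0L, 0L))
})
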