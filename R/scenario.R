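## Ground-truth delivery scenarios. Each simulated payload follows a
## scripted path built from the motion models: membrane contact, an
## optional residence period, then cytosolic motion (or not), so the
## true path class of every particle is known by construction.

.umToPx <- function(um, pixelSize) um / pixelSize

## One scripted particle. Returns a data.frame of per-frame positions
## (0-based px) plus the per-frame motion class.
.scriptParticle <- function(path_class, anchorXY, inwardXY, nFrames, dt,
                            pixelSize, residenceFrames, cellRadiusPx,
                            centerXY) {
  jitter <- function(n, R = 0.08)
    simulateTrajectory(motionModel("confined", 0.02, confinementRadius = R),
                       n, dt) / pixelSize
  toPx <- function(traj) traj / pixelSize
  n <- nFrames
  if (path_class == "attached") {
    xy <- jitter(n)
    pos <- cbind(anchorXY[1] + xy[, 1], anchorXY[2] + xy[, 2])
    cls <- rep("confined", n)
  } else if (path_class == "temporarily_fixed") {
    nRes <- residenceFrames
    xy <- jitter(nRes)
    res <- cbind(anchorXY[1] + xy[, 1], anchorXY[2] + xy[, 2])
    nOut <- n - nRes
    ## detach outward, normal to the membrane, 2 px per frame
    outDir <- -inwardXY
    steps <- outer(seq_len(nOut), outDir * 2)
    wob <- jitter(nOut, R = 0.1)
    out <- cbind(res[nRes, 1] + steps[, 1] + wob[, 1],
                 res[nRes, 2] + steps[, 2] + wob[, 2])
    pos <- rbind(res, out)
    cls <- c(rep("confined", nRes), rep("directed", nOut))
  } else if (path_class %in% c("fast", "slow")) {
    nRes <- residenceFrames
    xy <- jitter(nRes)
    res <- cbind(anchorXY[1] + xy[, 1], anchorXY[2] + xy[, 2])
    nIn <- n - nRes
    if (path_class == "fast") {
      ## directed transport toward the cell interior; speed chosen so the
      ## track stays inside the cell for the recording
      pathPx <- 0.8 * cellRadiusPx
      vPx <- min(2.5, pathPx / nIn)               # px per frame
      v <- vPx * pixelSize / dt                   # um/s
      tr <- toPx(simulateTrajectory(
        motionModel("normal", 0.005), nIn, dt))
      drift <- outer(seq_len(nIn), inwardXY * vPx)
      pos2 <- cbind(res[nRes, 1] + drift[, 1] + tr[, 1],
                    res[nRes, 2] + drift[, 2] + tr[, 2])
      cls2 <- rep("directed", nIn)
    } else {
      ## move a short way in, then strongly subdiffusive in the cytosol;
      ## step sizes stay well below the default linking budget of
      ## 5 px/frame so the scripted truth is trackable as declared
      depth <- 10
      nGo <- 4L
      go <- outer(seq_len(nGo), inwardXY * (depth / nGo))
      sub <- toPx(simulateTrajectory(
        motionModel("subdiffusive", 0.01, hurst = 0.05), nIn - nGo, dt))
      inner <- c(res[nRes, 1] + inwardXY[1] * depth,
                 res[nRes, 2] + inwardXY[2] * depth)
      pos2 <- rbind(
        cbind(res[nRes, 1] + go[, 1], res[nRes, 2] + go[, 2]),
        cbind(inner[1] + sub[, 1], inner[2] + sub[, 2]))
      cls2 <- c(rep("directed", nGo), rep("subdiffusive", nIn - nGo))
    }
    pos <- rbind(res, pos2)
    cls <- c(rep("confined", nRes), cls2)
  } else stop("unknown path class: ", path_class)
  data.frame(frame = seq_len(n), x_px = pos[, 1], y_px = pos[, 2],
             motion_class = cls)
}

#' Simulate a ground-truth delivery scenario
#'
#' Builds scripted payload trajectories on a circular cell: `fast`
#' payloads touch the membrane briefly and then undergo directed
#' transport into the cytosol; `slow` payloads enter and then move
#' strongly subdiffusively; `attached` payloads stay confined on the
#' membrane for the whole recording; `temporarily_fixed` payloads sit on
#' the membrane past the residence rule and then detach. Payloads are
#' anchored at well-separated membrane angles so trajectories are
#' unambiguous to link. In the `"cleavable"` condition the mobile
#' (`fast`, `slow`) payloads are single emitters (multiplicity 1,
#' cleaved dye) and membrane-resident ones are intact four-dye clusters;
#' in the `"noncleavable"` condition every payload keeps multiplicity 4.
#'
#' @param nPerClass named integer vector with entries `fast`, `slow`,
#'   `attached`, `temporarily_fixed`.
#' @param condition `"cleavable"` or `"noncleavable"`.
#' @param config a [SimulationConfig-class].
#' @param cellRadiusPx,membraneWidthPx cell geometry in pixels.
#' @param residenceFrames scripted membrane residence before entry for
#'   mobile payloads (default 5, below the 10-frame rule) and before
#'   detachment for `temporarily_fixed` payloads (fixed at 15, above
#'   it).
#' @param seed integer seed.
#' @return a list with `truth` (particle_id, frame, x_px, y_px,
#'   motion_class, multiplicity, path_class), `geometry`
#'   (a [CellGeometry-class]) and `perParticle` (particle_id,
#'   path_class, multiplicity).
#' @export
simulateScenario <- function(nPerClass = c(fast = 4L, slow = 4L,
                                           attached = 4L,
                                           temporarily_fixed = 4L),
                             condition = c("cleavable", "noncleavable"),
                             config = simulationConfig(),
                             cellRadiusPx = 150, membraneWidthPx = 4,
                             residenceFrames = 5L, seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(all(names(nPerClass) %in%
                  c("fast", "slow", "attached", "temporarily_fixed")))
  set.seed(seed)
  geom <- makeCellGeometry(config@imageShape, cellRadiusPx, membraneWidthPx,
                           pixelSize = config@pixelSize)
  h <- config@imageShape[1]; w <- config@imageShape[2]
  center <- c((w - 1) / 2, (h - 1) / 2)
  classes <- rep(names(nPerClass), times = nPerClass)
  nP <- length(classes)
  ## well-separated anchor angles with a small random rotation
  theta <- 2 * pi * (seq_len(nP) - 1) / nP + stats::runif(1, 0, 2 * pi / nP)
  rMem <- cellRadiusPx - membraneWidthPx / 2
  truth <- vector("list", nP)
  for (p in seq_len(nP)) {
    anchor <- c(center[1] + rMem * cos(theta[p]),
                center[2] + rMem * sin(theta[p]))
    inward <- c(-cos(theta[p]), -sin(theta[p]))
    sc <- .scriptParticle(classes[p], anchor, inward, config@nFrames,
                          config@frameInterval, config@pixelSize,
                          if (classes[p] == "temporarily_fixed") 15L
                          else residenceFrames,
                          cellRadiusPx, center)
    mult <- if (condition == "noncleavable") 4L
            else if (classes[p] %in% c("fast", "slow")) 1L else 4L
    sc$particle_id <- p
    sc$multiplicity <- mult
    sc$path_class <- classes[p]
    truth[[p]] <- sc
  }
  truth <- do.call(rbind, truth)
  ## clamp to image bounds (detached particles can drift near the edge)
  truth$x_px <- pmin(pmax(truth$x_px, 1), w - 2)
  truth$y_px <- pmin(pmax(truth$y_px, 1), h - 2)
  perParticle <- unique(truth[, c("particle_id", "path_class",
                                  "multiplicity")])
  rownames(perParticle) <- NULL
  list(truth = truth[, c("particle_id", "frame", "x_px", "y_px",
                         "motion_class", "multiplicity", "path_class")],
       geometry = geom, perParticle = perParticle)
}

#' Simulate a detected-spot population of given payload multiplicity
#'
#' Renders frames containing well-separated stationary payloads of the
#' given multiplicity, runs the detector, and returns the detected
#' spots. Used to compare the size/eccentricity of cleaved single-dye
#' against non-cleaved four-dye populations.
#'
#' @param n number of detected spots to aim for (payloads rendered).
#' @param multiplicity 1 or 4.
#' @param config a [SimulationConfig-class]; its `imageShape` bounds the
#'   payloads-per-frame packing.
#' @param minIntensity detection threshold in photons.
#' @param seed integer seed.
#' @return a spot data.frame (see [detectSpots()]).
#' @export
simulateSpotPopulation <- function(n, multiplicity, config = simulationConfig(),
                                   minIntensity = 700, seed = 1L) {
  set.seed(seed)
  h <- config@imageShape[1]; w <- config@imageShape[2]
  margin <- ceiling(6 * config@psfSigma) + 4
  sep <- 14
  gx <- seq(margin, w - 1 - margin, by = sep)
  gy <- seq(margin, h - 1 - margin, by = sep)
  perFrame <- length(gx) * length(gy)
  nFrames <- ceiling(n / perFrame)
  grid <- expand.grid(x = gx, y = gy)
  spots <- vector("list", nFrames)
  left <- n
  for (f in seq_len(nFrames)) {
    k <- min(left, perFrame)
    idx <- sample.int(perFrame, k)
    truth <- data.frame(particle_id = seq_len(k), frame = 1L,
                        x_px = grid$x[idx] + stats::runif(k, -1, 1),
                        y_px = grid$y[idx] + stats::runif(k, -1, 1),
                        multiplicity = multiplicity)
    cfg1 <- config
    cfg1@nFrames <- 1L
    cfg1@seed <- as.integer((seed * 1000L + f) %% .Machine$integer.max)
    r <- renderStack(truth, cfg1)
    spots[[f]] <- detectSpots(getFrame(r$stack, 1), cfg1@psfSigma,
                              minIntensity, frameIndex = f)
    left <- left - k
  }
  out <- do.call(rbind, spots)
  rownames(out) <- NULL
  out
}
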