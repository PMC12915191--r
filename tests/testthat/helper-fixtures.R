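## Shared fixtures and independent oracles, all built in code.

## Analytic pixel-integrated Gaussian patch (possibly anisotropic),
## centered at (cx, cy) in 0-based patch coordinates.
gaussPatch <- function(size, cx, cy, sigmaX, sigmaY = sigmaX, photons = 1000,
                       background = 0) {
  px <- diff(pnorm(seq(-0.5, size - 0.5), mean = cx, sd = sigmaX))
  py <- diff(pnorm(seq(-0.5, size - 0.5), mean = cy, sd = sigmaY))
  background + photons * (py %o% px)
}

## Brute-force time-averaged MSD: explicit double loop over all ordered
## observation pairs, grouped by true frame difference.
bruteMSD <- function(track, pixelSize = 1, dt = 1, maxLagFraction = 0.25) {
  o <- order(track$frame)
  f <- track$frame[o]; x <- track$x[o] * pixelSize; y <- track$y[o] * pixelSize
  n <- length(f)
  kmax <- max(1L, floor(maxLagFraction * n))
  sums <- numeric(kmax); cnts <- integer(kmax)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- f[j] - f[i]
      if (k >= 1 && k <= kmax) {
        sums[k] <- sums[k] + (x[j] - x[i])^2 + (y[j] - y[i])^2
        cnts[k] <- cnts[k] + 1L
      }
    }
  }
  keep <- cnts > 0
  data.frame(lag = (seq_len(kmax) * dt)[keep], msd = (sums / cnts)[keep],
             n_pairs = cnts[keep])
}

## Brute-force ECDF sweep for the two-sample KS statistic.
bruteKS <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
}

## Brute-force minimum-cost assignment by permutation enumeration.
bruteAssign <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (!length(v)) return(list(integer(0)))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(r) c(v[i], r))))
  }
  best <- Inf
  for (p in perms(seq_len(n)))
    best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  best
}

## Greedy closest-pair matching of detections to ground truth within a
## match radius; returns counts for precision/recall.
matchSpots <- function(truthXY, detXY, radius = 2) {
  if (!nrow(detXY) || !nrow(truthXY))
    return(list(matched = 0L, nTruth = nrow(truthXY), nDet = nrow(detXY)))
  d <- sqrt(outer(truthXY[, 1], detXY[, 1], "-")^2 +
            outer(truthXY[, 2], detXY[, 2], "-")^2)
  matched <- 0L
  while (TRUE) {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (d[m] > radius) break
    matched <- matched + 1L
    d[m[1], ] <- Inf
    d[, m[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  list(matched = matched, nTruth = nrow(truthXY), nDet = nrow(detXY))
}

## A minimal rendered single-emitter frame for detection tests.
singleEmitterFrame <- function(x, y, size = 64L, photons = 1500,
                               background = 10, psfSigma = 1.3,
                               noise = FALSE, seed = 1L) {
  cfg <- simulationConfig(nFrames = 1L, imageShape = c(size, size),
                          photonsPerEmitter = photons,
                          backgroundLevel = background, psfSigma = psfSigma,
                          seed = seed)
  truth <- data.frame(particle_id = 1L, frame = 1L, x_px = x, y_px = y,
                      multiplicity = 1L)
  getFrame(renderStack(truth, cfg, noise = noise)$stack, 1)
}
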