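#' Construct a motion model
#'
#' Convenience constructor for the four diffusion modes used to simulate
#' payload trajectories.
#'
#' @param kind one of `"normal"`, `"directed"`, `"confined"`,
#'   `"subdiffusive"`.
#' @param diffusionCoefficient diffusion coefficient D in um^2/s. For
#'   `"subdiffusive"` this is the generalized coefficient so that the
#'   two-dimensional MSD is \eqn{4 D \tau^{2H}}.
#' @param velocity drift speed in um/s; required for `"directed"`. The
#'   drift direction is drawn uniformly on the circle per trajectory.
#' @param confinementRadius radius in um of the reflecting confinement
#'   disk; required for `"confined"`.
#' @param hurst Hurst exponent in (0, 0.5]; required for
#'   `"subdiffusive"`. The resulting anomalous exponent is `2 * hurst`.
#' @return a validated [MotionModel-class] object.
#' @examples
#' motionModel("normal", 0.1)
#' motionModel("subdiffusive", 0.05, hurst = 0.25)
#' @export
motionModel <- function(kind = c("normal", "directed", "confined", "subdiffusive"),
                        diffusionCoefficient = 0.1,
                        velocity = NA_real_,
                        confinementRadius = NA_real_,
                        hurst = NA_real_) {
  kind <- match.arg(kind)
  new("MotionModel",
      kind = kind,
      diffusionCoefficient = as.numeric(diffusionCoefficient),
      velocity = as.numeric(velocity),
      confinementRadius = as.numeric(confinementRadius),
      hurst = as.numeric(hurst))
}

#' Construct a simulation configuration
#'
#' @param nFrames number of frames.
#' @param frameInterval seconds per frame (default 0.2 s as in the
#'   targeted acquisitions).
#' @param imageShape frame size (height, width) in pixels; default
#'   428 x 684, one camera channel.
#' @param pixelSize um per pixel; default 0.117 (50 um over 428 px and
#'   80 um over 684 px both give 0.117 to three figures).
#' @param psfSigma Gaussian PSF sigma in pixels.
#' @param photonsPerEmitter expected photons per emitter per frame.
#' @param backgroundLevel expected background photons per pixel.
#' @param readNoiseSd read noise standard deviation in photons.
#' @param clusterSpacing side length (px) of the square on whose corners
#'   the four emitters of a non-cleaved payload are placed.
#' @param seed integer RNG seed.
#' @return a validated [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nFrames = 50L,
                             frameInterval = 0.2,
                             imageShape = c(428L, 684L),
                             pixelSize = 0.117,
                             psfSigma = 1.3,
                             photonsPerEmitter = 1500,
                             backgroundLevel = 100,
                             readNoiseSd = 2,
                             clusterSpacing = 2,
                             seed = 1L) {
  new("SimulationConfig",
      nFrames = as.integer(nFrames),
      frameInterval = as.numeric(frameInterval),
      imageShape = as.integer(imageShape),
      pixelSize = as.numeric(pixelSize),
      psfSigma = as.numeric(psfSigma),
      photonsPerEmitter = as.numeric(photonsPerEmitter),
      backgroundLevel = as.numeric(backgroundLevel),
      readNoiseSd = as.numeric(readNoiseSd),
      clusterSpacing = as.numeric(clusterSpacing),
      seed = as.integer(seed))
}

## Exact fractional Gaussian noise by circulant embedding (Davies-Harte).
## Returns n increments of unit-variance fGn with Hurst exponent H; the
## circulant eigenvalues are non-negative for fGn so the embedding is
## exact (tiny negative values from round-off are clipped).
.fgnDaviesHarte <- function(n, H) {
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n))
  k <- 0:n
  r <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  row <- c(r, rev(r[2:n]))            # length 2n circulant first row
  lambda <- Re(stats::fft(row))
  lambda[lambda < 0 & lambda > -1e-8] <- 0
  if (any(lambda < 0))
    stop("circulant embedding failed: negative eigenvalue")
  m <- 2L * n
  w <- complex(length.out = m)
  w[1] <- stats::rnorm(1)
  w[n + 1] <- stats::rnorm(1)
  u <- stats::rnorm(n - 1)
  v <- stats::rnorm(n - 1)
  w[2:n] <- complex(real = u, imaginary = v) / sqrt(2)
  w[m:(n + 2)] <- Conj(w[2:n])
  x <- stats::fft(sqrt(lambda / m) * w)
  Re(x)[seq_len(n)]
}

#' Simulate one planar trajectory
#'
#' Generates `nSteps` positions (um, starting at the origin) under the
#' given motion model. Brownian steps are independent Gaussian increments
#' with per-axis variance `2 D dt`; directed motion adds a constant drift
#' `v dt` in a direction drawn uniformly on the circle; confined motion
#' reflects each Brownian step at the boundary of a disk of the given
#' radius centered on the start; subdiffusion uses exact fractional
#' Gaussian increments (Davies-Harte circulant embedding) so that the
#' ensemble MSD follows \eqn{4 D \tau^{2H}}.
#'
#' @param model a [MotionModel-class].
#' @param nSteps number of positions returned (>= 1).
#' @param dt time step in seconds.
#' @param seed optional integer seed; when given the trajectory is
#'   reproducible bit-for-bit.
#' @return an `nSteps` x 2 matrix of (x, y) positions in um.
#' @examples
#' xy <- simulateTrajectory(motionModel("normal", 0.1), 100, 0.2, seed = 1)
#' @export
simulateTrajectory <- function(model, nSteps, dt, seed = NULL) {
  stopifnot(is(model, "MotionModel"))
  validObject(model)
  if (nSteps < 1) stop("nSteps must be >= 1")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nSteps)
  D <- model@diffusionCoefficient
  if (n == 1L) return(matrix(0, 1, 2, dimnames = list(NULL, c("x", "y"))))
  nInc <- n - 1L
  pos <- switch(model@kind,
    normal = {
      s <- sqrt(2 * D * dt)
      apply(matrix(stats::rnorm(2L * nInc, sd = s), nInc, 2), 2, cumsum)
    },
    directed = {
      theta <- stats::runif(1, 0, 2 * pi)
      s <- sqrt(2 * D * dt)
      dx <- stats::rnorm(nInc, sd = s) + model@velocity * dt * cos(theta)
      dy <- stats::rnorm(nInc, sd = s) + model@velocity * dt * sin(theta)
      cbind(cumsum(dx), cumsum(dy))
    },
    confined = {
      R <- model@confinementRadius
      s <- sqrt(2 * D * dt)
      out <- matrix(0, n, 2)
      p <- c(0, 0)
      for (i in seq_len(nInc)) {
        p <- p + stats::rnorm(2, sd = s)
        r <- sqrt(sum(p^2))
        # radial reflection at the disk boundary; repeat for rare large steps
        while (r > R) {
          p <- p * (2 * R - r) / r
          r <- abs(2 * R - r)
        }
        out[i + 1L, ] <- p
      }
      out[-1L, , drop = FALSE]
    },
    subdiffusive = {
      H <- model@hurst
      scale <- sqrt(2 * D) * dt^H
      dx <- scale * .fgnDaviesHarte(nInc, H)
      dy <- scale * .fgnDaviesHarte(nInc, H)
      cbind(cumsum(dx), cumsum(dy))
    })
  pos <- rbind(c(0, 0), pos)
  dimnames(pos) <- list(NULL, c("x", "y"))
  if (n == 1L) pos <- pos[1L, , drop = FALSE]
  pos
}

#' Build a circular cell geometry with an annular membrane band
#'
#' Rasterizes a disk-shaped cell and a membrane annulus of the given
#' width on a pixel grid. A pixel belongs to the cell when its center
#' lies within `cellRadius` of the cell center, and to the membrane when
#' it additionally lies farther than `cellRadius - membraneWidth`.
#'
#' @param imageShape frame size (height, width) in pixels.
#' @param cellRadius cell radius in pixels.
#' @param membraneWidth width of the annular membrane band in pixels;
#'   0 gives an empty membrane mask.
#' @param center cell center as (x, y) in 0-based pixel coordinates;
#'   default is the image center.
#' @param pixelSize um per pixel.
#' @return a [CellGeometry-class].
#' @examples
#' geom <- makeCellGeometry(c(128L, 128L), cellRadius = 40, membraneWidth = 4)
#' @export
makeCellGeometry <- function(imageShape, cellRadius, membraneWidth,
                             center = NULL, pixelSize = 0.117) {
  imageShape <- as.integer(imageShape)
  stopifnot(length(imageShape) == 2L, cellRadius > 0, membraneWidth >= 0)
  if (is.null(center))
    center <- c((imageShape[2] - 1) / 2, (imageShape[1] - 1) / 2)
  if (center[1] - cellRadius < 0 || center[1] + cellRadius > imageShape[2] - 1 ||
      center[2] - cellRadius < 0 || center[2] + cellRadius > imageShape[1] - 1)
    stop("cell does not fit inside the image")
  ## 0-based pixel-center coordinates: x along columns, y along rows
  x <- matrix(rep(0:(imageShape[2] - 1), each = imageShape[1]),
              imageShape[1], imageShape[2])
  y <- matrix(rep(0:(imageShape[1] - 1), times = imageShape[2]),
              imageShape[1], imageShape[2])
  r <- sqrt((x - center[1])^2 + (y - center[2])^2)
  cell <- r <= cellRadius
  mem <- cell & r > (cellRadius - membraneWidth)
  if (membraneWidth == 0) mem[] <- FALSE
  new("CellGeometry", cellMask = cell, membraneMask = mem,
      pixelSize = as.numeric(pixelSize))
}
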