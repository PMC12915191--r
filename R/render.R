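## Pixel-integrated Gaussian rendering. Pixel (row i, col j), 0-based,
## covers [j - 0.5, j + 0.5] x [i - 0.5, i + 0.5] in continuous (x, y);
## a spot exactly on a pixel center has coordinates (x = j, y = i).

.erfDiff <- function(edges, mu, sigma) {
  ## P(edge_k < N(mu, sigma) < edge_{k+1}) for consecutive edges
  p <- stats::pnorm(edges, mean = mu, sd = sigma)
  diff(p)
}

## Add one emitter's expected photon image in place (returns matrix).
.addEmitter <- function(img, x, y, photons, sigma) {
  h <- nrow(img); w <- ncol(img)
  ## restrict to a window +/- 6 sigma for speed
  r <- ceiling(6 * sigma)
  cols <- max(0, floor(x) - r):min(w - 1, ceiling(x) + r)
  rows <- max(0, floor(y) - r):min(h - 1, ceiling(y) + r)
  if (!length(cols) || !length(rows)) return(img)
  px <- .erfDiff(c(cols - 0.5, max(cols) + 0.5), x, sigma)
  py <- .erfDiff(c(rows - 0.5, max(rows) + 0.5), y, sigma)
  img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
    photons * (py %o% px)
  img
}

## Emitter positions for one payload: a single emitter at the centroid or,
## for multiplicity 4, the corners of a square of side `spacing` centered
## on the centroid (layout radius of gyration = spacing / sqrt(2)).
.payloadEmitters <- function(x, y, multiplicity, spacing) {
  if (multiplicity == 1L) return(cbind(x = x, y = y))
  if (multiplicity == 4L) {
    d <- spacing / 2
    return(cbind(x = x + c(-d, d, -d, d), y = y + c(-d, -d, d, d)))
  }
  stop("payload multiplicity must be 1 or 4")
}

#' Render a synthetic image stack from ground-truth positions
#'
#' Renders each payload as one (cleaved, multiplicity 1) or four
#' (non-cleaved, multiplicity 4) diffraction-limited emitters using the
#' pixel-integrated Gaussian PSF model (erf differences over pixel
#' edges), adds the uniform background, then applies Poisson shot noise
#' followed by additive Gaussian read noise. With `noise = FALSE` the
#' expected photon image is returned unchanged, which is what the
#' centroid- and photon-conservation oracles use.
#'
#' @param truth a data.frame with columns `particle_id`, `frame`
#'   (1-based), `x_px`, `y_px` (0-based pixel coordinates) and
#'   `multiplicity` (1 or 4), e.g. from [simulateScenario()].
#' @param config a [SimulationConfig-class]; `seed` drives the noise.
#' @param noise logical; apply shot + read noise (default TRUE).
#' @return a list with `stack` (an [ImageStack-class]) and `emitters`, a
#'   data.frame of every rendered emitter (frame, x, y, photons,
#'   particle_id).
#' @export
renderStack <- function(truth, config, noise = TRUE) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  req <- c("particle_id", "frame", "x_px", "y_px", "multiplicity")
  if (!all(req %in% names(truth)))
    stop("truth must have columns: ", paste(req, collapse = ", "))
  h <- config@imageShape[1]; w <- config@imageShape[2]
  if (nrow(truth) &&
      (any(truth$x_px < 0 | truth$x_px > w - 1) ||
       any(truth$y_px < 0 | truth$y_px > h - 1)))
    stop("true positions must lie inside the image bounds")
  nf <- config@nFrames
  frames <- array(0, dim = c(h, w, nf))
  emitters <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- matrix(config@backgroundLevel, h, w)
    rowsF <- truth[truth$frame == f, , drop = FALSE]
    em <- NULL
    if (nrow(rowsF)) {
      emList <- lapply(seq_len(nrow(rowsF)), function(k) {
        e <- .payloadEmitters(rowsF$x_px[k], rowsF$y_px[k],
                              as.integer(rowsF$multiplicity[k]),
                              config@clusterSpacing)
        data.frame(frame = f, x = e[, "x"], y = e[, "y"],
                   photons = config@photonsPerEmitter,
                   particle_id = rowsF$particle_id[k])
      })
      em <- do.call(rbind, emList)
      for (k in seq_len(nrow(em)))
        img <- .addEmitter(img, em$x[k], em$y[k], em$photons[k],
                           config@psfSigma)
    }
    emitters[[f]] <- em
    frames[, , f] <- img
  }
  if (noise) {
    set.seed(config@seed)
    n <- length(frames)
    frames[] <- stats::rpois(n, lambda = frames) +
      stats::rnorm(n, sd = config@readNoiseSd)
    frames[frames < 0] <- 0
  }
  stack <- new("ImageStack", frames = frames,
               pixelSize = config@pixelSize,
               frameInterval = config@frameInterval,
               bitDepth = 16L)
  emitters <- do.call(rbind, emitters)
  if (is.null(emitters))
    emitters <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                           photons = numeric(), particle_id = integer())
  rownames(emitters) <- NULL
  list(stack = stack, emitters = emitters)
}

#' Peak signal-to-noise ratio implied by a configuration
#'
#' SNR is defined as the expected peak pixel signal of a single in-focus
#' emitter divided by the background noise standard deviation
#' \eqn{\sqrt{B + \sigma_{read}^2}} — the convention under which the
#' detection benchmark quotes "SNR 10".
#'
#' @param config a [SimulationConfig-class].
#' @return a single number.
#' @export
peakSnr <- function(config) {
  s <- config@psfSigma
  peakFrac <- (2 * stats::pnorm(0.5 / s) - 1)^2     # central-pixel mass
  peak <- config@photonsPerEmitter * peakFrac
  peak / sqrt(config@backgroundLevel + config@readNoiseSd^2)
}

#' Photons per emitter needed to reach a target peak SNR
#'
#' Inverts [peakSnr()] for the given background and read noise.
#'
#' @param snr target peak SNR.
#' @param psfSigma PSF sigma (px).
#' @param backgroundLevel background photons per pixel.
#' @param readNoiseSd read noise sd (photons).
#' @return photons per emitter.
#' @export
photonsForSnr <- function(snr, psfSigma, backgroundLevel, readNoiseSd) {
  peakFrac <- (2 * stats::pnorm(0.5 / psfSigma) - 1)^2
  snr * sqrt(backgroundLevel + readNoiseSd^2) / peakFrac
}
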