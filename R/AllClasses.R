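#' @import methods
NULL

#' Motion model for simulated particle trajectories
#'
#' An S4 container describing one of the four diffusion modes observed for
#' tracked payloads in live cells: free (Brownian) diffusion, directed
#' motion (diffusion plus constant drift, e.g. active transport),
#' confined diffusion inside a reflecting disk (e.g. membrane-embedded
#' particles), and subdiffusion modeled as fractional Brownian motion
#' (e.g. motion in the crowded cytosol).
#'
#' The long-run anomalous exponent implied by each mode is: normal 1,
#' directed approaching 2 when drift dominates, confined approaching 0 at
#' long lags, and subdiffusive \eqn{\alpha = 2H} for Hurst exponent
#' \eqn{H}.
#'
#' @slot kind character; one of `"normal"`, `"directed"`, `"confined"`,
#'   `"subdiffusive"`.
#' @slot diffusionCoefficient numeric; D in um^2/s (for subdiffusion the
#'   generalized coefficient in um^2/s^(2H)).
#' @slot velocity numeric; drift speed in um/s (directed only).
#' @slot confinementRadius numeric; disk radius in um (confined only).
#' @slot hurst numeric in (0, 0.5]; Hurst exponent (subdiffusive only).
#'
#' @seealso [motionModel()] for the user-facing constructor.
#' @exportClass MotionModel
setClass("MotionModel",
  representation(
    kind = "character",
    diffusionCoefficient = "numeric",
    velocity = "numeric",
    confinementRadius = "numeric",
    hurst = "numeric"
  ),
  prototype(
    kind = "normal",
    diffusionCoefficient = 0.1,
    velocity = NA_real_,
    confinementRadius = NA_real_,
    hurst = NA_real_
  )
)

setValidity("MotionModel", function(object) {
  msg <- character()
  kinds <- c("normal", "directed", "confined", "subdiffusive")
  if (length(object@kind) != 1L || !object@kind %in% kinds)
    msg <- c(msg, sprintf("kind must be one of: %s", paste(kinds, collapse = ", ")))
  D <- object@diffusionCoefficient
  if (length(D) != 1L || !is.finite(D) || D < 0)
    msg <- c(msg, "diffusionCoefficient must be a single finite value >= 0")
  if (identical(object@kind, "directed") &&
      (!is.finite(object@velocity) || object@velocity < 0))
    msg <- c(msg, "directed motion requires a finite velocity >= 0")
  if (identical(object@kind, "confined") &&
      (!is.finite(object@confinementRadius) || object@confinementRadius <= 0))
    msg <- c(msg, "confined motion requires confinementRadius > 0")
  if (identical(object@kind, "subdiffusive") &&
      (!is.finite(object@hurst) || object@hurst <= 0 || object@hurst > 0.5))
    msg <- c(msg, "subdiffusive motion requires hurst in (0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for synthetic time-lapse rendering
#'
#' Holds the acquisition geometry and noise model used to render synthetic
#' single-molecule stacks. Defaults mirror a HILO acquisition on a
#' 428 x 684-pixel camera channel spanning 50 um x 80 um (0.117 um/px)
#' at 200 ms per frame, 16-bit.
#'
#' @slot nFrames integer; frames to render.
#' @slot frameInterval numeric; seconds per frame.
#' @slot imageShape integer(2); frame size as (height, width) in pixels.
#' @slot pixelSize numeric; um per pixel.
#' @slot psfSigma numeric; Gaussian PSF standard deviation in pixels.
#' @slot photonsPerEmitter numeric; expected photons collected per emitter
#'   per frame.
#' @slot backgroundLevel numeric; expected background photons per pixel.
#' @slot readNoiseSd numeric; Gaussian read noise standard deviation
#'   (photons).
#' @slot clusterSpacing numeric; centroid-to-emitter distance scale in
#'   pixels for multiplicity-4 payloads (emitters sit on the corners of a
#'   square with this side length).
#' @slot seed integer; RNG seed; the same configuration and seed give a
#'   bit-identical stack.
#'
#' @seealso [simulationConfig()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nFrames = "integer",
    frameInterval = "numeric",
    imageShape = "integer",
    pixelSize = "numeric",
    psfSigma = "numeric",
    photonsPerEmitter = "numeric",
    backgroundLevel = "numeric",
    readNoiseSd = "numeric",
    clusterSpacing = "numeric",
    seed = "integer"
  ),
  prototype(
    nFrames = 50L,
    frameInterval = 0.2,
    imageShape = c(428L, 684L),
    pixelSize = 0.117,
    psfSigma = 1.3,
    photonsPerEmitter = 1500,
    backgroundLevel = 100,
    readNoiseSd = 2,
    clusterSpacing = 2,
    seed = 1L
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (!is.finite(object@frameInterval) || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be > 0")
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "imageShape must be two pixel counts >= 8")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be > 0")
  if (!is.finite(object@psfSigma) || object@psfSigma <= 0)
    msg <- c(msg, "psfSigma must be > 0")
  if (object@photonsPerEmitter < 0) msg <- c(msg, "photonsPerEmitter must be >= 0")
  if (object@backgroundLevel < 0) msg <- c(msg, "backgroundLevel must be >= 0")
  if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
  if (!is.finite(object@clusterSpacing) || object@clusterSpacing < 0)
    msg <- c(msg, "clusterSpacing must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Cell and membrane geometry masks
#'
#' Binary masks locating the cell interior and an annular membrane band,
#' standing in for the stained-membrane channel of a two-channel
#' acquisition. Masks are height x width logical matrices on the same
#' pixel grid as the image stack.
#'
#' @slot cellMask logical matrix; TRUE inside the cell (membrane band
#'   included).
#' @slot membraneMask logical matrix; TRUE on the annular membrane band.
#' @slot pixelSize numeric; um per pixel.
#' @exportClass CellGeometry
setClass("CellGeometry",
  representation(
    cellMask = "matrix",
    membraneMask = "matrix",
    pixelSize = "numeric"
  )
)

setValidity("CellGeometry", function(object) {
  msg <- character()
  if (!is.logical(object@cellMask)) msg <- c(msg, "cellMask must be logical")
  if (!is.logical(object@membraneMask)) msg <- c(msg, "membraneMask must be logical")
  if (!identical(dim(object@cellMask), dim(object@membraneMask)))
    msg <- c(msg, "cellMask and membraneMask must share dimensions")
  if (any(object@membraneMask & !object@cellMask))
    msg <- c(msg, "membraneMask must lie inside cellMask")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' A calibrated fluorescence image stack
#'
#' Frames are stored as a height x width x nFrames numeric array of
#' photon-scale intensities, with physical calibration attached. Pixel
#' coordinates used throughout the package are 0-based, x along columns
#' and y along rows, so a spot centered on pixel (row i, column j) has
#' continuous coordinates (x = j, y = i).
#'
#' @slot frames numeric array, dim = c(height, width, nFrames).
#' @slot pixelSize numeric; um per pixel.
#' @slot frameInterval numeric; seconds per frame.
#' @slot bitDepth integer; bit depth of the source data (16 for the
#'   acquisitions this package targets; rendering keeps full precision
#'   until written to disk).
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    frames = "array",
    pixelSize = "numeric",
    frameInterval = "numeric",
    bitDepth = "integer"
  ),
  prototype(bitDepth = 16L)
)

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a height x width x nFrames array")
  if (any(!is.finite(object@frames)))
    msg <- c(msg, "frames must be finite-valued")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be > 0")
  if (!is.finite(object@frameInterval) || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MotionModel", function(object) {
  extra <- switch(object@kind,
    directed = sprintf(", v = %.3g um/s", object@velocity),
    confined = sprintf(", R = %.3g um", object@confinementRadius),
    subdiffusive = sprintf(", H = %.3g (alpha = %.3g)", object@hurst, 2 * object@hurst),
    "")
  cat(sprintf("MotionModel: %s, D = %.3g um^2/s%s\n",
              object@kind, object@diffusionCoefficient, extra))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d frame(s) of %d x %d px, %.3g um/px, %.3g s/frame\n",
    object@nFrames, object@imageShape[1], object@imageShape[2],
    object@pixelSize, object@frameInterval))
  cat(sprintf(
    "  PSF sigma %.3g px, %g photons/emitter, background %g, read noise %g, seed %d\n",
    object@psfSigma, object@photonsPerEmitter, object@backgroundLevel,
    object@readNoiseSd, object@seed))
})

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf("CellGeometry: %d x %d px, %d cell px, %d membrane px, %.3g um/px\n",
              nrow(object@cellMask), ncol(object@cellMask),
              sum(object@cellMask), sum(object@membraneMask), object@pixelSize))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d frame(s) of %d x %d px (%.3g um/px, %.3g s/frame, %d-bit)\n",
              d[3], d[1], d[2], object@pixelSize, object@frameInterval,
              object@bitDepth))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@frames), max(object@frames)))
})
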