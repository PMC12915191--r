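#' @rdname ImageStack-class
#' @param object,x an object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ImageStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ImageStack-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname ImageStack-class
#' @param i frame index (1-based).
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname CellGeometry-class
#' @param x a `CellGeometry`.
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))

#' @rdname CellGeometry-class
#' @export
setGeneric("membraneMask", function(x) standardGeneric("membraneMask"))

#' @describeIn ImageStack-class number of frames.
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3])

#' @describeIn ImageStack-class pixel size in um.
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @describeIn CellGeometry-class pixel size in um.
setMethod("pixelSize", "CellGeometry", function(x) x@pixelSize)

#' @describeIn ImageStack-class frame interval in seconds.
setMethod("frameInterval", "ImageStack", function(x) x@frameInterval)

#' @describeIn ImageStack-class one frame as a height x width matrix.
setMethod("getFrame", "ImageStack", function(x, i) {
  stopifnot(i >= 1, i <= dim(x@frames)[3])
  x@frames[, , i]
})

#' @describeIn CellGeometry-class logical matrix of cell-interior pixels.
setMethod("cellMask", "CellGeometry", function(x) x@cellMask)

#' @describeIn CellGeometry-class logical matrix of membrane-band pixels.
setMethod("membraneMask", "CellGeometry", function(x) x@membraneMask)
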