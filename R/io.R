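## TIFF stack and CSV I/O. Stacks are written as multi-page 16-bit
## grayscale TIFF; reading preserves the 16-bit counts without
## rescaling. CSVs are comma-separated, header row, '.' decimal, with
## provenance recorded in '# key=value' comment lines above the header.

#' Read a TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into an
#' [ImageStack-class]; 16-bit data are preserved as integer counts.
#'
#' @param path file path.
#' @param pixelSize um per pixel to attach (default 0.117).
#' @param frameInterval seconds per frame to attach (default 0.2).
#' @return an [ImageStack-class].
#' @export
readStack <- function(path, pixelSize = 0.117, frameInterval = 0.2) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("unreadable TIFF '", path, "': ",
                           conditionMessage(e)))
  if (!length(pages)) stop("TIFF '", path, "' contains no pages")
  d <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), d))
      stop("TIFF '", path, "': page ", i, " has inconsistent dimensions")
  frames <- array(0, dim = c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  new("ImageStack", frames = frames, pixelSize = pixelSize,
      frameInterval = frameInterval, bitDepth = 16L)
}

#' Write an ImageStack as a multi-page 16-bit TIFF
#'
#' Intensities are rounded to integer photon counts and clipped to the
#' 16-bit range.
#'
#' @param stack an [ImageStack-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  pages <- lapply(seq_len(nFrames(stack)), function(i) {
    m <- round(getFrame(stack, i))
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as a single-page TIFF
#'
#' @param mask a logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is.logical(mask))
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask TIFF
#'
#' @param path file path.
#' @return a logical matrix (nonzero pixels TRUE).
#' @export
readMask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0
}

#' Write a data.frame as a stamped CSV
#'
#' Provenance (e.g. config hash and seed) is recorded as `# key=value`
#' comment lines before the header.
#'
#' @param df a data.frame.
#' @param path output path.
#' @param stamp named character vector of provenance values.
#' @return `path`, invisibly.
#' @export
writeStampedCsv <- function(df, path, stamp = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(stamp))
    writeLines(sprintf("# %s=%s", names(stamp), as.character(stamp)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a stamped CSV
#'
#' @param path file path.
#' @return a data.frame; the stamp lines are attached as the
#'   `"stamp"` attribute.
#' @export
readStampedCsv <- function(path) {
  lines <- readLines(path)
  stampLines <- grep("^# ", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!startsWith(lines, "# ")])
  attr(df, "stamp") <- sub("^# ", "", stampLines)
  df
}
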