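## Population-level statistics: two-sample KS and Welch tests with the
## field's significance-band convention, and native Pearson/Manders
## colocalization of segmented two-channel images.

#' Map a p-value to a significance band
#'
#' Bands follow the usual star convention: `n.s.` for p > 0.05, then
#' `*` (<= 0.05), `**` (<= 0.01), `***` (<= 0.001), `****` (<= 0.0001).
#'
#' @param p a p-value in `[0, 1]`.
#' @return a character band.
#' @export
significanceBand <- function(p) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  if (p <= 1e-4) "****"
  else if (p <= 1e-3) "***"
  else if (p <= 0.01) "**"
  else if (p <= 0.05) "*"
  else "n.s."
}

#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum distance between the two empirical
#' distribution functions; the p-value uses the exact distribution for
#' small samples (n1 * n2 < 10^4, no ties) and the asymptotic Kolmogorov
#' distribution with effective size n1 n2 / (n1 + n2) otherwise.
#'
#' @param a,b numeric samples (nonempty).
#' @return a list: `statistic` (D), `pValue`, `n1`, `n2`, `band`.
#' @export
ksTwoSample <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  res <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  p <- min(1, max(0, unname(res$p.value)))
  list(statistic = unname(res$statistic), pValue = p,
       n1 = length(a), n2 = length(b), band = significanceBand(p))
}

#' Two-sided unpaired t-test
#'
#' Welch's test by default (unequal variances); the pooled-variance
#' variant is available via `equalVariance = TRUE`. When both samples
#' are constant, the test is degenerate: equal means give p = 1 by
#' convention and unequal means give p = 0 with a flag.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @param equalVariance use the pooled-variance (Student) form.
#' @return a list: `statistic`, `df`, `pValue`, `n1`, `n2`, `band`,
#'   `degenerate` (logical).
#' @export
tTestUnpaired <- function(a, b, equalVariance = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(statistic = 0, df = NA_real_, pValue = 1,
                  n1 = length(a), n2 = length(b), band = "n.s.",
                  degenerate = TRUE))
    return(list(statistic = Inf, df = NA_real_, pValue = 0,
                n1 = length(a), n2 = length(b), band = "****",
                degenerate = TRUE))
  }
  res <- stats::t.test(a, b, var.equal = equalVariance,
                       alternative = "two.sided")
  p <- unname(res$p.value)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       pValue = p, n1 = length(a), n2 = length(b),
       band = significanceBand(p), degenerate = FALSE)
}

#' Compare size and eccentricity between two spot populations
#'
#' KS-tests the radius-of-gyration and eccentricity marginals of two
#' detected-spot populations (e.g. cleaved single-dye vs non-cleaved
#' four-dye payloads) and reports the direction of the median shifts
#' together with a joint 2-D histogram summary.
#'
#' @param popA,popB spot data.frames with `rg` and `eccentricity`.
#' @param nBins number of bins per axis for the joint histogram.
#' @return a list: `rgTest`, `eccTest` (from [ksTwoSample()]),
#'   `medianShift` (named vector of median(B) - median(A)),
#'   `hist2d` (list with `breaksRg`, `breaksEcc`, `countsA`, `countsB`).
#' @export
compareSizeEccentricity <- function(popA, popB, nBins = 32L) {
  stopifnot(all(c("rg", "eccentricity") %in% names(popA)),
            all(c("rg", "eccentricity") %in% names(popB)),
            nrow(popA) > 0, nrow(popB) > 0)
  rgTest <- ksTwoSample(popA$rg, popB$rg)
  eccTest <- ksTwoSample(popA$eccentricity, popB$eccentricity)
  breaksRg <- seq(min(popA$rg, popB$rg), max(popA$rg, popB$rg),
                  length.out = nBins + 1L)
  breaksEcc <- seq(0, max(popA$eccentricity, popB$eccentricity, 1e-9),
                   length.out = nBins + 1L)
  bin2d <- function(p) {
    i <- cut(p$rg, breaksRg, include.lowest = TRUE)
    j <- cut(p$eccentricity, breaksEcc, include.lowest = TRUE)
    table(i, j)
  }
  list(rgTest = rgTest, eccTest = eccTest,
       medianShift = c(rg = stats::median(popB$rg) - stats::median(popA$rg),
                       eccentricity = stats::median(popB$eccentricity) -
                         stats::median(popA$eccentricity)),
       hist2d = list(breaksRg = breaksRg, breaksEcc = breaksEcc,
                     countsA = bin2d(popA), countsB = bin2d(popB)))
}

#' Pearson colocalization of two channels within an ROI
#'
#' Pearson correlation of paired pixel intensities inside the ROI mask.
#'
#' @param channelA,channelB intensity matrices of equal size.
#' @param roiMask logical matrix; default all pixels.
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
pearsonColoc <- function(channelA, channelB, roiMask = NULL) {
  stopifnot(identical(dim(channelA), dim(channelB)))
  if (is.null(roiMask)) roiMask <- matrix(TRUE, nrow(channelA), ncol(channelA))
  stopifnot(identical(dim(roiMask), dim(channelA)))
  a <- channelA[roiMask]
  b <- channelB[roiMask]
  if (length(a) < 2) stop("ROI must contain at least 2 pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined Pearson correlation: zero variance within ROI")
  stats::cor(a, b)
}

#' Pearson colocalization across multiple ROIs
#'
#' @param channelA,channelB intensity matrices.
#' @param roiMasks a list of logical ROI masks.
#' @return a list with `perRoi` (numeric vector), `mean` and `sd`.
#' @export
pearsonColocRois <- function(channelA, channelB, roiMasks) {
  r <- vapply(roiMasks, function(m) pearsonColoc(channelA, channelB, m),
              numeric(1))
  list(perRoi = r, mean = mean(r), sd = stats::sd(r))
}

#' Manders colocalization coefficients on segmented channels
#'
#' M1 is the fraction of channel A's intensity within `maskA` that falls
#' inside `maskB`; M2 is the symmetric quantity for channel B.
#'
#' @param channelA,channelB intensity matrices.
#' @param maskA,maskB binary segmentation masks (logical matrices), e.g.
#'   from [segmentChannel()].
#' @return a list with `m1` and `m2`, each in `[0, 1]`.
#' @export
mandersColoc <- function(channelA, channelB, maskA, maskB) {
  stopifnot(identical(dim(channelA), dim(channelB)),
            identical(dim(maskA), dim(channelA)),
            identical(dim(maskB), dim(channelB)))
  sumA <- sum(channelA[maskA])
  sumB <- sum(channelB[maskB])
  if (sumA <= 0) stop("M1 undefined: channel A has no intensity in its mask")
  if (sumB <= 0) stop("M2 undefined: channel B has no intensity in its mask")
  m1 <- sum(channelA[maskA & maskB]) / sumA
  m2 <- sum(channelB[maskA & maskB]) / sumB
  list(m1 = m1, m2 = m2)
}

#' Threshold a channel into a binary mask
#'
#' Otsu's method by default (256-level histogram over the image range);
#' a fixed threshold is honored exactly. The mask is `image > level`.
#'
#' @param image an intensity matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param level threshold for `method = "fixed"`.
#' @return a logical matrix.
#' @export
segmentChannel <- function(image, method = c("otsu", "fixed"), level = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(!is.null(level))
    return(image > level)
  }
  rng <- range(image)
  if (rng[1] == rng[2]) stop("Otsu segmentation of a constant image is undefined")
  thr <- EBImage::otsu(EBImage::Image(image), range = rng, levels = 256)
  image > thr
}
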