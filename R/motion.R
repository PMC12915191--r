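## Time-averaged MSD, anomalous-exponent fitting and rule-based
## diffusion-mode segmentation.

#' Time-averaged mean-squared displacement of one track
#'
#' Averages the squared planar displacement over all ordered observation
#' pairs separated by each frame lag `k`, for `k = 1 ...
#' floor(maxLagFraction * n)`. Tracks with gaps are handled by pairing
#' on the true frame difference, so a pair spanning a gap contributes at
#' its true lag.
#'
#' @param track data.frame for one track with columns `frame`, `x`, `y`
#'   (pixel coordinates).
#' @param pixelSize um per pixel.
#' @param dt frame interval in seconds.
#' @param maxLagFraction largest lag as a fraction of the number of
#'   observations (default 0.25).
#' @return a data.frame with `lag` (s), `msd` (um^2) and `n_pairs`; lags
#'   with no observation pair are omitted.
#' @export
computeMSD <- function(track, pixelSize = 1, dt = 1, maxLagFraction = 0.25) {
  stopifnot(all(c("frame", "x", "y") %in% names(track)))
  n <- nrow(track)
  if (n < 2L) stop("track must have at least 2 observations")
  o <- order(track$frame)
  f <- as.integer(track$frame[o])
  x <- track$x[o] * pixelSize
  y <- track$y[o] * pixelSize
  kmax <- max(1L, as.integer(floor(maxLagFraction * n)))
  df <- outer(f, f, "-")
  sq <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  sel <- df >= 1L & df <= kmax
  if (!any(sel))
    return(data.frame(lag = numeric(), msd = numeric(), n_pairs = integer()))
  lagK <- df[sel]
  val <- sq[sel]
  msd <- tapply(val, lagK, mean)
  np <- tapply(val, lagK, length)
  k <- as.integer(names(msd))
  ord <- order(k)
  data.frame(lag = k[ord] * dt, msd = as.numeric(msd)[ord],
             n_pairs = as.integer(np)[ord])
}

#' Fit the anomalous diffusion exponent
#'
#' Ordinary least squares of `log(MSD)` on `log(lag)` over the first
#' `fitLags` usable lags. The slope is the anomalous exponent
#' \eqn{\alpha} (1 for free diffusion, >1 for directed, <1 for hindered
#' motion) and the intercept is \eqn{\log(4 D_\alpha)}, giving the
#' generalized diffusion coefficient in um^2/s^alpha. Zero-valued MSD
#' points are excluded with a warning.
#'
#' @param msd a data.frame from [computeMSD()].
#' @param fitLags number of leading lags to fit (default
#'   `min(10, floor(nrow(msd) / 1))` capped below by 3).
#' @return a list with `alpha`, `dGen`, `rSquared`, `fitLagRange`
#'   (seconds), `nLagsUsed`; or, when fewer than 3 usable points exist,
#'   a list with `alpha = NA` and `reason` describing the failure.
#' @export
fitAlpha <- function(msd, fitLags = min(10L, nrow(msd))) {
  stopifnot(all(c("lag", "msd") %in% names(msd)))
  use <- utils::head(msd, fitLags)
  pos <- use$msd > 0
  if (any(!pos)) {
    warning("excluding ", sum(!pos), " zero-valued MSD point(s) from the fit")
    use <- use[pos, , drop = FALSE]
  }
  if (nrow(use) < 3L)
    return(list(alpha = NA_real_, dGen = NA_real_, rSquared = NA_real_,
                fitLagRange = c(NA_real_, NA_real_), nLagsUsed = nrow(use),
                reason = "fewer than 3 usable MSD points"))
  lx <- log(use$lag)
  ly <- log(use$msd)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2])
  dGen <- exp(unname(fit$coefficients[1])) / 4
  ssRes <- sum(fit$residuals^2)
  ssTot <- sum((ly - mean(ly))^2)
  r2 <- if (ssTot <= .Machine$double.eps) 1 else 1 - ssRes / ssTot
  list(alpha = alpha, dGen = dGen, rSquared = r2,
       fitLagRange = range(use$lag), nLagsUsed = nrow(use))
}

#' Default thresholds for rule-based motion-mode segmentation
#'
#' The segmenter assigns each rolling window one of four diffusion
#' modes from three features: the window anomalous exponent, the
#' straightness (net displacement over path length) and the confinement
#' ratio (maximum pairwise squared distance over the MSD at the longest
#' computed lag). Rules, applied in order: directed when straightness
#' exceeds `sDir` and alpha exceeds `alphaDir`; confined when the
#' confinement ratio is below `cConf` and alpha is below `alphaConf`;
#' subdiffusive when alpha is below `alphaSub`; otherwise normal.
#'
#' Thresholds were calibrated on the package's own simulator (the
#' methods vignette records the calibration): a well-confined window's
#' confinement ratio plateaus near 4 (maximum pairwise distance ~ 2R
#' against an MSD plateau ~ R^2), while free-diffusion windows sit near
#' 8-15, so `cConf` separates the two at 5.5.
#'
#' @return a named list of thresholds.
#' @export
motionThresholds <- function() {
  list(sDir = 0.6, alphaDir = 1.4, cConf = 5.5, alphaConf = 0.5,
       alphaSub = 0.7)
}

.windowFeatures <- function(wx, wy, wf, pixelSize, dt) {
  msd <- computeMSD(data.frame(frame = wf, x = wx, y = wy),
                    pixelSize = pixelSize, dt = dt, maxLagFraction = 0.25)
  fit <- fitAlpha(msd, fitLags = min(10L, max(3L, floor(length(wf) / 4))))
  net <- sqrt((wx[length(wx)] - wx[1])^2 + (wy[length(wy)] - wy[1])^2)
  path <- sum(sqrt(diff(wx)^2 + diff(wy)^2))
  straight <- if (path > 0) net / path else 0
  maxPair2 <- max(outer(wx, wx, "-")^2 + outer(wy, wy, "-")^2) * pixelSize^2
  msdMax <- if (nrow(msd)) msd$msd[nrow(msd)] else NA_real_
  confRatio <- if (is.finite(msdMax) && msdMax > 0) maxPair2 / msdMax else Inf
  list(alpha = fit$alpha, straightness = straight, confinementRatio = confRatio)
}

.classifyWindow <- function(feat, th) {
  a <- feat$alpha
  if (is.na(a)) return(NA_character_)
  if (feat$straightness > th$sDir && a > th$alphaDir) return("directed")
  if (feat$confinementRatio < th$cConf && a < th$alphaConf) return("confined")
  if (a < th$alphaSub) return("subdiffusive")
  "normal"
}

#' Segment a track into diffusion-mode windows
#'
#' Slides a window along the track, computes per-window features
#' (anomalous exponent, straightness, confinement ratio), labels each
#' window by the rules of [motionThresholds()], and merges consecutive
#' windows of the same mode into segments. A track shorter than the
#' window yields a single segment labeled from the full-track features.
#'
#' @param track data.frame for one track (`frame`, `x`, `y`).
#' @param window window length in frames (default 30).
#' @param stride window step in frames (default 5).
#' @param thresholds rule thresholds, see [motionThresholds()].
#' @param pixelSize um per pixel.
#' @param dt seconds per frame.
#' @return a data.frame of segments: `start_frame`, `end_frame`,
#'   `motion_class`, `window_alpha` (mean window alpha of the segment),
#'   `n_windows`.
#' @export
segmentMotion <- function(track, window = 30L, stride = 5L,
                          thresholds = motionThresholds(),
                          pixelSize = 1, dt = 1) {
  stopifnot(all(c("frame", "x", "y") %in% names(track)), window >= 8L,
            stride >= 1L)
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < window) {
    feat <- .windowFeatures(track$x, track$y, track$frame, pixelSize, dt)
    cls <- .classifyWindow(feat, thresholds)
    return(data.frame(start_frame = track$frame[1],
                      end_frame = track$frame[n],
                      motion_class = cls,
                      window_alpha = feat$alpha,
                      n_windows = 1L))
  }
  starts <- seq(1L, n - window + 1L, by = stride)
  if (starts[length(starts)] != n - window + 1L)
    starts <- c(starts, n - window + 1L)
  lab <- character(length(starts))
  alp <- numeric(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + window - 1L)
    feat <- .windowFeatures(track$x[idx], track$y[idx], track$frame[idx],
                            pixelSize, dt)
    lab[k] <- .classifyWindow(feat, thresholds)
    alp[k] <- feat$alpha
  }
  ok <- !is.na(lab)
  starts <- starts[ok]; lab <- lab[ok]; alp <- alp[ok]
  if (!length(lab))
    return(data.frame(start_frame = track$frame[1], end_frame = track$frame[n],
                      motion_class = NA_character_, window_alpha = NA_real_,
                      n_windows = 0L))
  ## merge runs of identical labels; segment boundaries at window midpoints
  runEnd <- c(which(lab[-1] != lab[-length(lab)]), length(lab))
  runStart <- c(1L, utils::head(runEnd, -1L) + 1L)
  segs <- lapply(seq_along(runStart), function(r) {
    a <- runStart[r]; b <- runEnd[r]
    data.frame(start_frame = track$frame[if (r == 1L) 1L else starts[a]],
               end_frame = track$frame[if (r == length(runStart)) n
                                       else starts[b] + window - 1L],
               motion_class = lab[a],
               window_alpha = mean(alp[a:b]),
               n_windows = b - a + 1L)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Dominant diffusion mode of a segmented track
#'
#' @param segments a data.frame from [segmentMotion()].
#' @return a list with `dominant` (the mode covering the most frames)
#'   and `fractions`, a named numeric vector over the four modes summing
#'   to 1.
#' @export
classifyTrack <- function(segments) {
  stopifnot(nrow(segments) >= 1)
  classes <- c("normal", "directed", "confined", "subdiffusive")
  segments <- segments[!is.na(segments$motion_class), , drop = FALSE]
  if (!nrow(segments))
    return(list(dominant = NA_character_,
                fractions = stats::setNames(rep(NA_real_, 4), classes)))
  frames <- segments$end_frame - segments$start_frame + 1
  tot <- tapply(frames, factor(segments$motion_class, levels = classes), sum)
  tot[is.na(tot)] <- 0
  fractions <- stats::setNames(as.numeric(tot / sum(tot)), classes)
  dominant <- classes[which.max(tot)]
  list(dominant = dominant, fractions = fractions)
}
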