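## Delivery-path classification: membrane occupancy, the >10-frame
## residence rule and the alpha > 0.8 / alpha < 0.3 mobility cuts.

#' Per-frame membrane/cell occupancy of a track
#'
#' A spot is `on_membrane` when the Euclidean distance from its rounded
#' pixel position to the nearest membrane pixel (via distance transform)
#' is at most `dMem`; otherwise `in_cell` when inside the cell mask;
#' otherwise `outside`.
#'
#' @param track data.frame for one track (`frame`, `x`, `y`, 0-based
#'   pixel coordinates).
#' @param geometry a [CellGeometry-class].
#' @param dMem membrane colocalization distance in pixels (default 2).
#' @return a data.frame with `frame` and `occupancy` (factor with levels
#'   `on_membrane`, `in_cell`, `outside`).
#' @export
assignOccupancy <- function(track, geometry, dMem = 2) {
  stopifnot(is(geometry, "CellGeometry"),
            all(c("frame", "x", "y") %in% names(track)))
  mem <- membraneMask(geometry)
  cell <- cellMask(geometry)
  h <- nrow(mem); w <- ncol(mem)
  ri <- round(track$y) + 1L
  ci <- round(track$x) + 1L
  if (any(ri < 1L | ri > h | ci < 1L | ci > w))
    stop("track coordinates fall outside the geometry masks")
  if (any(mem)) {
    dm <- as.matrix(EBImage::distmap(matrix(as.numeric(!mem), h, w)))
    dMemAt <- dm[cbind(ri, ci)]
  } else {
    dMemAt <- rep(Inf, nrow(track))
  }
  occ <- ifelse(dMemAt <= dMem, "on_membrane",
                ifelse(cell[cbind(ri, ci)], "in_cell", "outside"))
  data.frame(frame = track$frame,
             occupancy = factor(occ, levels = c("on_membrane", "in_cell",
                                                "outside")))
}

#' Classify the delivery path of one track
#'
#' Applies the mobility and residence rules in a fixed order:
#' \enumerate{
#'   \item membrane contact followed by sustained movement into the cell
#'     (at least `mMove` consecutive `in_cell` frames after the first
#'     membrane contact): `fast` when the post-membrane anomalous
#'     exponent exceeds `alphaFast` (0.8), `slow` when below `alphaSlow`
#'     (0.3), otherwise `unclassified` (the band between the cuts is
#'     deliberately left open);
#'   \item membrane residence longer than `residenceRule` frames with
#'     alpha below `alphaSlow` and no subsequent movement off the
#'     membrane: `attached`;
#'   \item membrane residence longer than `residenceRule` frames
#'     followed by any movement: `temporarily_fixed`;
#'   \item otherwise `unclassified`.
#' }
#' Residence is the longest consecutive run of `on_membrane` frames.
#'
#' @param occupancy data.frame from [assignOccupancy()].
#' @param alphaPost anomalous exponent of the track after it leaves the
#'   membrane (or of the full track when no post-membrane sub-track is
#'   long enough to fit).
#' @param residenceRule residence threshold in frames (default 10).
#' @param alphaFast,alphaSlow mobility cuts (defaults 0.8 and 0.3).
#' @param mMove consecutive `in_cell` frames that count as sustained
#'   movement into the cell (default 3, rejecting boundary jitter).
#' @return a list with `label` (one of `fast`, `slow`, `attached`,
#'   `temporarily_fixed`, `unclassified`), `membraneResidence` (frames)
#'   and `alphaPost`.
#' @export
classifyPath <- function(occupancy, alphaPost = NA_real_,
                         residenceRule = 10L, alphaFast = 0.8,
                         alphaSlow = 0.3, mMove = 3L) {
  stopifnot(nrow(occupancy) >= 1)
  occ <- as.character(occupancy$occupancy)
  onMem <- occ == "on_membrane"
  inCell <- occ == "in_cell"
  runLen <- function(v) {
    if (!any(v)) return(0L)
    r <- rle(v)
    max(r$lengths[r$values])
  }
  residence <- runLen(onMem)
  firstMem <- if (any(onMem)) which(onMem)[1] else NA_integer_
  movedIn <- FALSE
  if (!is.na(firstMem) && firstMem < length(occ)) {
    after <- inCell[(firstMem + 1L):length(occ)]
    movedIn <- runLen(after) >= mMove
  }
  label <- "unclassified"
  if (movedIn && !is.na(alphaPost)) {
    if (alphaPost > alphaFast) label <- "fast"
    else if (alphaPost < alphaSlow) label <- "slow"
  } else if (residence > residenceRule) {
    runs <- rle(onMem)
    runEnds <- cumsum(runs$lengths)
    longRun <- which(runs$values & runs$lengths > residenceRule)[1]
    residentToEnd <- runEnds[longRun] == length(occ)
    if (residentToEnd && !is.na(alphaPost) && alphaPost < alphaSlow)
      label <- "attached"
    else if (!residentToEnd)
      label <- "temporarily_fixed"
  }
  list(label = label, membraneResidence = residence, alphaPost = alphaPost)
}

#' Classify delivery paths for a set of linked tracks
#'
#' Convenience wrapper: for every track, computes occupancy, fits the
#' anomalous exponent on the post-membrane (`in_cell`) sub-track when it
#' has at least `minSubLength` observations (full track as fallback,
#' flagged), and applies [classifyPath()].
#'
#' The transit from the membrane into the cytosol is a short directed
#' relocation; left in the fit it biases the exponent of the cytosolic
#' phase upward. The first `settleFrames` observations of the
#' post-membrane sub-track are therefore excluded whenever the remainder
#' is still at least `minSubLength` long, so the exponent describes the
#' settled cytosolic motion.
#'
#' @param tracks linked spot data.frame with `track_id`, `frame`, `x`,
#'   `y`.
#' @param geometry a [CellGeometry-class].
#' @param pixelSize um per pixel.
#' @param dt seconds per frame.
#' @param dMem membrane distance in pixels.
#' @param minSubLength minimum sub-track length for the post-membrane
#'   fit (default 10).
#' @param settleFrames post-membrane observations dropped before the
#'   exponent fit (default 5); see Details.
#' @param ... passed to [classifyPath()].
#' @return a data.frame with one row per track: `track_id`,
#'   `path_class`, `alpha_post`, `membrane_residence`,
#'   `alpha_on_subtrack` (logical; FALSE when the full-track fallback
#'   was used).
#' @export
classifyPaths <- function(tracks, geometry, pixelSize = 1, dt = 1,
                          dMem = 2, minSubLength = 10L, settleFrames = 5L,
                          ...) {
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    occ <- assignOccupancy(tr, geometry, dMem = dMem)
    inCell <- as.character(occ$occupancy) == "in_cell"
    onMem <- as.character(occ$occupancy) == "on_membrane"
    sub <- tr
    usedSub <- FALSE
    if (any(onMem)) {
      lastMem <- max(which(onMem))
      if (lastMem < nrow(tr) && nrow(tr) - lastMem >= minSubLength) {
        sub <- tr[(lastMem + 1L):nrow(tr), , drop = FALSE]
        usedSub <- TRUE
      } else if (sum(inCell) >= minSubLength) {
        sub <- tr[inCell, , drop = FALSE]
        usedSub <- TRUE
      }
      if (usedSub && nrow(sub) - settleFrames >= minSubLength)
        sub <- sub[-seq_len(settleFrames), , drop = FALSE]
    }
    alphaPost <- NA_real_
    if (nrow(sub) >= 4L) {
      msd <- computeMSD(sub, pixelSize = pixelSize, dt = dt,
                        maxLagFraction = if (nrow(sub) >= 16L) 0.25 else 0.75)
      fit <- fitAlpha(msd, fitLags = min(10L, max(3L, floor(nrow(sub) / 4))))
      alphaPost <- fit$alpha
    }
    cls <- classifyPath(occ, alphaPost = alphaPost, ...)
    data.frame(track_id = id, path_class = cls$label,
               alpha_post = cls$alphaPost,
               membrane_residence = cls$membraneResidence,
               alpha_on_subtrack = usedSub)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count tracked payloads per replicate and compare conditions
#'
#' Counts tracks per replicate in each condition (after any length
#' filtering the caller applied), reports mean +/- SD per condition, and
#' compares all condition pairs with a two-sided unpaired Welch t-test.
#'
#' @param countsByCondition a named list; each element is a numeric
#'   vector of per-replicate track counts for one condition.
#' @return a list with `summary` (condition, n replicates, mean, sd) and
#'   `tests` (pairwise comparisons with statistic, p-value and
#'   significance band).
#' @export
countPayloads <- function(countsByCondition) {
  stopifnot(is.list(countsByCondition), length(countsByCondition) >= 1,
            !is.null(names(countsByCondition)))
  summary <- do.call(rbind, lapply(names(countsByCondition), function(cond) {
    v <- countsByCondition[[cond]]
    data.frame(condition = cond, n_replicates = length(v),
               mean_count = mean(v), sd_count = stats::sd(v))
  }))
  conds <- names(countsByCondition)
  tests <- NULL
  if (length(conds) >= 2) {
    pairs <- utils::combn(conds, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- countsByCondition[[pairs[1, k]]]
      b <- countsByCondition[[pairs[2, k]]]
      tt <- tTestUnpaired(a, b)
      data.frame(condition_a = pairs[1, k], condition_b = pairs[2, k],
                 statistic = tt$statistic, p_value = tt$pValue,
                 band = tt$band)
    }))
  }
  list(summary = summary, tests = tests)
}
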