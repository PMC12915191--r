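## Frame-to-frame linking by minimum-total-distance bipartite assignment
## (Jonker-Volgenant shortest augmenting path), with gap closing.

#' Minimum-cost assignment of a square cost matrix
#'
#' Solves the linear assignment problem by shortest augmenting paths
#' with dual potentials (the algorithm behind standard LAP solvers).
#' Deterministic: ties resolve by the scan order of rows and columns.
#'
#' @param cost a square numeric matrix of finite costs.
#' @return an integer vector `a` with `a[i]` the column assigned to row
#'   `i`, minimizing `sum(cost[cbind(seq_len(n), a)])`.
#' @keywords internal
solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n); v <- numeric(n)
  col4row <- rep(NA_integer_, n)
  row4col <- rep(NA_integer_, n)
  for (cur in seq_len(n)) {
    shortest <- rep(Inf, n)
    pred <- rep(NA_integer_, n)        # predecessor row for each column
    done <- rep(FALSE, n)
    scanned <- integer(0)
    i <- cur; mind <- 0; sink <- NA_integer_
    while (is.na(sink)) {
      rem <- which(!done)
      red <- mind + cost[i, rem] - u[i] - v[rem]
      upd <- red < shortest[rem]
      shortest[rem[upd]] <- red[upd]
      pred[rem[upd]] <- i
      j <- rem[which.min(shortest[rem])]
      mind <- shortest[j]
      done[j] <- TRUE
      scanned <- c(scanned, j)
      if (is.na(row4col[j])) sink <- j else i <- row4col[j]
    }
    ## dual update over scanned columns
    u[cur] <- u[cur] + mind
    for (j in scanned) {
      if (j != sink) {
        u[row4col[j]] <- u[row4col[j]] + mind - shortest[j]
        v[j] <- v[j] - (mind - shortest[j])
      }
    }
    ## augment along the alternating path
    j <- sink
    repeat {
      i <- pred[j]
      row4col[j] <- i
      jnext <- col4row[i]
      col4row[i] <- j
      if (i == cur) break
      j <- jnext
    }
  }
  col4row
}

## Assign tracks (rows) to spots (cols) with per-pair distance limits.
## Returns integer vector over tracks: spot index or NA. Uses the
## augmented-matrix formulation: forbidden links and "leave unmatched"
## alternatives enter as finite costs so the square problem is feasible.
.assignFrame <- function(dists, maxDist) {
  nT <- nrow(dists); nS <- ncol(dists)
  if (nT == 0L || nS == 0L) return(rep(NA_integer_, nT))
  alt <- max(maxDist) + 1
  big <- 4 * (alt + 1) * (nT + nS)
  D <- dists
  D[D > maxDist] <- big                 # maxDist recycled per column-major
  C <- matrix(big, nT + nS, nT + nS)
  C[seq_len(nT), seq_len(nS)] <- D
  for (i in seq_len(nT)) C[i, nS + i] <- alt       # track not extended
  for (j in seq_len(nS)) C[nT + j, j] <- alt       # spot starts new track
  C[(nT + 1):(nT + nS), (nS + 1):(nS + nT)] <- 0
  a <- solveAssignment(C)
  out <- a[seq_len(nT)]
  out[out > nS] <- NA_integer_
  ## a feasible but forbidden pairing can only appear if forced; drop it
  forced <- !is.na(out) & dists[cbind(seq_len(nT), out)] >
    maxDist[cbind(seq_len(nT), out)]
  out[forced] <- NA_integer_
  out
}

#' Link per-frame spots into trajectories
#'
#' Links detections frame to frame by minimum-total-distance bipartite
#' assignment. Candidate links farther than `maxDisplacement` pixels are
#' forbidden; a track that misses up to `maxGap` consecutive frames may
#' be resumed, with its displacement budget scaled by `(gap + 1)`. Every
#' spot belongs to exactly one track; spots that start no continuation
#' become singleton tracks. Track ids are assigned in order of first
#' appearance (frame, then spot order within the frame).
#'
#' @param spots a data.frame with at least `frame`, `x`, `y`; extra
#'   columns are carried through.
#' @param maxDisplacement maximum per-frame displacement in pixels.
#' @param maxGap maximum number of missed frames bridged (default 0).
#' @return the input data.frame with a `track_id` column, ordered by
#'   track then frame.
#' @export
linkSpots <- function(spots, maxDisplacement = 5, maxGap = 0L) {
  stopifnot(all(c("frame", "x", "y") %in% names(spots)),
            maxDisplacement > 0, maxGap >= 0)
  if (!nrow(spots)) {
    spots$track_id <- integer(0)
    return(spots)
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  track_id <- rep(NA_integer_, nrow(spots))
  framesSeen <- sort(unique(spots$frame))
  ## active track state: id, last spot row, last frame
  actId <- integer(0); actRow <- integer(0); actFrame <- integer(0)
  nextId <- 1L
  for (f in framesSeen) {
    rows <- which(spots$frame == f)
    live <- actFrame >= f - 1L - maxGap
    actId <- actId[live]; actRow <- actRow[live]; actFrame <- actFrame[live]
    assigned <- rep(NA_integer_, length(rows))
    if (length(actId) && length(rows)) {
      dx <- outer(spots$x[actRow], spots$x[rows], "-")
      dy <- outer(spots$y[actRow], spots$y[rows], "-")
      d <- sqrt(dx^2 + dy^2)
      gap <- f - actFrame - 1L
      lim <- matrix(maxDisplacement * (gap + 1L), length(actId), length(rows))
      sel <- .assignFrame(d, lim)
      for (i in seq_along(sel)) if (!is.na(sel[i])) assigned[sel[i]] <- i
    }
    newAct <- actId; newRow <- actRow; newFrame <- actFrame
    for (k in seq_along(rows)) {
      if (!is.na(assigned[k])) {
        id <- actId[assigned[k]]
        newRow[assigned[k]] <- rows[k]
        newFrame[assigned[k]] <- f
      } else {
        id <- nextId
        nextId <- nextId + 1L
        newAct <- c(newAct, id)
        newRow <- c(newRow, rows[k])
        newFrame <- c(newFrame, f)
      }
      track_id[rows[k]] <- id
    }
    actId <- newAct; actRow <- newRow; actFrame <- newFrame
  }
  spots$track_id <- track_id
  spots <- spots[order(spots$track_id, spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  spots
}

#' Summarize linked tracks
#'
#' @param tracks a linked spot data.frame from [linkSpots()].
#' @return one row per track: `track_id`, `n_points`, `first_frame`,
#'   `last_frame`, `gap_frames` (total skipped frames).
#' @export
trackSummary <- function(tracks) {
  stopifnot("track_id" %in% names(tracks))
  ids <- unique(tracks$track_id)
  do.call(rbind, lapply(ids, function(id) {
    fr <- sort(tracks$frame[tracks$track_id == id])
    data.frame(track_id = id, n_points = length(fr),
               first_frame = fr[1], last_frame = fr[length(fr)],
               gap_frames = (fr[length(fr)] - fr[1] + 1L) - length(fr))
  }))
}

#' Filter tracks by minimum length
#'
#' Keeps tracks with at least `minLength` observations; order and
#' content of surviving tracks are unchanged.
#'
#' @param tracks a linked spot data.frame with `track_id`.
#' @param minLength minimum number of observations.
#' @return the filtered data.frame.
#' @export
filterTrajectories <- function(tracks, minLength = 20L) {
  stopifnot("track_id" %in% names(tracks), minLength >= 1)
  n <- table(tracks$track_id)
  keep <- names(n)[n >= minLength]
  out <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
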