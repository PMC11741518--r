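# Frame-to-frame linking of cell detections into trajectories by optimal
# assignment.  The pairing cost is the inverse distance between candidate
# positions (maximized, i.e. the negated inverse distance is minimized),
# with pairings beyond the population gate distance forbidden.  Unassigned
# detections open new tracks; unassigned tracks carry a gap and expire
# after max_gap missed frames.  Two tracks may share one detection for up
# to two consecutive frames (overlap from 3D-to-2D projection) before the
# share is dropped.

#' Create an empty track set
#'
#' @param population `"cancer"` or `"immune"`.
#' @return An object of class `"cell_tracks"`.
#' @export
new_track_set <- function(population = c("cancer", "immune")) {
  population <- match.arg(population)
  structure(list(population = population, tracks = list(), next_id = 1L),
            class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat("Track set (", x$population, "): ", length(x$tracks), " tracks\n",
      sep = "")
  invisible(x)
}

.track_last <- function(tr) {
  k <- max(which(!is.na(tr$x)))
  c(x = tr$x[k], y = tr$y[k])
}

#' Link one frame of detections into existing tracks
#'
#' Solves the optimal sub-pattern assignment between active tracks and the
#' detections of the current frame with the Hungarian algorithm, using an
#' assignment cost equal to the (negated) inverse distance between
#' candidate positions and forbidding pairs farther apart than
#' `max_link_distance`.
#'
#' @param track_set A `"cell_tracks"` object.
#' @param detections A data frame from [detect_cells()] (columns `x`, `y`,
#'   `radius`).
#' @param frame Frame index (1-based, consecutive).
#' @param max_link_distance Gate distance in px (40 for cancer cells, 20
#'   for immune cells in the reference settings).
#' @param max_gap Number of consecutive missed frames before a track is
#'   closed.
#' @return The updated `"cell_tracks"` object.
#' @export
link_frame <- function(track_set, detections, frame, max_link_distance,
                       max_gap = 5L) {
  stopifnot(inherits(track_set, "cell_tracks"))
  frame <- as.integer(frame)
  eps <- 1e-6
  tr <- track_set$tracks
  active <- which(vapply(tr, function(t)
    t$active && (frame - t$last_frame) <= max_gap + 1L, TRUE))
  nd <- if (is.null(detections)) 0L else nrow(detections)
  ass <- rep(NA_integer_, length(active))
  if (length(active) && nd) {
    cost <- matrix(Inf, length(active), nd)
    for (k in seq_along(active)) {
      last <- .track_last(tr[[active[k]]])
      d <- sqrt((detections$x - last["x"])^2 + (detections$y - last["y"])^2)
      ok <- d <= max_link_distance
      cost[k, ok] <- -1 / (d[ok] + eps)
    }
    ass <- solve_assignment(cost, reject_cost = 0)
  }
  taken <- stats::na.omit(ass)
  # extend matched tracks
  for (k in seq_along(active)) {
    i <- active[k]
    if (!is.na(ass[k])) {
      j <- ass[k]
      tr[[i]]$frames <- c(tr[[i]]$frames, frame)
      tr[[i]]$x <- c(tr[[i]]$x, detections$x[j])
      tr[[i]]$y <- c(tr[[i]]$y, detections$y[j])
      tr[[i]]$r <- c(tr[[i]]$r, detections$radius[j])
      tr[[i]]$last_frame <- frame
      tr[[i]]$gap <- 0L
      tr[[i]]$shared <- 0L
    }
  }
  # unmatched tracks: allow a brief shared detection, else record a gap
  for (k in seq_along(active)) {
    i <- active[k]
    if (is.na(ass[k])) {
      last <- .track_last(tr[[i]])
      shared_j <- NA_integer_
      if (nd && length(taken)) {
        d <- sqrt((detections$x - last["x"])^2 +
                    (detections$y - last["y"])^2)
        cand <- which(seq_len(nd) %in% taken &
                        d <= max_link_distance / 2)
        if (length(cand)) shared_j <- cand[which.min(d[cand])]
      }
      if (!is.na(shared_j) && tr[[i]]$shared < 2L) {
        tr[[i]]$frames <- c(tr[[i]]$frames, frame)
        tr[[i]]$x <- c(tr[[i]]$x, detections$x[shared_j])
        tr[[i]]$y <- c(tr[[i]]$y, detections$y[shared_j])
        tr[[i]]$r <- c(tr[[i]]$r, detections$radius[shared_j])
        tr[[i]]$last_frame <- frame
        tr[[i]]$shared <- tr[[i]]$shared + 1L
      } else {
        tr[[i]]$gap <- tr[[i]]$gap + 1L
        if (tr[[i]]$gap > max_gap) tr[[i]]$active <- FALSE
      }
    }
  }
  # unmatched detections start new tracks
  if (nd) {
    for (j in setdiff(seq_len(nd), taken)) {
      tr[[length(tr) + 1L]] <- list(
        id = track_set$next_id, frames = frame,
        x = detections$x[j], y = detections$y[j], r = detections$radius[j],
        last_frame = frame, gap = 0L, shared = 0L, active = TRUE)
      track_set$next_id <- track_set$next_id + 1L
    }
  }
  track_set$tracks <- tr
  track_set
}

#' Track positions as a per-frame table
#'
#' @param track_set A `"cell_tracks"` object.
#' @param n_frames Total number of frames.
#' @return A data frame with columns `id`, `frame`, `x`, `y`, `r`.
#' @export
tracks_table <- function(track_set, n_frames = NULL) {
  rows <- lapply(track_set$tracks, function(t)
    data.frame(id = t$id, frame = t$frames, x = t$x, y = t$y, r = t$r))
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(id = integer(), frame = integer(),
                                      x = numeric(), y = numeric(),
                                      r = numeric())
  out
}
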