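# Synthetic time-lapse microscopy generator: bright disk-like cells of two
# radius classes performing drifting random walks on a noisy background,
# with optional division and apoptosis events.  Ground truth (per-frame
# positions, radii and events) is returned alongside the rendered stack so
# the detection/tracking pipeline can be scored against it.

.soft_disk <- function(h, w, cx, cy, r, amplitude, edge = 1.0) {
  ys <- pmax(1L, floor(cy - r - 3)):pmin(h, ceiling(cy + r + 3))
  xs <- pmax(1L, floor(cx - r - 3)):pmin(w, ceiling(cx + r + 3))
  if (!length(ys) || !length(xs)) return(NULL)
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  list(ys = ys, xs = xs, v = amplitude / (1 + exp((d - r) / edge)))
}

#' Render a synthetic cell video with ground truth
#'
#' Bright cancer (radius about 14 px) and immune (radius about 4 px) disks
#' move as random walks with slowly varying drift on a noisy background;
#' one cancer cell starts at the crop center (the main cancer cell).
#' Division events split a disk into two; apoptosis events shrink and fade
#' the disk over a few frames.
#'
#' @param n_frames Number of frames.
#' @param image_size `(height, width)` in px.
#' @param n_cancer,n_immune Number of cells per population.
#' @param cancer_radius,immune_radius Mean radii (px).
#' @param noise_sd Gaussian background noise s.d. (image intensity units).
#' @param drift_sd Innovation s.d. of the slowly varying drift
#'   (px/frame); the per-frame random-walk jitter is `2*drift_sd` for
#'   immune cells and `drift_sd` for cancer cells.
#' @param events Optional data frame with columns `track_id`, `event`
#'   (`"division"`/`"apoptosis"`), `frame`.
#' @param seed Integer seed or `NULL`.
#' @return A list with `stack` (list of frame matrices in `[0, 1]`),
#'   `truth` (data frame `id`, `population`, `frame`, `x`, `y`, `radius`)
#'   and `events`.
#' @export
render_synthetic_video <- function(n_frames = 60L, image_size = c(300L, 300L),
                                   n_cancer = 1L, n_immune = 5L,
                                   cancer_radius = 14, immune_radius = 4,
                                   noise_sd = 0.02, drift_sd = 0.15,
                                   events = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- image_size[1L]; w <- image_size[2L]
  cells <- list()
  add_cell <- function(pop, x, y, r, from = 1L) {
    cells[[length(cells) + 1L]] <<- list(
      id = length(cells) + 1L, population = pop, x = x, y = y, r = r,
      dx = stats::rnorm(1, 0, drift_sd), dy = stats::rnorm(1, 0, drift_sd),
      from = from, alive = TRUE, fade = 1)
  }
  add_cell("cancer", w / 2, h / 2, cancer_radius)
  if (n_cancer > 1L) {
    for (k in seq_len(n_cancer - 1L))
      add_cell("cancer", stats::runif(1, 0.15 * w, 0.85 * w),
               stats::runif(1, 0.15 * h, 0.85 * h),
               cancer_radius * stats::runif(1, 0.9, 1.1))
  }
  for (k in seq_len(n_immune))
    add_cell("immune", stats::runif(1, 0.1 * w, 0.9 * w),
             stats::runif(1, 0.1 * h, 0.9 * h),
             immune_radius * stats::runif(1, 0.9, 1.1))
  stack <- vector("list", n_frames)
  truth <- list()
  for (f in seq_len(n_frames)) {
    # events
    if (!is.null(events) && nrow(events)) {
      ev <- events[events$frame == f, , drop = FALSE]
      for (e in seq_len(nrow(ev))) {
        ci <- which(vapply(cells, function(cc)
          cc$id == ev$track_id[e] && cc$alive, TRUE))
        if (!length(ci)) next
        ci <- ci[1L]
        if (ev$event[e] == "division") {
          mother <- cells[[ci]]
          off <- 1.4 * mother$r
          th <- stats::runif(1, 0, 2 * pi)
          cells[[ci]]$x <- mother$x - off / 2 * cos(th)
          cells[[ci]]$y <- mother$y - off / 2 * sin(th)
          cells[[ci]]$r <- mother$r * 0.8
          add_cell(mother$population, mother$x + off / 2 * cos(th),
                   mother$y + off / 2 * sin(th), mother$r * 0.8, from = f)
        } else if (ev$event[e] == "apoptosis") {
          cells[[ci]]$fade <- 0.999  # start fading
        }
      }
    }
    img <- matrix(0.15, h, w)
    for (ci in seq_along(cells)) {
      cc <- cells[[ci]]
      if (!cc$alive || cc$from > f) next
      # drifting random walk
      jit <- if (cc$population == "immune") 2 * drift_sd else drift_sd
      cc$dx <- 0.95 * cc$dx + stats::rnorm(1, 0, drift_sd / 2)
      cc$dy <- 0.95 * cc$dy + stats::rnorm(1, 0, drift_sd / 2)
      cc$x <- min(w - 5, max(5, cc$x + cc$dx + stats::rnorm(1, 0, jit)))
      cc$y <- min(h - 5, max(5, cc$y + cc$dy + stats::rnorm(1, 0, jit)))
      if (cc$fade < 1) {
        cc$fade <- cc$fade * 0.75
        cc$r <- cc$r * 0.9
        if (cc$fade < 0.2 || cc$r < 1.5) cc$alive <- FALSE
      }
      cells[[ci]] <- cc
      if (!cc$alive) next
      amp <- (if (cc$population == "cancer") 0.5 else 0.65) * cc$fade
      sd_ <- .soft_disk(h, w, cc$x, cc$y, cc$r, amp)
      if (!is.null(sd_))
        img[sd_$ys, sd_$xs] <- img[sd_$ys, sd_$xs] + sd_$v
      truth[[length(truth) + 1L]] <- data.frame(
        id = cc$id, population = cc$population, frame = f,
        x = cc$x, y = cc$y, radius = cc$r)
    }
    img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    img[img < 0] <- 0; img[img > 1] <- 1
    stack[[f]] <- img
  }
  list(stack = stack,
       truth = do.call(rbind, truth),
       events = events)
}
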