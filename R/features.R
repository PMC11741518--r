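# Morphodynamic, state and interaction descriptors of the main cancer cell
# (MCC), computed per frame from its trajectory, segmentation masks and the
# surrounding immune-cell tracks.  Together with the shape descriptors
# this yields the 15-descriptor feature table.

#' Interaction radii from the two cell radii
#'
#' Physical contact radius `r1 = r_im + r_ca + 2` and close-vicinity radius
#' `r2 = 2 * (r_im + r_ca)`; with the reference radii (4 px immune, 14 px
#' cancer) these are 20 px and 36 px.
#'
#' @param r_im Immune cell radius (px).
#' @param r_ca Cancer cell radius (px).
#' @return A list with `r1` and `r2` (px).
#' @export
interaction_radii <- function(r_im = 4, r_ca = 14) {
  list(r1 = r_im + r_ca + 2, r2 = 2 * (r_im + r_ca))
}

#' Motility descriptors along a trajectory
#'
#' Instantaneous velocity `d(p_i, p_(i-1)) / dt`, net displacement
#' `d(p_1, p_i)`, directionality (net displacement over curvilinear
#' distance; 1 for a perfectly straight path, 0 for a closed loop or a
#' stationary cell) and instantaneous shape change `|d_i - d_(i-1)|` of the
#' equivalent diameter.
#'
#' @param x,y Positions (px) per frame.
#' @param diameters Equivalent diameters per frame (optional; `NA`s allowed).
#' @param dt Time between consecutive frames (frame units by default).
#' @return A data frame with `velocity`, `net_displacement`,
#'   `directionality`, `shape_change` (first frame: `NA` velocity/shape
#'   change, 0 net displacement and directionality).
#' @export
motility_descriptors <- function(x, y, diameters = NULL, dt = 1) {
  n <- length(x)
  if (n < 2L) stop("track length must be >= 2")
  step <- c(NA, sqrt(diff(x)^2 + diff(y)^2))
  velocity <- step / dt
  net <- sqrt((x - x[1L])^2 + (y - y[1L])^2)
  curv <- cumsum(ifelse(is.na(step), 0, step))
  directionality <- ifelse(curv > 0, net / curv, 0)
  shape_change <- if (is.null(diameters)) rep(NA_real_, n)
  else c(NA, abs(diff(diameters)))
  data.frame(velocity = velocity, net_displacement = net,
             directionality = directionality, shape_change = shape_change)
}

#' Cancer-immune interaction descriptors at one frame
#'
#' Counts of immune cells within the vicinity radius `r2` and the contact
#' radius `r1` around the MCC, the minimal cancer-immune distance within
#' `r2`, and the mean instantaneous immune velocity norm within each
#' radius.  Distances are center-to-center.
#'
#' @param mcc_x,mcc_y MCC center at this frame (px).
#' @param immune_table A data frame of immune positions with columns `id`,
#'   `frame`, `x`, `y` (e.g. from [tracks_table()]).
#' @param frame Frame index.
#' @param r1,r2 Interaction radii (px), `r1 <= r2`.
#' @param dt Frame interval for the velocity norms.
#' @return A list with `n_interactions_r2`, `n_interactions_r1`,
#'   `min_distance_r2`, `mean_immune_velocity_r2`,
#'   `mean_immune_velocity_r1` (distances/velocities `NA` when no immune
#'   cell is in range).
#' @export
interaction_descriptors <- function(mcc_x, mcc_y, immune_table, frame,
                                    r1 = 20, r2 = 36, dt = 1) {
  if (r1 > r2) stop("r1 must be <= r2")
  cur <- immune_table[immune_table$frame == frame, , drop = FALSE]
  if (!nrow(cur)) {
    return(list(n_interactions_r2 = 0L, n_interactions_r1 = 0L,
                min_distance_r2 = NA_real_,
                mean_immune_velocity_r2 = NA_real_,
                mean_immune_velocity_r1 = NA_real_))
  }
  d <- sqrt((cur$x - mcc_x)^2 + (cur$y - mcc_y)^2)
  in2 <- d <= r2; in1 <- d <= r1
  prev <- immune_table[immune_table$frame == frame - 1L, , drop = FALSE]
  vel <- rep(NA_real_, nrow(cur))
  if (nrow(prev)) {
    m <- match(cur$id, prev$id)
    ok <- !is.na(m)
    vel[ok] <- sqrt((cur$x[ok] - prev$x[m[ok]])^2 +
                      (cur$y[ok] - prev$y[m[ok]])^2) / dt
  }
  mean_vel <- function(sel) {
    v <- vel[sel & !is.na(vel)]
    if (length(v)) mean(v) else NA_real_
  }
  list(n_interactions_r2 = sum(in2),
       n_interactions_r1 = sum(in1),
       min_distance_r2 = if (any(in2)) min(d[in2]) else NA_real_,
       mean_immune_velocity_r2 = mean_vel(in2),
       mean_immune_velocity_r1 = mean_vel(in1))
}

#' State descriptors from event annotations
#'
#' Converts per-track apoptosis/division event times into per-frame step
#' functions: `"No"` before the event, `"Yes"` from the event frame on.
#'
#' @param frames Frame indices of the track.
#' @param apoptosis_frame Frame of the apoptosis event (`NA` if none; at
#'   most one per track).
#' @param division_frames Frames of division events (possibly several; the
#'   flag stays `"Yes"` after the first).
#' @return A data frame with factor columns `apoptosis` and `division`.
#' @export
state_flags <- function(frames, apoptosis_frame = NA,
                        division_frames = integer()) {
  rng <- range(frames)
  chk <- c(apoptosis_frame[!is.na(apoptosis_frame)], division_frames)
  if (length(chk) && (any(chk < rng[1L]) || any(chk > rng[2L])))
    stop("event time outside the track span")
  lev <- c("No", "Yes")
  apo <- factor(ifelse(!is.na(apoptosis_frame) & frames >= apoptosis_frame,
                       "Yes", "No"), levels = lev)
  div <- factor(ifelse(length(division_frames) > 0 &
                         frames >= suppressWarnings(min(division_frames)),
                       "Yes", "No"), levels = lev)
  data.frame(apoptosis = apo, division = div)
}

#' Extract the per-frame feature table of a video crop
#'
#' Full feature-extraction pipeline: circular-Hough detection of the two
#' cell populations on every frame, optimal-assignment tracking, selection
#' of the main cancer cell (cancer track starting nearest the image
#' center), segmentation and shape descriptors, motility, state and
#' cancer-immune interaction descriptors — one row per frame with the 15
#' descriptors.
#'
#' @param image_stack A 3-D numeric array (y, x, frame) or list of
#'   matrices, values in `[0, 1]`.
#' @param events Optional data frame of event annotations with columns
#'   `track_id` (`NA` or id matching the MCC), `event`
#'   (`"apoptosis"`/`"division"`) and `frame`.
#' @param config A list overriding defaults: `r_im`, `r_ca` (theoretical
#'   radii, px), `gate_cancer`, `gate_immune` (link gates, px),
#'   `sensitivity`, `max_gap`, `dt`.
#' @param verbose Print progress.
#' @return A data frame, one row per frame of the MCC track, with the
#'   shape, motility, state and interaction descriptor columns.
#' @export
extract_feature_table <- function(image_stack, events = NULL,
                                  config = list(), verbose = FALSE) {
  cfg <- utils::modifyList(list(r_im = 4, r_ca = 14, gate_cancer = 40,
                                gate_immune = 20, sensitivity = 0.25,
                                max_gap = 5L, dt = 1), config)
  frames <- if (is.list(image_stack)) image_stack
  else lapply(seq_len(dim(image_stack)[3L]),
              function(k) image_stack[, , k])
  nF <- length(frames)
  rad <- interaction_radii(cfg$r_im, cfg$r_ca)
  ca <- new_track_set("cancer")
  im <- new_track_set("immune")
  for (f in seq_len(nF)) {
    det_ca <- detect_cells(frames[[f]], cfg$r_ca + c(-4, 4),
                           sensitivity = cfg$sensitivity)
    det_im <- detect_cells(frames[[f]], cfg$r_im + c(-2, 2),
                           sensitivity = cfg$sensitivity)
    # discard immune detections lying inside a cancer cell body
    if (nrow(det_im) && nrow(det_ca)) {
      keep <- vapply(seq_len(nrow(det_im)), function(j) {
        all(sqrt((det_ca$x - det_im$x[j])^2 +
                   (det_ca$y - det_im$y[j])^2) > 0.8 * det_ca$radius)
      }, TRUE)
      det_im <- det_im[keep, , drop = FALSE]
    }
    ca <- link_frame(ca, det_ca, f, cfg$gate_cancer, cfg$max_gap)
    im <- link_frame(im, det_im, f, cfg$gate_immune, cfg$max_gap)
    if (verbose && f %% 25 == 0) message("frame ", f)
  }
  ca_tab <- tracks_table(ca)
  if (!nrow(ca_tab)) stop("no cancer cell detected")
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  # MCC: cancer track starting nearest the crop center
  starts <- do.call(rbind, lapply(split(ca_tab, ca_tab$id), function(d)
    d[which.min(d$frame), ]))
  d0 <- sqrt((starts$x - w / 2)^2 + (starts$y - h / 2)^2)
  mcc_id <- starts$id[which.min(d0)]
  mcc <- ca_tab[ca_tab$id == mcc_id, , drop = FALSE]
  mcc <- mcc[order(mcc$frame), ]
  im_tab <- tracks_table(im)

  shp <- lapply(seq_len(nrow(mcc)), function(k) {
    msk <- segment_mcc(frames[[mcc$frame[k]]],
                       list(x = mcc$x[k], y = mcc$y[k], r = mcc$r[k],
                            radius = mcc$r[k]))
    if (isTRUE(attr(msk, "collapsed")))
      list(area = NA_real_, perimeter = NA_real_, circularity = NA_real_,
           eccentricity = NA_real_, equivalent_diameter = NA_real_)
    else shape_descriptors(msk)
  })
  shp <- do.call(rbind, lapply(shp, as.data.frame))
  mot <- motility_descriptors(mcc$x, mcc$y, shp$equivalent_diameter,
                              dt = cfg$dt)
  states <- {
    apo <- NA; dvf <- integer()
    if (!is.null(events) && nrow(events)) {
      ev <- events[is.na(events$track_id) | events$track_id == mcc_id, ,
                   drop = FALSE]
      a <- ev$frame[ev$event == "apoptosis"]
      if (length(a)) apo <- a[1L]
      dvf <- ev$frame[ev$event == "division"]
    }
    state_flags(mcc$frame, apo, dvf)
  }
  inter <- do.call(rbind, lapply(seq_len(nrow(mcc)), function(k)
    as.data.frame(interaction_descriptors(mcc$x[k], mcc$y[k], im_tab,
                                          mcc$frame[k], rad$r1, rad$r2,
                                          cfg$dt))))
  out <- cbind(data.frame(frame = mcc$frame, x = mcc$x, y = mcc$y),
               shp, mot, states, inter)
  rownames(out) <- NULL
  attr(out, "mcc_id") <- mcc_id
  out
}
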