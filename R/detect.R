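# Circular Hough transform detection of disk-like cells in grayscale
# frames.  Gradient orientations vote along their direction at each
# candidate radius; accumulator peaks above a sensitivity threshold yield
# centers and radii.

# Sobel gradients of a matrix (rows = y, cols = x)
.sobel <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- img
  pad[1L, ] <- pad[2L, ]; pad[h + 2L, ] <- pad[h + 1L, ]
  pad[, 1L] <- pad[, 2L]; pad[, w + 2L] <- pad[, w + 1L]
  sh <- function(dy, dx) pad[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L) -
           sh(-1L, -1L) - 2 * sh(0L, -1L) - sh(1L, -1L)) / 8
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L) -
           sh(-1L, -1L) - 2 * sh(-1L, 0L) - sh(-1L, 1L)) / 8
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# 3x3 box smoothing
.box3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  acc <- matrix(0, h, w)
  for (dy in -1:1) for (dx in -1:1)
    acc <- acc + pad[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx]
  acc / 9
}

#' Detect circular cells in a grayscale frame
#'
#' Circular-Hough-transform detector for bright disk-like objects: edge
#' pixels vote along their inward gradient direction at each candidate
#' radius; smoothed accumulator peaks above `sensitivity` (fraction of the
#' circle perimeter supported by edge votes) are returned, strongest first,
#' with non-maximum suppression.
#'
#' @param frame_image Numeric matrix in `[0, 1]` (rows = y, columns = x).
#' @param radius_range Length-2 vector `(min, max)` radius in pixels.
#' @param sensitivity Accumulator threshold in (0, 1).
#' @param edge_quantile Quantile of the gradient magnitude defining edge
#'   pixels.
#' @param min_gradient Absolute gradient floor for edge pixels (intensity
#'   units per px); suppresses votes from background noise.
#' @param max_cells Maximum number of detections returned.
#' @return A data frame with columns `x`, `y`, `radius`, `score`.
#' @export
detect_cells <- function(frame_image, radius_range, sensitivity = 0.25,
                         edge_quantile = 0.9, min_gradient = 0.05,
                         max_cells = Inf) {
  empty <- data.frame(x = numeric(), y = numeric(), radius = numeric(),
                      score = numeric())
  if (!length(frame_image) || all(frame_image == frame_image[1L]))
    return(empty)
  h <- nrow(frame_image); w <- ncol(frame_image)
  g <- .sobel(frame_image)
  thr <- max(stats::quantile(g$mag, edge_quantile, names = FALSE),
             min_gradient)
  if (thr <= 0) return(empty)
  edge <- which(g$mag > thr)
  if (!length(edge)) return(empty)
  ey <- (edge - 1L) %% h + 1L
  ex <- (edge - 1L) %/% h + 1L
  ux <- g$gx[edge] / g$mag[edge]
  uy <- g$gy[edge] / g$mag[edge]
  radii <- seq(floor(radius_range[1L]), ceiling(radius_range[2L]))
  best_score <- matrix(0, h, w)
  best_r <- matrix(radii[1L], h, w)
  for (r in radii) {
    # bright cells on a dark background: the gradient points inward
    cx <- round(ex + r * ux); cy <- round(ey + r * uy)
    ok <- cx >= 1L & cx <= w & cy >= 1L & cy <= h
    if (!any(ok)) next
    idx <- cy[ok] + h * (cx[ok] - 1L)
    agg <- rowsum(cbind(1, ux[ok], uy[ok]), idx)
    uidx <- as.integer(rownames(agg))
    cnt <- matrix(0, h, w); sx <- matrix(0, h, w); sy <- matrix(0, h, w)
    cnt[uidx] <- agg[, 1L]; sx[uidx] <- agg[, 2L]; sy[uidx] <- agg[, 3L]
    cnt <- .box3(cnt) * 9; sx <- .box3(sx) * 9; sy <- .box3(sy) * 9
    # a genuine center collects votes from all directions; an edge or arc
    # fragment votes coherently from one side and is discounted
    coherence <- sqrt(sx^2 + sy^2) / pmax(cnt, 1)
    acc <- cnt * (1 - coherence) / (2 * pi * r)
    better <- acc > best_score
    best_score[better] <- acc[better]
    best_r[better] <- r
  }
  out <- empty
  repeat {
    m <- which.max(best_score)
    sc <- best_score[m]
    if (!length(sc) || sc < sensitivity || nrow(out) >= max_cells) break
    my <- (m - 1L) %% h + 1L
    mx <- (m - 1L) %/% h + 1L
    r <- best_r[m]
    out <- rbind(out, data.frame(x = mx, y = my, radius = r, score = sc))
    # suppress the neighborhood of the accepted center
    sup <- max(3, round(1.5 * r))
    ys <- max(1L, my - sup):min(h, my + sup)
    xs <- max(1L, mx - sup):min(w, mx + sup)
    best_score[ys, xs] <- 0
  }
  rownames(out) <- NULL
  out
}
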