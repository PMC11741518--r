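# Segmentation of the main cancer cell around a detection seed, and the
# shape descriptors computed from the binary mask.

# Otsu threshold of a numeric vector
.otsu <- function(v, nbins = 64L) {
  br <- seq(min(v), max(v), length.out = nbins + 1L)
  if (br[1L] == br[nbins + 1L]) return(br[1L])
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mt <- mu[nbins]
  sb <- (mt * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# vectorized flood fill (4-connectivity) on a logical matrix from seeds
.flood <- function(mask, seed_idx) {
  h <- nrow(mask); w <- ncol(mask)
  reached <- matrix(FALSE, h, w)
  frontier <- seed_idx[mask[seed_idx]]
  reached[frontier] <- TRUE
  while (length(frontier)) {
    y <- (frontier - 1L) %% h + 1L
    x <- (frontier - 1L) %/% h + 1L
    nb <- c(frontier[y > 1L] - 1L, frontier[y < h] + 1L,
            frontier[x > 1L] - h, frontier[x < w] + h)
    nb <- unique(nb[mask[nb] & !reached[nb]])
    reached[nb] <- TRUE
    frontier <- nb
  }
  reached
}

#' Segment the main cancer cell around a detection seed
#'
#' Edge-adherent morphological segmentation: the neighborhood of the seed
#' is thresholded (Otsu), the connected component containing the seed
#' center is extracted, holes are filled and the boundary smoothed by a
#' majority filter.  Deterministic for fixed inputs.
#'
#' @param frame_image Numeric matrix in `[0, 1]`.
#' @param seed A list or one-row data frame with `x`, `y`, `radius`.
#' @param roi_factor Half-size of the working window, in units of the seed
#'   radius.
#' @param min_area Minimum region area in px^2; smaller regions are flagged
#'   as collapsed.
#' @param min_contrast Minimum foreground-background intensity difference;
#'   below it the window is considered empty (collapse).
#' @return A logical matrix of the image size; attribute `"collapsed"` is
#'   `TRUE` when no usable region was found.
#' @export
segment_mcc <- function(frame_image, seed, roi_factor = 2.2,
                        min_area = 9, min_contrast = 0.1) {
  h <- nrow(frame_image); w <- ncol(frame_image)
  sx <- round(seed$x); sy <- round(seed$y)
  if (sx < 1 || sx > w || sy < 1 || sy > h)
    stop("seed center outside the image")
  half <- max(4L, round(roi_factor * seed$radius))
  ys <- max(1L, sy - half):min(h, sy + half)
  xs <- max(1L, sx - half):min(w, sx + half)
  roi <- frame_image[ys, xs, drop = FALSE]
  out <- matrix(FALSE, h, w)
  thr <- .otsu(as.vector(roi))
  fg <- roi > thr
  if (!any(fg) || all(fg) ||
      mean(roi[fg]) - mean(roi[!fg]) < min_contrast) {
    attr(out, "collapsed") <- TRUE
    return(out)
  }
  sy0 <- sy - ys[1L] + 1L; sx0 <- sx - xs[1L] + 1L
  hr <- nrow(fg)
  # seed tolerance: search a small disk around the center for foreground
  cand <- as.matrix(expand.grid(dy = -2:2, dx = -2:2))
  cy <- pmin(pmax(sy0 + cand[, "dy"], 1L), hr)
  cx <- pmin(pmax(sx0 + cand[, "dx"], 1L), ncol(fg))
  seeds <- unique(cy + hr * (cx - 1L))
  comp <- .flood(fg, seeds)
  if (!any(comp)) {
    attr(out, "collapsed") <- TRUE
    return(out)
  }
  # fill holes: background not reachable from the ROI border
  bg <- !comp
  border <- unique(c(seq_len(hr), seq_len(hr) + hr * (ncol(bg) - 1L),
                     1L + hr * (seq_len(ncol(bg)) - 1L),
                     hr + hr * (seq_len(ncol(bg)) - 1L)))
  outside <- .flood(bg, border)
  comp <- comp | (!outside & bg)
  # majority smoothing
  comp <- .box3(comp * 1) >= 5 / 9
  comp <- .flood(comp, seeds)
  if (sum(comp) < min_area) {
    attr(out, "collapsed") <- TRUE
    return(out)
  }
  out[ys, xs] <- comp
  attr(out, "collapsed") <- FALSE
  out
}

#' Circularity from area and perimeter
#'
#' `4 * area * pi / perimeter^2`; equals 1 for a perfect circle.
#' @param area Region area (px^2).
#' @param perimeter Boundary length (px).
#' @export
circularity <- function(area, perimeter) 4 * area * pi / perimeter^2

#' Equivalent diameter of a region
#'
#' Diameter of the circle with the same area: `sqrt(4 * area / pi)`.
#' @param area Region area (px^2).
#' @export
equivalent_diameter <- function(area) sqrt(4 * area / pi)

#' Shape descriptors of a binary mask
#'
#' Area (pixel count), perimeter (length of the 0.5-level boundary
#' contour), circularity `4*area*pi/perimeter^2`, eccentricity of the
#' ellipse with the same second central moments (0 for a circle, 1 for a
#' line), and equivalent diameter `sqrt(4*area/pi)`.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return A list with `area`, `perimeter`, `circularity`, `eccentricity`,
#'   `equivalent_diameter`.
#' @export
shape_descriptors <- function(mask) {
  m <- mask * 1
  area <- sum(m)
  if (area == 0) stop("empty mask")
  # zero padding guarantees a closed outer contour even when the region
  # touches the image border
  mp <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  mp[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  cl <- grDevices::contourLines(x = seq_len(nrow(mp)), y = seq_len(ncol(mp)),
                                z = mp, levels = 0.5)
  # light circular smoothing of the contour vertices reduces the
  # stair-casing bias of the rasterized boundary length
  contour_len <- function(ct) {
    cx <- ct$x; cy <- ct$y
    k <- length(cx)
    if (k > 8L && cx[1L] == cx[k] && cy[1L] == cy[k]) {
      cx <- cx[-k]; cy <- cy[-k]
      for (it in 1:2) {
        cx <- 0.25 * c(cx[-1], cx[1]) + 0.5 * cx +
          0.25 * c(cx[length(cx)], cx[-length(cx)])
        cy <- 0.25 * c(cy[-1], cy[1]) + 0.5 * cy +
          0.25 * c(cy[length(cy)], cy[-length(cy)])
      }
      cx <- c(cx, cx[1L]); cy <- c(cy, cy[1L])
    }
    sum(sqrt(diff(cx)^2 + diff(cy)^2))
  }
  perimeter <- max(vapply(cl, contour_len, 0))
  idx <- which(m > 0)
  ys <- (idx - 1L) %% nrow(m) + 1L
  xs <- (idx - 1L) %/% nrow(m) + 1L
  # second central moments with the pixel self-moment 1/12
  mu20 <- stats::var(xs) * (length(xs) - 1) / length(xs) + 1 / 12
  mu02 <- stats::var(ys) * (length(ys) - 1) / length(ys) + 1 / 12
  mu11 <- stats::cov(xs, ys) * (length(xs) - 1) / length(xs)
  if (length(xs) == 1L) { mu20 <- mu02 <- 1 / 12; mu11 <- 0 }
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(pmax(0, 1 - l2 / l1))
  list(area = area, perimeter = perimeter,
       circularity = circularity(area, perimeter),
       eccentricity = ecc,
       equivalent_diameter = equivalent_diameter(area))
}
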