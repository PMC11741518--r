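# Cell detection, segmentation and descriptor formulas.

disk_mask <- function(r, pad = 4L) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad + 1L
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`))
  d <= r
}

test_that("a single bright disk is detected at its center and radius", {
  set.seed(1)
  img <- matrix(0.15 + rnorm(300 * 300, 0, 0.02), 300, 300)
  d <- sqrt(outer((1:300 - 150)^2, (1:300 - 150)^2, `+`))
  img <- img + 0.5 / (1 + exp((t(d) - 14)))
  det <- detect_cells(img, c(10, 18))
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$x - 150), 2.5)
  expect_lt(abs(det$y - 150), 2.5)
  expect_lt(abs(det$radius - 14), 2.5)
})

test_that("a blank frame yields no detections", {
  expect_identical(nrow(detect_cells(matrix(0.2, 120, 120), c(2, 6))), 0L)
  set.seed(2)
  noise <- matrix(0.2 + rnorm(120 * 120, 0, 0.02), 120, 120)
  expect_identical(nrow(detect_cells(noise, c(2, 6))), 0L)
})

test_that("two small disks 30 px apart are both found", {
  set.seed(3)
  img <- matrix(0.15 + rnorm(150 * 150, 0, 0.02), 150, 150)
  for (cx in c(60, 90)) {
    d <- sqrt(outer((1:150 - 75)^2, (1:150 - cx)^2, `+`))
    img <- img + 0.65 / (1 + exp(d - 4))
  }
  det <- detect_cells(img, c(2, 6))
  expect_identical(nrow(det), 2L)
  expect_setequal(round(det$x / 10) * 10, c(60, 90))
})

test_that("segmentation of a disk recovers its area", {
  set.seed(4)
  img <- matrix(0.15 + rnorm(120 * 120, 0, 0.02), 120, 120)
  d <- sqrt(outer((1:120 - 60)^2, (1:120 - 60)^2, `+`))
  img <- img + 0.5 / (1 + exp(d - 14))
  msk <- segment_mcc(img, list(x = 60, y = 60, radius = 14))
  expect_false(attr(msk, "collapsed"))
  expect_lt(abs(sum(msk) / (pi * 14^2) - 1), 0.1)
})

test_that("segmentation on a blank background flags a collapse", {
  set.seed(5)
  img <- matrix(0.2 + rnorm(60 * 60, 0, 0.01), 60, 60)
  msk <- segment_mcc(img, list(x = 30, y = 30, radius = 10))
  expect_true(attr(msk, "collapsed"))
})

test_that("an ellipse mask yields the analytic eccentricity", {
  a <- 20; b <- 10
  n <- 61L
  yy <- outer(seq_len(n) - 31, rep(1, n))
  xx <- t(yy)
  mask <- (xx / a)^2 + (yy / b)^2 <= 1
  sd_ <- shape_descriptors(mask)
  expect_lt(abs(sd_$eccentricity - sqrt(1 - b^2 / a^2)), 0.1)
})

test_that("descriptor formulas have their closed-form limits", {
  # ideal circle: circularity exactly 1, equivalent diameter inverts area
  r <- 7.3
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  expect_equal(equivalent_diameter(100 * pi), 20)
  # rasterized disk: eccentricity near 0, circularity within discretization
  sd_ <- shape_descriptors(disk_mask(20L))
  expect_lt(sd_$eccentricity, 0.05)
  expect_lt(abs(sd_$circularity - 1), 0.1)
})

test_that("circularity stays below 1 + discretization tolerance", {
  set.seed(6)
  shapes <- list(disk_mask(5L), disk_mask(12L),
                 matrix(TRUE, 10, 30) |> rbind(matrix(FALSE, 5, 30)))
  for (m in shapes) {
    sd_ <- shape_descriptors(m)
    expect_lte(sd_$circularity, 1.1)
    expect_true(sd_$eccentricity >= 0 && sd_$eccentricity <= 1)
  }
  expect_error(shape_descriptors(matrix(FALSE, 5, 5)), "empty")
})

test_that("motility descriptors match their definitions", {
  # 3-4-5 steps
  mot <- motility_descriptors(c(0, 3, 6), c(0, 4, 8))
  expect_equal(mot$velocity[2:3], c(5, 5))
  # straight equal steps: directionality 1 at every frame
  mot2 <- motility_descriptors(seq(0, 45, by = 5), rep(0, 10))
  expect_true(all(mot2$directionality[-1] == 1))
  expect_equal(mot2$net_displacement[10], 45)
  # closed loop: net displacement and directionality return to 0
  th <- seq(0, 2 * pi, length.out = 9)
  mot3 <- motility_descriptors(cos(th), sin(th))
  expect_equal(mot3$net_displacement[9], 0, tolerance = 1e-9)
  expect_equal(mot3$directionality[9], 0, tolerance = 1e-9)
  # shape change is the absolute diameter difference
  mot4 <- motility_descriptors(c(0, 1), c(0, 0), diameters = c(10, 12.5))
  expect_equal(mot4$shape_change[2], 2.5)
})

test_that("interaction radii and descriptors follow the definitions", {
  rad <- interaction_radii(4, 14)
  expect_identical(rad$r1, 20)
  expect_identical(rad$r2, 36)
  imm <- data.frame(id = 1:3, frame = 1L, x = c(10, 25, 50), y = 0)
  res <- interaction_descriptors(0, 0, imm, frame = 1L, r1 = 20, r2 = 36)
  expect_identical(res$n_interactions_r1, 1L)
  expect_identical(res$n_interactions_r2, 2L)
  expect_equal(res$min_distance_r2, 10)
  expect_true(is.na(res$mean_immune_velocity_r2))  # no previous frame
  none <- interaction_descriptors(200, 200, imm, frame = 1L)
  expect_identical(none$n_interactions_r2, 0L)
  expect_true(is.na(none$min_distance_r2))
  expect_error(interaction_descriptors(0, 0, imm, 1L, r1 = 40, r2 = 36),
               "r1")
})

test_that("state flags are monotone step functions", {
  st <- state_flags(1:200, apoptosis_frame = 100)
  expect_identical(as.character(st$apoptosis[99]), "No")
  expect_identical(as.character(st$apoptosis[100]), "Yes")
  expect_true(all(st$apoptosis[100:200] == "Yes"))
  st2 <- state_flags(1:50)
  expect_true(all(st2$apoptosis == "No") && all(st2$division == "No"))
  st3 <- state_flags(1:50, division_frames = 1)
  expect_true(all(st3$division == "Yes"))
  expect_error(state_flags(10:20, apoptosis_frame = 5), "outside")
})

test_that("detection and tracking close the loop with the video truth", {
  vid <- render_synthetic_video(n_frames = 15, n_immune = 4, seed = 17,
                                noise_sd = 0.015)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (f in c(1, 8, 15)) {
    tru <- vid$truth[vid$truth$frame == f & vid$truth$population == "immune", ]
    det <- detect_cells(vid$stack[[f]], c(2, 6))
    det <- det[vapply(seq_len(nrow(det)), function(j) {
      ca <- vid$truth[vid$truth$frame == f & vid$truth$population == "cancer", ]
      all(sqrt((ca$x - det$x[j])^2 + (ca$y - det$y[j])^2) > ca$radius)
    }, TRUE), , drop = FALSE]
    used <- rep(FALSE, nrow(det))
    for (k in seq_len(nrow(tru))) {
      dd <- sqrt((det$x - tru$x[k])^2 + (det$y - tru$y[k])^2)
      hit <- which(!used & dd <= 4)
      if (length(hit)) { tp <- tp + 1L; used[hit[1]] <- TRUE }
      else fn <- fn + 1L
    }
    fp <- fp + sum(!used)
  }
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gt(f1, 0.95)
})

test_that("the full feature table is extracted deterministically", {
  vid <- render_synthetic_video(n_frames = 12, n_immune = 3, seed = 18,
                                noise_sd = 0.015)
  ft1 <- extract_feature_table(vid$stack)
  ft2 <- extract_feature_table(vid$stack)
  expect_identical(ft1, ft2)
  need <- c("area", "perimeter", "circularity", "eccentricity",
            "equivalent_diameter", "shape_change", "velocity",
            "net_displacement", "directionality", "apoptosis", "division",
            "n_interactions_r2", "n_interactions_r1", "min_distance_r2",
            "mean_immune_velocity_r2", "mean_immune_velocity_r1")
  expect_true(all(need %in% names(ft1)))
  expect_true(all(ft1$n_interactions_r1 <= ft1$n_interactions_r2))
  expect_true(all(ft1$directionality <= 1 + 1e-9, na.rm = TRUE))
  # MCC stays close to the ground-truth center cell
  tru <- vid$truth[vid$truth$id == 1, ]
  m <- merge(ft1, tru, by = "frame")
  err <- mean(sqrt((m$x.x - m$x.y)^2 + (m$y.x - m$y.y)^2))
  expect_lt(err, 3)
})
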