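# Synthetic benchmark generators: analytic covariance agreement,
# stationarity, determinism, the two-variable counterexample models and
# the video generator's self-consistency.

test_that("linear generator covariances match the Yule-Walker solution", {
  sim <- generate_linear(n_nodes = 15, T = 30000, seed = 42)
  cm <- chronet:::.coef_matrices(sim$network)
  expect_lt(chronet:::.spectral_radius(cm$A1, cm$A2), 1)
  cov_fn <- yule_walker_cov(sim$network)
  X <- as.matrix(sim$dataset$data)
  Tn <- nrow(X)
  for (l in 0:2) {
    emp <- crossprod(X[(1 + l):Tn, , drop = FALSE],
                     X[1:(Tn - l), , drop = FALSE]) / (Tn - l)
    ana <- cov_fn(l)
    expect_lt(norm(emp - ana, "F") / norm(ana, "F"), 0.05)
  }
})

test_that("generators are deterministic and density 0 gives pure noise", {
  s1 <- generate_linear(T = 300, seed = 3)
  s2 <- generate_linear(T = 300, seed = 3)
  expect_identical(s1$dataset$data, s2$dataset$data)
  expect_identical(s1$network$edges, s2$network$edges)
  s0 <- generate_linear(T = 300, seed = 4, density = 0)
  expect_identical(nrow(s0$network$edges), 0L)
  n1 <- generate_nonlinear(T = 300, seed = 5)
  n2 <- generate_nonlinear(T = 300, seed = 5)
  expect_identical(n1$dataset$data, n2$dataset$data)
})

test_that("nonlinear series keep a bounded running variance", {
  sim <- generate_nonlinear(T = 6000, seed = 6)
  X <- as.matrix(sim$dataset$data)
  h <- nrow(X) %/% 2
  v1 <- apply(X[1:h, ], 2, stats::var)
  v2 <- apply(X[(h + 1):nrow(X), ], 2, stats::var)
  expect_true(all(v2 / v1 > 0.5 & v2 / v1 < 2))
  forms <- unique(sim$network$edges$form)
  expect_true(all(forms %in% c("linear", "quadratic", "cosine",
                               "piecewise", "multiplicative")))
})

test_that("the counterexample models have the stated structure", {
  a <- generate_te_models("a", T = 500, seed = 7)
  expect_false(any(a$network$edges$source == "Y" &
                     a$network$edges$target == "X"))
  b <- generate_te_models("b", T = 500, seed = 7)
  fb <- b$network$edges[b$network$edges$source == "Y" &
                          b$network$edges$target == "X", ]
  expect_identical(fb$lag, 2L)
  expect_identical(generate_te_models("a", T = 200, seed = 8)$dataset$data,
                   generate_te_models("a", T = 200, seed = 8)$dataset$data)
})

test_that("transfer entropy signs separate the two counterexample models", {
  neg <- 0L
  for (s in 1:5) {
    sim <- generate_te_models("a", T = 10000, seed = s)
    if (transfer_entropy(sim$dataset, "Y", "X", 2)$penalized <= 0)
      neg <- neg + 1L
    expect_gt(transfer_entropy(sim$dataset, "X", "Y", 2)$penalized, 0)
  }
  expect_gte(neg, 4L)
  simb <- generate_te_models("b", T = 10000, seed = 1)
  expect_gt(transfer_entropy(simb$dataset, "Y", "X", 2)$penalized, 0)
})

test_that("nonstationary drift leaves the ground truth unchanged", {
  sim <- generate_linear(T = 1000, seed = 9)
  before <- sim$network$edges
  ds2 <- make_nonstationary(sim$dataset, c("X1", "X2"),
                            list(type = "walk", scale = 0.2), seed = 10)
  expect_identical(sim$network$edges, before)
  expect_false(identical(ds2$data$X1, sim$dataset$data$X1))
  expect_identical(ds2$data$X3, sim$dataset$data$X3)
})

test_that("video ground truth is serializable and self-consistent", {
  vid <- render_synthetic_video(n_frames = 8, n_immune = 3, seed = 20,
                                noise_sd = 0.015)
  expect_identical(length(vid$stack), 8L)
  expect_true(all(c("id", "population", "frame", "x", "y", "radius") %in%
                    names(vid$truth)))
  # the rendered MCC is detectable at its ground-truth position
  tru <- vid$truth[vid$truth$frame == 4 & vid$truth$population == "cancer", ]
  det <- detect_cells(vid$stack[[4]], c(10, 18))
  expect_identical(nrow(det), 1L)
  expect_lt(sqrt((det$x - tru$x)^2 + (det$y - tru$y)^2), 3)
})

test_that("video events change the rendering as specified", {
  ev <- data.frame(track_id = 1, event = "apoptosis", frame = 4)
  vid <- render_synthetic_video(n_frames = 10, n_immune = 0, seed = 21,
                                events = ev)
  expect_lt(max(vid$truth$frame[vid$truth$id == 1]), 10)  # cell vanishes
  vd <- render_synthetic_video(n_frames = 10, n_immune = 0, seed = 22,
                               events = data.frame(track_id = 1,
                                                   event = "division",
                                                   frame = 5))
  expect_identical(length(unique(vd$truth$id)), 2L)
})

test_that("TIFF stack round trip preserves the frames", {
  vid <- render_synthetic_video(n_frames = 3, image_size = c(80, 80),
                                n_immune = 2, seed = 23)
  p <- withr::local_tempfile(fileext = ".tif")
  write_tiff_stack(vid$stack, p)
  back <- read_tiff_stack(p)
  expect_identical(length(back), 3L)
  expect_lt(max(abs(back[[1]] - vid$stack[[1]])), 1 / 255)
})
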