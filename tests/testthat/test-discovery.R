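# The discovery engine: automatic lag selection, skeleton learning with
# iterative contributors, orientation, and end-to-end properties on small
# generated systems.

test_that("relaxation-time rule recovers tau for an AR(1) process", {
  set.seed(5)
  n <- 4000
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), n))
  ds <- time_series_dataset(data.frame(X = x))
  est <- estimate_tau(ds)
  # ACF = 0.8^l crosses 1/e at l = 5; tau = 2 * relaxation
  expect_true(est$tau >= 8 && est$tau <= 11)
})

test_that("white noise yields the minimal lag window", {
  set.seed(6)
  ds <- time_series_dataset(data.frame(X = rnorm(500), Y = rnorm(500)))
  est <- estimate_tau(ds)
  expect_identical(est$tau, 2L)
  expect_identical(est$delta_tau, 1L)
})

test_that("slowly decaying variables inflate the relaxation estimate", {
  set.seed(7)
  ds <- time_series_dataset(data.frame(
    W = cumsum(rnorm(600)), X = rnorm(600)))
  est <- estimate_tau(ds)
  expect_gt(est$relaxation["W"], 10)
  expect_identical(unname(est$relaxation["X"]), 1)
})

test_that("independent white noise produces an empty skeleton", {
  set.seed(8)
  ds <- time_series_dataset(data.frame(X = rnorm(2000), Y = rnorm(2000),
                                       Z = rnorm(2000)))
  lay <- build_layout(ds, 2, 1)
  sk <- learn_skeleton(lag_samples(ds, lay), lay)
  expect_identical(nrow(sk$graph$edges), 0L)
  expect_true(all(sk$decisions$status == "removed"))
})

test_that("a lagged fork is cut with the mediating parent as separator", {
  # X_t <- X_{t-1}; Y_t <- X_{t-1}: the pair (Y,0)-(X,0) is spurious and
  # separated by (X,1)
  edges <- data.frame(source = "X", target = "Y", lag = 1L, weight = 0.7)
  df <- simulate_scm(edges, c("X", "Y"), T = 5000, seed = 9,
                     self_coefs = c(X = 0.6, Y = 0))
  ds <- time_series_dataset(df)
  lay <- build_layout(ds, 2, 1)
  sk <- learn_skeleton(lag_samples(ds, lay), lay)
  d <- sk$decisions
  row <- d[(d$x == "X@-0" & d$y == "Y@-0") |
             (d$x == "Y@-0" & d$y == "X@-0"), ]
  expect_identical(row$status, "removed")
  expect_match(row$separating_set, "X@-1")
})

test_that("removed-edge separating sets d-separate in the generating DAG", {
  # 4-variable linear SCM with lags <= 2 and strong coefficients; no
  # autodependences, so every d-connection in the unfolded DAG is a short,
  # detectable path and the oracle check is exact
  edges <- data.frame(
    source = c("A", "A", "B", "C"), target = c("B", "C", "D", "D"),
    lag = c(1L, 2L, 1L, 1L), weight = c(0.7, 0.6, 0.7, -0.6))
  vars <- c("A", "B", "C", "D")
  df <- simulate_scm(edges, vars, T = 8000, seed = 10)
  ds <- time_series_dataset(df)
  lay <- build_layout(ds, 2, 1)
  sk <- learn_skeleton(lag_samples(ds, lay), lay)
  truth <- chronet:::.new_benchmark_network(4, edges)
  dag <- unfold_truth(truth, depth = 14L)
  rem <- sk$decisions[sk$decisions$status == "removed", ]
  checked <- 0L
  for (r in seq_len(nrow(rem))) {
    Z <- if (nzchar(rem$separating_set[r]))
      strsplit(rem$separating_set[r], ",")[[1]] else character()
    if (d_separated(dag, rem$x[r], rem$y[r], Z)) checked <- checked + 1L
  }
  expect_identical(checked, nrow(rem))
})

test_that("lagged edges are pre-oriented toward the future", {
  sim <- generate_te_models("a", T = 4000, seed = 11)
  fit <- chronet(sim$dataset, tau = 2, delta_tau = 1)
  e <- fit$graph$edges
  lagged <- e[e$a_lag > e$b_lag, ]
  expect_true(all(lagged$mark_b == "arrow"))
  # no arrowhead claims the future causes the past except the latent rule:
  # a past-side arrow may only coexist with a future-side arrow
  bad <- lagged$mark_a == "arrow" & lagged$mark_b != "arrow"
  expect_false(any(bad))
})

test_that("a contemporaneous collider is recovered as in static analysis", {
  edges <- data.frame(source = c("X", "Y"), target = c("Z", "Z"),
                      lag = c(0L, 0L), weight = c(0.7, 0.7))
  df <- simulate_scm(edges, c("X", "Y", "Z"), T = 6000, seed = 12)
  ds <- time_series_dataset(df)
  fit <- chronet(ds, tau = 1, delta_tau = 1)
  sg <- fit$summary
  zx <- sg[sg$lag_ts == 0 & sg$target == "Z" & sg$source == "X", ]
  zy <- sg[sg$lag_ts == 0 & sg$target == "Z" & sg$source == "Y", ]
  expect_identical(zx$orientation, "directed")
  expect_identical(zy$orientation, "directed")
  # matches the sign of the three-point information
  tp <- three_point_information(df$X, df$Y, df$Z)
  expect_lt(tp$collider_score, 0)
})

test_that("a hidden common cause yields a bidirected (latent) lagged edge", {
  # L drives X_t and Y_{t+1}; L unobserved; X, Y with their own (distinct)
  # dynamics, so no observed variable can proxy the latent history
  set.seed(13)
  n <- 10000
  L <- rnorm(n + 1)
  x <- numeric(n + 1); y <- numeric(n + 1)
  for (t in 2:(n + 1)) {
    x[t] <- 0.6 * x[t - 1] + L[t] + 0.5 * rnorm(1)
    y[t] <- 0.4 * y[t - 1] + L[t - 1] + 0.5 * rnorm(1)
  }
  ds <- time_series_dataset(data.frame(X = x[-1], Y = y[-1]))
  fit <- chronet(ds, tau = 2, delta_tau = 1)
  sg <- fit$summary
  lat <- sg[sg$orientation == "bidirected" & sg$lag_ts == 1 &
              ((sg$source == "X" & sg$target == "Y") |
                 (sg$source == "Y" & sg$target == "X")), ]
  expect_identical(nrow(lat), 1L)
})

test_that("contextual conditions never receive arrowheads", {
  set.seed(14)
  n <- 3000
  cond <- rep(c(0, 1), each = n / 2)
  x <- 0.8 * cond + rnorm(n)
  df <- data.frame(X = x, cond = cond,
                   id = rep(c("a", "b"), each = n / 2))
  ds <- time_series_dataset(df, trajectory = "id", contextual = "cond")
  fit <- chronet(ds, tau = 1, delta_tau = 1)
  sg <- fit$summary
  ce <- sg[sg$source == "cond" | sg$target == "cond", ]
  expect_true(all(ce$source == "cond"))
  expect_true(all(ce$orientation == "directed"))
})

test_that("discovery is deterministic for a fixed dataset", {
  sim <- generate_te_models("b", T = 3000, seed = 15)
  f1 <- chronet(sim$dataset, tau = 2, delta_tau = 1)
  f2 <- chronet(sim$dataset, tau = 2, delta_tau = 1)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$graph$edges, f2$graph$edges)
})

test_that("the fitted object prints and summarizes", {
  sim <- generate_te_models("a", T = 2000, seed = 16)
  fit <- chronet(sim$dataset, tau = 2, delta_tau = 1)
  expect_output(print(fit), "Temporal causal network")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.chronet")
  expect_output(print(sm), "candidate pairs")
  pf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(pf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(pf))
})
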