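# Scoring of learned summary graphs, benchmark harness bookkeeping and
# ground-truth I/O.

toy_truth <- function() {
  chronet:::.new_benchmark_network(3, data.frame(
    source = c("X1", "X2", "X1", "X3"),
    target = c("X2", "X3", "X1", "X3"),
    lag = c(1L, 2L, 1L, 1L),
    weight = c(0.5, -0.4, 0.6, 0.3), form = "linear",
    stringsAsFactors = FALSE))
}

toy_pred <- function(edges) {
  structure(edges, class = c("summary_graph", "data.frame"))
}

test_that("a perfect prediction scores 1 in both modes", {
  tr <- toy_truth()
  sg <- toy_pred(data.frame(
    source = c("X1", "X2", "X1", "X3"), target = c("X2", "X3", "X1", "X3"),
    lag_ts = c(1L, 2L, 1L, 1L), orientation = "directed", sign = "+",
    confidence = 1, stringsAsFactors = FALSE))
  for (mode in c("skeleton", "oriented")) {
    sc <- score_graph(sg, tr, mode)
    expect_equal(sc$precision, 1)
    expect_equal(sc$recall, 1)
    expect_equal(sc$fscore, 1)
  }
})

test_that("an empty prediction has zero recall and zero precision", {
  sc <- score_graph(toy_pred(data.frame(
    source = character(), target = character(), lag_ts = integer(),
    orientation = character(), sign = character(),
    confidence = numeric())), toy_truth(), "skeleton")
  expect_equal(sc$recall, 0)
  expect_equal(sc$precision, 0)
  expect_equal(sc$fscore, 0)
})

test_that("3 of 4 correct edges give P = R = F = 0.75", {
  tr <- toy_truth()
  sg <- toy_pred(data.frame(
    source = c("X1", "X2", "X1", "X2"), target = c("X2", "X3", "X1", "X1"),
    lag_ts = c(1L, 2L, 1L, 2L), orientation = "directed", sign = "+",
    confidence = 1, stringsAsFactors = FALSE))
  sc <- score_graph(sg, tr, "skeleton")
  expect_equal(sc$precision, 0.75)
  expect_equal(sc$recall, 0.75)
  expect_equal(sc$fscore, 0.75)
})

test_that("oriented mode penalizes a bidirected edge as FP plus FN", {
  tr <- toy_truth()
  sg <- toy_pred(data.frame(
    source = c("X1", "X2", "X1", "X3"), target = c("X2", "X3", "X1", "X3"),
    lag_ts = c(1L, 2L, 1L, 1L),
    orientation = c("bidirected", "directed", "directed", "directed"),
    sign = "+", confidence = 1, stringsAsFactors = FALSE))
  sk <- score_graph(sg, tr, "skeleton")
  ori <- score_graph(sg, tr, "oriented")
  expect_equal(sk$fscore, 1)
  expect_identical(unname(ori$counts["TP"]), 3L)
  expect_identical(unname(ori$counts["FP"]), 1L)
  expect_identical(unname(ori$counts["FN"]), 1L)
})

test_that("a lagged edge only matches with the correct direction-in-time", {
  tr <- toy_truth()
  # X2 -> X1 at lag 1 is a different temporal edge than X1 -> X2 at lag 1
  sg <- toy_pred(data.frame(
    source = "X2", target = "X1", lag_ts = 1L, orientation = "directed",
    sign = "+", confidence = 1, stringsAsFactors = FALSE))
  sc <- score_graph(sg, tr, "skeleton")
  expect_identical(unname(sc$counts["TP"]), 0L)
})

test_that("swapping prediction and truth swaps precision and recall", {
  tr <- toy_truth()
  sg <- toy_pred(data.frame(
    source = c("X1", "X2", "X2"), target = c("X2", "X3", "X1"),
    lag_ts = c(1L, 2L, 2L), orientation = "directed", sign = "+",
    confidence = 1, stringsAsFactors = FALSE))
  sc1 <- score_graph(sg, tr, "skeleton")
  tr2 <- chronet:::.new_benchmark_network(3, data.frame(
    source = sg$source, target = sg$target, lag = sg$lag_ts,
    weight = 1, form = "linear", stringsAsFactors = FALSE))
  sg2 <- toy_pred(data.frame(
    source = tr$edges$source, target = tr$edges$target,
    lag_ts = tr$edges$lag, orientation = "directed", sign = "+",
    confidence = 1, stringsAsFactors = FALSE))
  sc2 <- score_graph(sg2, tr2, "skeleton")
  expect_equal(sc1$precision, sc2$recall)
  expect_equal(sc1$recall, sc2$precision)
})

test_that("unknown variables in the prediction raise an error", {
  sg <- toy_pred(data.frame(
    source = "Z9", target = "X1", lag_ts = 1L, orientation = "directed",
    sign = "+", confidence = 1, stringsAsFactors = FALSE))
  expect_error(score_graph(sg, toy_truth()), "universe")
})

test_that("ground-truth TSV round trip is lossless", {
  tr <- toy_truth()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth_tsv(tr, p)
  back <- read_ground_truth_tsv(p)
  expect_equal(back$edges, tr$edges)
  expect_identical(back$n_nodes, 3L)
})

test_that("time-series CSV round trip preserves data and conditions", {
  df <- data.frame(a = rnorm(20), b = rnorm(20),
                   cond = rep(c("ctl", "trt"), each = 10),
                   id = rep(1:2, each = 10))
  ds <- time_series_dataset(df, trajectory = "id", contextual = "cond")
  p <- withr::local_tempfile(fileext = ".csv")
  write_time_series_csv(ds, p, trajectory = "id")
  back <- read_time_series_csv(p, trajectory = "id", contextual = "cond")
  expect_equal(back$data$a, ds$data$a)
  expect_identical(back$specs$cond$kind, "contextual")
  expect_error(read_time_series_csv(p, trajectory = "nope"), "missing")
})

test_that("run_benchmark aggregates replicate scores", {
  gen <- function(T, seed) generate_te_models("a", T = T, seed = seed)
  res <- run_benchmark(gen, n_replicates = 2, sample_sizes = 3000,
                       seed = 1, tau = 2, delta_tau = 1)
  expect_s3_class(res, "benchmark_result")
  expect_identical(nrow(res), 4L)  # 2 replicates x 2 modes
  agg <- summary(res)
  expect_true(all(agg$fscore >= 0 & agg$fscore <= 1))
})
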