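# Penalized mutual-information estimator: exact discrete behavior,
# Gaussian oracle accuracy, calibration on independent data, and the
# algebraic invariants tying MI, CMI and three-point information together.

test_that("discrete MI matches the plug-in formula and is symmetric", {
  set.seed(11)
  x <- sample(0:1, 400, replace = TRUE, prob = c(0.3, 0.7))
  y <- ifelse(stats::runif(400) < 0.8, x, 1 - x)
  est <- mutual_information(x, y)
  # direct plug-in on the 2x2 joint table
  tb <- table(x, y) / length(x)
  px <- rowSums(tb); py <- colSums(tb)
  plug <- 0
  for (i in 1:2) for (j in 1:2)
    if (tb[i, j] > 0) plug <- plug + tb[i, j] * log(tb[i, j] / (px[i] * py[j]))
  # raw_info is Miller-Madow debiased; undo the correction for the check
  expect_equal(est$raw_info + 1 / (2 * length(x)),
               as.numeric(plug), tolerance = 1e-9)
  est_rev <- mutual_information(y, x)
  expect_identical(est$raw_info, est_rev$raw_info)
  expect_identical(est$penalized, est_rev$penalized)
})

test_that("self-information of a uniform 4-level variable approaches ln 4", {
  set.seed(7)
  x <- sample(1:4, 10000, replace = TRUE)
  est <- mutual_information(x, x)
  expect_equal(est$raw_info, log(4), tolerance = 0.01)
  expect_gt(est$penalized, 0)
})

test_that("continuous MI tracks the Gaussian closed form within 15%", {
  set.seed(21)
  n <- 10000
  for (rho in c(0.2, 0.5, 0.8)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    tru <- -0.5 * log(1 - rho^2)
    est <- mutual_information(x, y)
    expect_lt(abs(est$raw_info / tru - 1), 0.15)
  }
})

test_that("independent data give a negative penalized statistic", {
  set.seed(31)
  for (n in c(500, 2000)) {
    neg <- replicate(100, mutual_information(rnorm(n), rnorm(n))$penalized <= 0)
    expect_gte(mean(neg), 0.95)
  }
})

test_that("deterministic dependence is detected at n >= 100", {
  set.seed(41)
  x <- rnorm(100)
  expect_gt(mutual_information(x, x)$penalized, 0)
})

test_that("constant vectors give zero information, not an error", {
  est <- mutual_information(rep(1, 50), rnorm(50))
  expect_identical(est$raw_info, 0)
  expect_lte(est$penalized, 0)
})

test_that("input validation rejects length mismatch and missing values", {
  expect_error(mutual_information(rnorm(10), rnorm(11)), "length")
  expect_error(mutual_information(c(1, NA, 3), c(1, 2, 3)), "missing")
})

test_that("empty conditioning set reproduces mutual information exactly", {
  set.seed(51)
  x <- rnorm(500); y <- 0.5 * x + rnorm(500)
  a <- mutual_information(x, y)
  b <- conditional_mutual_information(x, y, Z = list())
  expect_identical(a$raw_info, b$raw_info)
  expect_identical(a$penalized, b$penalized)
})

test_that("CMI separates a Markov chain but not a direct dependence", {
  set.seed(61)
  n <- 5000
  x <- rnorm(n); z <- 0.8 * x + 0.6 * rnorm(n); y <- 0.8 * z + 0.6 * rnorm(n)
  expect_gt(mutual_information(x, y)$penalized, 0)
  expect_lte(conditional_mutual_information(x, y, list(z))$penalized, 0)
})

test_that("conditioning on a collider child activates a dependence", {
  set.seed(71)
  n <- 5000
  x <- rnorm(n); y <- rnorm(n); z <- 0.7 * x + 0.7 * y + rnorm(n)
  expect_lte(mutual_information(x, y)$penalized, 0)
  expect_gt(conditional_mutual_information(x, y, list(z))$penalized, 0)
})

test_that("three-point information is the exact difference of the CMIs", {
  set.seed(81)
  n <- 2000
  x <- rnorm(n); z <- 0.6 * x + rnorm(n); y <- 0.6 * z + rnorm(n)
  i1 <- conditional_mutual_information(x, y, list())
  i2 <- conditional_mutual_information(x, y, list(z))
  tp <- three_point_information(x, y, z)
  expect_equal(tp$raw_info, i1$raw_info - i2$raw_info, tolerance = 1e-9)
})

test_that("three-point information signs discriminate chain from collider", {
  set.seed(91)
  n <- 5000
  x <- rnorm(n); z <- 0.7 * x + rnorm(n); y <- 0.7 * z + rnorm(n)
  expect_gt(three_point_information(x, y, z)$raw_info, 0)
  x2 <- rnorm(n); y2 <- rnorm(n); z2 <- 0.7 * x2 + 0.7 * y2 + rnorm(n)
  tp <- three_point_information(x2, y2, z2)
  expect_lt(tp$raw_info, 0)
  expect_lt(tp$collider_score, 0)
  # an irrelevant third variable is not a significant contributor
  set.seed(95)
  a <- rnorm(n); b <- rnorm(n)
  tp0 <- three_point_information(a, b, rnorm(n))
  expect_lte(tp0$penalized, 0)
})

test_that("conditioning on an observed mediator removes transfer entropy", {
  # X -> V -> Y (all lag 1): the raw transfer X -> Y is indirect and
  # disappears when the mediator's past is conditioned on
  set.seed(99)
  n <- 8000
  x <- numeric(n); v <- numeric(n); y <- numeric(n)
  for (t in 2:n) {
    x[t] <- 0.5 * x[t - 1] + rnorm(1)
    v[t] <- 0.7 * x[t - 1] + rnorm(1)
    y[t] <- 0.7 * v[t - 1] + 0.3 * y[t - 1] + rnorm(1)
  }
  ds <- time_series_dataset(data.frame(X = x, V = v, Y = y))
  expect_gt(transfer_entropy(ds, "X", "Y", max_lag = 2)$penalized, 0)
  expect_lte(transfer_entropy(ds, "X", "Y", max_lag = 2,
                              extra_conditioning = "V")$penalized, 0)
})

test_that("complexity grows with level counts and conditioning size", {
  set.seed(101)
  n <- 5000
  # categorical route: the penalty is an explicit function of the table
  k2 <- mutual_information(sample(1:2, n, TRUE),
                           sample(1:2, n, TRUE))$complexity
  k6 <- mutual_information(sample(1:6, n, TRUE),
                           sample(1:6, n, TRUE))$complexity
  expect_gt(k6, k2)
  x <- sample(1:3, n, TRUE); y <- sample(1:3, n, TRUE)
  zs <- replicate(2, sample(1:3, n, TRUE), simplify = FALSE)
  ks <- vapply(0:2, function(m)
    conditional_mutual_information(x, y, zs[seq_len(m)])$complexity, 0)
  expect_true(all(diff(ks) > 0))
})

test_that("InfoEstimate invariants hold across random inputs", {
  set.seed(111)
  for (r in 1:10) {
    n <- sample(c(200, 1000), 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    est <- conditional_mutual_information(x, y, list(rnorm(n)))
    expect_gte(est$raw_info, 0)
    expect_lte(est$penalized, est$n_samples * est$raw_info + 1e-9)
    expect_gte(est$complexity, 0)
  }
})
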