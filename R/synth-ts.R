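# Ground-truthed synthetic time-series generators: 15-node stationary
# autoregressive structural causal models with linear or nonlinear parent
# combinations (lags up to 2), nonstationary variants, and the two-variable
# counterexample models relating transfer entropy to temporal v-structures.

.new_benchmark_network <- function(n_nodes, edges, noise = "gaussian") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  structure(list(n_nodes = n_nodes, edges = edges, noise = noise),
            class = "benchmark_network")
}

#' @export
print.benchmark_network <- function(x, ...) {
  cat("Benchmark network:", x$n_nodes, "nodes,", nrow(x$edges),
      "ground-truth edges\n")
  invisible(x)
}

# companion-matrix spectral radius of a VAR(2) coefficient structure
.spectral_radius <- function(A1, A2) {
  p <- nrow(A1)
  comp <- rbind(cbind(A1, A2), cbind(diag(p), matrix(0, p, p)))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# draw a sparse random lagged structure: every node keeps a linear
# self-dependence at lag 1; cross edges (mean degree ~ 2*density) get lags
# in {1, 2} and weights of magnitude [0.2, 0.8] with random sign
.draw_structure <- function(n_nodes, density) {
  edges <- data.frame(source = paste0("X", seq_len(n_nodes)),
                      target = paste0("X", seq_len(n_nodes)),
                      lag = 1L,
                      weight = stats::runif(n_nodes, 0.3, 0.7),
                      form = "linear", stringsAsFactors = FALSE)
  n_cross <- round(density * n_nodes)
  if (n_cross > 0) {
    pairs <- which(outer(seq_len(n_nodes), seq_len(n_nodes), `!=`))
    pick <- sample(pairs, n_cross)
    src <- (pick - 1L) %% n_nodes + 1L
    tgt <- (pick - 1L) %/% n_nodes + 1L
    cross <- data.frame(
      source = paste0("X", src), target = paste0("X", tgt),
      lag = sample(1:2, n_cross, replace = TRUE),
      weight = sample(c(-1, 1), n_cross, replace = TRUE) *
        stats::runif(n_cross, 0.2, 0.8),
      form = "linear", stringsAsFactors = FALSE)
    edges <- rbind(edges, cross)
  }
  edges
}

.coef_matrices <- function(net) {
  p <- net$n_nodes
  A1 <- matrix(0, p, p); A2 <- matrix(0, p, p)
  si <- as.integer(sub("X", "", net$edges$source))
  ti <- as.integer(sub("X", "", net$edges$target))
  for (k in seq_len(nrow(net$edges))) {
    if (net$edges$lag[k] == 1L) A1[ti[k], si[k]] <- net$edges$weight[k]
    else A2[ti[k], si[k]] <- net$edges$weight[k]
  }
  list(A1 = A1, A2 = A2)
}

#' Generate a linear 15-node benchmark time series
#'
#' Draws a stationary linear autoregressive structural causal model with
#' lags up to 2 (self-dependence at lag 1 for every node plus sparse cross
#' edges, weights of magnitude 0.2-0.8, unit Gaussian innovations), checks
#' stability (companion spectral radius < 1, redrawing if needed), and
#' simulates it.
#'
#' @param n_nodes Number of variables.
#' @param T Number of emitted time steps (>= 100).
#' @param seed Integer seed (reproducible draw); `NULL` leaves the RNG state
#'   alone.
#' @param density Expected cross edges per node (default 1, i.e. mean cross
#'   degree about 2); 0 gives independent noise and an empty ground truth.
#' @param burn_in Discarded initial steps.
#' @return A list with `network` (a `"benchmark_network"` with the
#'   ground-truth edges) and `dataset` (a [time_series_dataset()]).
#' @export
generate_linear <- function(n_nodes = 15L, T = 10000L, seed = NULL,
                            density = 1, burn_in = 200L) {
  if (T < 100L) stop("T must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  if (density == 0) {
    X <- matrix(stats::rnorm(T * n_nodes), T, n_nodes)
    colnames(X) <- paste0("X", seq_len(n_nodes))
    net <- .new_benchmark_network(n_nodes, data.frame(
      source = character(), target = character(), lag = integer(),
      weight = numeric(), form = character(), stringsAsFactors = FALSE))
    return(list(network = net,
                dataset = time_series_dataset(as.data.frame(X))))
  }
  for (attempt in seq_len(100L)) {
    edges <- .draw_structure(n_nodes, density)
    net <- .new_benchmark_network(n_nodes, edges)
    cm <- .coef_matrices(net)
    if (.spectral_radius(cm$A1, cm$A2) < 0.98) break
    if (attempt == 100L) stop("no stable coefficient draw in 100 attempts")
  }
  Ttot <- T + burn_in
  X <- matrix(0, Ttot, n_nodes)
  E <- matrix(stats::rnorm(Ttot * n_nodes), Ttot, n_nodes)
  for (t in 3:Ttot) {
    X[t, ] <- cm$A1 %*% X[t - 1L, ] + cm$A2 %*% X[t - 2L, ] + E[t, ]
  }
  X <- X[(burn_in + 1L):Ttot, , drop = FALSE]
  colnames(X) <- paste0("X", seq_len(n_nodes))
  list(network = net, dataset = time_series_dataset(as.data.frame(X)))
}

# bounded per-edge nonlinearities applied to the squashed parent value
.nonlin_forms <- c("quadratic", "cosine", "piecewise", "multiplicative")

.apply_form <- function(form, u, u2 = NULL) {
  switch(form,
         quadratic = 2 * (tanh(u)^2 - 0.4),
         cosine = 1.6 * cos(1.5 * u),
         piecewise = 1.4 * sign(u) * pmin(abs(u), 1),
         multiplicative = 2.2 * tanh(u) * tanh(u2),
         u)
}

#' Generate a nonlinear 15-node benchmark time series
#'
#' Same sparse lagged structure as [generate_linear()], but each cross-edge
#' contribution passes through a bounded nonlinearity drawn from quadratic,
#' cosine, piecewise-linear (saturating) or multiplicative pairing (the
#' product with another parent).  Self-dependences stay linear, so node
#' variances remain bounded and the process stationary (checked empirically
#' by comparing half-series variances).
#'
#' @inheritParams generate_linear
#' @return As [generate_linear()]; the `form` column of the ground truth
#'   records each edge's nonlinearity.
#' @export
generate_nonlinear <- function(n_nodes = 15L, T = 10000L, seed = NULL,
                               density = 1, burn_in = 200L) {
  if (T < 100L) stop("T must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  if (density == 0) return(generate_linear(n_nodes, T, NULL, 0, burn_in))
  edges <- .draw_structure(n_nodes, density)
  cross <- edges$source != edges$target
  edges$form[cross] <- sample(.nonlin_forms, sum(cross), replace = TRUE)
  # multiplicative pairing needs a partner parent on the same target
  for (k in which(edges$form == "multiplicative")) {
    partners <- setdiff(which(edges$target == edges$target[k] & cross),
                        k)
    if (!length(partners)) edges$form[k] <- "quadratic"
  }
  net <- .new_benchmark_network(n_nodes, edges)
  Ttot <- T + burn_in
  p <- n_nodes
  X <- matrix(0, Ttot, p)
  E <- matrix(stats::rnorm(Ttot * p), Ttot, p)
  ti <- as.integer(sub("X", "", edges$target))
  si <- as.integer(sub("X", "", edges$source))
  partner_of <- vapply(seq_len(nrow(edges)), function(k) {
    if (edges$form[k] != "multiplicative") return(NA_integer_)
    setdiff(which(edges$target == edges$target[k] & cross), k)[1L]
  }, 0L)
  for (t in 3:Ttot) {
    acc <- E[t, ]
    for (k in seq_len(nrow(edges))) {
      xv <- X[t - edges$lag[k], si[k]]
      if (edges$form[k] == "linear") {
        acc[ti[k]] <- acc[ti[k]] + edges$weight[k] * xv
      } else if (edges$form[k] == "multiplicative") {
        kp <- partner_of[k]
        x2 <- X[t - edges$lag[kp], si[kp]]
        acc[ti[k]] <- acc[ti[k]] +
          edges$weight[k] * .apply_form("multiplicative", xv, x2)
      } else {
        acc[ti[k]] <- acc[ti[k]] +
          edges$weight[k] * .apply_form(edges$form[k], xv)
      }
    }
    X[t, ] <- acc
  }
  X <- X[(burn_in + 1L):Ttot, , drop = FALSE]
  colnames(X) <- paste0("X", seq_len(p))
  list(network = net, dataset = time_series_dataset(as.data.frame(X)))
}

#' Inject nonstationarity into selected variables
#'
#' Adds a deterministic trend or a slow random walk to the chosen variables.
#' The generating causal structure (ground truth) is unchanged; the drift
#' makes the marginal dynamics nonstationary, which a time-unfolded learner
#' absorbs as additional lagged self-loops at the drifting variables.
#'
#' @param dataset A [time_series_dataset()].
#' @param variables Character vector of variable names to perturb.
#' @param drift_spec A list with `type` (`"walk"` or `"trend"`) and `scale`
#'   (walk: innovation s.d. per step; trend: total drift over the series, in
#'   units of the variable's s.d.).
#' @param seed Optional integer seed (the walk is random).
#' @return The perturbed dataset.
#' @export
make_nonstationary <- function(dataset, variables,
                               drift_spec = list(type = "walk", scale = 0.15),
                               seed = NULL) {
  stopifnot(inherits(dataset, "ts_dataset"))
  if (!is.null(seed)) set.seed(seed)
  bad <- setdiff(variables, names(dataset$data))
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  idx <- .traj_split(dataset)
  for (v in variables) {
    for (ii in idx) {
      Tn <- length(ii)
      drift <- if (identical(drift_spec$type, "trend")) {
        seq(0, drift_spec$scale * stats::sd(dataset$data[[v]][ii]),
            length.out = Tn)
      } else {
        cumsum(stats::rnorm(Tn, 0, drift_spec$scale))
      }
      dataset$data[[v]][ii] <- dataset$data[[v]][ii] + drift
    }
  }
  dataset
}

#' Two-variable models relating transfer entropy and temporal v-structures
#'
#' Case `"a"`: X is an autonomous AR(1) (coefficient 0.6) and
#' Y_t = 0.5 X_t + 0.5 Y_(t-1) + noise, so the transfer entropy from Y to X
#' vanishes structurally while temporal v-structures Y_(t') -> Y_t <- X_t
#' appear in the time-unfolded graph.  Case `"b"` adds a feedback edge
#' Y_(t-2) -> X_t (weight 0.4): the temporal v-structure at Y_t persists,
#' yet the transfer entropy from Y to X is strictly positive — temporal
#' v-structures do not imply vanishing transfer entropy.
#'
#' @param case `"a"` or `"b"`.
#' @param T Number of time steps.
#' @param seed Integer seed or `NULL`.
#' @return A list with `network` and `dataset` as in [generate_linear()].
#' @export
generate_te_models <- function(case = c("a", "b"), T = 10000L,
                                 seed = NULL) {
  case <- match.arg(case)
  if (!is.null(seed)) set.seed(seed)
  burn <- 100L
  Ttot <- T + burn
  x <- numeric(Ttot); y <- numeric(Ttot)
  ex <- stats::rnorm(Ttot); ey <- stats::rnorm(Ttot)
  for (t in 3:Ttot) {
    x[t] <- 0.6 * x[t - 1L] + (if (case == "b") 0.3 * y[t - 2L] else 0) +
      ex[t]
    y[t] <- 0.5 * x[t] + 0.5 * y[t - 1L] + ey[t]
  }
  sel <- (burn + 1L):Ttot
  edges <- data.frame(
    source = c("X", "X", "Y"), target = c("X", "Y", "Y"),
    lag = c(1L, 0L, 1L), weight = c(0.6, 0.5, 0.5),
    form = "linear", stringsAsFactors = FALSE)
  if (case == "b")
    edges <- rbind(edges, data.frame(source = "Y", target = "X", lag = 2L,
                                     weight = 0.3, form = "linear",
                                     stringsAsFactors = FALSE))
  net <- .new_benchmark_network(2L, edges)
  ds <- time_series_dataset(data.frame(X = x[sel], Y = y[sel]))
  list(network = net, dataset = ds)
}
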