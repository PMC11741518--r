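#' Fit a temporal causal network to multivariate time series
#'
#' Learns a translation-invariant time-unfolded causal graph from a
#' multivariate, mixed-type time-series dataset and collapses it to a
#' summary graph whose edges are annotated with time delays, association
#' signs and confidences.  Independence decisions use penalized mutual
#' information (see [mutual_information()]); lagged edges are pre-oriented
#' toward the future; v-structures are oriented from penalized three-point
#' information, which can also place a second, backward arrowhead on a
#' lagged edge — the signature of a time-lagged latent common cause,
#' reported as a bidirected summary edge.
#'
#' @param dataset A [time_series_dataset()], or a data frame (then
#'   `trajectory` / `contextual` are used to wrap it).
#' @param tau Maximum time lag in time steps, or `"auto"` to set it to twice
#'   the mean relaxation time of the variables (see [estimate_tau()]).
#' @param delta_tau Layer spacing in time steps, or `"auto"`
#'   (`max(1, round(tau / target_layers))`).
#' @param target_layers Desired number of lagged layers when `delta_tau` is
#'   automatic.
#' @param stride Window anchor spacing for [lag_samples()].
#' @param alpha Tail probability of the complexity penalty of every
#'   independence test.
#' @param conf_cutoff Orientation confidence cutoff in (0.5, 1].
#' @param max_contributors Maximum conditioning-set size.
#' @param trajectory,contextual Passed to [time_series_dataset()] when
#'   `dataset` is a plain data frame.
#' @param verbose Print progress messages.
#' @return An object of class `"chronet"`: a list with components `summary`
#'   (the [collapse_summary()] graph), `graph` (the oriented time-unfolded
#'   graph), `decisions` (per-candidate-pair audit table), `layout`,
#'   `tau_info`, `n_windows` and `call`.
#' @examples
#' sim <- generate_te_models("a", T = 2000, seed = 1)
#' fit <- chronet(sim$dataset, tau = 2)
#' fit
#' @export
chronet <- function(dataset, tau = "auto", delta_tau = "auto",
                    target_layers = 12L, stride = 1L, alpha = 1e-4,
                    conf_cutoff = 0.95, max_contributors = 3L,
                    trajectory = NULL, contextual = character(),
                    verbose = FALSE) {
  cl <- match.call()
  if (!inherits(dataset, "ts_dataset"))
    dataset <- time_series_dataset(dataset, trajectory = trajectory,
                                   contextual = contextual)
  tau_info <- NULL
  if (identical(tau, "auto")) {
    tau_info <- estimate_tau(dataset, target_layers = target_layers)
    tau <- tau_info$tau
    delta_tau <- tau_info$delta_tau
  } else if (identical(delta_tau, "auto")) {
    delta_tau <- max(1L, as.integer(round(tau / target_layers)))
    tau <- max(delta_tau, (as.integer(tau) %/% delta_tau) * delta_tau)
  }
  tau <- as.integer(tau); delta_tau <- as.integer(delta_tau)
  if (verbose) message("tau = ", tau, ", delta_tau = ", delta_tau)
  layout <- build_layout(dataset, tau, delta_tau)
  samples <- lag_samples(dataset, layout, stride = stride)
  sk <- learn_skeleton(samples, layout, alpha = alpha,
                       max_contributors = max_contributors,
                       verbose = verbose)
  g <- orient_graph(sk$graph, samples, sk$decisions,
                    conf_cutoff = conf_cutoff, alpha = alpha)
  signs <- .edge_signs(g, samples, layout)
  sg <- collapse_summary(g, signs)
  structure(list(summary = sg, graph = g, decisions = sk$decisions,
                 layout = layout, tau_info = tau_info,
                 n_windows = nrow(samples),
                 config = list(tau = tau, delta_tau = delta_tau,
                               stride = stride, alpha = alpha,
                               conf_cutoff = conf_cutoff,
                               max_contributors = max_contributors),
                 call = cl),
            class = "chronet")
}

# association sign of each summary-edge representative:
# Pearson for continuous pairs, point-biserial for mixed pairs,
# dominant Pearson-residual sign for categorical tables
.edge_signs <- function(g, samples, layout) {
  e <- g$edges
  if (!nrow(e)) return(NULL)
  kinds <- vapply(layout$variables, `[[`, "", "kind")
  names(kinds) <- vapply(layout$variables, `[[`, "", "name")
  num <- function(x) if (is.numeric(x)) x else as.numeric(factor(x))
  sgn <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    xa <- samples[[.node_id(e$a_var[i], e$a_lag[i])]]
    xb <- samples[[.node_id(e$b_var[i], e$b_lag[i])]]
    ka <- kinds[e$a_var[i]]; kb <- kinds[e$b_var[i]]
    cat_a <- ka != "continuous"; cat_b <- kb != "continuous"
    if (cat_a && cat_b) {
      tb <- table(xa, xb)
      if (nrow(tb) < 2L || ncol(tb) < 2L) { sgn[i] <- "none"; next }
      exp_ <- outer(rowSums(tb), colSums(tb)) / sum(tb)
      res <- (tb - exp_) / sqrt(pmax(exp_, 1e-12))
      dom <- which.max(abs(res))
      rc <- arrayInd(dom, dim(res))
      # dominant Pearson residual; off-diagonal dominance flips the sign
      s <- sign(res[dom]) * (if (rc[1L] == rc[2L]) 1 else -1)
      sgn[i] <- if (s > 0) "+" else if (s < 0) "-" else "none"
    } else {
      cc <- suppressWarnings(stats::cor(num(xa), num(xb)))
      sgn[i] <- if (is.na(cc) || cc == 0) "none"
      else if (cc > 0) "+" else "-"
    }
  }
  data.frame(a_var = e$a_var, a_lag = e$a_lag, b_var = e$b_var,
             b_lag = e$b_lag, sign = sgn, stringsAsFactors = FALSE)
}

#' @export
print.chronet <- function(x, ...) {
  cat("Temporal causal network (chronet fit)\n")
  cat("  tau =", x$config$tau, "ts, delta_tau =", x$config$delta_tau,
      "ts,", x$n_windows, "sample windows\n")
  cat("  time-unfolded graph:", nrow(x$graph$edges), "edges;",
      "summary graph:", nrow(x$summary), "edges\n")
  print(x$summary)
  invisible(x)
}

#' @export
summary.chronet <- function(object, ...) {
  d <- object$decisions
  out <- list(
    n_candidate_pairs = nrow(d),
    n_retained = sum(d$status == "retained"),
    n_removed = sum(d$status == "removed"),
    n_summary_edges = nrow(object$summary),
    n_latent = sum(object$summary$orientation == "bidirected"),
    n_self_loops = sum(object$summary$source == object$summary$target),
    conflicts = attr(object$graph, "conflicts"),
    summary_graph = object$summary)
  class(out) <- "summary.chronet"
  out
}

#' @export
print.summary.chronet <- function(x, ...) {
  cat("chronet fit summary\n")
  cat(sprintf("  candidate pairs: %d (retained %d, removed %d)\n",
              x$n_candidate_pairs, x$n_retained, x$n_removed))
  cat(sprintf("  summary edges: %d (bidirected/latent %d, self-loops %d)\n",
              x$n_summary_edges, x$n_latent, x$n_self_loops))
  if (!is.null(x$conflicts) && x$conflicts > 0)
    cat("  orientation conflicts downgraded:", x$conflicts, "\n")
  print(x$summary_graph)
  invisible(x)
}

#' Plot a fitted temporal causal network
#'
#' Draws the summary graph with nodes on a circle; edge labels give the time
#' delays (in time steps), red/blue hues positive/negative associations,
#' dashed double-arrow edges latent common causes, and curved self-loops
#' lagged self-dependences.
#'
#' @param x A `"chronet"` fit (or pass a `"summary_graph"` to
#'   [plot_summary_graph()]).
#' @param ... Passed to [plot_summary_graph()].
#' @export
plot.chronet <- function(x, ...) {
  plot_summary_graph(x$summary, ...)
}

#' @rdname plot.chronet
#' @param sg A `"summary_graph"`.
#' @param main Plot title.
#' @export
plot_summary_graph <- function(sg, main = "Summary causal graph", ...) {
  vars <- sort(unique(c(sg$source, sg$target)))
  k <- length(vars)
  if (!k) {
    graphics::plot.new(); graphics::title(main = main)
    return(invisible(NULL))
  }
  th <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  px <- cos(th); py <- sin(th)
  names(px) <- names(py) <- vars
  graphics::plot(NA, xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45),
                 axes = FALSE, xlab = "", ylab = "", main = main, asp = 1)
  for (i in seq_len(nrow(sg))) {
    s <- sg$source[i]; t <- sg$target[i]
    col <- switch(sg$sign[i], "+" = "firebrick", "-" = "steelblue", "grey30")
    lty <- if (sg$orientation[i] == "bidirected") 2L else 1L
    if (s == t) {
      graphics::symbols(px[s] * 1.18, py[s] * 1.18, circles = 0.09,
                        add = TRUE, inches = FALSE, fg = col)
      graphics::text(px[s] * 1.33, py[s] * 1.33, sg$lag_ts[i],
                     cex = 0.6, col = col)
      next
    }
    shr <- 0.12
    dx <- px[t] - px[s]; dy <- py[t] - py[s]
    len <- sqrt(dx^2 + dy^2)
    x0 <- px[s] + shr * dx / len; y0 <- py[s] + shr * dy / len
    x1 <- px[t] - shr * dx / len; y1 <- py[t] - shr * dy / len
    code <- switch(sg$orientation[i], directed = 2L, bidirected = 3L, 0L)
    if (code == 0L) graphics::segments(x0, y0, x1, y1, col = col, lty = lty)
    else graphics::arrows(x0, y0, x1, y1, length = 0.08, code = code,
                          col = col, lty = lty)
    if (sg$lag_ts[i] > 0)
      graphics::text((x0 + x1) / 2, (y0 + y1) / 2, sg$lag_ts[i],
                     cex = 0.6, col = col, pos = 3, offset = 0.15)
  }
  graphics::points(px, py, pch = 21, bg = "white", cex = 3.2)
  graphics::text(px, py, vars, cex = 0.6)
  invisible(NULL)
}
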