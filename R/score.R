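# Scoring of learned summary graphs against ground-truth temporal networks.
# A temporal edge is identified by (past variable, future variable, lag):
# for lag > 0 the roles are fixed by time, for lag = 0 the pair is unordered
# in skeleton mode.  Self-loops are part of the scoring universe.

.truth_keys <- function(truth) {
  e <- truth$edges
  # collapse duplicate (pair, lag) entries (e.g. multiplicative pairings)
  unique(paste(e$source, e$target, e$lag))
}

.pred_keys <- function(sg) {
  if (!nrow(sg)) return(character())
  unique(paste(sg$source, sg$target, sg$lag_ts))
}

.skel_key <- function(src, tgt, lag) {
  ifelse(lag > 0, paste(src, tgt, lag),
         ifelse(src <= tgt, paste(src, tgt, lag), paste(tgt, src, lag)))
}

#' Score a learned summary graph against a ground-truth network
#'
#' In `"skeleton"` mode an edge counts as a true positive iff its
#' (lagged-pair, lag) matches a ground-truth edge; in `"oriented"` mode the
#' arrow direction must match as well, and a bidirected or undirected
#' predicted edge facing a directed ground-truth edge counts as one false
#' positive plus one false negative.
#'
#' @param predicted A `"summary_graph"`.
#' @param truth A `"benchmark_network"`.
#' @param mode `"skeleton"` or `"oriented"`.
#' @return A `"score_report"`: precision, recall, fscore, mode, counts.
#' @export
score_graph <- function(predicted, truth, mode = c("skeleton", "oriented")) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "benchmark_network"))
  pvars <- unique(c(predicted$source, predicted$target))
  tvars <- paste0("X", seq_len(truth$n_nodes))
  tvars <- unique(c(tvars, truth$edges$source, truth$edges$target))
  if (length(setdiff(pvars, tvars)))
    stop("predicted graph mentions variables outside the truth universe: ",
         paste(setdiff(pvars, tvars), collapse = ", "))
  te <- unique(data.frame(source = truth$edges$source,
                          target = truth$edges$target,
                          lag = truth$edges$lag, stringsAsFactors = FALSE))
  pe <- as.data.frame(predicted, stringsAsFactors = FALSE)
  if (mode == "skeleton") {
    tk <- unique(.skel_key(te$source, te$target, te$lag))
    pk <- if (nrow(pe)) unique(.skel_key(pe$source, pe$target, pe$lag_ts))
    else character()
    tp <- sum(pk %in% tk)
    fp <- sum(!pk %in% tk)
    fn <- sum(!tk %in% pk)
  } else {
    # oriented: only directed predicted edges can match directed truth
    tk <- unique(paste(te$source, te$target, te$lag))
    dir_pred <- pe[pe$orientation == "directed", , drop = FALSE]
    und_pred <- pe[pe$orientation != "directed", , drop = FALSE]
    pk_dir <- if (nrow(dir_pred))
      unique(paste(dir_pred$source, dir_pred$target, dir_pred$lag_ts))
    else character()
    tp <- sum(pk_dir %in% tk)
    fp <- sum(!pk_dir %in% tk) + nrow(und_pred)
    fn <- sum(!tk %in% pk_dir)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else
    (if (fn == 0) 1 else 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else
    (if (fp == 0) 1 else 0)
  fscore <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, fscore = fscore,
                 mode = mode, counts = c(TP = tp, FP = fp, FN = fn)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("Score (%s): precision %.3f, recall %.3f, Fscore %.3f (TP %d, FP %d, FN %d)\n",
              x$mode, x$precision, x$recall, x$fscore,
              x$counts["TP"], x$counts["FP"], x$counts["FN"]))
  invisible(x)
}

#' Run a replicated benchmark of the discovery engine
#'
#' Generates `n_replicates` ground-truthed datasets per sample size, runs
#' [chronet()] on each and scores the result.
#'
#' @param generator `"linear"`, `"nonlinear"`, or a function
#'   `(T, seed) -> list(network, dataset)`.
#' @param n_replicates Replicate datasets per sample size.
#' @param sample_sizes Vector of time-series lengths.
#' @param seed Master seed; replicate r at any size uses `seed + r - 1`.
#' @param tau,delta_tau,... Passed to [chronet()].
#' @return A data frame of per-replicate scores (both modes) plus the
#'   mean/sd rows, with class `"benchmark_result"`.
#' @export
run_benchmark <- function(generator = "linear", n_replicates = 10L,
                          sample_sizes = 10000L, seed = 1L,
                          tau = 2L, delta_tau = 1L, ...) {
  gen <- if (is.function(generator)) generator
  else switch(generator,
              linear = function(T, seed) generate_linear(T = T, seed = seed),
              nonlinear = function(T, seed)
                generate_nonlinear(T = T, seed = seed),
              stop("unknown generator: ", generator))
  rows <- list()
  for (Tn in sample_sizes) {
    for (r in seq_len(n_replicates)) {
      sim <- gen(Tn, seed + r - 1L)
      fit <- chronet(sim$dataset, tau = tau, delta_tau = delta_tau, ...)
      for (mode in c("skeleton", "oriented")) {
        sc <- score_graph(fit$summary, sim$network, mode)
        rows[[length(rows) + 1L]] <- data.frame(
          T = Tn, replicate = r, mode = mode, precision = sc$precision,
          recall = sc$recall, fscore = sc$fscore, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("benchmark_result", "data.frame")
  res
}

#' @export
summary.benchmark_result <- function(object, ...) {
  agg <- stats::aggregate(cbind(precision, recall, fscore) ~ T + mode,
                          data = object, FUN = mean)
  sds <- stats::aggregate(fscore ~ T + mode, data = object, FUN = stats::sd)
  agg$fscore_sd <- sds$fscore[match(paste(agg$T, agg$mode),
                                    paste(sds$T, sds$mode))]
  agg
}

# skeleton-level symmetric difference between two summary graphs
.summary_dist <- function(sg1, sg2) {
  k1 <- if (nrow(sg1)) unique(.skel_key(sg1$source, sg1$target, sg1$lag_ts))
  else character()
  k2 <- if (nrow(sg2)) unique(.skel_key(sg2$source, sg2$target, sg2$lag_ts))
  else character()
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Robustness of the learned graph to an overestimated maximum lag
#'
#' Refits the network at several values of tau and reports the pairwise
#' edit distances (symmetric differences of (pair, lag) edge sets) between
#' the summary graphs, plus per-variable lagged self-loop counts — the
#' diagnostic used to spot nonstationary variables.
#'
#' @param dataset A [time_series_dataset()].
#' @param tau_values Maximum lags to compare.
#' @param ... Passed to [chronet()].
#' @return A list with `fits`, `summaries`, `edit_distance` (matrix),
#'   `relative_change` (distance to the first tau, relative to its edge
#'   count) and `self_loops` (variable x tau count matrix).
#' @export
robustness_tau <- function(dataset, tau_values = c(2L, 5L, 10L), ...) {
  fits <- lapply(tau_values, function(tv)
    chronet(dataset, tau = tv, delta_tau = 1L, ...))
  names(fits) <- paste0("tau", tau_values)
  sgs <- lapply(fits, `[[`, "summary")
  k <- length(sgs)
  dmat <- matrix(0L, k, k, dimnames = list(names(fits), names(fits)))
  for (i in seq_len(k)) for (j in seq_len(k))
    dmat[i, j] <- .summary_dist(sgs[[i]], sgs[[j]])
  ref <- max(1L, nrow(sgs[[1L]]))
  rel <- dmat[1L, ] / ref
  vars <- names(dataset$data)
  loops <- sapply(sgs, function(sg) {
    sl <- sg[sg$source == sg$target & sg$lag_ts > 0, , drop = FALSE]
    vapply(vars, function(v) sum(sl$source == v), 0L)
  })
  if (is.null(dim(loops))) loops <- matrix(loops, nrow = length(vars),
                                           dimnames = list(vars, names(fits)))
  list(fits = fits, summaries = sgs, edit_distance = dmat,
       relative_change = rel, self_loops = loops)
}
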