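# Time-unfolded graph machinery.  A variable v observed at relative lags
# 0, delta_tau, ..., tau is represented by one lagged node per layer;
# lag 0 is the contemporaneous layer and lags are expressed in original
# time steps.  Contextual (time-invariant) variables live at lag 0 only.
# Edges are stored explicitly with endpoint marks; the past-most endpoint
# is endpoint "a" (so a directed lagged edge is a -> b with the arrow at
# the lag-0 / future side).

.node_id <- function(var, lag) paste0(var, "@-", lag)

#' Build the layer layout of a time-unfolded graph
#'
#' @param variables A list of [variable_spec()] objects (or a
#'   [time_series_dataset()], whose specs are used).
#' @param tau Maximum time lag (time steps).
#' @param delta_tau Time increment between consecutive layers; `tau` must be
#'   a multiple of `delta_tau`.
#' @return An object of class `"layer_layout"` with `nu = tau/delta_tau`
#'   lagged layers plus the contemporaneous layer, and a node table
#'   (contextual variables at lag 0 only).
#' @export
build_layout <- function(variables, tau, delta_tau = 1L) {
  if (inherits(variables, "ts_dataset")) variables <- variables$specs
  tau <- as.integer(tau); delta_tau <- as.integer(delta_tau)
  if (delta_tau < 1L || tau < delta_tau) stop("need tau >= delta_tau >= 1")
  if (tau %% delta_tau != 0L) stop("tau must be a multiple of delta_tau")
  lags <- seq.int(0L, tau, by = delta_tau)
  nodes <- do.call(rbind, lapply(variables, function(sp) {
    l <- if (sp$kind == "contextual") 0L else lags
    data.frame(var = sp$name, lag = l, stringsAsFactors = FALSE)
  }))
  nodes$id <- .node_id(nodes$var, nodes$lag)
  rownames(nodes) <- NULL
  structure(list(variables = variables, tau = tau, delta_tau = delta_tau,
                 nu = tau %/% delta_tau, nodes = nodes),
            class = "layer_layout")
}

#' @export
print.layer_layout <- function(x, ...) {
  cat("Layer layout: tau =", x$tau, "ts, delta_tau =", x$delta_tau,
      "ts (", x$nu, "lagged layers ),", nrow(x$nodes), "lagged nodes\n")
  invisible(x)
}

#' Build the lagged sample matrix of a time-series dataset
#'
#' Realizes the sliding-window view of the time-unfolded graph: one row per
#' window anchor, one column per lagged node.  Column \eqn{(v, \ell)} at a
#' window anchored at time t holds v's value at \eqn{t - \ell}; contextual
#' columns repeat the trajectory constant.
#'
#' @param dataset A [time_series_dataset()].
#' @param layout A [build_layout()] result.
#' @param stride Anchor spacing in time steps (1 = maximally overlapping
#'   windows).
#' @return A data frame with attribute `"nodes"` (the layout node table);
#'   rows are windows pooled over all usable trajectories.
#' @export
lag_samples <- function(dataset, layout, stride = 1L) {
  stopifnot(inherits(dataset, "ts_dataset"), inherits(layout, "layer_layout"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  tau <- layout$tau
  idx <- .traj_split(dataset)
  short <- lengths(idx) < tau + 1L
  if (any(short) && !all(short))
    warning(sum(short), " trajectory(ies) shorter than tau + 1 skipped")
  idx <- idx[!short]
  if (!length(idx)) stop("all trajectories shorter than tau + 1 = ", tau + 1L)
  nodes <- layout$nodes
  out <- lapply(idx, function(ii) {
    anchors <- seq.int(tau + 1L, length(ii), by = stride)
    cols <- lapply(seq_len(nrow(nodes)), function(j) {
      dataset$data[[nodes$var[j]]][ii[anchors - nodes$lag[j]]]
    })
    names(cols) <- nodes$id
    as.data.frame(cols, check.names = FALSE, optional = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "nodes") <- nodes
  res
}

# canonical edge form: endpoint a is the past-most endpoint
# (lag_a >= lag_b; ties broken by variable name order)
.canon_edges <- function(e) {
  if (!nrow(e)) return(e)
  swap <- e$a_lag < e$b_lag | (e$a_lag == e$b_lag & e$a_var > e$b_var)
  if (any(swap)) {
    tmp <- e[swap, c("a_var", "a_lag", "mark_a")]
    e[swap, c("a_var", "a_lag", "mark_a")] <-
      e[swap, c("b_var", "b_lag", "mark_b")]
    e[swap, c("b_var", "b_lag", "mark_b")] <- tmp
  }
  e
}

.empty_edges <- function() {
  data.frame(a_var = character(), a_lag = integer(),
             b_var = character(), b_lag = integer(),
             mark_a = character(), mark_b = character(),
             penalized = numeric(), confidence = numeric(),
             stringsAsFactors = FALSE)
}

#' Construct a time-unfolded graph
#'
#' @param layout A [build_layout()] result.
#' @param edges A data frame with columns `a_var`, `a_lag`, `b_var`, `b_lag`
#'   and optionally `mark_a`, `mark_b` (`"tail"`, `"arrow"`, `"unknown"`),
#'   `penalized`, `confidence`.
#' @return An object of class `"tug"` (time-unfolded graph).
#' @export
time_unfolded_graph <- function(layout, edges = NULL) {
  stopifnot(inherits(layout, "layer_layout"))
  if (is.null(edges) || !nrow(edges)) {
    edges <- .empty_edges()
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$mark_a)) edges$mark_a <- "unknown"
    if (is.null(edges$mark_b)) edges$mark_b <- "unknown"
    if (is.null(edges$penalized)) edges$penalized <- NA_real_
    if (is.null(edges$confidence)) edges$confidence <- NA_real_
    ok <- paste(edges$a_var, edges$a_lag) %in%
      paste(layout$nodes$var, layout$nodes$lag) &
      paste(edges$b_var, edges$b_lag) %in%
      paste(layout$nodes$var, layout$nodes$lag)
    if (any(!ok)) stop("edge endpoint outside the layout")
    edges <- .canon_edges(edges)
  }
  structure(list(layout = layout, edges = edges), class = "tug")
}

.edge_key <- function(e) {
  paste(e$a_var, e$a_lag, e$b_var, e$b_lag, sep = "\r")
}

.is_contextual <- function(layout, var) {
  kinds <- vapply(layout$variables, `[[`, "", "kind")
  names(kinds) <- vapply(layout$variables, `[[`, "", "name")
  unname(kinds[var] == "contextual")
}

#' Enforce translation invariance of a time-unfolded graph
#'
#' Duplicates every edge at all time shifts that keep both endpoints inside
#' the lag window `[0, tau]`, copying endpoint marks.  Edges touching a
#' contextual variable are not shifted (contextual nodes exist at lag 0
#' only).  The operation is idempotent.
#'
#' @param g A `"tug"` object.
#' @return The translation-closed `"tug"`.
#' @export
close_translation <- function(g) {
  stopifnot(inherits(g, "tug"))
  e <- g$edges
  if (!nrow(e)) return(g)
  dt <- g$layout$delta_tau
  tau <- g$layout$tau
  ctx <- .is_contextual(g$layout, e$a_var) | .is_contextual(g$layout, e$b_var)
  out <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    if (ctx[i]) { out[[i]] <- e[i, , drop = FALSE]; next }
    base <- e[i, , drop = FALSE]
    lo <- min(base$a_lag, base$b_lag)
    shifts <- seq.int(-lo, tau - max(base$a_lag, base$b_lag), by = dt)
    rep_e <- base[rep(1L, length(shifts)), , drop = FALSE]
    rep_e$a_lag <- base$a_lag + shifts
    rep_e$b_lag <- base$b_lag + shifts
    out[[i]] <- rep_e
  }
  all_e <- do.call(rbind, out)
  all_e <- all_e[!duplicated(.edge_key(all_e)), , drop = FALSE]
  rownames(all_e) <- NULL
  g$edges <- all_e
  g
}

#' @export
print.tug <- function(x, ...) {
  cat("Time-unfolded graph:", nrow(x$layout$nodes), "nodes,",
      nrow(x$edges), "edges (tau =", x$layout$tau,
      ", delta_tau =", x$layout$delta_tau, ")\n")
  invisible(x)
}

# orientation of a canonical edge (a = past-most endpoint)
.edge_orientation <- function(lagdiff, mark_a, mark_b) {
  if (lagdiff > 0L) {
    if (mark_a == "arrow" && mark_b == "arrow") "bidirected" else "directed"
  } else {
    if (mark_a == "arrow" && mark_b == "arrow") "bidirected"
    else if (mark_b == "arrow" && mark_a != "arrow") "directed"
    else if (mark_a == "arrow" && mark_b != "arrow") "directed_rev"
    else "undirected"
  }
}

#' Collapse a time-unfolded graph to a summary graph
#'
#' Each shift-equivalence class of edges becomes one summary edge annotated
#' with its time delay (in time steps).  Lagged arrow-arrow edges map to
#' bidirected edges (time-lagged latent common cause); lagged self-loops
#' are kept (signature of nonstationary dynamics).
#'
#' @param g A translation-closed `"tug"`.
#' @param signs Optional data frame with columns `a_var`, `a_lag`, `b_var`,
#'   `b_lag`, `sign` (`"+"`, `"-"` or `"none"`) giving association signs for
#'   (representatives of) edges.
#' @return An object of class `"summary_graph"`: a data frame with columns
#'   `source`, `target`, `lag_ts`, `orientation`, `sign`, `confidence`.
#' @export
collapse_summary <- function(g, signs = NULL) {
  stopifnot(inherits(g, "tug"))
  e <- g$edges
  sg <- data.frame(source = character(), target = character(),
                   lag_ts = integer(), orientation = character(),
                   sign = character(), confidence = numeric(),
                   stringsAsFactors = FALSE)
  if (nrow(e)) {
    lagdiff <- e$a_lag - e$b_lag
    grp <- paste(e$a_var, e$b_var, lagdiff, sep = "\r")
    reps <- !duplicated(grp)
    er <- e[reps, , drop = FALSE]
    ld <- lagdiff[reps]
    ori <- character(nrow(er))
    src <- er$a_var; tgt <- er$b_var
    for (i in seq_len(nrow(er))) {
      o <- .edge_orientation(ld[i], er$mark_a[i], er$mark_b[i])
      if (o == "directed_rev") {
        o <- "directed"
        tmp <- src[i]; src[i] <- tgt[i]; tgt[i] <- tmp
      }
      ori[i] <- o
    }
    sgn <- rep("none", nrow(er))
    if (!is.null(signs) && nrow(signs)) {
      sk <- paste(signs$a_var, signs$a_lag - signs$b_lag, signs$b_var,
                  sep = "\r")
      ek <- paste(er$a_var, ld, er$b_var, sep = "\r")
      hit <- match(ek, sk)
      sgn[!is.na(hit)] <- signs$sign[hit[!is.na(hit)]]
    }
    sg <- data.frame(source = src, target = tgt, lag_ts = ld,
                     orientation = ori, sign = sgn,
                     confidence = er$confidence, stringsAsFactors = FALSE)
    # one summary edge per (unordered pair, lag)
    upair <- ifelse(sg$source <= sg$target,
                    paste(sg$source, sg$target, sg$lag_ts, sep = "\r"),
                    paste(sg$target, sg$source, sg$lag_ts, sep = "\r"))
    sg <- sg[!duplicated(upair), , drop = FALSE]
    rownames(sg) <- NULL
  }
  structure(sg, class = c("summary_graph", "data.frame"))
}

#' @export
print.summary_graph <- function(x, ...) {
  cat("Summary causal graph:", nrow(x), "edges\n")
  if (nrow(x)) {
    glyph <- c(directed = "->", undirected = "--", bidirected = "<->")
    lab <- sprintf("  %s %s %s  (lag %d%s%s)", x$source,
                   glyph[x$orientation], x$target, x$lag_ts,
                   ifelse(x$sign == "none", "", paste0(", sign ", x$sign)),
                   ifelse(is.na(x$confidence), "",
                          sprintf(", conf %.2f", x$confidence)))
    cat(lab, sep = "\n")
  }
  invisible(x)
}
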