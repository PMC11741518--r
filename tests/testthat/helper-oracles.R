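# Independent oracles used by the tests: a d-separation checker on
# time-unfolded ground-truth DAGs, a Yule-Walker covariance solver for
# linear VAR models, and a brute-force assignment minimizer.

# Unfold a benchmark network into an explicit DAG over `depth` time points.
# Nodes are "var@-lag" with lag 0 the anchor; edges point from the past to
# the future.  Includes every edge whose endpoints fall inside the window.
unfold_truth <- function(network, depth = 12L) {
  e <- network$edges
  out <- list()
  for (k in seq_len(nrow(e))) {
    for (lag_to in 0:(depth - e$lag[k])) {
      out[[length(out) + 1L]] <- data.frame(
        from = paste0(e$source[k], "@-", lag_to + e$lag[k]),
        to = paste0(e$target[k], "@-", lag_to),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# classical d-separation via ancestral moral graph
d_separated <- function(dag, x, y, Z = character()) {
  nodes <- unique(c(dag$from, dag$to, x, y, Z))
  parents <- split(dag$from, factor(dag$to, levels = nodes))
  # ancestors of x, y, Z
  anc <- unique(c(x, y, Z))
  repeat {
    more <- unique(unlist(parents[anc]))
    more <- more[!is.na(more)]
    new <- setdiff(more, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  sub <- dag[dag$from %in% anc & dag$to %in% anc, , drop = FALSE]
  # moralize: undirected skeleton + marry co-parents
  und <- rbind(sub[, c("from", "to")],
               stats::setNames(sub[, c("to", "from")], c("from", "to")))
  for (v in unique(sub$to)) {
    ps <- unique(sub$from[sub$to == v])
    if (length(ps) > 1L) {
      cmb <- utils::combn(ps, 2L)
      und <- rbind(und,
                   data.frame(from = cmb[1L, ], to = cmb[2L, ]),
                   data.frame(from = cmb[2L, ], to = cmb[1L, ]))
    }
  }
  # remove Z, test connectivity x -> y
  und <- und[!(und$from %in% Z) & !(und$to %in% Z), , drop = FALSE]
  reach <- x
  repeat {
    nxt <- unique(und$to[und$from %in% reach])
    new <- setdiff(nxt, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  !(y %in% reach)
}

# stationary covariance of the VAR(2) model via the companion-form
# Lyapunov fixed point; returns function(l) = Cov(X_t, X_{t-l})
yule_walker_cov <- function(network, iters = 400L) {
  cm <- chronet:::.coef_matrices(network)
  p <- network$n_nodes
  A <- rbind(cbind(cm$A1, cm$A2), cbind(diag(p), matrix(0, p, p)))
  Q <- matrix(0, 2 * p, 2 * p)
  Q[seq_len(p), seq_len(p)] <- diag(p)
  S <- Q
  for (i in seq_len(iters)) S <- A %*% S %*% t(A) + Q
  function(l) {
    if (l == 0L) S[seq_len(p), seq_len(p)]
    else if (l == 1L) S[seq_len(p), p + seq_len(p)]
    else {
      # Cov(X_t, X_{t-2}) = A1 Cov(X_{t-1}, X_{t-2}) + A2 Var(X_{t-2})
      cm$A1 %*% S[seq_len(p), p + seq_len(p)] +
        cm$A2 %*% S[seq_len(p), seq_len(p)]
    }
  }
}

# exhaustive assignment minimizer (reject cost 0), total-cost oracle
brute_assignment_cost <- function(cost, reject = 0) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- Inf
  rec <- function(i, used, tot) {
    if (i > nr) { if (tot < best) best <<- tot; return(invisible(NULL)) }
    rec(i + 1L, used, tot + reject)
    for (j in seq_len(nc)) {
      if (!(j %in% used) && is.finite(cost[i, j]))
        rec(i + 1L, c(used, j), tot + cost[i, j])
    }
  }
  rec(1L, integer(0), 0)
  best
}

assignment_total_cost <- function(cost, ass, reject = 0) {
  s <- 0
  for (i in seq_along(ass))
    s <- s + if (is.na(ass[i])) reject else cost[i, ass[i]]
  s
}

# simulate a small named linear SCM (list of edges source,target,lag,weight)
simulate_scm <- function(edges, vars, T, seed, self_coefs = NULL,
                         burn = 100L) {
  set.seed(seed)
  p <- length(vars)
  Tt <- T + burn
  X <- matrix(0, Tt, p, dimnames = list(NULL, vars))
  ord <- order(edges$lag == 0L)   # lagged contributions first
  for (t in 3:Tt) {
    x <- stats::setNames(stats::rnorm(p), vars)
    if (!is.null(self_coefs)) x <- x + self_coefs * X[t - 1L, ]
    for (k in ord) {
      src_val <- if (edges$lag[k] == 0L) x[edges$source[k]]
      else X[t - edges$lag[k], edges$source[k]]
      x[edges$target[k]] <- x[edges$target[k]] + edges$weight[k] * src_val
    }
    X[t, ] <- x
  }
  as.data.frame(X[(burn + 1L):Tt, , drop = FALSE])
}
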