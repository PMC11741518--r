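# Skeleton learning on the lagged sample matrix.  Candidate edges are all
# node pairs with at least one contemporaneous (lag-0) endpoint (contextual
# variables pair with lag-0 nodes only).  For each pair, significant
# information contributors are collected iteratively (greedy, highest
# positive penalized three-point information first); the edge is removed as
# soon as the penalized conditional mutual information given the collected
# contributors drops to zero or below.

# internal state shared by skeleton and orientation
.make_state <- function(samples, layout, alpha) {
  nodes <- attr(samples, "nodes")
  if (is.null(nodes)) stop("samples must come from lag_samples()")
  kinds <- vapply(layout$variables, `[[`, "", "kind")
  names(kinds) <- vapply(layout$variables, `[[`, "", "name")
  n <- nrow(samples)
  keep <- vapply(seq_len(nrow(nodes)), function(j) {
    length(unique(samples[[nodes$id[j]]])) > 1L
  }, TRUE)
  if (any(!keep))
    warning("dropping degenerate constant column(s): ",
            paste(nodes$id[!keep], collapse = ", "))
  nodes <- nodes[keep, , drop = FALSE]
  rownames(nodes) <- NULL
  nodes$ctx <- unname(kinds[nodes$var] == "contextual")
  nodes$cat <- unname(kinds[nodes$var] != "continuous")
  descs <- lapply(seq_len(nrow(nodes)), function(j) {
    x <- samples[[nodes$id[j]]]
    .col_desc(if (nodes$cat[j]) x else as.numeric(x), nodes$cat[j])
  })
  st <- new.env(parent = emptyenv())
  st$nodes <- nodes
  st$descs <- descs
  st$n <- n
  st$alpha <- alpha
  st$tau <- layout$tau
  st$dt <- layout$delta_tau
  st$midx <- stats::setNames(seq_len(nrow(nodes)),
                             paste(nodes$var, nodes$lag))
  st$relmem <- new.env(parent = emptyenv())
  st
}

# neighbors of node ui under translation closure of the anchored edge list
.nbrs <- function(st, ui) {
  E <- st$edges
  if (!nrow(E)) return(integer(0))
  v <- st$nodes$var[ui]; l <- st$nodes$lag[ui]
  res <- integer(0)
  for (side in 1:2) {
    svar <- if (side == 1L) E$a_var else E$b_var
    slag <- if (side == 1L) E$a_lag else E$b_lag
    ovar <- if (side == 1L) E$b_var else E$a_var
    olag <- if (side == 1L) E$b_lag else E$a_lag
    sel <- which(svar == v)
    if (!length(sel)) next
    s <- l - slag[sel]
    ol <- olag[sel] + s
    good <- ol >= 0L & ol <= st$tau & (!E$ctx[sel] | s == 0L)
    if (any(good)) {
      hits <- st$midx[paste(ovar[sel][good], ol[good])]
      res <- c(res, hits[!is.na(hits)])
    }
  }
  res <- unique(res)
  res[res != ui]
}

.pair_cmi <- function(st, xi, yi, U) {
  .pen_cmi(st$descs[[xi]], st$descs[[yi]], st$descs[U], st$n, st$alpha)
}

# memoized quick pairwise-information relevance score (plug-in n*I at a
# fixed coarse resolution; used only for ranking conditioning candidates)
.quick_rel <- function(st, i, j) {
  key <- if (i < j) paste0(i, ":", j) else paste0(j, ":", i)
  v <- st$relmem[[key]]
  if (is.null(v)) {
    bi <- .col_bins(st$descs[[i]], 5L)
    bj <- .col_bins(st$descs[[j]], 5L)
    v <- .cmi_counts(bi$bin, bi$nb, bj$bin, bj$nb,
                     rep.int(1L, st$n), 1L, st$n)$nI
    st$relmem[[key]] <- v
  }
  v
}

#' Learn the skeleton of a time-unfolded graph
#'
#' @param samples A lagged sample matrix from [lag_samples()].
#' @param layout The matching [build_layout()].
#' @param alpha Penalty tail probability of the independence tests.
#' @param max_contributors Maximum size of a conditioning set.
#' @param verbose Print progress.
#' @return A list with `graph` (translation-closed `"tug"`), and
#'   `decisions` (one row per candidate pair: status, contributors,
#'   final penalized information, separating set).
#' @export
learn_skeleton <- function(samples, layout, alpha = 1e-4,
                           max_contributors = 3L, verbose = FALSE) {
  st <- .make_state(samples, layout, alpha)
  if (st$n < 10L) stop("need at least 10 sample rows")
  nodes <- st$nodes
  np <- nrow(nodes)
  cand <- list()
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      if (nodes$var[i] == nodes$var[j] && nodes$lag[i] == nodes$lag[j]) next
      if (min(nodes$lag[i], nodes$lag[j]) != 0L) next
      if ((nodes$ctx[i] || nodes$ctx[j]) &&
          max(nodes$lag[i], nodes$lag[j]) != 0L) next
      cand[[length(cand) + 1L]] <- c(i, j)
    }
  }
  cand <- do.call(rbind, cand)
  if (verbose) message(nrow(cand), " candidate pairs")

  # phase 1: unconditional screening
  est1 <- lapply(seq_len(nrow(cand)), function(r)
    .pair_cmi(st, cand[r, 1L], cand[r, 2L], integer(0)))
  pen1 <- vapply(est1, `[[`, 0, "penalized")
  dec <- vector("list", nrow(cand))
  surv <- which(pen1 > 0)
  for (r in which(pen1 <= 0)) {
    dec[[r]] <- data.frame(
      x = nodes$id[cand[r, 1L]], y = nodes$id[cand[r, 2L]],
      status = "removed", contributors = "", separating_set = "",
      raw_info = est1[[r]]$raw_info, final_penalized = pen1[r],
      stringsAsFactors = FALSE)
  }

  mk_edges <- function(rows) {
    data.frame(a_var = nodes$var[cand[rows, 1L]],
               a_lag = nodes$lag[cand[rows, 1L]],
               b_var = nodes$var[cand[rows, 2L]],
               b_lag = nodes$lag[cand[rows, 2L]],
               ai = cand[rows, 1L], bi = cand[rows, 2L],
               ctx = nodes$ctx[cand[rows, 1L]] | nodes$ctx[cand[rows, 2L]],
               row = rows, stringsAsFactors = FALSE)
  }
  st$edges <- mk_edges(surv)

  # phase 2: iterative contributors, weakest pairs first
  ord <- surv[order(pen1[surv], nodes$id[cand[surv, 1L]],
                    nodes$id[cand[surv, 2L]])]
  final_est <- est1
  for (r in ord) {
    xi <- cand[r, 1L]; yi <- cand[r, 2L]
    U <- integer(0)
    estU <- est1[[r]]
    status <- "retained"; sep <- integer(0)
    lagged_pair <- max(nodes$lag[xi], nodes$lag[yi]) > 0L
    repeat {
      pool <- setdiff(sort(union(.nbrs(st, xi), .nbrs(st, yi))),
                      c(xi, yi, U))
      if (!length(pool)) break
      # for a lagged pair, prefer contributors strictly in the past of the
      # contemporaneous endpoint: conditioning on a contemporaneous
      # descendant can explain away the dependence (near-cancellation) and
      # corrupt separating sets, so lag-0 nodes are tried only if no
      # past-side contributor is significant
      tiers <- if (lagged_pair)
        list(pool[nodes$lag[pool] > 0L], pool[nodes$lag[pool] == 0L])
      else list(pool)
      best_pen3 <- -Inf; best_zi <- NA_integer_; best_est <- NULL
      for (tier in tiers) {
        for (zi in tier) {
          estZ <- .pair_cmi(st, xi, yi, c(U, zi))
          pen3 <- st$n * (estU$raw_info - estZ$raw_info) -
            max(0, estZ$complexity - estU$complexity)
          if (pen3 > best_pen3) {
            best_pen3 <- pen3; best_zi <- zi; best_est <- estZ
          }
        }
        if (best_pen3 > 0) break
      }
      if (best_pen3 <= 0) break
      U <- c(U, best_zi)
      estU <- best_est
      if (estU$penalized <= 0) {
        status <- "removed"; sep <- U
        break
      }
      if (length(U) >= max_contributors) break
    }
    if (status == "removed") {
      st$edges <- st$edges[st$edges$row != r, , drop = FALSE]
    }
    final_est[[r]] <- estU
    dec[[r]] <- data.frame(
      x = nodes$id[xi], y = nodes$id[yi], status = status,
      contributors = paste(nodes$id[U], collapse = ","),
      separating_set = paste(nodes$id[sep], collapse = ","),
      raw_info = estU$raw_info, final_penalized = estU$penalized,
      stringsAsFactors = FALSE)
  }
  # phase 3: forced-depth re-examination of the surviving pairs.  The
  # greedy contributor search requires each contributor to be individually
  # significant and so can miss separating sets whose members are weak
  # (e.g. a faint common parent spreading dependence over several lags).
  # Each retained pair is re-tested conditioning on its most relevant
  # past-side neighbors (ranked by a quick pairwise-information score),
  # sequentially up to max_contributors; contemporaneous neighbors are not
  # used here because conditioning on a contemporaneous descendant can
  # cancel a genuine dependence by explaining-away.
  if (nrow(st$edges)) {
    rows3 <- st$edges$row
    pen_now <- vapply(final_est[rows3], `[[`, 0, "penalized")
    rows3 <- rows3[order(pen_now, nodes$id[cand[rows3, 1L]],
                         nodes$id[cand[rows3, 2L]])]
    for (r in rows3) {
      xi <- cand[r, 1L]; yi <- cand[r, 2L]
      pool <- setdiff(sort(union(.nbrs(st, xi), .nbrs(st, yi))), c(xi, yi))
      pool <- pool[nodes$lag[pool] > 0L]
      if (!length(pool)) next
      rel <- vapply(pool, function(zi)
        max(.quick_rel(st, zi, xi), .quick_rel(st, zi, yi)), 0)
      pool <- pool[order(-rel, nodes$id[pool])]
      pool <- pool[seq_len(min(length(pool), max_contributors))]
      removed3 <- FALSE
      for (k in seq_along(pool)) {
        estS <- .pair_cmi(st, xi, yi, pool[seq_len(k)])
        if (estS$penalized <= 0) {
          st$edges <- st$edges[st$edges$row != r, , drop = FALSE]
          dec[[r]] <- data.frame(
            x = nodes$id[xi], y = nodes$id[yi], status = "removed",
            contributors = dec[[r]]$contributors,
            separating_set = paste(nodes$id[pool[seq_len(k)]],
                                   collapse = ","),
            raw_info = estS$raw_info,
            final_penalized = estS$penalized, stringsAsFactors = FALSE)
          final_est[[r]] <- estS
          removed3 <- TRUE
          break
        }
      }
      if (removed3) next
    }
  }

  decisions <- do.call(rbind, dec)
  rownames(decisions) <- NULL

  ek <- st$edges
  edges <- if (nrow(ek)) {
    data.frame(a_var = ek$a_var, a_lag = ek$a_lag,
               b_var = ek$b_var, b_lag = ek$b_lag,
               mark_a = "unknown", mark_b = "unknown",
               penalized = vapply(final_est[ek$row], `[[`, 0, "penalized"),
               confidence = NA_real_, stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(edges))
    edges$confidence <- 1 / (1 + exp(-pmin(edges$penalized, 700)))
  g <- time_unfolded_graph(layout, edges)
  g <- close_translation(g)
  list(graph = g, decisions = decisions)
}
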