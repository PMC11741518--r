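# Orientation of a translation-closed skeleton:
#  (i)  lagged edges get a first arrowhead at their lag-0 (future) endpoint;
#       contextual edges point from the contextual condition into the feature;
#  (ii) unshielded triples whose penalized three-point information is
#       significantly negative become colliders (confidence from a logistic
#       transform of the score, applied above the confidence cutoff); this is
#       the only rule that can place a backward arrowhead on a lagged edge,
#       producing arrow-arrow (time-lagged latent cause) edges;
#  (iii) Meek rule-1 propagation on definite non-collider triples, never
#       orienting an arrow into the past or into a contextual node;
#  marks are re-closed by translation after orientation (conflicting marks
#  among shifted copies are downgraded to unknown and logged).

.sepset_lookup <- function(sep_env, id_a, id_b) {
  key <- if (id_a < id_b) paste(id_a, id_b) else paste(id_b, id_a)
  sep_env[[key]]
}

.parse_node <- function(id) {
  m <- regmatches(id, regexec("^(.*)@-([0-9]+)$", id))[[1L]]
  list(var = m[2L], lag = as.integer(m[3L]))
}

.shift_id <- function(id, s) {
  p <- .parse_node(id)
  .node_id(p$var, p$lag + s)
}

# conservative check of a candidate collider a -> z <- b: look for a
# conditioning set that contains z and separates (a, b) among subsets of
# the endpoints' neighborhoods; if one exists, z explains (part of) the
# dependence and the triple must not be oriented as a collider
.collider_refuted <- function(st, ai, bi, zi, nbr, all_ids, max_extra = 2L) {
  ids <- c(.node_id(st$nodes$var[ai], st$nodes$lag[ai]),
           .node_id(st$nodes$var[bi], st$nodes$lag[bi]))
  pool_ids <- setdiff(sort(unique(c(nbr[[ids[1L]]], nbr[[ids[2L]]]))), ids)
  pool <- st$midx[vapply(pool_ids, function(id) {
    p <- .parse_node(id); paste(p$var, p$lag)
  }, "")]
  pool <- unname(pool[!is.na(pool)])
  pool <- setdiff(pool, c(ai, bi, zi))
  if (length(pool) > 8L) pool <- pool[seq_len(8L)]
  subsets <- list(integer(0))
  if (max_extra >= 1L) subsets <- c(subsets, as.list(pool))
  if (max_extra >= 2L && length(pool) >= 2L) {
    cmb <- utils::combn(pool, 2L)
    subsets <- c(subsets, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  for (S in subsets) {
    est <- .pair_cmi(st, ai, bi, c(zi, S))
    if (est$penalized <= 0) return(TRUE)
  }
  FALSE
}

#' Orient a learned time-unfolded skeleton
#'
#' @param g A translation-closed `"tug"` from [learn_skeleton()].
#' @param samples The lagged sample matrix used for learning.
#' @param decisions The decision table from [learn_skeleton()] (provides the
#'   separating sets of removed pairs).
#' @param conf_cutoff Minimum orientation confidence in (0.5, 1] for
#'   accepting a collider.
#' @param alpha Penalty tail probability.
#' @return The graph with endpoint marks set; attribute `"conflicts"` counts
#'   orientation conflicts (downgraded to unknown marks), attribute
#'   `"colliders"` lists accepted colliders.
#' @export
orient_graph <- function(g, samples, decisions, conf_cutoff = 0.95,
                         alpha = 1e-4) {
  stopifnot(inherits(g, "tug"))
  if (conf_cutoff <= 0.5 || conf_cutoff > 1)
    stop("conf_cutoff must be in (0.5, 1]")
  layout <- g$layout
  st <- .make_state(samples, layout, alpha)
  e <- g$edges
  conflicts <- 0L
  if (!nrow(e)) return(g)

  ctx_a <- .is_contextual(layout, e$a_var)
  ctx_b <- .is_contextual(layout, e$b_var)
  # (i) first arrowhead toward the future
  lagged <- e$a_lag > e$b_lag
  e$mark_b[lagged] <- "arrow"
  e$mark_a[!lagged & ctx_a & !ctx_b] <- "tail"
  e$mark_b[!lagged & ctx_a & !ctx_b] <- "arrow"
  e$mark_a[!lagged & ctx_b & !ctx_a] <- "arrow"
  e$mark_b[!lagged & ctx_b & !ctx_a] <- "tail"

  ekey <- .edge_key(e)
  find_edge <- function(id1, id2) {
    p1 <- .parse_node(id1); p2 <- .parse_node(id2)
    cn <- .canon_edges(data.frame(a_var = p1$var, a_lag = p1$lag,
                                  b_var = p2$var, b_lag = p2$lag,
                                  mark_a = "", mark_b = "",
                                  stringsAsFactors = FALSE))
    match(.edge_key(cn), ekey)
  }
  # endpoint mark setter with conflict handling
  set_mark <- function(id_edge_row, at_id, mark) {
    row <- id_edge_row
    at_a <- .node_id(e$a_var[row], e$a_lag[row]) == at_id
    cur <- if (at_a) e$mark_a[row] else e$mark_b[row]
    if (cur == mark || cur == "conflict") return(invisible(NULL))
    if (cur != "unknown") {
      conflicts <<- conflicts + 1L
      new <- "conflict"
    } else new <- mark
    if (at_a) e$mark_a[row] <<- new else e$mark_b[row] <<- new
    invisible(NULL)
  }

  # adjacency (closed graph is explicit)
  ids_a <- .node_id(e$a_var, e$a_lag)
  ids_b <- .node_id(e$b_var, e$b_lag)
  all_ids <- sort(unique(c(ids_a, ids_b)))
  nbr <- lapply(stats::setNames(all_ids, all_ids), function(id)
    sort(unique(c(ids_b[ids_a == id], ids_a[ids_b == id]))))
  adj <- function(i1, i2) any(ids_a == i1 & ids_b == i2) ||
    any(ids_a == i2 & ids_b == i1)

  # separating sets from the decision table
  sep_env <- new.env(parent = emptyenv())
  rem <- decisions[decisions$status == "removed", , drop = FALSE]
  for (r in seq_len(nrow(rem))) {
    a <- rem$x[r]; b <- rem$y[r]
    key <- if (a < b) paste(a, b) else paste(b, a)
    sep_env[[key]] <- if (nzchar(rem$separating_set[r]))
      strsplit(rem$separating_set[r], ",", fixed = TRUE)[[1L]] else character()
  }

  node_lag <- function(id) .parse_node(id)$lag
  is_ctx_id <- function(id) .is_contextual(layout, .parse_node(id)$var)

  # (ii) collider orientation on anchored unshielded triples
  colliders <- list()
  noncolliders <- list()
  for (z in all_ids) {
    if (is_ctx_id(z)) next
    nb <- nbr[[z]]
    if (length(nb) < 2L) next
    for (i1 in seq_len(length(nb) - 1L)) {
      for (i2 in (i1 + 1L):length(nb)) {
        a <- nb[i1]; b <- nb[i2]
        if (adj(a, b)) next
        lags <- c(node_lag(a), node_lag(z), node_lag(b))
        if (min(lags) != 0L) next  # anchored representatives only
        # sepset of (a,b), looked up in the pair's own anchored frame
        shp <- min(node_lag(a), node_lag(b))
        sep <- .sepset_lookup(sep_env, .shift_id(a, -shp), .shift_id(b, -shp))
        if (is.null(sep)) next
        sep <- vapply(sep, .shift_id, "", s = shp)
        if (z %in% sep) {
          noncolliders[[length(noncolliders) + 1L]] <- c(a, z, b)
          next
        }
        sidx <- st$midx[vapply(sep, function(id) {
          p <- .parse_node(id); paste(p$var, p$lag)
        }, "")]
        if (anyNA(sidx) || max(vapply(sep, node_lag, 0L),
                               0L) > layout$tau) next
        pz <- .parse_node(z)
        zi <- st$midx[paste(pz$var, pz$lag)]
        pa <- .parse_node(a); pb <- .parse_node(b)
        ai <- st$midx[paste(pa$var, pa$lag)]
        bi <- st$midx[paste(pb$var, pb$lag)]
        if (anyNA(c(zi, ai, bi))) next
        i1e <- .pair_cmi(st, ai, bi, unname(sidx))
        i2e <- .pair_cmi(st, ai, bi, c(unname(sidx), zi))
        tp <- .three_point_from(i1e, i2e, alpha)
        conf <- 1 / (1 + exp(max(-700, min(700, tp$collider_score))))
        if (tp$collider_score < 0 && conf >= conf_cutoff &&
            .collider_refuted(st, ai, bi, zi, nbr, all_ids)) {
          # some conditioning set containing z separates the pair, so the
          # apparent activation comes from an unblocked side path, not from
          # a collider at z: treat the triple as ambiguous
          noncolliders[[length(noncolliders) + 1L]] <- c(a, z, b)
          next
        }
        if (tp$collider_score < 0 && conf >= conf_cutoff) {
          r1 <- find_edge(a, z); r2 <- find_edge(b, z)
          if (!is.na(r1)) set_mark(r1, z, "arrow")
          if (!is.na(r2)) set_mark(r2, z, "arrow")
          colliders[[length(colliders) + 1L]] <-
            data.frame(a = a, z = z, b = b, score = tp$collider_score,
                       confidence = conf, stringsAsFactors = FALSE)
        } else {
          noncolliders[[length(noncolliders) + 1L]] <- c(a, z, b)
        }
      }
    }
  }

  # (iii) Meek rule 1 on definite non-colliders
  get_mark <- function(row, at_id) {
    if (.node_id(e$a_var[row], e$a_lag[row]) == at_id) e$mark_a[row]
    else e$mark_b[row]
  }
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (tr in noncolliders) {
      for (ordr in list(c(1L, 3L), c(3L, 1L))) {
        a <- tr[ordr[1L]]; z <- tr[2L]; b <- tr[ordr[2L]]
        raz <- find_edge(a, z); rzb <- find_edge(z, b)
        if (is.na(raz) || is.na(rzb)) next
        if (get_mark(raz, z) != "arrow") next
        mz <- get_mark(rzb, z); mb <- get_mark(rzb, b)
        if (mz != "unknown" || mb != "unknown") next
        if (is_ctx_id(b)) next
        if (node_lag(b) > node_lag(z)) next  # never point into the past
        set_mark(rzb, z, "tail"); set_mark(rzb, b, "arrow")
        changed <- TRUE
      }
    }
  }

  e$mark_a[e$mark_a == "conflict"] <- "unknown"
  e$mark_b[e$mark_b == "conflict"] <- "unknown"

  # re-close marks by translation within shift-equivalence classes
  ctx_edge <- ctx_a | ctx_b
  cls <- ifelse(ctx_edge, paste("ctx", seq_len(nrow(e))),
                paste(e$a_var, e$b_var, e$a_lag - e$b_lag))
  for (cl in unique(cls)) {
    rows <- which(cls == cl)
    if (length(rows) < 2L) next
    for (side in c("mark_a", "mark_b")) {
      mk <- unique(e[[side]][rows])
      mk <- mk[mk != "unknown"]
      if (length(mk) == 1L) {
        e[[side]][rows] <- mk
      } else if (length(mk) > 1L) {
        conflicts <- conflicts + 1L
        e[[side]][rows] <- "unknown"
      }
    }
  }

  g$edges <- e
  attr(g, "conflicts") <- conflicts
  attr(g, "colliders") <- if (length(colliders))
    do.call(rbind, colliders) else NULL
  g
}
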