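# Internal kernel for penalized mutual-information estimation on
# discretized data.  All information values are in nats.
#
# The estimator follows a finite-sample supremum principle: continuous
# variables are discretized by equal-frequency binning and the penalized
# statistic n*I - k is maximized over a grid of bin counts.  The complexity
# penalty k is a chi-square tail quantile in the degrees of freedom of the
# underlying contingency test, so that independent data yield a negative
# penalized statistic with high probability at any n.  The reported raw
# information is Miller-Madow debiased and maximized over the same grid.

.CHRONET_BIN_GRID <- c(2L, 3L, 5L, 8L, 12L, 16L, 22L)

# bin counts eligible at sample size n (need n >> cells)
.pair_grid <- function(n) {
  g <- .CHRONET_BIN_GRID[.CHRONET_BIN_GRID <= max(2, floor(sqrt(n / 5)))]
  if (!length(g)) g <- 2L
  g
}

# per-variable bin count for conditioning variables, given |Z| = m.
# Two resolutions are used: a coarse one (max power for the tested pair)
# and a finer one (tighter conditioning, so that dependence mediated by Z
# is not mistaken for a direct edge at large n); the penalized statistic
# of a conditional test is the minimum over the two.
.bz_rule <- function(n, m) {
  cmax <- min(64, max(8, floor(n / 50)))
  max(2L, min(5L, as.integer(floor(cmax^(1 / m)))))
}

.bz_rule_fine <- function(n, m) {
  coarse <- .bz_rule(n, m)
  fine <- if (m <= 3L) c(12L, 8L, 6L)[m] else coarse
  # never exceed what the sample size supports (a few samples per cell)
  while (fine > coarse && fine^m > n / 30) fine <- fine - 1L
  max(coarse, fine)
}

# equal-frequency binning; returns integer bins 1..nb (nb <= B, ties
# merged) plus the marginal bin counts
.ef_bins <- function(x, B) {
  if (B <= 1L)
    return(list(bin = rep.int(1L, length(x)), nb = 1L, tab = length(x)))
  qs <- unique(stats::quantile(x, probs = seq_len(B - 1L) / B,
                               type = 1, names = FALSE))
  b <- findInterval(x, qs, left.open = TRUE) + 1L
  tab <- tabulate(b, nbins = max(b))
  if (any(tab == 0L)) {
    keep <- which(tab > 0L)
    remap <- integer(length(tab)); remap[keep] <- seq_along(keep)
    b <- remap[b]
    tab <- tab[keep]
  }
  list(bin = b, nb = length(tab), tab = tab)
}

# integer coding of a categorical vector
.cat_code <- function(x) {
  f <- as.integer(factor(x))
  list(bin = f, nb = max(f), tab = tabulate(f, nbins = max(f)))
}

# memoized chi-square tail penalty (0.5 * qchisq(1 - alpha, df))
.penalty_env <- new.env(parent = emptyenv())
.chisq_penalty <- function(df, alpha) {
  if (df <= 0) return(0)
  key <- paste0(format(alpha), ":", df)
  p <- .penalty_env[[key]]
  if (is.null(p)) {
    p <- 0.5 * stats::qchisq(1 - alpha, df)
    .penalty_env[[key]] <- p
  }
  p
}

.xlgx <- function(v) {
  v <- v[v > 0]
  sum(v * log(v))
}

# Combine a list of integer bin vectors into one compressed code.
# Returns list(code (1..nc), nc).
.combine_codes <- function(bins, nbs, n) {
  if (!length(bins)) return(list(code = rep.int(1L, n), nc = 1L))
  code <- bins[[1L]]
  mult <- nbs[[1L]]
  if (length(bins) > 1L) {
    for (j in 2L:length(bins)) {
      code <- code + mult * (bins[[j]] - 1L)
      mult <- mult * nbs[[j]]
    }
  }
  occ <- tabulate(code, nbins = mult)
  present <- which(occ > 0L)
  if (length(present) < mult) {
    remap <- integer(mult)
    remap[present] <- seq_along(present)
    code <- remap[code]
  }
  list(code = code, nc = length(present), tab = occ[present])
}

# Penalized conditional mutual information from integer codes.
# Returns n*I (plug-in), degrees of freedom of the contingency test.
# bin codes passed here are always compressed (every marginal cell
# occupied), so the marginal tables can be supplied precomputed
.cmi_counts <- function(xc, nx, yc, ny, zc, nz, n,
                        x_tab = NULL, y_tab = NULL, z_tab = NULL) {
  if (is.null(x_tab)) x_tab <- tabulate(xc, nbins = nx)
  if (is.null(y_tab)) y_tab <- tabulate(yc, nbins = ny)
  if (nz == 1L) {
    cnt <- tabulate(xc + nx * (yc - 1L), nbins = nx * ny)
    nI <- .xlgx(cnt) - .xlgx(x_tab) - .xlgx(y_tab) + n * log(n)
    df <- (sum(x_tab > 0) - 1L) * (sum(y_tab > 0) - 1L)
    return(list(nI = max(0, nI), df = df))
  }
  if (is.null(z_tab)) z_tab <- tabulate(zc, nbins = nz)
  cnt <- tabulate(xc + nx * (yc - 1L) + (nx * ny) * (zc - 1L),
                  nbins = nx * ny * nz)
  n_xz <- tabulate(xc + nx * (zc - 1L), nbins = nx * nz)
  n_yz <- tabulate(yc + ny * (zc - 1L), nbins = ny * nz)
  nI <- .xlgx(cnt) - .xlgx(n_xz) - .xlgx(n_yz) + .xlgx(z_tab)
  df <- (sum(x_tab > 0) - 1L) * (sum(y_tab > 0) - 1L) * sum(z_tab > 0)
  list(nI = max(0, nI), df = df)
}

# Column descriptor used by the estimator: either categorical (fixed code)
# or continuous (binned on demand, cached).
.col_desc <- function(x, categorical) {
  if (categorical) {
    cc <- .cat_code(x)
    list(cat = TRUE, bins = list(cc), cache = NULL, x = NULL)
  } else {
    list(cat = FALSE, bins = NULL, cache = new.env(parent = emptyenv()),
         x = as.numeric(x))
  }
}

.col_bins <- function(d, B) {
  if (d$cat) return(d$bins[[1L]])
  key <- as.character(B)
  b <- d$cache[[key]]
  if (is.null(b)) {
    b <- .ef_bins(d$x, B)
    d$cache[[key]] <- b
  }
  b
}

# z-code at a given per-variable resolution
.z_code <- function(zds, bz, n) {
  if (!length(zds))
    return(list(code = rep.int(1L, n), nc = 1L, tab = n))
  zb <- lapply(zds, function(d) .col_bins(d, bz))
  .combine_codes(lapply(zb, `[[`, "bin"), vapply(zb, `[[`, 1L, "nb"), n)
}

# max over the pair bin grid at one fixed conditioning code.
# The pair resolution is capped so that the total table keeps a few
# samples per cell on average; sparser tables inflate the plug-in MI
# beyond what the chi-square penalty can absorb.
.pen_cmi_at <- function(xd, yd, z, n, alpha) {
  grid_x <- if (xd$cat) 0L else .pair_grid(n)
  grid_y <- if (yd$cat) 0L else .pair_grid(n)
  cell_budget <- n / 4
  best_pen <- -Inf
  best_raw <- 0
  tried <- FALSE
  for (gx in grid_x) {
    xb <- .col_bins(xd, gx)
    for (gy in grid_y) {
      if (!xd$cat && !yd$cat && gy != gx) next  # symmetric grid: Bx = By
      yb <- .col_bins(yd, gy)
      if (tried && xb$nb * yb$nb * z$nc > cell_budget) next
      tried <- TRUE
      cm <- .cmi_counts(xb$bin, xb$nb, yb$bin, yb$nb, z$code, z$nc, n,
                        xb$tab, yb$tab, z$tab)
      k <- .chisq_penalty(cm$df, alpha)
      pen <- cm$nI - k
      raw <- cm$nI / n - cm$df / (2 * n)      # Miller-Madow debiasing
      if (pen > best_pen) best_pen <- pen
      if (raw > best_raw) best_raw <- raw
    }
  }
  list(pen = best_pen, raw = max(0, best_raw))
}

# Residual-route conditional test for all-continuous triples: partial out
# the conditioning set from both variables (binned-mean backfitting plus a
# coarse joint-cell pass for interactions), then estimate penalized MI
# between the residuals.  Cell-based conditioning pays an exponential
# sample-size price in |Z|; the residual route keeps full power for
# additive dependences and is used as a second opinion: dependence found by
# either route retains the edge.
.resid_pen <- function(xd, yd, zds, n, alpha) {
  if (xd$cat || yd$cat || any(vapply(zds, `[[`, TRUE, "cat")))
    return(NULL)
  m <- length(zds)
  breg <- max(8L, min(32L, as.integer(n / 40)))
  zb <- lapply(zds, function(d) .col_bins(d, breg)$bin)
  rx <- xd$x; ry <- yd$x
  demean2 <- function(rx, ry, g) {
    mu <- rowsum(cbind(rx, ry), g, reorder = TRUE) / tabulate(g)
    list(rx = rx - mu[g, 1L], ry = ry - mu[g, 2L])
  }
  for (it in 1:2) {
    for (b in zb) {
      d2 <- demean2(rx, ry, b)
      rx <- d2$rx; ry <- d2$ry
    }
  }
  zc <- .z_code(zds, .bz_rule(n, m), n)$code
  d2 <- demean2(rx, ry, zc)
  rx <- d2$rx; ry <- d2$ry
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NULL)
  .pen_mi_ranked(rx, ry, n, alpha)
}

# fast penalized MI between two continuous vectors (rank binning)
.pen_mi_ranked <- function(rx, ry, n, alpha) {
  r1 <- rank(rx, ties.method = "first")
  r2 <- rank(ry, ties.method = "first")
  best_pen <- -Inf; best_raw <- 0
  for (B in .pair_grid(n)) {
    b1 <- as.integer(ceiling(r1 * B / n))
    b2 <- as.integer(ceiling(r2 * B / n))
    # rank bins of both variables share one deterministic size profile
    sz <- tabulate(b1, nbins = B)
    cnt <- tabulate(b1 + B * (b2 - 1L), nbins = B * B)
    nI <- max(0, .xlgx(cnt) - 2 * .xlgx(sz) + n * log(n))
    df <- (B - 1L)^2
    k <- .chisq_penalty(df, alpha)
    pen <- nI - k
    raw <- nI / n - df / (2 * n)
    if (pen > best_pen) best_pen <- pen
    if (raw > best_raw) best_raw <- raw
  }
  list(pen = best_pen, raw = max(0, best_raw))
}

# Penalized CMI between two single columns given a conditioning list.
# xd, yd, zds: column descriptors.  Returns the full estimate.
.pen_cmi <- function(xd, yd, zds, n, alpha) {
  m <- length(zds)
  res <- NULL
  if (m) {
    # For all-continuous triples the residual route is authoritative: it
    # keeps full power for additive dependences and does not leak residual
    # confounding through coarse conditioning cells.  The cell route is
    # the test whenever a categorical/contextual variable is involved.
    res <- .resid_pen(xd, yd, zds, n, alpha)
  }
  if (is.null(res)) {
    res <- .pen_cmi_at(xd, yd, .z_code(zds, .bz_rule(n, m), n), n, alpha)
    if (m) {
      bzf <- .bz_rule_fine(n, m)
      if (bzf > .bz_rule(n, m)) {
        resf <- .pen_cmi_at(xd, yd, .z_code(zds, bzf, n), n, alpha)
        if (resf$pen < res$pen) res <- resf
      }
    }
  }
  structure(list(raw_info = res$raw,
                 complexity = max(0, n * res$raw - res$pen),
                 n_samples = n,
                 penalized = res$pen),
            class = "info_estimate")
}

# Grouped penalized CMI: x-group vs y-group given z-group, used for
# transfer entropy where the source past enters as a joint block.
# Each continuous group member is scanned over small per-component grids
# (1 = component dropped), and the penalized statistic is maximized.
# All-continuous groups use the residual route for the conditioning (as in
# .pen_cmi): each member is partialled on the conditioning block before
# the grouped test, which keeps power when |Z| is large.
.pen_cmi_group <- function(xds, yds, zds, n, alpha) {
  m <- length(zds)
  all_cont <- !any(vapply(c(xds, yds, zds), `[[`, TRUE, "cat"))
  if (m && all_cont) {
    rxds <- .resid_group(c(xds, yds), zds, n)
    res <- .pen_cmi_group_at(rxds[seq_along(xds)],
                             rxds[length(xds) + seq_along(yds)],
                             list(code = rep.int(1L, n), nc = 1L, tab = n),
                             n, alpha)
  } else {
    res <- .pen_cmi_group_at(xds, yds, .z_code(zds, .bz_rule(n, m), n),
                             n, alpha)
    if (m) {
      bzf <- .bz_rule_fine(n, m)
      if (bzf > .bz_rule(n, m)) {
        resf <- .pen_cmi_group_at(xds, yds, .z_code(zds, bzf, n), n, alpha)
        if (resf$pen < res$pen) res <- resf
      }
    }
  }
  structure(list(raw_info = res$raw,
                 complexity = max(0, n * res$raw - res$pen),
                 n_samples = n,
                 penalized = res$pen),
            class = "info_estimate")
}

# partial a list of continuous descriptors on a conditioning block by
# binned-mean backfitting plus one joint coarse-cell pass
.resid_group <- function(ds, zds, n) {
  m <- length(zds)
  breg <- max(8L, min(32L, as.integer(n / 40)))
  zb <- lapply(zds, function(d) .col_bins(d, breg)$bin)
  vals <- lapply(ds, `[[`, "x")
  V <- do.call(cbind, vals)
  for (it in 1:2) {
    for (b in zb) {
      mu <- rowsum(V, b, reorder = TRUE) / tabulate(b)
      V <- V - mu[b, , drop = FALSE]
    }
  }
  zc <- .z_code(zds, .bz_rule(n, m), n)$code
  mu <- rowsum(V, zc, reorder = TRUE) / tabulate(zc)
  V <- V - mu[zc, , drop = FALSE]
  lapply(seq_len(ncol(V)), function(j) .col_desc(V[, j], FALSE))
}

.pen_cmi_group_at <- function(xds, yds, z, n, alpha) {
  xgrids <- lapply(xds, function(d) if (d$cat) 0L else c(2L, 3L, 5L))
  ygrids <- lapply(yds, function(d) if (d$cat) 0L else
    (if (length(yds) > 2L) c(1L, 2L) else c(1L, 2L, 3L)))
  xcombos <- expand.grid(xgrids, KEEP.OUT.ATTRS = FALSE)
  ycombos <- expand.grid(ygrids, KEEP.OUT.ATTRS = FALSE)
  best_pen <- -Inf
  best_raw <- 0
  tried <- FALSE
  for (i in seq_len(nrow(xcombos))) {
    xb <- .group_code(xds, as.integer(xcombos[i, ]), n)
    if (xb$nc < 2L) next
    for (j in seq_len(nrow(ycombos))) {
      yb <- .group_code(yds, as.integer(ycombos[j, ]), n)
      if (yb$nc < 2L) next
      if (tried && xb$nc * yb$nc * z$nc > n / 4) next
      tried <- TRUE
      cm <- .cmi_counts(xb$code, xb$nc, yb$code, yb$nc, z$code, z$nc, n)
      k <- .chisq_penalty(cm$df, alpha)
      pen <- cm$nI - k
      raw <- cm$nI / n - cm$df / (2 * n)
      if (pen > best_pen) best_pen <- pen
      if (raw > best_raw) best_raw <- raw
    }
  }
  if (!is.finite(best_pen)) best_pen <- 0
  list(pen = best_pen, raw = max(0, best_raw))
}

.group_code <- function(ds, Bs, n) {
  keep <- which(Bs != 1L | vapply(ds, `[[`, TRUE, "cat"))
  if (!length(keep)) return(list(code = rep.int(1L, n), nc = 1L))
  bl <- lapply(keep, function(j) .col_bins(ds[[j]], Bs[j]))
  .combine_codes(lapply(bl, `[[`, "bin"), vapply(bl, `[[`, 1L, "nb"), n)
}
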