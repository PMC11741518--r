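# Optimal assignment (Hungarian / Jonker-Volgenant shortest augmenting
# paths).  Used to link cell detections across frames at globally minimal
# cost; forbidden pairings carry an infinite cost and unmatched objects are
# absorbed by zero-cost dummy rows/columns.

.LAP_INF <- 1e30

# square LAP, minimizing; returns for each row its assigned column
.solve_lap_square <- function(C) {
  n <- nrow(C)
  if (n == 0L) return(integer(0))
  u <- numeric(n); v <- numeric(n + 1L)
  p <- integer(n + 1L)        # p[j]: row assigned to column j-1 (p[1] virtual)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(.LAP_INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cols <- which(!used)
      cur <- C[i0, cols - 1L] - u[i0] - v[cols]
      upd <- cur < minv[cols]
      if (any(upd)) {
        minv[cols[upd]] <- cur[upd]
        way[cols[upd]] <- j0
      }
      j1 <- cols[which.min(minv[cols])]
      delta <- minv[j1]
      usel <- which(used)
      u[p[usel]] <- u[p[usel]] + delta
      v[usel] <- v[usel] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ass <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) ass[p[j]] <- j - 1L
  ass
}

#' Solve an assignment problem with optional rejection
#'
#' Minimizes the total cost of a (possibly rectangular) assignment.
#' Entries of `Inf` are forbidden pairings; any row or column may stay
#' unassigned at `reject_cost`.
#'
#' @param cost Numeric cost matrix (rows: e.g. existing tracks; columns:
#'   e.g. new detections).
#' @param reject_cost Cost of leaving a row/column unmatched.
#' @return An integer vector of length `nrow(cost)`: the column assigned to
#'   each row, or `NA` for unassigned rows.
#' @export
solve_assignment <- function(cost, reject_cost = 0) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L) return(integer(0))
  if (nc == 0L) return(rep(NA_integer_, nr))
  n <- nr + nc
  C <- matrix(.LAP_INF, n, n)
  Cin <- cost
  Cin[!is.finite(Cin)] <- .LAP_INF
  C[seq_len(nr), seq_len(nc)] <- Cin
  for (i in seq_len(nr)) C[i, nc + i] <- reject_cost   # row rejection
  for (j in seq_len(nc)) C[nr + j, j] <- reject_cost   # column rejection
  C[nr + seq_len(nc), nc + seq_len(nr)] <- 0           # dummy-dummy
  ass <- .solve_lap_square(C)
  out <- ass[seq_len(nr)]
  out[out > nc] <- NA_integer_
  out
}
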