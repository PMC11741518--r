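#' Choose the maximum lag and layer spacing from the data
#'
#' The relaxation time of each (non-contextual, non-categorical) variable is
#' the smallest lag at which its autocorrelation drops below 1/e, averaged
#' over trajectories.  The maximum lag tau is set to twice the mean
#' relaxation time over variables, so that the lag window has little effect
#' on the learned graph; the layer spacing is
#' `delta_tau = max(1, round(tau / target_layers))` and tau is snapped down
#' to a multiple of `delta_tau`.
#'
#' Variables whose autocorrelation never crosses 1/e within half the series
#' length are flagged as nonstationary and excluded from the mean.
#'
#' @param dataset A [time_series_dataset()].
#' @param target_layers Desired number of lagged layers (default 12).
#' @return A list with `tau`, `delta_tau`, per-variable `relaxation` and
#'   the names of `nonstationary` (excluded) variables.
#' @export
estimate_tau <- function(dataset, target_layers = 12L) {
  stopifnot(inherits(dataset, "ts_dataset"))
  idx <- .traj_split(dataset)
  usable <- names(dataset$specs)[vapply(dataset$specs, function(sp) {
    sp$kind == "continuous" ||
      (sp$kind == "categorical" && !is.na(sp$n_levels) && sp$n_levels == 2L)
  }, TRUE)]
  if (!length(usable) || max(lengths(idx)) < 50L)
    stop("need at least one non-contextual variable with >= 50 time steps")
  relax <- rep(NA_real_, length(usable))
  names(relax) <- usable
  for (v in usable) {
    per_traj <- vapply(idx, function(ii) {
      x <- as.numeric(dataset$data[[v]][ii])
      Tn <- length(x)
      if (Tn < 50L || stats::sd(x) == 0) return(NA_real_)
      lag_max <- floor(Tn / 2)
      ac <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
      hit <- which(ac < exp(-1))
      if (!length(hit)) return(Inf)   # no crossing: nonstationary signal
      hit[1L]
    }, 0)
    per_traj <- per_traj[!is.na(per_traj)]
    if (length(per_traj)) relax[v] <- mean(per_traj)
  }
  nonstat <- names(relax)[!is.finite(relax)]
  ok <- relax[is.finite(relax)]
  if (!length(ok))
    stop("no variable with a finite relaxation time; ",
         "set tau manually (all variables look nonstationary)")
  tau <- max(1L, as.integer(round(2 * mean(ok))))
  delta_tau <- max(1L, as.integer(round(tau / target_layers)))
  tau <- max(delta_tau, (tau %/% delta_tau) * delta_tau)
  list(tau = tau, delta_tau = delta_tau, relaxation = relax,
       nonstationary = nonstat)
}
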