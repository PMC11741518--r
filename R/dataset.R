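#' Describe a variable for information estimation
#'
#' @param name Variable name.
#' @param kind One of `"continuous"`, `"categorical"`, `"contextual"`.
#'   Contextual variables are time-invariant experimental conditions
#'   (treated as categorical and constant within a trajectory).
#' @param n_levels Number of levels (categorical/contextual only).
#' @return An object of class `"variable_spec"`.
#' @export
variable_spec <- function(name, kind = c("continuous", "categorical", "contextual"),
                          n_levels = NA_integer_) {
  kind <- match.arg(kind)
  structure(list(name = as.character(name), kind = kind,
                 n_levels = as.integer(n_levels)),
            class = "variable_spec")
}

# heuristic spec inference from a vector
.infer_spec <- function(x, name = "x") {
  if (is.factor(x) || is.character(x) || is.logical(x)) {
    variable_spec(name, "categorical", length(unique(x)))
  } else {
    u <- unique(x)
    if (length(u) <= min(10, max(2, floor(sqrt(length(x))))) &&
        all(u == round(u))) {
      variable_spec(name, "categorical", length(u))
    } else {
      variable_spec(name, "continuous")
    }
  }
}

.spec_is_cat <- function(spec) spec$kind %in% c("categorical", "contextual")

#' Assemble a multivariate time-series dataset
#'
#' Wraps a data frame of observations ordered in time into the container
#' consumed by [chronet()] and [transfer_entropy()].  Rows are time steps;
#' a trajectory-identifier column separates independent recordings (e.g.,
#' one tracked cell per trajectory).  Contextual columns hold time-invariant
#' experimental conditions (treatment, co-culture presence, ...) and are
#' checked to be constant within each trajectory.
#'
#' @param data A data frame; rows must be consecutive time steps within each
#'   trajectory.
#' @param trajectory Name of the trajectory-id column, or `NULL` for a single
#'   trajectory.
#' @param contextual Character vector of contextual column names.
#' @param kinds Optional named character vector overriding the inferred
#'   variable kinds (`"continuous"` or `"categorical"`).
#' @return An object of class `"ts_dataset"`.
#' @export
time_series_dataset <- function(data, trajectory = NULL,
                                contextual = character(), kinds = NULL) {
  data <- as.data.frame(data)
  if (!is.null(trajectory)) {
    if (!trajectory %in% names(data))
      stop("trajectory column '", trajectory, "' not found")
    id <- data[[trajectory]]
    data[[trajectory]] <- NULL
  } else {
    id <- rep.int(1L, nrow(data))
  }
  if (anyNA(data)) stop("missing values are not supported")
  bad <- setdiff(contextual, names(data))
  if (length(bad)) stop("unknown contextual column(s): ",
                        paste(bad, collapse = ", "))
  specs <- lapply(names(data), function(v) {
    if (v %in% contextual) {
      sp <- variable_spec(v, "contextual", length(unique(data[[v]])))
    } else if (!is.null(kinds) && v %in% names(kinds)) {
      sp <- variable_spec(v, kinds[[v]],
                          if (kinds[[v]] == "continuous") NA_integer_
                          else length(unique(data[[v]])))
    } else {
      sp <- .infer_spec(data[[v]], v)
    }
    sp
  })
  names(specs) <- names(data)
  for (v in contextual) {
    if (any(tapply(data[[v]], id, function(u) length(unique(u))) > 1L))
      stop("contextual variable '", v, "' varies within a trajectory")
  }
  structure(list(data = data, trajectory = id, specs = specs),
            class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  nk <- table(vapply(x$specs, `[[`, "", "kind"))
  cat("Time-series dataset: ", nrow(x$data), " time steps, ",
      length(unique(x$trajectory)), " trajectory(ies)\n", sep = "")
  cat("Variables:", paste(sprintf("%s (%d)", names(nk), nk), collapse = ", "),
      "\n")
  invisible(x)
}

.traj_split <- function(ds) {
  split(seq_len(nrow(ds$data)), factor(ds$trajectory,
                                       levels = unique(ds$trajectory)))
}
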