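# File I/O: time-series CSV (trajectory id + contextual columns), summary
# graph and ground-truth TSV edge lists, unfolded-graph TSV export, and
# multi-page TIFF image stacks.

#' Read a multivariate time-series CSV
#'
#' @param path CSV file; rows are time steps ordered within trajectory.
#' @param trajectory Name of the trajectory-id column (`NULL` for one
#'   trajectory).
#' @param contextual Character vector of contextual condition columns.
#' @param kinds Optional named kind overrides (see
#'   [time_series_dataset()]).
#' @return A [time_series_dataset()].
#' @export
read_time_series_csv <- function(path, trajectory = NULL,
                                 contextual = character(), kinds = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c(trajectory, contextual), names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  time_series_dataset(df, trajectory = trajectory, contextual = contextual,
                      kinds = kinds)
}

#' Write a time-series dataset to CSV
#'
#' @param dataset A [time_series_dataset()].
#' @param path Output file.
#' @param trajectory Name for the trajectory-id column.
#' @export
write_time_series_csv <- function(dataset, path, trajectory = "trajectory") {
  stopifnot(inherits(dataset, "ts_dataset"))
  df <- cbind(stats::setNames(data.frame(dataset$trajectory), trajectory),
              dataset$data)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a summary graph as a TSV edge list
#'
#' Columns: `source`, `target`, `lag_ts`, `orientation`, `sign`,
#' `confidence`.  The round trip is lossless.
#'
#' @param sg A `"summary_graph"`.
#' @param path TSV file.
#' @export
write_summary_tsv <- function(sg, path) {
  utils::write.table(as.data.frame(sg), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "lag_ts", "orientation", "sign",
            "confidence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed summary TSV, missing column(s): ",
         paste(miss, collapse = ", "))
  df$confidence <- as.numeric(df$confidence)
  structure(df[need], class = c("summary_graph", "data.frame"))
}

#' Write / read a ground-truth network as a TSV edge list
#'
#' Columns: `source`, `target`, `lag`, `weight`, `form`.
#'
#' @param network A `"benchmark_network"`.
#' @param path TSV file.
#' @export
write_ground_truth_tsv <- function(network, path) {
  stopifnot(inherits(network, "benchmark_network"))
  utils::write.table(network$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth_tsv
#' @param n_nodes Number of nodes (inferred from the variable names when
#'   `NULL`).
#' @export
read_ground_truth_tsv <- function(path, n_nodes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "lag", "weight", "form")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed ground-truth TSV, missing column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(n_nodes)) {
    ids <- suppressWarnings(as.integer(sub("^X", "",
                                           c(df$source, df$target))))
    n_nodes <- if (all(!is.na(ids))) max(ids)
    else length(unique(c(df$source, df$target)))
  }
  .new_benchmark_network(n_nodes, df[need])
}

#' Export a time-unfolded graph as a TSV edge list
#'
#' Node identifiers have the form `var@-lag` (e.g. `"area@-7"` is the area
#' 7 time steps in the past).
#'
#' @param g A `"tug"`.
#' @param path TSV file.
#' @export
write_unfolded_tsv <- function(g, path) {
  stopifnot(inherits(g, "tug"))
  e <- g$edges
  out <- data.frame(node_a = .node_id(e$a_var, e$a_lag),
                    node_b = .node_id(e$b_var, e$b_lag),
                    mark_a = e$mark_a, mark_b = e$mark_b,
                    penalized = e$penalized, confidence = e$confidence)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a grayscale image stack as multi-page TIFF
#'
#' @param path TIFF file.
#' @return A list of numeric matrices in `[0, 1]`.
#' @export
read_tiff_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(im) {
    if (length(dim(im)) == 3L) im <- im[, , 1L]
    im
  })
}

#' @rdname read_tiff_stack
#' @param stack A list of numeric matrices (or 3-D array) in `[0, 1]`.
#' @export
write_tiff_stack <- function(stack, path) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3L]), function(k) stack[, , k])
  tiff::writeTIFF(stack, path)
  invisible(path)
}

#' Write / read an extracted feature table as CSV
#'
#' @param features A data frame from [extract_feature_table()].
#' @param path CSV file.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
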