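#' Read a long-format event table into event series
#'
#' Expects a UTF-8 CSV with header `learner_id, task_index,
#' completion_time_days`. Malformed content is reported with the offending
#' rows: missing columns, duplicate (learner, task) pairs, non-finite or
#' negative times.
#'
#' @param path CSV path.
#' @param n_total_tasks Total available tasks; defaults to the maximum
#'   observed task index.
#' @return Named list of `event_series`, ordered by learner id.
#' @examples
#' f <- system.file("extdata", "example_events.csv", package = "tempoclust")
#' read_events(f)
#' @export
read_events <- function(path, n_total_tasks = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("learner_id", "task_index", "completion_time_days")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(tab$completion_time_days) |
                 tab$completion_time_days < 0)
  if (length(bad))
    stop("negative or non-numeric completion times at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(tab$learner_id, tab$task_index)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (learner, task) row(s) at data row(s) ",
         paste(utils::head(dup, 5), collapse = ", "),
         " (e.g. ", key[dup[1]], ")")
  if (is.null(n_total_tasks)) n_total_tasks <- max(tab$task_index)
  out <- as_event_series(tab, n_total_tasks = n_total_tasks)
  out[order(names(out))]
}

#' Write event series (or a cohort table) as a long-format CSV
#'
#' @param x Named list of `event_series`, or a `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  if (inherits(x, "cohort_table")) {
    tab <- x$events
  } else {
    tab <- do.call(rbind, lapply(x, function(s) {
      data.frame(learner_id = s$learner_id,
                 task_index = seq_along(s$times),
                 completion_time_days = s$times,
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground-truth labels as a two-column CSV
#' @param labels Named vector (learner_id -> label).
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(learner_id = names(labels),
                              label = unname(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a per-day click-count series into an event series
#'
#' Interaction logs from some learning platforms record page clicks
#' coarse-grained to days rather than task completions. Each click becomes
#' one pseudo-event at its day, so the identical downstream pipeline
#' (DTW kernel, graph, multiscale clustering) applies unchanged.
#'
#' @param counts Nonnegative integer click counts.
#' @param days Day of each count (defaults to `0, 1, 2, ...`).
#' @param learner_id Identifier.
#' @return `event_series` (empty, with a warning, if all counts are zero).
#' @export
clicks_to_trajectory <- function(counts, days = seq_along(counts) - 1,
                                 learner_id = "learner") {
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("`counts` must be nonnegative integers")
  if (length(days) != length(counts)) stop("`days` must match `counts`")
  times <- rep(days, counts)
  if (length(times) == 0L)
    warning("all-zero click counts for ", learner_id, ": empty series")
  event_series(learner_id, times, n_total_tasks = max(length(times), 1L))
}

#' Write a square matrix as CSV with id header row/column
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a square matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Export a learner graph as GraphML and an edge-list CSV
#'
#' @param graph `learner_graph`.
#' @param graphml_path Optional GraphML output (node attribute
#'   `learner_id`, edge attribute `weight`).
#' @param edgelist_path Optional 3-column CSV (source, target, weight).
#' @export
write_graph_files <- function(graph, graphml_path = NULL,
                              edgelist_path = NULL) {
  a <- graph$adjacency
  dimnames(a) <- list(graph$ids, graph$ids)
  g <- igraph::graph_from_adjacency_matrix(a, weighted = TRUE,
                                           mode = "undirected")
  igraph::V(g)$learner_id <- graph$ids
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el) <- c("source", "target", "weight")
    utils::write.csv(el, edgelist_path, row.names = FALSE, quote = FALSE)
  }
  invisible(graph)
}
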