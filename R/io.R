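# Delimited-text readers and writers binding the pipeline stages together.

#' Read parcel time series from delimited text
#'
#' One column per parcel, one row per volume, header row of parcel labels.
#'
#' @param path File path (tab- or whitespace-delimited).
#' @param tr Repetition time in seconds (from the sidecar configuration).
#' @param ... Passed to [parcel_ts()] (`subject`, `condition`, `run`).
#' @return A [parcel_ts()].
#' @export
read_parcel_ts <- function(path, tr, ...) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  parcel_ts(as.matrix(tab), tr = tr, parcel_ids = colnames(tab), ...)
}

#' Read a task events table
#'
#' Three-column delimited text with header: `onset`, `duration`,
#' `trial_type` (the sidecar-events convention).
#'
#' @param path File path.
#' @return A validated events data frame.
#' @export
read_events <- function(path) {
  events_table(utils::read.table(path, header = TRUE,
                                 stringsAsFactors = FALSE))
}

#' Read a behavior table
#'
#' Delimited text with header: `subject`, `task`, `condition`, `accuracy`
#' (percent correct, 0-100), `reaction_time` (ms).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_behavior <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("subject", "task", "condition", "accuracy", "reaction_time")
  if (!all(need %in% names(tab)))
    stop("behavior table must have columns: ", paste(need, collapse = ", "))
  bad <- !is.na(tab$accuracy) & (tab$accuracy < 0 | tab$accuracy > 100)
  if (any(bad)) stop("accuracy outside [0, 100] for ", sum(bad), " row(s)")
  tab
}

#' Read parcel centroid coordinates for spin tests
#'
#' Delimited text with header: `parcel_id`, `x`, `y`, `z`, `hemisphere`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_coordinates <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("parcel_id", "x", "y", "z", "hemisphere")
  if (!all(need %in% names(tab)))
    stop("coordinates table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Write a covariance or correlation matrix as delimited text
#'
#' @param m Matrix.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
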