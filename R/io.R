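# Plain-text interchange: trace CSV with a YAML metadata/ground-truth
# sidecar, visit-log CSV, and firing-record / summary tables.

#' Write a trace to CSV with a YAML sidecar
#'
#' The CSV has two headered columns, `time_s` and `voltage_mv`; metadata and
#' any synthetic ground truth go to `<path>.yaml`.
#'
#' @param trace A [grn_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "grn_trace"))
  n <- length(trace$samples)
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / trace$sample_rate,
                              voltage_mv = trace$samples),
                   path, row.names = FALSE)
  meta <- list(sample_rate = trace$sample_rate, bee_id = trace$bee_id,
               sensillum_id = trace$sensillum_id, location = trace$location,
               stimulus = trace$stimulus)
  if (!is.null(trace$truth)) {
    meta$truth <- list(
      spike_times = as.numeric(trace$truth$spike_times),
      artifact_times = as.numeric(trace$truth$artifacts$time),
      artifact_types = as.character(trace$truth$artifacts$type))
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a trace CSV (and its YAML sidecar if present)
#'
#' @param path Path to a CSV written by [write_trace_csv()] (or any
#'   two-column `time_s,voltage_mv` file).
#' @return A [grn_trace()].
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "voltage_mv") %in% names(d)))
  sr <- if (nrow(d) > 1) 1 / stats::median(diff(d$time_s)) else 30000
  meta <- list()
  side <- paste0(path, ".yaml")
  if (file.exists(side)) meta <- yaml::read_yaml(side)
  if (!is.null(meta$sample_rate)) sr <- meta$sample_rate
  truth <- NULL
  if (!is.null(meta$truth)) {
    truth <- list(
      spike_times = as.numeric(meta$truth$spike_times),
      artifacts = data.frame(
        time = as.numeric(meta$truth$artifact_times),
        type = as.character(meta$truth$artifact_types)))
  }
  grn_trace(d$voltage_mv, sr,
            bee_id = meta$bee_id %||% NA_character_,
            sensillum_id = meta$sensillum_id %||% NA_character_,
            location = meta$location %||% "mid",
            stimulus = meta$stimulus %||% NA_character_,
            truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a visit-log CSV
#'
#' Headered CSV with columns bee_id, group, phase, bout, visit_index,
#' flower_class, probed, mouthpart_contact.
#'
#' @param visits A visit-log data frame.
#' @param path CSV path.
#' @return `path` invisibly (write) or the data frame (read).
#' @export
write_visit_log <- function(visits, path) {
  cols <- c("bee_id", "group", "phase", "bout", "visit_index",
            "flower_class", "probed", "mouthpart_contact")
  stopifnot(all(cols %in% names(visits)))
  utils::write.csv(visits[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_visit_log
#' @export
read_visit_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("bee_id", "group", "phase", "bout", "visit_index",
            "flower_class", "probed", "mouthpart_contact")
  if (!all(cols %in% names(d))) {
    stop(sprintf("visit log is missing columns: %s",
                 paste(setdiff(cols, names(d)), collapse = ", ")),
         call. = FALSE)
  }
  d
}
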