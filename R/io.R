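# Plain-text serialization: tidy CSV for traces (time_s, ch1..chK), JSON
# sidecars for labels/covariates, JSON lines for events.

#' Write / read a sensor trace
#'
#' The trace goes to a tidy CSV (`time_s`, `ch1` ... `chK`); labels and
#' covariates go to a JSON sidecar at `<path>.json`.
#'
#' @param trace a `sensor_trace`.
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` the
#'   restored `sensor_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  k <- nrow(trace$values)
  n <- ncol(trace$values)
  df <- data.frame(time_s = (seq_len(n) - 1L) / trace$sampling_rate)
  for (c in seq_len(k)) df[[paste0("ch", c)]] <- trace$values[c, ]
  write.csv(df, path, row.names = FALSE)
  sidecar <- list(sampling_rate = trace$sampling_rate,
                  severity_class = trace$severity_class,
                  labels = trace$labels, covariates = trace$covariates)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) {
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  } else {
    list()
  }
  rate <- side$sampling_rate
  if (is.null(rate)) {
    rate <- 1 / median(diff(df$time_s))
  }
  rate <- as.numeric(rate)
  values <- t(as.matrix(df[, grep("^ch", names(df)), drop = FALSE]))
  dimnames(values) <- NULL
  labels <- side$labels
  if (is.null(labels) || length(labels) == 0) {
    labels <- data.frame(start = integer(0), end = integer(0),
                         kind = character(0))
  }
  covariates <- side$covariates
  if (is.null(covariates) || length(covariates) == 0) {
    covariates <- data.frame(contact_area = numeric(0),
                             contact_points = integer(0),
                             pain_level = integer(0))
  }
  sev <- side$severity_class
  structure(
    list(values = values, sampling_rate = rate,
         labels = as.data.frame(labels),
         covariates = as.data.frame(covariates),
         severity_class = if (is.null(sev)) NA_integer_ else sev),
    class = "sensor_trace"
  )
}

#' Write / read a quantized count trace as integer CSV
#'
#' @param counts a `count_trace`.
#' @param path CSV file path; ADC metadata goes to `<path>.json`.
#' @return `write_count_trace` returns `path` invisibly.
#' @export
write_count_trace <- function(counts, path) {
  stopifnot(inherits(counts, "count_trace"))
  df <- as.data.frame(t(counts$counts))
  names(df) <- paste0("ch", seq_len(nrow(counts$counts)))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate = counts$sampling_rate,
         reference_voltage = counts$adc$reference_voltage,
         resolution_bits = counts$adc$resolution_bits),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_count_trace
#' @export
read_count_trace <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  counts <- t(as.matrix(df))
  dimnames(counts) <- NULL
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts,
         adc = adc_config(side$reference_voltage, side$resolution_bits),
         sampling_rate = as.numeric(side$sampling_rate)),
    class = "count_trace"
  )
}

#' Write detected events as JSON lines
#'
#' One JSON object per line with `start_s`, `end_s`, `duration_s`,
#' `mean_force` and per-channel peaks.
#'
#' @param events event data frame from [detect_events()].
#' @param sampling_rate Hz, to convert sample indices to seconds.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, sampling_rate, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  peak_cols <- grep("^peak\\.", names(events), value = TRUE)
  for (i in seq_len(nrow(events))) {
    rec <- list(start_s = (events$start[i] - 1) / sampling_rate,
                end_s = (events$end[i] - 1) / sampling_rate,
                duration_s = events$duration[i],
                mean_force = events$mean_force[i],
                peaks = as.numeric(events[i, peak_cols]))
    writeLines(jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE), con)
  }
  invisible(path)
}
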