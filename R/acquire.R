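#' ADC configuration
#'
#' Models the multichannel successive-approximation ADC on the splint's
#' microcontroller. The transfer constants (3.6 V reference, 1024 = 2^10
#' steps) follow the firmware coding equation `volts = counts * 3.6 / 1024`,
#' so the full-scale count is `2^resolution_bits` and 1024 counts decode to
#' exactly the reference voltage.
#'
#' @param reference_voltage full-scale reference in volts.
#' @param resolution_bits ADC resolution (>= 1).
#' @return An `adc_config` object with a `full_scale` count field.
#' @export
#' @examples
#' counts_to_voltage(1024, adc_config())  # 3.6 V
adc_config <- function(reference_voltage = 3.6, resolution_bits = 10L) {
  stopifnot_scalar(reference_voltage, "reference_voltage", positive = TRUE)
  stopifnot_scalar(resolution_bits, "resolution_bits", positive = TRUE)
  if (resolution_bits < 1) stop("`resolution_bits` must be >= 1", call. = FALSE)
  structure(
    list(reference_voltage = reference_voltage,
         resolution_bits = as.integer(resolution_bits),
         full_scale = as.integer(2^resolution_bits)),
    class = "adc_config"
  )
}

#' Quantize a voltage trace to ADC counts
#'
#' `count = clamp(floor(volts * 2^bits / reference), 0, 2^bits)`. Floor
#' quantization with clamping: out-of-range samples saturate at 0 or the
#' full-scale count instead of erroring, as the hardware does.
#'
#' @param trace a `sensor_trace` (or a bare numeric matrix/vector of volts).
#' @param adc an [adc_config()].
#' @return A `count_trace`: list with integer `counts` (channels x samples),
#'   `adc`, and `sampling_rate`.
#' @export
adc_encode <- function(trace, adc = adc_config()) {
  stopifnot(inherits(adc, "adc_config"))
  if (inherits(trace, "sensor_trace")) {
    values <- trace$values
    rate <- trace$sampling_rate
  } else {
    values <- rbind(trace)
    rate <- NA_real_
  }
  if (!all(is.finite(values))) {
    stop("trace contains non-finite values", call. = FALSE)
  }
  fs <- adc$full_scale
  counts <- floor(values * fs / adc$reference_voltage)
  counts[] <- pmin(fs, pmax(0, counts))
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, adc = adc, sampling_rate = rate),
    class = "count_trace"
  )
}

#' Decode ADC counts back to volts
#'
#' The firmware transfer equation: `volts = counts * reference / 2^bits`
#' (with the default 10-bit, 3.6 V configuration, `counts * 3.6 / 1024`).
#'
#' @param counts integer counts, or a `count_trace`.
#' @param adc an [adc_config()]; ignored when `counts` is a `count_trace`
#'   carrying its own.
#' @return Volts, same shape as the input counts.
#' @export
counts_to_voltage <- function(counts, adc = adc_config()) {
  if (inherits(counts, "count_trace")) {
    adc <- counts$adc
    counts <- counts$counts
  }
  stopifnot(inherits(adc, "adc_config"))
  if (any(counts < 0 | counts > adc$full_scale)) {
    stop("counts outside [0, full_scale]", call. = FALSE)
  }
  counts * adc$reference_voltage / 2^adc$resolution_bits
}

#' Detector configuration for the sleep/wake event state machine
#'
#' The splint sleeps until the occlusal force crosses a dentist-set
#' threshold. Debounce counts suppress the false positives the threshold
#' exists to avoid; a refractory gap merges bursts belonging to one
#' episode.
#'
#' @param threshold wake-up threshold in ADC counts.
#' @param debounce_on consecutive supra-threshold samples required to open
#'   an event.
#' @param debounce_off consecutive sub-threshold samples required to close
#'   it.
#' @param refractory minimum gap (samples) between distinct events; closer
#'   events are merged. 50 samples = 0.5 s at the default 100 Hz.
#' @param full_scale ADC full-scale count, bounding admissible thresholds.
#' @return A `detector_config` with an (initially empty) threshold audit
#'   log.
#' @export
detector_config <- function(threshold = 100L, debounce_on = 3L,
                            debounce_off = 3L, refractory = 50L,
                            full_scale = 1024L) {
  stopifnot_scalar(threshold, "threshold", nonneg = TRUE)
  stopifnot_scalar(debounce_on, "debounce_on", positive = TRUE)
  stopifnot_scalar(debounce_off, "debounce_off", positive = TRUE)
  stopifnot_scalar(refractory, "refractory", nonneg = TRUE)
  if (debounce_on < 1 || debounce_off < 1) {
    stop("debounce values must be >= 1", call. = FALSE)
  }
  if (threshold > full_scale) {
    stop("`threshold` must be <= `full_scale`", call. = FALSE)
  }
  structure(
    list(threshold = as.integer(threshold),
         debounce_on = as.integer(debounce_on),
         debounce_off = as.integer(debounce_off),
         refractory = as.integer(refractory),
         full_scale = as.integer(full_scale),
         log = data.frame(time = as.POSIXct(character(0)),
                          threshold = integer(0))),
    class = "detector_config"
  )
}

#' Detect occlusion events in a quantized trace
#'
#' Sleep/wake state machine over the across-channel maximum count (the
#' "resultant force"): the detector wakes after `debounce_on` consecutive
#' samples strictly above the threshold and sleeps again after
#' `debounce_off` consecutive samples at or below it; events separated by
#' fewer than `refractory` samples are merged. Events are returned in time
#' order and never overlap.
#'
#' Event bounds are 1-based with a half-open `end` (first sample after the
#' event), so `duration = (end - start) / sampling_rate` exactly.
#'
#' @param counts a `count_trace` from [adc_encode()].
#' @param cfg a [detector_config()].
#' @return Data frame with one row per event: `start`, `end`, `duration`
#'   (seconds, `NA` if the trace has no sampling rate), `mean_force` (mean
#'   across-channel-max count over the event), and `peak.1` ... `peak.K`
#'   per-channel peak counts.
#' @export
detect_events <- function(counts, cfg) {
  stopifnot(inherits(counts, "count_trace"), inherits(cfg, "detector_config"))
  x <- counts$counts
  if (length(x) == 0L) stop("empty count trace", call. = FALSE)
  k <- nrow(x)
  n <- ncol(x)
  empty <- empty_events(k)
  if (cfg$threshold >= counts$adc$full_scale) {
    warning("threshold at or above ADC full scale: detector can never fire",
            call. = FALSE)
    return(empty)
  }

  resultant <- if (k == 1L) as.numeric(x) else apply(x, 2, max)
  above <- resultant > cfg$threshold

  # Run-length pass is equivalent to the per-sample machine: any single
  # opposite sample resets the debounce counter, so only whole runs count.
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev_start <- integer(0)
  ev_end <- integer(0)
  state_active <- FALSE
  cur_start <- NA_integer_
  cur_end <- NA_integer_
  for (i in seq_along(r$lengths)) {
    if (!state_active) {
      if (r$values[i] && r$lengths[i] >= cfg$debounce_on) {
        state_active <- TRUE
        cur_start <- starts[i]
        cur_end <- ends[i]
      }
    } else {
      if (r$values[i]) {
        cur_end <- ends[i]
      } else if (r$lengths[i] >= cfg$debounce_off || i == length(r$lengths)) {
        ev_start <- c(ev_start, cur_start)
        ev_end <- c(ev_end, cur_end)
        state_active <- FALSE
      }
      # short sub-threshold run inside an event: stay active
    }
  }
  if (state_active) {
    ev_start <- c(ev_start, cur_start)
    ev_end <- c(ev_end, cur_end)
  }
  if (length(ev_start) == 0L) return(empty)

  # Merge events separated by fewer than `refractory` samples.
  if (cfg$refractory > 0 && length(ev_start) > 1L) {
    ms <- ev_start[1]
    me <- ev_end[1]
    out_s <- integer(0)
    out_e <- integer(0)
    for (i in seq_along(ev_start)[-1]) {
      if (ev_start[i] - me - 1L < cfg$refractory) {
        me <- ev_end[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- ev_start[i]; me <- ev_end[i]
      }
    }
    ev_start <- c(out_s, ms)
    ev_end <- c(out_e, me)
  }

  events <- data.frame(start = ev_start, end = ev_end + 1L)
  events$duration <- (events$end - events$start) / counts$sampling_rate
  events$mean_force <- vapply(seq_len(nrow(events)), function(i) {
    mean(resultant[events$start[i]:(events$end[i] - 1L)])
  }, numeric(1))
  for (c in seq_len(k)) {
    events[[paste0("peak.", c)]] <- vapply(seq_len(nrow(events)), function(i) {
      max(x[c, events$start[i]:(events$end[i] - 1L)])
    }, numeric(1))
  }
  events
}

empty_events <- function(k) {
  out <- data.frame(start = integer(0), end = integer(0),
                    duration = numeric(0), mean_force = numeric(0))
  for (c in seq_len(k)) out[[paste0("peak.", c)]] <- numeric(0)
  out
}

#' Remotely reset the detector threshold
#'
#' Mirrors the dentist's remote threshold update during biofeedback: the
#' new value is validated against the ADC full scale and the change is
#' appended to the config's audit log with a timestamp.
#'
#' @param cfg a [detector_config()].
#' @param new_threshold new threshold in counts, in `[0, full_scale]`.
#' @param time timestamp for the audit log (defaults to `Sys.time()`).
#' @return The updated `detector_config`.
#' @export
update_threshold <- function(cfg, new_threshold, time = Sys.time()) {
  stopifnot(inherits(cfg, "detector_config"))
  if (!is.numeric(new_threshold) || length(new_threshold) != 1L ||
      is.na(new_threshold) || new_threshold < 0 ||
      new_threshold > cfg$full_scale) {
    stop(sprintf("new threshold must lie in [0, %d]", cfg$full_scale),
         call. = FALSE)
  }
  cfg$threshold <- as.integer(new_threshold)
  cfg$log <- rbind(cfg$log,
                   data.frame(time = time, threshold = cfg$threshold))
  cfg
}
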