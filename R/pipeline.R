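#' Pipeline configuration
#'
#' Bundles the stage configurations of a full monitoring session:
#' denoising, ADC coding, event detection, windowed statistics, feature
#' framing and (optionally) grading with a trained model.
#'
#' @param adc an [adc_config()].
#' @param detector a [detector_config()].
#' @param wavelet a [wavelet_config()], or `NULL` to skip denoising.
#' @param window monitoring window in seconds.
#' @param model a `bruxnet_model`, a checkpoint path, or `NULL` (the
#'   report then stops at the feature stage with a warning).
#' @param denoise_domain `"analog"` (default) denoises the voltage signal
#'   before ADC coding; `"digital"` denoises the decoded counts after.
#' @param block_length temporal frames per network input block.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(adc = adc_config(),
                            detector = detector_config(),
                            wavelet = wavelet_config(),
                            window = 60,
                            model = NULL,
                            denoise_domain = c("analog", "digital"),
                            block_length = 128L) {
  denoise_domain <- match.arg(denoise_domain)
  stopifnot(inherits(adc, "adc_config"), inherits(detector, "detector_config"))
  if (!is.null(wavelet)) stopifnot(inherits(wavelet, "wavelet_config"))
  stopifnot_scalar(window, "window", positive = TRUE)
  if (is.character(model)) model <- load_checkpoint(model)
  if (!is.null(model)) stopifnot(inherits(model, "bruxnet_model"))
  structure(
    list(adc = adc, detector = detector, wavelet = wavelet, window = window,
         model = model, denoise_domain = denoise_domain,
         block_length = as.integer(block_length)),
    class = "pipeline_config"
  )
}

#' Run a full monitoring session
#'
#' Executes the biofeedback analysis chain on one recording:
#' denoise -> ADC encode -> detect events -> window statistics ->
#' feature vectors -> input block -> adjustment-level prediction.
#' Detected events are matched to the trace's labeled episodes (by
#' overlap, in time order) to pick up the per-episode covariates; events
#' with no matching episode get quiet-window default covariates.
#'
#' @param config a [pipeline_config()].
#' @param input a `sensor_trace` or a path readable by [read_trace()].
#' @return A `session_report`: list with `n_events`, `events`,
#'   `summaries`, `features`, `predicted_level` (`NULL` without a model),
#'   `threshold_history`, and `flags` (`quiet_windows`,
#'   `saturated_windows`).
#' @export
run_session <- function(config, input) {
  stopifnot(inherits(config, "pipeline_config"))
  trace <- if (inherits(input, "sensor_trace")) input else read_trace(input)

  if (!is.null(config$wavelet) && config$denoise_domain == "analog") {
    trace <- denoise_trace(trace, config$wavelet)
  }
  counts <- adc_encode(trace, config$adc)
  if (!is.null(config$wavelet) && config$denoise_domain == "digital") {
    volts <- counts_to_voltage(counts)
    den <- trace
    den$values <- volts
    den <- denoise_trace(den, config$wavelet)
    counts <- adc_encode(den, config$adc)
  }

  events <- detect_events(counts, config$detector)
  covariates <- covariates_for_events(events, trace)
  summaries <- window_statistics(counts, config$window)
  frames <- session_frames(counts, events, covariates, config$window)
  block <- frames_to_tensor(frames, length_out = config$block_length)

  predicted <- NULL
  if (is.null(config$model)) {
    warning("no model configured: report stops at the feature stage",
            call. = FALSE)
  } else {
    predicted <- predict_level(config$model, block)
  }

  quiet <- vapply(frames$features, function(f) isTRUE(f$quiet), logical(1))
  saturated <- vapply(summaries, function(s) {
    any(s$max >= counts$adc$full_scale)
  }, logical(1))

  structure(
    list(n_events = nrow(events),
         events = events,
         summaries = summaries_to_df(summaries),
         features = do.call(rbind, lapply(frames$features, function(f) {
           data.frame(mean_force_magnitude = f$mean_force_magnitude,
                      mean_force_duration = f$mean_force_duration,
                      mean_contact_area = f$mean_contact_area,
                      contact_points = f$contact_points,
                      pain_level = f$pain_level, quiet = f$quiet)
         })),
         predicted_level = predicted,
         threshold_history = config$detector$log,
         flags = list(quiet_windows = which(quiet),
                      saturated_windows = which(saturated))),
    class = "session_report"
  )
}

# Match detected events to labeled episodes by interval overlap (half-open
# bounds) and carry the episode covariates over; unmatched events get the
# neutral defaults of an unlabeled recording.
covariates_for_events <- function(events, trace) {
  n_ev <- nrow(events)
  out <- data.frame(contact_area = numeric(n_ev),
                    contact_points = integer(n_ev),
                    pain_level = integer(n_ev))
  labs <- trace$labels
  if (n_ev == 0L) return(out)
  for (i in seq_len(n_ev)) {
    hit <- which(labs$start < events$end[i] & labs$end > events$start[i])
    if (length(hit) > 0 && nrow(trace$covariates) >= max(hit)) {
      h <- hit[1]
      out$contact_area[i] <- trace$covariates$contact_area[h]
      out$contact_points[i] <- trace$covariates$contact_points[h]
      out$pain_level[i] <- trace$covariates$pain_level[h]
    }
  }
  out
}

#' Serialize a session report to JSON
#'
#' Fixed key order and full-precision numbers: re-running a session with
#' an identical config and seed writes a byte-identical file.
#'
#' @param report a `session_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_session_report <- function(report, path) {
  stopifnot(inherits(report, "session_report"))
  payload <- unclass(report)
  if (!is.null(payload$predicted_level)) {
    payload$predicted_level$probs <- as.numeric(payload$predicted_level$probs)
  }
  payload$threshold_history <- if (nrow(report$threshold_history) > 0) {
    data.frame(time = format(report$threshold_history$time,
                             "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
               threshold = report$threshold_history$threshold)
  } else {
    list()
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Read a session report back from JSON
#'
#' @param path JSON path written by [write_session_report()].
#' @return A `session_report` (data-frame fields restored).
#' @export
read_session_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$events <- as.data.frame(payload$events)
  payload$summaries <- as.data.frame(payload$summaries)
  payload$features <- as.data.frame(payload$features)
  structure(payload, class = "session_report")
}

#' Threshold feedback rule
#'
#' Declarative rule for the remote threshold-update loop: when the
#' session's event rate exceeds `trigger_rate` events/hour, raise the
#' detector threshold by `increment` counts (clamped to the ADC range
#' with a warning).
#'
#' @param trigger_rate events per hour above which the threshold is
#'   raised.
#' @param increment counts added per feedback step.
#' @return A `feedback_rule`.
#' @export
feedback_rule <- function(trigger_rate = 60, increment = 50L) {
  stopifnot_scalar(trigger_rate, "trigger_rate", nonneg = TRUE)
  structure(list(trigger_rate = trigger_rate,
                 increment = as.integer(increment)),
            class = "feedback_rule")
}

#' Apply one threshold feedback step
#'
#' Computes the session's event rate from the report and, when the rule
#' triggers, returns the detector config with the threshold raised via
#' [update_threshold()] (so the change lands in the audit log). Out of
#' range updates are clamped with a warning.
#'
#' @param report a `session_report`.
#' @param cfg the current [detector_config()].
#' @param rule a [feedback_rule()].
#' @param session_hours session length in hours used for the rate; when
#'   `NULL`, inferred from the report's summaries.
#' @param time audit-log timestamp.
#' @return The (possibly updated) `detector_config`.
#' @export
feedback_step <- function(report, cfg, rule = feedback_rule(),
                          session_hours = NULL, time = Sys.time()) {
  stopifnot(inherits(report, "session_report"),
            inherits(cfg, "detector_config"),
            inherits(rule, "feedback_rule"))
  if (is.null(session_hours)) {
    session_hours <- max(report$summaries$window_end) / 3600
  }
  rate <- report$n_events / session_hours
  if (rate <= rule$trigger_rate) return(cfg)
  target <- cfg$threshold + rule$increment
  if (target > cfg$full_scale) {
    warning("feedback rule clamped at ADC full scale", call. = FALSE)
    target <- cfg$full_scale
  }
  if (target < 0) {
    warning("feedback rule clamped at 0 counts", call. = FALSE)
    target <- 0L
  }
  update_threshold(cfg, target, time = time)
}
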