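#' Simulation parameters for a synthetic occlusal-force recording
#'
#' Describes one simulated wearing session of the sensor splint: six
#' piezoresistive channels by default, bite episodes arriving as a Poisson
#' process, each episode a smooth force pulse on top of a resting baseline
#' with additive Gaussian sensor noise.
#'
#' The three `severity_class` regimes (0 = mild, 1 = moderate, 2 = severe)
#' are ordered in both mean episode amplitude and episode rate, and drive
#' the per-episode covariates (occlusal contact area, number of contact
#' points, patient-reported pain on a 0-10 ordinal scale).
#'
#' @param n_channels number of sensor channels (>= 1).
#' @param sampling_rate sampling frequency in Hz. Bite-force dynamics live
#'   well below 50 Hz, so the 100 Hz default oversamples comfortably.
#' @param duration recording length in seconds.
#' @param episode_rate expected bite episodes per hour.
#' @param amplitude_range length-2 numeric, min/max episode peak amplitude
#'   in volts above baseline.
#' @param episode_duration_range length-2 numeric, min/max episode length in
#'   seconds.
#' @param noise_sigma additive Gaussian noise standard deviation in volts.
#' @param baseline resting sensor output in volts.
#' @param severity_class optional regime label in `{0, 1, 2}`. When given,
#'   `episode_rate` and `amplitude_range` default to the regime values and
#'   covariates are drawn from the regime means.
#' @param seed integer RNG seed; every stochastic draw is a deterministic
#'   function of it.
#'
#' @return An object of class `simulation_params`.
#' @export
#' @examples
#' p <- simulation_params(duration = 60, severity_class = 2, seed = 1)
#' p$episode_rate
simulation_params <- function(n_channels = 6L,
                              sampling_rate = 100,
                              duration = 300,
                              episode_rate = NULL,
                              amplitude_range = NULL,
                              episode_duration_range = c(1, 6),
                              noise_sigma = 0.05,
                              baseline = 0.2,
                              severity_class = NULL,
                              seed = 1L) {
  stopifnot_scalar(n_channels, "n_channels", positive = TRUE)
  if (n_channels < 1) stop("`n_channels` must be >= 1", call. = FALSE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(duration, "duration", nonneg = TRUE)
  stopifnot_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)
  stopifnot_scalar(baseline, "baseline", nonneg = TRUE)

  if (!is.null(severity_class)) {
    if (!severity_class %in% 0:2) {
      stop("`severity_class` must be 0, 1 or 2", call. = FALSE)
    }
    reg <- severity_regime(severity_class)
    if (is.null(episode_rate)) episode_rate <- reg$episode_rate
    if (is.null(amplitude_range)) amplitude_range <- reg$amplitude_range
  }
  if (is.null(episode_rate)) episode_rate <- 30
  if (is.null(amplitude_range)) amplitude_range <- c(0.5, 1.5)
  stopifnot_scalar(episode_rate, "episode_rate", nonneg = TRUE)
  if (length(amplitude_range) != 2L || amplitude_range[1] >= amplitude_range[2]) {
    stop("`amplitude_range` must be c(min, max) with min < max", call. = FALSE)
  }
  if (length(episode_duration_range) != 2L ||
      episode_duration_range[1] <= 0 ||
      episode_duration_range[1] > episode_duration_range[2]) {
    stop("`episode_duration_range` must be 0 < min <= max", call. = FALSE)
  }

  structure(
    list(
      n_channels = as.integer(n_channels),
      sampling_rate = sampling_rate,
      duration = duration,
      episode_rate = episode_rate,
      amplitude_range = amplitude_range,
      episode_duration_range = episode_duration_range,
      noise_sigma = noise_sigma,
      baseline = baseline,
      severity_class = if (is.null(severity_class)) NA_integer_ else as.integer(severity_class),
      seed = as.integer(seed)
    ),
    class = "simulation_params"
  )
}

# Severity regimes: ordered in mean amplitude AND rate (class 0 < 1 < 2).
# Amplitudes sit inside the 0..3.6 V ADC range with headroom; rates span
# mild background clenching to near-continuous severe bruxism.
severity_regime <- function(class) {
  switch(as.character(class),
    "0" = list(episode_rate = 20,  amplitude_range = c(0.4, 0.8),
               contact_area_mean = 20, contact_points_mean = 4, pain_mean = 1),
    "1" = list(episode_rate = 60,  amplitude_range = c(0.9, 1.6),
               contact_area_mean = 35, contact_points_mean = 7, pain_mean = 4),
    "2" = list(episode_rate = 120, amplitude_range = c(1.8, 3.0),
               contact_area_mean = 50, contact_points_mean = 10, pain_mean = 8),
    stop("unknown severity class ", class, call. = FALSE)
  )
}

#' Draw a non-overlapping bite-episode schedule
#'
#' Episode onsets follow a homogeneous Poisson process at
#' `params$episode_rate` events/hour, truncated to the recording; episodes
#' that would overlap an earlier one are dropped (a negligible thinning at
#' realistic rates). Each episode gets a duration, a peak amplitude per
#' channel, and a kind (`"clench"` or `"grind"`).
#'
#' @param params a [simulation_params()] object.
#' @return A data frame with one row per episode: `start`, `end` (sample
#'   indices, 1-based, `end` half-open = first sample after the episode),
#'   `kind`, and `peak.1` ... `peak.K` peak voltages above baseline per
#'   channel. Zero episodes gives a zero-row frame, not an error.
#' @export
schedule_episodes <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- round(params$duration * params$sampling_rate)
  empty <- data.frame(start = integer(0), end = integer(0),
                      kind = character(0))
  for (c in seq_len(params$n_channels)) empty[[paste0("peak.", c)]] <- numeric(0)
  if (n < 2L || params$episode_rate <= 0) return(empty)

  with_seed(params$seed, {
    n_cand <- rpois(1, params$episode_rate * params$duration / 3600)
    if (n_cand == 0L) return(empty)
    onset_s <- sort(runif(n_cand, 0, params$duration))
    dur_s <- runif(n_cand, params$episode_duration_range[1],
                   params$episode_duration_range[2])
    kind <- sample(c("clench", "grind"), n_cand, replace = TRUE)
    base_peak <- runif(n_cand, params$amplitude_range[1], params$amplitude_range[2])
    # Spatial spread of the bite across the arch: each sensor sees a
    # channel-specific fraction of the peak force.
    mult <- matrix(runif(n_cand * params$n_channels, 0.5, 1),
                   nrow = n_cand)

    start <- pmax(1L, pmin(n, as.integer(floor(onset_s * params$sampling_rate) + 1L)))
    end <- pmin(n + 1L, start + pmax(2L, as.integer(round(dur_s * params$sampling_rate))))
    keep <- logical(n_cand)
    last_end <- -Inf
    for (i in seq_len(n_cand)) {
      if (start[i] >= last_end && end[i] > start[i] + 1L) {
        keep[i] <- TRUE
        last_end <- end[i]
      }
    }
    out <- data.frame(start = start[keep], end = end[keep],
                      kind = kind[keep], stringsAsFactors = FALSE)
    pk <- base_peak[keep] * mult[keep, , drop = FALSE]
    for (c in seq_len(params$n_channels)) out[[paste0("peak.", c)]] <- pk[, c]
    out
  })
}

# Smooth unit-peak pulse envelope over m samples; grind episodes carry a
# slow amplitude modulation that still attains 1 at the apex.
episode_envelope <- function(m, kind, am_freq, sampling_rate) {
  s <- seq_len(m)
  env <- 0.5 * (1 - cos(2 * pi * (s - 0.5) / m))
  env <- env / max(env)
  if (kind == "grind") {
    apex <- which.max(env)
    t_rel <- (s - apex) / sampling_rate
    env <- env * (1 - 0.35 * (1 - cos(2 * pi * am_freq * t_rel)))
  }
  env
}

#' Render a schedule into a multichannel voltage trace
#'
#' Builds `baseline + pulses + noise` on each channel. Clench pulses are
#' raised-cosine force bumps; grind pulses add a 1-2 Hz amplitude
#' modulation emulating rhythmic grinding. Per-episode covariates (contact
#' area, contact points, pain level) are drawn from the severity regime
#' when `params$severity_class` is set.
#'
#' @param schedule data frame from [schedule_episodes()].
#' @param params the [simulation_params()] used to draw the schedule.
#' @return A `sensor_trace`: list with `values` (channels x samples volts),
#'   `sampling_rate`, `labels` (the schedule), `covariates` (one row per
#'   episode: `contact_area`, `contact_points`, `pain_level`).
#' @export
render_trace <- function(schedule, params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- round(params$duration * params$sampling_rate)
  k <- params$n_channels
  if (nrow(schedule) > 0 && max(schedule$end) > n + 1L) {
    stop("schedule extends beyond the trace duration", call. = FALSE)
  }

  with_seed(params$seed + 104729L, {
    values <- matrix(params$baseline, nrow = k, ncol = n)
    for (i in seq_len(nrow(schedule))) {
      s0 <- schedule$start[i]
      s1 <- schedule$end[i] - 1L
      m <- s1 - s0 + 1L
      am_freq <- runif(1, 1, 2)
      env <- episode_envelope(m, schedule$kind[i], am_freq, params$sampling_rate)
      for (c in seq_len(k)) {
        values[c, s0:s1] <- values[c, s0:s1] +
          schedule[[paste0("peak.", c)]][i] * env
      }
    }
    if (params$noise_sigma > 0) {
      values <- values + matrix(rnorm(k * n, 0, params$noise_sigma), nrow = k)
    }
    covariates <- draw_covariates(nrow(schedule), params)
    structure(
      list(values = values, sampling_rate = params$sampling_rate,
           labels = schedule, covariates = covariates,
           severity_class = params$severity_class),
      class = "sensor_trace"
    )
  })
}

# Linear-in-class covariate means with Gaussian jitter, clipped to valid
# ranges; pain is ordinal 0-10. Falls back to the moderate regime when no
# severity class is set.
draw_covariates <- function(n_episodes, params) {
  reg <- severity_regime(if (is.na(params$severity_class)) 1L else params$severity_class)
  if (n_episodes == 0L) {
    return(data.frame(contact_area = numeric(0), contact_points = integer(0),
                      pain_level = integer(0)))
  }
  data.frame(
    contact_area = pmax(1, rnorm(n_episodes, reg$contact_area_mean, 4)),
    contact_points = pmax(1L, as.integer(round(rnorm(n_episodes, reg$contact_points_mean, 1)))),
    pain_level = pmin(10L, pmax(0L, as.integer(round(rnorm(n_episodes, reg$pain_mean, 1)))))
  )
}

#' Simulate a complete trace in one call
#'
#' Convenience wrapper: [schedule_episodes()] then [render_trace()].
#'
#' @inheritParams schedule_episodes
#' @return A `sensor_trace`.
#' @export
simulate_trace <- function(params) {
  render_trace(schedule_episodes(params), params)
}

#' Generate a balanced labeled dataset of simulated sessions
#'
#' @param n_per_class traces per severity class.
#' @param params_by_class named list (`"0"`, `"1"`, `"2"`) of
#'   [simulation_params()]; the seed field of each is overridden by a
#'   per-trace seed derived from `seed`. All three classes must be present.
#' @param seed master seed.
#' @return List with `traces` (list of `sensor_trace`) and `classes`
#'   (integer vector of generating severity classes).
#' @export
generate_dataset <- function(n_per_class, params_by_class, seed = 1L) {
  classes <- c("0", "1", "2")
  missing <- setdiff(classes, names(params_by_class))
  if (length(missing) > 0) {
    stop("missing simulation parameters for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (n_per_class == 0L) {
    return(list(traces = list(), classes = integer(0)))
  }
  total <- 3L * n_per_class
  seeds <- derive_seeds(seed, total)
  traces <- vector("list", total)
  labels <- integer(total)
  i <- 0L
  for (cl in classes) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      p <- params_by_class[[cl]]
      p$seed <- seeds[i]
      traces[[i]] <- simulate_trace(p)
      labels[i] <- as.integer(cl)
    }
  }
  list(traces = traces, classes = labels)
}

#' Default per-class simulation parameters
#'
#' The stated world for dataset generation: three severity regimes sharing
#' sampling rate, duration, noise and baseline, differing in episode rate
#' and amplitude per [severity regimes][simulation_params()].
#'
#' @param duration seconds per session.
#' @param sampling_rate Hz.
#' @param noise_sigma volts.
#' @param ... passed on to [simulation_params()].
#' @return Named list of three [simulation_params()].
#' @export
default_class_params <- function(duration = 300, sampling_rate = 100,
                                 noise_sigma = 0.05, ...) {
  stats::setNames(lapply(0:2, function(cl) {
    simulation_params(duration = duration, sampling_rate = sampling_rate,
                      noise_sigma = noise_sigma, severity_class = cl, ...)
  }), c("0", "1", "2"))
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> %d channel(s) x %d samples @ %g Hz, %d labeled episode(s)\n",
              nrow(x$values), ncol(x$values), x$sampling_rate, nrow(x$labels)))
  invisible(x)
}
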