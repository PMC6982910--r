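#' Per-window monitoring statistics
#'
#' Splits a quantized trace into tumbling windows and computes, per
#' window, the six monitoring statistics kept for each channel over a
#' monitoring period: mean (AVG), maximum (MAX), minimum (MIN), standard
#' deviation (sigma), variance (psi), and the cross-channel covariance
#' matrix (phi). Population (1/n) normalization is used throughout, so
#' `variance == sd^2` and the covariance diagonal equals the per-channel
#' variance exactly.
#'
#' The final partial window is retained when it covers at least half the
#' window length, otherwise dropped.
#'
#' @param counts a `count_trace` from [adc_encode()].
#' @param window window length in seconds (must span >= 2 samples).
#' @return A list of `monitoring_summary` objects, each with fields `avg`,
#'   `max`, `min`, `sd`, `variance` (per-channel vectors), `covariance`
#'   (channels x channels matrix), `window_start`, `window_end` (seconds).
#' @export
window_statistics <- function(counts, window) {
  stopifnot(inherits(counts, "count_trace"))
  stopifnot_scalar(window, "window", positive = TRUE)
  x <- counts$counts
  n <- ncol(x)
  if (n == 0L) stop("empty count trace", call. = FALSE)
  rate <- counts$sampling_rate
  w <- round(window * rate)
  if (is.na(w) || w < 2) {
    stop("window must span at least 2 samples", call. = FALSE)
  }
  starts <- seq(1L, n, by = w)
  out <- list()
  for (s in starts) {
    e <- min(n, s + w - 1L)
    if (e - s + 1L < w && (e - s + 1L) < w / 2) next
    seg <- x[, s:e, drop = FALSE]
    m <- ncol(seg)
    mu <- rowMeans(seg)
    centered <- seg - mu
    cv <- tcrossprod(centered) / m
    vr <- diag(cv)
    out[[length(out) + 1L]] <- structure(
      list(avg = mu, max = apply(seg, 1, max), min = apply(seg, 1, min),
           sd = sqrt(vr), variance = vr, covariance = cv,
           window_start = (s - 1L) / rate, window_end = e / rate),
      class = "monitoring_summary"
    )
  }
  out
}

#' @export
print.monitoring_summary <- function(x, ...) {
  cat(sprintf("<monitoring_summary> [%.1f, %.1f) s, %d channel(s), mean avg %.2f counts\n",
              x$window_start, x$window_end, length(x$avg), mean(x$avg)))
  invisible(x)
}

#' Flatten monitoring summaries to a data frame
#'
#' One row per window per channel; the covariance matrix is flattened into
#' `cov.1` ... `cov.K` columns (that channel's row of phi).
#'
#' @param summaries list from [window_statistics()].
#' @return A data frame.
#' @export
summaries_to_df <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    k <- length(s$avg)
    df <- data.frame(window_start = s$window_start, window_end = s$window_end,
                     channel = seq_len(k), avg = s$avg, max = s$max,
                     min = s$min, sd = s$sd, variance = s$variance)
    cov_cols <- as.data.frame(s$covariance)
    names(cov_cols) <- paste0("cov.", seq_len(k))
    rownames(df) <- NULL
    cbind(df, cov_cols)
  }))
}

modal_value <- function(x) {
  if (length(x) == 0L) return(0L)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Assemble the five-element feature vector for one monitoring window
#'
#' The five network inputs per unit time: mean occlusal-force magnitude,
#' mean occlusal-force duration, mean contact area, (modal) number of
#' contact points, and the latest patient-reported pain level. Force and
#' duration come from detected events; contact area/points and pain come
#' from covariate records measured externally (occlusion paper / T-Scan /
#' patient feedback) and must be aligned one-to-one with the events.
#'
#' @param events event data frame from [detect_events()] (the events
#'   falling inside the window).
#' @param covariates data frame with one row per event: `contact_area`,
#'   `contact_points`, `pain_level`.
#' @param window window length in seconds (kept as framing metadata).
#' @param last_pain pain level carried forward for quiet windows.
#' @return A `feature_vector`: list with the five features, `window`, and
#'   a `quiet` flag set when the window held no events.
#' @export
build_feature_vector <- function(events, covariates, window = 60,
                                 last_pain = 0L) {
  n_ev <- nrow(events)
  if (n_ev != nrow(covariates)) {
    unmatched <- if (n_ev > nrow(covariates)) {
      paste("events", paste(seq_len(n_ev)[-seq_len(nrow(covariates))],
                            collapse = ", "))
    } else {
      paste("covariate rows", paste(seq_len(nrow(covariates))[-seq_len(max(n_ev, 0L))],
                                    collapse = ", "))
    }
    stop("covariates are not aligned to events; unmatched: ", unmatched,
         call. = FALSE)
  }
  if (n_ev == 0L) {
    return(structure(
      list(mean_force_magnitude = 0, mean_force_duration = 0,
           mean_contact_area = 0, contact_points = 0,
           pain_level = as.integer(last_pain), window = window,
           quiet = TRUE),
      class = "feature_vector"
    ))
  }
  structure(
    list(mean_force_magnitude = mean(events$mean_force),
         mean_force_duration = mean(events$duration),
         mean_contact_area = mean(covariates$contact_area),
         contact_points = modal_value(covariates$contact_points),
         pain_level = as.integer(tail(covariates$pain_level, 1L)),
         window = window,
         quiet = FALSE),
    class = "feature_vector"
  )
}

feature_values <- function(fv) {
  c(fv$mean_force_magnitude, fv$mean_force_duration, fv$mean_contact_area,
    fv$contact_points, fv$pain_level)
}

#' Build per-window frames for one session
#'
#' Walks the monitoring windows of a session, collecting for each window
#' the [build_feature_vector()] features of the events it contains and the
#' per-channel mean counts (the six sensors' mean forces). Detected events
#' are matched to covariate records by their order of occurrence.
#'
#' @param counts a `count_trace`.
#' @param events event data frame for the whole session.
#' @param covariates covariate records, one row per event (in event
#'   order).
#' @param window window length in seconds.
#' @return List with `features` (list of `feature_vector` per window) and
#'   `channel_means` (windows x channels matrix of mean counts).
#' @export
session_frames <- function(counts, events, covariates, window = 60) {
  stopifnot(inherits(counts, "count_trace"))
  if (nrow(events) != nrow(covariates)) {
    stop("covariates are not aligned to events (", nrow(events), " events, ",
         nrow(covariates), " covariate rows)", call. = FALSE)
  }
  n <- ncol(counts$counts)
  rate <- counts$sampling_rate
  w <- round(window * rate)
  if (w < 2) stop("window must span at least 2 samples", call. = FALSE)
  starts <- seq(1L, n, by = w)
  feats <- list()
  ch_means <- NULL
  last_pain <- 0L
  for (s in starts) {
    e <- min(n, s + w - 1L)
    if (e - s + 1L < w && (e - s + 1L) < w / 2) next
    # an event belongs to the window containing its start sample
    in_win <- which(events$start >= s & events$start <= e)
    fv <- build_feature_vector(events[in_win, , drop = FALSE],
                               covariates[in_win, , drop = FALSE],
                               window = window, last_pain = last_pain)
    last_pain <- fv$pain_level
    feats[[length(feats) + 1L]] <- fv
    ch_means <- rbind(ch_means, rowMeans(counts$counts[, s:e, drop = FALSE]))
  }
  list(features = feats, channel_means = ch_means)
}

#' Pack session frames into a fixed-size network input block
#'
#' The network consumes blocks of 16 channels x `length_out` frames:
#' channels 1-6 carry the per-sensor mean forces, channels 7-11 the five
#' feature values, channels 12-16 are zero padding up to the 16-channel
#' input width of the first convolution. Sessions shorter than
#' `length_out` frames are zero-padded at the end; longer sessions keep
#' the most recent `length_out` frames.
#'
#' @param frames output of [session_frames()].
#' @param scaler optional standardizer from [fit_block_scaler()]; applied
#'   per channel.
#' @param length_out temporal frames per block (network default 128).
#' @param n_sensor_channels sensor channels packed into rows 1-6.
#' @return A 16 x `length_out` numeric matrix.
#' @export
frames_to_tensor <- function(frames, scaler = NULL, length_out = 128L,
                             n_sensor_channels = 6L) {
  n_f <- length(frames$features)
  if (n_f < 1L) stop("need at least one frame", call. = FALSE)
  fmat <- vapply(frames$features, feature_values, numeric(5))  # 5 x n_f
  cmeans <- t(frames$channel_means)                            # K x n_f
  if (nrow(cmeans) > n_sensor_channels) {
    cmeans <- cmeans[seq_len(n_sensor_channels), , drop = FALSE]
  } else if (nrow(cmeans) < n_sensor_channels) {
    cmeans <- rbind(cmeans,
                    matrix(0, n_sensor_channels - nrow(cmeans), ncol(cmeans)))
  }
  block16 <- rbind(cmeans, fmat, matrix(0, 5, n_f))
  if (n_f >= length_out) {
    block16 <- block16[, (n_f - length_out + 1L):n_f, drop = FALSE]
  } else {
    block16 <- cbind(block16, matrix(0, 16, length_out - n_f))
  }
  if (!is.null(scaler)) block16 <- apply_block_scaler(block16, scaler)
  block16
}

#' Fit per-channel standardization statistics on a training set
#'
#' Computes per-channel mean and sd over all frames of all training
#' blocks. Channels with (near-)zero spread — e.g. the zero-padding
#' channels — get sd 1 so standardization leaves them untouched.
#'
#' @param blocks list of unstandardized 16 x L blocks.
#' @return A `block_scaler` with `mean` and `sd` vectors (length 16).
#' @export
fit_block_scaler <- function(blocks) {
  stopifnot(length(blocks) > 0)
  flat <- do.call(cbind, blocks)
  mu <- rowMeans(flat)
  sdv <- sqrt(rowMeans((flat - mu)^2))
  sdv[sdv < 1e-9] <- 1
  structure(list(mean = mu, sd = sdv), class = "block_scaler")
}

#' @rdname fit_block_scaler
#' @param block a 16 x L block to standardize.
#' @param scaler a `block_scaler`.
#' @export
apply_block_scaler <- function(block, scaler) {
  stopifnot(inherits(scaler, "block_scaler"))
  (block - scaler$mean) / scaler$sd
}
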