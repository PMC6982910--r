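#' Wavelet denoising configuration
#'
#' Parameters of the translation-invariant wavelet denoiser. The base
#' denoiser `T` applies a periodized discrete wavelet transform, soft- (or
#' hard-) thresholds every detail coefficient at the Donoho universal
#' threshold `lambda = sigma * sqrt(2 log n)`, and inverts the transform.
#' Cycle spinning averages `T` over circular shifts to remove the
#' shift-dependent artifacts of the decimated transform.
#'
#' @param family wavelet family (see [wavelet_filter()]).
#' @param decomposition_level levels of the DWT; `NULL` picks
#'   `min(4, max feasible for the signal length)` at call time.
#' @param threshold_mode `"soft"` (default) or `"hard"`.
#' @param sigma noise standard deviation in volts; `NULL` estimates it from
#'   the data via [estimate_sigma()].
#' @param n_shifts number of circular shifts for cycle spinning; values
#'   `>= n` mean the full shift set `0 .. n-1`. Default 32 evenly spaced
#'   shifts is a tractable stand-in for the full set.
#' @return A `wavelet_config`.
#' @export
wavelet_config <- function(family = "db4", decomposition_level = NULL,
                           threshold_mode = c("soft", "hard"),
                           sigma = NULL, n_shifts = 32L) {
  threshold_mode <- match.arg(threshold_mode)
  wavelet_filter(family)  # validate
  if (!is.null(decomposition_level)) {
    stopifnot_scalar(decomposition_level, "decomposition_level", positive = TRUE)
  }
  if (!is.null(sigma)) stopifnot_scalar(sigma, "sigma", nonneg = TRUE)
  stopifnot_scalar(n_shifts, "n_shifts", positive = TRUE)
  structure(
    list(family = family,
         decomposition_level = decomposition_level,
         threshold_mode = threshold_mode,
         sigma = sigma,
         n_shifts = as.integer(n_shifts)),
    class = "wavelet_config"
  )
}

resolve_level <- function(cfg, n) {
  feasible <- max_dwt_level(n)
  if (is.null(cfg$decomposition_level)) {
    lv <- min(4L, feasible)
    if (lv < 1L) {
      stop("signal length ", n, " admits no periodized DWT level ",
           "(length must be even)", call. = FALSE)
    }
    return(lv)
  }
  lv <- as.integer(cfg$decomposition_level)
  if (lv > feasible) {
    stop(sprintf(
      "decomposition level %d too deep for length %d: maximum feasible level is %d",
      lv, n, feasible), call. = FALSE)
  }
  lv
}

#' Estimate the noise standard deviation of a signal
#'
#' Robust estimate from the finest-scale wavelet detail coefficients:
#' `median(|d1|) / 0.6745`. The finest details of a smooth signal are
#' dominated by noise, so the estimate tracks the noise floor rather than
#' the signal's own variance. A constant signal gives 0.
#'
#' The details are computed by circular convolution with the highpass
#' filter *without* decimation, so the estimate is exactly invariant to
#' circular shifts of the signal — which keeps the cycle-spinning
#' estimator exactly shift-equivariant when `sigma` is estimated.
#'
#' @param signal numeric vector, length >= 4.
#' @param family wavelet family used for the finest-level transform.
#' @return Estimated noise sd, in the units of the signal.
#' @export
estimate_sigma <- function(signal, family = "db4") {
  if (length(signal) < 4L) stop("signal must have length >= 4", call. = FALSE)
  n <- length(signal)
  g <- highpass_of(wavelet_filter(family))
  d1 <- numeric(n)
  for (k in seq_along(g)) {
    idx <- (seq_len(n) - 1L + (k - 1L)) %% n + 1L
    d1 <- d1 + g[k] * signal[idx]
  }
  median(abs(d1)) / 0.6745
}

apply_threshold <- function(d, lambda, mode) {
  if (mode == "soft") {
    sign(d) * pmax(abs(d) - lambda, 0)
  } else {
    d * (abs(d) > lambda)
  }
}

#' Single-pass wavelet denoising (the base denoiser T)
#'
#' Forward periodized DWT, universal-threshold shrinkage of all detail
#' coefficients (single global `lambda = sigma * sqrt(2 log n)`), inverse
#' transform. Output length equals input length.
#'
#' @param signal numeric vector; length must be divisible by
#'   `2^decomposition_level` (periodized transform).
#' @param cfg a [wavelet_config()].
#' @return Denoised numeric vector.
#' @export
denoise_once <- function(signal, cfg = wavelet_config()) {
  stopifnot(inherits(cfg, "wavelet_config"))
  n <- length(signal)
  if (n < 2L) stop("signal too short to denoise", call. = FALSE)
  level <- resolve_level(cfg, n)
  h <- wavelet_filter(cfg$family)
  sigma <- if (is.null(cfg$sigma)) estimate_sigma(signal, cfg$family) else cfg$sigma
  lambda <- sigma * sqrt(2 * log(n))
  coeffs <- dwt_periodic(signal, h, level)
  coeffs$details <- lapply(coeffs$details, apply_threshold,
                           lambda = lambda, mode = cfg$threshold_mode)
  idwt_periodic(coeffs, h)
}

circ_shift <- function(x, h) {
  n <- length(x)
  h <- ((h %% n) + n) %% n
  if (h == 0) return(x)
  c(x[(h + 1):n], x[1:h])  # S_h(t) = X(t + h)
}

#' Translation-invariant (cycle-spinning) wavelet denoising
#'
#' The translation-invariant estimator averages the base denoiser over a
#' set of circular shifts:
#' `T_bar(x) = Ave_h [ unshift_h( T( shift_h(x) ) ) ]`.
#' With the full shift set `H_n = {0, ..., n-1}` the estimator commutes
#' exactly with circular shifts of the input and suppresses the
#' pseudo-Gibbs oscillations of the decimated transform near signal jumps.
#'
#' When `cfg$sigma` is `NULL` the noise level is estimated once from the
#' unshifted signal and shared across shifts (shifting does not change the
#' noise level, and a shared `lambda` keeps the estimator exactly
#' shift-equivariant).
#'
#' @inheritParams denoise_once
#' @return Denoised numeric vector, same length as the input.
#' @export
cycle_spin_denoise <- function(signal, cfg = wavelet_config()) {
  stopifnot(inherits(cfg, "wavelet_config"))
  n <- length(signal)
  if (cfg$n_shifts > n) {
    stop("n_shifts exceeds the signal length", call. = FALSE)
  }
  # Consecutive shifts 0 .. n_shifts-1: with n_shifts >= 2^level these
  # cover every residue class of the decimation grid. (Evenly *spaced*
  # shifts can all be multiples of 2^level, which merely permute the
  # periodized coefficients and spin nothing.)
  shifts <- 0:(min(cfg$n_shifts, n) - 1L)
  base_cfg <- cfg
  if (is.null(base_cfg$sigma)) {
    base_cfg$sigma <- estimate_sigma(signal, cfg$family)
  }
  acc <- numeric(n)
  for (h in shifts) {
    y <- denoise_once(circ_shift(signal, h), base_cfg)
    acc <- acc + circ_shift(y, -h)
  }
  acc / length(shifts)
}

#' Denoise every channel of a sensor trace
#'
#' Applies [cycle_spin_denoise()] channel-wise. Lengths not divisible by
#' `2^level` are symmetrically reflection-padded to the next multiple,
#' denoised, and cropped; this sacrifices exact shift equivariance at the
#' two boundaries in exchange for accepting arbitrary-length recordings.
#'
#' @param trace a `sensor_trace`.
#' @param cfg a [wavelet_config()].
#' @return A `sensor_trace` with denoised `values`.
#' @export
denoise_trace <- function(trace, cfg = wavelet_config()) {
  stopifnot(inherits(trace, "sensor_trace"))
  n <- ncol(trace$values)
  lv <- if (is.null(cfg$decomposition_level)) {
    min(4L, max(1L, floor(log2(max(n, 2))) - 2L))
  } else {
    as.integer(cfg$decomposition_level)
  }
  block <- 2L^lv
  pad <- (block - n %% block) %% block
  cfg$decomposition_level <- lv
  out <- trace
  for (c in seq_len(nrow(trace$values))) {
    x <- trace$values[c, ]
    if (pad > 0) {
      left <- pad %/% 2L
      right <- pad - left
      x <- c(rev(head(x, left)), x, rev(tail(x, right)))
    }
    y <- cycle_spin_denoise(x, cfg)
    if (pad > 0) y <- y[(pad %/% 2L + 1L):(pad %/% 2L + n)]
    out$values[c, ] <- y
  }
  out
}
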