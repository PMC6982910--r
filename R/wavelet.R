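# Orthonormal Daubechies filter banks and the periodized (circular)
# decimated DWT. Periodic boundary handling is what makes exact
# circular-shift equivariance of cycle spinning possible, so the
# transform is written for it from the start rather than by padding.

#' Wavelet analysis filters
#'
#' Returns the orthonormal scaling (lowpass) filter for a Daubechies
#' family member; the wavelet (highpass) filter is derived by quadrature
#' mirroring. Supported: `"haar"`, `"db2"` (4 taps), `"db4"` (8 taps,
#' default family of the denoiser).
#'
#' @param family wavelet family name.
#' @return Numeric vector of lowpass filter taps (unit norm, sum sqrt(2)).
#' @export
wavelet_filter <- function(family = "db4") {
  switch(family,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.2303778133088961, 0.7148465705529147, 0.6308807679298586,
            -0.0279837694168588, -0.1870348117190924, 0.0308413818355607,
            0.0328830116668851, -0.0105974017850690),
    stop("unsupported wavelet family: ", family, call. = FALSE)
  )
}

highpass_of <- function(h) {
  k <- length(h)
  rev(h) * (-1)^(seq_len(k) - 1)
}

# One analysis level of the periodized DWT.
#   a[i] = sum_k h[k] x[(2(i-1)+k-1) mod n + 1]
#   d[i] = sum_k g[k] x[(2(i-1)+k-1) mod n + 1]
# Requires even n; the transform matrix is orthogonal, so the inverse is
# the adjoint (scatter-add with the same filters).
dwt_level <- function(x, h) {
  n <- length(x)
  if (n %% 2L != 0L) stop("periodized DWT needs even length", call. = FALSE)
  g <- highpass_of(h)
  m <- n %/% 2L
  a <- numeric(m)
  d <- numeric(m)
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    a <- a + h[k] * x[idx]
    d <- d + g[k] * x[idx]
  }
  list(approx = a, detail = d)
}

idwt_level <- function(approx, detail, h) {
  g <- highpass_of(h)
  m <- length(approx)
  n <- 2L * m
  x <- numeric(n)
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    contrib <- h[k] * approx + g[k] * detail
    # scatter-add; idx values are distinct within one k
    x[idx] <- x[idx] + contrib
  }
  x
}

# Multi-level periodized DWT: list(approx, details = list(level1..levelL))
# where details[[1]] is the finest scale.
dwt_periodic <- function(x, h, level) {
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    res <- dwt_level(a, h)
    details[[l]] <- res$detail
    a <- res$approx
  }
  list(approx = a, details = details)
}

idwt_periodic <- function(coeffs, h) {
  a <- coeffs$approx
  for (l in rev(seq_along(coeffs$details))) {
    a <- idwt_level(a, coeffs$details[[l]], h)
  }
  a
}

# Largest usable decomposition level for length n under periodization:
# n must be divisible by 2^level and the coarsest band non-trivial.
max_dwt_level <- function(n) {
  lv <- 0L
  while (n %% 2L == 0L && n >= 2L) {
    lv <- lv + 1L
    n <- n %/% 2L
  }
  lv
}
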