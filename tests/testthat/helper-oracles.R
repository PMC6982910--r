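# Independent oracles: deliberately naive implementations kept free of
# the package's vectorized code paths.

# Periodized DWT analysis level by direct convolution + downsampling,
# written with explicit double loops.
oracle_dwt_level <- function(x, h) {
  n <- length(x)
  g <- numeric(length(h))
  for (k in seq_along(h)) g[k] <- (-1)^(k - 1) * h[length(h) - k + 1]
  m <- n / 2
  a <- numeric(m)
  d <- numeric(m)
  for (i in seq_len(m)) {
    for (k in seq_along(h)) {
      j <- (2 * (i - 1) + (k - 1)) %% n + 1
      a[i] <- a[i] + h[k] * x[j]
      d[i] <- d[i] + g[k] * x[j]
    }
  }
  list(approx = a, detail = d)
}

oracle_idwt_level <- function(a, d, h) {
  g <- numeric(length(h))
  for (k in seq_along(h)) g[k] <- (-1)^(k - 1) * h[length(h) - k + 1]
  m <- length(a)
  n <- 2 * m
  x <- numeric(n)
  for (i in seq_len(m)) {
    for (k in seq_along(h)) {
      j <- (2 * (i - 1) + (k - 1)) %% n + 1
      x[j] <- x[j] + h[k] * a[i] + g[k] * d[i]
    }
  }
  x
}

# Full single-pass denoiser on the oracle transform: multi-level
# analysis, soft threshold, synthesis.
oracle_denoise <- function(x, h, level, lambda) {
  details <- list()
  a <- x
  for (l in seq_len(level)) {
    r <- oracle_dwt_level(a, h)
    details[[l]] <- sign(r$detail) * pmax(abs(r$detail) - lambda, 0)
    a <- r$approx
  }
  for (l in rev(seq_len(level))) {
    a <- oracle_idwt_level(a, details[[l]], h)
  }
  a
}

# Brute-force per-sample detector state machine, mirroring the sleep/wake
# contract sample by sample (start = first sample of the qualifying
# supra-threshold run; end = last supra-threshold sample before
# debounce_off sub-threshold samples or end of trace; merge events with
# gaps < refractory).
oracle_detect <- function(resultant, threshold, debounce_on, debounce_off,
                          refractory) {
  n <- length(resultant)
  active <- FALSE
  cnt_on <- 0L
  cnt_off <- 0L
  starts <- integer(0)
  ends <- integer(0)
  cur_start <- NA_integer_
  cur_end <- NA_integer_
  for (t in seq_len(n)) {
    above <- resultant[t] > threshold
    if (!active) {
      if (above) {
        cnt_on <- cnt_on + 1L
        if (cnt_on >= debounce_on) {
          active <- TRUE
          cur_start <- t - debounce_on + 1L
          cur_end <- t
          cnt_off <- 0L
        }
      } else {
        cnt_on <- 0L
      }
    } else {
      if (above) {
        cur_end <- t
        cnt_off <- 0L
      } else {
        cnt_off <- cnt_off + 1L
        if (cnt_off >= debounce_off) {
          starts <- c(starts, cur_start)
          ends <- c(ends, cur_end)
          active <- FALSE
          cnt_on <- 0L
          cnt_off <- 0L
        }
      }
    }
  }
  if (active) {
    starts <- c(starts, cur_start)
    ends <- c(ends, cur_end)
  }
  if (length(starts) > 1 && refractory > 0) {
    ms <- starts[1]; me <- ends[1]
    s2 <- integer(0); e2 <- integer(0)
    for (i in 2:length(starts)) {
      if (starts[i] - me - 1 < refractory) {
        me <- ends[i]
      } else {
        s2 <- c(s2, ms); e2 <- c(e2, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
    starts <- c(s2, ms); ends <- c(e2, me)
  }
  data.frame(start = starts, end = ends + 1L)
}

# Two-pass textbook statistics for one window segment (channels x
# samples), population normalization.
oracle_window_stats <- function(seg) {
  k <- nrow(seg)
  m <- ncol(seg)
  avg <- numeric(k); mx <- numeric(k); mn <- numeric(k); vr <- numeric(k)
  for (c in seq_len(k)) {
    s <- 0
    for (j in seq_len(m)) s <- s + seg[c, j]
    avg[c] <- s / m
    mx[c] <- seg[c, 1]; mn[c] <- seg[c, 1]
    for (j in seq_len(m)) {
      if (seg[c, j] > mx[c]) mx[c] <- seg[c, j]
      if (seg[c, j] < mn[c]) mn[c] <- seg[c, j]
    }
    ss <- 0
    for (j in seq_len(m)) ss <- ss + (seg[c, j] - avg[c])^2
    vr[c] <- ss / m
  }
  cv <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      s <- 0
      for (j in seq_len(m)) s <- s + (seg[a, j] - avg[a]) * (seg[b, j] - avg[b])
      cv[a, b] <- s / m
    }
  }
  list(avg = avg, max = mx, min = mn, sd = sqrt(vr), variance = vr,
       covariance = cv)
}

# Closed-form parameter count for the grading network.
oracle_param_count <- function(stage_widths, fc_width, expansion, k,
                               n_in = 16, n_classes = 3, n_bottleneck = 6) {
  conv_p <- function(ci, co) ci * co * k
  bn_p <- function(c) 2 * c
  bott_p <- function(c) {
    e <- c * expansion
    c * e + bn_p(e) +        # pw1 + bn
      e * k + bn_p(e) +      # dw + bn
      e * c + bn_p(c)        # pw2 + bn
  }
  total <- 0
  ci <- n_in
  for (s in seq_along(stage_widths)) {
    co <- stage_widths[s]
    total <- total + conv_p(ci, co) + bn_p(co)
    if (s < length(stage_widths)) {
      total <- total + n_bottleneck * bott_p(co)
    }
    ci <- co
  }
  total + ci * fc_width + fc_width + fc_width * n_classes + n_classes
}
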