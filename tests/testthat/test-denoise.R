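test_that("analysis filters are orthonormal quadrature pairs", {
  for (fam in c("haar", "db2", "db4")) {
    h <- wavelet_filter(fam)
    expect_equal(sum(h), sqrt(2), tolerance = 1e-12)
    expect_equal(sum(h^2), 1, tolerance = 1e-12)
    # orthogonality to even shifts of itself
    k <- length(h)
    for (s in seq_len(k / 2 - 1)) {
      expect_equal(sum(h[1:(k - 2 * s)] * h[(2 * s + 1):k]), 0,
                   tolerance = 1e-12)
    }
  }
})

test_that("periodized DWT matches the direct-convolution oracle", {
  set.seed(21)
  for (fam in c("haar", "db2", "db4")) {
    h <- wavelet_filter(fam)
    for (rep in 1:20) {
      n <- sample(c(8, 16, 32, 64), 1)
      x <- rnorm(n)
      got <- bruxsense:::dwt_level(x, h)
      want <- oracle_dwt_level(x, h)
      expect_lt(max(abs(got$approx - want$approx)), 1e-10)
      expect_lt(max(abs(got$detail - want$detail)), 1e-10)
      back <- bruxsense:::idwt_level(got$approx, got$detail, h)
      expect_lt(max(abs(back - x)), 1e-10)     # perfect reconstruction
    }
  }
})

test_that("multi-level transform round-trips and conserves energy", {
  set.seed(3)
  h <- wavelet_filter("db4")
  x <- rnorm(128)
  co <- bruxsense:::dwt_periodic(x, h, 4)
  expect_lt(abs(sum(x^2) -
                (sum(co$approx^2) + sum(unlist(co$details)^2))), 1e-9)
  expect_lt(max(abs(bruxsense:::idwt_periodic(co, h) - x)), 1e-10)
})

test_that("estimate_sigma recovers the noise floor", {
  expect_equal(estimate_sigma(rep(1.5, 64)), 0)
  set.seed(17)
  ests <- vapply(1:50, function(s) {
    set.seed(s)
    estimate_sigma(rnorm(2^14, 0, 0.1))
  }, numeric(1))
  expect_true(all(ests > 0.09 & ests < 0.11))

  # with a large smooth signal the estimate tracks the noise, not the
  # total sd
  set.seed(5)
  t <- seq(0, 4 * pi, length.out = 4096)
  sig <- 3 * sin(t)
  noisy <- sig + rnorm(4096, 0, 0.1)
  est <- estimate_sigma(noisy)
  expect_lt(abs(est - 0.1), abs(sd(noisy) - 0.1))
  expect_lt(est, 0.3)
  expect_error(estimate_sigma(c(1, 2)), "length")
})

test_that("denoise_once: zero-threshold limit is the identity", {
  t <- seq(0, 2 * pi, length.out = 256)
  x <- sin(t)
  y <- denoise_once(x, wavelet_config(sigma = 0))
  expect_lt(max(abs(y - x)), 1e-8)
})

test_that("denoise_once matches the oracle denoiser end-to-end", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(c(16, 32, 64), 1)
    x <- rnorm(n)
    lv <- sample(1:3, 1)
    sg <- runif(1, 0, 0.5)
    cfg <- wavelet_config(decomposition_level = lv, sigma = sg)
    got <- denoise_once(x, cfg)
    want <- oracle_denoise(x, wavelet_filter("db4"), lv,
                           sg * sqrt(2 * log(n)))
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("denoise_once reduces RMSE on noisy steps", {
  # n = 1024: at much shorter lengths the universal-threshold bias of the
  # 8-tap filter around dense jumps can exceed the noise reduction
  clean <- make_step_signal(1024)
  wins <- vapply(1:50, function(s) {
    set.seed(s)
    noisy <- clean + rnorm(1024, 0, 0.1)
    den <- denoise_once(noisy, wavelet_config())
    sqrt(mean((den - clean)^2)) < sqrt(mean((noisy - clean)^2))
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("level too deep errors with the maximum level named", {
  expect_error(denoise_once(rnorm(64), wavelet_config(decomposition_level = 9)),
               "maximum feasible level is 6")
  # odd-even mixed length: only finitely divisible by 2
  expect_error(denoise_once(rnorm(24), wavelet_config(decomposition_level = 4)),
               "maximum feasible level is 3")
})

test_that("cycle spinning degenerates to denoise_once at a single shift", {
  set.seed(2)
  x <- make_step_signal(128) + rnorm(128, 0, 0.1)
  cfg <- wavelet_config(n_shifts = 1, sigma = 0.1)
  expect_equal(cycle_spin_denoise(x, cfg), denoise_once(x, cfg),
               tolerance = 1e-14)
  expect_error(cycle_spin_denoise(rnorm(16),
                                  wavelet_config(n_shifts = 64)),
               "n_shifts")
})

test_that("constant signals pass through any shift set untouched", {
  x <- rep(0.7, 64)
  y <- cycle_spin_denoise(x, wavelet_config(n_shifts = 64))
  expect_lt(max(abs(y - 0.7)), 1e-10)
})

test_that("full-shift cycle spinning commutes with circular shifts", {
  set.seed(77)
  x <- make_step_signal(256) + rnorm(256, 0, 0.1)
  cfg <- wavelet_config(n_shifts = 256)
  base <- cycle_spin_denoise(x, cfg)
  for (sh in c(1, 17, 100)) {
    shifted <- cycle_spin_denoise(bruxsense:::circ_shift(x, sh), cfg)
    expect_lt(max(abs(shifted - bruxsense:::circ_shift(base, sh))), 1e-8)
  }
})

test_that("soft thresholding never expands the L2 norm", {
  set.seed(4)
  for (rep in 1:10) {
    x <- rnorm(128, 0, runif(1, 0.1, 2))
    y <- cycle_spin_denoise(x, wavelet_config(n_shifts = 16))
    expect_lte(sum(y^2), sum(x^2) + 1e-8)
  }
})

test_that("cycle spinning beats single-pass denoising on average", {
  clean <- make_step_signal(1024)
  rmse <- function(a) sqrt(mean((a - clean)^2))
  res <- vapply(1:30, function(s) {
    set.seed(s)
    noisy <- clean + rnorm(1024, 0, 0.1)
    c(single = rmse(denoise_once(noisy, wavelet_config())),
      spun = rmse(cycle_spin_denoise(noisy, wavelet_config(n_shifts = 32))))
  }, numeric(2))
  expect_lt(mean(res["spun", ]), mean(res["single", ]))
})

test_that("denoise_trace handles arbitrary lengths channel-wise", {
  set.seed(6)
  v <- rbind(make_step_signal(250) + rnorm(250, 0, 0.1),
             rnorm(250, 0.5, 0.1))
  tr <- make_sensor_trace(v, rate = 50)
  out <- denoise_trace(tr, wavelet_config(n_shifts = 8))
  expect_identical(dim(out$values), dim(v))
  expect_lt(sd(out$values[2, ]), sd(v[2, ]))
})
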