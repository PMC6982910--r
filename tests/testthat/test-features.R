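test_that("window statistics on degenerate traces", {
  ct <- make_count_trace(matrix(7L, nrow = 2, ncol = 200), rate = 100)
  s <- window_statistics(ct, 1)
  expect_length(s, 2)
  expect_equal(s[[1]]$avg, c(7, 7))
  expect_equal(s[[1]]$max, c(7, 7))
  expect_equal(s[[1]]$min, c(7, 7))
  expect_equal(s[[1]]$sd, c(0, 0))
  expect_equal(s[[1]]$variance, c(0, 0))
  expect_true(all(s[[1]]$covariance == 0))
  expect_error(window_statistics(ct, 0.01), "at least 2 samples")
})

test_that("linearly dependent channels have proportional covariance", {
  base <- sample(0:100, 300, replace = TRUE)
  ct <- make_count_trace(rbind(base, 2L * base), rate = 100)
  s <- window_statistics(ct, 3)[[1]]
  expect_equal(s$covariance[1, 2], 2 * s$variance[1], tolerance = 1e-12)
  expect_equal(s$variance[2], 4 * s$variance[1], tolerance = 1e-12)
})

test_that("all six statistics match the two-pass textbook oracle", {
  set.seed(14)
  x <- matrix(sample(0:1024, 4 * 500, replace = TRUE), nrow = 4)
  ct <- make_count_trace(x, rate = 100)
  sums <- window_statistics(ct, 1.2)
  w <- 120
  for (i in seq_along(sums)) {
    s0 <- (i - 1L) * w + 1L
    seg <- x[, s0:min(ncol(x), s0 + w - 1L), drop = FALSE]
    want <- oracle_window_stats(seg)
    got <- sums[[i]]
    rel <- function(a, b) max(abs(a - b) / pmax(1, abs(b)))
    expect_lt(rel(got$avg, want$avg), 1e-12)
    expect_equal(got$max, want$max)
    expect_equal(got$min, want$min)
    expect_lt(rel(got$sd, want$sd), 1e-12)
    expect_lt(rel(got$variance, want$variance), 1e-12)
    expect_lt(rel(got$covariance, want$covariance), 1e-12)
    # PSD + symmetry + diagonal = variance
    expect_equal(got$covariance, t(got$covariance))
    expect_true(min(eigen(got$covariance, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-9)
    expect_equal(diag(got$covariance), got$variance, tolerance = 1e-12)
  }
})

test_that("partial last window kept only when >= half length", {
  ct <- make_count_trace(matrix(1L, 1, 250), rate = 100)  # 2.5 windows of 1 s
  expect_length(window_statistics(ct, 1), 3)              # 50 >= 100/2
  ct2 <- make_count_trace(matrix(1L, 1, 240), rate = 100)
  expect_length(window_statistics(ct2, 1), 2)             # 40 < 50 dropped
})

test_that("statistics are equivariant to channel permutation and scaling", {
  set.seed(15)
  x <- matrix(sample(0:500, 3 * 200, replace = TRUE), nrow = 3)
  perm <- c(3, 1, 2)
  s1 <- window_statistics(make_count_trace(x), 2)[[1]]
  s2 <- window_statistics(make_count_trace(x[perm, ]), 2)[[1]]
  expect_equal(s2$avg, s1$avg[perm])
  expect_equal(s2$covariance, s1$covariance[perm, perm])

  a <- 3L
  s3 <- window_statistics(make_count_trace(a * x), 2)[[1]]
  expect_equal(s3$avg, a * s1$avg)
  expect_equal(s3$max, a * s1$max)
  expect_equal(s3$sd, a * s1$sd)
  expect_equal(s3$variance, a^2 * s1$variance)
  expect_equal(s3$covariance, a^2 * s1$covariance)
})

test_that("build_feature_vector aggregates events and covariates", {
  ev <- data.frame(start = c(1L, 500L), end = c(101L, 800L),
                   duration = c(1, 3), mean_force = c(200, 400))
  cov <- data.frame(contact_area = c(20, 40), contact_points = c(5L, 5L),
                    pain_level = c(3L, 6L))
  fv <- build_feature_vector(ev, cov, window = 60)
  expect_equal(fv$mean_force_duration, 2)
  expect_equal(fv$mean_force_magnitude, 300)
  expect_equal(fv$mean_contact_area, 30)
  expect_equal(fv$contact_points, 5)
  expect_identical(fv$pain_level, 6L)     # latest report wins
  expect_false(fv$quiet)

  quiet <- build_feature_vector(ev[0, ], cov[0, ], last_pain = 4L)
  expect_true(quiet$quiet)
  expect_equal(unlist(quiet[1:4]),
               c(mean_force_magnitude = 0, mean_force_duration = 0,
                 mean_contact_area = 0, contact_points = 0))
  expect_identical(quiet$pain_level, 4L)

  expect_error(build_feature_vector(ev, cov[1, , drop = FALSE]), "unmatched")
})

test_that("simulated severe windows dominate mild windows in feature norm", {
  params <- default_class_params(duration = 600, sampling_rate = 20,
                                 noise_sigma = 0.02)
  norms <- function(cl, seed) {
    p <- params[[as.character(cl)]]
    p$seed <- seed
    tr <- simulate_trace(p)
    ct <- adc_encode(tr)
    ev <- detect_events(ct, detector_config(threshold = 80, full_scale = 1024))
    cov <- bruxsense:::covariates_for_events(ev, tr)
    fr <- session_frames(ct, ev, cov, window = 60)
    vapply(fr$features, function(f) sqrt(sum(unlist(f[1:5])^2)), numeric(1))
  }
  n0 <- unlist(lapply(1:5, function(s) norms(0, s)))
  n2 <- unlist(lapply(1:5, function(s) norms(2, s)))
  expect_gte(length(n0) + length(n2), 100)
  expect_gt(mean(n2), mean(n0))
})

test_that("frames_to_tensor pads, truncates, and standardizes", {
  one <- list(features = list(build_feature_vector(
    data.frame(start = 1L, end = 11L, duration = 1, mean_force = 100),
    data.frame(contact_area = 30, contact_points = 5L, pain_level = 2L))),
    channel_means = matrix(50, 1, 6))
  b <- frames_to_tensor(one, length_out = 128)
  expect_identical(dim(b), c(16L, 128L))
  expect_true(all(b[, 2:128] == 0))
  expect_true(all(b[12:16, ] == 0))
  expect_equal(b[7, 1], 100)

  many <- list(features = rep(one$features, 200),
               channel_means = matrix(seq_len(200), 200, 6))
  b2 <- frames_to_tensor(many, length_out = 128)
  expect_identical(dim(b2), c(16L, 128L))
  expect_equal(b2[1, 1], 73)   # most recent 128 frames kept
  expect_equal(b2[1, 128], 200)

  # standardization: per-channel mean ~ 0, sd ~ 1 on the training set
  set.seed(30)
  blocks <- lapply(rep(0:2, each = 10), make_class_block)
  sc <- fit_block_scaler(blocks)
  scaled <- lapply(blocks, apply_block_scaler, scaler = sc)
  flat <- do.call(cbind, scaled)
  active <- which(apply(flat, 1, sd) > 0)
  expect_lt(max(abs(rowMeans(flat[active, ]))), 1e-10)
  expect_lt(max(abs(sqrt(rowMeans(flat[active, ]^2)) - 1)), 1e-10)
  expect_error(frames_to_tensor(list(features = list(),
                                     channel_means = NULL)), "frame")
})
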