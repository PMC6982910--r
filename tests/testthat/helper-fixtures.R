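# Shared fixture builders (all generated in code, no stored data).

# A count trace built directly from an integer matrix.
make_count_trace <- function(counts, rate = 100, adc = adc_config()) {
  counts <- rbind(counts)
  dimnames(counts) <- NULL
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, adc = adc, sampling_rate = rate),
            class = "count_trace")
}

# A sensor trace from a plain voltage matrix.
make_sensor_trace <- function(values, rate = 100) {
  values <- rbind(values)
  structure(
    list(values = values, sampling_rate = rate,
         labels = data.frame(start = integer(0), end = integer(0),
                             kind = character(0)),
         covariates = data.frame(contact_area = numeric(0),
                                 contact_points = integer(0),
                                 pain_level = integer(0)),
         severity_class = NA_integer_),
    class = "sensor_trace"
  )
}

# Piecewise-constant step signal used throughout the denoising tests.
make_step_signal <- function(n = 256) {
  x <- numeric(n)
  x[seq_len(n) > n / 4] <- 1
  x[seq_len(n) > n / 2] <- -0.5
  x[seq_len(n) > 3 * n / 4] <- 0.5
  x
}

# Synthetic separable 16-channel feature blocks for classifier unit
# tests, mimicking the packing of frames_to_tensor: 6 sensor-mean rows,
# 5 feature rows, 5 zero rows; class signal in means and features.
make_class_block <- function(cl, n_frames = 12, length_out = 32) {
  b <- matrix(0, 16, length_out)
  nf <- min(n_frames, length_out)
  b[1:6, 1:nf] <- 100 + 150 * cl + matrix(rnorm(6 * nf, 0, 20), 6)
  b[7, 1:nf] <- 200 + 200 * cl + rnorm(nf, 0, 30)
  b[8, 1:nf] <- 1 + cl + rnorm(nf, 0, 0.3)
  b[9, 1:nf] <- 20 + 15 * cl + rnorm(nf, 0, 4)
  b[10, 1:nf] <- 4 + 3 * cl
  b[11, 1:nf] <- 1 + 3 * cl
  b
}

make_class_dataset <- function(n_per_class, seed = 1, length_out = 32) {
  set.seed(seed)
  classes <- rep(0:2, each = n_per_class)
  blocks <- lapply(classes, make_class_block, length_out = length_out)
  list(blocks = blocks, classes = classes)
}
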