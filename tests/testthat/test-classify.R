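test_that("network maps input blocks to 3 logits at any valid length", {
  net <- build_network(network_config(width_divisor = 8), seed = 1)
  for (L in c(16, 32, 128)) {
    x <- array(rnorm(16 * L * 2), c(16, L, 2))
    logits <- forward_network(net, x, training = FALSE)$logits
    expect_identical(dim(logits), c(3L, 2L))
    expect_true(all(is.finite(logits)))
  }
})

test_that("config validation names the deviating row", {
  expect_error(network_config(stage_widths = c(32, 64, 100, 256)),
               "row 7")
  expect_error(network_config(fc_width = 32), "row 13")
  expect_error(network_config(width_divisor = 3), "width_divisor")
})

test_that("bottleneck with zeroed convolutions is the identity path", {
  net <- build_network(network_config(width_divisor = 8), seed = 2)
  bl <- net$layers$stage1_block1
  for (nm in c("pw1", "dw", "pw2")) bl$sub[[nm]]$params$W[] <- 0
  # zero the final projection's BN shift too, so the branch is exactly 0
  bl$sub$bn3$params$beta[] <- 0
  x <- array(rnorm(4 * 32 * 2), c(4, 32, 2))
  y <- bruxsense:::forward_layer(bl, x, training = TRUE)$y
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("parameter count equals the closed-form sum over the layer plan", {
  for (div in c(1L, 4L, 8L)) {
    cfg <- network_config(width_divisor = div)
    net <- build_network(cfg, seed = 3)
    expect_identical(count_parameters(net),
                     oracle_param_count(cfg$stage_widths, cfg$fc_width,
                                        cfg$expansion, cfg$kernel_size))
  }
})

test_that("layer gradients match numerical differentiation", {
  set.seed(8)
  net <- build_network(network_config(width_divisor = 8), seed = 2)
  # shrink weights to keep activations off the ReLU6 kinks, where the
  # subgradient and the central difference legitimately disagree
  shrink <- function(l) {
    if (l$type == "bottleneck") { l$sub <- lapply(l$sub, shrink); return(l) }
    if (!is.null(l$params$W)) l$params$W <- l$params$W * 0.3
    l
  }
  net$layers <- lapply(net$layers, shrink)
  x <- array(rnorm(16 * 32 * 3) * 0.5, c(16, 32, 3))
  labels <- c(1L, 2L, 3L)
  loss_of <- function(n) {
    bruxsense:::softmax_ce(
      bruxsense:::forward_network(n, x, training = TRUE)$logits, labels)$loss
  }
  fw <- bruxsense:::forward_network(net, x, training = TRUE)
  grads <- bruxsense:::backward_network(
    fw$net, fw$caches, bruxsense:::softmax_ce(fw$logits, labels)$grad)

  cases <- list(
    list("conv1", NULL, "W", 5L), list("bn1", NULL, "gamma", 2L),
    list("bn1", NULL, "beta", 1L), list("fc2", NULL, "b", 2L),
    list("fc1", NULL, "W", 3L),
    list("stage1_block2", "pw1", "W", 4L),
    list("stage1_block2", "dw", "W", 2L),
    list("stage2_block1", "bn2", "gamma", 3L),
    list("stage3_block6", "pw2", "W", 1L)
  )
  eps <- 1e-6
  for (cs in cases) {
    nm <- cs[[1]]; sub <- cs[[2]]; pm <- cs[[3]]; idx <- cs[[4]]
    bump <- function(v) {
      n2 <- net
      if (is.null(sub)) {
        n2$layers[[nm]]$params[[pm]][idx] <- n2$layers[[nm]]$params[[pm]][idx] + v
      } else {
        n2$layers[[nm]]$sub[[sub]]$params[[pm]][idx] <-
          n2$layers[[nm]]$sub[[sub]]$params[[pm]][idx] + v
      }
      n2
    }
    gn <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
    li <- which(names(net$layers) == nm)
    ga <- if (is.null(sub)) grads[[li]][[pm]][idx] else grads[[li]]$sub[[sub]][[pm]][idx]
    expect_lt(abs(ga - gn) / max(1e-6, abs(gn)), 1e-5)
  }
})

test_that("softmax probabilities sum to one", {
  set.seed(10)
  z <- matrix(rnorm(3 * 20, 0, 10), 3)
  p <- bruxsense:::softmax_cols(z)
  expect_lt(max(abs(colSums(p) - 1)), 1e-6)
})

test_that("altitude mapping is the symmetric 0.5 mm scheme", {
  expect_identical(altitude_of(0), -0.5)
  expect_identical(altitude_of(1), 0)
  expect_identical(altitude_of(2), 0.5)
  expect_error(altitude_of(3), "level")
})

test_that("predict_level argmax with tie toward level 1", {
  net <- build_network(network_config(width_divisor = 8), seed = 4)
  # direct logit rule checks (bypass the network)
  fake_predict <- function(logits) {
    mx <- max(logits)
    if (logits[2] == mx) 1L else as.integer(which.max(logits) - 1L)
  }
  expect_identical(fake_predict(c(0, 10, 0)), 1L)
  expect_identical(fake_predict(c(5, 5, 5)), 1L)
  expect_identical(fake_predict(c(7, 5, 5)), 0L)
  # through the network: warns on untrained use, returns coherent output
  b <- matrix(rnorm(16 * 32), 16, 32)
  expect_warning(res <- predict_level(net, b), "untrained")
  expect_true(res$level %in% 0:2)
  expect_equal(sum(res$probs), 1, tolerance = 1e-6)
  expect_identical(res$altitude, altitude_of(res$level))
})

test_that("train config carries the published optimizer settings", {
  cfg <- train_config()
  expect_identical(cfg$momentum, 0.9)
  expect_identical(cfg$batch_size, 128L)
  expect_identical(cfg$train_groups, 80L)
  expect_identical(cfg$test_groups, 20L)
  expect_error(train_config(momentum = 1), "momentum")
})

test_that("zero learning rate leaves the weights unchanged", {
  d <- make_class_dataset(4, seed = 20)
  net <- build_network(network_config(width_divisor = 8), seed = 5)
  model <- train_network(net, d$blocks, d$classes,
                         train_config(batch_size = 4, epochs = 2,
                                      learning_rate = 0, seed = 6))
  expect_identical(model$net$layers$conv1$params$W, net$layers$conv1$params$W)
  expect_identical(model$net$layers$fc2$params$W, net$layers$fc2$params$W)
})

test_that("training refuses a single-class dataset", {
  d <- make_class_dataset(4, seed = 21)
  keep <- d$classes == 1
  net <- build_network(network_config(width_divisor = 8), seed = 5)
  expect_error(train_network(net, d$blocks[keep], d$classes[keep]),
               "one class")
})

test_that("seeded training is bit-reproducible", {
  d <- make_class_dataset(4, seed = 22)
  cfg <- train_config(batch_size = 6, epochs = 2, learning_rate = 0.005,
                      seed = 11)
  net <- build_network(network_config(width_divisor = 8), seed = 5)
  m1 <- train_network(net, d$blocks, d$classes, cfg)
  m2 <- train_network(net, d$blocks, d$classes, cfg)
  expect_identical(m1$net$layers, m2$net$layers)
  expect_identical(m1$history, m2$history)
})

test_that("loss stays finite and descends across epochs (10 seeds)", {
  # Momentum (0.9) makes the per-epoch loss curve oscillate by small
  # amounts at any learning rate, so strict epoch-to-epoch monotonicity
  # is not a property this optimizer has; the descent guarantee tested
  # here is finiteness plus net decrease over the run.
  d <- make_class_dataset(8, seed = 23)
  ok <- vapply(1:10, function(s) {
    net <- build_network(network_config(width_divisor = 8), seed = s)
    m <- train_network(net, d$blocks, d$classes,
                       train_config(batch_size = 24, epochs = 5,
                                    learning_rate = 0.02, seed = s))
    all(is.finite(m$history$epoch_loss)) &&
      tail(m$history$epoch_loss, 1) < m$history$epoch_loss[1]
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("checkpoints round-trip predictions exactly", {
  d <- make_class_dataset(4, seed = 24)
  net <- build_network(network_config(width_divisor = 8), seed = 7)
  model <- train_network(net, d$blocks, d$classes,
                         train_config(batch_size = 6, epochs = 2,
                                      learning_rate = 0.01, seed = 8))
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  for (b in d$blocks[c(1, 5, 9)]) {
    expect_equal(predict_level(back, b)$probs,
                 predict_level(model, b)$probs, tolerance = 1e-12)
  }
  unlink(path)
})
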