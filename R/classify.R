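# Reference stage plan for the grading network: channel widths row-for-row
# as published, each bottleneck stage recurring 6 times.
TABLE_STAGE_WIDTHS <- c(32L, 64L, 128L, 256L)
TABLE_FC_WIDTH <- 64L
TABLE_N_BOTTLENECK <- 6L

#' Network configuration for the occlusion-adjustment grader
#'
#' Describes the 1-D inverted-bottleneck residual CNN. The reference
#' architecture is, row for row: Conv1d 16->32, MaxPool, Bottleneck1d
#' 32->32 (x6), Conv1d 32->64, MaxPool, Bottleneck1d 64->64 (x6), Conv1d
#' 64->128, MaxPool, Bottleneck1d 128->128 (x6), Conv1d 128->256, MaxPool,
#' global average pooling over 256 channels, then fully connected 256->64
#' and 64->3. Each bottleneck is a pointwise expansion, a depthwise
#' convolution and a linear pointwise projection (BN after each, ReLU6
#' after the first two) with an identity residual.
#'
#' `width_divisor` scales every internal width down for desk-scale
#' training (the 16-channel input and 3-class output are fixed); any
#' other deviation from the reference widths is rejected.
#'
#' @param width_divisor divide all internal channel widths by this (1, 2,
#'   4 or 8).
#' @param expansion bottleneck expansion ratio.
#' @param kernel_size depthwise / stage convolution kernel taps (odd).
#' @param stage_widths,fc_width widths after division; supplied values
#'   are validated row-for-row against the reference plan.
#' @return A `network_config`.
#' @export
network_config <- function(width_divisor = 1L, expansion = 4L,
                           kernel_size = 3L, stage_widths = NULL,
                           fc_width = NULL) {
  if (!width_divisor %in% c(1L, 2L, 4L, 8L)) {
    stop("`width_divisor` must be 1, 2, 4 or 8", call. = FALSE)
  }
  if (kernel_size %% 2L != 1L) stop("`kernel_size` must be odd", call. = FALSE)
  ref_stage <- TABLE_STAGE_WIDTHS %/% as.integer(width_divisor)
  ref_fc <- TABLE_FC_WIDTH %/% as.integer(width_divisor)
  if (is.null(stage_widths)) stage_widths <- ref_stage
  if (is.null(fc_width)) fc_width <- ref_fc
  for (i in seq_along(ref_stage)) {
    if (stage_widths[i] != ref_stage[i]) {
      stop(sprintf(
        "stage width %d deviates from the reference plan at row %d (Conv1d -> %d expected, got %d)",
        i, 3L * (i - 1L) + 1L, ref_stage[i], stage_widths[i]), call. = FALSE)
    }
  }
  if (fc_width != ref_fc) {
    stop(sprintf(
      "fully-connected width deviates from the reference plan at row 13 (%d expected, got %d)",
      ref_fc, fc_width), call. = FALSE)
  }
  structure(
    list(width_divisor = as.integer(width_divisor),
         expansion = as.integer(expansion),
         kernel_size = as.integer(kernel_size),
         stage_widths = as.integer(stage_widths),
         fc_width = as.integer(fc_width),
         n_input_channels = 16L, n_classes = 3L,
         n_bottleneck = TABLE_N_BOTTLENECK),
    class = "network_config"
  )
}

#' Build the grading network
#'
#' Assembles the configured network with seeded He-normal weight
#' initialization. The forward pass maps a `(16 x L x batch)` input block
#' to `(3 x batch)` logits for any length L surviving the four pooling
#' halvings (L a multiple of 16).
#'
#' @param cfg a [network_config()].
#' @param seed RNG seed for the weight initialization.
#' @return A `bruxnet` object.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  with_seed(seed, {
    layers <- list()
    c_prev <- cfg$n_input_channels
    for (s in seq_along(cfg$stage_widths)) {
      cw <- cfg$stage_widths[s]
      layers[[paste0("conv", s)]] <- layer_conv1d(c_prev, cw, cfg$kernel_size)
      layers[[paste0("bn", s)]] <- layer_batchnorm(cw)
      layers[[paste0("act", s)]] <- layer_relu6()
      layers[[paste0("pool", s)]] <- layer_maxpool()
      if (s < length(cfg$stage_widths)) {
        for (b in seq_len(cfg$n_bottleneck)) {
          layers[[paste0("stage", s, "_block", b)]] <-
            layer_bottleneck(cw, cfg$expansion, cfg$kernel_size)
        }
      }
      c_prev <- cw
    }
    layers[["gap"]] <- layer_gap()
    layers[["fc1"]] <- layer_fc(c_prev, cfg$fc_width)
    layers[["fc_act"]] <- layer_relu6()
    layers[["fc2"]] <- layer_fc(cfg$fc_width, cfg$n_classes)
    structure(list(layers = layers, cfg = cfg, trained = FALSE,
                   init_seed = as.integer(seed)),
              class = "bruxnet")
  })
}

#' Run the network forward pass
#'
#' @param net a `bruxnet`.
#' @param x input array `(16, L, batch)` with L a multiple of 16.
#' @param training `TRUE` uses batch statistics in the batch-norm layers
#'   (and updates their running averages), `FALSE` uses the running
#'   statistics.
#' @return List with `logits` (`3 x batch`), per-layer `caches`, and the
#'   (possibly BN-updated) `net`.
#' @export
forward_network <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  h <- x
  for (i in seq_along(net$layers)) {
    r <- forward_layer(net$layers[[i]], h, training)
    h <- r$y
    caches[[i]] <- r$cache
    net$layers[[i]] <- r$layer
  }
  list(logits = h, caches = caches, net = net)
}

backward_network <- function(net, caches, glogits) {
  grads <- vector("list", length(net$layers))
  g <- glogits
  for (i in rev(seq_along(net$layers))) {
    r <- backward_layer(net$layers[[i]], caches[[i]], g)
    g <- r$gx
    grads[[i]] <- r$grads
  }
  grads
}

#' Number of trainable parameters in the network
#'
#' Counts convolution, depthwise, batch-norm (gamma/beta) and
#' fully-connected weights; running BN statistics are not trainable.
#'
#' @param net a `bruxnet`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "bruxnet"))
  sum(vapply(net$layers, n_layer_params, numeric(1)))
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# Cross-entropy over a batch; labels are 1-based class indices.
softmax_ce <- function(logits, labels) {
  p <- softmax_cols(logits)
  b <- ncol(logits)
  idx <- cbind(labels, seq_len(b))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, nrow(logits), b)
  onehot[idx] <- 1
  list(loss = loss, grad = (p - onehot) / b)
}

#' Training configuration
#'
#' Momentum gradient descent with the published coefficient 0.9 and batch
#' size 128; data are split 80/20 train/test at the group (session) level.
#' The learning rate (unpublished) defaults to 0.01 with a x0.1 decay at
#' two-thirds of the epochs.
#'
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param batch_size samples per gradient step.
#' @param learning_rate initial learning rate.
#' @param epochs training epochs.
#' @param seed RNG seed governing the split and batch shuffling.
#' @param train_groups,test_groups split proportions at the group level.
#' @return A `train_config`.
#' @export
train_config <- function(momentum = 0.9, batch_size = 128L,
                         learning_rate = 0.01, epochs = 30L, seed = 1L,
                         train_groups = 80L, test_groups = 20L) {
  if (momentum < 0 || momentum >= 1) stop("`momentum` must be in [0, 1)", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  stopifnot_scalar(learning_rate, "learning_rate", nonneg = TRUE)
  structure(
    list(momentum = momentum, batch_size = as.integer(batch_size),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         seed = as.integer(seed), train_groups = as.integer(train_groups),
         test_groups = as.integer(test_groups)),
    class = "train_config"
  )
}

# Stratified group split honoring train_groups:test_groups.
split_dataset <- function(labels, cfg) {
  frac <- cfg$train_groups / (cfg$train_groups + cfg$test_groups)
  train_idx <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(frac * length(idx)))
    train_idx <- c(train_idx, idx[seq_len(min(n_tr, length(idx)))])
  }
  # deterministic order within the shuffled index stream set up by caller
  sort(train_idx)
}

#' Train the grading network
#'
#' Minimizes softmax cross-entropy with momentum gradient descent
#' (coefficient per [train_config()]). Input blocks are standardized with
#' statistics fitted on the training split only. Deterministic given the
#' seed.
#'
#' @param net a `bruxnet` from [build_network()].
#' @param blocks list of unstandardized 16 x L input blocks (from
#'   [frames_to_tensor()] without a scaler).
#' @param classes integer vector of severity / adjustment classes in
#'   `{0, 1, 2}`, one per block. All three classes must be present.
#' @param cfg a [train_config()].
#' @return A `bruxnet_model`: the trained network plus `scaler`,
#'   `history` (per-epoch train/test loss and accuracy), and the split
#'   indices.
#' @export
train_network <- function(net, blocks, classes, cfg = train_config()) {
  stopifnot(inherits(net, "bruxnet"), inherits(cfg, "train_config"))
  if (length(blocks) != length(classes)) {
    stop("one class label per block required", call. = FALSE)
  }
  if (length(unique(classes)) < 2L) {
    stop("training data must contain more than one class; got only class ",
         unique(classes), call. = FALSE)
  }
  labels <- as.integer(classes) + 1L

  with_seed(cfg$seed, {
    perm <- sample(length(blocks))
    blocks <- blocks[perm]
    labels <- labels[perm]
    train_idx <- split_dataset(labels, cfg)
    test_idx <- setdiff(seq_along(blocks), train_idx)

    scaler <- fit_block_scaler(blocks[train_idx])
    xall <- simplify2array(lapply(blocks, apply_block_scaler, scaler = scaler))
    decay_epoch <- ceiling(2 / 3 * cfg$epochs)
    lr <- cfg$learning_rate
    vel <- vector("list", length(net$layers))
    history <- NULL

    for (epoch in seq_len(cfg$epochs)) {
      if (cfg$epochs > 1L && epoch == decay_epoch + 1L) lr <- lr * 0.1
      order <- sample(train_idx)
      batch_losses <- numeric(0)
      for (b0 in seq(1L, length(order), by = cfg$batch_size)) {
        bi <- order[b0:min(length(order), b0 + cfg$batch_size - 1L)]
        xb <- xall[, , bi, drop = FALSE]
        fw <- forward_network(net, xb, training = TRUE)
        net <- fw$net
        ce <- softmax_ce(fw$logits, labels[bi])
        batch_losses <- c(batch_losses, ce$loss)
        grads <- backward_network(net, fw$caches, ce$grad)
        if (lr > 0) {
          for (i in seq_along(net$layers)) {
            r <- update_layer(net$layers[[i]], grads[[i]], vel[[i]], lr,
                              cfg$momentum)
            net$layers[[i]] <- r$layer
            vel[i] <- list(r$vel)
          }
        }
      }
      # "Precise BN": inference statistics are re-estimated from the
      # training split with the current weights (a momentum-1 capture
      # pass). Running averages lag the rapidly moving weights badly
      # enough, across 50+ stacked normalizations, to wreck inference
      # otherwise.
      net <- refresh_bn_stats(net, xall[, , train_idx, drop = FALSE])
      tr <- evaluate_network(net, xall, labels, train_idx)
      te <- if (length(test_idx) > 0) {
        evaluate_network(net, xall, labels, test_idx)
      } else {
        list(loss = NA_real_, acc = NA_real_)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr,
        epoch_loss = mean(batch_losses),       # in-training (batch-stat) loss
        train_loss = tr$loss, train_acc = tr$acc,
        test_loss = te$loss, test_acc = te$acc))
    }

    net$trained <- TRUE
    structure(
      list(net = net, scaler = scaler, train_cfg = cfg, history = history,
           train_idx = perm[train_idx], test_idx = perm[test_idx]),
      class = "bruxnet_model"
    )
  })
}

refresh_bn_stats <- function(net, x) {
  net$layers <- lapply(net$layers, set_bn_momentum, m = 1)
  net <- forward_network(net, x, training = TRUE)$net
  net$layers <- lapply(net$layers, set_bn_momentum, m = 0.1)
  net
}

evaluate_network <- function(net, xall, labels, idx) {
  logits <- forward_network(net, xall[, , idx, drop = FALSE],
                            training = FALSE)$logits
  ce <- softmax_ce(logits, labels[idx])
  pred <- apply(logits, 2, which.max)
  list(loss = ce$loss, acc = mean(pred == labels[idx]))
}

#' Occlusal-adjustment altitude of a level
#'
#' Levels map to a symmetric 0.5 mm adjustment: level 0 lowers the splint
#' surface by 0.5 mm, level 1 leaves it unchanged, level 2 raises it by
#' 0.5 mm.
#'
#' @param level integer in `{0, 1, 2}`.
#' @return Altitude in millimetres.
#' @export
altitude_of <- function(level) {
  if (length(level) != 1L || is.na(level) || !level %in% 0:2) {
    stop("`level` must be 0, 1 or 2", call. = FALSE)
  }
  c(-0.5, 0, 0.5)[level + 1L]
}

#' Predict the occlusion-adjustment level for one input block
#'
#' Runs the forward pass in inference mode and takes the argmax over the
#' three logits; exact ties are broken toward level 1 (no adjustment).
#'
#' @param model a `bruxnet_model` from [train_network()] (applies the
#'   stored standardizer), or a bare `bruxnet` (block used as-is; warns
#'   when the network is untrained).
#' @param block a 16 x L input block.
#' @return List with `level` (0/1/2), `altitude` (mm), `confidence`
#'   (softmax probability of the chosen level) and `probs` (all three).
#' @export
predict_level <- function(model, block) {
  if (inherits(model, "bruxnet_model")) {
    net <- model$net
    block <- apply_block_scaler(block, model$scaler)
  } else if (inherits(model, "bruxnet")) {
    net <- model
    if (!net$trained) {
      warning("predicting with an untrained network", call. = FALSE)
    }
  } else {
    stop("`model` must be a bruxnet or bruxnet_model", call. = FALSE)
  }
  x <- array(block, c(dim(block), 1L))
  logits <- forward_network(net, x, training = FALSE)$logits[, 1]
  probs <- as.numeric(softmax_cols(matrix(logits, ncol = 1)))
  mx <- max(logits)
  level <- if (logits[2] == mx) 1L else as.integer(which.max(logits) - 1L)
  list(level = level, altitude = altitude_of(level),
       confidence = probs[level + 1L], probs = probs)
}

#' Confusion matrix of a trained model on indexed blocks
#'
#' @param model a `bruxnet_model`.
#' @param blocks list of unstandardized blocks.
#' @param classes true classes in `{0, 1, 2}`.
#' @return 3 x 3 matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(model, blocks, classes) {
  pred <- vapply(blocks, function(b) predict_level(model, b)$level, integer(1))
  tab <- matrix(0L, 3, 3, dimnames = list(true = 0:2, predicted = 0:2))
  for (i in seq_along(classes)) {
    tab[classes[i] + 1L, pred[i] + 1L] <- tab[classes[i] + 1L, pred[i] + 1L] + 1L
  }
  tab
}

flatten_params <- function(layer) {
  if (layer$type == "bottleneck") {
    return(lapply(layer$sub, flatten_params))
  }
  out <- layer$params
  if (layer$type == "batchnorm") {
    out$running_mean <- layer$running_mean
    out$running_var <- layer$running_var
  }
  out
}

restore_params <- function(layer, saved) {
  if (layer$type == "bottleneck") {
    for (nm in names(layer$sub)) {
      layer$sub[[nm]] <- restore_params(layer$sub[[nm]], saved[[nm]])
    }
    return(layer)
  }
  for (nm in names(layer$params)) {
    p <- layer$params[[nm]]
    p[] <- unlist(saved[[nm]])
    layer$params[[nm]] <- p
  }
  if (layer$type == "batchnorm") {
    layer$running_mean <- as.numeric(unlist(saved$running_mean))
    layer$running_var <- as.numeric(unlist(saved$running_var))
  }
  layer
}

#' Save / load a model checkpoint
#'
#' Single JSON text file carrying the network configuration, the
#' standardizer and every weight (full double precision), so a restored
#' model reproduces predictions exactly.
#'
#' @param model a `bruxnet_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `bruxnet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "bruxnet_model"))
  payload <- list(
    format = "bruxsense-checkpoint-v1",
    cfg = unclass(model$net$cfg),
    init_seed = model$net$init_seed,
    scaler = list(mean = model$scaler$mean, sd = model$scaler$sd),
    history = model$history,
    weights = lapply(model$net$layers, flatten_params)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "bruxsense-checkpoint-v1")) {
    stop("not a bruxsense checkpoint: ", path, call. = FALSE)
  }
  cfg <- do.call(network_config, payload$cfg[c("width_divisor", "expansion",
                                               "kernel_size")])
  net <- build_network(cfg, seed = payload$init_seed)
  for (nm in names(net$layers)) {
    net$layers[[nm]] <- restore_params(net$layers[[nm]], payload$weights[[nm]])
  }
  net$trained <- TRUE
  structure(
    list(net = net,
         scaler = structure(list(mean = payload$scaler$mean,
                                 sd = payload$scaler$sd),
                            class = "block_scaler"),
         train_cfg = NULL, history = payload$history,
         train_idx = NULL, test_idx = NULL),
    class = "bruxnet_model"
  )
}
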