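# Minimal 1-D CNN layer engine: forward passes, analytic gradients, and
# momentum-SGD updates, written against base R matrix algebra. Batch
# tensors use dim (channels, length, batch) so channel-wise parameters
# broadcast by R's first-dimension recycling and convolutions reduce to
# one BLAS matmul per layer via im2col.

he_init <- function(n_out, n_in_fan, n_cols) {
  matrix(rnorm(n_out * n_cols, 0, sqrt(2 / n_in_fan)), n_out, n_cols)
}

layer_conv1d <- function(c_in, c_out, k = 3L) {
  list(type = "conv1d", c_in = c_in, c_out = c_out, k = as.integer(k),
       params = list(W = he_init(c_out, c_in * k, c_in * k)))
}

layer_depthwise <- function(c, k = 3L) {
  list(type = "depthwise", c = c, k = as.integer(k),
       params = list(W = matrix(rnorm(c * k, 0, sqrt(2 / k)), c, k)))
}

layer_batchnorm <- function(c, momentum = 0.1, eps = 1e-3) {
  list(type = "batchnorm", c = c, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, c), beta = rep(0, c)),
       running_mean = rep(0, c), running_var = rep(1, c))
}

layer_relu6 <- function() list(type = "relu6", params = list())

layer_maxpool <- function() list(type = "maxpool", params = list())

layer_gap <- function() list(type = "gap", params = list())

layer_fc <- function(c_in, c_out) {
  list(type = "fc", c_in = c_in, c_out = c_out,
       params = list(W = he_init(c_out, c_in, c_in), b = rep(0, c_out)))
}

# Inverted residual: pointwise expand -> depthwise -> pointwise project,
# BN after each conv, ReLU6 after the first two, linear projection,
# identity skip (input/output widths always match here).
layer_bottleneck <- function(c, expansion = 4L, k = 3L) {
  e <- c * expansion
  list(type = "bottleneck", c = c,
       params = list(),
       sub = list(
         pw1 = layer_conv1d(c, e, 1L), bn1 = layer_batchnorm(e), a1 = layer_relu6(),
         dw = layer_depthwise(e, k), bn2 = layer_batchnorm(e), a2 = layer_relu6(),
         pw2 = layer_conv1d(e, c, 1L), bn3 = layer_batchnorm(c)
       ))
}

im2col <- function(x, k) {
  d <- dim(x)
  c_in <- d[1]; L <- d[2]; B <- d[3]
  if (k == 1L) return(matrix(x, c_in, L * B))
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(c_in, L + 2L * p, B))
  xp[, (p + 1L):(p + L), ] <- x
  cols <- array(0, c(c_in * k, L, B))
  for (t in seq_len(k)) {
    cols[((t - 1L) * c_in + 1L):(t * c_in), , ] <- xp[, t:(t + L - 1L), , drop = FALSE]
  }
  matrix(cols, c_in * k, L * B)
}

col2im <- function(gmat, c_in, k, L, B) {
  if (k == 1L) return(array(gmat, c(c_in, L, B)))
  p <- (k - 1L) %/% 2L
  gc <- array(gmat, c(c_in * k, L, B))
  gxp <- array(0, c(c_in, L + 2L * p, B))
  for (t in seq_len(k)) {
    gxp[, t:(t + L - 1L), ] <- gxp[, t:(t + L - 1L), , drop = FALSE] +
      gc[((t - 1L) * c_in + 1L):(t * c_in), , , drop = FALSE]
  }
  gxp[, (p + 1L):(p + L), , drop = FALSE]
}

forward_layer <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv1d = {
      d <- dim(x)
      mat <- im2col(x, layer$k)
      y <- layer$params$W %*% mat
      list(y = array(y, c(layer$c_out, d[2], d[3])),
           cache = list(mat = mat, dims = d), layer = layer)
    },
    depthwise = {
      d <- dim(x); L <- d[2]; B <- d[3]
      k <- layer$k; p <- (k - 1L) %/% 2L
      xp <- array(0, c(layer$c, L + 2L * p, B))
      xp[, (p + 1L):(p + L), ] <- x
      y <- array(0, c(layer$c, L, B))
      for (t in seq_len(k)) {
        y <- y + layer$params$W[, t] * xp[, t:(t + L - 1L), , drop = FALSE]
      }
      list(y = y, cache = list(xp = xp, dims = d), layer = layer)
    },
    batchnorm = {
      d <- dim(x)
      m <- prod(d[-1])
      xm <- matrix(x, d[1], m)
      if (training) {
        mu <- rowMeans(xm)
        vr <- rowMeans((xm - mu)^2)
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
        layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * vr
      } else {
        mu <- layer$running_mean
        vr <- layer$running_var
      }
      inv_sd <- 1 / sqrt(vr + layer$eps)
      xhat <- (x - mu) * inv_sd
      y <- layer$params$gamma * xhat + layer$params$beta
      list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, m = m, dims = d),
           layer = layer)
    },
    relu6 = {
      y <- pmin(pmax(x, 0), 6)
      list(y = y, cache = list(mask = (x > 0) & (x < 6)), layer = layer)
    },
    maxpool = {
      d <- dim(x); L <- d[2]
      odd <- x[, seq(1L, L, 2L), , drop = FALSE]
      even <- x[, seq(2L, L, 2L), , drop = FALSE]
      sel <- odd >= even
      list(y = pmax(odd, even), cache = list(sel = sel, dims = d), layer = layer)
    },
    gap = {
      d <- dim(x)
      m <- matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3])
      list(y = matrix(colMeans(m), d[1], d[3]), cache = list(dims = d),
           layer = layer)
    },
    fc = {
      list(y = layer$params$W %*% x + layer$params$b,
           cache = list(x = x), layer = layer)
    },
    bottleneck = {
      caches <- vector("list", length(layer$sub))
      h <- x
      for (i in seq_along(layer$sub)) {
        r <- forward_layer(layer$sub[[i]], h, training)
        h <- r$y
        caches[[i]] <- r$cache
        layer$sub[[i]] <- r$layer
      }
      list(y = x + h, cache = list(sub = caches), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

backward_layer <- function(layer, cache, gy) {
  switch(layer$type,
    conv1d = {
      d <- cache$dims
      gym <- matrix(gy, layer$c_out, d[2] * d[3])
      gW <- tcrossprod(gym, cache$mat)
      gmat <- crossprod(layer$params$W, gym)
      list(gx = col2im(gmat, layer$c_in, layer$k, d[2], d[3]),
           grads = list(W = gW))
    },
    depthwise = {
      d <- cache$dims; L <- d[2]; B <- d[3]
      k <- layer$k; p <- (k - 1L) %/% 2L
      gW <- matrix(0, layer$c, k)
      gxp <- array(0, c(layer$c, L + 2L * p, B))
      for (t in seq_len(k)) {
        slice <- cache$xp[, t:(t + L - 1L), , drop = FALSE]
        gW[, t] <- rowSums(matrix(gy * slice, layer$c))
        gxp[, t:(t + L - 1L), ] <- gxp[, t:(t + L - 1L), , drop = FALSE] +
          layer$params$W[, t] * gy
      }
      list(gx = gxp[, (p + 1L):(p + L), , drop = FALSE], grads = list(W = gW))
    },
    batchnorm = {
      d <- cache$dims
      gym <- matrix(gy, d[1], cache$m)
      xhatm <- matrix(cache$xhat, d[1], cache$m)
      gbeta <- rowSums(gym)
      ggamma <- rowSums(gym * xhatm)
      gxhat_mean <- gbeta / cache$m
      gxhat_xhat_mean <- ggamma / cache$m
      gx <- (layer$params$gamma * cache$inv_sd) *
        (gy - gxhat_mean - cache$xhat * gxhat_xhat_mean)
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    relu6 = list(gx = gy * cache$mask, grads = list()),
    maxpool = {
      d <- cache$dims
      gx <- array(0, d)
      gx[, seq(1L, d[2], 2L), ] <- gy * cache$sel
      gx[, seq(2L, d[2], 2L), ] <- gy * (!cache$sel)
      list(gx = gx, grads = list())
    },
    gap = {
      d <- cache$dims
      gx <- array(0, d)
      g2 <- gy / d[2]
      for (l in seq_len(d[2])) gx[, l, ] <- g2
      list(gx = gx, grads = list())
    },
    fc = {
      list(gx = crossprod(layer$params$W, gy),
           grads = list(W = tcrossprod(gy, cache$x), b = rowSums(gy)))
    },
    bottleneck = {
      gh <- gy
      grads <- vector("list", length(layer$sub))
      names(grads) <- names(layer$sub)
      for (i in rev(seq_along(layer$sub))) {
        r <- backward_layer(layer$sub[[i]], cache$sub[[i]], gh)
        gh <- r$gx
        grads[[i]] <- r$grads
      }
      list(gx = gy + gh, grads = list(sub = grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Momentum SGD: v <- mu v - lr g; w <- w + v. `vel` mirrors the grads
# structure and is created lazily on first use.
update_layer <- function(layer, grads, vel, lr, momentum) {
  if (layer$type == "bottleneck") {
    if (is.null(vel)) vel <- vector("list", length(layer$sub))
    for (i in seq_along(layer$sub)) {
      r <- update_layer(layer$sub[[i]], grads$sub[[i]], vel[[i]], lr, momentum)
      layer$sub[[i]] <- r$layer
      vel[i] <- list(r$vel)  # plain [[<- would drop the element when NULL
    }
    return(list(layer = layer, vel = vel))
  }
  if (length(layer$params) == 0L) return(list(layer = layer, vel = vel))
  if (is.null(vel)) {
    vel <- lapply(layer$params, function(p) { p[] <- 0; p })
  }
  for (nm in names(layer$params)) {
    vel[[nm]] <- momentum * vel[[nm]] - lr * grads[[nm]]
    layer$params[[nm]] <- layer$params[[nm]] + vel[[nm]]
  }
  list(layer = layer, vel = vel)
}

set_bn_momentum <- function(layer, m) {
  if (layer$type == "bottleneck") {
    layer$sub <- lapply(layer$sub, set_bn_momentum, m = m)
  } else if (layer$type == "batchnorm") {
    layer$momentum <- m
  }
  layer
}

n_layer_params <- function(layer) {
  if (layer$type == "bottleneck") {
    return(sum(vapply(layer$sub, n_layer_params, numeric(1))))
  }
  sum(vapply(layer$params, length, numeric(1)))
}
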