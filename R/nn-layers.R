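# Layer primitives of the 3D CNN: constructors, forward and backward.
#
# Each forward returns list(out = tensor, cache = ...) and, for layers
# with running buffers (batch norm in training mode), an updated layer.
# Backwards return list(dx = matrix, grads = named list) with gradient
# arrays shaped exactly like the parameters.  `cache` controls whether
# backward caches are kept and is independent of batch-norm `train`
# mode, so gradients can also be taken through an evaluation-mode
# forward (Grad-CAM++).

conv3d_layer <- function(c_in, c_out, kernel, stride = c(1L, 1L, 1L),
                         pad = NULL) {
  kernel <- as.integer(kernel); stride <- as.integer(stride)
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  K <- c_in * prod(kernel)
  list(type = "conv3d", c_in = c_in, c_out = c_out,
       kernel = kernel, stride = stride, pad = as.integer(pad),
       W = matrix(rnorm(c_out * K, sd = sqrt(2 / K)), nrow = c_out))
}

conv3d_out_dims <- function(layer, dims) {
  thw <- dims[2:4]
  c(dims[1L], (thw + 2L * layer$pad - layer$kernel) %/% layer$stride + 1L)
}

conv3d_fwd <- function(layer, ten, cache = FALSE) {
  d <- ten$dims
  col <- .im2col3d(ten$x, d[1L], d[2L], d[3L], d[4L],
                   layer$kernel[1L], layer$kernel[2L], layer$kernel[3L],
                   layer$stride[1L], layer$stride[2L], layer$stride[3L],
                   layer$pad[1L], layer$pad[2L], layer$pad[3L])
  out <- new_tensor(col %*% t(layer$W), conv3d_out_dims(layer, d))
  list(out = out, cache = if (cache) list(x = ten$x, dims = d))
}

conv3d_bwd <- function(layer, dy, cache) {
  d <- cache$dims
  col <- .im2col3d(cache$x, d[1L], d[2L], d[3L], d[4L],
                   layer$kernel[1L], layer$kernel[2L], layer$kernel[3L],
                   layer$stride[1L], layer$stride[2L], layer$stride[3L],
                   layer$pad[1L], layer$pad[2L], layer$pad[3L])
  dW <- t(dy) %*% col
  dx <- .col2im3d(dy %*% layer$W, layer$c_in,
                  d[1L], d[2L], d[3L], d[4L],
                  layer$kernel[1L], layer$kernel[2L], layer$kernel[3L],
                  layer$stride[1L], layer$stride[2L], layer$stride[3L],
                  layer$pad[1L], layer$pad[2L], layer$pad[3L])
  list(dx = dx, grads = list(W = dW))
}

bn_layer <- function(c_out, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", c_out = c_out, momentum = momentum, eps = eps,
       gamma = rep(1, c_out), beta = rep(0, c_out),
       run_mean = rep(0, c_out), run_var = rep(1, c_out))
}

bn_fwd <- function(layer, ten, train = FALSE, cache = train) {
  x <- ten$x
  P <- nrow(x)
  if (train) {
    m <- colMeans(x)
    xc <- sweep(x, 2L, m, "-")
    v <- colMeans(xc * xc)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * m
    vu <- if (P > 1L) v * P / (P - 1L) else v
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * vu
  } else {
    m <- layer$run_mean
    v <- layer$run_var
    xc <- sweep(x, 2L, m, "-")
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
  list(out = new_tensor(y, ten$dims), layer = layer,
       cache = if (cache) list(xhat = xhat, invstd = invstd, train = train))
}

bn_bwd <- function(layer, dy, cache) {
  P <- nrow(dy)
  xhat <- cache$xhat
  if (!cache$train) {
    # Running statistics are constants: d(xhat)/dx is just invstd.
    dgamma <- colSums(dy * xhat)
    dbeta <- colSums(dy)
    dx <- sweep(dy, 2L, layer$gamma * cache$invstd, "*")
    return(list(dx = dx, grads = list(gamma = dgamma, beta = dbeta)))
  }
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  # dx = gamma*invstd/P * (P*dy - dbeta - xhat*dgamma)
  tmp <- P * dy
  tmp <- sweep(tmp, 2L, dbeta, "-")
  tmp <- tmp - sweep(xhat, 2L, dgamma, "*")
  dx <- sweep(tmp, 2L, layer$gamma * cache$invstd / P, "*")
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(ten, cache = FALSE) {
  y <- ten$x
  mask <- y > 0
  y[!mask] <- 0
  list(out = new_tensor(y, ten$dims), cache = if (cache) mask)
}

relu_bwd <- function(dy, mask) {
  dy[!mask] <- 0
  dy
}

maxpool_layer <- function(kernel = c(1L, 3L, 3L), stride = c(1L, 2L, 2L),
                          pad = c(0L, 1L, 1L)) {
  list(type = "maxpool", kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad))
}

maxpool_fwd <- function(layer, ten, cache = FALSE) {
  d <- ten$dims
  r <- .maxpool3d(ten$x, d[1L], d[2L], d[3L], d[4L],
                  layer$kernel[1L], layer$kernel[2L], layer$kernel[3L],
                  layer$stride[1L], layer$stride[2L], layer$stride[3L],
                  layer$pad[1L], layer$pad[2L], layer$pad[3L])
  odims <- c(d[1L], (d[2:4] + 2L * layer$pad - layer$kernel) %/% layer$stride + 1L)
  list(out = new_tensor(r$y, odims),
       cache = if (cache) list(argmax = r$argmax, p_in = nrow(ten$x)))
}

maxpool_bwd <- function(dy, cache) {
  .maxpool3d_backward(dy, cache$argmax, cache$p_in)
}

# Global spatiotemporal average pool: (P x C) -> (N x C).
gap_fwd <- function(ten) {
  d <- ten$dims
  per <- prod(d[2:4])
  grp <- rep(seq_len(d[1L]), each = per)
  feat <- rowsum(ten$x, grp, reorder = FALSE) / per
  list(out = feat, per = per, dims = d)
}

gap_bwd <- function(dfeat, per, dims) {
  dfeat[rep(seq_len(dims[1L]), each = per), , drop = FALSE] / per
}

fc_layer <- function(c_in, c_out, init_sd = 0.01) {
  list(type = "fc", c_in = c_in, c_out = c_out,
       W = matrix(rnorm(c_out * c_in, sd = init_sd), nrow = c_out),
       b = rep(0, c_out))
}

fc_fwd <- function(layer, x) sweep(x %*% t(layer$W), 2L, layer$b, "+")

fc_bwd <- function(layer, dy, x) {
  list(dx = dy %*% layer$W,
       grads = list(W = t(dy) %*% x, b = colSums(dy)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))
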