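# Bottleneck 3D residual network: assembly, forward and backward.
#
# Topology (for 224x224 input): conv1 3x7x7/64 stride 1x2x2 -> max pool
# 1x3x3 stride 1x2x2 -> four stages of bottleneck blocks
# (1x1x1 reduce, 3x3x3, 1x1x1 expand x4) -> global spatiotemporal average
# pool -> fully connected head with per-class sigmoid.  All temporal
# strides are 1, so the temporal extent T is preserved until the pool.

bottleneck_block <- function(c_in, inner, spatial_stride = 1L) {
  outer <- 4L * inner
  stride <- c(1L, spatial_stride, spatial_stride)
  blk <- list(
    conv_a = conv3d_layer(c_in, inner, c(1L, 1L, 1L)),
    bn_a   = bn_layer(inner),
    conv_b = conv3d_layer(inner, inner, c(3L, 3L, 3L), stride = stride),
    bn_b   = bn_layer(inner),
    conv_c = conv3d_layer(inner, outer, c(1L, 1L, 1L)),
    bn_c   = bn_layer(outer))
  if (c_in != outer || spatial_stride != 1L) {
    blk$proj_conv <- conv3d_layer(c_in, outer, c(1L, 1L, 1L), stride = stride)
    blk$proj_bn <- bn_layer(outer)
  }
  blk
}

block_fwd <- function(blk, ten, train = FALSE, cache = train) {
  ca <- conv3d_fwd(blk$conv_a, ten, cache)
  ba <- bn_fwd(blk$bn_a, ca$out, train, cache)
  ra <- relu_fwd(ba$out, cache)
  cb <- conv3d_fwd(blk$conv_b, ra$out, cache)
  bb <- bn_fwd(blk$bn_b, cb$out, train, cache)
  rb <- relu_fwd(bb$out, cache)
  cc <- conv3d_fwd(blk$conv_c, rb$out, cache)
  bc <- bn_fwd(blk$bn_c, cc$out, train, cache)
  if (!is.null(blk$proj_conv)) {
    pc <- conv3d_fwd(blk$proj_conv, ten, cache)
    pb <- bn_fwd(blk$proj_bn, pc$out, train, cache)
    shortcut <- pb$out$x
  } else {
    pc <- pb <- NULL
    shortcut <- ten$x
  }
  pre <- new_tensor(bc$out$x + shortcut, bc$out$dims)
  ro <- relu_fwd(pre, cache)
  if (train) {
    blk$bn_a <- ba$layer; blk$bn_b <- bb$layer; blk$bn_c <- bc$layer
    if (!is.null(pb)) blk$proj_bn <- pb$layer
  }
  list(out = ro$out, layer = blk,
       cache = if (cache) list(ca = ca$cache, ba = ba$cache, ra = ra$cache,
                               cb = cb$cache, bb = bb$cache, rb = rb$cache,
                               cc = cc$cache, bc = bc$cache,
                               pc = if (!is.null(pc)) pc$cache,
                               pb = if (!is.null(pb)) pb$cache,
                               ro = ro$cache))
}

block_bwd <- function(blk, dy, cache) {
  dpre <- relu_bwd(dy, cache$ro)
  g <- list()
  b3 <- bn_bwd(blk$bn_c, dpre, cache$bc); g$bn_c <- b3$grads
  c3 <- conv3d_bwd(blk$conv_c, b3$dx, cache$cc); g$conv_c <- c3$grads
  drb <- relu_bwd(c3$dx, cache$rb)
  b2 <- bn_bwd(blk$bn_b, drb, cache$bb); g$bn_b <- b2$grads
  c2 <- conv3d_bwd(blk$conv_b, b2$dx, cache$cb); g$conv_b <- c2$grads
  dra <- relu_bwd(c2$dx, cache$ra)
  b1 <- bn_bwd(blk$bn_a, dra, cache$ba); g$bn_a <- b1$grads
  c1 <- conv3d_bwd(blk$conv_a, b1$dx, cache$ca); g$conv_a <- c1$grads
  dx <- c1$dx
  if (!is.null(blk$proj_conv)) {
    pb <- bn_bwd(blk$proj_bn, dpre, cache$pb); g$proj_bn <- pb$grads
    pc <- conv3d_bwd(blk$proj_conv, pb$dx, cache$pc); g$proj_conv <- pc$grads
    dx <- dx + pc$dx
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = g)
}

# Full-network forward.  `train = TRUE` additionally returns per-layer
# caches and the model with updated batch-norm running statistics.
# `keep_stage` (1..4) retains that stage's output activation tensor and
# its position so Grad-CAM++ can request gradients there.
net_fwd <- function(model, ten, train = FALSE, cache = train,
                    keep_stage = NULL) {
  caches <- list()
  c1 <- conv3d_fwd(model$conv1, ten, cache); caches$conv1 <- c1$cache
  b1 <- bn_fwd(model$bn1, c1$out, train, cache); caches$bn1 <- b1$cache
  if (train) model$bn1 <- b1$layer
  r1 <- relu_fwd(b1$out, cache); caches$relu1 <- r1$cache
  p1 <- maxpool_fwd(model$pool1, r1$out, cache); caches$pool1 <- p1$cache
  x <- p1$out
  stage_out <- NULL
  caches$stages <- vector("list", length(model$stages))
  for (s in seq_along(model$stages)) {
    caches$stages[[s]] <- vector("list", length(model$stages[[s]]))
    for (i in seq_along(model$stages[[s]])) {
      bf <- block_fwd(model$stages[[s]][[i]], x, train, cache)
      if (train) model$stages[[s]][[i]] <- bf$layer
      caches$stages[[s]][[i]] <- bf$cache
      x <- bf$out
    }
    if (!is.null(keep_stage) && s == keep_stage) stage_out <- x
  }
  gp <- gap_fwd(x)
  logits <- fc_fwd(model$head, gp$out)
  list(scores = sigmoid(logits), logits = logits, features = gp$out,
       model = model,
       internals = list(caches = caches, gap = gp, stage_out = stage_out))
}

# Backward from d(loss)/d(logits).  Returns the nested gradient tree and,
# when `want_stage` is set, the gradient w.r.t. that stage's output.
net_bwd <- function(model, internals, dlogits, want_stage = NULL) {
  caches <- internals$caches
  hb <- fc_bwd(model$head, dlogits, internals$gap$out)
  grads <- list(head = hb$grads)
  dy <- gap_bwd(hb$dx, internals$gap$per, internals$gap$dims)
  dstage <- NULL
  grads$stages <- vector("list", length(model$stages))
  for (s in rev(seq_along(model$stages))) {
    if (!is.null(want_stage) && s == want_stage) dstage <- dy
    grads$stages[[s]] <- vector("list", length(model$stages[[s]]))
    for (i in rev(seq_along(model$stages[[s]]))) {
      bb <- block_bwd(model$stages[[s]][[i]], dy, caches$stages[[s]][[i]])
      grads$stages[[s]][[i]] <- bb$grads
      dy <- bb$dx
    }
  }
  dy <- maxpool_bwd(dy, caches$pool1)
  dy <- relu_bwd(dy, caches$relu1)
  b1 <- bn_bwd(model$bn1, dy, caches$bn1); grads$bn1 <- b1$grads
  c1 <- conv3d_bwd(model$conv1, b1$dx, caches$conv1); grads$conv1 <- c1$grads
  list(grads = grads, dstage = dstage, dx = c1$dx)
}

# Apply `f(param, grad, path)` to every numeric leaf of the gradient tree,
# writing the result back into the model.  Used by the Adam step.
tree_update <- function(model, grads, f, path = "") {
  for (nm in names(grads)) {
    child <- grads[[nm]]
    key <- paste0(path, ".", nm)
    if (is.list(child)) {
      model[[nm]] <- tree_update(model[[nm]], child, f, key)
    } else {
      model[[nm]] <- f(model[[nm]], child, key)
    }
  }
  if (is.null(names(grads)) && length(grads)) {  # unnamed list of blocks
    for (i in seq_along(grads)) {
      model[[i]] <- tree_update(model[[i]], grads[[i]], f,
                                paste0(path, "[", i, "]"))
    }
  }
  model
}
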