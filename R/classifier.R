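#' Architecture specification for the bottleneck 3D residual network
#'
#' Describes the classification-stage network: a 3D residual CNN whose
#' stem is a 3x7x7 convolution (64 filters, stride 1x2x2) followed by a
#' 1x3x3 max pool (stride 1x2x2), then four stages of bottleneck blocks
#' with a 4x channel expansion (inner widths 64/128/256/512), a global
#' spatiotemporal average pool and a fully connected head with
#' per-class sigmoid outputs.  With the default block counts
#' \code{c(3, 4, 6, 3)} and \code{width_multiplier = 1} the pooled
#' feature has length 2048 and, for 224x224 input, the stage outputs
#' have spatial sizes 112, 56, 56, 28, 14, 7.  All temporal strides are
#' 1, so the clip length \code{T} survives untouched until the pool.
#'
#' @param block_counts integer(4); bottleneck blocks per stage.
#' @param n_classes number of output classes (2 = ASD vs non-ASD).
#' @param t_frames nominal clip length T (informational; the network is
#'   fully convolutional in time).
#' @param width_multiplier scales every channel width; e.g. 0.25 gives a
#'   512-length pooled feature.  Useful for CPU-scale experiments.
#' @return an object of class \code{gait_arch_spec}.
#' @export
arch_spec <- function(block_counts = c(3L, 4L, 6L, 3L), n_classes = 2L,
                      t_frames = 8L, width_multiplier = 1) {
  block_counts <- as.integer(block_counts)
  if (length(block_counts) != 4L || any(block_counts < 1L))
    stop("block_counts must be four integers >= 1")
  if (width_multiplier <= 0) stop("width_multiplier must be > 0")
  if (n_classes < 1L) stop("n_classes must be >= 1")
  inner <- as.integer(round(64 * 2^(0:3) * width_multiplier))
  if (any(inner < 1L)) stop("width_multiplier too small")
  structure(list(block_counts = block_counts,
                 n_classes = as.integer(n_classes),
                 t_frames = as.integer(t_frames),
                 width_multiplier = width_multiplier,
                 stem_filters = as.integer(round(64 * width_multiplier)),
                 inner_widths = inner,
                 outer_widths = 4L * inner,
                 feature_dim = 4L * inner[4L]),
            class = "gait_arch_spec")
}

#' Build the classification-stage network
#'
#' Instantiates the bottleneck 3D CNN described by an
#' \code{\link{arch_spec}} with He-initialized convolution weights and
#' unit-gamma batch normalization.  Spatial downsampling by stride 2
#' happens in the first block of stages 2-4 (on the 3x3x3 convolution,
#' with 1x1x1 projection shortcuts); stage 1 keeps the post-pool size.
#'
#' @param spec a \code{gait_arch_spec}.
#' @param seed optional integer for reproducible initialization.
#' @return an object of class \code{gait_cnn}.
#' @export
build_model <- function(spec = arch_spec(), seed = NULL) {
  stopifnot(inherits(spec, "gait_arch_spec"))
  with_seed(seed, {
    model <- list(
      spec = spec,
      conv1 = conv3d_layer(3L, spec$stem_filters, c(3L, 7L, 7L),
                           stride = c(1L, 2L, 2L), pad = c(1L, 3L, 3L)),
      bn1 = bn_layer(spec$stem_filters),
      pool1 = maxpool_layer(),
      stages = vector("list", 4L))
    c_in <- spec$stem_filters
    for (s in 1:4) {
      blocks <- vector("list", spec$block_counts[s])
      for (i in seq_along(blocks)) {
        blocks[[i]] <- bottleneck_block(
          c_in, spec$inner_widths[s],
          spatial_stride = if (i == 1L && s > 1L) 2L else 1L)
        c_in <- spec$outer_widths[s]
      }
      model$stages[[s]] <- blocks
    }
    model$head <- fc_layer(spec$feature_dim, spec$n_classes)
    structure(model, class = "gait_cnn")
  })
}

#' Forward pass of the classifier
#'
#' Evaluation-mode forward: deterministic for fixed weights and input
#' (batch norm uses running statistics).  Scores are independent
#' per-class sigmoids; the predicted label is the argmax and the
#' positive-class score used for ROC analysis is the ASD column.
#'
#' @param model a \code{gait_cnn}.
#' @param clips one \code{(3, T, side, side)} array or a list of them
#'   (see \code{\link{resize_for_model}}).
#' @return matrix (N x n_classes) of sigmoid scores in [0, 1], with
#'   attribute \code{"logits"}.
#' @export
forward <- function(model, clips) {
  stopifnot(inherits(model, "gait_cnn"))
  ten <- if (is.list(clips) || length(dim(clips)) == 4L)
    clips_to_tensor(clips) else stop("clips must be (3, T, side, side) arrays")
  if (ncol(ten$x) != 3L) stop("clips must have 3 channels first")
  out <- net_fwd(model, ten, train = FALSE)
  structure(out$scores, logits = out$logits)
}

#' @export
predict.gait_cnn <- function(object, clips,
                             type = c("scores", "label", "features"), ...) {
  type <- match.arg(type)
  if (type == "features") return(pooled_features(object, clips))
  sc <- forward(object, clips)
  if (type == "scores") return(sc)
  lab <- c("ASD", "non-ASD")[max.col(sc, ties.method = "first")]
  factor(lab, levels = c("ASD", "non-ASD"))
}

#' Pooled feature vectors
#'
#' Returns the post-pool, pre-head feature vectors (length
#' \code{spec$feature_dim}; 2048 at width multiplier 1).
#'
#' @inheritParams forward
#' @return matrix (N x feature_dim).
#' @export
pooled_features <- function(model, clips) {
  stopifnot(inherits(model, "gait_cnn"))
  ten <- clips_to_tensor(clips)
  net_fwd(model, ten, train = FALSE)$features
}

#' Replace the classification head (transfer-learning head swap)
#'
#' Swaps the final fully connected layer for a freshly initialized
#' \code{n_classes}-way layer, e.g. turning a 400-way action-recognition
#' network into the 2-way ASD/non-ASD classifier.  All other weights are
#' left bitwise unchanged.
#'
#' @param model a \code{gait_cnn}.
#' @param n_classes width of the new head.
#' @param seed optional seed for the new head's initialization.
#' @return the model with a new head; \code{spec$n_classes} updated.
#' @export
adapt_head <- function(model, n_classes = 2L, seed = NULL) {
  stopifnot(inherits(model, "gait_cnn"))
  if (is.null(model$head$W)) stop("model has no fully connected head")
  with_seed(seed, {
    model$head <- fc_layer(model$spec$feature_dim, as.integer(n_classes))
  })
  model$spec$n_classes <- as.integer(n_classes)
  model
}

#' Save / load model checkpoints
#'
#' Checkpoints hold the parameter and buffer arrays plus the
#' architecture spec.  Loading validates shapes: a checkpoint whose
#' feature width disagrees with the model errors rather than silently
#' truncating.
#'
#' @param model a \code{gait_cnn}.
#' @param path file path.
#' @return \code{load_checkpoint} returns the restored \code{gait_cnn}.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gait_cnn"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  if (!identical(dim(ck$head$W)[2L], dim(model$head$W)[2L]))
    stop_gaitscreen("checkpoint feature width does not match model",
                    "gaitscreen_shape_mismatch")
  if (!identical(ck$spec$block_counts, model$spec$block_counts) ||
      !identical(ck$spec$width_multiplier, model$spec$width_multiplier))
    stop_gaitscreen("checkpoint architecture does not match model",
                    "gaitscreen_shape_mismatch")
  structure(ck, class = "gait_cnn")
}

#' @export
print.gait_cnn <- function(x, ...) {
  s <- x$spec
  cat("Bottleneck 3D residual network\n")
  cat(sprintf("  blocks per stage: %s\n", paste(s$block_counts, collapse = ", ")))
  cat(sprintf("  width multiplier: %g (pooled feature length %d)\n",
              s$width_multiplier, s$feature_dim))
  cat(sprintf("  head: %d-way, per-class sigmoid\n", s$n_classes))
  np <- sum(vapply(param_leaves(x), length, integer(1)))
  cat(sprintf("  parameters: %s\n", format(np, big.mark = ",")))
  invisible(x)
}

# Flat list of all trainable parameter arrays (for counting/comparison).
param_leaves <- function(model) {
  out <- list()
  walk <- function(node, path) {
    for (nm in c("W", "b", "gamma", "beta")) {
      if (!is.null(node[[nm]]) && is.numeric(node[[nm]]))
        out[[paste0(path, ".", nm)]] <<- node[[nm]]
    }
    for (nm in names(node)) {
      if (is.list(node[[nm]]) && nm != "spec")
        walk(node[[nm]], paste0(path, ".", nm))
    }
    if (is.null(names(node))) {
      for (i in seq_along(node)) {
        if (is.list(node[[i]])) walk(node[[i]], paste0(path, "[", i, "]"))
      }
    }
  }
  walk(model, "model")
  out
}
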