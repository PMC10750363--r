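# Training protocol: Adam, early stopping on validation loss,
# learning-rate halving on a validation-accuracy plateau.

#' Training configuration
#'
#' Defaults follow the clinical training protocol: Adam at learning
#' rate 1e-5, batch size 8, early stop after 5 epochs without
#' validation-loss improvement, learning rate halved after 3 epochs
#' without validation-accuracy improvement.  \code{max_epochs} is a
#' hard stop on top of early stopping.
#'
#' @param learning_rate initial Adam learning rate (> 0).
#' @param batch_size minibatch size.
#' @param early_stop_patience epochs without val-loss improvement
#'   before stopping (>= 1).
#' @param lr_halve_patience epochs without val-accuracy improvement
#'   before halving the learning rate (>= 1).
#' @param max_epochs hard epoch cap.
#' @param seed integer seed governing shuffling (and any weight
#'   initialization done by the caller).
#' @param mode "scratch" or "transfer" (transfer = start from an
#'   externally supplied checkpoint with the head swapped).
#' @return object of class \code{gait_train_config}.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 8L,
                         early_stop_patience = 5L, lr_halve_patience = 3L,
                         max_epochs = 100L, seed = 1L,
                         mode = c("scratch", "transfer")) {
  mode <- match.arg(mode)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (early_stop_patience < 1L || lr_halve_patience < 1L)
    stop("patiences must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_halve_patience = as.integer(lr_halve_patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), mode = mode),
            class = "gait_train_config")
}

#' Early-stopping check
#'
#' TRUE when the best (lowest) validation loss has not improved for
#' \code{patience} consecutive epochs.
#'
#' @param val_losses per-epoch validation losses so far.
#' @param patience number of non-improving epochs tolerated.
#' @return logical.
#' @export
early_stop_check <- function(val_losses, patience = 5L) {
  stopifnot(length(val_losses) >= 1L)
  best <- which.min(val_losses)  # first epoch attaining the minimum
  (length(val_losses) - best) >= patience
}

#' Learning-rate plateau schedule
#'
#' Halves the learning rate when validation accuracy has not improved
#' (strictly exceeded its running best) for \code{patience} consecutive
#' epochs.  The plateau counter restarts both on improvement and after
#' a halving, so two back-to-back plateaus of length \code{patience}
#' quarter the rate.
#'
#' @param val_accs per-epoch validation accuracies so far.
#' @param lr_history per-epoch learning rates in effect so far (used to
#'   locate the most recent halving).
#' @param patience plateau length (>= 1).
#' @param current_lr learning rate in effect.
#' @return the (possibly halved) learning rate.
#' @export
lr_schedule_step <- function(val_accs, lr_history, patience = 3L,
                             current_lr = NULL) {
  stopifnot(length(val_accs) >= 1L)
  if (is.null(current_lr)) current_lr <- lr_history[length(lr_history)]
  # most recent record-setting epoch
  record <- cummax(val_accs)
  improved <- val_accs >= record & c(TRUE, diff(record) > 0)
  last_record <- max(which(improved), 1L)
  last_halve <- if (length(lr_history) > 1L && any(diff(lr_history) < 0))
    max(which(diff(lr_history) < 0)) + 1L else 0L
  stagnant <- length(val_accs) - max(last_record, last_halve)
  if (stagnant >= patience) current_lr / 2 else current_lr
}

bce_loss <- function(scores, y_onehot) {
  eps <- 1e-12
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(y_onehot * log(p) + (1 - y_onehot) * log(1 - p))
}

labels_to_onehot <- function(labels) {
  yt <- as_gait_factor(labels)
  cbind(ASD = as.numeric(yt == "ASD"), `non-ASD` = as.numeric(yt == "non-ASD"))
}

# One Adam update over the nested gradient tree; moment estimates live
# in `state` (an environment) keyed by parameter path.
adam_step <- function(model, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  tree_update(model, grads, function(param, grad, path) {
    m <- state$m[[path]]
    v <- state$v[[path]]
    if (is.null(m)) { m <- grad * 0; v <- grad * 0 }
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad * grad
    state$m[[path]] <- m
    state$v[[path]] <- v
    param - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
}

#' Train the classifier on one CV fold
#'
#' Minibatch training with Adam and mean binary cross-entropy over the
#' two sigmoid outputs against one-hot labels.  After every epoch the
#' validation loss and accuracy are computed in evaluation mode; the
#' checkpoint with the lowest validation loss is retained, the
#' learning rate follows \code{\link{lr_schedule_step}}, and training
#' ends per \code{\link{early_stop_check}} (or at \code{max_epochs}).
#' Fully reproducible for a fixed seed under single-threaded
#' execution.
#'
#' @param model a \code{gait_cnn} (freshly built, or pretrained with
#'   the head swapped for transfer mode).
#' @param train_set,val_set lists with \code{clips} (list of
#'   \code{(3, T, side, side)} arrays), \code{labels}
#'   ("ASD"/"non-ASD"), and optionally \code{patient} ids.  Patient
#'   sets must be disjoint when ids are given.
#' @param config a \code{\link{train_config}}.
#' @return object of class \code{gait_fit}: \code{model} (best
#'   checkpoint), \code{final_model}, \code{history} data.frame
#'   (epoch, train_loss, val_loss, val_acc, lr), \code{config}.
#' @export
train_fold <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "gait_cnn"),
            inherits(config, "gait_train_config"))
  if (length(train_set$clips) == 0L || length(val_set$clips) == 0L)
    stop_gaitscreen("train and validation sets must be non-empty",
                    "gaitscreen_empty")
  if (!is.null(train_set$patient) && !is.null(val_set$patient) &&
      length(intersect(unique(train_set$patient),
                       unique(val_set$patient))) > 0L)
    stop_gaitscreen("train and validation patients must be disjoint",
                    "gaitscreen_leak")
  y_train <- labels_to_onehot(train_set$labels)
  y_val_f <- as_gait_factor(val_set$labels)
  val_ten <- clips_to_tensor(val_set$clips)
  y_val <- labels_to_onehot(val_set$labels)
  n <- length(train_set$clips)
  state <- new.env(parent = emptyenv())
  state$t <- 0L; state$m <- list(); state$v <- list()
  lr <- config$learning_rate
  hist <- data.frame()
  best_loss <- Inf
  best_model <- model
  with_seed(derive_seed(config$seed, 17L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tl <- 0
      for (b in batches) {
        ten <- clips_to_tensor(train_set$clips[b])
        fw <- net_fwd(model, ten, train = TRUE)
        model <- fw$model  # batch-norm running stats
        yb <- y_train[b, , drop = FALSE]
        tl <- tl + bce_loss(fw$scores, yb) * length(b)
        dlogits <- (fw$scores - yb) / (length(b) * ncol(yb))
        bw <- net_bwd(model, fw$internals, dlogits)
        model <- adam_step(model, bw$grads, state, lr)
      }
      ev <- net_fwd(model, val_ten, train = FALSE)
      val_loss <- bce_loss(ev$scores, y_val)
      pred <- GAIT_LEVELS[max.col(ev$scores, ties.method = "first")]
      val_acc <- mean(pred == as.character(y_val_f))
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / n,
                                     val_loss = val_loss,
                                     val_acc = val_acc, lr = lr))
      if (val_loss < best_loss) {
        best_loss <- val_loss
        best_model <- model
      }
      if (early_stop_check(hist$val_loss, config$early_stop_patience)) break
      lr <- lr_schedule_step(hist$val_acc, hist$lr,
                             config$lr_halve_patience, lr)
    }
  })
  structure(list(model = best_model, final_model = model, history = hist,
                 config = config),
            class = "gait_fit")
}

#' @export
print.gait_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Trained %d epochs (lr %g -> %g); best val loss %.4f at epoch %d; final val acc %.3f\n",
              nrow(h), h$lr[1L], h$lr[nrow(h)], min(h$val_loss),
              which.min(h$val_loss), h$val_acc[nrow(h)]))
  invisible(x)
}

#' @export
predict.gait_fit <- function(object, clips, ...) {
  predict(object$model, clips, ...)
}
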