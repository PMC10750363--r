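# Grad-CAM++: gradient-weighted class-activation maps per frame, fused
# into one explanation image.

#' Grad-CAM++ attention maps for a clip
#'
#' Computes, per temporal slice of the chosen convolutional stage, the
#' Grad-CAM++ channel weights — built from the positive partial
#' derivatives of the target-class logit w.r.t. the stage activations,
#' with the second-order alpha weighting of the method — then forms the
#' rectified weighted activation sum, upsamples it bilinearly to the
#' requested frame size and min-max normalizes over the whole clip.
#' Since every temporal stride of the network is 1, the stage has one
#' temporal slice per sampled frame, giving a true per-frame map.
#'
#' The model is evaluated in inference mode (running batch-norm
#' statistics); the call has no training side effects.
#'
#' @param model a \code{gait_cnn}.
#' @param clip a \code{(3, T, side, side)} array.
#' @param target_class "ASD" or "non-ASD" (or a class index).
#' @param stage which residual stage to visualize, 1-4 (default 4, the
#'   last stage — standard CAM practice).
#' @param frame_size \code{c(H, W)} of the output maps (defaults to
#'   the clip's spatial size).
#' @return object of class \code{gait_cam}: array (T, H, W) in [0, 1],
#'   with attributes \code{target} and \code{stage}.
#' @export
gradcam_pp <- function(model, clip, target_class = "ASD", stage = 4L,
                       frame_size = NULL) {
  stopifnot(inherits(model, "gait_cnn"))
  if (!stage %in% seq_along(model$stages))
    stop_gaitscreen("unknown stage: must be 1-4", "gaitscreen_bad_layer")
  tc <- if (is.character(target_class))
    match(match.arg(target_class, GAIT_LEVELS), GAIT_LEVELS)
  else as.integer(target_class)
  d <- dim(clip)
  if (is.null(frame_size)) frame_size <- c(d[3L], d[4L])
  ten <- clips_to_tensor(clip)
  fw <- net_fwd(model, ten, train = FALSE, cache = TRUE, keep_stage = stage)
  dlogits <- matrix(0, nrow = 1L, ncol = ncol(fw$logits))
  dlogits[1L, tc] <- 1
  bw <- net_bwd(model, fw$internals, dlogits, want_stage = stage)
  A <- fw$internals$stage_out$x          # (P x C), post-ReLU
  G <- bw$dstage                         # dS/dA, same shape
  dims <- fw$internals$stage_out$dims    # (1, T', H', W')
  tprime <- dims[2L]; hh <- dims[3L]; ww <- dims[4L]
  per <- hh * ww
  maps <- array(0, dim = c(tprime, frame_size[1L], frame_size[2L]))
  for (t in seq_len(tprime)) {
    rows <- ((t - 1L) * per + 1L):(t * per)
    a <- A[rows, , drop = FALSE]
    g <- G[rows, , drop = FALSE]
    g2 <- g * g
    # alpha_kij = g^2 / (2 g^2 + (sum_ab A_k) g^3), zero where the
    # denominator vanishes (no gradient flow to that channel)
    denom <- 2 * g2 + sweep(g2 * g, 2L, colSums(a), "*")
    alpha <- ifelse(abs(denom) < 1e-12, 0, g2 / denom)
    w <- colSums(alpha * pmax(g, 0))
    m <- pmax(as.vector(a %*% w), 0)
    m <- matrix(m, nrow = hh, ncol = ww, byrow = TRUE)  # rows ordered w-fastest
    maps[t, , ] <- resize_image(m, frame_size[1L], frame_size[2L])
  }
  rng <- range(maps)
  if (rng[2L] > rng[1L]) maps <- (maps - rng[1L]) / (rng[2L] - rng[1L])
  else maps[] <- 0
  structure(maps, class = "gait_cam", target = GAIT_LEVELS[tc], stage = stage)
}

#' Fuse per-frame attention maps into one image
#'
#' Pixelwise maximum (default) or mean across the T per-frame maps —
#' the maximum preserves each frame's attention peaks; both are
#' invariant to frame order.
#'
#' @param m a \code{gait_cam} (T, H, W array).
#' @param method "max" or "mean".
#' @return (H, W) matrix in [0, 1].
#' @export
fuse_maps <- function(m, method = c("max", "mean")) {
  method <- match.arg(method)
  stopifnot(length(dim(m)) == 3L)
  apply(unclass(m), c(2L, 3L), if (method == "max") max else mean)
}

# Blue -> cyan -> green -> yellow -> red colormap on [0, 1].
colormap_jet <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b)
}

#' Overlay an attention map on a frame
#'
#' Alpha-blends the colormapped attention map onto the frame: red
#' marks areas contributing most positively to the target class, blue
#' least.
#'
#' @param map (H, W) matrix in [0, 1].
#' @param frame (H, W, 3) array in [0, 1].
#' @param alpha blend weight in [0, 1]; 0 returns the frame, 1 the
#'   pure colormap.
#' @return (H, W, 3) array.
#' @export
overlay <- function(map, frame, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  dm <- dim(map); df <- dim(frame)
  if (!identical(as.integer(dm), as.integer(df[1:2])))
    stop_gaitscreen("map and frame sizes differ", "gaitscreen_bad_shape")
  cols <- colormap_jet(as.vector(map))
  heat <- array(cols, dim = c(dm[1L], dm[2L], 3L))
  (1 - alpha) * frame + alpha * heat
}
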