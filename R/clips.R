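# Clip pipeline: 1-second shots, uniform 8-frame sampling, model-ready
# tensors.

#' Slice a frame sequence into 1-second clips
#'
#' Consecutive, non-overlapping windows of \code{fps} frames; a
#' trailing remainder shorter than one second is dropped (training uses
#' full 1-s shots only).
#'
#' @param frames list of (H, W, 3) arrays.
#' @param fps frames per clip (default 30).
#' @param patient_id,label,video_id optional metadata attached to each
#'   clip.
#' @return list of \code{gait_clip} objects (fields: \code{frames},
#'   \code{start_frame} 0-based, \code{patient_id}, \code{label},
#'   \code{video_id}).
#' @export
slice_one_second_clips <- function(frames, fps = 30L, patient_id = NA,
                                   label = NA, video_id = NA) {
  if (fps < 1L) stop("fps must be >= 1")
  n <- length(frames) %/% fps
  lapply(seq_len(n), function(k) {
    structure(list(frames = frames[((k - 1L) * fps + 1L):(k * fps)],
                   start_frame = (k - 1L) * as.integer(fps),
                   patient_id = patient_id, label = label,
                   video_id = video_id),
              class = "gait_clip")
  })
}

#' Uniformly sample T frames from a clip
#'
#' Stride-based uniform sampling: with F frames and T samples, frame
#' \code{floor(k * F / T)} (0-based) is taken for k = 0..T-1.  For
#' F = 30, T = 8 this selects 0, 3, 7, 11, 15, 18, 22, 26.
#' Deterministic and order-preserving.
#'
#' @param clip a \code{gait_clip} (or any list with a \code{frames}
#'   field).
#' @param t_frames number of frames T to keep (default 8).
#' @return a \code{gait_sampled_clip}: the T frames, the 0-based
#'   \code{indices} sampled, and inherited metadata.
#' @export
sample_frames <- function(clip, t_frames = 8L) {
  f_count <- length(clip$frames)
  if (t_frames > f_count)
    stop_gaitscreen("cannot sample more frames than the clip holds",
                    "gaitscreen_bad_sample")
  idx0 <- floor((seq_len(t_frames) - 1L) * f_count / t_frames)
  structure(list(frames = clip$frames[idx0 + 1L],
                 indices = as.integer(idx0),
                 patient_id = clip$patient_id %||% NA,
                 label = clip$label %||% NA,
                 video_id = clip$video_id %||% NA,
                 start_frame = clip$start_frame %||% NA),
            class = "gait_sampled_clip")
}

#' Convert a sampled clip to the model input tensor
#'
#' Isotropically resizes the (square) frames to \code{side} pixels and
#' stacks them channel-first as a \code{(3, T, side, side)} array with
#' values in [0, 1] — the input contract of \code{\link{forward}}.
#' The default side of 224 matches the network's stage geometry
#' (112/56/28/14/7); passing \code{side = 512} feeds crops through
#' unresized.
#'
#' @param s a \code{gait_sampled_clip} (or list of square frames).
#' @param side output spatial size.
#' @return (3, T, side, side) array.
#' @export
resize_for_model <- function(s, side = 224L) {
  frames <- if (is.list(s) && !is.null(s$frames)) s$frames else s
  t_frames <- length(frames)
  out <- array(0, dim = c(3L, t_frames, side, side))
  for (k in seq_len(t_frames)) {
    f <- frames[[k]]
    d <- dim(f)
    if (d[1L] != d[2L])
      stop_gaitscreen("model input frames must be square",
                      "gaitscreen_bad_shape")
    if (d[1L] != side) f <- resize_image(f, side, side)
    f <- pmin(pmax(f, 0), 1)
    out[1L, k, , ] <- f[, , 1L]
    out[2L, k, , ] <- f[, , 2L]
    out[3L, k, , ] <- f[, , 3L]
  }
  out
}

#' Short-side scale and center crop
#'
#' The "without preprocessing" ablation input: scale the shorter image
#' side to \code{target} pixels (keeping aspect ratio) and center-crop
#' a \code{target x target} square — no detection, no tracking.
#'
#' @param frame (H, W, 3) array.
#' @param target square side (default 512).
#' @return (target, target, 3) array.
#' @export
short_side_scale <- function(frame, target = 512L) {
  H <- dim(frame)[1L]; W <- dim(frame)[2L]
  sc <- target / min(H, W)
  H2 <- max(target, round(H * sc)); W2 <- max(target, round(W * sc))
  f <- resize_image(frame, H2, W2)
  r0 <- (H2 - target) %/% 2L
  c0 <- (W2 - target) %/% 2L
  f[r0 + seq_len(target), c0 + seq_len(target), , drop = FALSE]
}

#' Build a dataset index
#'
#' Tabulates clips with patient, label and disease code, enforcing the
#' deterministic code-to-label mapping (ASD -> ASD; DHS, LCS, HipOA ->
#' non-ASD).
#'
#' @param clip_ref character vector of clip references (paths or ids).
#' @param patient_id character vector.
#' @param disease code in \code{c("ASD", "DHS", "LCS", "HipOA")}.
#' @return data.frame with columns clip_ref, patient_id, disease,
#'   label.
#' @export
dataset_index <- function(clip_ref, patient_id, disease) {
  disease <- match.arg(disease, c("ASD", "DHS", "LCS", "HipOA"),
                       several.ok = TRUE)
  stopifnot(length(clip_ref) == length(patient_id),
            length(patient_id) == length(disease))
  label <- ifelse(disease == "ASD", "ASD", "non-ASD")
  data.frame(clip_ref = clip_ref, patient_id = patient_id,
             disease = disease,
             label = factor(label, levels = c("ASD", "non-ASD")),
             stringsAsFactors = FALSE)
}
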