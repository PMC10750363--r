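# Detection stage: locate the patient in every frame, keep their
# identity when a second person enters later, and emit square
# patient-centered crops.
#
# Coordinates are 0-based pixels; boxes are half-open
# [x1, x2) x [y1, y2).  The tracker realizes the first-entrant prior:
# the patient is initialized from frame 0 and followed by the
# shortest-center-distance rule between adjacent frames.

#' Construct a detection
#'
#' A backend-agnostic person detection: bounding box, optional COCO-17
#' keypoints, and a confidence score.  Any detector (the bundled
#' ground-truth oracle, or an external region-based detector with a
#' keypoint head) that produces these satisfies the tracking contract.
#'
#' @param box numeric \code{c(x1, y1, x2, y2)}, half-open, x2 > x1 and
#'   y2 > y1.
#' @param keypoints 17 x 3 matrix (x, y, confidence) in COCO ordering
#'   (rows 12/13 = left/right hip), or \code{NULL}.
#' @param score detection confidence in [0, 1].
#' @return object of class \code{gait_detection}.
#' @export
detection <- function(box, keypoints = NULL, score = 1.0) {
  box <- as.numeric(box)
  names(box) <- c("x1", "y1", "x2", "y2")
  if (box["x2"] <= box["x1"] || box["y2"] <= box["y1"])
    stop("degenerate box: need x2 > x1 and y2 > y1")
  if (score < 0 || score > 1) stop("score must lie in [0, 1]")
  if (!is.null(keypoints)) {
    keypoints <- as.matrix(keypoints)
    if (nrow(keypoints) != 17L || ncol(keypoints) != 3L)
      stop("keypoints must be a 17 x 3 matrix")
    if (any(keypoints[, 3L] < 0 | keypoints[, 3L] > 1))
      stop("keypoint confidences must lie in [0, 1]")
  }
  structure(list(box = box, keypoints = keypoints, score = score),
            class = "gait_detection")
}

#' @rdname detection
#' @param frame_index 0-based frame index (>= 0).
#' @param detections list of \code{gait_detection} objects (possibly
#'   empty).
#' @export
frame_detections <- function(frame_index, detections = list()) {
  if (frame_index < 0) stop("frame_index must be >= 0")
  structure(list(frame_index = as.integer(frame_index),
                 detections = detections),
            class = "gait_frame_detections")
}

box_center <- function(box) {
  c((box[["x1"]] + box[["x2"]]) / 2, (box[["y1"]] + box[["y2"]]) / 2)
}

#' Body center point of a detection
#'
#' The midpoint of the two hip keypoints when both are confidently
#' detected, otherwise the bounding-box center.  When both estimates
#' exist and disagree by more than \code{tolerance_px} (Euclidean), the
#' hip midpoint is kept and the disagreement is flagged for audit.
#'
#' @param det a \code{gait_detection}.
#' @param tolerance_px flag threshold in pixels.
#' @param conf_threshold minimum hip-keypoint confidence for the
#'   keypoint route (a common visibility cutoff).
#' @return list with \code{center} (x, y), \code{source}
#'   ("hips"/"box"), \code{flag}.
#' @export
body_center <- function(det, tolerance_px = 10, conf_threshold = 0.3) {
  stopifnot(inherits(det, "gait_detection"))
  bc <- box_center(det$box)
  kp <- det$keypoints
  if (!is.null(kp) && kp[12L, 3L] >= conf_threshold &&
      kp[13L, 3L] >= conf_threshold) {
    hips <- (kp[12L, 1:2] + kp[13L, 1:2]) / 2
    disagreement <- sqrt(sum((hips - bc)^2))
    list(center = unname(hips), source = "hips",
         flag = disagreement > tolerance_px)
  } else {
    list(center = unname(bc), source = "box", flag = FALSE)
  }
}

#' Select the patient in the first frame
#'
#' The patient always enters the frame before the doctor, so frame 0 is
#' expected to contain the patient alone.  With exactly one detection
#' it is returned; with several (prior violated), the largest-area box
#' wins (ties: lowest x1); with none, a \code{gaitscreen_no_patient}
#' error signals that the first-entrant prior does not hold.
#'
#' @param first a \code{gait_frame_detections} with
#'   \code{frame_index == 0}.
#' @return a \code{gait_detection}.
#' @export
select_initial_patient <- function(first) {
  stopifnot(inherits(first, "gait_frame_detections"))
  if (first$frame_index != 0L) stop("expected detections of frame 0")
  dets <- first$detections
  if (length(dets) == 0L)
    stop_gaitscreen("no person detected in the first frame",
                    "gaitscreen_no_patient")
  if (length(dets) == 1L) return(dets[[1L]])
  areas <- vapply(dets, function(d)
    (d$box[["x2"]] - d$box[["x1"]]) * (d$box[["y2"]] - d$box[["y1"]]),
    numeric(1))
  x1s <- vapply(dets, function(d) d$box[["x1"]], numeric(1))
  best <- which(areas == max(areas))
  if (length(best) > 1L) best <- best[which.min(x1s[best])]
  dets[[best]]
}

#' Track the patient across frames
#'
#' Initializes from frame 0 via \code{\link{select_initial_patient}},
#' then, frame by frame, chooses the detection whose body center is
#' nearest (Euclidean) to the previously chosen center — the same
#' person moves the shortest distance between adjacent frames.  Ties
#' pick the lowest detection index.  Frames with no detections carry
#' the previous detection over (recorded in \code{gap_frames}); more
#' than \code{max_gap} consecutive empty frames raise a
#' \code{gaitscreen_track_lost} error.
#'
#' @param frames list of \code{gait_frame_detections}, ordered,
#'   starting at frame 0.
#' @param max_gap maximum consecutive carry-over frames.
#' @param tolerance_px passed to \code{\link{body_center}}.
#' @return object of class \code{gait_track}: data.frame
#'   \code{track} (frame, x1, y1, x2, y2, cx, cy, carried, flag) plus
#'   \code{gap_frames} and the chosen detections.
#' @export
track_patient <- function(frames, max_gap = 5L, tolerance_px = 10) {
  stopifnot(length(frames) >= 1L)
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (idx[1L] != 0L || any(diff(idx) != 1L))
    stop("frame indices must be contiguous starting at 0")
  current <- select_initial_patient(frames[[1L]])
  cc <- body_center(current, tolerance_px)
  n <- length(frames)
  rows <- vector("list", n)
  chosen <- vector("list", n)
  gap_frames <- integer(0)
  consec <- 0L
  rows[[1L]] <- data.frame(frame = 0L, x1 = current$box[["x1"]],
                           y1 = current$box[["y1"]], x2 = current$box[["x2"]],
                           y2 = current$box[["y2"]], cx = cc$center[1L],
                           cy = cc$center[2L], carried = FALSE,
                           flag = cc$flag)
  chosen[[1L]] <- current
  for (i in 2:n) {
    if (n < 2L) break
    dets <- frames[[i]]$detections
    if (length(dets) == 0L) {
      consec <- consec + 1L
      if (consec > max_gap)
        stop_gaitscreen(sprintf("track lost: more than %d consecutive frames without detections", max_gap),
                        "gaitscreen_track_lost")
      gap_frames <- c(gap_frames, idx[i])
      rows[[i]] <- transform(rows[[i - 1L]], frame = idx[i], carried = TRUE)
      chosen[[i]] <- chosen[[i - 1L]]
      next
    }
    consec <- 0L
    centers <- lapply(dets, body_center, tolerance_px = tolerance_px)
    d2 <- vapply(centers, function(ctr)
      sum((ctr$center - c(rows[[i - 1L]]$cx, rows[[i - 1L]]$cy))^2),
      numeric(1))
    j <- which.min(d2)  # first minimum = lowest index on ties
    current <- dets[[j]]
    cc <- centers[[j]]
    rows[[i]] <- data.frame(frame = idx[i], x1 = current$box[["x1"]],
                            y1 = current$box[["y1"]], x2 = current$box[["x2"]],
                            y2 = current$box[["y2"]], cx = cc$center[1L],
                            cy = cc$center[2L], carried = FALSE,
                            flag = cc$flag)
    chosen[[i]] <- current
  }
  structure(list(track = do.call(rbind, rows), gap_frames = gap_frames,
                 detections = chosen),
            class = "gait_track")
}

#' @export
print.gait_track <- function(x, ...) {
  cat(sprintf("Patient track over %d frames (%d carried over)\n",
              nrow(x$track), length(x$gap_frames)))
  invisible(x)
}

#' Square patient-centered crop
#'
#' Extracts a square region whose side equals the bounding-box height
#' (y2 - y1) — the retained patient height is the base length for
#' cropping — centered at the tracked body center, then resizes it
#' isotropically to \code{out_side} pixels.  Because the source region
#' is square, no aspect distortion occurs.  Parts of the square falling
#' outside the frame are filled by edge-pixel replication (or zeros).
#'
#' @param frame (H, W, 3) array in [0, 1].
#' @param box the detection box, \code{c(x1, y1, x2, y2)}.
#' @param center the body center (x, y); defaults to the box center.
#' @param out_side output side in pixels (default 512).
#' @param fill \code{"replicate"} (default) or \code{"zero"}.
#' @return (out_side, out_side, 3) array.
#' @export
crop_square <- function(frame, box, center = NULL, out_side = 512L,
                        fill = c("replicate", "zero")) {
  fill <- match.arg(fill)
  if (out_side < 1L) stop("out_side must be >= 1")
  s <- box[["y2"]] - box[["y1"]]
  if (s <= 0) stop_gaitscreen("box height must be positive",
                              "gaitscreen_bad_box")
  if (is.null(center)) center <- box_center(box)
  H <- dim(frame)[1L]; W <- dim(frame)[2L]
  side <- max(1L, round(s))
  x_start <- round(center[1L] - s / 2)  # 0-based column of square
  y_start <- round(center[2L] - s / 2)
  cols <- x_start + seq_len(side)  # 1-based pixel indices
  rows <- y_start + seq_len(side)
  cc <- pmin(pmax(cols, 1L), W)
  rc <- pmin(pmax(rows, 1L), H)
  src <- frame[rc, cc, , drop = FALSE]
  if (fill == "zero") {
    src[rows < 1L | rows > H, , ] <- 0
    src[, cols < 1L | cols > W, ] <- 0
  }
  if (side == out_side) return(src)
  resize_image(src, out_side, out_side)
}

#' Extract the cropped patient clip from a video
#'
#' Runs the full detection stage: per-frame detections (from a backend
#' function or a precomputed list), patient tracking with the
#' first-entrant prior, and one square patient-centered crop per frame.
#'
#' @param frames list of (H, W, 3) arrays.
#' @param detections either a list of \code{gait_frame_detections}
#'   (one per frame) or a function \code{f(frame, frame_index)}
#'   returning one.
#' @param out_side crop side (default 512).
#' @param max_gap,tolerance_px,fill passed through.
#' @return list with \code{frames} (cropped, all
#'   \code{out_side x out_side x 3}) and \code{track}.
#' @export
extract_patient_clip <- function(frames, detections, out_side = 512L,
                                 max_gap = 5L, tolerance_px = 10,
                                 fill = "replicate") {
  stopifnot(length(frames) >= 1L)
  if (is.function(detections)) {
    detections <- lapply(seq_along(frames), function(i)
      detections(frames[[i]], i - 1L))
  }
  stopifnot(length(detections) == length(frames))
  trk <- track_patient(detections, max_gap = max_gap,
                       tolerance_px = tolerance_px)
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    r <- trk$track[i, ]
    out[[i]] <- crop_square(frames[[i]],
                            c(x1 = r$x1, y1 = r$y1, x2 = r$x2, y2 = r$y2),
                            center = c(r$cx, r$cy), out_side = out_side,
                            fill = fill)
  }
  list(frames = out, track = trk)
}
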