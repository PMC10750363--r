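# Synthetic walking scenes.
#
# A side-view camera at a fixed location watches a single figure cross
# the frame; an optional second figure (the accompanying doctor) enters
# later and trails the first.  Figures are articulated stick figures
# with an elliptical torso and head drawn on a static cluttered
# background, so limb oscillation, trunk pitch and head drop exist as
# real pixel motion and every frame carries exact ground truth (boxes,
# 17 keypoints in COCO ordering, identities).

#' Gait motion signature
#'
#' Class-dependent kinematic parameters of a synthetic walker.
#'
#' @param trunk_pitch_deg forward trunk lean amplitude (degrees, >= 0).
#' @param head_drop_deg head flexion relative to the trunk (degrees, >= 0).
#' @param stride_px horizontal translation per frame (pixels, > 0).
#' @param sway_px vertical pelvis bob amplitude (pixels, >= 0).
#' @param limb_phase gait-cycle phase offset in [0, 2*pi).
#' @return object of class \code{gait_signature}.
#' @export
motion_signature <- function(trunk_pitch_deg = 5, head_drop_deg = 3,
                             stride_px = 4, sway_px = 2, limb_phase = 0) {
  if (trunk_pitch_deg < 0 || head_drop_deg < 0 || sway_px < 0)
    stop("amplitudes must be >= 0")
  if (stride_px <= 0) stop("stride_px must be > 0")
  if (limb_phase < 0 || limb_phase >= 2 * pi)
    stop("limb_phase must lie in [0, 2*pi)")
  structure(list(trunk_pitch_deg = trunk_pitch_deg,
                 head_drop_deg = head_drop_deg,
                 stride_px = stride_px, sway_px = sway_px,
                 limb_phase = limb_phase),
            class = "gait_signature")
}

#' Synthetic scene configuration
#'
#' @param frame_width,frame_height frame size in pixels (defaults
#'   640 x 360; the clinical recording geometry, 1920 x 1080, is
#'   available by passing those values).
#' @param fps frames per second (default 30).
#' @param n_frames number of frames (>= 1).
#' @param patient_signature a \code{\link{motion_signature}}.
#' @param distractor_entry_frame 0-based frame at which a second figure
#'   appears, or \code{NULL} for none.  Must be >= 1: the patient is
#'   always alone in frame 0 (the first-entrant prior).
#' @param distractor_gap_px minimum horizontal center distance by which
#'   the second figure trails the patient.
#' @param background_clutter number of static background shapes.
#' @param start_x patient pelvis x at frame 0 (pixels; default places
#'   the figure near the left edge).
#' @param seed integer seed; generation is a pure function of
#'   config + seed.
#' @return object of class \code{gait_scene_config}.
#' @export
scene_config <- function(frame_width = 640L, frame_height = 360L, fps = 30L,
                         n_frames = 30L,
                         patient_signature = motion_signature(),
                         distractor_entry_frame = NULL,
                         distractor_gap_px = 90,
                         background_clutter = 8L,
                         start_x = NULL, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (fps <= 0L) stop("fps must be > 0")
  if (!is.null(distractor_entry_frame) && distractor_entry_frame < 1L)
    stop("distractor_entry_frame must be >= 1 (patient enters first)")
  stopifnot(inherits(patient_signature, "gait_signature"))
  structure(list(frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 fps = as.integer(fps), n_frames = as.integer(n_frames),
                 patient_signature = patient_signature,
                 distractor_entry_frame =
                   if (is.null(distractor_entry_frame)) NULL
                   else as.integer(distractor_entry_frame),
                 distractor_gap_px = distractor_gap_px,
                 background_clutter = as.integer(background_clutter),
                 start_x = start_x, seed = as.integer(seed)),
            class = "gait_scene_config")
}

# --- figure kinematics ------------------------------------------------

# Joint positions of a stick walker at one frame.  `pelvis` is (x, y) in
# pixel coordinates (y grows downward); returns a named list of joints
# plus the COCO-17 keypoint matrix.
walker_pose <- function(pelvis, fig_h, sig, phase) {
  deg <- pi / 180
  lean <- (sig$trunk_pitch_deg * (0.85 + 0.15 * sin(phase))) * deg
  trunk_len <- 0.34 * fig_h
  neck <- c(pelvis[1] + trunk_len * sin(lean),
            pelvis[2] - trunk_len * cos(lean))
  head_ang <- lean + sig$head_drop_deg * deg
  head_len <- 0.16 * fig_h
  head <- c(neck[1] + head_len * sin(head_ang),
            neck[2] - head_len * cos(head_ang))
  thigh <- 0.24 * fig_h; shin <- 0.24 * fig_h
  arm_u <- 0.16 * fig_h; arm_l <- 0.15 * fig_h
  swing <- 28 * deg * sin(phase)
  knee_bend <- 20 * deg * pmax(0, sin(phase + pi / 2))
  leg <- function(s, bend_side) {
    hip_ang <- s * swing
    knee <- c(pelvis[1] + thigh * sin(hip_ang),
              pelvis[2] + thigh * cos(hip_ang))
    ank_ang <- hip_ang - bend_side
    ankle <- c(knee[1] + shin * sin(ank_ang), knee[2] + shin * cos(ank_ang))
    list(knee = knee, ankle = ankle)
  }
  lleg <- leg(+1, knee_bend)
  rleg <- leg(-1, 20 * deg * pmax(0, sin(phase - pi / 2)))
  arm <- function(s) {
    sh_ang <- lean - s * 0.7 * swing
    elbow <- c(neck[1] + arm_u * sin(sh_ang), neck[2] + arm_u * cos(sh_ang))
    wrist <- c(elbow[1] + arm_l * sin(sh_ang + 15 * deg),
               elbow[2] + arm_l * cos(sh_ang + 15 * deg))
    list(elbow = elbow, wrist = wrist)
  }
  larm <- arm(+1); rarm <- arm(-1)
  shoulder_off <- 0.035 * fig_h
  hip_off <- 0.03 * fig_h
  kp <- rbind(
    nose = c(head[1] + 0.05 * fig_h * sin(head_ang + 30 * deg),
             head[2] - 0.05 * fig_h * cos(head_ang + 30 * deg)),
    left_eye = head + c(0.02 * fig_h, -0.02 * fig_h),
    right_eye = head + c(-0.02 * fig_h, -0.02 * fig_h),
    left_ear = head + c(0.03 * fig_h, 0),
    right_ear = head + c(-0.03 * fig_h, 0),
    left_shoulder = neck + c(shoulder_off, 0),
    right_shoulder = neck + c(-shoulder_off, 0),
    left_elbow = larm$elbow, right_elbow = rarm$elbow,
    left_wrist = larm$wrist, right_wrist = rarm$wrist,
    left_hip = pelvis + c(hip_off, 0),
    right_hip = pelvis + c(-hip_off, 0),
    left_knee = lleg$knee, right_knee = rleg$knee,
    left_ankle = lleg$ankle, right_ankle = rleg$ankle)
  list(pelvis = pelvis, neck = neck, head = head,
       lleg = lleg, rleg = rleg, larm = larm, rarm = rarm,
       keypoints = cbind(kp, confidence = 1))
}

# --- rasterization ----------------------------------------------------

disc_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE])
}

# Stamp a thick segment onto an (H, W, 3) canvas.  Pixel (row, col) has
# center (col - 0.5, row - 0.5) in 0-based x/y coordinates.
draw_segment <- function(canvas, p1, p2, col, thick = 2L) {
  len <- sqrt(sum((p2 - p1)^2))
  n <- max(2L, ceiling(len / 0.7))
  tt <- seq(0, 1, length.out = n)
  pts <- cbind(p1[2] + tt * (p2[2] - p1[2]), p1[1] + tt * (p2[1] - p1[1]))
  off <- disc_offsets(thick)
  rows <- round(rep(pts[, 1] + 0.5, each = nrow(off)) + off[, "dy"])
  cols <- round(rep(pts[, 2] + 0.5, each = nrow(off)) + off[, "dx"])
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  keep <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  rows <- rows[keep]; cols <- cols[keep]
  for (ch in 1:3) canvas[cbind(rows, cols, ch)] <- col[ch]
  canvas
}

draw_ellipse <- function(canvas, center, rx, ry, col, angle = 0) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  r <- ceiling(max(rx, ry)) + 1L
  rows <- max(1L, floor(center[2] - r)):min(H, ceiling(center[2] + r))
  cols <- max(1L, floor(center[1] - r)):min(W, ceiling(center[1] + r))
  if (!length(rows) || !length(cols)) return(canvas)
  g <- expand.grid(row = rows, col = cols)
  dx <- (g$col - 0.5) - center[1]
  dy <- (g$row - 0.5) - center[2]
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  if (!any(inside)) return(canvas)
  g <- g[inside, , drop = FALSE]
  for (ch in 1:3) canvas[cbind(g$row, g$col, ch)] <- col[ch]
  canvas
}

draw_walker <- function(canvas, pose, fig_h, col) {
  seg <- function(cv, a, b, th = max(2L, round(fig_h / 50)))
    draw_segment(cv, a, b, col, th)
  lean_ang <- atan2(pose$neck[1] - pose$pelvis[1],
                    -(pose$neck[2] - pose$pelvis[2]))
  canvas <- draw_ellipse(canvas,
                         (pose$pelvis + pose$neck) / 2,
                         rx = 0.07 * fig_h,
                         ry = 0.20 * fig_h, col, angle = -lean_ang)
  canvas <- seg(canvas, pose$pelvis, pose$neck)
  canvas <- seg(canvas, pose$pelvis, pose$lleg$knee)
  canvas <- seg(canvas, pose$lleg$knee, pose$lleg$ankle)
  canvas <- seg(canvas, pose$pelvis, pose$rleg$knee)
  canvas <- seg(canvas, pose$rleg$knee, pose$rleg$ankle)
  canvas <- seg(canvas, pose$neck, pose$larm$elbow)
  canvas <- seg(canvas, pose$larm$elbow, pose$larm$wrist)
  canvas <- seg(canvas, pose$neck, pose$rarm$elbow)
  canvas <- seg(canvas, pose$rarm$elbow, pose$rarm$wrist)
  draw_ellipse(canvas, pose$head, rx = 0.07 * fig_h, ry = 0.08 * fig_h, col)
}

# Ground-truth box from joint extremes, padded, clamped to the frame.
pose_box <- function(pose, fig_h, W, H) {
  pts <- rbind(pose$keypoints[, 1:2], pose$pelvis, pose$neck, pose$head)
  pad <- 0.09 * fig_h
  box <- c(x1 = max(0, min(pts[, 1]) - pad),
           y1 = max(0, min(pts[, 2]) - pad - 0.08 * fig_h),
           x2 = min(W, max(pts[, 1]) + pad),
           y2 = min(H, max(pts[, 2]) + pad))
  box
}

render_background <- function(W, H, clutter) {
  base <- seq(0.55, 0.75, length.out = H)
  canvas <- array(rep(base, times = W * 3), dim = c(H, W, 3))
  canvas <- canvas + array(runif(H * W, -0.02, 0.02), dim = c(H, W, 3))
  for (i in seq_len(clutter)) {
    col <- runif(3, 0.2, 0.9)
    cx <- runif(1, 0, W); cy <- runif(1, 0, H)
    if (runif(1) < 0.5) {
      w2 <- runif(1, 8, W / 6); h2 <- runif(1, 8, H / 4)
      rows <- max(1, round(cy - h2)):min(H, round(cy + h2))
      cols <- max(1, round(cx - w2)):min(W, round(cx + w2))
      for (ch in 1:3) canvas[rows, cols, ch] <- col[ch]
    } else {
      canvas <- draw_ellipse(canvas, c(cx, cy), runif(1, 6, W / 10),
                             runif(1, 6, H / 8), col)
    }
  }
  pmin(pmax(canvas, 0), 1)
}

#' Generate a synthetic walking scene
#'
#' Renders a walking figure crossing a static cluttered background from
#' left to right, with per-frame ground truth (identity, bounding box,
#' 17 COCO-ordered keypoints, all in 0-based pixel coordinates with
#' half-open boxes).  If \code{distractor_entry_frame} is set, a second
#' figure appears from that frame onward, trailing the patient by at
#' least \code{distractor_gap_px}.  If the patient would leave the frame
#' before \code{n_frames}, the scene is truncated and flagged
#' (\code{scene$truncated}), never wrapped around.  Output is bitwise
#' deterministic for a fixed config.
#'
#' @param config a \code{\link{scene_config}}.
#' @return object of class \code{gait_scene}: list with \code{frames}
#'   (list of (H, W, 3) arrays in [0, 1]), \code{truth} (per-frame list
#'   of persons: \code{id}, \code{box}, \code{keypoints}),
#'   \code{config}, \code{truncated}.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "gait_scene_config"))
  with_seed(config$seed, {
    W <- config$frame_width; H <- config$frame_height
    sig <- config$patient_signature
    fig_h <- 0.42 * H
    background <- render_background(W, H, config$background_clutter)
    dsig <- motion_signature(
      trunk_pitch_deg = 2, head_drop_deg = 2,
      stride_px = sig$stride_px, sway_px = 1.5,
      limb_phase = (sig$limb_phase + pi) %% (2 * pi))
    x0 <- config$start_x %||% (0.18 * W)
    y0 <- H - 0.30 * H  # pelvis height above floor line
    omega <- 2 * pi / config$fps
    frames <- vector("list", config$n_frames)
    truth <- vector("list", config$n_frames)
    truncated <- FALSE
    n_done <- 0L
    for (t in seq_len(config$n_frames) - 1L) {
      px <- x0 + sig$stride_px * t
      if (px > W - 0.25 * fig_h) { truncated <- TRUE; break }
      py <- y0 - fig_h * 0.48 + sig$sway_px * sin(2 * omega * t + sig$limb_phase)
      pose <- walker_pose(c(px, py), fig_h, sig, omega * t + sig$limb_phase)
      canvas <- background
      persons <- list()
      if (!is.null(config$distractor_entry_frame) &&
          t >= config$distractor_entry_frame) {
        dx <- px - config$distractor_gap_px
        dpose <- walker_pose(c(dx, py), fig_h * 0.95, dsig,
                             omega * t + dsig$limb_phase)
        if (dx > -0.1 * fig_h) {  # at least partially visible
          canvas <- draw_walker(canvas, dpose, fig_h * 0.95, c(0.35, 0.25, 0.45))
          persons <- c(persons, list(list(
            id = "distractor",
            box = pose_box(dpose, fig_h * 0.95, W, H),
            keypoints = dpose$keypoints)))
        }
      }
      canvas <- draw_walker(canvas, pose, fig_h, c(0.10, 0.15, 0.55))
      persons <- c(list(list(id = "patient",
                             box = pose_box(pose, fig_h, W, H),
                             keypoints = pose$keypoints)), persons)
      frames[[t + 1L]] <- canvas
      truth[[t + 1L]] <- persons
      n_done <- t + 1L
    }
    if (n_done == 0L)
      stop_gaitscreen("figure leaves the frame before the first frame",
                      "gaitscreen_bad_scene")
    structure(list(frames = frames[seq_len(n_done)],
                   truth = truth[seq_len(n_done)],
                   config = config, truncated = truncated),
              class = "gait_scene")
  })
}

#' @export
print.gait_scene <- function(x, ...) {
  cat(sprintf("Synthetic walking scene: %d frames of %dx%d%s\n",
              length(x$frames), x$config$frame_width,
              x$config$frame_height,
              if (x$truncated) " (truncated: figure reached frame edge)" else ""))
  invisible(x)
}

#' Oracle person detector
#'
#' Returns the stored ground truth of one frame as detections with
#' confidence 1.0 and identity tags stripped — a perfect detection
#' backend satisfying the same contract as a learned detector, used to
#' test the tracking and cropping stages in isolation.
#'
#' @param scene a \code{gait_scene}.
#' @param frame_index 0-based frame index.
#' @return a frame-detections object: list(frame_index, detections),
#'   each detection holding \code{box}, \code{keypoints}, \code{score}.
#' @export
oracle_detector <- function(scene, frame_index) {
  stopifnot(inherits(scene, "gait_scene"))
  if (frame_index < 0 || frame_index >= length(scene$frames))
    stop_gaitscreen("frame_index out of range", "gaitscreen_bad_index")
  persons <- scene$truth[[frame_index + 1L]]
  dets <- lapply(persons, function(p)
    detection(box = p$box, keypoints = p$keypoints, score = 1.0))
  frame_detections(frame_index, dets)
}

#' All-frame oracle detections for a scene
#'
#' @param scene a \code{gait_scene}.
#' @return list of frame-detections objects, frames 0..n-1.
#' @export
detect_scene <- function(scene) {
  lapply(seq_along(scene$frames) - 1L, function(i) oracle_detector(scene, i))
}

# --- cohorts ----------------------------------------------------------

# Class-mean signatures.  ASD walkers lean forward with a dropped head,
# a slightly shorter stride and more vertical sway than non-ASD
# walkers; `separation` in [0, 1] interpolates both class means toward
# their midpoint (0 = identical distributions, the no-signal control).
class_mean_signature <- function(label, separation = 1) {
  asd <- c(trunk_pitch = 22, head_drop = 15, stride = 3.6, sway = 3.5)
  non <- c(trunk_pitch = 4, head_drop = 3, stride = 4.4, sway = 1.5)
  mid <- (asd + non) / 2
  m <- if (label == "ASD") mid + separation * (asd - mid)
       else mid + separation * (non - mid)
  m
}

#' Generate a synthetic patient cohort
#'
#' Emulates the structure of a clinical gait-video dataset: patients
#' with a binary diagnosis (ASD / non-ASD), each contributing several
#' 1-second walking scenes.  ASD-labeled patients draw their motion
#' signature from one parameter family (pronounced trunk pitch and head
#' drop), non-ASD patients from another; per-patient signatures are
#' jittered around the class mean, and \code{separation} scales the
#' distance between the two class means (0 gives identical
#' distributions — a no-signal control).
#'
#' Scenes are stored as configurations and rendered on demand by
#' \code{\link{cohort_scenes}} (a 12-patient cohort of full RGB frames
#' would not fit comfortably in memory).
#'
#' @param n_patients number of patients (>= 2).
#' @param class_ratio fraction of ASD patients in (0, 1); the default
#'   mirrors the 54/81 clinical imbalance.
#' @param clips_per_patient 1-second scenes per patient.
#' @param seed integer seed.
#' @param separation class-mean separation scale in [0, 1].
#' @param frame_width,frame_height,fps scene geometry.
#' @return object of class \code{gait_cohort}: \code{patients}
#'   data.frame (patient_id, label), \code{signatures},
#'   \code{scene_configs}, \code{class_ratio}, \code{seed}.
#' @export
generate_cohort <- function(n_patients, class_ratio = 54 / 81,
                            clips_per_patient = 3L, seed = 1L,
                            separation = 1,
                            frame_width = 640L, frame_height = 360L,
                            fps = 30L) {
  if (n_patients < 2L) stop("n_patients must be >= 2")
  if (class_ratio <= 0 || class_ratio >= 1)
    stop("class_ratio must be in (0, 1)")
  n_asd <- round(n_patients * class_ratio)
  if (n_asd < 1L || n_asd > n_patients - 1L)
    stop_gaitscreen("n_patients too small to realize both classes",
                    "gaitscreen_bad_cohort")
  with_seed(seed, {
    labels <- sample(c(rep("ASD", n_asd), rep("non-ASD", n_patients - n_asd)))
    patients <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      label = factor(labels, levels = c("ASD", "non-ASD")),
      stringsAsFactors = FALSE)
    signatures <- list()
    scene_configs <- list()
    for (i in seq_len(n_patients)) {
      m <- class_mean_signature(as.character(patients$label[i]), separation)
      sig <- motion_signature(
        trunk_pitch_deg = max(0, m["trunk_pitch"] + rnorm(1, 0, 1.5)),
        head_drop_deg = max(0, m["head_drop"] + rnorm(1, 0, 1.5)),
        stride_px = max(1.5, m["stride"] + rnorm(1, 0, 0.25)),
        sway_px = max(0, m["sway"] + rnorm(1, 0, 0.4)),
        limb_phase = runif(1, 0, 2 * pi - 1e-9))
      signatures[[patients$patient_id[i]]] <- sig
      cfgs <- vector("list", clips_per_patient)
      for (k in seq_len(clips_per_patient)) {
        with_doctor <- runif(1) < 0.5
        cfgs[[k]] <- scene_config(
          frame_width = frame_width, frame_height = frame_height,
          fps = fps, n_frames = fps,
          patient_signature = sig,
          distractor_entry_frame = if (with_doctor)
            sample(5:(fps %/% 2), 1L) else NULL,
          distractor_gap_px = 0.22 * frame_width,
          start_x = runif(1, 0.25, 0.45) * frame_width,
          seed = derive_seed(seed, i * 1000L + k))
      }
      scene_configs[[patients$patient_id[i]]] <- cfgs
    }
    structure(list(patients = patients, signatures = signatures,
                   scene_configs = scene_configs,
                   class_ratio = class_ratio, seed = as.integer(seed),
                   separation = separation),
              class = "gait_cohort")
  })
}

#' Render the scenes of one cohort patient
#'
#' @param cohort a \code{gait_cohort}.
#' @param patient_id one of \code{cohort$patients$patient_id}.
#' @return list of \code{gait_scene} objects.
#' @export
cohort_scenes <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "gait_cohort"))
  cfgs <- cohort$scene_configs[[patient_id]]
  if (is.null(cfgs)) stop("unknown patient_id")
  lapply(cfgs, generate_scene)
}

#' @export
print.gait_cohort <- function(x, ...) {
  tab <- table(x$patients$label)
  cat(sprintf("Synthetic gait cohort: %d patients (%d ASD / %d non-ASD), %d scenes each, separation %g\n",
              nrow(x$patients), tab[["ASD"]], tab[["non-ASD"]],
              length(x$scene_configs[[1L]]), x$separation))
  invisible(x)
}

#' Write a scene to disk (PNG frames + JSON ground truth)
#'
#' Frames are written as zero-padded PNGs and the ground truth as a
#' JSON sidecar with per-frame boxes (pixel coordinates) and keypoints
#' as (x, y, confidence) triples.
#'
#' @param scene a \code{gait_scene}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "gait_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(scene$frames)) {
    img <- EBImage::Image(aperm(scene$frames[[i]], c(2L, 1L, 3L)),
                          colormode = "Color")
    EBImage::writeImage(img, file.path(dir, sprintf("frame_%04d.png", i - 1L)))
  }
  truth <- lapply(scene$truth, function(persons)
    lapply(persons, function(p)
      list(id = p$id, box = as.numeric(p$box),
           keypoints = unname(as.matrix(p$keypoints)))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
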