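hip_kp <- function(lx, ly, rx, ry, conf = 0.9) {
  kp <- matrix(c(0, 0, 0.9), 17L, 3L, byrow = TRUE)
  kp[12L, ] <- c(lx, ly, conf)
  kp[13L, ] <- c(rx, ry, conf)
  kp
}

test_that("body center uses the hip midpoint and falls back to the box center", {
  d <- detection(box = c(0, 0, 40, 40), keypoints = hip_kp(10, 20, 30, 20))
  bc <- body_center(d, tolerance_px = 20)
  expect_equal(bc$center, c(20, 20))
  expect_identical(bc$source, "hips")
  expect_false(bc$flag)

  d2 <- detection(box = c(0, 0, 100, 200))
  bc2 <- body_center(d2)
  expect_equal(bc2$center, c(50, 100))
  expect_identical(bc2$source, "box")

  # low hip confidence also falls back to the box center
  d3 <- detection(box = c(0, 0, 100, 200),
                  keypoints = hip_kp(10, 20, 30, 20, conf = 0.1))
  expect_identical(body_center(d3)$source, "box")

  # hip midpoint kept but flagged when it disagrees with the box center
  d4 <- detection(box = c(10, 0, 110, 40), keypoints = hip_kp(10, 20, 30, 20))
  bc4 <- body_center(d4, tolerance_px = 10)  # box center (60, 20)
  expect_equal(bc4$center, c(20, 20))
  expect_true(bc4$flag)
})

test_that("initial patient selection follows the first-entrant prior", {
  one <- frame_detections(0L, list(detection(c(0, 0, 10, 10))))
  expect_identical(select_initial_patient(one), one$detections[[1]])

  two <- frame_detections(0L, list(detection(c(0, 0, 10, 10)),      # area 100
                                   detection(c(20, 0, 40, 20))))    # area 400
  expect_equal(select_initial_patient(two)$box[["x1"]], 20)

  tie <- frame_detections(0L, list(detection(c(50, 0, 60, 10)),
                                   detection(c(5, 0, 15, 10))))
  expect_equal(select_initial_patient(tie)$box[["x1"]], 5)  # tie -> lowest x1

  expect_error(select_initial_patient(frame_detections(0L, list())),
               class = "gaitscreen_no_patient")
})

test_that("tracking follows the sole person and applies the tie rule", {
  frames <- lapply(0:4, function(i)
    frame_detections(i, list(detection(c(10 + 4 * i, 0, 30 + 4 * i, 50)))))
  trk <- track_patient(frames)
  expect_equal(trk$track$x1, 10 + 4 * (0:4))
  expect_length(trk$gap_frames, 0L)

  # two candidates equidistant from the previous center: index 0 wins
  f0 <- frame_detections(0L, list(detection(c(40, 0, 60, 50))))  # center x 50
  f1 <- frame_detections(1L, list(detection(c(50, 0, 70, 50)),   # center x 60
                                  detection(c(30, 0, 50, 50))))  # center x 40
  trk2 <- track_patient(list(f0, f1))
  expect_equal(trk2$track$x1[2], 50)
})

test_that("empty frames carry over up to max_gap, then the track is lost", {
  det <- detection(c(10, 0, 30, 50))
  frames <- list(frame_detections(0L, list(det)),
                 frame_detections(1L, list()),
                 frame_detections(2L, list()),
                 frame_detections(3L, list(detection(c(22, 0, 42, 50)))))
  trk <- track_patient(frames, max_gap = 2L)
  expect_identical(trk$gap_frames, c(1L, 2L))
  expect_true(all(trk$track$carried == c(FALSE, TRUE, TRUE, FALSE)))
  expect_equal(trk$track$x1[2], 10)  # carried box

  lost <- c(frames[1], lapply(1:3, function(i) frame_detections(i, list())))
  expect_error(track_patient(lost, max_gap = 2L),
               class = "gaitscreen_track_lost")
})

test_that("tracking never switches identity when figures stay far apart", {
  for (seed in 1:3) {
    sc <- generate_scene(small_scene_config(seed = seed, entry = 5L))
    trk <- track_patient(detect_scene(sc))
    truth_x1 <- vapply(sc$truth, function(tr) tr[[1]]$box[["x1"]], numeric(1))
    expect_equal(trk$track$x1, truth_x1)
  }
})

test_that("crop geometry matches the stated rule exactly", {
  fr <- coord_frame(480L, 640L)
  box <- c(x1 = 100, y1 = 200, x2 = 180, y2 = 400)
  out <- crop_square(fr, box, center = c(140, 300), out_side = 200L)
  expect_identical(dim(out), c(200L, 200L, 3L))
  # source square x in [40, 240), y in [200, 400): first/last pixel centers
  expect_equal(out[1, 1, 1], 41 / 640)    # column 41 = x 40.5
  expect_equal(out[1, 200, 1], 240 / 640)
  expect_equal(out[1, 1, 2], 201 / 480)   # row 201 = y 200.5
  expect_equal(out[200, 1, 2], 400 / 480)
})

test_that("out-of-frame crop regions are edge-replicated (or zero-filled)", {
  fr <- coord_frame(480L, 640L)
  box <- c(x1 = 0, y1 = 100, x2 = 60, y2 = 300)   # height 200
  out <- crop_square(fr, box, center = c(20, 200), out_side = 200L)
  # shortfall = 100 - 20 = 80 replicated columns on the left
  expect_true(all(out[, 1:80, 1] == 1 / 640))
  expect_equal(out[1, 81, 1], 1 / 640)  # first real column is column 1
  expect_equal(out[1, 82, 1], 2 / 640)
  outz <- crop_square(fr, box, center = c(20, 200), out_side = 200L,
                      fill = "zero")
  expect_true(all(outz[, 1:80, ] == 0))
  expect_error(crop_square(fr, c(x1 = 0, y1 = 50, x2 = 60, y2 = 50)),
               class = "gaitscreen_bad_box")
})

test_that("extract_patient_clip crops every frame at the tracked center", {
  sc <- generate_scene(small_scene_config(seed = 13, entry = 6L,
                                          n_frames = 12L))
  ext <- extract_patient_clip(sc$frames, detect_scene(sc), out_side = 64L)
  expect_length(ext$frames, length(sc$frames))
  for (f in ext$frames) expect_identical(dim(f), c(64L, 64L, 3L))
  # tracked center equals ground-truth hip midpoint (the oracle's center)
  for (i in seq_along(sc$frames)) {
    hips <- (sc$truth[[i]][[1]]$keypoints[12L, 1:2] +
             sc$truth[[i]][[1]]$keypoints[13L, 1:2]) / 2
    expect_lt(abs(ext$track$track$cx[i] - hips[1]), 1)
    expect_lt(abs(ext$track$track$cy[i] - hips[2]), 1)
  }
})
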