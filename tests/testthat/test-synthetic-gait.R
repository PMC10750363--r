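test_that("scene generation is deterministic and honours the distractor entry frame", {
  cfg <- small_scene_config(seed = 7, entry = 10L)
  sc1 <- generate_scene(cfg)
  sc2 <- generate_scene(cfg)
  expect_identical(sc1$frames, sc2$frames)
  expect_identical(sc1$truth, sc2$truth)
  n_persons <- lengths(sc1$truth)
  expect_true(all(n_persons[1:10] == 1L))          # frames 0..9
  expect_true(all(n_persons[11:length(n_persons)] == 2L))
  expect_identical(sc1$truth[[1]][[1]]$id, "patient")
})

test_that("frame 0 always contains exactly one person and boxes stay in frame", {
  for (seed in c(1, 5, 9)) {
    sc <- generate_scene(small_scene_config(seed = seed, entry = 3L))
    expect_length(sc$truth[[1]], 1L)
    W <- sc$config$frame_width; H <- sc$config$frame_height
    for (persons in sc$truth) {
      for (p in persons) {
        expect_gte(p$box[["x1"]], 0)
        expect_gte(p$box[["y1"]], 0)
        expect_lte(p$box[["x2"]], W)
        expect_lte(p$box[["y2"]], H)
        expect_gt(p$box[["x2"]], p$box[["x1"]])
      }
    }
  }
})

test_that("the walking figure advances by stride_px per frame", {
  cfg <- scene_config(frame_width = 640L, frame_height = 360L, n_frames = 20L,
                      patient_signature = motion_signature(stride_px = 4),
                      background_clutter = 0L, seed = 3)
  sc <- generate_scene(cfg)
  # the hip midpoint is the figure's translation reference: exactly
  # stride_px per frame
  hx <- vapply(sc$truth, function(tr)
    (tr[[1]]$keypoints[12L, 1L] + tr[[1]]$keypoints[13L, 1L]) / 2, numeric(1))
  expect_equal(diff(hx), rep(4, 19))
  # the box center advances by stride_px on average (limb swing makes
  # the tight box breathe frame to frame)
  cx <- vapply(sc$truth, function(tr)
    (tr[[1]]$box[["x1"]] + tr[[1]]$box[["x2"]]) / 2, numeric(1))
  expect_equal(mean(diff(cx)), 4, tolerance = 0.15)
  # and the *rendered* figure tracks the truth: centroid of non-background
  # pixels stays near the hip midpoint
  centroid_x <- vapply(sc$frames, function(fr) {
    fig <- fr[, , 3] - fr[, , 1] > 0.2   # figure is navy on a grey background
    mean(col(fig)[fig]) - 0.5
  }, numeric(1))
  expect_true(all(abs(centroid_x - hx) < 15))
})

test_that("a figure reaching the frame edge truncates the scene with a flag", {
  cfg <- scene_config(frame_width = 200L, frame_height = 180L, n_frames = 60L,
                      patient_signature = motion_signature(stride_px = 8),
                      start_x = 100, seed = 2)
  sc <- generate_scene(cfg)
  expect_true(sc$truncated)
  expect_lt(length(sc$frames), 60L)
  expect_identical(length(sc$frames), length(sc$truth))
})

test_that("oracle detector returns stored truth with identities stripped", {
  sc <- generate_scene(small_scene_config(seed = 11, entry = 8L))
  fd0 <- oracle_detector(sc, 0L)
  expect_s3_class(fd0, "gait_frame_detections")
  expect_length(fd0$detections, 1L)
  fd12 <- oracle_detector(sc, 12L)
  expect_length(fd12$detections, 2L)
  expect_identical(fd12$detections[[1]]$box, sc$truth[[13]][[1]]$box)
  expect_identical(fd12$detections[[1]]$score, 1.0)
  expect_null(fd12$detections[[1]]$id)
  expect_error(oracle_detector(sc, length(sc$frames)), class = "gaitscreen_bad_index")
  # hip midpoint lies inside the corresponding box in every frame
  for (i in seq_along(sc$frames) - 1L) {
    for (d in oracle_detector(sc, i)$detections) {
      hips <- (d$keypoints[12L, 1:2] + d$keypoints[13L, 1:2]) / 2
      expect_true(hips[1] >= d$box[["x1"]] && hips[1] <= d$box[["x2"]])
      expect_true(hips[2] >= d$box[["y1"]] && hips[2] <= d$box[["y2"]])
    }
  }
})

test_that("cohort generation respects class ratio, determinism and label consistency", {
  co <- generate_cohort(12L, class_ratio = 0.5, clips_per_patient = 2L, seed = 21)
  expect_identical(as.integer(table(co$patients$label)), c(6L, 6L))
  co2 <- generate_cohort(12L, class_ratio = 0.5, clips_per_patient = 2L, seed = 21)
  expect_identical(co, co2)
  expect_false(anyDuplicated(co$patients$patient_id) > 0)
  # every stored scene config of a patient reuses that patient's signature
  for (pid in co$patients$patient_id) {
    for (cfg in co$scene_configs[[pid]])
      expect_identical(cfg$patient_signature, co$signatures[[pid]])
  }
  expect_error(generate_cohort(2L, class_ratio = 0.05),
               class = "gaitscreen_bad_cohort")
})

test_that("separation dial collapses the class signature families", {
  co0 <- generate_cohort(10L, clips_per_patient = 1L, seed = 5, separation = 0)
  tp <- vapply(co0$signatures, `[[`, numeric(1), "trunk_pitch_deg")
  by_class <- split(tp, co0$patients$label)
  # with zero separation both classes draw from one distribution:
  # class means differ only by sampling jitter
  expect_lt(abs(mean(by_class$ASD) - mean(by_class$`non-ASD`)), 3)
  co1 <- generate_cohort(10L, clips_per_patient = 1L, seed = 5, separation = 1)
  tp1 <- vapply(co1$signatures, `[[`, numeric(1), "trunk_pitch_deg")
  by1 <- split(tp1, co1$patients$label)
  expect_gt(mean(by1$ASD) - mean(by1$`non-ASD`), 10)
})
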