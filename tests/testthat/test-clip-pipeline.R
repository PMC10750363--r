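tiny_frames <- function(n, side = 8L) {
  lapply(seq_len(n), function(i) array(i / n, dim = c(side, side, 3L)))
}

test_that("1-second slicing drops the trailing remainder and conserves frames", {
  expect_length(slice_one_second_clips(tiny_frames(90L)), 3L)
  clips <- slice_one_second_clips(tiny_frames(75L))
  expect_length(clips, 2L)
  expect_length(slice_one_second_clips(tiny_frames(29L)), 0L)
  # conservation: fps * n_clips + dropped == input frames
  for (n in c(30L, 59L, 61L, 90L, 100L)) {
    cl <- slice_one_second_clips(tiny_frames(n))
    expect_identical(30L * length(cl) + (n %% 30L), n)
  }
  # windows are consecutive and non-overlapping
  expect_identical(vapply(clips, `[[`, integer(1), "start_frame"), c(0L, 30L))
  expect_equal(clips[[2]]$frames[[1]][1, 1, 1], 31 / 75)
})

test_that("uniform sampling uses floor(k*F/T) and preserves order", {
  clip <- slice_one_second_clips(tiny_frames(30L))[[1]]
  s <- sample_frames(clip, 8L)
  expect_identical(s$indices, c(0L, 3L, 7L, 11L, 15L, 18L, 22L, 26L))
  # F == T is the identity
  s2 <- sample_frames(clip, 30L)
  expect_identical(s2$indices, 0:29)
  # strictly increasing for every valid (F, T)
  for (f_count in c(8L, 13L, 30L, 31L)) {
    cl <- list(frames = tiny_frames(f_count))
    for (t_frames in c(1L, 3L, 8L, f_count)) {
      idx <- sample_frames(cl, t_frames)$indices
      expect_length(idx, t_frames)
      expect_true(all(diff(idx) > 0) || t_frames == 1L)
      expect_true(all(idx >= 0L & idx < f_count))
    }
  }
  expect_error(sample_frames(clip, 31L), class = "gaitscreen_bad_sample")
  # resampling is deterministic
  expect_identical(sample_frames(clip, 8L)$indices, s$indices)
})

test_that("model tensor conversion is channel-first, [0,1], isotropic", {
  clip <- slice_one_second_clips(tiny_frames(30L, side = 64L))[[1]]
  s <- sample_frames(clip, 8L)
  x <- resize_for_model(s, side = 32L)
  expect_identical(dim(x), c(3L, 8L, 32L, 32L))
  expect_true(all(x >= 0 & x <= 1))
  # constant-valued frames stay constant through the resize
  expect_equal(max(x[, 1, , ]) - min(x[, 1, , ]), 0)
  expect_equal(x[1, 1, 1, 1], clip$frames[[1]][1, 1, 1])
  # non-square input is rejected
  bad <- list(frames = list(array(0.5, dim = c(16L, 20L, 3L))))
  expect_error(resize_for_model(bad, side = 16L),
               class = "gaitscreen_bad_shape")
})

test_that("short-side scale yields a centered square crop", {
  fr <- coord_frame(180L, 320L)
  out <- short_side_scale(fr, target = 64L)
  expect_identical(dim(out), c(64L, 64L, 3L))
  # vertical extent is used fully; horizontal crop is centered
  expect_equal(mean(out[, , 1]), 0.5, tolerance = 0.02)
  expect_lt(abs(out[1, 1, 2] - 0), 0.05)
  expect_gt(out[64, 1, 2], 0.9)
})

test_that("dataset index maps disease codes to the binary label deterministically", {
  idx <- dataset_index(paste0("c", 1:4), paste0("p", 1:4),
                       c("ASD", "DHS", "LCS", "HipOA"))
  expect_identical(as.character(idx$label),
                   c("ASD", "non-ASD", "non-ASD", "non-ASD"))
  expect_error(dataset_index("c1", "p1", "XYZ"))
})
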