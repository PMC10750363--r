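# Shared builders for small, fast fixtures.

# Tiny architecture for unit tests: one block per stage, 1/16 width.
micro_spec <- function() arch_spec(c(1L, 1L, 1L, 1L), width_multiplier = 1 / 16)

# Random model-input clip (3, T, side, side).
random_clip <- function(t_frames = 2L, side = 16L, seed = 1L) {
  set.seed(seed)
  array(runif(3 * t_frames * side * side), dim = c(3L, t_frames, side, side))
}

# Small scene used by detection tests: distractor enters mid-scene,
# inter-person gap far above twice the per-frame stride.
small_scene_config <- function(seed, n_frames = 30L, entry = 5L) {
  scene_config(frame_width = 320L, frame_height = 180L, n_frames = n_frames,
               patient_signature = motion_signature(trunk_pitch_deg = 10,
                                                    stride_px = 4),
               distractor_entry_frame = entry, distractor_gap_px = 60,
               start_x = 90, seed = seed)
}

# A coordinate-coded frame: channel 1 encodes column, channel 2 row.
coord_frame <- function(h, w) {
  fr <- array(0, dim = c(h, w, 3))
  fr[, , 1] <- matrix(rep(seq_len(w), each = h), h, w) / w
  fr[, , 2] <- matrix(rep(seq_len(h), times = w), h, w) / h
  fr
}

# Four small clips, two per class, with a class-dependent mean shift --
# the smallest possible separable training set.
four_clip_set <- function(side = 16L, t_frames = 8L, seed = 4L) {
  set.seed(seed)
  mk <- function(shift) array(runif(3 * t_frames * side * side) * 0.2 + shift,
                              dim = c(3L, t_frames, side, side))
  list(clips = list(mk(0.6), mk(0.65), mk(0.1), mk(0.15)),
       labels = c("ASD", "ASD", "non-ASD", "non-ASD"))
}
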