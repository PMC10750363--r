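test_that("architecture spec validates and scales widths", {
  s <- arch_spec()
  expect_identical(s$block_counts, c(3L, 4L, 6L, 3L))
  expect_identical(s$feature_dim, 2048L)
  expect_identical(s$outer_widths, 4L * s$inner_widths)
  expect_identical(arch_spec(width_multiplier = 0.25)$feature_dim, 512L)
  expect_error(arch_spec(c(0, 1, 1, 1)))
  expect_error(arch_spec(width_multiplier = 0))
})

test_that("stage shape ladder halves spatial size and preserves T", {
  m <- build_model(micro_spec(), seed = 1)
  x <- random_clip(t_frames = 3L, side = 64L)
  ten <- gaitscreen:::clips_to_tensor(x)
  sizes <- vapply(1:4, function(s)
    gaitscreen:::net_fwd(m, ten, keep_stage = s)$internals$stage_out$dims[3L],
    integer(1))
  # conv1 64 -> 32, pool -> 16; stages: 16, 8, 4, 2
  expect_identical(sizes, c(16L, 8L, 4L, 2L))
  tdims <- gaitscreen:::net_fwd(m, ten, keep_stage = 4L)$internals$stage_out$dims
  expect_identical(tdims[2L], 3L)  # temporal extent untouched
})

test_that("forward is deterministic in eval mode with sigmoid-range scores", {
  m <- build_model(micro_spec(), seed = 2)
  x <- list(random_clip(seed = 1), random_clip(seed = 2), random_clip(seed = 3))
  sc <- forward(m, x)
  expect_identical(dim(sc), c(3L, 2L))
  expect_true(all(sc > 0 & sc < 1))
  expect_identical(unclass(sc), unclass(forward(m, x)))
  ft <- pooled_features(m, x)
  expect_identical(dim(ft), c(3L, micro_spec()$feature_dim))
  expect_identical(dim(predict(m, x)), dim(sc))
  expect_s3_class(predict(m, x, type = "label"), "factor")
})

test_that("head adaptation replaces only the final layer", {
  m400 <- build_model(arch_spec(c(1L, 1L, 1L, 1L), n_classes = 400L,
                                width_multiplier = 1 / 16), seed = 3)
  m2 <- adapt_head(m400, 2L, seed = 4)
  expect_identical(nrow(m2$head$W), 2L)
  expect_identical(dim(forward(m2, random_clip())), c(1L, 2L))
  p400 <- gaitscreen:::param_leaves(m400)
  p2 <- gaitscreen:::param_leaves(m2)
  non_head <- setdiff(names(p400), c("model.head.W", "model.head.b"))
  expect_identical(p400[non_head], p2[non_head])
})

test_that("checkpoints round-trip and reject mismatched architectures", {
  m <- build_model(micro_spec(), seed = 5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(build_model(micro_spec(), seed = 99), path)
  x <- random_clip()
  expect_identical(forward(m, x), forward(m2, x))
  wider <- build_model(arch_spec(c(1L, 1L, 1L, 1L), width_multiplier = 0.25),
                       seed = 1)
  expect_error(load_checkpoint(wider, path),
               class = "gaitscreen_shape_mismatch")
})

test_that("a bottleneck block with a zeroed residual branch is the identity", {
  set.seed(6)
  blk <- gaitscreen:::bottleneck_block(16L, 4L)  # outer = 16 = c_in, no projection
  expect_null(blk$proj_conv)
  blk$conv_c$W[] <- 0
  x <- matrix(abs(rnorm(2 * 4 * 4 * 16)), ncol = 16L)  # positive input
  ten <- gaitscreen:::new_tensor(x, c(1L, 2L, 4L, 4L))
  out <- gaitscreen:::block_fwd(blk, ten)
  expect_equal(out$out$x, x)
})
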