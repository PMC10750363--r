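# Batched activation tensors.
#
# The network represents a batch of N volumes with C channels and
# (T, H, W) extent as a (P x C) matrix, P = N*T*H*W, where row
# r = ((n*T + t)*H + h)*W + w (0-based, w fastest).  Channels live in
# columns so convolution reduces to im2col + one GEMM and batch norm to
# column-wise moments.

new_tensor <- function(x, dims) {
  stopifnot(is.matrix(x), length(dims) == 4L,
            nrow(x) == prod(dims))
  list(x = x, dims = as.integer(dims))  # dims = c(N, T, H, W)
}

# `clips`: one (C, T, H, W) array or a list of them -> tensor batch.
clips_to_tensor <- function(clips) {
  if (!is.list(clips)) clips <- list(clips)
  d <- dim(clips[[1L]])
  stopifnot(length(d) == 4L)
  rows <- lapply(clips, function(a) {
    stopifnot(identical(dim(a), d))
    matrix(aperm(a, c(4L, 3L, 2L, 1L)), ncol = d[1L])
  })
  new_tensor(do.call(rbind, rows), c(length(clips), d[2L], d[3L], d[4L]))
}

# Inverse of clips_to_tensor for one sample n (1-based).
tensor_to_clip <- function(ten, n = 1L) {
  d <- ten$dims
  per <- prod(d[2:4])
  rows <- ((n - 1L) * per + 1L):(n * per)
  a <- array(ten$x[rows, , drop = FALSE], dim = c(d[4L], d[3L], d[2L], ncol(ten$x)))
  aperm(a, c(4L, 3L, 2L, 1L))
}
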