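# Internal helpers shared across modules.

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic fan-out of one user seed into per-purpose streams,
# kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% .Machine$integer.max)
}

stop_gaitscreen <- function(msg, class) {
  stop(structure(class = c(class, "gaitscreen_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bilinear resize of an (H, W) matrix or (H, W, 3) array via EBImage.
# EBImage stores images as (x = column, y = row), hence the transposes.
resize_image <- function(img, h, w) {
  if (length(dim(img)) == 2L) {
    ebi <- EBImage::Image(t(img))
    out <- EBImage::resize(ebi, w = w, h = h)
    return(t(EBImage::imageData(out)))
  }
  ebi <- EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(ebi, w = w, h = h)
  aperm(EBImage::imageData(out), c(2L, 1L, 3L))
}
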