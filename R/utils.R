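# Internal helpers shared across modules.

# Evaluate `code` under a temporarily-seeded RNG, restoring the caller's
# random state afterwards. All stochastic entry points route through this so
# one master seed fixes every draw.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of per-item child seeds from one master seed,
# kept inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric matrix of pixel intensities", arg))
  }
  if (anyNA(img) || any(!is.finite(img))) {
    abort(sprintf("`%s` contains non-finite intensities", arg))
  }
  if (any(img < 0)) {
    abort(sprintf("`%s` contains negative intensities", arg))
  }
  invisible(img)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}
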