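# Lazily-built fixtures shared across test files (computed once per run).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 3x3 image with a given center and uniform ring.
ring_image <- function(center, ring) {
  img <- matrix(ring, 3, 3)
  img[2, 2] <- center
  img
}

# Synthetic tabular selection problem: k informative features (class-mean
# shift `shift`), the rest pure noise.
selection_problem <- function(seed, n = 100, m = 50, k = 5, shift = 1) {
  set.seed(seed)
  y <- rep(c(-1L, 1L), each = n / 2)
  x <- matrix(rnorm(n * m), n, m)
  x[, seq_len(k)] <- x[, seq_len(k)] + shift * outer(y, rep(1, k))
  list(x = x, y = y, informative = seq_len(k))
}

# The full-size study set: 100 mass + 100 normal ROIs at contrast 5 with
# their MSWLD_24,3(4, 4, 5, 4x4) descriptors. Built once; used by the
# end-to-end and acceptance tests.
study_features <- function() {
  fixture("study_features", function() {
    rois <- synth_rois(n_per_class = 100, size_range = c(64, 256),
                       contrast = 5, seed = 20260924)
    mswld_features(rois, wld_params(4, 4, 5), "4x4", "24:3")
  })
}

# seed-scoped sampling without disturbing the global RNG stream
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
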