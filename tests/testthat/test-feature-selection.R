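# Margin-based local-learning selector: probabilities, margin vectors,
# weight fitting, thresholding and the (sigma, lambda) wrapper search.

toy_xy <- function() {
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 2), c(3, 3), c(-1, -1))
  y <- c(-1L, 1L, -1L, 1L, 1L, -1L)
  list(x = x, y = y)
}

test_that("hit/miss probabilities form normalized softmax distributions", {
  d <- toy_xy()
  w <- rep(1, 2)
  p <- hit_miss_probabilities(d$x, d$y, 1, w, sigma = 1)
  expect_equal(sum(p$miss), 1, tolerance = 1e-9)
  expect_equal(sum(p$hit), 1, tolerance = 1e-9)

  # single miss candidate gets probability 1
  x <- rbind(c(0, 0), c(1, 1), c(0.5, 0))
  y <- c(-1L, 1L, -1L)
  p <- hit_miss_probabilities(x, y, 1, w, sigma = 0.5)
  expect_equal(unname(p$miss), 1)

  # two equidistant misses split evenly
  x <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 2))
  y <- c(-1L, 1L, 1L, -1L)
  p <- hit_miss_probabilities(x, y, 1, w, sigma = 0.3)
  expect_equal(unname(p$miss), c(0.5, 0.5))

  # three misses at weighted L1 distances 1, 2, 3 with sigma = 1
  x <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(0, 1))
  y <- c(-1L, 1L, 1L, 1L, -1L)
  p <- hit_miss_probabilities(x, y, 1, w, sigma = 1)
  want <- exp(-(1:3)) / sum(exp(-(1:3)))
  expect_equal(unname(p$miss), want, tolerance = 1e-12)

  # a singleton class has no hits
  x <- rbind(c(0, 0), c(1, 0), c(2, 0))
  y <- c(-1L, 1L, 1L)
  expect_error(hit_miss_probabilities(x, y, 1, w, 1), "degenerate hit set")
})

test_that("margin vectors equal single-neighbor expectations and are antisymmetric", {
  w <- rep(1, 2)
  x <- rbind(c(0, 0), c(1, 0), c(0, 1))
  y1 <- c(-1L, 1L, -1L)  # sample 1: miss = (1,0), hit = (0,1)
  expect_equal(margin_vector(x, y1, 1, w, 1), c(1, -1))

  # hit and miss identical to the sample itself
  x0 <- rbind(c(2, 2), c(2, 2), c(2, 2))
  expect_equal(margin_vector(x0, y1, 1, w, 1), c(0, 0))

  # swapping hit and miss roles flips the sign
  y2 <- c(-1L, -1L, 1L)  # now miss = (0,1), hit = (1,0)
  expect_equal(margin_vector(x, y2, 1, w, 1), -margin_vector(x, y1, 1, w, 1))
})

test_that("compiled margin vectors match the scalar reference on random data", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(6:14, 1)
    m <- sample(2:8, 1)
    x <- matrix(rnorm(n * m), n, m)
    y <- c(-1L, 1L, sample(c(-1L, 1L), n - 2, replace = TRUE))
    w <- runif(m, 0, 2)
    sigma <- runif(1, 0.2, 2)
    z_cpp <- mswld:::margin_vectors(x, y, w, sigma)
    for (j in sample(n, 3)) {
      expect_equal(z_cpp[j, ], margin_vector(x, y, j, w, sigma),
                   tolerance = 1e-10)
    }
  }
})

test_that("an informative feature gets the top weight and noise is suppressed", {
  set.seed(5)
  n <- 60
  y <- rep(c(-1L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  x[, 4] <- x[, 4] + 3 * y  # separates with a wide margin
  # relevance oracle: 1-NN accuracy collapses only when the informative
  # feature is removed
  full_acc <- oracle_loo_1nn_acc(x, y)
  drops <- vapply(1:10, function(j) {
    full_acc - oracle_loo_1nn_acc(x[, -j, drop = FALSE], y)
  }, numeric(1))
  expect_gt(drops[4], 0.3)
  expect_true(all(drops[-4] < 0.3))

  fit <- fit_feature_weights(x, y = y, sigma = 0.5, lambda = 0.5)
  expect_identical(which.max(fit$w), 4L)
  expect_gte(sum(fit$w[-4] < 1e-3), 5)
  expect_true(4L %in% select_features(fit))
})

test_that("extreme regularization drives all weights to zero", {
  d <- selection_problem(1, n = 40, m = 10)
  fit <- suppressWarnings(fit_feature_weights(d$x, y = d$y, sigma = 0.5,
                                              lambda = 50))
  expect_true(all(fit$w < 1e-4))
  expect_error(select_features(fit), "no features selected")
})

test_that("duplicated feature columns receive equal weights", {
  d <- selection_problem(2, n = 60, m = 6, k = 2)
  x <- cbind(d$x, d$x[, 1])  # column 7 duplicates column 1
  fit <- fit_feature_weights(x, y = d$y, sigma = 0.5, lambda = 0.3)
  expect_equal(fit$w[7], fit$w[1], tolerance = 1e-6)
})

test_that("permuting feature columns permutes the fitted weights identically", {
  d <- selection_problem(3, n = 50, m = 12, k = 3)
  fit <- fit_feature_weights(d$x, y = d$y, sigma = 0.5, lambda = 0.3)
  perm <- c(5, 1, 12, 3, 7, 2, 9, 11, 4, 10, 6, 8)
  fit_p <- fit_feature_weights(d$x[, perm], y = d$y, sigma = 0.5, lambda = 0.3)
  expect_equal(fit_p$w, fit$w[perm], tolerance = 1e-12)
})

test_that("weights are always nonnegative", {
  for (seed in 1:5) {
    d <- selection_problem(seed, n = 30, m = 8, k = 2)
    fit <- suppressWarnings(fit_feature_weights(d$x, y = d$y, sigma = 0.3,
                                                lambda = runif(1, 0, 2)))
    expect_true(all(fit$w >= 0))
  }
})

test_that("feature thresholding follows the documented rule", {
  expect_identical(select_features(c(0, 5, 0.2), threshold = 0.5), 2L)
  w <- c(0.4, 1.2, 0.01)
  expect_identical(select_features(w, threshold = 0), 1:3)
  expect_error(select_features(c(0, 0, 0), threshold = 0), "no features")
})

test_that("selected-feature count is non-increasing in lambda", {
  d <- selection_problem(4)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 1, 2), function(lam) {
    fit <- suppressWarnings(fit_feature_weights(d$x, y = d$y, sigma = 0.5,
                                                lambda = lam))
    length(tryCatch(select_features(fit), error = function(e) integer(0)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the wrapper grid search returns a sensible (sigma, lambda) pair", {
  d <- selection_problem(6, n = 60, m = 12, k = 3)
  colnames(d$x) <- sprintf("f%04d", 1:12)
  df <- tibble::as_tibble(d$x)
  df$label <- d$y

  # a 1x1 grid must return that pair
  one <- tune_feature_weights(df, sigma_grid = 0.3, lambda_grid = 0.7,
                              folds = 3, seed = 9)
  expect_equal(one$sigma, 0.3)
  expect_equal(one$lambda, 0.7)
  expect_s3_class(one$weights, "wld_weights")

  # the default grids cover the published optima
  expect_true(all(c(0.3, 0.1) %in% eval(formals(tune_feature_weights)$sigma_grid)))
  expect_true(all(c(0.7, 0.5) %in% eval(formals(tune_feature_weights)$lambda_grid)))

  # a small search picks a pair that actually recovers informative features
  tuned <- tune_feature_weights(df, sigma_grid = c(0.1, 0.5),
                                lambda_grid = c(0.3, 1), folds = 3, seed = 9)
  expect_true(tuned$search$mean_az[which(
    tuned$search$sigma == tuned$sigma & tuned$search$lambda == tuned$lambda
  )] == max(tuned$search$mean_az))
  expect_true(length(intersect(tuned$selected, d$informative)) >= 2)
})
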