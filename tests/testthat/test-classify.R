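# RBF-SVM harness: training, decision orientation, grid search, stratified
# folds, confusion metrics and ROC AUC.

blob_data <- function(n = 40, gap = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c(-1L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 2, sd = 0.5), n, 2) + gap * outer(y, c(1, 1)) / 2
  list(x = x, y = y)
}

test_that("well-separated clouds are classified perfectly on training data", {
  d <- blob_data()
  m <- svm_rbf(d$x, d$y, C = 10, gamma = 0.5)
  dec <- svm_decision(m, d$x)
  expect_identical(ifelse(dec > 0, 1L, -1L), d$y)
  expect_error(svm_rbf(d$x, rep(1L, 40)), "both classes")
})

test_that("decision values are oriented toward the normal (+1) class", {
  d <- blob_data()
  m <- svm_rbf(d$x, d$y, C = 10, gamma = 0.5)
  dec <- svm_decision(m, d$x)
  expect_true(all(dec[d$y == 1L] > 0))
  expect_true(all(dec[d$y == -1L] < 0))
})

test_that("the RBF kernel resolves the XOR pattern", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(-1L, -1L, 1L, 1L)
  m <- svm_rbf(x, y, C = 1e3, gamma = 2)
  expect_identical(ifelse(svm_decision(m, x) > 0, 1L, -1L), y)
})

test_that("stratified folds partition the data and balance the classes", {
  y <- rep(c(-1L, 1L), each = 5)
  folds <- stratified_folds(y, 5, seed = 3)
  expect_length(folds, 5)
  expect_true(all(vapply(folds, length, numeric(1)) == 2))
  for (f in folds) expect_setequal(y[f], c(-1L, 1L))
  expect_setequal(unlist(folds), seq_along(y))
  expect_identical(folds, stratified_folds(y, 5, seed = 3))
  expect_false(identical(folds, stratified_folds(y, 5, seed = 4)))

  # proportions within one sample of global for unbalanced data
  y2 <- c(rep(-1L, 23), rep(1L, 37))
  folds2 <- stratified_folds(y2, 5, seed = 1)
  pos_counts <- vapply(folds2, function(f) sum(y2[f] == -1L), numeric(1))
  expect_true(max(pos_counts) - min(pos_counts) <= 1)

  expect_error(stratified_folds(c(-1L, 1L, 1L, 1L), 3), "cannot stratify")
})

test_that("confusion metrics follow their definitions", {
  m <- confusion_metrics(50, 0, 50, 0)
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, accuracy = 1))
  m <- confusion_metrics(3, 1, 4, 0)
  expect_equal(unlist(m),
               c(sensitivity = 0.75, specificity = 1, accuracy = 0.875))
  m <- confusion_metrics(0, 4, 4, 0)
  expect_equal(unlist(m), c(sensitivity = 0, specificity = 1, accuracy = 0.5))
  expect_error(confusion_metrics(0, 0, 4, 1), "undefined metric")
})

test_that("ROC AUC equals the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(-1, -1, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(-1, -1, -1, 1, 1, 1)), 0.5)
  expect_equal(roc_auc(c(0.8, 0.3, 0.5, 0.1), c(-1, -1, 1, 1)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "undefined AUC")
  set.seed(12)
  for (i in 1:30) {
    n <- sample(4:200, 1)
    y <- c(-1L, 1L, sample(c(-1L, 1L), n - 2, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("our AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- sample(c(-1L, 1L), 80, replace = TRUE, prob = c(0.4, 0.6))
  s <- rnorm(80) + (y == -1L)
  ours <- roc_auc(s, y, positive = -1L)
  ref <- as.numeric(pROC::auc(pROC::roc(response = factor(y == -1L),
                                        predictor = s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("grid search covers the published optimum and breaks ties toward small C", {
  # the coarse grid must contain (C, gamma) = (2^9, 2^-17)
  coarse_c <- seq(-5, 15, by = 2)
  coarse_g <- seq(-25, 3, by = 2)
  expect_true(9 %in% coarse_c && -17 %in% coarse_g)

  d <- blob_data(n = 30, gap = 8, seed = 2)
  tuned <- tune_svm_rbf(d$x, d$y, folds = 3, seed = 5)
  # separable data: many (C, gamma) tie at accuracy 1; winner is the
  # smallest C (then smallest gamma) among the fine-grid ties
  best_acc <- max(tuned$fine$accuracy)
  ties <- tuned$fine[tuned$fine$accuracy == best_acc, ]
  expect_equal(tuned$log2c, min(ties$log2c))
  expect_equal(tuned$log2g,
               min(ties$log2g[ties$log2c == tuned$log2c]))
  # fine grid brackets the coarse winner at half-exponent steps
  expect_true(all(diff(sort(unique(tuned$fine$log2c))) == 0.5))
})
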