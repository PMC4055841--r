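# RBF-SVM training (libsvm via e1071), coarse-then-fine (C, gamma) tuning,
# stratified k-fold utilities and evaluation metrics.
#
# Label convention: y = +1 for a normal ROI, y = -1 for a mass ROI. The mass
# class (-1) is the positive class of the detection metrics (TP = mass
# called mass).

fit_standardizer <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(center = mu, scale = s)
}

apply_standardizer <- function(x, std) {
  scale(x, center = std$center, scale = std$scale)[, , drop = FALSE]
}

#' Train an RBF-kernel SVM
#'
#' Thin wrapper around libsvm (e1071) fixing the kernel to the radial basis
#' function `K(u, v) = exp(-gamma * ||u - v||^2)` and the label convention
#' (+1 normal / -1 mass). Feature scaling is left to the caller (the
#' cross-validation harness standardizes on each training split).
#'
#' @param x Numeric sample-by-feature matrix.
#' @param y Labels in `{+1, -1}` (or "mass"/"normal").
#' @param C Penalty parameter (> 0).
#' @param gamma RBF kernel parameter (> 0).
#' @return Object of class `wld_svm` wrapping the fitted model.
#' @export
svm_rbf <- function(x, y, C = 1, gamma = 1 / ncol(x)) {
  y <- encode_labels(y)
  check_dataset(x, y)
  if (C <= 0 || gamma <= 0) abort("`C` and `gamma` must be > 0")
  fit <- e1071::svm(
    x = x, y = factor(y, levels = c(-1L, 1L)),
    type = "C-classification", kernel = "radial",
    cost = C, gamma = gamma, scale = FALSE
  )
  structure(list(fit = fit, C = C, gamma = gamma), class = "wld_svm")
}

#' Decision values of a fitted SVM
#'
#' Returns the real-valued decision function oriented so that positive
#' values favor the normal class (+1) and negative values the mass class
#' (-1); the predicted label is the sign.
#'
#' @param model A `wld_svm` from [svm_rbf()].
#' @param x New sample matrix.
#' @return Numeric vector of decision values.
#' @export
svm_decision <- function(model, x) {
  stopifnot(inherits(model, "wld_svm"))
  pred <- predict(model$fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  score <- as.numeric(dv[, 1])
  if (first == "-1") score <- -score  # orient positive toward class +1
  score
}

#' @export
print.wld_svm <- function(x, ...) {
  cat(sprintf("RBF-SVM: C = %g, gamma = %g, %d support vectors\n",
              x$C, x$gamma, x$fit$tot.nSV))
  invisible(x)
}

#' Stratified k-fold test indices
#'
#' Partitions `seq_along(y)` into `k` disjoint test sets with per-fold class
#' proportions within one sample of the global proportions; deterministic
#' given `seed`.
#'
#' @param y Label vector.
#' @param k Fold count; every class must have at least `k` members.
#' @param seed Integer seed.
#' @return List of `k` integer index vectors.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  if (!is_count(k) || k < 2) abort("`k` must be an integer >= 2")
  if (min(table(y)) < k) abort("cannot stratify: a class has fewer members than folds")
  assign_fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      assign_fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) which(assign_fold == f))
}

#' Coarse-then-fine (C, gamma) grid search
#'
#' Searches the coarse grid `C = 2^{-5, -3, ..., 15}`,
#' `gamma = 2^{-25, -23, ..., 3}` by stratified inner-CV accuracy, then a
#' fine grid of half-exponent steps within two exponents of the coarse
#' winner. Ties prefer smaller `C`, then smaller `gamma`.
#'
#' @param x Sample-by-feature matrix.
#' @param y Labels in `{+1, -1}` (or "mass"/"normal").
#' @param folds Inner cross-validation folds (default 3).
#' @param seed Integer seed for the inner folds.
#' @return List with `C`, `gamma`, the winning exponents, and the searched
#'   grids (`coarse`, `fine` tibbles with mean accuracies).
#' @export
tune_svm_rbf <- function(x, y, folds = 3L, seed = 1L) {
  y <- encode_labels(y)
  check_dataset(x, y)
  fold_sets <- stratified_folds(y, folds, seed)
  cv_accuracy <- function(log2c, log2g) {
    acc <- vapply(fold_sets, function(test_idx) {
      model <- svm_rbf(x[-test_idx, , drop = FALSE], y[-test_idx],
                       C = 2^log2c, gamma = 2^log2g)
      pred <- ifelse(svm_decision(model, x[test_idx, , drop = FALSE]) > 0, 1L, -1L)
      mean(pred == y[test_idx])
    }, numeric(1))
    mean(acc)
  }
  search <- function(log2c_grid, log2g_grid) {
    g <- expand.grid(log2c = log2c_grid, log2g = log2g_grid)
    g$accuracy <- purrr::map2_dbl(g$log2c, g$log2g, cv_accuracy)
    as_tibble(g)
  }
  pick <- function(g) g[order(-g$accuracy, g$log2c, g$log2g)[1], ]
  coarse <- search(seq(-5, 15, by = 2), seq(-25, 3, by = 2))
  cb <- pick(coarse)
  fine <- search(seq(cb$log2c - 2, cb$log2c + 2, by = 0.5),
                 seq(cb$log2g - 2, cb$log2g + 2, by = 0.5))
  fb <- pick(fine)
  list(
    C = 2^fb$log2c, gamma = 2^fb$log2g,
    log2c = fb$log2c, log2g = fb$log2g,
    coarse = coarse, fine = fine
  )
}

#' Confusion-matrix rates
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/(TP+TN+FP+FN)` from raw counts.
#'
#' @param tp,fn,tn,fp Nonnegative confusion counts; positives = mass ROIs.
#' @return Named list of the three rates (fractions in `[0, 1]`).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0)) abort("confusion counts must be >= 0")
  if (tp + fn == 0 || tn + fp == 0) {
    abort("undefined metric: a class has no members")
  }
  list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / sum(counts)
  )
}

#' Area under the ROC curve (Az)
#'
#' Mann-Whitney formulation on continuous decision values: the probability
#' that a random positive outranks a random negative, ties counting one
#' half. Equals the trapezoidal area under the ROC curve.
#'
#' @param scores Real-valued scores, larger meaning more positive-class.
#' @param y Labels.
#' @param positive The label treated as positive (default `-1`, the mass
#'   class).
#' @return Az in `[0, 1]`.
#' @export
roc_auc <- function(scores, y, positive = -1L) {
  pos <- y == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) abort("undefined AUC: single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
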