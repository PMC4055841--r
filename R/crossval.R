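# Stratified cross-validated evaluation of the full pipeline:
# per-fold feature selection -> per-fold SVM tuning -> held-out metrics.

#' Cross-validated evaluation of the MSWLD pipeline
#'
#' Runs stratified k-fold cross-validation over a feature tibble. Inside
#' every fold — and only on its training split — feature weights are fitted
#' and thresholded, features are standardized, and the RBF-SVM is tuned
#' (coarse-then-fine grid search by default) and trained; metrics come from
#' the untouched held-out fold. The mass class (-1) is the positive class:
#' sensitivity is the fraction of masses called mass. If a fold's selector
#' retains no features (typical under label noise), that fold falls back to
#' the full descriptor with a warning and reports `n_selected = 0`.
#'
#' @param data Feature tibble ([mswld_features()]): a label column plus
#'   `f...` feature columns.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Master seed; folds and inner tuning derive from it.
#' @param selection `NULL` to skip feature selection, or a list:
#'   `list(sigma = 0.3, lambda = 0.1)` (optionally `eta`, `max_iter`, `tol`,
#'   `threshold`) for a fixed-parameter fit on each training split.
#' @param svm `list(method = "grid", folds = 3)` for coarse-then-fine tuning
#'   per fold, or `list(method = "fixed", C = , gamma = )`.
#' @param standardize Standardize features (z-score fitted on the training
#'   split) before selection and the SVM, so both operate in the same
#'   feature space and the (`sigma`, `lambda`) defaults keep consistent
#'   units across descriptor configurations; default `TRUE`.
#' @param label_col Label column name.
#' @return Object of class `mswld_eval` with per-fold results (`$folds`),
#'   pooled decision scores (`$scores`), and the configuration. Supports
#'   [tidy()], [glance()], [autoplot()].
#' @export
mswld_crossval <- function(data, folds = 5L, seed = 1L,
                           selection = list(sigma = 0.3, lambda = 0.1),
                           svm = list(method = "grid", folds = 3L),
                           standardize = TRUE,
                           label_col = "label") {
  y <- encode_labels(data[[label_col]])
  x <- feature_matrix(data)
  check_dataset(x, y)
  fold_sets <- stratified_folds(y, folds, seed)
  inner_seeds <- derive_seeds(seed, folds)

  fold_rows <- vector("list", folds)
  score_rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- fold_sets[[f]]
    tr_x <- x[-test_idx, , drop = FALSE]
    tr_y <- y[-test_idx]
    te_x <- x[test_idx, , drop = FALSE]
    te_y <- y[test_idx]

    if (standardize) {
      # one standardized feature space for both the selector and the SVM,
      # fitted on the training split only
      std <- fit_standardizer(tr_x)
      tr_x <- apply_standardizer(tr_x, std)
      te_x <- apply_standardizer(te_x, std)
    }
    if (!is.null(selection)) {
      fit <- fit_feature_weights(
        tr_x, y = tr_y,
        sigma = selection$sigma %||% 0.3,
        lambda = selection$lambda %||% 0.1,
        eta = selection$eta %||% 0.1,
        max_iter = selection$max_iter %||% 200L,
        tol = selection$tol %||% 1e-4
      )
      sel <- tryCatch(select_features(fit, threshold = selection$threshold),
                      error = function(e) integer(0))
      n_retained <- length(sel)
      if (n_retained == 0) {
        # selector found nothing informative (e.g. label noise); the fold
        # classifier falls back to the full descriptor
        warn(sprintf("fold %d: selector retained no features; using all", f))
        sel <- seq_len(ncol(x))
      }
      sel_sigma <- fit$sigma
      sel_lambda <- fit$lambda
    } else {
      sel <- seq_len(ncol(x))
      n_retained <- length(sel)
      sel_sigma <- NA_real_
      sel_lambda <- NA_real_
    }
    tr_sel <- tr_x[, sel, drop = FALSE]
    te_sel <- te_x[, sel, drop = FALSE]
    if (identical(svm$method %||% "grid", "grid")) {
      tuned <- tune_svm_rbf(tr_sel, tr_y, folds = svm$folds %||% 3L,
                            seed = inner_seeds[f])
      C <- tuned$C
      gamma <- tuned$gamma
    } else {
      C <- svm$C
      gamma <- svm$gamma %||% (1 / length(sel))
    }
    model <- svm_rbf(tr_sel, tr_y, C = C, gamma = gamma)
    dec <- svm_decision(model, te_sel)       # positive -> normal (+1)
    pred <- ifelse(dec > 0, 1L, -1L)
    tp <- sum(te_y == -1L & pred == -1L)
    fn <- sum(te_y == -1L & pred == 1L)
    tn <- sum(te_y == 1L & pred == 1L)
    fp <- sum(te_y == 1L & pred == -1L)
    rates <- confusion_metrics(tp, fn, tn, fp)
    fold_rows[[f]] <- tibble(
      fold = f, n_test = length(test_idx),
      tp = tp, fn = fn, tn = tn, fp = fp,
      sensitivity = 100 * rates$sensitivity,
      specificity = 100 * rates$specificity,
      accuracy = 100 * rates$accuracy,
      az = roc_auc(-dec, te_y, positive = -1L),
      n_selected = n_retained,
      sigma = sel_sigma, lambda = sel_lambda,
      C = C, gamma = gamma
    )
    score_rows[[f]] <- tibble(
      fold = f, index = test_idx, label = te_y,
      score = -dec  # oriented so larger favors the mass (positive) class
    )
  }
  structure(
    list(
      folds = dplyr::bind_rows(fold_rows),
      scores = dplyr::bind_rows(score_rows),
      seed = seed,
      config = list(folds = folds, selection = selection, svm = svm,
                    standardize = standardize)
    ),
    class = "mswld_eval"
  )
}

eval_summary <- function(x) {
  f <- x$folds
  tibble(
    folds = nrow(f),
    sensitivity = mean(f$sensitivity), sensitivity_sd = sd(f$sensitivity),
    specificity = mean(f$specificity), specificity_sd = sd(f$specificity),
    accuracy = mean(f$accuracy), accuracy_sd = sd(f$accuracy),
    az = mean(f$az), az_sd = sd(f$az),
    seed = x$seed
  )
}

#' @export
print.mswld_eval <- function(x, ...) {
  s <- eval_summary(x)
  cat(sprintf(
    paste0(
      "Cross-validated evaluation (%d folds, seed %d)\n",
      "  sensitivity %5.2f +/- %.2f %%\n",
      "  specificity %5.2f +/- %.2f %%\n",
      "  accuracy    %5.2f +/- %.2f %%\n",
      "  Az          %5.3f +/- %.3f\n"
    ),
    s$folds, x$seed,
    s$sensitivity, s$sensitivity_sd,
    s$specificity, s$specificity_sd,
    s$accuracy, s$accuracy_sd,
    s$az, s$az_sd
  ))
  invisible(x)
}

#' ROC points of a cross-validated evaluation
#'
#' Pools (or splits by fold) the held-out decision scores into
#' (1 - specificity, sensitivity) operating points.
#'
#' @param x An `mswld_eval` object.
#' @param by_fold Compute one curve per fold instead of pooling.
#' @return Tibble with columns `fold` (if `by_fold`), `fpr`, `tpr`.
#' @export
roc_points <- function(x, by_fold = FALSE) {
  stopifnot(inherits(x, "mswld_eval"))
  one_curve <- function(df) {
    ord <- order(-df$score)
    lab <- df$label[ord] == -1L
    tibble(
      fpr = c(0, cumsum(!lab) / sum(!lab)),
      tpr = c(0, cumsum(lab) / sum(lab))
    )
  }
  if (by_fold) {
    x$scores |>
      dplyr::group_by(.data$fold) |>
      dplyr::group_modify(~one_curve(.x)) |>
      dplyr::ungroup()
  } else {
    one_curve(x$scores)
  }
}
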