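# Margin-based local-learning feature weighting (nearest-hit/-miss softmax
# margins + L1-regularized logistic loss), with a cross-validated
# (sigma, lambda) grid-search wrapper.

check_dataset <- function(x, y) {
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix")
  if (anyNA(x) || any(!is.finite(x))) abort("`x` contains non-finite values")
  if (length(y) != nrow(x)) abort("length(y) must equal nrow(x)")
  if (!all(y %in% c(-1L, 1L))) abort("labels must be +1/-1")
  if (length(unique(y)) < 2) abort("both classes must be present")
  invisible(NULL)
}

weighted_l1 <- function(a, b, w) sum(w * abs(a - b))

#' Nearest-miss / nearest-hit probability distributions
#'
#' For sample `i`, the probability that sample `r` is the nearest miss
#' (opposite class) or nearest hit (same class, the sample excluded) under feature
#' weights `w` is proportional to `exp(-d_w(i, r) / sigma)` with `d_w` the
#' `w`-weighted L1 distance; each distribution is normalized to sum to 1.
#' This is the pure-R reference; [fit_feature_weights()] uses a compiled
#' equivalent.
#'
#' @param x Numeric sample-by-feature matrix.
#' @param y Labels in `{+1, -1}`.
#' @param i Sample index.
#' @param w Nonnegative feature weights.
#' @param sigma Kernel width (> 0).
#' @return List with named probability vectors `miss` (over opposite-class
#'   indices) and `hit` (over same-class indices), each summing to 1.
#' @export
hit_miss_probabilities <- function(x, y, i, w, sigma) {
  check_dataset(x, y)
  if (sigma <= 0) abort("`sigma` must be > 0")
  miss_idx <- which(y != y[i])
  hit_idx <- setdiff(which(y == y[i]), i)
  if (length(hit_idx) == 0) {
    abort("degenerate hit set: sample's class has a single member")
  }
  soft <- function(idx) {
    d <- vapply(idx, function(r) weighted_l1(x[i, ], x[r, ], w), numeric(1))
    e <- exp(-(d - min(d)) / sigma)
    setNames(e / sum(e), idx)
  }
  list(miss = soft(miss_idx), hit = soft(hit_idx))
}

#' Margin vector of one sample
#'
#' The expected elementwise distance to the (probabilistic) nearest miss
#' minus the expected elementwise distance to the nearest hit:
#' `z_i = sum_{r in M_i} P(r|w) |x_i - x_r| - sum_{r in H_i} P(r|w) |x_i - x_r|`.
#' Positive components mark features along which same-class points sit
#' closer than opposite-class points.
#'
#' @inheritParams hit_miss_probabilities
#' @return Numeric vector of length `ncol(x)`.
#' @export
margin_vector <- function(x, y, i, w, sigma) {
  p <- hit_miss_probabilities(x, y, i, w, sigma)
  acc <- function(prob) {
    idx <- as.integer(names(prob))
    colSums(prob * abs(x[idx, , drop = FALSE] -
                         matrix(x[i, ], length(idx), ncol(x), byrow = TRUE)))
  }
  unname(acc(p$miss) - acc(p$hit))
}

# All margin vectors at once (compiled path; samples contiguous in memory).
margin_vectors <- function(x, y, w, sigma) {
  margin_vectors_t_cpp(t(x), as.integer(y), as.numeric(w), sigma)
}

logistic_objective <- function(w, z, lambda) {
  s <- as.numeric(z %*% w)
  # stable log(1 + exp(-s))
  loss <- ifelse(s > 0, log1p(exp(-s)), -s + log1p(exp(s)))
  mean(loss) + lambda * sum(w)
}

#' Fit feature relevance weights
#'
#' Learns a nonnegative weight vector by alternating two steps: (a) with the
#' current weights frozen, compute every sample's margin vector `z_i`;
#' (b) descend the L1-regularized logistic margin loss
#' `mean(log(1 + exp(-<w, z_i>))) + lambda * sum(w)` with a short run of
#' backtracking gradient steps, keeping `w >= 0` through the squared
#' parameterization `w_j = v_j^2`.
#' Deterministic: weights start at all-ones and the data order is fixed.
#'
#' @param data Feature tibble (label column + `f...` feature columns) or a
#'   numeric matrix (then `y` is required).
#' @param sigma Kernel width of the neighbor softmax (> 0).
#' @param lambda L1 regularization strength (>= 0); larger values give
#'   sparser weights.
#' @param eta Initial gradient step size.
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on `||w_new - w_old||_2`.
#' @param y Labels in `{+1, -1}` (or "mass"/"normal"), only when `data` is
#'   a matrix.
#' @param label_col Label column name when `data` is a data frame.
#' @return Object of class `wld_weights`: weights `w`, the parameters,
#'   iteration count, convergence flag and objective trace. Supports
#'   [tidy()], [glance()], [autoplot()].
#' @export
fit_feature_weights <- function(data, sigma = 0.3, lambda = 0.1, eta = 0.1,
                                max_iter = 200L, tol = 1e-4,
                                y = NULL, label_col = "label") {
  if (is.data.frame(data)) {
    y <- encode_labels(data[[label_col]])
    x <- feature_matrix(data)
  } else {
    x <- data
    y <- encode_labels(y)
  }
  check_dataset(x, y)
  if (sigma <= 0) abort("`sigma` must be > 0")
  if (lambda < 0) abort("`lambda` must be >= 0")
  if (eta <= 0) abort("`eta` must be > 0")
  if (min(table(y)) < 2) abort("degenerate hit set: each class needs >= 2 samples")

  m <- ncol(x)
  v <- rep(1, m)
  w <- v^2
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  xt <- t(x)  # feature-major copy for the compiled kernel
  for (it in seq_len(max_iter)) {
    iters <- it
    z <- margin_vectors_t_cpp(xt, as.integer(y), as.numeric(w), sigma)
    trace <- c(trace, logistic_objective(w, z, lambda))
    # descend the frozen-margin objective (a few damped gradient steps,
    # mirroring the per-iteration subproblem solve of the source algorithm)
    v_new <- v
    for (inner in 1:10) {
      w_cur <- v_new^2
      f0 <- logistic_objective(w_cur, z, lambda)
      s <- as.numeric(z %*% w_cur)
      p <- 1 / (1 + exp(pmin(s, 700)))        # sigmoid(-s), overflow-safe
      grad_v <- 2 * v_new * (-colMeans(p * z) + lambda)
      step <- eta
      accepted <- FALSE
      for (bt in 1:30) {
        cand <- v_new - step * grad_v
        if (logistic_objective(cand^2, z, lambda) <= f0) {
          v_new <- cand
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
    }
    w_new <- v_new^2
    delta <- sqrt(sum((w_new - w)^2))
    v <- v_new
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("feature-weight fit did not converge in %d iterations", max_iter))
  }
  structure(
    list(
      w = unname(w), sigma = sigma, lambda = lambda, eta = eta,
      iterations = iters, converged = converged, objective = trace,
      n = nrow(x), m = m
    ),
    class = "wld_weights"
  )
}

#' @export
print.wld_weights <- function(x, ...) {
  cat(sprintf(
    "Feature weights: %d features, sigma = %g, lambda = %g\n%s after %d iterations; %d features above default threshold\n",
    x$m, x$sigma, x$lambda,
    if (x$converged) "converged" else "not converged",
    x$iterations,
    length(tryCatch(select_features(x), error = function(e) integer(0)))
  ))
  invisible(x)
}

#' Indices of retained features
#'
#' Features whose weight exceeds `threshold`, in ascending index order. The
#' default cutoff is `1e-4 * max(max(w), 1)`: relative to the largest fitted
#' weight, but never below `1e-4` absolute — weights start at 1, so a fit
#' driven entirely to ~0 by heavy regularization retains nothing rather
#' than everything.
#'
#' @param w A `wld_weights` object or a nonnegative numeric weight vector.
#' @param threshold Nonnegative cutoff; weights strictly above it are kept.
#' @return Integer vector of selected feature indices.
#' @export
select_features <- function(w, threshold = NULL) {
  wv <- if (inherits(w, "wld_weights")) w$w else w
  if (any(wv < 0)) abort("weights must be nonnegative")
  if (is.null(threshold)) threshold <- 1e-4 * max(max(wv), 1)
  if (threshold < 0) abort("`threshold` must be >= 0")
  idx <- which(wv > threshold)
  if (length(idx) == 0) abort("no features selected: all weights at or below threshold")
  idx
}

#' Cross-validated (sigma, lambda) grid search for the selector
#'
#' For every grid pair, fits weights on each training split (features
#' z-scored on that split, the same space the downstream SVM sees), selects
#' features, trains the RBF-SVM of the classification module on them and
#' scores ROC AUC on the validation fold; the pair with the best mean
#' validation AUC wins (ties broken toward smaller `lambda`, then smaller
#' `sigma`). The winner is refit on all data.
#'
#' @inheritParams fit_feature_weights
#' @param sigma_grid,lambda_grid Candidate values (non-empty).
#' @param folds Cross-validation fold count.
#' @param seed Integer seed controlling the fold assignment.
#' @param svm_params `list(C = , gamma = )` used for the wrapper SVM;
#'   `gamma = NULL` means `1 / n_selected_features`.
#' @param ... Passed on to [fit_feature_weights()] (`eta`, `max_iter`, `tol`).
#' @return List: `sigma`, `lambda`, `weights` (`wld_weights` refit on all
#'   data), `selected` indices, and the per-pair `search` tibble.
#' @export
tune_feature_weights <- function(data,
                                 sigma_grid = c(0.05, 0.1, 0.2, 0.3, 0.5, 1),
                                 lambda_grid = c(0.1, 0.3, 0.5, 0.7, 1, 2),
                                 folds = 5L, seed = 1L,
                                 svm_params = list(C = 1, gamma = NULL),
                                 y = NULL, label_col = "label", ...) {
  if (length(sigma_grid) == 0 || length(lambda_grid) == 0) {
    abort("sigma and lambda grids must be non-empty")
  }
  if (is.data.frame(data)) {
    y <- encode_labels(data[[label_col]])
    x <- feature_matrix(data)
  } else {
    x <- data
    y <- encode_labels(y)
  }
  check_dataset(x, y)
  fold_sets <- stratified_folds(y, folds, seed)
  grid <- expand.grid(sigma = sigma_grid, lambda = lambda_grid)
  score_pair <- function(sigma, lambda) {
    az <- vapply(fold_sets, function(test_idx) {
      std <- fit_standardizer(x[-test_idx, , drop = FALSE])
      tr_x <- apply_standardizer(x[-test_idx, , drop = FALSE], std)
      te_x <- apply_standardizer(x[test_idx, , drop = FALSE], std)
      tr_y <- y[-test_idx]
      fit <- fit_feature_weights(tr_x, sigma = sigma, lambda = lambda,
                                 y = tr_y, ...)
      sel <- tryCatch(select_features(fit), error = function(e) integer(0))
      if (length(sel) == 0) return(0.5)
      gamma <- svm_params$gamma %||% (1 / length(sel))
      model <- svm_rbf(tr_x[, sel, drop = FALSE], tr_y,
                       C = svm_params$C, gamma = gamma)
      scores <- svm_decision(model, te_x[, sel, drop = FALSE])
      roc_auc(-scores, y[test_idx], positive = -1L)
    }, numeric(1))
    mean(az)
  }
  grid$mean_az <- purrr::map2_dbl(grid$sigma, grid$lambda, score_pair)
  ord <- order(-grid$mean_az, grid$lambda, grid$sigma)
  best <- grid[ord[1], ]
  x_all <- apply_standardizer(x, fit_standardizer(x))
  weights <- fit_feature_weights(x_all, sigma = best$sigma, lambda = best$lambda,
                                 y = y, ...)
  list(
    sigma = best$sigma,
    lambda = best$lambda,
    weights = weights,
    selected = tryCatch(select_features(weights),
                        error = function(e) integer(0)),
    search = as_tibble(grid)
  )
}
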