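# broom-style tidiers for fitted objects.

#' Tidy a feature-weight fit
#'
#' @param x A `wld_weights` object.
#' @param threshold Passed to [select_features()] to mark retained features.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature`, `weight`, `selected`.
#' @method tidy wld_weights
#' @export
tidy.wld_weights <- function(x, threshold = NULL, ...) {
  sel <- tryCatch(select_features(x, threshold), error = function(e) integer(0))
  tibble(
    feature = seq_along(x$w),
    weight = x$w,
    selected = seq_along(x$w) %in% sel
  )
}

#' One-row summary of a feature-weight fit
#'
#' @param x A `wld_weights` object.
#' @param ... Unused.
#' @return One-row tibble: parameters, iteration count, convergence,
#'   final objective, selected-feature count.
#' @method glance wld_weights
#' @export
glance.wld_weights <- function(x, ...) {
  tibble(
    n = x$n, m = x$m, sigma = x$sigma, lambda = x$lambda,
    iterations = x$iterations, converged = x$converged,
    objective = x$objective[length(x$objective)],
    n_selected = length(tryCatch(select_features(x),
                                 error = function(e) integer(0)))
  )
}

#' Per-fold results of a cross-validated evaluation
#'
#' @param x An `mswld_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per fold: confusion counts, sensitivity /
#'   specificity / accuracy (percent), Az, and tuned parameters.
#' @method tidy mswld_eval
#' @export
tidy.mswld_eval <- function(x, ...) {
  x$folds
}

#' Aggregate summary of a cross-validated evaluation
#'
#' @param x An `mswld_eval` object.
#' @param ... Unused.
#' @return One-row tibble of mean and standard deviation of sensitivity,
#'   specificity, accuracy (percent) and Az across folds.
#' @method glance mswld_eval
#' @export
glance.mswld_eval <- function(x, ...) {
  eval_summary(x)
}
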