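#' Coefficient of determination
#'
#' \deqn{R^2 = 1 - \sum_j (X_j - Y_j)^2 / \sum_j (X_j - \bar X)^2} with
#' \eqn{X_j} the reference values and \eqn{Y_j} the predictions.
#'
#' @param y_true reference values (length >= 2, nonzero variance).
#' @param y_pred predictions, same length.
#' @return Scalar R-squared.
#' @export
r_squared <- function(y_true, y_pred) {
  check_eval_set(y_true, y_pred)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst <= 0) stop("y_true has zero variance; R^2 undefined")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Root mean square error
#'
#' \deqn{RMSE = \sqrt{\sum_j (X_j - Y_j)^2 / n}} (denominator n).
#'
#' @inheritParams r_squared
#' @return Scalar RMSE in the units of `y` (%).
#' @export
rmse <- function(y_true, y_pred) {
  check_eval_set(y_true, y_pred, min_n = 1L)
  sqrt(mean((y_true - y_pred)^2))
}

#' Residual predictive deviation
#'
#' \deqn{RPD = SD / RMSE} where SD is the population (denominator n)
#' standard deviation of the reference values on the same evaluation set.
#' Under this convention RPD is algebraically identical to
#' \eqn{1/\sqrt{1 - R^2}} when \eqn{R^2} is computed on the same set —
#' the only SD convention consistent with the conventional printed
#' (R-squared, RPD) pairs. An RPD above 3 is the usual threshold for a
#' model considered good for quantitative prediction.
#'
#' @inheritParams r_squared
#' @return Scalar RPD (> 0); errors when RMSE is exactly 0 (infinite RPD).
#' @export
rpd <- function(y_true, y_pred) {
  check_eval_set(y_true, y_pred)
  rm_ <- rmse(y_true, y_pred)
  if (rm_ == 0) stop("RMSE is zero: RPD is infinite")
  sd_pop <- sqrt(mean((y_true - mean(y_true))^2))
  sd_pop / rm_
}

#' RPD implied by an R-squared value
#'
#' The population-SD metric identity \eqn{RPD = 1/\sqrt{1 - R^2}}; useful
#' for checking that reported (R-squared, RPD) pairs are internally
#' consistent.
#'
#' @param r2 R-squared value(s), `< 1`.
#' @return RPD value(s).
#' @export
rpd_from_r2 <- function(r2) {
  if (any(r2 >= 1)) stop("r2 must be < 1")
  1 / sqrt(1 - r2)
}

check_eval_set <- function(y_true, y_pred, min_n = 2L) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (length(y_true) < min_n) stop("need at least ", min_n, " observations")
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred))) {
    stop("non-finite values in evaluation set")
  }
  invisible(TRUE)
}

#' Evaluate a fitted model on the prediction set
#'
#' Computes predictions and all three evaluation metrics from the same
#' evaluation set. A leakage guard refuses to evaluate when the supplied
#' prediction indices intersect the calibration indices.
#'
#' @param model a fitted model with a `predict` method (`plsr_model`,
#'   `lssvm_model`, `trained_network`), or a function `X -> predictions`.
#' @param X_pred prediction-set spectra (`spectrum_set` or matrix).
#' @param y_pred_ref prediction-set reference values.
#' @param cal_indices,pred_indices optional index vectors used only for the
#'   disjointness guard.
#' @return List with `metrics` (list `r2`, `rmse`, `rpd`; `rpd` is `Inf`
#'   when RMSE is exactly 0) and `predictions`.
#' @export
evaluate_model <- function(model, X_pred, y_pred_ref,
                           cal_indices = NULL, pred_indices = NULL) {
  if (!is.null(cal_indices) && !is.null(pred_indices) &&
      length(intersect(cal_indices, pred_indices))) {
    stop("leakage guard: prediction indices intersect calibration indices")
  }
  pred <- if (is.function(model)) model(X_pred) else predict(model, X_pred)
  pred <- as.numeric(pred)
  r2 <- r_squared(y_pred_ref, pred)
  rm_ <- rmse(y_pred_ref, pred)
  rp <- if (rm_ == 0) Inf else rpd(y_pred_ref, pred)
  list(metrics = list(r2 = r2, rmse = rm_, rpd = rp), predictions = pred)
}

#' Random calibration/prediction split
#'
#' Seeded permutation split: the first `floor(fraction * n)` permuted
#' indices form the calibration set, the remainder the prediction set
#' (disjoint and exhaustive).
#'
#' @param n number of samples (>= 10).
#' @param fraction calibration fraction in (0, 1); default 0.7, the usual
#'   seven-tenths assignment.
#' @param seed integer seed.
#' @return List with sorted integer vectors `calibration` and `prediction`.
#' @export
split_calibration_prediction <- function(n, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (n < 10L) stop("need at least 10 samples to split")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  perm <- sample(n)
  n_cal <- floor(fraction * n)
  list(calibration = sort(perm[seq_len(n_cal)]),
       prediction = sort(perm[(n_cal + 1L):n]))
}
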