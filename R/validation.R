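## Internal and external validation statistics for MLR QSAR models:
## training R2/RMSE, cross-validated Q2 (leave-one-out and leave-many-out),
## the external predictivity family Q2F1/F2/F3, Lin's concordance
## correlation coefficient, and Y-scrambling against chance correlation.

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Undefined for a constant
#' response.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return R2 (at most 1; can be negative for predictions worse than the mean).
#' @export
r_squared <- function(y, yhat) {
  check_paired(y, yhat, min_n = 2L)
  tss <- sum((y - mean(y))^2)
  if (tss == 0)
    qsar_stop("arqsar_constant_response_error", "y is constant; R2 undefined")
  1 - sum((y - yhat)^2) / tss
}

#' Root mean squared error
#'
#' `sqrt(mean((y - yhat)^2))` — the 1/n convention, not a
#' degrees-of-freedom-corrected estimate.
#'
#' @inheritParams r_squared
#' @return RMSE in the units of `y`.
#' @export
rmse <- function(y, yhat) {
  check_paired(y, yhat, min_n = 1L)
  sqrt(mean((y - yhat)^2))
}

#' Leave-one-out cross-validated Q2
#'
#' `1 - PRESS / sum((y - mean(y))^2)` where PRESS accumulates each
#' compound's squared error when predicted by the model refitted without
#' it. Uses the exact hat-matrix identity `e_i / (1 - h_ii)` for the
#' deleted residuals (algebraically equal to explicit refitting for OLS).
#' A row with leverage 1 is exactly interpolated by the remaining data's
#' fit and makes LOO degenerate.
#'
#' @param x numeric matrix of the model's descriptor columns (n x p).
#' @param y numeric response.
#' @return Q2(LOO); at most 1, below 0 when the model predicts worse than
#'   the training mean.
#' @export
q2_loo <- function(x, y) {
  x <- as.matrix(unclass(x)); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 2L)
    qsar_stop("arqsar_precondition_error", "need n > p + 2 for LOO (n = %d, p = %d)", n, p)
  fit <- fit_ols(x, y)
  h <- leverages(x)
  if (any(h >= 1 - 1e-10))
    qsar_stop("arqsar_degenerate_loo_error",
              "a training row has leverage 1; LOO prediction undefined")
  press <- sum((fit$residuals / (1 - h))^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0)
    qsar_stop("arqsar_constant_response_error", "y is constant; Q2 undefined")
  1 - press / tss
}

#' Leave-many-out cross-validated Q2
#'
#' Repeatedly holds out a random fraction of the training compounds, refits
#' on the remainder, and scores the held-out predictions against the kept
#' set's mean: the reported value is the mean over iterations of
#' `1 - sum((y_out - yhat_out)^2) / sum((y_out - mean(y_kept))^2)`.
#'
#' @inheritParams q2_loo
#' @param leave_out_fraction fraction of compounds withheld per iteration
#'   (default 0.3, a common leave-30%-out convention).
#' @param iterations number of random splits (default 1000).
#' @param seed integer seed for the split generator.
#' @return mean Q2(LMO) with the per-iteration values in attribute
#'   `"iterations"`.
#' @export
q2_lmo <- function(x, y, leave_out_fraction = 0.3, iterations = 1000L,
                   seed = 1L) {
  x <- as.matrix(unclass(x)); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  n_out <- max(1L, floor(leave_out_fraction * n))
  if (n - n_out <= p + 2L)
    qsar_stop("arqsar_argument_error",
              "leave_out_fraction too large: keeps %d rows for p = %d", n - n_out, p)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  vals <- vapply(seq_len(iterations), function(i) {
    out <- sample.int(n, n_out)
    fit <- fit_ols(x[-out, , drop = FALSE], y[-out])
    pred <- predict(fit$model, x[out, , drop = FALSE])
    1 - sum((y[out] - pred)^2) / sum((y[out] - mean(y[-out]))^2)
  }, numeric(1L))
  structure(mean(vals), iterations = vals)
}

#' External predictivity statistics Q2F1, Q2F2, Q2F3
#'
#' The three conventions differ in the reference variance that scales the
#' external prediction error:
#' * F1: external deviations from the *training* mean,
#'   `1 - sum((y - yhat)^2) / sum((y - ybar_train)^2)`;
#' * F2: external deviations from the *external* mean;
#' * F3: per-compound external MSE over the per-compound training variance,
#'   `1 - (PRESS_ext / n_ext) / (TSS_train / n_train)`.
#'
#' @param y_ext observed external activities.
#' @param yhat_ext predicted external activities.
#' @param ybar_train mean of the training activities (F1).
#' @param y_train the training activities themselves (F3).
#' @return the statistic (at most 1).
#' @export
q2_f1 <- function(y_ext, yhat_ext, ybar_train) {
  check_paired(y_ext, yhat_ext, min_n = 2L)
  stopifnot_scalar_number(ybar_train, "ybar_train")
  denom <- sum((y_ext - ybar_train)^2)
  if (denom == 0)
    qsar_stop("arqsar_constant_response_error", "zero reference variance in Q2F1")
  1 - sum((y_ext - yhat_ext)^2) / denom
}

#' @rdname q2_f1
#' @export
q2_f2 <- function(y_ext, yhat_ext) {
  check_paired(y_ext, yhat_ext, min_n = 2L)
  denom <- sum((y_ext - mean(y_ext))^2)
  if (denom == 0)
    qsar_stop("arqsar_constant_response_error", "external set is constant in Q2F2")
  1 - sum((y_ext - yhat_ext)^2) / denom
}

#' @rdname q2_f1
#' @export
q2_f3 <- function(y_ext, yhat_ext, y_train) {
  check_paired(y_ext, yhat_ext, min_n = 1L)
  if (length(y_train) < 2L)
    qsar_stop("arqsar_argument_error", "need >= 2 training activities for Q2F3")
  denom <- sum((y_train - mean(y_train))^2) / length(y_train)
  if (denom == 0)
    qsar_stop("arqsar_constant_response_error", "training set is constant in Q2F3")
  1 - (sum((y_ext - yhat_ext)^2) / length(y_ext)) / denom
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of predictions with the identity line:
#' `2 * S_xy / (S_xx + S_yy + n * (xbar - ybar)^2)` with uncentred sums of
#' squares about the respective means. Equals the Pearson correlation when
#' means and variances match, and never exceeds it in magnitude.
#'
#' @inheritParams r_squared
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(y, yhat) {
  check_paired(y, yhat, min_n = 2L)
  n <- length(y)
  sy <- sum((y - mean(y))^2); sh <- sum((yhat - mean(yhat))^2)
  if (sy == 0 && sh == 0)
    qsar_stop("arqsar_constant_response_error", "both sequences constant; CCC undefined")
  2 * sum((y - mean(y)) * (yhat - mean(yhat))) /
    (sy + sh + n * (mean(y) - mean(yhat))^2)
}

#' Y-scrambling (response randomization)
#'
#' Permutes the response, refits the same descriptor subset, and records R2
#' and Q2(LOO) per iteration. A real structure-activity relationship shows
#' scrambled R2 far below the unscrambled value; overlap indicates chance
#' correlation.
#'
#' @inheritParams q2_loo
#' @param iterations number of permutations (5000 in the reference
#'   protocol; reduce for quick checks).
#' @param seed integer seed for the permutation stream.
#' @return list of class `y_scramble`: `mean_r2`, `mean_q2_loo`, and the
#'   per-iteration vectors `r2`, `q2_loo`.
#' @export
y_scramble <- function(x, y, iterations = 5000L, seed = 1L) {
  x <- as.matrix(unclass(x)); y <- as.numeric(y)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  r2v <- numeric(iterations); q2v <- numeric(iterations)
  for (i in seq_len(iterations)) {
    ys <- sample(y)
    fit <- fit_ols(x, ys)
    r2v[i] <- r_squared(ys, fit$fitted)
    q2v[i] <- tryCatch(q2_loo(x, ys), arqsar_error = function(e) NA_real_)
  }
  structure(list(mean_r2 = mean(r2v), mean_q2_loo = mean(q2v, na.rm = TRUE),
                 r2 = r2v, q2_loo = q2v, iterations = iterations, seed = seed),
            class = "y_scramble")
}

#' @export
print.y_scramble <- function(x, ...) {
  cat(sprintf("Y-scrambling over %d permutations: mean R2 = %.3f, mean Q2(LOO) = %.3f\n",
              x$iterations, x$mean_r2, x$mean_q2_loo))
  invisible(x)
}

#' Full validation metrics report
#'
#' Computes the internal battery (R2, training RMSE, Q2 LOO, Q2 LMO,
#' Y-scrambling means) on the training data, and the external battery
#' (Q2F1/F2/F3, concordance correlation, prediction RMSE) when an external
#' set is supplied. External predictions come from the model fitted on the
#' full training set.
#'
#' @param x_train matrix of the model's descriptor columns for the training
#'   compounds.
#' @param y_train training activities.
#' @param x_ext,y_ext optional external descriptor rows / activities.
#' @param lmo_fraction,lmo_iterations leave-many-out settings (defaults:
#'   30% out, 1000 iterations).
#' @param scramble_iterations Y-scrambling permutations (default 5000).
#' @param seed integer seed shared by the LMO and scrambling streams.
#' @return list of class `metrics_report` with the metric fields plus
#'   configuration echoes (`lmo_config`, `scramble_config`).
#' @export
validation_metrics <- function(x_train, y_train, x_ext = NULL, y_ext = NULL,
                               lmo_fraction = 0.3, lmo_iterations = 1000L,
                               scramble_iterations = 5000L, seed = 1L) {
  x_train <- as.matrix(unclass(x_train))
  fit <- fit_ols(x_train, y_train)
  scr <- y_scramble(x_train, y_train, iterations = scramble_iterations, seed = seed)
  rep <- list(r2 = r_squared(y_train, fit$fitted),
              rmse_train = rmse(y_train, fit$fitted),
              q2_loo = q2_loo(x_train, y_train),
              q2_lmo = as.numeric(q2_lmo(x_train, y_train, lmo_fraction,
                                         lmo_iterations, seed = seed)),
              q2_f1 = NA_real_, q2_f2 = NA_real_, q2_f3 = NA_real_,
              ccc = NA_real_, rmse_prediction = NA_real_,
              y_scramble_mean_r2 = scr$mean_r2,
              y_scramble_mean_q2 = scr$mean_q2_loo,
              lmo_config = list(fraction = lmo_fraction,
                                iterations = lmo_iterations, seed = seed),
              scramble_config = list(iterations = scramble_iterations, seed = seed))
  if (!is.null(x_ext)) {
    yhat_ext <- predict(fit$model, x_ext)
    rep$q2_f1 <- q2_f1(y_ext, yhat_ext, mean(y_train))
    rep$q2_f2 <- q2_f2(y_ext, yhat_ext)
    rep$q2_f3 <- q2_f3(y_ext, yhat_ext, y_train)
    rep$ccc <- ccc(y_ext, yhat_ext)
    rep$rmse_prediction <- rmse(y_ext, yhat_ext)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Validation metrics\n")
  cat(sprintf("  R2 = %.*f   RMSE(train) = %.*f\n", digits, x$r2, digits, x$rmse_train))
  cat(sprintf("  Q2(LOO) = %.*f   Q2(LMO, %d%% out) = %.*f\n",
              digits, x$q2_loo, round(100 * x$lmo_config$fraction), digits, x$q2_lmo))
  if (!is.na(x$q2_f1))
    cat(sprintf("  Q2F1 = %.*f   Q2F2 = %.*f   Q2F3 = %.*f   CCC = %.*f   RMSE(pred) = %.*f\n",
                digits, x$q2_f1, digits, x$q2_f2, digits, x$q2_f3,
                digits, x$ccc, digits, x$rmse_prediction))
  cat(sprintf("  Y-scrambled means (%d iter): R2 = %.*f, Q2 = %.*f\n",
              x$scramble_config$iterations, digits, x$y_scramble_mean_r2,
              digits, x$y_scramble_mean_q2))
  invisible(x)
}

check_paired <- function(y, yhat, min_n) {
  if (length(y) != length(yhat))
    qsar_stop("arqsar_shape_error", "y and yhat differ in length (%d vs %d)",
              length(y), length(yhat))
  if (length(y) < min_n)
    qsar_stop("arqsar_argument_error", "need at least %d paired values", min_n)
  if (!all(is.finite(y)) || !all(is.finite(yhat)))
    qsar_stop("arqsar_missing_value_error", "non-finite values in y or yhat")
  invisible(TRUE)
}
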