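## Leverage-based applicability domain. The leverage of a query compound,
## h = x (X'X)^-1 x' with x the intercept-augmented descriptor row and X the
## intercept-augmented training design, measures its distance from the
## training descriptor centroid in model space. Predictions with
## h > h* = 3(p + 1)/n are extrapolations. Labelled compounds are inspected
## on the Williams plot (h vs standardized residual); unlabelled screening
## compounds on the Insubria graph (h vs predicted activity).

#' Leverage cutoff for the applicability domain
#'
#' `h* = 3(p + 1)/n`, the conventional warning leverage: three times the
#' mean training leverage of a p-descriptor model with intercept.
#'
#' @param p number of model descriptors (>= 1).
#' @param n training-set size (> p + 1).
#' @return the cutoff h*.
#' @examples
#' leverage_cutoff(4, 29)  # 0.517 for the published antagonist model
#' @export
leverage_cutoff <- function(p, n) {
  stopifnot_scalar_number(p, "p"); stopifnot_scalar_number(n, "n")
  if (p < 1 || p != round(p) || n != round(n))
    qsar_stop("arqsar_argument_error", "p and n must be integers with p >= 1")
  if (n <= p + 1)
    qsar_stop("arqsar_argument_error", "need n > p + 1 (n = %d, p = %d)", n, p)
  3 * (p + 1) / n
}

#' Leverages (hat values) against a training design
#'
#' Augments each descriptor row with a leading 1 (the intercept column) and
#' evaluates `h_i = x_i (X'X)^-1 x_i'`. Queried with the training rows
#' themselves this returns the hat-matrix diagonal, so training leverages
#' sum to p + 1.
#'
#' @param x_train numeric matrix of training rows restricted to the model's
#'   descriptor columns.
#' @param x_query rows to score (defaults to the training rows); columns
#'   must align with `x_train`.
#' @return numeric vector of leverages, one per query row.
#' @export
leverages <- function(x_train, x_query = x_train) {
  x_train <- as.matrix(unclass(x_train))
  x_query <- as.matrix(unclass(x_query))
  if (ncol(x_query) != ncol(x_train))
    qsar_stop("arqsar_shape_error", "query has %d columns, training %d",
              ncol(x_query), ncol(x_train))
  if (!is.null(colnames(x_train)) && !is.null(colnames(x_query)) &&
      !identical(colnames(x_train), colnames(x_query)))
    qsar_stop("arqsar_shape_error", "query columns not aligned to training columns")
  xt <- cbind(1, x_train)
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(xt))),
                      error = function(e)
                        qsar_stop("arqsar_singular_fit_error",
                                  "X'X is singular; cannot compute leverages"))
  xq <- cbind(1, x_query)
  h <- rowSums((xq %*% xtx_inv) * xq)
  names(h) <- rownames(x_query)
  h
}

#' Standardized prediction residuals
#'
#' Residuals divided by the sample standard deviation (1/(n-1)
#' normalization) of the *training* residuals — the scale is always set by
#' the training fit, also when standardizing external-set residuals. Values
#' beyond 2.5 in magnitude conventionally flag poorly predicted compounds.
#'
#' @param y observed activities.
#' @param yhat predicted activities.
#' @param scale_residuals residuals defining the standardization scale;
#'   defaults to `y - yhat` itself (training use). Pass the training
#'   residuals when standardizing an external set.
#' @param flag_threshold magnitude beyond which a residual is flagged
#'   (default 2.5).
#' @return numeric vector with attribute `"flagged"` (logical, |value| >
#'   threshold).
#' @export
standardized_residuals <- function(y, yhat, scale_residuals = y - yhat,
                                   flag_threshold = 2.5) {
  check_paired(y, yhat, min_n = 1L)
  s <- sd(scale_residuals)
  if (!is.finite(s) || s == 0)
    qsar_stop("arqsar_zero_variance_error",
              "zero residual variance; standardization undefined")
  z <- (y - yhat) / s
  attr(z, "flagged") <- abs(z) > flag_threshold
  z
}

#' Williams-plot data (leverage vs standardized residual)
#'
#' One record per compound: leverage, standardized residual (on the
#' training-residual scale), whether it sits inside the structural
#' applicability domain (`h <= h*`), and whether its residual exceeds the
#' 2.5 sigma band. External compounds are scored against the training
#' design.
#'
#' @param model a [model_spec()] fitted on `x_train`.
#' @param x_train,y_train training descriptor rows (model columns) and
#'   activities.
#' @param x_ext,y_ext optional external rows and activities.
#' @param flag_threshold residual band half-width (default 2.5).
#' @return list of class `leverage_report`: `h_star` and `points`, a data
#'   frame with columns `compound_id`, `set`, `h`, `std_residual`,
#'   `inside_ad`, `residual_flag`.
#' @export
williams_points <- function(model, x_train, y_train, x_ext = NULL, y_ext = NULL,
                            flag_threshold = 2.5) {
  x_train <- as.matrix(unclass(x_train))
  p <- length(model$descriptor_names); n <- nrow(x_train)
  h_star <- leverage_cutoff(p, n)
  train_resid <- y_train - predict(model, x_train)
  rows <- list(leverage_block(model, x_train, x_train, y_train, "train",
                              train_resid, flag_threshold))
  if (!is.null(x_ext))
    rows <- c(rows, list(leverage_block(model, x_train, as.matrix(unclass(x_ext)),
                                        y_ext, "external", train_resid,
                                        flag_threshold)))
  pts <- do.call(rbind, rows)
  pts$inside_ad <- pts$h <= h_star
  structure(list(h_star = h_star, points = pts), class = "leverage_report")
}

leverage_block <- function(model, x_train, x_block, y_block, set_name,
                           train_resid, flag_threshold) {
  h <- leverages(x_train, x_block)
  z <- standardized_residuals(y_block, predict(model, x_block),
                              scale_residuals = train_resid,
                              flag_threshold = flag_threshold)
  data.frame(compound_id = rownames(x_block) %||% seq_len(nrow(x_block)),
             set = set_name, h = unname(h), std_residual = as.numeric(z),
             inside_ad = NA, residual_flag = as.logical(attr(z, "flagged")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.leverage_report <- function(x, ...) {
  cat(sprintf("Leverage report: h* = %.3f; %d/%d compounds inside the AD\n",
              x$h_star, sum(x$points$inside_ad), nrow(x$points)))
  out <- sum(!x$points$inside_ad | x$points$residual_flag, na.rm = TRUE)
  if (out) print(x$points[!x$points$inside_ad | x$points$residual_flag, ], ...)
  invisible(x)
}

#' Insubria-graph data (leverage vs predicted activity)
#'
#' Applicability-domain inspection for screening compounds without
#' experimental activity: per compound, the leverage against the training
#' design, the model prediction, and the inside-AD flag using the training
#' h*. An empty screening table yields an empty data frame.
#'
#' @param model a [model_spec()].
#' @param x_train training rows (model descriptor columns).
#' @param x_screen screening rows, same columns.
#' @return data frame with columns `compound_id`, `h`, `predicted_pIC50`,
#'   `inside_ad`; attribute `"h_star"` carries the cutoff.
#' @export
insubria_points <- function(model, x_train, x_screen) {
  x_train <- as.matrix(unclass(x_train))
  h_star <- leverage_cutoff(length(model$descriptor_names), nrow(x_train))
  x_screen <- as.matrix(unclass(x_screen))
  if (nrow(x_screen) == 0L)
    return(structure(data.frame(compound_id = character(), h = numeric(),
                                predicted_pIC50 = numeric(), inside_ad = logical(),
                                stringsAsFactors = FALSE),
                     h_star = h_star))
  h <- leverages(x_train, x_screen)
  structure(data.frame(
    compound_id = rownames(x_screen) %||% as.character(seq_len(nrow(x_screen))),
    h = unname(h),
    predicted_pIC50 = unname(predict(model, x_screen)),
    inside_ad = unname(h <= h_star),
    stringsAsFactors = FALSE, row.names = NULL), h_star = h_star)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
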