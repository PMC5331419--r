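## The user-facing fitting function. Wraps the GA subset search and the OLS
## fit of the winning subset into a single classed model object that the
## usual verbs (print, summary, coef, predict, plot, residuals, simulate)
## understand.

#' Fit a GA-selected MLR QSAR model
#'
#' Runs the genetic-algorithm descriptor-subset search on a curated
#' descriptor table, fits the best subset by ordinary least squares, and
#' returns a model object. Training fit statistics (R2, RMSE, leave-one-out
#' Q2) are computed at fit time; the heavier validation (leave-many-out,
#' external Q2, Y-scrambling) is available through [summary()] /
#' [validation_metrics()].
#'
#' @param x a [descriptor_table()] (or numeric matrix with dimnames) of the
#'   training compounds.
#' @param y numeric pIC50 vector aligned to the rows of `x`.
#' @param model_size number of descriptors in the model (4 in the published
#'   antagonist model).
#' @param config a [ga_config()]; `model_size` and `seed` arguments override
#'   the corresponding config fields.
#' @param seed integer seed driving the GA.
#' @return an object of class `qsar_gamlr` with components `model`
#'   (a [model_spec()]), `fit` (`fit_result`), `search` (`ga_result`),
#'   `r2`, `rmse_train`, `q2_loo`, `lof`, plus the training data (`x`, `y`)
#'   needed by the leverage and validation methods.
#' @examples
#' d <- generate_synthetic(synthetic_spec(n_train = 25, n_ext = 0, n_screen = 0,
#'   n_descriptors = 12, true_descriptor_indices = c(2, 9), seed = 3,
#'   true_coefficients = c(0.8, -0.6), n_correlated_pairs = 0))
#' fit <- qsar_gamlr(d$descriptors, d$activity$pIC50, model_size = 2,
#'   config = ga_config(population_size = 30, max_generations = 60,
#'                      stagnation_patience = 25))
#' coef(fit)
#' @export
qsar_gamlr <- function(x, y, model_size = 4L, config = ga_config(),
                       seed = config$seed) {
  x <- as_descriptor_table(x)
  y <- as.numeric(y)
  config$model_size <- as.integer(model_size)
  config$seed <- as.integer(seed)
  config <- do.call(ga_config, unclass(config))
  search <- run_ga(x, y, config)
  top <- search$models[[1L]]
  if (is.null(top$fit))
    qsar_stop("arqsar_singular_fit_error", "no non-singular model found")
  fit <- top$fit
  xm <- unclass(x)[, top$descriptors, drop = FALSE]
  structure(list(call = match.call(),
                 model = fit$model, fit = fit, search = search,
                 x = x, x_model = xm, y = y,
                 lof = top$lof,
                 r2 = r_squared(y, fit$fitted),
                 rmse_train = rmse(y, fit$fitted),
                 q2_loo = q2_loo(xm, y),
                 config = config),
            class = "qsar_gamlr")
}

#' @export
print.qsar_gamlr <- function(x, digits = 3, ...) {
  cat("GA-MLR QSAR model\n\n")
  print(x$model, digits = digits + 1)
  cat(sprintf("  R2 = %.*f   RMSE = %.*f   Q2(LOO) = %.*f   LOF = %.*g\n",
              digits, x$r2, digits, x$rmse_train, digits, x$q2_loo, digits + 2, x$lof))
  invisible(x)
}

#' @export
coef.qsar_gamlr <- function(object, ...) coef(object$model)

#' @export
residuals.qsar_gamlr <- function(object, ...) object$fit$residuals

#' @export
fitted.qsar_gamlr <- function(object, ...) object$fit$fitted

#' Predict from a fitted GA-MLR model
#'
#' @param object a [qsar_gamlr()] fit.
#' @param newdata descriptor table containing the model's descriptor
#'   columns; omitted, the training fitted values are returned.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.qsar_gamlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fit$fitted)
  predict(object$model, newdata)
}

#' Simulate responses from a fitted GA-MLR model
#'
#' Draws `nsim` response vectors as fitted values plus Gaussian noise with
#' the residual standard deviation of the training fit.
#'
#' @param object a `qsar_gamlr` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with `nsim` columns.
#' @export
simulate.qsar_gamlr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- sd(object$fit$residuals)
  n <- length(object$y)
  out <- as.data.frame(replicate(nsim, object$fit$fitted + rnorm(n, 0, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Summarize a GA-MLR fit with the full validation battery
#'
#' Computes the complete metrics report ([validation_metrics()]) for the
#' fit, including leave-many-out cross-validation and Y-scrambling, and, if
#' an external set is supplied, the external predictivity statistics
#' (Q2F1/F2/F3, concordance correlation, external RMSE).
#'
#' @param object a `qsar_gamlr` fit.
#' @param x_ext,y_ext optional external (prediction-set) descriptor rows and
#'   activities.
#' @param ... passed to [validation_metrics()] (e.g. `lmo_iterations`,
#'   `scramble_iterations`, `seed`).
#' @return a `summary.qsar_gamlr` object wrapping the `metrics_report`.
#' @export
summary.qsar_gamlr <- function(object, x_ext = NULL, y_ext = NULL, ...) {
  x_ext_m <- if (!is.null(x_ext))
    as.matrix(x_ext)[, object$model$descriptor_names, drop = FALSE]
  metrics <- validation_metrics(object$x_model, object$y,
                                x_ext = x_ext_m, y_ext = y_ext, ...)
  structure(list(model = object$model, lof = object$lof, metrics = metrics,
                 generations = object$search$generations),
            class = "summary.qsar_gamlr")
}

#' @export
print.summary.qsar_gamlr <- function(x, ...) {
  print(x$model)
  cat(sprintf("  selected in %d GA generations, LOF = %.5g\n\n",
              x$generations, x$lof))
  print(x$metrics)
  invisible(x)
}

#' Williams plot of a fitted GA-MLR model
#'
#' Plots leverage against standardized residual for the training compounds
#' (and an external set if given), with the leverage cutoff
#' `h* = 3(p + 1)/n` and the +/-2.5 sigma residual bands.
#'
#' @param x a `qsar_gamlr` fit.
#' @param x_ext,y_ext optional external descriptor rows and activities.
#' @param ... passed to [graphics::plot()].
#' @return the underlying `leverage_report`, invisibly.
#' @export
plot.qsar_gamlr <- function(x, x_ext = NULL, y_ext = NULL, ...) {
  rep <- williams_points(x$model, x$x_model, x$y,
                         x_ext = if (!is.null(x_ext))
                           as.matrix(x_ext)[, x$model$descriptor_names, drop = FALSE],
                         y_ext = y_ext)
  pts <- rep$points
  graphics::plot(pts$h, pts$std_residual,
                 pch = ifelse(pts$set == "train", 19, 17),
                 col = ifelse(pts$inside_ad, "black", "red"),
                 xlab = "leverage h", ylab = "standardized residual",
                 main = "Williams plot", ...)
  graphics::abline(v = rep$h_star, lty = 2)
  graphics::abline(h = c(-2.5, 2.5), lty = 3)
  invisible(rep)
}
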