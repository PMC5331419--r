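## Frozen MLR model specification: ordered descriptor names, aligned
## coefficients, intercept. This is the portable artefact the screening
## stage consumes, e.g. the published four-descriptor antagonist model
## pIC50 = -2.89 IC5 + 1.01 GATS5e - 3.17 DISPp - 12.99 HATS3u + 27.13.

#' Construct a frozen MLR model specification
#'
#' @param descriptor_names character, ordered descriptor names (length p >= 1).
#' @param coefficients numeric, aligned to `descriptor_names`.
#' @param intercept single finite number.
#' @param n_train training-set size the model was fitted on, or `NA`.
#' @param training_stats optional metrics report (see [validation_metrics()])
#'   carried as metadata.
#' @return a list of class `model_spec`.
#' @examples
#' m <- model_spec(c("IC5", "GATS5e"), c(-2.89, 1.01), 27.13)
#' @export
model_spec <- function(descriptor_names, coefficients, intercept,
                       n_train = NA_integer_, training_stats = NULL) {
  descriptor_names <- as.character(descriptor_names)
  coefficients <- as.numeric(coefficients)
  if (length(descriptor_names) < 1L)
    qsar_stop("arqsar_model_validation_error", "a model needs at least one descriptor")
  if (anyDuplicated(descriptor_names))
    qsar_stop("arqsar_duplicate_descriptor_error", "duplicate descriptor names in model")
  if (length(coefficients) != length(descriptor_names))
    qsar_stop("arqsar_model_validation_error",
              "%d coefficients for %d descriptors",
              length(coefficients), length(descriptor_names))
  if (!all(is.finite(coefficients)))
    qsar_stop("arqsar_model_validation_error", "non-finite coefficient")
  stopifnot_scalar_number(intercept, "intercept")
  structure(list(descriptor_names = descriptor_names,
                 coefficients = stats::setNames(coefficients, descriptor_names),
                 intercept = as.numeric(intercept),
                 n_train = if (is.na(n_train)) NA_integer_ else as.integer(n_train),
                 training_stats = training_stats),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, digits = 4, ...) {
  terms <- sprintf("%s %s*%s",
                   ifelse(x$coefficients < 0, "-", "+"),
                   format(abs(x$coefficients), digits = digits, trim = TRUE),
                   x$descriptor_names)
  cat("MLR model: pIC50 =", format(x$intercept, digits = digits),
      paste(terms, collapse = " "), "\n")
  if (!is.na(x$n_train)) cat(sprintf("  fitted on n = %d compounds\n", x$n_train))
  invisible(x)
}

#' @export
coef.model_spec <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict activities from a frozen model
#'
#' Applies the linear model to a descriptor table (or any matrix/data frame
#' with named columns), matching descriptor columns by exact name. A missing
#' model descriptor column or a non-finite descriptor value is an error.
#'
#' @param object a [model_spec()].
#' @param newdata matrix or data frame containing all model descriptor columns.
#' @param ... unused.
#' @return named numeric vector of predicted pIC50, one per row of `newdata`.
#' @examples
#' m <- model_spec(c("a", "b"), c(1, -1), 0.5)
#' predict(m, matrix(1, 1, 2, dimnames = list("c1", c("a", "b"))))
#' @export
predict.model_spec <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  missing_cols <- setdiff(object$descriptor_names, colnames(x))
  if (length(missing_cols))
    qsar_stop("arqsar_missing_descriptor_error",
              "descriptor column(s) absent from table: %s",
              paste(missing_cols, collapse = ", "))
  x <- x[, object$descriptor_names, drop = FALSE]
  if (!is.numeric(x) || !all(is.finite(x)))
    qsar_stop("arqsar_missing_value_error",
              "non-finite descriptor values in prediction table")
  drop(object$intercept + x %*% object$coefficients)
}

#' Serialize / deserialize a model specification as JSON
#'
#' The JSON round trip preserves descriptor names and full-precision
#' coefficient values (17 significant digits), so `read_model(write_model(m))`
#' reproduces `m` exactly.
#'
#' @param model a [model_spec()].
#' @param path file path for the JSON document.
#' @return `write_model` returns `path` invisibly; `read_model` returns a
#'   [model_spec()].
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "model_spec"))
    qsar_stop("arqsar_argument_error", "`model` must be a model_spec")
  # 17 significant digits uniquely identify a double, so the decimal strings
  # survive the trip bit-exactly
  payload <- list(descriptor_names = model$descriptor_names,
                  coefficients = sprintf("%.17g", unname(model$coefficients)),
                  intercept = sprintf("%.17g", model$intercept),
                  n_train = model$n_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    qsar_stop("arqsar_schema_error", "malformed model JSON: %s",
                              conditionMessage(e)))
  need <- c("descriptor_names", "coefficients", "intercept")
  if (!all(need %in% names(doc)))
    qsar_stop("arqsar_schema_error", "model JSON missing field(s): %s",
              paste(setdiff(need, names(doc)), collapse = ", "))
  n_train <- doc$n_train
  coefs <- suppressWarnings(as.numeric(doc$coefficients))
  intercept <- suppressWarnings(as.numeric(doc$intercept))
  if (any(is.na(coefs)) || length(intercept) != 1L || is.na(intercept))
    qsar_stop("arqsar_schema_error", "non-numeric coefficients in model JSON")
  model_spec(doc$descriptor_names, coefs, intercept,
             n_train = if (is.null(n_train) || is.na(n_train)) NA_integer_ else n_train)
}
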