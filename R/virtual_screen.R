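## Virtual screening: apply a frozen MLR model to a screening descriptor
## table, attach leverage-based applicability-domain flags (Y inside,
## N outside, as in the reference screening table), and rank by predicted
## activity.

#' Screen a compound library with a frozen model
#'
#' Predicts activities for the screening rows, computes their leverages
#' against the training design, flags each compound `Y` (inside the
#' structural applicability domain, `h <= h*`) or `N` (outside), and ranks
#' by descending predicted activity with ties broken by ascending compound
#' id.
#'
#' @param model a [model_spec()].
#' @param x_train training descriptor rows (the model's columns) defining
#'   the leverage context.
#' @param x_screen screening descriptor rows, same columns.
#' @param threshold optional minimum predicted activity; rows below it are
#'   dropped from the report (ranks are assigned before filtering).
#' @return data frame of class `screen_result` with columns `compound_id`,
#'   `predicted_pIC50`, `h`, `ad_flag` (`"Y"`/`"N"`), `rank`; attribute
#'   `"h_star"`.
#' @export
screen_compounds <- function(model, x_train, x_screen, threshold = NULL) {
  pts <- insubria_points(model, x_train, x_screen)
  res <- data.frame(compound_id = pts$compound_id,
                    predicted_pIC50 = pts$predicted_pIC50,
                    h = pts$h,
                    ad_flag = ifelse(pts$inside_ad, "Y", "N"),
                    stringsAsFactors = FALSE)
  res <- rank_screen(res)
  if (!is.null(threshold)) {
    stopifnot_scalar_number(threshold, "threshold")
    res <- res[res$predicted_pIC50 >= threshold, , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(res, h_star = attr(pts, "h_star"),
            class = c("screen_result", "data.frame"))
}

## descending predicted activity, ties by ascending compound id
rank_screen <- function(res) {
  ord <- order(-res$predicted_pIC50, res$compound_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Wrap an externally produced screening table as a screen result
#'
#' Accepts a data frame with columns `compound_id`, `predicted_pIC50` and
#' `ad_flag` (and optionally `h`), e.g. the packaged reference screening
#' predictions whose descriptor values are not available, and attaches the
#' ranking used by [top_hits()].
#'
#' @param df data frame with at least `compound_id`, `predicted_pIC50`,
#'   `ad_flag`.
#' @return a `screen_result` data frame.
#' @export
as_screen_result <- function(df) {
  need <- c("compound_id", "predicted_pIC50", "ad_flag")
  if (!all(need %in% names(df)))
    qsar_stop("arqsar_schema_error", "screen table needs columns %s",
              paste(need, collapse = ", "))
  if (!all(df$ad_flag %in% c("Y", "N")))
    qsar_stop("arqsar_schema_error", "ad_flag must be 'Y' or 'N'")
  res <- data.frame(compound_id = as.character(df$compound_id),
                    predicted_pIC50 = as.numeric(df$predicted_pIC50),
                    h = if ("h" %in% names(df)) as.numeric(df$h) else NA_real_,
                    ad_flag = as.character(df$ad_flag),
                    stringsAsFactors = FALSE)
  structure(rank_screen(res), class = c("screen_result", "data.frame"))
}

#' Top screening hits, inside and outside the applicability domain
#'
#' Returns the best-ranked compounds overall together with the best
#' compound *inside* the applicability domain — the screening deliverable:
#' an outside-AD prediction may rank higher but is an extrapolation.
#'
#' @param results a `screen_result` (from [screen_compounds()] or
#'   [as_screen_result()]).
#' @param k number of top compounds to return (default 5; capped at the
#'   table size).
#' @param activity_cutoff optional minimum predicted activity applied
#'   before selection.
#' @return list of class `top_hits`: `top` (best-k rows), `best_overall`
#'   (single row), `best_inside_ad` (single row, or `NULL` when no compound
#'   is inside the domain), `inside`, `outside` (full partitions).
#' @export
top_hits <- function(results, k = 5L, activity_cutoff = NULL) {
  if (!inherits(results, "screen_result"))
    qsar_stop("arqsar_argument_error", "`results` must be a screen_result")
  if (nrow(results) == 0L)
    qsar_stop("arqsar_argument_error", "empty screening results")
  res <- as.data.frame(results)
  if (!is.null(activity_cutoff))
    res <- res[res$predicted_pIC50 >= activity_cutoff, , drop = FALSE]
  res <- res[order(res$rank), , drop = FALSE]
  inside <- res[res$ad_flag == "Y", , drop = FALSE]
  outside <- res[res$ad_flag == "N", , drop = FALSE]
  structure(list(top = head(res, min(k, nrow(res))),
                 best_overall = head(res, 1L),
                 best_inside_ad = if (nrow(inside)) head(inside, 1L) else NULL,
                 inside = inside, outside = outside),
            class = "top_hits")
}

#' @export
print.top_hits <- function(x, ...) {
  cat("Top screening hits\n")
  if (nrow(x$best_overall))
    cat(sprintf("  best overall:   %s (predicted pIC50 %.2f, AD %s)\n",
                x$best_overall$compound_id, x$best_overall$predicted_pIC50,
                x$best_overall$ad_flag))
  if (!is.null(x$best_inside_ad))
    cat(sprintf("  best inside AD: %s (predicted pIC50 %.2f)\n",
                x$best_inside_ad$compound_id, x$best_inside_ad$predicted_pIC50))
  else cat("  no compound inside the applicability domain\n")
  print(x$top, ...)
  invisible(x)
}
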