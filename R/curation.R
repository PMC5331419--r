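## Descriptor pre-selection: remove constant and near-constant columns, then
## prune highly collinear pairs. Standard QSAR practice before any subset
## search — collinear descriptor pairs make the GA's OLS fits unstable and
## waste search effort on interchangeable columns.

curation_report <- function(removed_constant = character(),
                            removed_near_constant = character(),
                            removed_correlated = NULL,
                            kept = character()) {
  if (is.null(removed_correlated))
    removed_correlated <- data.frame(dropped = character(), partner = character(),
                                     r = numeric(), stringsAsFactors = FALSE)
  structure(list(removed_constant = removed_constant,
                 removed_near_constant = removed_near_constant,
                 removed_correlated = removed_correlated,
                 kept = kept),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Descriptor curation report\n")
  cat(sprintf("  constant removed:      %d\n", length(x$removed_constant)))
  cat(sprintf("  near-constant removed: %d\n", length(x$removed_near_constant)))
  cat(sprintf("  correlated removed:    %d\n", nrow(x$removed_correlated)))
  cat(sprintf("  kept:                  %d\n", length(x$kept)))
  invisible(x)
}

#' Remove constant and near-constant descriptors
#'
#' Drops zero-variance columns and columns whose standard deviation is a
#' negligible fraction of the largest column standard deviation. The
#' near-constant threshold is a relative sd fraction (default `1e-4`):
#' a column is near-constant when `sd(col) / max(sd)` falls below it.
#' Survivor order is the input column order.
#'
#' @param table a [descriptor_table()] (or numeric matrix with dimnames).
#' @param near_constant_sd_fraction non-negative fraction of the maximum
#'   column standard deviation below which a column counts as near-constant.
#' @return list with elements `table` (curated [descriptor_table()]) and
#'   `report` (a `curation_report`).
#' @export
remove_constant <- function(table, near_constant_sd_fraction = 1e-4) {
  table <- as_descriptor_table(table)
  stopifnot_scalar_number(near_constant_sd_fraction, "near_constant_sd_fraction")
  if (near_constant_sd_fraction < 0)
    qsar_stop("arqsar_argument_error", "`near_constant_sd_fraction` must be >= 0")
  sds <- apply(unclass(table), 2L, sd)
  constant <- sds == 0
  ref <- max(sds)
  near <- !constant & ref > 0 & (sds / ref) < near_constant_sd_fraction
  keep <- !(constant | near)
  if (!any(keep))
    qsar_stop("arqsar_empty_result_error",
              "curation removed every descriptor column")
  list(table = descriptor_table(unclass(table)[, keep, drop = FALSE]),
       report = curation_report(
         removed_constant = colnames(table)[constant],
         removed_near_constant = colnames(table)[near],
         kept = colnames(table)[keep]))
}

#' Prune highly correlated descriptor pairs
#'
#' Iteratively enforces a pairwise collinearity cap: while any surviving
#' pair has `|Pearson r| > r_cutoff`, the worst-offending pair is found and
#' the member with the larger mean absolute correlation against all other
#' surviving columns is dropped (on a tie, the later column in table order).
#' Each drop is recorded with its partner and the offending correlation.
#' Zero-variance columns are a precondition violation — run
#' [remove_constant()] first.
#'
#' @param table a [descriptor_table()] with at least two columns.
#' @param r_cutoff correlation cutoff in (0, 1]; default 0.98, the
#'   conventional QSAR pre-selection cap.
#' @return list with elements `table` (pruned [descriptor_table()]) and
#'   `report` (a `curation_report`); after pruning no surviving pair has
#'   `|r| > r_cutoff`.
#' @export
prune_correlated <- function(table, r_cutoff = 0.98) {
  table <- as_descriptor_table(table)
  stopifnot_scalar_number(r_cutoff, "r_cutoff")
  if (r_cutoff <= 0 || r_cutoff > 1)
    qsar_stop("arqsar_argument_error", "`r_cutoff` must be in (0, 1]")
  if (ncol(table) < 2L)
    qsar_stop("arqsar_argument_error", "pruning needs at least two columns")
  x <- unclass(table)
  if (any(apply(x, 2L, sd) == 0))
    qsar_stop("arqsar_zero_variance_error",
              "zero-variance column present; run remove_constant() first")
  cm <- abs(cor(x))
  diag(cm) <- 0
  order_idx <- stats::setNames(seq_len(ncol(x)), colnames(x))
  drops <- list()
  while (max(cm) > r_cutoff) {
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]  # symmetric; first hit
    pair <- sort(worst)
    # mean |r| of each pair member against all other surviving columns
    score <- rowMeans(cm[pair, , drop = FALSE]) * ncol(cm) / max(1L, ncol(cm) - 1L)
    victim <- if (abs(score[1L] - score[2L]) <= 1e-12) {
      # tie: drop the later column in original table order
      pair[which.max(order_idx[rownames(cm)[pair]])]
    } else pair[which.max(score)]
    partner <- setdiff(pair, victim)
    drops[[length(drops) + 1L]] <- data.frame(
      dropped = rownames(cm)[victim], partner = rownames(cm)[partner],
      r = sign(cor(x[, rownames(cm)[victim]], x[, rownames(cm)[partner]])) *
        cm[victim, partner],
      stringsAsFactors = FALSE)
    cm <- cm[-victim, -victim, drop = FALSE]
    if (nrow(cm) < 2L) break
  }
  kept <- rownames(cm)
  if (length(kept) == 0L)
    qsar_stop("arqsar_empty_result_error", "pruning removed every column")
  removed <- if (length(drops)) do.call(rbind, drops) else NULL
  list(table = descriptor_table(x[, kept, drop = FALSE]),
       report = curation_report(removed_correlated = removed, kept = kept))
}

as_descriptor_table <- function(x) {
  if (inherits(x, "descriptor_table")) x else descriptor_table(x)
}
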