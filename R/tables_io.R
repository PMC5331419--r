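## Data model and CSV readers for descriptor and activity tables.
##
## A descriptor table is the X of every regression in the package: a numeric
## matrix with compound ids as row names and descriptor names as column
## names, all entries finite. An activity table carries the response (pIC50,
## the negative decadic log of the molar IC50) together with the set split:
## training, external prediction set a or b, or unlabelled screening rows.

SPLIT_LEVELS <- c("train", "pred_a", "pred_b", "screen")

#' Construct a descriptor table
#'
#' A descriptor table is a numeric compounds-by-descriptors matrix with
#' unique compound ids as row names and unique descriptor names as column
#' names. All entries must be finite: missing descriptor values are a
#' validation error, never imputed, because the modelling pipeline assumes
#' complete descriptor-generator output.
#'
#' @param values numeric matrix, rows = compounds, columns = descriptors.
#' @param compound_ids character vector of unique compound ids; defaults to
#'   `rownames(values)`.
#' @param descriptor_names character vector of unique descriptor names;
#'   defaults to `colnames(values)`.
#' @return a matrix of class `descriptor_table`.
#' @examples
#' x <- descriptor_table(matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("c1", "c2", "c3"), c("IC5", "GATS5e"))))
#' @export
descriptor_table <- function(values, compound_ids = rownames(values),
                             descriptor_names = colnames(values)) {
  values <- as.matrix(values)
  if (length(values) == 0L || nrow(values) == 0L || ncol(values) == 0L)
    qsar_stop("arqsar_empty_table_error", "descriptor table is empty")
  if (!is.numeric(values))
    qsar_stop("arqsar_nonnumeric_error", "descriptor values must be numeric")
  if (is.null(compound_ids))  # programmatic matrices may omit row ids
    compound_ids <- sprintf("c%d", seq_len(nrow(values)))
  if (is.null(descriptor_names))
    qsar_stop("arqsar_argument_error", "descriptor names are required")
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  if (length(compound_ids) != nrow(values) ||
      length(descriptor_names) != ncol(values))
    qsar_stop("arqsar_shape_error",
              "id/name counts do not match the matrix shape (%d x %d)",
              nrow(values), ncol(values))
  if (anyDuplicated(compound_ids))
    qsar_stop("arqsar_duplicate_id_error", "duplicate compound ids: %s",
              paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  if (anyDuplicated(descriptor_names))
    qsar_stop("arqsar_duplicate_descriptor_error", "duplicate descriptor names: %s",
              paste(unique(descriptor_names[duplicated(descriptor_names)]), collapse = ", "))
  if (!all(is.finite(values)))
    qsar_stop("arqsar_missing_value_error",
              "descriptor table contains %d non-finite or missing entries",
              sum(!is.finite(values)))
  dimnames(values) <- list(compound_ids, descriptor_names)
  class(values) <- c("descriptor_table", class(values))
  values
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("Descriptor table: %d compounds x %d descriptors\n",
              nrow(x), ncol(x)))
  y <- unclass(x)
  print(y[seq_len(min(6L, nrow(y))), seq_len(min(6L, ncol(y))), drop = FALSE], ...)
  if (nrow(x) > 6L || ncol(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read a descriptor table from CSV
#'
#' The first column holds compound ids; the header row gives descriptor
#' names. Row and column order are preserved as in the file. Duplicate ids
#' or names, blank or non-numeric cells, and empty tables each raise a
#' distinct classed error (`arqsar_duplicate_id_error`,
#' `arqsar_duplicate_descriptor_error`, `arqsar_missing_value_error`,
#' `arqsar_nonnumeric_error`, `arqsar_empty_table_error`).
#'
#' @param path path to a CSV file with a header row.
#' @return a [descriptor_table()].
#' @export
read_descriptor_table <- function(path) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    qsar_stop("arqsar_empty_table_error",
              "'%s' holds no compounds or no descriptor columns", path)
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- !is.finite(num)
  if (any(bad)) {
    blank <- bad & (is.na(vals) | trimws(vals) == "")
    if (any(blank))
      qsar_stop("arqsar_missing_value_error",
                "'%s' has %d blank/missing descriptor cells", path, sum(blank))
    qsar_stop("arqsar_nonnumeric_error",
              "'%s' has %d non-numeric descriptor cells (e.g. '%s')",
              path, sum(bad), vals[bad][1L])
  }
  descriptor_table(num, compound_ids = ids,
                   descriptor_names = colnames(raw)[-1L])
}

#' Write a descriptor table to CSV
#'
#' @param table a [descriptor_table()].
#' @param path output file path.
#' @param id_column name for the leading id column.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path, id_column = "compound_id") {
  df <- data.frame(rownames(table), unclass(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an activity table
#'
#' Binds compound ids to pIC50 responses and set-split labels. Split labels
#' must be one of `train`, `pred_a`, `pred_b`, `screen`. Screening rows are
#' unlabelled by definition and must carry `NA` activity; every other row
#' needs a finite pIC50.
#'
#' @param compound_id character ids (case-sensitive, exact).
#' @param pIC50 numeric activities; `NA` for screen rows.
#' @param split character split labels.
#' @return a data frame of class `activity_table`.
#' @export
activity_table <- function(compound_id, pIC50, split) {
  compound_id <- as.character(compound_id)
  split <- as.character(split)
  pIC50 <- as.numeric(pIC50)
  if (length(compound_id) != length(pIC50) || length(pIC50) != length(split))
    qsar_stop("arqsar_shape_error", "activity table columns differ in length")
  if (anyDuplicated(compound_id))
    qsar_stop("arqsar_duplicate_id_error", "duplicate compound ids in activity table")
  unknown <- setdiff(unique(split), SPLIT_LEVELS)
  if (length(unknown))
    qsar_stop("arqsar_unknown_split_error", "unknown split label(s): %s",
              paste(unknown, collapse = ", "))
  labelled <- split != "screen"
  if (any(labelled & !is.finite(pIC50)))
    qsar_stop("arqsar_missing_value_error",
              "non-finite pIC50 on non-screen rows: %s",
              paste(compound_id[labelled & !is.finite(pIC50)], collapse = ", "))
  pIC50[!labelled] <- NA_real_
  structure(data.frame(compound_id = compound_id, pIC50 = pIC50, split = split,
                       stringsAsFactors = FALSE),
            class = c("activity_table", "data.frame"))
}

#' Read an activity table from CSV
#'
#' Expects columns `compound_id`, `pIC50` and `split`; the pIC50 cell may be
#' empty on `screen` rows only. Unknown split labels and unparseable or
#' missing activities on labelled rows raise classed errors.
#'
#' @param path path to a CSV file.
#' @return an [activity_table()].
#' @export
read_activity_table <- function(path) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("compound_id", "pIC50", "split")
  if (!all(need %in% names(raw)))
    qsar_stop("arqsar_schema_error", "'%s' must have columns %s", path,
              paste(need, collapse = ", "))
  txt <- trimws(raw$pIC50)
  suppressWarnings(val <- as.numeric(txt))
  unparsed <- !is.na(txt) & txt != "" & !is.finite(val)
  if (any(unparsed))
    qsar_stop("arqsar_nonnumeric_error", "unparseable pIC50 value '%s' for %s",
              txt[unparsed][1L], raw$compound_id[unparsed][1L])
  activity_table(raw$compound_id, val, raw$split)
}

#' Reference data for the dihydrotestosterone antagonist series
#'
#' Loads the packaged study data for the 7-alpha-substituted
#' dihydrotestosterone androgen-receptor antagonists: the 38-compound
#' activity table with experimental and model-predicted pIC50 and split
#' markers (29 training, 7 prediction-set-a, 2 prediction-set-b), the frozen
#' four-descriptor MLR model (IC5, GATS5e, DISPp, HATS3u), the 110 PubChem
#' screening compounds with predicted activities and applicability-domain
#' flags, and the MM/GBSA energy terms for the four simulated complexes.
#'
#' The published predicted value for training compound 7 (6.76) is
#' inconsistent with the published training statistics (R2 = 0.760,
#' RMSE = 0.226), which are only reproduced with 5.76 — a suspected
#' transcription slip in the source table. The shipped table keeps the value
#' as printed; setting `correct_compound7 = TRUE` substitutes 5.76. The
#' anomaly is also described in the `anomaly` element so it is never applied
#' silently.
#'
#' @param correct_compound7 logical; replace compound 7's predicted pIC50
#'   (6.76 as printed) with the reconstructed 5.76. Default `FALSE`.
#' @return a list of class `dht_fixture` with elements `activity` (data frame:
#'   compound_id, experimental_pIC50, predicted_pIC50, split), `model`
#'   (a [model_spec()]), `screen` (data frame: compound_id, predicted_pIC50,
#'   ad_flag), `energies` (data frame of MM/GBSA terms per complex) and
#'   `anomaly` (record of the compound-7 inconsistency).
#' @examples
#' fx <- dht_antagonists()
#' table(fx$activity$split)
#' @export
dht_antagonists <- function(correct_compound7 = FALSE) {
  ext <- function(f) system.file("extdata", f, package = "arqsar", mustWork = TRUE)
  act <- read.csv(ext("dht_activity_table.csv"), stringsAsFactors = FALSE,
                  colClasses = c(compound_id = "character"))
  if (isTRUE(correct_compound7))
    act$predicted_pIC50[act$compound_id == "7"] <- 5.76
  screen <- read.csv(ext("dht_screen_predictions.csv"), stringsAsFactors = FALSE)
  energies <- read.csv(ext("dht_gbsa_terms.csv"), stringsAsFactors = FALSE,
                       check.names = FALSE)
  structure(list(
    activity = act,
    model = read_model(ext("dht_model.json")),
    screen = screen,
    energies = energies,
    anomaly = list(
      compound_id = "7",
      printed_predicted = 6.76,
      corrected_predicted = 5.76,
      corrected = isTRUE(correct_compound7),
      note = paste("Printed predicted pIC50 for training compound 7 (6.76) is",
                   "inconsistent with the printed training R2/RMSE;",
                   "5.76 reproduces them. Correction is opt-in, never silent."))),
    class = "dht_fixture")
}

#' @export
print.dht_fixture <- function(x, ...) {
  cat("Dihydrotestosterone AR-antagonist reference data\n")
  cat(sprintf("  activity: %d compounds (%s)\n", nrow(x$activity),
              paste(sprintf("%d %s", table(x$activity$split),
                            names(table(x$activity$split))), collapse = ", ")))
  cat(sprintf("  model:    %s\n",
              paste(x$model$descriptor_names, collapse = " + ")))
  cat(sprintf("  screen:   %d compounds (%d inside AD)\n", nrow(x$screen),
              sum(x$screen$ad_flag == "Y")))
  cat(sprintf("  energies: %d complexes\n", nrow(x$energies)))
  if (x$anomaly$corrected) cat("  compound-7 prediction corrected to 5.76\n")
  invisible(x)
}
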