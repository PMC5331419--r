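## Synthetic descriptor/activity generator. Emulates the statistical shape
## of the study data — a small training set (29 compounds), a handful of
## external compounds, ~110 screening rows, a few hundred curated
## descriptors — with a planted linear signal (four true descriptors plus
## intercept and Gaussian noise), near-duplicate decoy pairs to exercise
## correlation pruning, and screening rows constructed beyond the training
## leverage cutoff. Descriptor marginals are standard Gaussians: the
## pipeline's mathematics only assumes numeric full-rank columns, not the
## heterogeneous scales of real topological/autocorrelation descriptors.

#' Specification for a synthetic QSAR dataset
#'
#' Defaults mirror the study conditions: 29 training, 7 external and 110
#' screening compounds over 358 curated descriptors, a planted
#' four-descriptor signal with coefficients of magnitude at least 0.5,
#' noise sd 0.2 pIC50 units, 5 near-duplicate descriptor pairs
#' (|r| > 0.98), 26 of the 110 screening rows outside the training leverage
#' domain, and an activity scale centred like the observed pIC50 range
#' (5–8).
#'
#' @param n_train,n_ext,n_screen compounds per split (`n_ext` rows are
#'   labelled `pred_a`).
#' @param n_descriptors descriptor columns.
#' @param true_descriptor_indices columns carrying the signal; `NULL` draws
#'   them at random under `seed`.
#' @param true_coefficients signal coefficients, one per true descriptor.
#' @param intercept signal intercept; defaults to the midpoint of
#'   `activity_range`.
#' @param noise_sd Gaussian noise sd in pIC50 units.
#' @param n_correlated_pairs near-duplicate decoy pairs with |r| > 0.98.
#' @param n_outlier_screen screening rows constructed with leverage above
#'   `3(p + 1)/n_train` in the true-descriptor design.
#' @param activity_range numeric length-2; sets the default intercept.
#' @param seed integer seed; generation is fully reproducible under it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_train = 29L, n_ext = 7L, n_screen = 110L,
                           n_descriptors = 358L,
                           true_descriptor_indices = NULL,
                           true_coefficients = c(0.6, -0.5, 0.8, -0.7),
                           intercept = mean(activity_range),
                           noise_sd = 0.2, n_correlated_pairs = 5L,
                           n_outlier_screen = 26L,
                           activity_range = c(5, 8), seed = 1L) {
  spec <- list(n_train = as.integer(n_train), n_ext = as.integer(n_ext),
               n_screen = as.integer(n_screen),
               n_descriptors = as.integer(n_descriptors),
               true_descriptor_indices = true_descriptor_indices,
               true_coefficients = as.numeric(true_coefficients),
               intercept = as.numeric(intercept),
               noise_sd = as.numeric(noise_sd),
               n_correlated_pairs = as.integer(n_correlated_pairs),
               n_outlier_screen = as.integer(n_outlier_screen),
               activity_range = as.numeric(activity_range),
               seed = as.integer(seed))
  k <- length(spec$true_coefficients)
  if (spec$n_train < k + 3L)
    qsar_stop("arqsar_argument_error", "n_train too small for %d true descriptors", k)
  if (spec$noise_sd < 0)
    qsar_stop("arqsar_argument_error", "noise_sd must be >= 0")
  if (!is.null(spec$true_descriptor_indices)) {
    spec$true_descriptor_indices <- as.integer(spec$true_descriptor_indices)
    if (length(spec$true_descriptor_indices) != k)
      qsar_stop("arqsar_argument_error",
                "need one true index per coefficient (%d vs %d)",
                length(spec$true_descriptor_indices), k)
    if (anyDuplicated(spec$true_descriptor_indices) ||
        any(spec$true_descriptor_indices < 1L) ||
        any(spec$true_descriptor_indices > spec$n_descriptors))
      qsar_stop("arqsar_argument_error", "true descriptor indices out of bounds")
  }
  if (k + 2L * spec$n_correlated_pairs > spec$n_descriptors)
    qsar_stop("arqsar_argument_error",
              "not enough columns for %d correlated pairs besides %d true descriptors",
              spec$n_correlated_pairs, k)
  if (spec$n_outlier_screen > spec$n_screen)
    qsar_stop("arqsar_argument_error", "more outliers than screening rows")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic descriptor/activity dataset
#'
#' Draws the descriptor matrix, plants the linear signal
#' `y = intercept + sum(beta * x_true) + N(0, noise_sd)` for the labelled
#' rows, overwrites the requested decoy pairs with near-duplicates
#' (partner = column + N(0, 0.05), giving |r| well above 0.98), assigns
#' split labels, and replaces the requested number of screening rows with
#' leverage outliers built by [generate_screen_outliers()]. The ground
#' truth (indices, coefficients, pair layout) is returned alongside so
#' recovery tests never re-derive it.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `descriptors` (a [descriptor_table()] over all rows),
#'   `activity` (an [activity_table()]; screening rows have `NA` pIC50) and
#'   `ground_truth` (list: `indices`, `names`, `coefficients`, `intercept`,
#'   `noise_sd`, `correlated_pairs` data frame, `outlier_ids`, `seed`).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  k <- length(spec$true_coefficients)
  m <- spec$n_descriptors
  n_all <- spec$n_train + spec$n_ext + spec$n_screen
  true_idx <- spec$true_descriptor_indices %||% sort(sample.int(m, k))

  x <- matrix(rnorm(n_all * m), n_all, m)
  colnames(x) <- sprintf("D%03d", seq_len(m))
  rownames(x) <- c(sprintf("T%02d", seq_len(spec$n_train)),
                   if (spec$n_ext) sprintf("E%02d", seq_len(spec$n_ext)),
                   if (spec$n_screen) sprintf("S%03d", seq_len(spec$n_screen)))

  # near-duplicate decoy pairs among the non-signal columns
  pairs <- NULL
  if (spec$n_correlated_pairs > 0L) {
    decoys <- setdiff(seq_len(m), true_idx)
    picked <- sample(decoys, 2L * spec$n_correlated_pairs)
    a <- picked[seq_len(spec$n_correlated_pairs)]
    b <- picked[spec$n_correlated_pairs + seq_len(spec$n_correlated_pairs)]
    for (j in seq_along(a))
      x[, b[j]] <- x[, a[j]] + rnorm(n_all, sd = 0.05)
    pairs <- data.frame(column = colnames(x)[a], duplicate = colnames(x)[b],
                        stringsAsFactors = FALSE)
  }

  labelled <- seq_len(spec$n_train + spec$n_ext)
  y <- rep(NA_real_, n_all)
  y[labelled] <- spec$intercept +
    x[labelled, true_idx, drop = FALSE] %*% spec$true_coefficients +
    rnorm(length(labelled), sd = spec$noise_sd)

  outlier_ids <- character(0)
  if (spec$n_screen > 0L) {
    train_rows <- x[seq_len(spec$n_train), true_idx, drop = FALSE]
    h_star <- leverage_cutoff(k, spec$n_train)
    screen_rows <- spec$n_train + spec$n_ext + seq_len(spec$n_screen)
    slots <- integer(0)
    if (spec$n_outlier_screen > 0L) {
      out <- generate_screen_outliers(train_rows, spec$n_outlier_screen,
                                      h_star = h_star)
      slots <- spec$n_train + spec$n_ext +
        sample.int(spec$n_screen, spec$n_outlier_screen)
      x[slots, true_idx] <- out
      outlier_ids <- rownames(x)[slots]
    }
    # the remaining screen rows are inside the domain by construction:
    # resample any that land beyond h* in the signal columns
    inside <- setdiff(screen_rows, slots)
    for (i in inside) {
      ok <- FALSE
      for (try in seq_len(100L)) {
        if (leverages(train_rows, x[i, true_idx, drop = FALSE]) <= h_star) {
          ok <- TRUE
          break
        }
        x[i, true_idx] <- rnorm(k)
      }
      if (!ok)
        qsar_stop("arqsar_outlier_budget_error",
                  "could not place screen row %s inside h* = %.3f",
                  rownames(x)[i], h_star)
    }
  }

  split <- c(rep("train", spec$n_train), rep("pred_a", spec$n_ext),
             rep("screen", spec$n_screen))
  list(descriptors = descriptor_table(x),
       activity = activity_table(rownames(x), y, split),
       ground_truth = list(indices = true_idx, names = colnames(x)[true_idx],
                           coefficients = spec$true_coefficients,
                           intercept = spec$intercept, noise_sd = spec$noise_sd,
                           correlated_pairs = pairs, outlier_ids = outlier_ids,
                           seed = spec$seed))
}

#' Construct screening rows outside the training leverage domain
#'
#' Builds `n` descriptor rows whose leverage against the given training
#' design (intercept-augmented) exceeds `h* = 3(p + 1)/n_train`: each row
#' is the training centroid plus a random direction scaled outward, with
#' the scale doubled until the leverage clears the cutoff. Every returned
#' row is verified; failure to reach the target within the iteration
#' budget is an error.
#'
#' @param x_train numeric training matrix (rows x model descriptors).
#' @param n number of outlier rows (0 returns an empty matrix).
#' @param h_star leverage cutoff to exceed; defaults to
#'   `leverage_cutoff(ncol(x_train), nrow(x_train))`.
#' @param max_doublings scale-doubling budget per row.
#' @return numeric matrix with `n` rows and the training columns.
#' @export
generate_screen_outliers <- function(x_train, n,
                                     h_star = leverage_cutoff(ncol(x_train),
                                                              nrow(x_train)),
                                     max_doublings = 40L) {
  x_train <- as.matrix(unclass(x_train))
  n <- as.integer(n)
  p <- ncol(x_train)
  if (n == 0L)
    return(matrix(numeric(0), 0L, p, dimnames = list(NULL, colnames(x_train))))
  centroid <- colMeans(x_train)
  spread <- apply(x_train, 2L, sd)
  out <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(x_train)))
  for (i in seq_len(n)) {
    dir <- rnorm(p)
    dir <- dir / sqrt(sum(dir^2))
    scale <- 2
    for (try in seq_len(max_doublings)) {
      row <- centroid + scale * spread * dir
      if (leverages(x_train, matrix(row, 1L)) > h_star) break
      scale <- scale * 2
      row <- NULL
    }
    if (is.null(row))
      qsar_stop("arqsar_outlier_budget_error",
                "could not push row %d beyond h* = %.3f", i, h_star)
    out[i, ] <- row
  }
  stopifnot(all(leverages(x_train, out) > h_star))  # contract: verified
  out
}
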