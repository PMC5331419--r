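## Genetic-algorithm descriptor-subset selection scored by ordinary least
## squares and the Friedman lack-of-fit (LOF) statistic,
##
##   LOF = SSE / (1 - (c + d p) / n)^2,
##
## where SSE is the training sum of squared errors, p the number of
## descriptors in the model, c the number of basis functions (p + 1 with the
## intercept), d a smoothness factor (default 0.5) and n the training-set
## size. Lower is better; the denominator penalizes model size so the search
## does not simply grow SSE down.

#' Fit an MLR model on a fixed descriptor subset
#'
#' Ordinary least squares with an always-included intercept, via base R's QR
#' path. Requires `n > p + 1` and a full-column-rank design; a rank-deficient
#' design (e.g. a duplicated descriptor column) raises
#' `arqsar_singular_fit_error`.
#'
#' @param x numeric matrix of the chosen descriptor columns (n x p), with
#'   column names.
#' @param y numeric response (pIC50), length n.
#' @return list of class `fit_result`: `model` (a [model_spec()]), `sse`,
#'   `residuals`, `fitted`, `n`, `c` (basis functions, p + 1), `p_terms`.
#' @examples
#' x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("d1", "d2")))
#' y <- 1 + x[, 1] - 2 * x[, 2] + rnorm(20, sd = 0.1)
#' fit_ols(x, y)$model
#' @export
fit_ols <- function(x, y) {
  x <- as.matrix(unclass(x))
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n)
    qsar_stop("arqsar_shape_error", "x has %d rows but y has %d values", n, length(y))
  if (n <= p + 1L)
    qsar_stop("arqsar_precondition_error",
              "need n > p + 1 observations (n = %d, p = %d)", n, p)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(p))
  design <- cbind(`(Intercept)` = 1, x)
  fit <- .lm.fit(design, y)
  if (fit$rank < ncol(design))
    qsar_stop("arqsar_singular_fit_error",
              "design matrix is rank deficient (rank %d < %d)",
              fit$rank, ncol(design))
  beta <- fit$coefficients
  res <- as.numeric(fit$residuals)
  ids <- rownames(x)
  if (!is.null(ids)) names(res) <- ids
  structure(list(
    model = model_spec(colnames(x), beta[-1L], beta[1L], n_train = n),
    sse = sum(res^2),
    residuals = res,
    fitted = as.numeric(y - res),
    n = n, c = p + 1L, p_terms = p), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  print(x$model, ...)
  cat(sprintf("  SSE = %.6g on n = %d (p = %d)\n", x$sse, x$n, x$p_terms))
  invisible(x)
}

#' Friedman lack-of-fit statistic
#'
#' `LOF = SSE / (1 - (c + d*p)/n)^2`. Strictly increasing in `SSE`, and in
#' `p` at fixed `SSE`, so it trades training error against model size.
#' Degenerate when `c + d*p >= n` (penalty denominator zero or negative).
#'
#' @param sse training sum of squared errors (>= 0).
#' @param c number of basis functions; `p + 1` for an MLR with intercept.
#' @param d smoothness factor, conventionally 0.5.
#' @param p number of descriptors in the model.
#' @param n number of training samples.
#' @return the LOF value (lower is better).
#' @examples
#' friedman_lof(2, c = 5, d = 0.5, p = 4, n = 29)  # 2 / (22/29)^2
#' @export
friedman_lof <- function(sse, c, d, p, n) {
  stopifnot_scalar_number(sse, "sse")
  for (nm in c("c", "d", "p", "n"))
    stopifnot_scalar_number(get(nm), nm)
  if (sse < 0) qsar_stop("arqsar_argument_error", "`sse` must be >= 0")
  if (n <= 0) qsar_stop("arqsar_argument_error", "`n` must be positive")
  pen <- 1 - (c + d * p) / n
  if (pen <= 0)
    qsar_stop("arqsar_degenerate_penalty_error",
              "c + d*p = %.3g >= n = %d: LOF penalty is degenerate", c + d * p, n)
  sse / pen^2
}

#' Genetic-algorithm search configuration
#'
#' Defaults follow common genetic-function-approximation practice for QSAR
#' subset selection: population 200, at most 10000 generations, per-gene
#' mutation probability 0.05, smoothness factor 0.5, with early stopping
#' after `stagnation_patience` generations without improvement of the best
#' LOF. Selection is binary tournament; crossover samples the child subset
#' uniformly from the union of the parents' genes (so duplicate genes cannot
#' arise); elitism carries the best chromosomes over unchanged.
#'
#' @param population_size chromosomes per generation (>= 2).
#' @param max_generations hard generation cap.
#' @param mutation_probability per-gene probability of replacing a
#'   descriptor index with a random unused one.
#' @param model_size descriptors per chromosome (fixed subset size).
#' @param smoothing_d Friedman LOF smoothness factor `d`.
#' @param seed integer seed; all GA randomness flows from it.
#' @param elitism_count chromosomes copied unchanged into each generation.
#' @param crossover_probability probability a child is produced by crossover
#'   rather than cloning the first parent.
#' @param stagnation_patience generations without best-LOF improvement
#'   before the search stops early.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 200L, max_generations = 10000L,
                      mutation_probability = 0.05, model_size = 4L,
                      smoothing_d = 0.5, seed = 1L, elitism_count = 2L,
                      crossover_probability = 0.9,
                      stagnation_patience = 500L) {
  cfg <- list(population_size = as.integer(population_size),
              max_generations = as.integer(max_generations),
              mutation_probability = mutation_probability,
              model_size = as.integer(model_size),
              smoothing_d = smoothing_d,
              seed = as.integer(seed),
              elitism_count = as.integer(elitism_count),
              crossover_probability = crossover_probability,
              stagnation_patience = as.integer(stagnation_patience))
  if (cfg$population_size < 2L)
    qsar_stop("arqsar_argument_error", "population_size must be >= 2")
  if (cfg$model_size < 1L)
    qsar_stop("arqsar_argument_error", "model_size must be >= 1")
  if (cfg$mutation_probability < 0 || cfg$mutation_probability > 1 ||
      cfg$crossover_probability < 0 || cfg$crossover_probability > 1)
    qsar_stop("arqsar_argument_error", "probabilities must be in [0, 1]")
  if (cfg$max_generations < 0L || cfg$stagnation_patience < 0L)
    qsar_stop("arqsar_argument_error", "generation counts must be >= 0")
  if (cfg$elitism_count < 0L || cfg$elitism_count >= cfg$population_size)
    qsar_stop("arqsar_argument_error", "elitism_count must be in [0, population_size)")
  structure(cfg, class = "ga_config")
}

## LOF of one chromosome, memoized: populations converge, so most
## evaluations after the first few hundred generations are cache hits.
## Singular subsets score +Inf rather than aborting the search.
ga_fitness_fn <- function(x, y, cfg) {
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  n <- nrow(x)
  function(idx) {
    key <- paste(idx, collapse = ".")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- tryCatch({
      fit <- .lm.fit(cbind(1, x[, idx, drop = FALSE]), y)
      if (fit$rank < length(idx) + 1L) Inf
      else friedman_lof(sum(fit$residuals^2), c = length(idx) + 1L,
                        d = cfg$smoothing_d, p = length(idx), n = n)
    }, arqsar_error = function(e) Inf)
    cache[[key]] <- val
    val
  }
}

#' Genetic-algorithm descriptor-subset search
#'
#' Searches fixed-size descriptor subsets of a curated table for the model
#' minimizing the Friedman LOF of its OLS fit. Reproducible for a given
#' seed; the best LOF is non-increasing over generations (elitism). Stops at
#' `max_generations` or once the best LOF has not improved for
#' `stagnation_patience` consecutive generations.
#'
#' @param table a [descriptor_table()] (curated: no constant columns).
#' @param y numeric activities aligned to the table rows.
#' @param config a [ga_config()].
#' @return list of class `ga_result`: `models`, a list of the final
#'   population's distinct chromosomes sorted by ascending LOF, each with
#'   elements `indices`, `descriptors`, `lof`, `fit` (a `fit_result`);
#'   `best_lof_history`, the per-generation best LOF; `generations` run;
#'   `config` echo.
#' @examples
#' x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("d", 1:10)))
#' y <- 2 + x[, 3] - x[, 7] + rnorm(20, 0.05)
#' res <- run_ga(descriptor_table(x), y,
#'               ga_config(population_size = 30, max_generations = 50,
#'                         model_size = 2, stagnation_patience = 20, seed = 7))
#' res$models[[1]]$descriptors
#' @export
run_ga <- function(table, y, config = ga_config()) {
  table <- as_descriptor_table(table)
  if (!inherits(config, "ga_config")) config <- do.call(ga_config, config)
  x <- unclass(table)
  y <- as.numeric(y)
  m <- ncol(x); k <- config$model_size
  if (k > m)
    qsar_stop("arqsar_argument_error",
              "model_size = %d exceeds the %d available descriptors", k, m)
  if (nrow(x) <= k + 1L)
    qsar_stop("arqsar_precondition_error",
              "need more than model_size + 1 training rows")
  fitness <- ga_fitness_fn(x, y, config)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  pop_size <- config$population_size
  new_chrom <- function() sort(sample.int(m, k))
  pop <- replicate(pop_size, new_chrom(), simplify = FALSE)
  fit_vals <- vapply(pop, fitness, numeric(1L))

  mutate <- function(idx) {
    hit <- runif(k) < config$mutation_probability
    if (any(hit)) {
      free <- setdiff(seq_len(m), idx)
      for (g in which(hit)) {
        if (!length(free)) break
        pick <- free[sample.int(length(free), 1L)]
        free <- c(free[free != pick], idx[g])
        idx[g] <- pick
      }
      idx <- sort(idx)
    }
    idx
  }
  tournament <- function() {
    a <- sample.int(pop_size, 2L)
    if (fit_vals[a[1L]] <= fit_vals[a[2L]]) a[1L] else a[2L]
  }

  best_hist <- numeric(0L)
  best <- min(fit_vals)
  stagnant <- 0L
  gen <- 0L
  while (gen < config$max_generations) {
    gen <- gen + 1L
    elite_idx <- order(fit_vals)[seq_len(config$elitism_count)]
    children <- vector("list", pop_size)
    children[seq_along(elite_idx)] <- pop[elite_idx]
    for (i in seq.int(length(elite_idx) + 1L, pop_size)) {
      p1 <- pop[[tournament()]]
      child <- if (runif(1L) < config$crossover_probability) {
        p2 <- pop[[tournament()]]
        pool <- union(p1, p2)
        sort(pool[sample.int(length(pool), k)])
      } else p1
      children[[i]] <- mutate(child)
    }
    pop <- children
    fit_vals <- vapply(pop, fitness, numeric(1L))
    gen_best <- min(fit_vals)
    if (gen_best < best - 1e-12) {
      best <- gen_best
      stagnant <- 0L
    } else stagnant <- stagnant + 1L
    best_hist[gen] <- best
    if (config$stagnation_patience > 0L && stagnant >= config$stagnation_patience)
      break
  }

  keys <- vapply(pop, paste, character(1L), collapse = ".")
  uniq <- !duplicated(keys)
  ord <- order(fit_vals[uniq])
  models <- lapply(which(uniq)[ord], function(i) {
    idx <- pop[[i]]
    fit <- if (is.finite(fit_vals[i])) fit_ols(x[, idx, drop = FALSE], y) else NULL
    list(indices = idx, descriptors = colnames(x)[idx],
         lof = fit_vals[i], fit = fit)
  })
  structure(list(models = models, best_lof_history = best_hist,
                 generations = gen, config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA-MLR search: %d generations, %d distinct final models\n",
              x$generations, length(x$models)))
  top <- head(x$models, 5L)
  for (i in seq_along(top))
    cat(sprintf("  %d. LOF %.5g  [%s]\n", i, top[[i]]$lof,
                paste(top[[i]]$descriptors, collapse = ", ")))
  invisible(x)
}
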