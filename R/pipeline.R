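## End-to-end orchestration: simulate (or load) -> curate -> GA-MLR fit ->
## validate -> applicability domain -> screen, writing every stage artefact
## plus a manifest. Reports are deterministic for a given config and seed:
## no timestamps are written, so a rerun is byte-identical.

PIPELINE_KEYS <- c("seed", "n_train", "n_ext", "n_screen", "n_descriptors",
                   "noise_sd", "n_correlated_pairs", "n_outlier_screen",
                   "near_constant_sd_fraction", "r_cutoff", "model_size",
                   "population_size", "max_generations", "mutation_probability",
                   "stagnation_patience", "lmo_fraction", "lmo_iterations",
                   "scramble_iterations", "descriptor_csv", "activity_csv",
                   "verbose")

#' Pipeline configuration
#'
#' A flat list of stage parameters; unknown keys are rejected so a typo
#' never silently falls back to a default. By default the pipeline runs on
#' a synthetic dataset drawn under `seed` (see [synthetic_spec()] for the
#' data-shape defaults); supplying `descriptor_csv`/`activity_csv` runs the
#' same stages on files instead. The effective config is echoed into every
#' report and into the manifest.
#'
#' @param ... key = value pairs overriding the defaults; see
#'   `arqsar:::PIPELINE_KEYS` for the accepted keys.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(seed = 1L, n_train = 29L, n_ext = 7L, n_screen = 110L,
              n_descriptors = 358L, noise_sd = 0.2, n_correlated_pairs = 5L,
              n_outlier_screen = 26L, near_constant_sd_fraction = 1e-4,
              r_cutoff = 0.98, model_size = 4L, population_size = 200L,
              max_generations = 10000L, mutation_probability = 0.05,
              stagnation_patience = 500L, lmo_fraction = 0.3,
              lmo_iterations = 1000L, scramble_iterations = 5000L,
              descriptor_csv = NULL, activity_csv = NULL, verbose = TRUE)
  override <- list(...)
  if (length(override) && (is.null(names(override)) || any(names(override) == "")))
    qsar_stop("arqsar_config_error", "all config entries must be named")
  unknown <- setdiff(names(override), PIPELINE_KEYS)
  if (length(unknown))
    qsar_stop("arqsar_config_error", "unknown config key(s): %s",
              paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  structure(cfg, class = "pipeline_config")
}

#' Run the full QSAR pipeline
#'
#' Executes curation, GA-MLR model selection, validation, applicability-
#' domain analysis and virtual screening in order, writing each stage's
#' artefact (CSV/JSON) under `out_dir` and a `manifest.json` listing them
#' together with the effective config and the package version. Stage
#' failures are re-signalled with the stage name attached
#' (`arqsar_pipeline_error`).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `status` (0 on success), `manifest`,
#'   and the in-memory stage results (`data`, `curation`, `fit`, `metrics`,
#'   `ad`, `screen`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("arqsar_run_")) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage, fmt, ...) {
    if (isTRUE(config$verbose))
      message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                          class = c("arqsar_pipeline_error", "arqsar_error", "error")))
    })
  }
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }

  ## -- data: simulate, or load the supplied tables ------------------------
  data <- stage("simulate", {
    if (!is.null(config$descriptor_csv)) {
      list(descriptors = read_descriptor_table(config$descriptor_csv),
           activity = read_activity_table(config$activity_csv),
           ground_truth = NULL)
    } else {
      generate_synthetic(synthetic_spec(
        n_train = config$n_train, n_ext = config$n_ext,
        n_screen = config$n_screen, n_descriptors = config$n_descriptors,
        noise_sd = config$noise_sd,
        n_correlated_pairs = config$n_correlated_pairs,
        n_outlier_screen = config$n_outlier_screen, seed = config$seed))
    }
  })
  act <- data$activity
  log_msg("simulate", "%d compounds x %d descriptors",
          nrow(data$descriptors), ncol(data$descriptors))
  if (!is.null(data$ground_truth))
    emit("ground_truth.json", function(p)
      jsonlite::write_json(data$ground_truth, p, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null"))

  ## -- curation ------------------------------------------------------------
  curated <- stage("curate", {
    step1 <- remove_constant(data$descriptors, config$near_constant_sd_fraction)
    step2 <- prune_correlated(step1$table, config$r_cutoff)
    list(table = step2$table,
         report = list(constant = step1$report, correlated = step2$report))
  })
  log_msg("curate", "%d -> %d descriptors",
          ncol(data$descriptors), ncol(curated$table))
  emit("curated_descriptors.csv", function(p) write_descriptor_table(curated$table, p))
  emit("curation_report.json", function(p)
    jsonlite::write_json(
      list(config = config[c("near_constant_sd_fraction", "r_cutoff", "seed")],
           removed_constant = curated$report$constant$removed_constant,
           removed_near_constant = curated$report$constant$removed_near_constant,
           removed_correlated = curated$report$correlated$removed_correlated,
           kept = curated$report$correlated$kept),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE))

  ## -- GA-MLR fit ----------------------------------------------------------
  train_ids <- act$compound_id[act$split == "train"]
  x_all <- unclass(curated$table)
  fit <- stage("fit", {
    qsar_gamlr(x_all[train_ids, , drop = FALSE],
               act$pIC50[act$split == "train"],
               model_size = config$model_size,
               config = ga_config(population_size = config$population_size,
                                  max_generations = config$max_generations,
                                  mutation_probability = config$mutation_probability,
                                  model_size = config$model_size,
                                  stagnation_patience = config$stagnation_patience,
                                  seed = config$seed))
  })
  log_msg("fit", "best model [%s], LOF %.4g, %d generations",
          paste(fit$model$descriptor_names, collapse = ", "), fit$lof,
          fit$search$generations)
  emit("model.json", function(p) write_model(fit$model, p))
  emit("ranked_models.json", function(p)
    jsonlite::write_json(lapply(head(fit$search$models, 10L), function(mod)
      list(descriptors = mod$descriptors, lof = mod$lof)),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE))

  ## -- validation ----------------------------------------------------------
  ext_ids <- act$compound_id[act$split %in% c("pred_a", "pred_b")]
  metrics <- stage("validate", {
    summary(fit,
            x_ext = if (length(ext_ids)) x_all[ext_ids, , drop = FALSE],
            y_ext = if (length(ext_ids)) act$pIC50[match(ext_ids, act$compound_id)],
            lmo_fraction = config$lmo_fraction,
            lmo_iterations = config$lmo_iterations,
            scramble_iterations = config$scramble_iterations,
            seed = config$seed)$metrics
  })
  log_msg("validate", "R2 %.3f, Q2loo %.3f", metrics$r2, metrics$q2_loo)
  emit("metrics.json", function(p)
    jsonlite::write_json(c(list(seed = config$seed), unclass(metrics)), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"))

  ## -- applicability domain ------------------------------------------------
  model_cols <- fit$model$descriptor_names
  screen_ids <- act$compound_id[act$split == "screen"]
  ad <- stage("ad", {
    wp <- williams_points(fit$model, x_all[train_ids, model_cols, drop = FALSE],
                          act$pIC50[act$split == "train"],
                          x_ext = if (length(ext_ids)) x_all[ext_ids, model_cols, drop = FALSE],
                          y_ext = if (length(ext_ids)) act$pIC50[match(ext_ids, act$compound_id)])
    ip <- insubria_points(fit$model, x_all[train_ids, model_cols, drop = FALSE],
                          x_all[screen_ids, model_cols, drop = FALSE])
    list(williams = wp, insubria = ip)
  })
  log_msg("ad", "h* = %.3f", ad$williams$h_star)
  emit("williams.csv", function(p) write.csv(ad$williams$points, p, row.names = FALSE))
  emit("insubria.csv", function(p) write.csv(ad$insubria, p, row.names = FALSE))

  ## -- virtual screening ---------------------------------------------------
  screen <- stage("screen", {
    if (length(screen_ids) == 0L) NULL
    else screen_compounds(fit$model, x_all[train_ids, model_cols, drop = FALSE],
                          x_all[screen_ids, model_cols, drop = FALSE])
  })
  if (!is.null(screen)) {
    log_msg("screen", "%d compounds, %d inside AD", nrow(screen),
            sum(screen$ad_flag == "Y"))
    emit("screen_results.csv", function(p)
      write.csv(as.data.frame(screen), p, row.names = FALSE))
  }

  ## -- manifest ------------------------------------------------------------
  manifest <- list(package = "arqsar",
                   version = as.character(utils::packageVersion("arqsar")),
                   seed = config$seed,
                   config = config[setdiff(PIPELINE_KEYS, c("descriptor_csv", "activity_csv"))],
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(list(status = 0L, out_dir = out_dir, manifest = manifest,
                 data = data, curation = curated$report, fit = fit,
                 metrics = metrics, ad = ad, screen = screen))
}
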