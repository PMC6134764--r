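pipeline_known_keys <- c("input", "gate", "chunk_size", "clubbing",
                         "split", "autoencoder", "models", "seed",
                         "log_level")

#' Pipeline configuration
#'
#' A validated configuration for the end-to-end run: simulate or ingest
#' -> gate -> vectorize -> label/club -> split -> autoencoder anomaly
#' screen -> model comparison -> reports. Unknown keys anywhere in the
#' configuration are errors, which guards against silently misspelled
#' hyperparameter names.
#'
#' @param input Either `list(mode = "synthetic", design = <study_design>,
#'   format = "csv")` or `list(mode = "manifest", manifest = <path>)`.
#' @param gate `NULL` (no-op) or arguments for [gate_config()].
#' @param chunk_size Events per fingerprint vector.
#' @param clubbing `NULL` (keep perturbation labels), `TRUE` (use
#'   [default_clubbing_map()]), or a named map.
#' @param split `list(train_fraction =, group_by_replicate =)`.
#' @param autoencoder `NULL` to skip the anomaly screen, or
#'   [autoencoder_config()] arguments plus `threshold` (numeric, or
#'   `NULL` for the training-quantile policy), `quantile` and
#'   `aggregate`.
#' @param models Named list, one entry per algorithm (`GB`, `NB`, `DRF`,
#'   `DL`): hyperparameter overrides, optionally with a `grid` element to
#'   trigger a nested-CV grid search for that algorithm.
#' @param seed Top-level seed; every stage draws a named sub-seed from it.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input, gate = NULL, chunk_size = 1000,
                            clubbing = NULL,
                            split = list(train_fraction = 0.75,
                                         group_by_replicate = FALSE),
                            autoencoder = list(),
                            models = list(GB = list(), NB = list(),
                                          DRF = list(), DL = list()),
                            seed = 1, log_level = "info") {
  cfg <- list(input = input, gate = gate, chunk_size = chunk_size,
              clubbing = clubbing, split = split,
              autoencoder = autoencoder, models = models,
              seed = as.integer(seed), log_level = log_level)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), pipeline_known_keys)
  assert_that(length(unknown) == 0,
              sprintf("Unknown configuration key(s): %s",
                      paste(unknown, collapse = ", ")),
              class = "cytofp_config_error")
  assert_that(cfg$chunk_size >= 1, "`chunk_size` must be >= 1.",
              class = "cytofp_config_error")
  bad_in <- setdiff(names(cfg$input),
                    c("mode", "design", "manifest", "format"))
  assert_that(length(bad_in) == 0,
              sprintf("Unknown input option(s): %s",
                      paste(bad_in, collapse = ", ")),
              class = "cytofp_config_error")
  mode <- cfg$input$mode %||% ""
  assert_that(mode %in% c("synthetic", "manifest"),
              "input$mode must be 'synthetic' or 'manifest'.",
              class = "cytofp_config_error")
  if (mode == "manifest") {
    assert_that(file.exists(cfg$input$manifest %||% ""),
                sprintf("Manifest '%s' does not exist.",
                        cfg$input$manifest %||% "<missing>"),
                class = "cytofp_config_error")
  } else {
    assert_that(inherits(cfg$input$design, "study_design"),
                "input$design must be a study_design.",
                class = "cytofp_config_error")
  }
  for (alg in names(cfg$models)) {
    assert_that(alg %in% c("GB", "NB", "DRF", "DL"),
                sprintf("Unknown algorithm '%s' in models.", alg),
                class = "cytofp_config_error")
    hp <- cfg$models[[alg]]
    known_hp <- c(names(default_hyperparameters(alg)), "grid")
    bad <- setdiff(names(hp), known_hp)
    assert_that(length(bad) == 0,
                sprintf("Unknown hyperparameter(s) for %s: %s", alg,
                        paste(bad, collapse = ", ")),
                class = "cytofp_config_error")
  }
  if (!is.null(cfg$autoencoder)) {
    known_ae <- c(names(formals(autoencoder_config)), "threshold",
                  "quantile", "aggregate")
    bad <- setdiff(names(cfg$autoencoder), known_ae)
    assert_that(length(bad) == 0,
                sprintf("Unknown autoencoder option(s): %s",
                        paste(bad, collapse = ", ")),
                class = "cytofp_config_error")
  }
  invisible(TRUE)
}

#' Run the end-to-end pipeline
#'
#' Executes every configured stage under `out_dir` and writes the
#' resolved configuration, the fingerprint datasets, the anomaly report,
#' the per-model accuracy/AUC/confusion/ROC/probability/importance
#' reports and a machine-readable stage log. A completed run directory,
#' with its resolved config and seeds, fully determines all numeric
#' outputs: re-running reproduces them byte for byte. A failing stage
#' aborts with the stage name; partial outputs stay on disk next to a
#' `FAILED` marker naming the stage.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Run directory. Defaults to a timestamped directory
#'   under the session temporary directory.
#' @return `out_dir`, invisibly, with the key result objects attached as
#'   attribute `results`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- out_dir %||%
    file.path(tempdir(), format(Sys.time(), "cytofp-run-%Y%m%d-%H%M%S"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_rows <- list()
  log_stage <- function(stage, message, n_in = NA, n_out = NA) {
    log_rows[[length(log_rows) + 1]] <<- tibble(
      stage = stage, message = message, n_in = n_in, n_out = n_out)
    if (identical(cfg$log_level, "info")) {
      message(sprintf("[%s] %s", stage, message))
    }
  }
  flush_log <- function() {
    readr::write_csv(bind_rows(log_rows), file.path(out_dir, "run_log.csv"))
  }
  stage <- "configure"
  results <- list()
  tryCatch({
    writeLines(yaml::as.yaml(resolve_config(cfg)),
               file.path(out_dir, "resolved_config.yaml"))

    stage <- "ingest"
    if (cfg$input$mode == "synthetic") {
      data_dir <- file.path(out_dir, "data")
      manifest_path <- simulate_study(cfg$input$design, data_dir,
                                      format = cfg$input$format %||% "csv")
      log_stage(stage, sprintf("simulated study into %s/",
                               basename(data_dir)))
    } else {
      manifest_path <- cfg$input$manifest
    }
    manifest <- read_manifest(manifest_path)
    log_stage(stage, sprintf("%d samples in manifest", nrow(manifest)),
              n_out = nrow(manifest))

    stage <- "vectorize"
    gate <- if (is.null(cfg$gate)) gate_config() else
      do.call(gate_config, cfg$gate)
    ds <- fingerprint_dataset(manifest, gate = gate,
                              chunk_size = cfg$chunk_size,
                              seed = derive_seed(cfg$seed, "vectorize"))
    log_stage(stage, sprintf("%d fingerprint vectors of length %d",
                             nrow(ds), 3 * cfg$chunk_size),
              n_in = nrow(manifest), n_out = nrow(ds))

    stage <- "club"
    if (!is.null(cfg$clubbing)) {
      map <- if (isTRUE(cfg$clubbing)) default_clubbing_map() else
        unlist(cfg$clubbing)
      ds <- club_labels(ds, map)
      log_stage(stage, sprintf("labels clubbed to: %s",
                               paste(sort(unique(ds$label)), collapse = ", ")),
                n_in = nrow(ds), n_out = nrow(ds))
    }

    stage <- "split"
    parts <- split_train_test(
      ds, train_fraction = cfg$split$train_fraction %||% 0.75,
      seed = derive_seed(cfg$seed, "split"),
      group_by_replicate = isTRUE(cfg$split$group_by_replicate))
    write_fingerprints(parts$train, file.path(out_dir, "train.csv"))
    write_fingerprints(parts$test, file.path(out_dir, "test.csv"))
    log_stage(stage, sprintf("train %d / test %d", nrow(parts$train),
                             nrow(parts$test)),
              n_in = nrow(ds), n_out = nrow(parts$train))

    if (!is.null(cfg$autoencoder)) {
      stage <- "anomaly"
      ae_opts <- cfg$autoencoder
      thr <- ae_opts$threshold
      q <- ae_opts$quantile %||% 0.95
      aggregate <- ae_opts$aggregate %||% "mean"
      ae_opts[c("threshold", "quantile", "aggregate")] <- NULL
      ae_opts$seed <- ae_opts$seed %||% derive_seed(cfg$seed, "autoencoder")
      ae_cfg <- do.call(autoencoder_config, ae_opts)
      ae <- train_autoencoder(parts$train, ae_cfg)
      if (is.null(thr)) {
        thr <- training_threshold(ae, parts$train, q = q,
                                  aggregate = aggregate)
      }
      report <- score_samples(ae, ds, threshold = thr,
                              aggregate = aggregate)
      write_anomaly_report(report, file.path(out_dir, "anomaly_report.csv"))
      results$anomaly <- report
      log_stage(stage, sprintf("threshold %.4g, %d outlier(s)", thr,
                               sum(report$per_sample$is_outlier)),
                n_in = nrow(ds), n_out = nrow(report$per_sample))
    }

    stage <- "models"
    models <- list()
    for (alg in names(cfg$models)) {
      hp <- cfg$models[[alg]]
      seed_alg <- derive_seed(cfg$seed, "model", alg)
      if (!is.null(hp$grid)) {
        grid <- hp$grid
        hp$grid <- NULL
        sel <- nested_cv_grid_search(alg, grid, parts$train,
                                     seed = seed_alg)
        readr::write_csv(tidy(sel$cv),
                         file.path(out_dir, sprintf("cv_%s.csv", alg)))
        spec <- sel$best_spec
        log_stage(stage, sprintf(
          "%s: nested CV mean accuracy %.4f (sd %.4f)", alg, sel$cv$mean,
          sel$cv$sd))
      } else {
        spec <- model_spec(alg, hp, seed = seed_alg)
      }
      models[[alg]] <- train_classifier(spec, parts$train)
      log_stage(stage, sprintf("%s trained on %d vectors", alg,
                               nrow(parts$train)),
                n_in = nrow(parts$train))
    }
    results$models <- models

    stage <- "evaluate"
    acc <- accuracy_table(models, parts$test)
    readr::write_csv(acc, file.path(out_dir, "accuracy_table.csv"))
    aucs <- auc_table(models, parts$test)
    readr::write_csv(aucs, file.path(out_dir, "auc_table.csv"))
    for (alg in names(models)) {
      pred <- predict_class(models[[alg]], parts$test)
      cm <- confusion_matrix(pred, parts$test$label)
      readr::write_csv(as_tibble(as.data.frame.matrix(cm), rownames = "truth"),
                       file.path(out_dir, sprintf("confusion_%s.csv", alg)))
      readr::write_csv(roc_points(models[[alg]], parts$test),
                       file.path(out_dir, sprintf("roc_points_%s.csv", alg)))
      readr::write_csv(
        class_probability_summary(predict_proba(models[[alg]], parts$test),
                                  parts$test$label),
        file.path(out_dir, sprintf("class_probabilities_%s.csv", alg)))
    }
    if ("DL" %in% names(models)) {
      imp <- gedeon_importance(models$DL)
      readr::write_csv(imp$per_block,
                       file.path(out_dir, "importance_DL.csv"))
      results$importance <- imp
    }
    results$accuracy_table <- acc
    results$auc_table <- aucs
    log_stage(stage, sprintf("reports written for %s",
                             paste(names(models), collapse = ", ")),
              n_in = nrow(parts$test))
    flush_log()
  }, error = function(e) {
    writeLines(sprintf("stage: %s\n%s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    flush_log()
    abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "cytofp_stage_error", parent = e)
  })
  invisible(structure(out_dir, results = results))
}

# serializable view of the configuration (study designs flattened)
resolve_config <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$input$design)) {
    d <- out$input$design
    out$input$design <- list(
      seed = d$seed, replicates = d$replicates, timepoints = d$timepoints,
      events_per_sample = d$events_per_sample,
      classes = lapply(d$classes, function(cl) {
        list(label = cl$class_label,
             drift_per_day = cl$drift_per_day,
             components = lapply(cl$components, function(co) {
               list(weight = co$weight, mean = co$mean, sd = co$sd)
             }))
      }))
  }
  out
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]; a synthetic-input design is
#' given under `input.design` with `classes` as a list of
#' `{label, drift_per_day, components: [{weight, mean, sd}]}` entries.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (identical(raw$input$mode, "synthetic") &&
      !inherits(raw$input$design, "study_design")) {
    d <- raw$input$design
    classes <- lapply(d$classes, function(cl) {
      class_distribution(cl$label, lapply(cl$components, function(co) {
        list(weight = co$weight, mean = as.numeric(co$mean),
             sd = as.numeric(co$sd))
      }), drift_per_day = as.numeric(cl$drift_per_day %||% c(0, 0, 0)))
    })
    raw$input$design <- study_design(
      classes, replicates = d$replicates %||% 3,
      timepoints = d$timepoints %||% 5,
      events_per_sample = d$events_per_sample %||% 100000,
      seed = d$seed %||% 1)
  }
  do.call(pipeline_config, raw)
}
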