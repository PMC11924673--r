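# End-to-end orchestration: simulate -> extract -> gate -> select ->
# model -> longitudinal, with full provenance (config echo, seeds,
# per-stage timings) written to a run directory.

stage_log <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %-12s %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full texture-analysis pipeline on synthetic cohorts
#'
#' Executes the configured stages in order and writes every intermediate
#' artifact (cohort manifests, feature tables, gate report, selection
#' record, model metrics, longitudinal fit) plus a config echo and a
#' timing log into `outdir`. Reruns with the same config are
#' reproducible.
#'
#' Stage summary: `simulate` draws the reader-study cases, the
#' cross-sectional cohort, and the longitudinal cohort; `extract`
#' computes feature tables; `gate` applies the ICC/CV reproducibility
#' filter; `select` runs split/balance, Boruta, LASSO, clustering and
#' VIF; `model` fits per-feature logistic models with cross-validation,
#' evaluates them on the held-out cohort, ranks them by AIC, and derives
#' the decision-stump threshold for the best feature; `longitudinal`
#' fits the random-intercept logistic mixed model for the best feature.
#'
#' @param config a [pipeline_config()]
#' @param outdir run directory (created if missing)
#' @param stages subset of c("simulate", "extract", "gate", "select",
#'   "model", "longitudinal"); earlier stages are implied
#' @param verbose log progress to stderr
#' @return invisibly, a list with all stage results
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run_"),
                         stages = c("simulate", "extract", "gate", "select",
                                    "model", "longitudinal"),
                         verbose = TRUE) {
  all_stages <- c("simulate", "extract", "gate", "select", "model",
                  "longitudinal")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stages: %s", paste(bad, collapse = ", "))
  last <- max(match(stages, all_stages))
  stages <- all_stages[seq_len(last)]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- if (verbose) file.path(outdir, "pipeline.log") else NULL
  say <- function(stage, fmt, ...) {
    if (verbose) stage_log(log_path, stage, sprintf(fmt, ...))
  }
  echo <- config
  echo$synthetic <- unclass(echo$synthetic)
  jsonlite::write_json(unclass(echo), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- list(config = config, outdir = outdir)
  timing <- list()
  tic <- function() proc.time()[["elapsed"]]

  # --- simulate -------------------------------------------------------------
  t0 <- tic()
  scfg <- config$synthetic
  gate_cfg <- scfg
  gate_cfg$n_pos <- ceiling(config$n_gate_cases / 2)
  gate_cfg$n_neg <- config$n_gate_cases - gate_cfg$n_pos
  gate_cases <- generate_cohort(gate_cfg, seed = config$seed + 11L)
  gate_variants <- lapply(seq_along(gate_cases), function(i) {
    generate_reader_variants(gate_cases[[i]], n_readers = 2L, n_repeats = 2L,
                             jitter_px = config$jitter_px,
                             seed = config$seed + 100L + i)
  })
  cohort <- generate_cohort(scfg, seed = config$seed + 12L)
  longit <- generate_longitudinal_cohort(scfg,
                                         n_patients = config$glmm_patients,
                                         n_years = config$glmm_years,
                                         effect_size = config$glmm_effect,
                                         seed = config$seed + 13L)
  write_cohort_manifest(cohort, file.path(outdir, "cohort_manifest.csv"))
  write_cohort_manifest(longit, file.path(outdir, "longitudinal_manifest.csv"))
  res$cohort <- cohort
  res$longitudinal_cases <- longit
  timing$simulate <- tic() - t0
  say("simulate", "%d gate + %d cohort + %d longitudinal cases (%.1f s)",
      length(gate_cases), length(cohort), length(longit), timing$simulate)
  if (!"extract" %in% stages) return(invisible(res))

  # --- extract --------------------------------------------------------------
  t0 <- tic()
  variant_key <- c("r1p1", "r1p2", "r2p1", "r2p2")
  gate_tables <- lapply(seq_along(variant_key), function(vi) {
    tab <- extract_cohort(lapply(seq_along(gate_cases), function(i) {
      cs <- gate_cases[[i]]
      cs$contours <- gate_variants[[i]][[vi]]
      cs
    }), config)
    tab
  })
  names(gate_tables) <- variant_key
  features <- extract_cohort(cohort, config)
  write_feature_table(features, file.path(outdir, "features.csv"))
  write_catalog_manifest(file.path(outdir, "feature_catalog.json"),
                         config$filters)
  res$gate_tables <- gate_tables
  res$features <- features
  timing$extract <- tic() - t0
  say("extract", "%d features x %d cases (%.1f s)",
      length(feature_columns(features)), nrow(features), timing$extract)
  if (!"gate" %in% stages) return(invisible(res))

  # --- gate -----------------------------------------------------------------
  t0 <- tic()
  gate <- reproducibility_gate(gate_tables,
                               icc_threshold = config$icc_threshold,
                               cv_threshold = config$cv_threshold)
  utils::write.csv(gate, file.path(outdir, "gate_report.csv"),
                   row.names = FALSE)
  gated <- gate$feature[gate$passed]
  res$gate <- gate
  res$gated_features <- gated
  timing$gate <- tic() - t0
  say("gate", "%d of %d features reproducible (%.1f s)", length(gated),
      nrow(gate), timing$gate)
  if (!"select" %in% stages) return(invisible(res))

  # --- select ---------------------------------------------------------------
  t0 <- tic()
  if (!length(gated)) stopf("select: no feature passed the gate")
  sel <- select_features(features, gated, config)
  sel_json <- sel
  sel_json$clusters <- as.list(sel_json$clusters)
  jsonlite::write_json(unclass(sel_json), file.path(outdir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$selection <- sel
  timing$select <- tic() - t0
  say("select", "boruta %d, lasso %d, union %d, independent %d (%.1f s)",
      length(sel$boruta_selected), length(sel$lasso_selected),
      length(sel$union), length(sel$independent), timing$select)
  if (!"model" %in% stages) return(invisible(res))

  # --- model ----------------------------------------------------------------
  t0 <- tic()
  if (!length(sel$independent)) stopf("model: no independent feature selected")
  train <- features[features$case_id %in% sel$train_ids, ]
  test <- features[features$case_id %in% sel$test_ids, ]
  metrics <- list()
  cvs <- list()
  for (f in sel$independent) {
    z <- zscore_train_test(train[[f]], test[[f]])
    cvs[[f]] <- cross_validate(z$train, train$lge_status,
                               folds = min(config$cv_folds,
                                           min(table(train$lge_status))),
                               seed = config$seed + 21L)
    metrics[[f]] <- evaluate_model(cvs[[f]]$final_fit, z$test,
                                   test$lge_status)
  }
  ranking <- rank_models(metrics)
  best <- ranking[1]
  zb <- zscore_train_test(train[[best]], test[[best]])
  stump <- stump_threshold(train[[best]], train$lge_status)
  stump_pred <- stump$predict(test[[best]])
  stump_m <- evaluate_confusion(tp = sum(stump_pred == 1 & test$lge_status == 1),
                                fp = sum(stump_pred == 1 & test$lge_status == 0),
                                fn = sum(stump_pred == 0 & test$lge_status == 1),
                                tn = sum(stump_pred == 0 & test$lge_status == 0))
  model_rec <- list(ranking = ranking, best_feature = best,
                    metrics = lapply(metrics, unclass),
                    cv_accuracy = lapply(cvs, function(cv) {
                      list(mean = cv$mean_accuracy, sd = cv$sd_accuracy)
                    }),
                    stump = list(feature = best,
                                 threshold = stump$threshold,
                                 upper_class = stump$upper_class,
                                 test_metrics = stump_m))
  jsonlite::write_json(model_rec, file.path(outdir, "model_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$metrics <- metrics
  res$ranking <- ranking
  res$best_feature <- best
  res$stump <- model_rec$stump
  timing$model <- tic() - t0
  say("model", "best by AIC: %s (accuracy %.3f) (%.1f s)", best,
      metrics[[best]]$accuracy, timing$model)
  if (!"longitudinal" %in% stages) return(invisible(res))

  # --- longitudinal ---------------------------------------------------------
  t0 <- tic()
  lfeat <- extract_cohort(longit, config)
  records <- data.frame(patient_id = lfeat$patient_id,
                        exam_year = lfeat$exam_year,
                        feature_value = lfeat[[best]],
                        lge_status = lfeat$lge_status)
  utils::write.csv(records, file.path(outdir, "longitudinal_records.csv"),
                   row.names = FALSE)
  glmm <- fit_glmm_logistic(records)
  report <- longitudinal_report(glmm, best)
  write_longitudinal_report(report, file.path(outdir, "longitudinal_fit.json"))
  res$glmm <- glmm
  res$longitudinal_report <- report
  timing$longitudinal <- tic() - t0
  say("longitudinal", "%s: estimate %s, p = %.3g (%.1f s)", best,
      report$estimate_label, report$p, timing$longitudinal)

  res$timing <- timing
  jsonlite::write_json(timing, file.path(outdir, "timings.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
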