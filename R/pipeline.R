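#' Experiment configuration for the end-to-end pipeline
#'
#' Bundles every stage's parameters with the reference defaults: 4096-point
#' Blackman STFT with hop 2048 (2049 one-sided features), optional PSO or
#' harmony-search wrapper selection on the feature axis, an SVM-RBF
#' classifier (`C = 1`, `sigma = 100`), class targets 0.85/0.65, and
#' stratified 10-fold cross-validation. Selection is off by default (the
#' no-feature-selection branch); set `selection_method` to `"pso"` or
#' `"hs"` to enable it.
#'
#' @param window a [window_spec()].
#' @param aggregate frame aggregation for [spectral_features()].
#' @param selection_method `"none"`, `"pso"` or `"hs"`.
#' @param subset_size number of spectral features kept by selection.
#' @param selection_params extra arguments for [pso_config()]/[hs_config()].
#' @param classifier classifier kind for [train_classifier()].
#' @param classifier_params extra arguments for the classifier fit.
#' @param cv_scheme `"kfold"` or `"split"` (single stratified 85/15 split).
#' @param k folds for `"kfold"` (default 10).
#' @param train_fraction training fraction for `"split"` (default 0.85).
#' @param t_adeno,t_meso class target values.
#' @param seed master seed; every stage derives its randomness from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(window = window_spec(), aggregate = "mean",
                              selection_method = c("none", "pso", "hs"),
                              subset_size = 30L, selection_params = list(),
                              classifier = "svm-rbf",
                              classifier_params = list(),
                              cv_scheme = c("kfold", "split"), k = 10L,
                              train_fraction = 0.85,
                              t_adeno = 0.85, t_meso = 0.65, seed = 1L) {
  cfg <- list(window = window, aggregate = aggregate,
              selection_method = match.arg(selection_method),
              subset_size = as.integer(subset_size),
              selection_params = selection_params,
              classifier = classifier, classifier_params = classifier_params,
              cv_scheme = match.arg(cv_scheme), k = as.integer(k),
              train_fraction = train_fraction,
              t_adeno = t_adeno, t_meso = t_meso, seed = as.integer(seed))
  class(cfg) <- "experiment_config"
  cfg
}

.stage_error <- function(stage, fold, e) {
  stop(sprintf("pipeline stage '%s'%s failed: %s", stage,
               if (is.null(fold)) "" else sprintf(" (fold %d)", fold),
               conditionMessage(e)), call. = FALSE)
}

#' Run the full extract / select / classify / evaluate experiment
#'
#' Executes the pipeline on an expression matrix: STFT feature extraction,
#' optional wrapper feature selection (on the feature axis, using the whole
#' cohort, as a preprocessing step), then stratified cross-validation of
#' the configured classifier. Within each fold, features are min-max
#' scaled to the unit interval using the training fold's ranges; training
#' and testing MSE (predicted-class target vs true-class target) are
#' recorded per fold, per-fold confusion matrices are summed
#' (micro-averaging) and the metric suite is computed on the pooled matrix.
#'
#' @param data an [expression_matrix()].
#' @param config an [experiment_config()].
#' @return An `experiment_report` list: the echoed config, selection result
#'   (if any), per-fold records, pooled confusion matrix and pooled
#'   metrics.
#' @export
run_experiment <- function(data, config = experiment_config()) {
  stopifnot(inherits(data, "ExpressionMatrix"))
  targets <- .default_targets()
  targets$t_adeno <- config$t_adeno
  targets$t_meso <- config$t_meso

  feats <- tryCatch(spectral_features(data, config$window, config$aggregate),
                    error = function(e) .stage_error("extract", NULL, e))
  y <- feats$labels
  selection <- NULL
  keep <- seq_len(nrow(feats$values))
  if (config$selection_method != "none") {
    selection <- tryCatch({
      if (config$selection_method == "pso") {
        sel_cfg <- do.call(pso_config, c(list(subset_size = config$subset_size,
                                              seed = config$seed),
                                         config$selection_params))
        pso_select(feats, config = sel_cfg, axis = "rows")
      } else {
        sel_cfg <- do.call(hs_config, c(list(subset_size = config$subset_size,
                                             seed = config$seed),
                                        config$selection_params))
        hs_select(feats, config = sel_cfg, axis = "rows")
      }
    }, error = function(e) .stage_error("select", NULL, e))
    keep <- selection$selected_indices
  }
  X <- t(feats$values[keep, , drop = FALSE])

  folds <- if (config$cv_scheme == "kfold") {
    kfold_plan(y, k = config$k, stratified = TRUE, seed = config$seed)
  } else {
    ifelse(.split_plan(y, config$train_fraction, seed = config$seed), 1L, 0L)
  }
  fold_ids <- sort(unique(folds[folds > 0L]))

  pooled <- list(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
  class(pooled) <- "confusion_matrix"
  fold_records <- vector("list", length(fold_ids))
  for (fi in seq_along(fold_ids)) {
    f <- fold_ids[fi]
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    rec <- tryCatch({
      x_train <- scale_unit(X[train_idx, , drop = FALSE])
      x_test <- scale_unit(X[test_idx, , drop = FALSE],
                           reference = X[train_idx, , drop = FALSE])
      y_train <- y[train_idx]
      model <- train_classifier(config$classifier, x_train, y_train,
                                config$classifier_params)
      pred_train <- classifier_predict(model, x_train)
      pred_test <- classifier_predict(model, x_test)
      cm <- confusion(y[test_idx], pred_test)
      list(fold = f,
           train_mse = mse(.label_targets(pred_train, targets),
                           .label_targets(.as_binary_factor(y_train), targets)),
           test_mse = mse(.label_targets(pred_test, targets),
                          .label_targets(factor(y[test_idx],
                                                levels = levels(y)), targets)),
           confusion = unclass(cm)[c("tp", "fn", "fp", "tn")],
           metrics = unclass(metrics(cm))[c("accuracy", "precision", "recall",
                                            "f1", "mcc", "error_rate",
                                            "kappa", "degenerate")])
    }, error = function(e) .stage_error("classify", f, e))
    pooled <- .cm_add(pooled, rec$confusion)
    fold_records[[fi]] <- rec
  }

  report <- list(
    config = list(
      window = unclass(config$window), aggregate = config$aggregate,
      selection_method = config$selection_method,
      subset_size = if (config$selection_method == "none") NULL else config$subset_size,
      classifier = config$classifier,
      classifier_params = config$classifier_params,
      cv_scheme = config$cv_scheme, k = config$k,
      train_fraction = config$train_fraction,
      t_adeno = config$t_adeno, t_meso = config$t_meso, seed = config$seed),
    n_subjects = ncol(data$values), n_genes = nrow(data$values),
    n_features = nrow(feats$values),
    note = if (config$selection_method == "none") "no feature selection" else NULL,
    selection = if (!is.null(selection)) {
      list(method = selection$method,
           selected_indices = selection$selected_indices,
           best_fitness = selection$best_fitness,
           fitness_trace = selection$fitness_trace)
    },
    folds = fold_records,
    pooled_confusion = unclass(pooled)[c("tp", "fn", "fp", "tn")],
    pooled_metrics = unclass(metrics(pooled))[c("accuracy", "precision",
                                                "recall", "f1", "mcc",
                                                "error_rate", "kappa",
                                                "degenerate")])
  class(report) <- "experiment_report"
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment: %s classifier, %s, %s\n", x$config$classifier,
              if (x$config$cv_scheme == "kfold") {
                sprintf("%d-fold CV", x$config$k)
              } else "single 85/15 split",
              if (is.null(x$selection)) "no feature selection" else {
                sprintf("%s selection (%d features)", toupper(x$selection$method),
                        length(x$selection$selected_indices))
              }))
  cm <- x$pooled_confusion
  cat(sprintf("Pooled confusion: TP=%d FN=%d FP=%d TN=%d\n",
              cm$tp, cm$fn, cm$fp, cm$tn))
  m <- x$pooled_metrics
  cat(sprintf(paste0("Pooled: accuracy %.5f%%, precision %.5f%%, recall %.5f%%, ",
                     "F1 %.5f%%\n        MCC %.5f, error rate %.5f%%, kappa %.5f\n"),
              m$accuracy, m$precision, m$recall, m$f1, m$mcc, m$error_rate,
              m$kappa))
  invisible(x)
}

#' Serialize an experiment report (or any pipeline artifact) as JSON
#'
#' Deterministic: identical reports produce byte-identical files.
#'
#' @param x a report or artifact list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' One-call reproducible run: simulate, extract, select, train, evaluate
#'
#' Generates (or loads) an expression matrix, runs [run_experiment()], fits
#' a final model on the full scaled cohort, and writes four artifacts to
#' `out_dir`: `features.tsv` (spectral features in the matrix-with-label-row
#' dialect), `selection.json`, `model.json` and `report.json`. The echoed
#' configuration inside `report.json` is sufficient to reproduce the run.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if missing).
#' @param synth a [synth_config()] used to generate the cohort, or `NULL`
#'   together with `data`.
#' @param data an existing [expression_matrix()]; overrides `synth`.
#' @return The `experiment_report`, invisibly, with paths attached.
#' @export
run_all <- function(config = experiment_config(), out_dir = ".",
                    synth = synth_config(), data = NULL) {
  if (is.null(data)) data <- generate_dataset(synth)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  feats <- spectral_features(data, config$window, config$aggregate)
  features_path <- file.path(out_dir, "features.tsv")
  write_matrix(expression_matrix(feats$values, feats$labels), features_path)

  report <- run_experiment(data, config)

  selection_path <- file.path(out_dir, "selection.json")
  write_report(if (is.null(report$selection)) {
    list(method = "none", note = "no feature selection")
  } else report$selection, selection_path)

  keep <- if (is.null(report$selection)) {
    seq_len(nrow(feats$values))
  } else report$selection$selected_indices
  X <- scale_unit(t(feats$values[keep, , drop = FALSE]))
  model <- train_classifier(config$classifier, X, feats$labels,
                            config$classifier_params)
  model_path <- file.path(out_dir, "model.json")
  write_report(.serialize_model(model), model_path)

  report_path <- file.path(out_dir, "report.json")
  write_report(report, report_path)

  attr(report, "paths") <- c(features = features_path,
                             selection = selection_path, model = model_path,
                             report = report_path)
  invisible(report)
}

# flatten a fitted model into JSON-serializable parameter lists
.serialize_model <- function(model) {
  kind <- attr(model, "kind")
  out <- lapply(unclass(model), function(el) {
    if (is.matrix(el)) {
      apply(el, 1L, as.numeric, simplify = FALSE)
    } else if (is.list(el)) {
      lapply(el, function(e2) if (is.matrix(e2)) {
        apply(e2, 1L, as.numeric, simplify = FALSE)
      } else e2)
    } else el
  })
  c(list(kind = kind), out)
}
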