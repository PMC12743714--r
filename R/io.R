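#' Write a case table to CSV
#'
#' One row per case; the identifier and label columns come first, then the
#' cohort fields and feature columns. Missing values are written as empty
#' cells. The writer is deterministic: identical datasets produce
#' byte-identical files.
#'
#' @param dataset a [pu_dataset()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_case_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "pu_dataset"))
  utils::write.csv(dataset$cases, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a case table from CSV
#'
#' Requires at least the `case_id` and `s` columns; an absent `y` column
#' (real data) yields an unknown latent class for every case. Empty cells
#' are read as missing values.
#'
#' @param path CSV path.
#' @param feature_cols feature column names; when `NULL`, every column not
#'   among the known identifier/label/cohort columns is treated as a
#'   feature.
#' @return A [pu_dataset()].
#' @export
load_case_table <- function(path, feature_cols = NULL) {
  cases <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = "")
  mandatory <- c("case_id", "s")
  absent <- setdiff(mandatory, names(cases))
  if (length(absent)) {
    stop("case table schema error, missing columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!"y" %in% names(cases)) cases$y <- NA_integer_
  if (is.null(feature_cols)) {
    known <- c("case_id", "s", "y", "explicit_flag", "implicit_flag",
               "age_band", "length_of_stay_days", "has_main_diagnosis",
               "has_drg")
    feature_cols <- setdiff(names(cases), known)
  }
  pu_dataset(cases, feature_cols = feature_cols)
}

#' Write a prediction set to CSV
#'
#' @param predictions named probabilities.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(data.frame(case_id = names(predictions),
                              probability = as.numeric(predictions)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Default experiment configuration
#'
#' Assembles a complete pipeline configuration: generator, preprocessing
#' (noise fractions and undersampling), both learners, evaluation and
#' validity settings. All child seeds derive from the single master seed.
#'
#' @param n_cases generator size.
#' @param master_seed master seed for the whole run.
#' @param spy_n_repeats step-1 repeats for the spy learner.
#' @param ada_ensemble_size ensemble size for the adaptive learner.
#' @param n_folds cross-validation folds.
#' @param n_unlabeled unlabeled cases retained by undersampling (`NULL`
#'   keeps all).
#' @param ... further overrides merged into the configuration list.
#' @return A nested list of class `"experiment_config"`.
#' @export
experiment_config <- function(n_cases = 5000L, master_seed = 1L,
                              spy_n_repeats = 100L,
                              ada_ensemble_size = 20L,
                              n_folds = 5L, n_unlabeled = NULL, ...) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    generator = list(n_cases = as.integer(n_cases), class_prior = 0.2,
                     label_frequency = 0.5, propensity_mode = "SCAR"),
    preprocessing = list(noise_fractions = NULL,
                         n_unlabeled = n_unlabeled),
    spy = list(spy_fraction = 0.10, n_repeats = as.integer(spy_n_repeats),
               step1_classifier = "logistic",
               step2_classifier = "naive_bayes"),
    ada = list(n_iterations = 5L,
               ensemble_size = as.integer(ada_ensemble_size),
               base_classifier = "svm_radial"),
    evaluation = list(n_folds = as.integer(n_folds), ks = c(10, 20, 30),
                      scenarios = evaluation_scenarios()),
    validity = list(frame = "from-generator", ks = c(5, 10, 15, 20, 25, 30))
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from YAML/JSON
#'
#' @param path YAML (or JSON) file with the sections of
#'   [experiment_config()].
#' @return An `"experiment_config"`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- experiment_config()
  for (nm in names(raw)) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

#' Run the full PU pipeline
#'
#' Executes generate, filter, undersample, cross-validate, fit both PU
#' learners out-of-fold, evaluate across coding scenarios, and run the
#' external validity check. All artifacts are persisted under `out_dir`:
#' the case table, per-model prediction sets, metrics and validity
#' reports, CDF curves, the filter report, and a manifest with the
#' configuration, seeds and a checksum of every output file. Identical
#' configurations produce byte-identical artifacts.
#'
#' Per fold, min-max feature bounds are fitted on the training partition
#' only and applied unclipped to the held-out fold; the spy learner's
#' classification threshold is its step-2 training label mean, the
#' adaptive learner's the PU training label mean.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if absent).
#' @param models character subset of `c("spy", "ada")`.
#' @return A list with the in-memory reports (`metrics`, `validity`,
#'   `cdf`, `filter_report`, `manifest`), invisibly the artifacts on disk.
#' @export
run_experiment <- function(config = experiment_config(), out_dir,
                           models = c("spy", "ada")) {
  models <- match.arg(models, several.ok = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$master_seed

  initial <- stage("generate", {
    gen_args <- config$generator
    gen_args$seed <- child_seed(seed, 1L)
    dataset <- generate_pu_dataset(do.call(generator_config, gen_args))
    nf <- config$preprocessing$noise_fractions
    if (!is.null(nf) && any(unlist(nf) > 0)) {
      dataset <- inject_cohort_noise(dataset, unlist(nf),
                                     seed = child_seed(seed, 2L))$dataset
    }
    dataset
  })

  filtered <- stage("filter", apply_cohort_filters(initial))
  learning <- stage("undersample", {
    n_unl <- config$preprocessing$n_unlabeled
    if (is.null(n_unl)) filtered$dataset
    else undersample(filtered$dataset, n_unl, seed = child_seed(seed, 3L))
  })

  fold <- make_cv_folds(learning, config$evaluation$n_folds,
                        seed = child_seed(seed, 4L))
  fits <- stage("cross-validate", {
    cv_fit_models(learning, fold, config, models, seed)
  })

  results <- list(filter_report = filtered$report, datasets = list(
    initial = initial, learning = learning), fold = fold)
  frame <- if (identical(config$validity$frame, "from-generator")) {
    population_frame_from_datasets(filtered$dataset, learning)
  } else {
    do.call(population_frame, config$validity$frame)
  }

  write_case_table(learning, file.path(out_dir, "dataset.csv"))
  jsonlite::write_json(
    list(n_input = filtered$report$n_input,
         n_excluded = as.list(filtered$report$n_excluded),
         n_output = filtered$report$n_output),
    file.path(out_dir, "filter_report.json"), auto_unbox = TRUE)

  for (model in models) {
    preds <- fits[[model]]$predictions
    thresholds <- fits[[model]]$thresholds
    metrics <- evaluate_all(preds, learning, fold, thresholds,
                            scenarios = config$evaluation$scenarios,
                            ks = config$evaluation$ks)
    validity <- validity_report(preds, learning, frame,
                                class_label_mean_threshold = mean(thresholds),
                                ks = config$validity$ks, fold = fold)
    cdf <- prediction_cdf(preds, stats::setNames(
      ifelse(learning$cases$s == 1L, "labeled", "unlabeled"),
      learning$cases$case_id))
    write_predictions(preds, file.path(out_dir,
                                       sprintf("predictions_%s.csv", model)))
    utils::write.csv(metrics, file.path(out_dir,
                                        sprintf("metrics_%s.csv", model)),
                     row.names = FALSE)
    utils::write.csv(validity, file.path(out_dir,
                                         sprintf("validity_%s.csv", model)),
                     row.names = FALSE)
    utils::write.csv(cdf, file.path(out_dir, sprintf("cdf_%s.csv", model)),
                     row.names = FALSE)
    results[[model]] <- list(predictions = preds, thresholds = thresholds,
                             metrics = metrics, validity = validity,
                             cdf = cdf)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("puadmin")),
    master_seed = seed,
    config = unclass(config),
    files = as.list(tools::md5sum(sort(setdiff(
      list.files(out_dir, full.names = TRUE),
      file.path(out_dir, "manifest.json")))))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

# out-of-fold fitting of the requested learners; per-fold min-max bounds
# are fitted on the training partition only
cv_fit_models <- function(learning, fold, config, models, seed) {
  n_folds <- max(fold)
  ids <- learning$cases$case_id
  out <- list()
  for (model in models) {
    out[[model]] <- list(
      predictions = stats::setNames(rep(NA_real_, length(ids)), ids),
      thresholds = numeric(n_folds))
  }
  for (f in seq_len(n_folds)) {
    test_idx <- fold[ids] == f
    train <- subset_cases(learning, !test_idx)
    test <- subset_cases(learning, test_idx)
    bounds <- minmax_fit(train$cases[, learning$feature_cols, drop = FALSE])
    train_n <- normalized_copy(train, bounds)
    test_n <- normalized_copy(test, bounds)
    if ("spy" %in% models) {
      cfg <- spy_config(
        spy_fraction = config$spy$spy_fraction,
        n_repeats = config$spy$n_repeats,
        step1_classifier = as_classifier(config$spy$step1_classifier),
        step2_classifier = as_classifier(config$spy$step2_classifier),
        seed = child_seed(seed, 100L + f))
      fit <- spy_fit(train_n, cfg)
      out$spy$predictions[test$cases$case_id] <- spy_predict(fit, test_n)
      out$spy$thresholds[f] <- fit$step2_train_label_mean
    }
    if ("ada" %in% models) {
      cfg <- ada_config(
        n_iterations = config$ada$n_iterations,
        ensemble_size = config$ada$ensemble_size,
        base_classifier = as_classifier(config$ada$base_classifier),
        seed = child_seed(seed, 200L + f))
      fit <- ada_fit(train_n, cfg)
      out$ada$predictions[test$cases$case_id] <- ada_predict(fit, test_n)
      out$ada$thresholds[f] <- fit$train_label_mean
    }
  }
  out
}

as_classifier <- function(x) {
  if (inherits(x, "classifier_spec")) x else classifier_spec(x)
}

normalized_copy <- function(dataset, bounds) {
  norm <- minmax_apply(bounds, dataset$cases[, dataset$feature_cols,
                                             drop = FALSE])
  dataset$cases[, dataset$feature_cols] <- norm
  dataset
}
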