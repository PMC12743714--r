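#' Configuration for the adaptive-resampling PU ensemble
#'
#' The adaptive-resampling learner starts from the putative labeling
#' (labeled cases positive, unlabeled cases negative) and iteratively
#' estimates each case's probability of being mislabeled: in every
#' iteration a training set is resampled from the data — each putative
#' class at its original size, with replacement, with inclusion
#' probability proportional to one minus the current mislabel probability,
#' so that likely-mislabeled cases are progressively excluded — the base
#' classifier is refitted, and the mislabel probability is updated to the
#' predicted probability of the class opposite to the putative label.
#' Cases that look mislabeled (unlabeled latent positives above all) are
#' thereby pushed out of the training sets while the class sizes stay
#' stable. The final model is an ensemble fitted on independent
#' low-mislabel resamples; its prediction is the unweighted mean of the
#' member probabilities.
#'
#' @param n_iterations adaptive iterations (default 5, with early stopping
#'   once the largest mislabel-probability change falls below `tol`).
#' @param ensemble_size number of final ensemble members (default 20).
#' @param base_classifier a [classifier_spec()]; default is the
#'   radial-kernel SVM, intended for min-max normalized features.
#' @param resample_mode `"weighted_subsample"` (exclusion resampling, the
#'   default) or `"weighted_fit"` (per-observation weights `1 - mislabel`;
#'   only for base classifiers accepting case weights, i.e. `"logistic"`).
#' @param tol early-stopping tolerance on the mislabel-probability update.
#' @param seed master seed.
#' @return An object of class `"ada_config"`.
#' @export
ada_config <- function(n_iterations = 5L, ensemble_size = 20L,
                       base_classifier = classifier_spec("svm_radial"),
                       resample_mode = c("weighted_subsample", "weighted_fit"),
                       tol = 1e-3, seed = 1L) {
  resample_mode <- match.arg(resample_mode)
  stopifnot(n_iterations >= 1, ensemble_size >= 1,
            inherits(base_classifier, "classifier_spec"))
  if (resample_mode == "weighted_fit" && base_classifier$name != "logistic") {
    stop("weighted_fit requires a base classifier with per-observation ",
         "weights (use \"logistic\")", call. = FALSE)
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 ensemble_size = as.integer(ensemble_size),
                 base_classifier = base_classifier,
                 resample_mode = resample_mode,
                 tol = tol, seed = as.integer(seed)),
            class = "ada_config")
}

#' Fit the adaptive-resampling PU ensemble
#'
#' @param train a [pu_dataset()] with labeled positives and unlabeled
#'   cases. Features should be on comparable scales (min-max normalized)
#'   when the base classifier is distance-based.
#' @param config an [ada_config()].
#' @return An object of class `"ada_fit"` with the ensemble members, the
#'   final per-case mislabel probabilities, and the training-set label mean
#'   (used downstream as classification threshold).
#' @export
ada_fit <- function(train, config = ada_config()) {
  stopifnot(inherits(train, "pu_dataset"), inherits(config, "ada_config"))
  cases <- train$cases
  if ("no labeled positives" %in% train$flags || sum(cases$s) == 0L) {
    stop("dataset has no labeled positives; the adaptive learner needs them",
         call. = FALSE)
  }
  if (all(cases$s == 1L)) {
    stop("training data contain no unlabeled cases", call. = FALSE)
  }
  x <- feature_matrix(train)
  z <- cases$s                      # putative labels
  n <- nrow(x)
  mislabel <- numeric(n)

  for (iter in seq_len(config$n_iterations)) {
    seed_i <- child_seed(config$seed, iter)
    model <- ada_fit_member(config, x, z, mislabel, seed_i)
    p <- predict_classifier(config$base_classifier, model, x)
    new_mislabel <- ifelse(z == 1L, 1 - p, p)
    delta <- max(abs(new_mislabel - mislabel))
    mislabel <- new_mislabel
    if (delta < config$tol) break
  }

  members <- lapply(seq_len(config$ensemble_size), function(j) {
    ada_fit_member(config, x, z, mislabel,
                   child_seed(config$seed, 10000L + j))
  })
  structure(list(member_models = members,
                 mislabel_probability = stats::setNames(mislabel,
                                                        cases$case_id),
                 train_label_mean = mean(z),
                 feature_cols = train$feature_cols,
                 config = config),
            class = "ada_fit")
}

# one resample-and-fit. Each putative class is resampled at its original
# size with replacement, inclusion probability proportional to
# 1 - mislabel, so high-mislabel cases are progressively excluded while
# class sizes stay stable. A draw losing an entire class is rejected and
# redrawn (at most 100 attempts) — a defensive guard that cannot trigger
# under per-class draws with the floored weights.
ada_fit_member <- function(config, x, z, mislabel, seed) {
  spec <- config$base_classifier
  if (config$resample_mode == "weighted_fit") {
    w <- pmax(1 - mislabel, 1e-6)
    model <- suppressWarnings(
      stats::glm.fit(cbind(1, x), z, weights = w,
                     family = stats::binomial())
    )
    cf <- model$coefficients
    cf[is.na(cf)] <- 0
    return(list(coef = cf))
  }
  set.seed(as.integer(seed))
  for (attempt in seq_len(100L)) {
    idx <- unlist(lapply(c(0L, 1L), function(cl) {
      pool <- which(z == cl)
      w <- pmax(1 - mislabel[pool], 1e-9)
      pool[sample.int(length(pool), length(pool), replace = TRUE, prob = w)]
    }))
    if (length(unique(z[idx])) == 2L) {
      return(fit_classifier(spec, x[idx, , drop = FALSE], z[idx],
                            seed = seed))
    }
  }
  stop("resampling lost an entire class in 100 consecutive draws; ",
       "mislabel probabilities look degenerate", call. = FALSE)
}

#' @export
print.ada_fit <- function(x, ...) {
  cat(sprintf(
    "ada_fit: %d ensemble members (%s); train label mean = %.4f\n",
    length(x$member_models), x$config$base_classifier$name,
    x$train_label_mean))
  cat(sprintf("  mean final mislabel probability = %.4f\n",
              mean(x$mislabel_probability)))
  invisible(x)
}

#' Predict positive-class probabilities from the adaptive ensemble
#'
#' The per-case probability is the unweighted arithmetic mean of the
#' member-model probabilities, which makes it invariant to member order.
#'
#' @param fit an `"ada_fit"`.
#' @param newdata a [pu_dataset()] or data.frame with the training feature
#'   columns.
#' @return Named numeric vector of probabilities in \[0, 1\].
#' @export
ada_predict <- function(fit, newdata) {
  stopifnot(inherits(fit, "ada_fit"))
  x <- prediction_features(newdata, fit$feature_cols)
  spec <- fit$config$base_classifier
  probs <- vapply(fit$member_models, function(m) {
    if (fit$config$resample_mode == "weighted_fit") {
      predict_logistic(m, x)
    } else {
      predict_classifier(spec, m, x)
    }
  }, numeric(nrow(x)))
  p <- if (nrow(x) == 1L) mean(probs) else rowMeans(probs)
  stats::setNames(pmin(pmax(p, 0), 1), rownames(x))
}
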