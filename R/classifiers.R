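#' Probabilistic classifier specifications
#'
#' Both PU learners are agnostic to the supervised base classifier: anything
#' that can be fitted on a numeric feature matrix with 0/1 labels and return
#' positive-class probabilities satisfies the interface. Built-in
#' specifications cover the classifiers used in the sepsis study:
#'
#' * `"logistic"` — unpenalized logistic regression via [stats::glm.fit()]
#'   (fast linear scorer; the spy step-1 baseline).
#' * `"naive_bayes"` — Gaussian naive Bayes via [e1071::naiveBayes()]
#'   (the spy step-2 baseline).
#' * `"xgboost"` — gradient boosted trees via \pkg{xgboost} with library
#'   defaults (`binary:logistic`, 100 rounds; the updated spy variant).
#' * `"svm_radial"` — radial-kernel support vector machine via
#'   [e1071::svm()]; probabilities come from Platt scaling (a logistic
#'   sigmoid fitted to the training decision values), the standard
#'   score-to-probability calibration for maximum-margin classifiers.
#'
#' A custom classifier is supplied as `classifier_spec("custom",
#' fit = function(x, y, seed) model, predict = function(model, x) prob)`.
#'
#' @param name one of `"logistic"`, `"naive_bayes"`, `"xgboost"`,
#'   `"svm_radial"`, or `"custom"`.
#' @param fit,predict for `name = "custom"`: the fitting and prediction
#'   functions. `fit(x, y, seed)` receives a numeric matrix `x`, an integer
#'   0/1 vector `y` and a seed; `predict(model, x)` must return a numeric
#'   vector of positive-class probabilities in `[0, 1]`.
#' @param ... additional arguments stored with the spec and passed to the
#'   underlying fitting function (e.g. `nrounds` for xgboost).
#' @return An object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(name = c("logistic", "naive_bayes", "xgboost",
                                     "svm_radial", "custom"),
                            fit = NULL, predict = NULL, ...) {
  name <- match.arg(name)
  extra <- list(...)
  spec <- switch(
    name,
    logistic = list(fit = fit_logistic, predict = predict_logistic),
    naive_bayes = list(fit = fit_nb, predict = predict_nb),
    xgboost = list(fit = fit_xgb, predict = predict_xgb),
    svm_radial = list(fit = fit_svm_platt, predict = predict_svm_platt),
    custom = {
      if (!is.function(fit) || !is.function(predict)) {
        stop("custom classifier_spec needs `fit` and `predict` functions",
             call. = FALSE)
      }
      list(fit = fit, predict = predict)
    }
  )
  structure(c(spec, list(name = name, args = extra)),
            class = "classifier_spec")
}

fit_classifier <- function(spec, x, y, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("classifier training set must contain both classes", call. = FALSE)
  }
  do.call(spec$fit, c(list(x = x, y = y, seed = seed), spec$args))
}

predict_classifier <- function(spec, model, x) {
  p <- as.numeric(spec$predict(model, x))
  if (length(p) != nrow(x) || any(!is.finite(p))) {
    stop("classifier failed to produce one finite probability per case",
         call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

# ---- logistic regression (glm.fit; perfect separation warnings are expected
#      on separable PU fixtures and carry no information here) ----

fit_logistic <- function(x, y, seed = NULL, ...) {
  xm <- cbind(1, as.matrix(x))
  fit <- suppressWarnings(
    stats::glm.fit(xm, y, family = stats::binomial())
  )
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(coef = cf)
}

predict_logistic <- function(model, x) {
  as.numeric(stats::plogis(cbind(1, as.matrix(x)) %*% model$coef))
}

# ---- Gaussian naive Bayes ----

fit_nb <- function(x, y, seed = NULL, ...) {
  e1071::naiveBayes(as.data.frame(x), factor(y, levels = c(0L, 1L)))
}

predict_nb <- function(model, x) {
  pr <- stats::predict(model, as.data.frame(x), type = "raw")
  as.numeric(pr[, "1"])
}

# ---- gradient boosted trees ----

fit_xgb <- function(x, y, seed = NULL, nrounds = 100, ...) {
  with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    seed = as.integer(seed %||% 0L), ...),
      data = dtrain, nrounds = nrounds, verbose = 0
    )
  })
}

predict_xgb <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x), nthread = 1))
}

# ---- radial-kernel SVM with Platt-scaled probabilities ----
# Features are assumed min-max normalized upstream, so scale = FALSE.
# The Platt sigmoid is fitted on 3-fold cross-validated decision values
# (deterministic interleaved folds): in-sample decision values are
# overconfident and would polarize borderline cases.

fit_svm_platt <- function(x, y, seed = NULL, ...) {
  x <- as.matrix(x)
  m <- e1071::svm(x, factor(y, levels = c(0L, 1L)),
                  kernel = "radial", scale = FALSE, ...)
  dv <- platt_decision_values(x, y, m, ...)
  platt <- if (stats::sd(dv) < 1e-12) {
    # degenerate margin: fall back to the empirical positive rate
    c(stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)), 0)
  } else {
    cf <- suppressWarnings(
      stats::glm.fit(cbind(1, dv), y, family = stats::binomial())
    )$coefficients
    cf[is.na(cf)] <- 0
    cf
  }
  list(svm = m, platt = platt)
}

platt_decision_values <- function(x, y, full_model, n_calib_folds = 3L, ...) {
  n <- nrow(x)
  fold <- rep_len(seq_len(n_calib_folds), n)
  ok <- all(vapply(seq_len(n_calib_folds), function(f) {
    length(unique(y[fold != f])) == 2L
  }, logical(1)))
  if (n < 2L * n_calib_folds || !ok) {
    # too small to calibrate out-of-fold; use in-sample decision values
    return(svm_decision_values(full_model, x))
  }
  dv <- numeric(n)
  for (f in seq_len(n_calib_folds)) {
    hold <- fold == f
    mf <- e1071::svm(x[!hold, , drop = FALSE],
                     factor(y[!hold], levels = c(0L, 1L)),
                     kernel = "radial", scale = FALSE, ...)
    dv[hold] <- svm_decision_values(mf, x[hold, , drop = FALSE])
  }
  dv
}

predict_svm_platt <- function(model, x) {
  dv <- svm_decision_values(model$svm, x)
  as.numeric(stats::plogis(model$platt[1] + model$platt[2] * dv))
}

# decision values oriented so that positive always means class "1"
# (libsvm orients by the class encountered first in the training data)
svm_decision_values <- function(m, x) {
  att <- attr(stats::predict(m, as.matrix(x), decision.values = TRUE),
              "decision.values")
  dv <- as.numeric(att)
  if (identical(colnames(att)[1], "0/1")) dv <- -dv
  dv
}
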