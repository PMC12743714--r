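#' Configuration for the two-step spy PU learner
#'
#' The spy technique seeds a fraction of the labeled positives into the
#' unlabeled pool, fits a classifier treating positives as class 1 and
#' unlabeled cases (including the spies) as class 0, and uses the lowest
#' spy prediction probability as the threshold below which unlabeled cases
#' are deemed reliable negatives. Because a single spy draw can contain an
#' outlier whose probability is near zero, step 1 is repeated `n_repeats`
#' times with a fresh spy draw each repeat and the threshold is the mean of
#' the per-repeat spy minima.
#'
#' @param spy_fraction fraction of labeled positives used as spies
#'   (default 0.10).
#' @param n_repeats number of step-1 repetitions (default 1000).
#' @param step1_classifier,step2_classifier [classifier_spec()] objects;
#'   defaults are logistic regression (step 1) and Gaussian naive Bayes
#'   (step 2), the baseline pairing. Pass
#'   `classifier_spec("xgboost")` for both to get the boosted-tree variant.
#' @param seed master seed; each repeat derives a child seed.
#' @return An object of class `"spy_config"`.
#' @export
spy_config <- function(spy_fraction = 0.10, n_repeats = 1000L,
                       step1_classifier = classifier_spec("logistic"),
                       step2_classifier = classifier_spec("naive_bayes"),
                       seed = 1L) {
  if (!(spy_fraction > 0 && spy_fraction < 1)) {
    stop("spy_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(n_repeats >= 1, inherits(step1_classifier, "classifier_spec"),
            inherits(step2_classifier, "classifier_spec"))
  structure(list(spy_fraction = spy_fraction,
                 n_repeats = as.integer(n_repeats),
                 step1_classifier = step1_classifier,
                 step2_classifier = step2_classifier,
                 seed = as.integer(seed)),
            class = "spy_config")
}

#' Select spy cases among the labeled positives
#'
#' Draws `max(1, round(fraction * n))` spies uniformly without replacement;
#' the remaining positives are retained as the step-1 positive class.
#'
#' @param positive_ids ids of the labeled positives (at least 2).
#' @param fraction spy fraction in (0, 1).
#' @param seed sampling seed.
#' @return A list with `spy_ids` and `retained_positive_ids` (a disjoint
#'   partition of `positive_ids`).
#' @export
select_spies <- function(positive_ids, fraction, seed = 1L) {
  positive_ids <- as.character(positive_ids)
  if (length(positive_ids) < 2L) {
    stop("need at least 2 labeled positives to draw spies", call. = FALSE)
  }
  n_spies <- max(1L, round(fraction * length(positive_ids)))
  spy_ids <- with_seed(seed, sample(positive_ids, n_spies))
  list(spy_ids = spy_ids,
       retained_positive_ids = setdiff(positive_ids, spy_ids))
}

#' Spy step 1: repeat-averaged reliable-negative threshold
#'
#' For each repeat, spies are redrawn, the step-1 classifier is fitted on
#' retained positives (class 1) versus unlabeled cases plus spies (class 0),
#' and the minimum predicted positive-class probability among that repeat's
#' spies is recorded. The threshold is the arithmetic mean of the
#' per-repeat minima. Each unlabeled case's step-1 probability is its mean
#' predicted probability across repeats (per-repeat draws are averaged so
#' that the reliable-negative decision does not hinge on one spy draw).
#'
#' @param train a [pu_dataset()] with labeled positives and unlabeled cases;
#'   features are assumed normalized where the classifier needs it.
#' @param config a [spy_config()].
#' @return A list with `threshold_t`, `per_repeat_min` (length
#'   `n_repeats`), and `step1_prob` (named by unlabeled case id).
#' @export
spy_step1 <- function(train, config) {
  stopifnot(inherits(train, "pu_dataset"), inherits(config, "spy_config"))
  cases <- train$cases
  if (sum(cases$s) < 2L) {
    stop("training data must contain at least 2 labeled positives",
         call. = FALSE)
  }
  if (all(cases$s == 1L)) {
    stop("training data contain no unlabeled cases", call. = FALSE)
  }
  x <- feature_matrix(train)
  pos_ids <- cases$case_id[cases$s == 1L]
  unl_ids <- cases$case_id[cases$s == 0L]
  idx <- stats::setNames(seq_len(nrow(cases)), cases$case_id)

  minima <- numeric(config$n_repeats)
  prob_sum <- stats::setNames(numeric(length(unl_ids)), unl_ids)
  for (r in seq_len(config$n_repeats)) {
    seed_r <- child_seed(config$seed, r)
    spies <- select_spies(pos_ids, config$spy_fraction, seed_r)
    lab <- integer(nrow(cases))
    lab[idx[spies$retained_positive_ids]] <- 1L
    model <- fit_classifier(config$step1_classifier, x, lab, seed = seed_r)
    p <- predict_classifier(config$step1_classifier, model, x)
    minima[r] <- min(p[idx[spies$spy_ids]])
    prob_sum <- prob_sum + p[idx[unl_ids]]
  }
  list(threshold_t = mean(minima), per_repeat_min = minima,
       step1_prob = prob_sum / config$n_repeats)
}

#' Identify reliable negatives
#'
#' Returns exactly the unlabeled cases whose step-1 probability lies
#' strictly below the threshold.
#'
#' @param step1_prob named probabilities of the unlabeled cases.
#' @param threshold_t the repeat-averaged spy minimum.
#' @return Character vector of reliable-negative case ids.
#' @export
identify_reliable_negatives <- function(step1_prob, threshold_t) {
  assert_prob(step1_prob, "step1_prob")
  names(step1_prob)[step1_prob < threshold_t]
}

#' Spy step 2: supervised fit on positives versus reliable negatives
#'
#' The spies are added back to the positive class and the step-2 classifier
#' is fitted on all labeled positives (class 1) versus the reliable
#' negatives (class 0). The training-set label mean of this step is
#' recorded: it is the classification threshold later used for binary
#' decisions from the spy model.
#'
#' @param train a [pu_dataset()].
#' @param reliable_negative_ids ids from [identify_reliable_negatives()].
#' @param config a [spy_config()].
#' @param step1 optional step-1 output to carry into the fit object.
#' @return An object of class `"spy_fit"`.
#' @export
spy_step2_fit <- function(train, reliable_negative_ids, config,
                          step1 = NULL) {
  stopifnot(inherits(train, "pu_dataset"), inherits(config, "spy_config"))
  cases <- train$cases
  if (length(reliable_negative_ids) == 0L) {
    stop("no reliable negatives identified: inspect the spy threshold and ",
         "the step-1 classifier's probability calibration", call. = FALSE)
  }
  pos_ids <- cases$case_id[cases$s == 1L]
  rn_ids <- as.character(reliable_negative_ids)
  if (!all(rn_ids %in% cases$case_id[cases$s == 0L])) {
    stop("reliable negatives must be unlabeled cases of the training data",
         call. = FALSE)
  }
  sel <- c(pos_ids, rn_ids)
  x <- feature_matrix(train, cases[match(sel, cases$case_id), , drop = FALSE])
  ylab <- c(rep(1L, length(pos_ids)), rep(0L, length(rn_ids)))
  model <- fit_classifier(config$step2_classifier, x, ylab,
                          seed = child_seed(config$seed, 0L))
  structure(list(threshold_t = step1$threshold_t,
                 per_repeat_min = step1$per_repeat_min,
                 step1_prob = step1$step1_prob,
                 reliable_negative_ids = rn_ids,
                 step2_model = model,
                 step2_classifier = config$step2_classifier,
                 step2_train_label_mean = mean(ylab),
                 feature_cols = train$feature_cols,
                 config = config),
            class = "spy_fit")
}

#' Fit the full two-step spy learner
#'
#' Runs step 1 ([spy_step1()]), identifies reliable negatives, and fits
#' step 2 ([spy_step2_fit()]). Unlabeled cases that are neither spies nor
#' reliable negatives are excluded from step-2 training and are scored by
#' the step-2 model at prediction time.
#'
#' @param train a [pu_dataset()].
#' @param config a [spy_config()].
#' @return An object of class `"spy_fit"`.
#' @export
spy_fit <- function(train, config = spy_config()) {
  if ("no labeled positives" %in% train$flags) {
    stop("dataset is flagged 'no labeled positives'; the spy learner needs ",
         "labeled positives", call. = FALSE)
  }
  step1 <- spy_step1(train, config)
  rn <- identify_reliable_negatives(step1$step1_prob, step1$threshold_t)
  spy_step2_fit(train, rn, config, step1 = step1)
}

#' @export
print.spy_fit <- function(x, ...) {
  cat(sprintf("spy_fit: threshold t = %.5f (mean of %d spy minima)\n",
              x$threshold_t, length(x$per_repeat_min)))
  cat(sprintf("  reliable negatives: %d; step-2 train label mean = %.4f\n",
              length(x$reliable_negative_ids), x$step2_train_label_mean))
  invisible(x)
}

#' Predict positive-class probabilities from a spy fit
#'
#' @param fit a `"spy_fit"`.
#' @param newdata a [pu_dataset()] or a data.frame carrying the training
#'   feature columns.
#' @return Named numeric vector of probabilities (a prediction set), one
#'   per requested case.
#' @export
spy_predict <- function(fit, newdata) {
  stopifnot(inherits(fit, "spy_fit"))
  x <- prediction_features(newdata, fit$feature_cols)
  p <- predict_classifier(fit$step2_classifier, fit$step2_model, x)
  stats::setNames(p, rownames(x))
}

prediction_features <- function(newdata, feature_cols) {
  df <- if (inherits(newdata, "pu_dataset")) newdata$cases else
    as.data.frame(newdata)
  absent <- setdiff(feature_cols, names(df))
  if (length(absent)) {
    stop("prediction data lack feature columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(df[, feature_cols, drop = FALSE])
  rownames(x) <- if ("case_id" %in% names(df)) as.character(df$case_id) else
    rownames(df)
  storage.mode(x) <- "double"
  x
}
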