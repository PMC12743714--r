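#' Coding-strategy evaluation scenarios
#'
#' Because a PU dataset has no reliable negatives, models are evaluated by
#' counting actual positives under five constellations of the observed
#' coding flags:
#'
#' * `A` — positive by the explicit coding strategy (the training
#'   definition, main scenario);
#' * `B` — positive by both the explicit and the implicit strategy;
#' * `C` — positive by the implicit strategy;
#' * `D` — positive by the explicit or the implicit strategy;
#' * `E` — positive only by the implicit strategy.
#'
#' On any dataset `E` is contained in `C`, `C` in `D`, `B` in `A`, and `A`
#' in `D`, and the counts satisfy `|D| = |A| + |C| - |B|`.
#'
#' @return Character vector of the scenario codes.
#' @export
evaluation_scenarios <- function() c("A", "B", "C", "D", "E")

#' Scenario truth flags
#'
#' Evaluates one scenario predicate on the coding flags of a dataset.
#' Scenario `A` falls back to the observed label `s` when the explicit flag
#' is absent (labels are assigned by explicit coding, so the two coincide).
#'
#' @param dataset a [pu_dataset()].
#' @param scenario one of `"A"`–`"E"`.
#' @return Named logical vector (by case id).
#' @export
scenario_truth <- function(dataset, scenario) {
  stopifnot(inherits(dataset, "pu_dataset"))
  scenario <- match.arg(scenario, evaluation_scenarios())
  cases <- dataset$cases
  expl <- if ("explicit_flag" %in% names(cases)) cases$explicit_flag == 1L
          else cases$s == 1L
  if (scenario == "A") {
    return(stats::setNames(expl, cases$case_id))
  }
  if (!"implicit_flag" %in% names(cases)) {
    stop("implicit coding flag absent; scenarios B-E unavailable",
         call. = FALSE)
  }
  impl <- cases$implicit_flag == 1L
  truth <- switch(scenario,
                  B = expl & impl,
                  C = impl,
                  D = expl | impl,
                  E = impl & !expl)
  stats::setNames(truth, cases$case_id)
}

#' Stratified cross-validation folds
#'
#' Partitions the dataset into `n_folds` disjoint folds of sizes differing
#' by at most one, stratified on the observed label `s` so that every fold
#' carries approximately the overall label mean.
#'
#' @param dataset a [pu_dataset()].
#' @param n_folds number of folds (default 5).
#' @param seed shuffling seed.
#' @return Named integer vector assigning each case id a fold in
#'   `1:n_folds`.
#' @export
make_cv_folds <- function(dataset, n_folds = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "pu_dataset"))
  n <- nrow(dataset$cases)
  if (n == 0L) stop("dataset is empty", call. = FALSE)
  if (n_folds > n) stop("more folds than cases", call. = FALSE)
  s <- dataset$cases$s
  ids <- dataset$cases$case_id
  ord <- with_seed(seed, c(sample(which(s == 1L)), sample(which(s == 0L))))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(n_folds), n)
  stats::setNames(fold, ids)
}

#' Binary classification at a probability threshold
#'
#' A case is classified positive when its predicted probability is greater
#' than or equal to the threshold.
#'
#' @param predictions named numeric probabilities.
#' @param threshold classification threshold in \[0, 1\].
#' @return Named integer 0/1 vector.
#' @export
classify <- function(predictions, threshold) {
  assert_prob(threshold, "threshold")
  stats::setNames(as.integer(predictions >= threshold), names(predictions))
}

#' Recall of truth positives
#'
#' `TP / (TP + FN)` against the scenario truth flags. Undefined (returned
#' as `NA`) when the truth contains no positives.
#'
#' @param predicted_labels named 0/1 vector from [classify()].
#' @param truth named logical truth flags aligned by case id.
#' @return Recall in \[0, 1\], or `NA` if no truth positives exist.
#' @export
compute_recall <- function(predicted_labels, truth) {
  truth <- align_truth(truth, predicted_labels)
  if (sum(truth) == 0L) return(NA_real_)
  sum(predicted_labels == 1L & truth) / sum(truth)
}

#' Probability ranking of cases
#'
#' Ranks all cases by descending predicted probability, breaking ties by
#' ascending case id (deterministic and auditable), and returns the ids of
#' the top `floor(k * N / 100)` cases.
#'
#' @param predictions named numeric probabilities.
#' @param k_percent top share in percent, in (0, 100\].
#' @return Character vector of the top-ranked case ids.
#' @export
rank_top_ids <- function(predictions, k_percent) {
  stopifnot(k_percent > 0, k_percent <= 100)
  m <- floor(k_percent * length(predictions) / 100)
  ids <- names(predictions)
  ord <- order(-predictions, ids)
  ids[ord][seq_len(m)]
}

#' Recall at the top k percent of predictions
#'
#' Share of all truth positives that appear among the top k% of
#' probability-ranked cases.
#'
#' @inheritParams rank_top_ids
#' @param truth named logical truth flags.
#' @return `r_k` in \[0, 1\], or `NA` if no truth positives exist.
#' @export
compute_recall_at_k <- function(predictions, truth, k_percent) {
  truth <- align_truth(truth, predictions)
  if (sum(truth) == 0L) return(NA_real_)
  top <- rank_top_ids(predictions, k_percent)
  sum(truth[top]) / sum(truth)
}

#' Precision at the top k percent of predictions
#'
#' Share of truth positives among the top k% of probability-ranked cases.
#' Undefined (returned as `NA`) when the top set is empty.
#'
#' @inheritParams compute_recall_at_k
#' @return `p_k` in \[0, 1\], or `NA` for an empty top set.
#' @export
compute_precision_at_k <- function(predictions, truth, k_percent) {
  truth <- align_truth(truth, predictions)
  top <- rank_top_ids(predictions, k_percent)
  if (length(top) == 0L) return(NA_real_)
  sum(truth[top]) / length(top)
}

align_truth <- function(truth, predictions) {
  nm <- names(truth)
  if (!is.null(nm) && !is.null(names(predictions))) {
    if (!all(names(predictions) %in% nm)) {
      stop("truth flags missing for some predicted cases", call. = FALSE)
    }
    truth <- truth[names(predictions)]
    nm <- names(predictions)
  }
  stats::setNames(as.logical(truth), nm)
}

#' Cross-validated PU evaluation across coding scenarios
#'
#' Computes recall, recall-at-k and precision-at-k per scenario, both per
#' fold and pooled over the concatenated out-of-fold predictions.
#' Classification thresholds are the per-fold training-set label means
#' supplied by the caller (the step-2 label mean for the spy learner, the
#' PU training label mean for the adaptive learner). When the dataset
#' carries the latent class (synthetic data), a `"latent"` scenario with
#' truth `y = 1` is appended as oracle metrics.
#'
#' @param predictions named out-of-fold probabilities covering every case
#'   exactly once.
#' @param dataset the evaluated [pu_dataset()].
#' @param fold named fold assignment from [make_cv_folds()].
#' @param thresholds numeric vector of per-fold classification thresholds
#'   (one per fold, in fold order), or a single value reused for all folds.
#' @param scenarios scenario codes to evaluate.
#' @param ks top-k percentages (default `c(10, 20, 30)`).
#' @param include_latent append latent-truth oracle metrics when `y` is
#'   available (default `TRUE`).
#' @return A data.frame with one row per (scenario, fold or `"pooled"`):
#'   threshold, number of truth positives, recall, and the `r_k`/`p_k`
#'   columns. Class `"metrics_report"`.
#' @export
evaluate_all <- function(predictions, dataset, fold, thresholds,
                         scenarios = evaluation_scenarios(),
                         ks = c(10, 20, 30), include_latent = TRUE) {
  stopifnot(inherits(dataset, "pu_dataset"))
  ids <- dataset$cases$case_id
  if (!setequal(names(predictions), ids)) {
    stop("out-of-fold predictions must cover every case exactly once",
         call. = FALSE)
  }
  fold <- fold[ids]
  predictions <- predictions[ids]
  n_folds <- max(fold)
  if (length(thresholds) == 1L) thresholds <- rep(thresholds, n_folds)
  stopifnot(length(thresholds) == n_folds)

  if (!"implicit_flag" %in% names(dataset$cases) &&
      length(setdiff(scenarios, "A"))) {
    warning("implicit coding flag absent; skipping scenarios B-E",
            call. = FALSE)
    scenarios <- intersect(scenarios, "A")
  }
  truth_sets <- lapply(scenarios, function(sc) scenario_truth(dataset, sc))
  names(truth_sets) <- scenarios
  if (include_latent && "y" %in% names(dataset$cases) &&
      !anyNA(dataset$cases$y)) {
    truth_sets$latent <- stats::setNames(dataset$cases$y == 1L, ids)
  }

  labels <- integer(length(predictions))
  names(labels) <- ids
  for (f in seq_len(n_folds)) {
    in_f <- fold == f
    labels[in_f] <- classify(predictions[in_f], thresholds[f])
  }

  rows <- list()
  for (sc in names(truth_sets)) {
    truth <- truth_sets[[sc]]
    rows[[length(rows) + 1L]] <-
      metric_row(sc, "pooled", mean(thresholds), predictions, labels, truth, ks)
    for (f in seq_len(n_folds)) {
      in_f <- fold == f
      rows[[length(rows) + 1L]] <-
        metric_row(sc, as.character(f), thresholds[f], predictions[in_f],
                   labels[in_f], truth[in_f], ks)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metrics_report", "data.frame")
  out
}

metric_row <- function(scenario, fold, threshold, predictions, labels,
                       truth, ks) {
  row <- data.frame(scenario = scenario, fold = fold,
                    classification_threshold = threshold,
                    n_true_positives_available = sum(truth),
                    recall = compute_recall(labels, truth),
                    stringsAsFactors = FALSE)
  for (k in ks) {
    row[[sprintf("recall_at_%d", k)]] <-
      compute_recall_at_k(predictions, truth, k)
    row[[sprintf("precision_at_%d", k)]] <-
      compute_precision_at_k(predictions, truth, k)
  }
  row
}

#' Empirical CDF of prediction probabilities by group
#'
#' The cumulative-distribution diagnostic used to inspect separability: for
#' each group (typically labeled positives versus unlabeled cases) the
#' empirical distribution function of the predicted probabilities is
#' evaluated at the observed probability values. A well-separated PU model
#' concentrates unlabeled mass near probability 0 and labeled mass near 1.
#'
#' @param predictions named numeric probabilities.
#' @param groups named character/factor group labels aligned by case id.
#' @return A data.frame (`group`, `probability`, `cumulative_share`) with a
#'   nondecreasing step per group ending at 1.
#' @export
prediction_cdf <- function(predictions, groups) {
  stopifnot(length(predictions) == length(groups))
  if (!is.null(names(groups)) && !is.null(names(predictions))) {
    groups <- groups[names(predictions)]
  }
  out <- lapply(split(as.numeric(predictions), as.character(groups)),
                function(p) {
                  xs <- sort(unique(p))
                  data.frame(probability = xs,
                             cumulative_share = stats::ecdf(p)(xs))
                })
  res <- do.call(rbind, Map(function(g, df) cbind(group = g, df),
                            names(out), out))
  rownames(res) <- NULL
  res
}
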