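#' Population frame for the external validity check
#'
#' Describes the initial (pre-undersampling) sample the relabeling rates
#' are transferred back to: `l_i` labeled positives and `u_i` unlabeled
#' cases in the initial sample (`n_i = l_i + u_i`), and `u_t` unlabeled
#' cases in the undersampled learning sample. The raw disease rate is
#' `l_i / n_i`.
#'
#' @param l_i labeled positives in the initial sample.
#' @param u_i unlabeled cases in the initial sample.
#' @param u_t unlabeled cases in the learning sample (`u_t <= u_i`).
#' @return An object of class `"population_frame"`.
#' @export
population_frame <- function(l_i, u_i, u_t) {
  stopifnot(l_i >= 0, u_i >= 0, u_t >= 0)
  if (u_t > u_i) stop("u_t cannot exceed u_i", call. = FALSE)
  n_i <- l_i + u_i
  if (n_i == 0) stop("empty population frame", call. = FALSE)
  structure(list(l_i = l_i, u_i = u_i, u_t = u_t, n_i = n_i,
                 raw_rate = l_i / n_i),
            class = "population_frame")
}

#' Population frame from generator truth
#'
#' Builds the [population_frame()] of a synthetic run from the initial
#' (filtered, pre-undersampling) dataset and the learning sample.
#'
#' @param initial the initial [pu_dataset()].
#' @param learning the undersampled learning [pu_dataset()].
#' @return A `"population_frame"`.
#' @export
population_frame_from_datasets <- function(initial, learning) {
  stopifnot(inherits(initial, "pu_dataset"), inherits(learning, "pu_dataset"))
  population_frame(l_i = sum(initial$cases$s == 1L),
                   u_i = sum(initial$cases$s == 0L),
                   u_t = sum(learning$cases$s == 0L))
}

#' Relabeling threshold from the top k percent of predictions
#'
#' Per fold, the threshold is the predicted probability of the
#' `floor(k * N / 100)`-th ranked case (descending, ties by ascending case
#' id): the smallest probability a case needed to be in the fold's top k%.
#' The reported threshold is the mean across folds.
#'
#' @param predictions named out-of-fold probabilities.
#' @param k_percent top share in percent, in (0, 100\].
#' @param fold optional named fold assignment; when `NULL` all predictions
#'   form one fold.
#' @return The (fold-averaged) threshold probability.
#' @export
derive_topk_threshold <- function(predictions, k_percent, fold = NULL) {
  stopifnot(k_percent > 0, k_percent <= 100)
  if (is.null(fold)) fold <- stats::setNames(rep(1L, length(predictions)),
                                             names(predictions))
  fold <- fold[names(predictions)]
  per_fold <- vapply(split(predictions, fold), function(p) {
    if (length(p) == 0L) stop("empty cross-validation fold", call. = FALSE)
    m <- floor(k_percent * length(p) / 100)
    if (m == 0L) stop("top set empty: k too small for fold size",
                      call. = FALSE)
    ord <- order(-p, names(p))
    unname(p[ord][m])
  }, numeric(1))
  mean(per_fold)
}

#' Count relabeled unlabeled cases
#'
#' Number of unlabeled cases whose predicted probability reaches the
#' threshold. Only unlabeled cases are ever relabeled; labeled positives
#' are never counted.
#'
#' @param predictions named probabilities of the *unlabeled* cases.
#' @param threshold relabeling threshold in \[0, 1\].
#' @return Integer count.
#' @export
relabel_count <- function(predictions, threshold) {
  assert_prob(threshold, "threshold")
  sum(predictions >= threshold)
}

#' Transfer a relabel count to the initial sample and derive the new rate
#'
#' Applies the relabeling rate observed in the learning sample,
#' `relabel_count_t / u_t`, to all unlabeled cases of the initial sample:
#' \deqn{s_k = \frac{l_i + u_i \, r_k / u_t}{l_i + u_i}}
#' The transferred count is kept unrounded until report formatting. The
#' ratio is the new rate over the raw rate; since both share the
#' denominator `n_i`, it equals `new_positive_count / l_i`.
#'
#' @param frame a [population_frame()].
#' @param relabel_count_t relabeled unlabeled cases in the learning sample
#'   (between 0 and `u_t`).
#' @return A list with `transferred_relabeled`, `new_positive_count`,
#'   `new_rate` and `ratio`.
#' @export
compute_new_rate <- function(frame, relabel_count_t) {
  stopifnot(inherits(frame, "population_frame"))
  if (frame$u_t == 0) stop("u_t is zero: no unlabeled learning sample",
                           call. = FALSE)
  if (relabel_count_t < 0 || relabel_count_t > frame$u_t) {
    stop("relabel_count_t must lie between 0 and u_t", call. = FALSE)
  }
  transferred <- frame$u_i * relabel_count_t / frame$u_t
  new_positive <- frame$l_i + transferred
  new_rate <- new_positive / frame$n_i
  list(transferred_relabeled = transferred,
       new_positive_count = new_positive,
       new_rate = new_rate,
       ratio = new_rate / frame$raw_rate)
}

#' Compare a rate ratio to the medical-record-review range
#'
#' Medical record review studies report disease rates 2.4 to 4.1 times the
#' raw administrative rates; a model whose relabeling produces a ratio
#' inside this closed interval passes the external plausibility check.
#'
#' @param ratio new-rate to raw-rate ratio (positive).
#' @param empirical_range closed interval, default `c(2.4, 4.1)`.
#' @return One of `"below"`, `"within"`, `"above"`.
#' @export
benchmark_ratio <- function(ratio, empirical_range = c(2.4, 4.1)) {
  stopifnot(ratio > 0, length(empirical_range) == 2L)
  if (ratio < empirical_range[1]) "below"
  else if (ratio > empirical_range[2]) "above"
  else "within"
}

#' Count false negatives among labeled positives
#'
#' @param predicted_labels named 0/1 classifications covering all labeled
#'   positives.
#' @param labeled_positive_ids ids of the labeled positives.
#' @return Number of labeled positives classified negative.
#' @export
count_false_negatives <- function(predicted_labels, labeled_positive_ids) {
  labeled_positive_ids <- as.character(labeled_positive_ids)
  if (!all(labeled_positive_ids %in% names(predicted_labels))) {
    stop("classifications must cover all labeled positives", call. = FALSE)
  }
  sum(predicted_labels[labeled_positive_ids] == 0L)
}

#' External validity report over relabeling threshold rules
#'
#' For each threshold rule (top 5% through top 30% of pooled out-of-fold
#' predictions, plus the class-label-mean threshold), derives the
#' relabeling threshold, counts relabeled unlabeled cases, transfers the
#' relabel rate to the initial sample, computes the new disease rate and
#' its ratio to the raw rate, classifies the ratio against the
#' medical-record-review range, and reports recall and false negatives
#' among the labeled positives at that threshold. Pooled out-of-fold
#' predictions are used so each unlabeled case receives exactly one
#' relabeling decision.
#'
#' @param predictions named pooled out-of-fold probabilities for every case
#'   of the learning sample.
#' @param dataset the learning [pu_dataset()].
#' @param frame a [population_frame()].
#' @param class_label_mean_threshold the classification threshold of the
#'   class-label-mean rule (typically the mean of the per-fold training
#'   label means).
#' @param ks top-k percentages, default `c(5, 10, 15, 20, 25, 30)`.
#' @param fold optional fold assignment for fold-averaged top-k thresholds.
#' @param empirical_range benchmark interval for [benchmark_ratio()].
#' @return A data.frame of class `"validity_report"`, one row per rule.
#' @export
validity_report <- function(predictions, dataset, frame,
                            class_label_mean_threshold,
                            ks = c(5, 10, 15, 20, 25, 30), fold = NULL,
                            empirical_range = c(2.4, 4.1)) {
  stopifnot(inherits(dataset, "pu_dataset"))
  ids <- dataset$cases$case_id
  if (!setequal(names(predictions), ids)) {
    stop("predictions must cover the learning sample exactly", call. = FALSE)
  }
  predictions <- predictions[ids]
  unl <- predictions[dataset$cases$s == 0L]
  pos_ids <- ids[dataset$cases$s == 1L]

  rules <- c(stats::setNames(ks, paste0("top", ks)),
             class_label_mean = NA_real_)
  rows <- lapply(names(rules), function(rule) {
    thr <- if (rule == "class_label_mean") class_label_mean_threshold
           else derive_topk_threshold(predictions, rules[[rule]], fold)
    labels <- classify(predictions, thr)
    r_t <- relabel_count(unl, thr)
    rates <- compute_new_rate(frame, r_t)
    data.frame(threshold_rule = rule,
               classification_threshold = thr,
               relabel_count_t = r_t,
               transferred_relabeled = rates$transferred_relabeled,
               new_positive_count = rates$new_positive_count,
               new_rate = rates$new_rate,
               ratio = rates$ratio,
               verdict = benchmark_ratio(rates$ratio, empirical_range),
               recall = compute_recall(labels,
                                       stats::setNames(ids %in% pos_ids, ids)),
               false_negatives = count_false_negatives(labels, pos_ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validity_report", "data.frame")
  out
}

#' Format a validity report for display
#'
#' Rounds to the precision used in published tables: thresholds to 5
#' decimals, counts to integers, rates to percentages with 2 decimals,
#' ratios to 1 decimal, recall to 3 decimals.
#'
#' @param report a `"validity_report"`.
#' @return A data.frame of formatted character columns.
#' @export
format_validity_report <- function(report) {
  stopifnot(inherits(report, "validity_report"))
  data.frame(
    threshold_rule = report$threshold_rule,
    classification_threshold = sprintf("%.5f",
                                       report$classification_threshold),
    relabeled_examples = sprintf("%.0f", round(report$transferred_relabeled)),
    new_positive_cases = sprintf("%.0f", round(report$new_positive_count)),
    new_rate = sprintf("%.2f%%", 100 * report$new_rate),
    ratio = sprintf("%.1f", report$ratio),
    recall = sprintf("%.3f", report$recall),
    false_negatives = report$false_negatives,
    verdict = report$verdict,
    stringsAsFactors = FALSE
  )
}
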