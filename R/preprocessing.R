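#' Apply the cohort inclusion and exclusion criteria
#'
#' Restricts a case table to the study cohort: adults (age band at least
#' 20-24), cases with a main diagnosis and a DRG code, no missing cost
#' cells, positive total costs, and a length of stay of at least one day.
#' Exclusions are logged under the first matching rule, in the fixed order
#' main diagnosis, DRG, missing costs, zero costs, zero length of stay,
#' age; the order only affects the report, never the set of survivors.
#'
#' @param dataset a [pu_dataset()] carrying the cohort fields.
#' @return A list with the filtered `dataset` and a `report` of class
#'   `"filter_report"` (`n_input`, named `n_excluded`, `n_output`).
#' @export
apply_cohort_filters <- function(dataset) {
  stopifnot(inherits(dataset, "pu_dataset"))
  cases <- dataset$cases
  needed <- c("age_band", "length_of_stay_days", "total_costs",
              "has_main_diagnosis", "has_drg")
  absent <- setdiff(needed, names(cases))
  if (length(absent)) {
    stop("cohort fields missing from dataset: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  feature_na <- if (length(dataset$feature_cols)) {
    rowSums(is.na(cases[, dataset$feature_cols, drop = FALSE])) > 0
  } else rep(FALSE, nrow(cases))

  rules <- list(
    missing_main_diagnosis = !cases$has_main_diagnosis,
    missing_drg = !cases$has_drg,
    missing_cost = feature_na | is.na(cases$total_costs),
    zero_total_costs = !is.na(cases$total_costs) & cases$total_costs <= 0,
    zero_los = cases$length_of_stay_days <= 0,
    underage = age_band_lower(cases$age_band) < 20L
  )

  excluded_by <- rep(NA_character_, nrow(cases))
  for (rule in names(rules)) {
    hit <- rules[[rule]] & is.na(excluded_by)
    excluded_by[hit] <- rule
  }
  keep <- is.na(excluded_by)
  report <- structure(
    list(n_input = nrow(cases),
         n_excluded = vapply(names(rules),
                             function(r) sum(excluded_by == r, na.rm = TRUE),
                             integer(1)),
         n_output = sum(keep)),
    class = "filter_report")
  list(dataset = subset_cases(dataset, keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("cohort filter:", x$n_input, "cases in,", x$n_output, "retained\n")
  for (r in names(x$n_excluded)) {
    if (x$n_excluded[[r]] > 0) cat(sprintf("  excluded (%s): %d\n", r,
                                           x$n_excluded[[r]]))
  }
  invisible(x)
}

#' Coding-strategy code sets
#'
#' Holds the ICD-style code sets that define the explicit coding strategy
#' (codes naming the condition directly) and the implicit strategy (an
#' infection code together with an organ-dysfunction code). Codes are
#' matched as trailing-wildcard prefixes, so `"A41"` matches `"A41.9"`.
#'
#' @param explicit_codes,infection_codes,organ_dysfunction_codes character
#'   vectors of code prefixes; may be empty when the dataset already carries
#'   flags.
#' @return An object of class `"coding_strategy_config"`.
#' @export
coding_strategy_config <- function(explicit_codes = character(),
                                   infection_codes = character(),
                                   organ_dysfunction_codes = character()) {
  structure(list(explicit_codes = as.character(explicit_codes),
                 infection_codes = as.character(infection_codes),
                 organ_dysfunction_codes = as.character(organ_dysfunction_codes)),
            class = "coding_strategy_config")
}

#' Read a coding-strategy configuration from YAML/JSON
#'
#' The file must contain the three lists `explicit_codes`,
#' `infection_codes` and `organ_dysfunction_codes`.
#'
#' @param path path to a YAML (or JSON) file.
#' @return A [coding_strategy_config()].
#' @export
read_coding_strategy <- function(path) {
  cfg <- yaml::read_yaml(path)
  coding_strategy_config(
    explicit_codes = cfg$explicit_codes %||% character(),
    infection_codes = cfg$infection_codes %||% character(),
    organ_dysfunction_codes = cfg$organ_dysfunction_codes %||% character()
  )
}

#' Derive explicit and implicit coding flags from case codes
#'
#' The explicit flag is set when any case code matches an explicit code
#' prefix. The implicit flag (Angus-style) requires both an infection code
#' and an organ-dysfunction code on the same case.
#'
#' @param case_codes character vector of diagnosis codes of one case.
#' @param config a [coding_strategy_config()].
#' @return Named integer vector `c(explicit_flag =, implicit_flag =)`.
#' @export
apply_coding_strategy <- function(case_codes, config) {
  stopifnot(inherits(config, "coding_strategy_config"))
  case_codes <- as.character(case_codes)
  matches_any <- function(set) {
    length(set) > 0 && length(case_codes) > 0 &&
      any(vapply(set, function(p) any(startsWith(case_codes, p)), logical(1)))
  }
  c(explicit_flag = as.integer(matches_any(config$explicit_codes)),
    implicit_flag = as.integer(matches_any(config$infection_codes) &&
                                 matches_any(config$organ_dysfunction_codes)))
}

#' Undersample the unlabeled pool
#'
#' Keeps every labeled positive and a uniform random subsample (without
#' replacement) of at most `n_unlabeled` unlabeled cases — the scheme used
#' to balance the learning sample and bound computation before fitting the
#' PU learners.
#'
#' @param dataset a [pu_dataset()].
#' @param n_unlabeled number of unlabeled cases to retain (all are retained
#'   when fewer are available).
#' @param seed sampling seed.
#' @return A [pu_dataset()] in the original case order.
#' @export
undersample <- function(dataset, n_unlabeled, seed = 1L) {
  stopifnot(inherits(dataset, "pu_dataset"), n_unlabeled >= 1)
  s <- dataset$cases$s
  unl_idx <- which(s == 0L)
  take <- min(as.integer(n_unlabeled), length(unl_idx))
  chosen <- with_seed(seed, sample(unl_idx, take))
  keep <- sort(c(which(s == 1L), chosen))
  subset_cases(dataset, keep)
}

#' Positive class label mean
#'
#' The fraction of labeled positives in a dataset — the quantity used both
#' to describe the learning sample and, per training fold, as the
#' classification threshold.
#'
#' @param dataset a [pu_dataset()].
#' @return A proportion in \[0, 1\].
#' @export
compute_class_label_mean <- function(dataset) {
  stopifnot(inherits(dataset, "pu_dataset"))
  if (nrow(dataset$cases) == 0L) stop("dataset is empty", call. = FALSE)
  mean(dataset$cases$s)
}

#' Fit min-max normalization bounds
#'
#' Feature bounds are always fitted on the training partition only, so that
#' no information from held-out folds leaks into the scaling. Values of
#' held-out cases outside the training range are deliberately not clipped.
#'
#' @param train numeric data.frame or matrix of training features.
#' @return An object of class `"minmax_bounds"`.
#' @export
minmax_fit <- function(train) {
  m <- as.matrix(train)
  if (anyNA(m)) stop("features must not contain missing values", call. = FALSE)
  structure(list(min = apply(m, 2, min), max = apply(m, 2, max),
                 cols = colnames(m)),
            class = "minmax_bounds")
}

#' Apply fitted min-max bounds
#'
#' Maps each feature through `(v - min) / (max - min)` with the bounds from
#' [minmax_fit()]. Constant training features map to 0; out-of-range values
#' fall outside \[0, 1\] and are kept as is.
#'
#' @param bounds a `"minmax_bounds"` object.
#' @param x numeric data.frame or matrix with the same columns.
#' @return A numeric matrix of normalized features.
#' @export
minmax_apply <- function(bounds, x) {
  stopifnot(inherits(bounds, "minmax_bounds"))
  m <- as.matrix(x)
  if (!is.null(colnames(m)) && !is.null(bounds$cols)) {
    missing_cols <- setdiff(bounds$cols, colnames(m))
    if (length(missing_cols)) {
      stop("features absent from input: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    m <- m[, bounds$cols, drop = FALSE]
  }
  range <- bounds$max - bounds$min
  out <- sweep(m, 2, bounds$min)
  out <- sweep(out, 2, ifelse(range > 0, range, 1), "/")
  out[, range == 0] <- 0
  out
}
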