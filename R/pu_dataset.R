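#' PU case dataset container
#'
#' A `pu_dataset` bundles a case-level table with the feature columns used
#' for learning and, for synthetic data, the generator truth (class prior
#' \eqn{\alpha}, label frequency \eqn{c}, latent classes). One row is one
#' inpatient case. Mandatory columns are `case_id` (unique) and the observed
#' label `s` (1 = labeled positive, 0 = unlabeled). Optional columns carry
#' the latent class `y` (synthetic data only; `NA` when unknown), the coding
#' flags `explicit_flag`/`implicit_flag`, and the cohort fields `age_band`,
#' `length_of_stay_days`, `total_costs`, `has_main_diagnosis`, `has_drg`.
#'
#' PU structure is enforced on construction: a labeled case is always a
#' latent positive (`s = 1` implies `y = 1`), a latent negative is never
#' labeled, and a labeled case always carries the explicit coding flag,
#' because labels are assigned by explicit coding.
#'
#' @param cases data.frame of cases.
#' @param feature_cols character vector naming the learning-feature columns
#'   of `cases` (may be empty).
#' @param truth optional list of generator truth (e.g. `class_prior`,
#'   `label_frequency`, `propensity_mode`).
#' @return An object of class `"pu_dataset"`: a list with elements `cases`,
#'   `feature_cols`, `truth` and `flags`.
#' @export
pu_dataset <- function(cases, feature_cols = character(), truth = NULL) {
  stopifnot(is.data.frame(cases))
  if (!all(c("case_id", "s") %in% names(cases))) {
    stop("cases must contain columns: ",
         paste(setdiff(c("case_id", "s"), names(cases)), collapse = ", "),
         call. = FALSE)
  }
  cases$case_id <- as.character(cases$case_id)
  if (anyDuplicated(cases$case_id)) {
    stop("case_id values must be unique", call. = FALSE)
  }
  if (!all(cases$s %in% c(0L, 1L))) {
    stop("observed label s must be 0 or 1", call. = FALSE)
  }
  cases$s <- as.integer(cases$s)
  if ("y" %in% names(cases)) {
    known <- !is.na(cases$y)
    if (!all(cases$y[known] %in% c(0L, 1L))) {
      stop("latent class y must be 0, 1 or NA", call. = FALSE)
    }
    if (any(known & cases$s == 1L & cases$y != 1L)) {
      stop("PU violation: a labeled case (s = 1) must be a latent positive",
           call. = FALSE)
    }
  }
  if ("explicit_flag" %in% names(cases) &&
      any(cases$s == 1L & cases$explicit_flag != 1L)) {
    stop("PU violation: labels are assigned by explicit coding, so s = 1 ",
         "requires explicit_flag = 1", call. = FALSE)
  }
  missing_feats <- setdiff(feature_cols, names(cases))
  if (length(missing_feats)) {
    stop("feature columns absent from cases: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  flags <- character()
  if (sum(cases$s) == 0L) flags <- c(flags, "no labeled positives")
  structure(list(cases = cases, feature_cols = feature_cols,
                 truth = truth, flags = flags),
            class = "pu_dataset")
}

#' @export
print.pu_dataset <- function(x, ...) {
  n <- nrow(x$cases)
  cat("pu_dataset:", n, "cases,", sum(x$cases$s), "labeled positives",
      sprintf("(label mean %.4f)", if (n) mean(x$cases$s) else NA_real_), "\n")
  cat("  features:", length(x$feature_cols),
      if (length(x$feature_cols))
        paste0("(", paste(utils::head(x$feature_cols, 5), collapse = ", "),
               if (length(x$feature_cols) > 5) ", ..." else "", ")") else "",
      "\n")
  if (!is.null(x$truth)) {
    cat(sprintf("  generator truth: class prior %.4g, label frequency %.4g (%s)\n",
                x$truth$class_prior, x$truth$label_frequency,
                x$truth$propensity_mode %||% "SCAR"))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Number of cases in a PU dataset
#' @param x a [pu_dataset()].
#' @export
n_cases <- function(x) {
  stopifnot(inherits(x, "pu_dataset"))
  nrow(x$cases)
}

# feature matrix (rows named by case_id)
feature_matrix <- function(dataset, cases = dataset$cases) {
  m <- as.matrix(cases[, dataset$feature_cols, drop = FALSE])
  rownames(m) <- cases$case_id
  storage.mode(m) <- "double"
  m
}

# keep a row subset, preserving truth and feature declaration
subset_cases <- function(dataset, keep) {
  pu_dataset(dataset$cases[keep, , drop = FALSE],
             feature_cols = dataset$feature_cols, truth = dataset$truth)
}
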