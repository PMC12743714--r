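#' Default cost-attribute distributions
#'
#' Class-conditional zero-inflated log-normal specifications for the cost
#' attributes the generator emulates. Real hospital case-cost tables show
#' strongly right-skewed cost cells with many exact zeros (most patients
#' never enter the ICU, the operating room, or dialysis), and sepsis cases
#' carry a large location shift: in the motivating application their mean
#' total costs are more than three times those of unlabeled cases, with ICU,
#' laboratory, pharmaceutical and nursing costs all markedly higher. Each
#' entry gives, per class (negative, positive): the probability of an exact
#' zero, the log-normal location, and a shared log-scale.
#'
#' `other_services` aggregates the base hotel/administration costs every
#' inpatient case incurs, so every generated case has positive total costs.
#'
#' @return A list of cost-feature specifications understood by
#'   [generator_config()].
#' @export
default_cost_features <- function() {
  cf <- function(name, zero, mloc, sdlog) {
    list(name = name, zero_prob = zero, meanlog = log(mloc), sdlog = sdlog)
  }
  list(
    cf("icu_overheads",     c(0.93, 0.30), c(3000, 12000), 1.0),
    cf("icu_physicians",    c(0.94, 0.35), c(600, 2400),   1.0),
    cf("imcu",              c(0.96, 0.70), c(1500, 3500),  1.0),
    cf("operating_room",    c(0.55, 0.45), c(1400, 2600),  0.9),
    cf("anesthesia",        c(0.50, 0.40), c(900, 1600),   0.8),
    cf("laboratory",        c(0.35, 0.02), c(150, 900),    0.8),
    cf("pharmaceuticals",   c(0.25, 0.02), c(70, 450),     0.9),
    cf("blood_products",    c(0.90, 0.55), c(400, 1100),   1.0),
    cf("medical_material",  c(0.20, 0.05), c(120, 280),    0.9),
    cf("nursing",           c(0.01, 0.00), c(1300, 5200),  0.8),
    cf("emergency",         c(0.60, 0.15), c(230, 340),    0.8),
    cf("emergency_doctors", c(0.65, 0.25), c(90, 180),     0.8),
    cf("imaging",           c(0.45, 0.05), c(180, 650),    0.8),
    cf("dialysis",          c(0.97, 0.75), c(2000, 2600),  1.0),
    cf("physicians",        c(0.05, 0.01), c(800, 2100),   0.8),
    cf("physiotherapy",     c(0.55, 0.20), c(250, 550),    0.9),
    cf("other_services",    c(0.00, 0.00), c(5000, 9500),  0.6)
  )
}

#' Default procedure-chapter count distributions
#'
#' Poisson means per class (negative, positive) for aggregated
#' procedure-chapter counts; sepsis cases receive considerably more
#' respiratory, cardiovascular and digestive-tract procedures.
#'
#' @return A list of count-feature specifications for [generator_config()].
#' @export
default_count_features <- function() {
  list(
    list(name = "proc_respiratory",   mean = c(0.04, 0.23)),
    list(name = "proc_cardiovascular", mean = c(0.19, 0.68)),
    list(name = "proc_digestive",     mean = c(0.18, 0.68))
  )
}

#' Configuration for the synthetic PU case generator
#'
#' Defines the statistical structure of a generated case table: the class
#' prior \eqn{\alpha = p(y = 1)}, the label frequency
#' \eqn{c = p(s = 1 \mid y = 1)}, the labeling mechanism (SCAR: constant
#' propensity equal to `label_frequency`; SAR: logistic propensity in a
#' named feature subset, mean-calibrated to `label_frequency`), the
#' class-conditional cost and count feature distributions, and the overlap
#' structure of the explicit and implicit coding flags.
#'
#' @param n_cases number of cases to generate.
#' @param class_prior class prior \eqn{\alpha} in (0, 1).
#' @param label_frequency label frequency \eqn{c} in \[0, 1\].
#' @param propensity_mode `"SCAR"` (default) or `"SAR"`.
#' @param propensity_attributes named numeric vector of weights over feature
#'   names (SAR mode only): the propensity attributes that drive the
#'   labeling probability of latent positives.
#' @param cost_features list of cost-feature specs, see
#'   [default_cost_features()].
#' @param count_features list of count-feature specs, see
#'   [default_count_features()].
#' @param implicit_given_positive probability that a latent positive also
#'   satisfies the implicit (infection + organ dysfunction) coding rule.
#' @param implicit_only_rate probability that a latent negative satisfies
#'   the implicit rule.
#' @param seed master seed; all stochastic stages derive child seeds from it.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n_cases,
                             class_prior = 0.2,
                             label_frequency = 0.5,
                             propensity_mode = c("SCAR", "SAR"),
                             propensity_attributes = NULL,
                             cost_features = default_cost_features(),
                             count_features = default_count_features(),
                             implicit_given_positive = 0.65,
                             implicit_only_rate = 0.05,
                             seed = 1L) {
  propensity_mode <- match.arg(propensity_mode)
  stopifnot(length(n_cases) == 1L, n_cases >= 1)
  if (!(class_prior > 0 && class_prior < 1)) {
    stop("class_prior must lie strictly between 0 and 1", call. = FALSE)
  }
  assert_prob(label_frequency, "label_frequency")
  assert_prob(implicit_given_positive, "implicit_given_positive")
  assert_prob(implicit_only_rate, "implicit_only_rate")
  if (propensity_mode == "SAR") {
    if (is.null(propensity_attributes) || is.null(names(propensity_attributes))) {
      stop("SAR mode requires a named weight vector `propensity_attributes`",
           call. = FALSE)
    }
    feat_names <- c(vapply(cost_features, `[[`, "", "name"),
                    vapply(count_features, `[[`, "", "name"))
    unknown <- setdiff(names(propensity_attributes), feat_names)
    if (length(unknown)) {
      stop("propensity_attributes name unknown features: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_cases = as.integer(n_cases), class_prior = class_prior,
                 label_frequency = label_frequency,
                 propensity_mode = propensity_mode,
                 propensity_attributes = propensity_attributes,
                 cost_features = cost_features,
                 count_features = count_features,
                 implicit_given_positive = implicit_given_positive,
                 implicit_only_rate = implicit_only_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic PU case dataset
#'
#' Draws latent classes `y ~ Bernoulli(class_prior)`, class-conditional
#' zero-inflated log-normal cost features and Poisson procedure counts,
#' then selects latent positives for labeling with probability `e(x)`:
#' constant and equal to the label frequency under SCAR, logistic in the
#' propensity attributes and rescaled so that the mean propensity among
#' latent positives equals the label frequency under SAR. The explicit
#' coding flag equals the observed label (labels are assigned by explicit
#' coding); implicit flags are drawn from the configured overlap rates.
#' Cohort fields are generated clean (adult age bands, positive length of
#' stay and total costs, main diagnosis and DRG present); violations for
#' filter testing are planted separately with [inject_cohort_noise()].
#'
#' The PU identities hold exactly on every generated dataset: no latent
#' negative is ever labeled, and every labeled case is a latent positive.
#' With `label_frequency = 0` the dataset is produced but flagged
#' `"no labeled positives"`; the learners reject such input.
#'
#' @param config a [generator_config()].
#' @return A [pu_dataset()] with generator truth attached.
#' @export
generate_pu_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_cases

  y <- with_seed(child_seed(config$seed, 1L),
                 stats::rbinom(n, 1L, config$class_prior))

  feats <- with_seed(child_seed(config$seed, 2L), {
    cols <- list()
    for (cf in config$cost_features) {
      zero <- stats::rbinom(n, 1L, cf$zero_prob[y + 1L]) == 1L
      v <- stats::rlnorm(n, meanlog = cf$meanlog[y + 1L], sdlog = cf$sdlog)
      v[zero] <- 0
      cols[[cf$name]] <- round(v, 2)
    }
    for (kf in config$count_features) {
      cols[[kf$name]] <- stats::rpois(n, kf$mean[y + 1L])
    }
    as.data.frame(cols)
  })
  feats$total_costs <- rowSums(
    feats[, vapply(config$cost_features, `[[`, "", "name"), drop = FALSE])

  e <- propensity_scores(config, feats, y)
  s <- with_seed(child_seed(config$seed, 3L),
                 as.integer(y == 1L & stats::rbinom(n, 1L, e) == 1L))

  impl <- with_seed(child_seed(config$seed, 4L), {
    p_impl <- ifelse(y == 1L, config$implicit_given_positive,
                     config$implicit_only_rate)
    stats::rbinom(n, 1L, p_impl)
  })

  cohort <- with_seed(child_seed(config$seed, 5L), {
    age <- round(ifelse(y == 1L, stats::rnorm(n, 70, 15),
                        stats::rnorm(n, 52, 20)))
    age <- pmin(pmax(age, 20), 99)
    los <- 1L + stats::rpois(n, ifelse(y == 1L, 14, 5))
    list(age_band = age_to_band(age), length_of_stay_days = los)
  })

  cases <- data.frame(
    case_id = sprintf("case%07d", seq_len(n)),
    s = s, y = y,
    explicit_flag = s, implicit_flag = impl,
    age_band = cohort$age_band,
    length_of_stay_days = cohort$length_of_stay_days,
    total_costs = feats$total_costs,
    has_main_diagnosis = TRUE, has_drg = TRUE,
    stringsAsFactors = FALSE
  )
  feature_cols <- c("total_costs", setdiff(names(feats), "total_costs"))
  cases <- cbind(cases, feats[, setdiff(names(feats), "total_costs"),
                              drop = FALSE])

  truth <- list(class_prior = config$class_prior,
                label_frequency = config$label_frequency,
                propensity_mode = config$propensity_mode,
                propensity_attributes = config$propensity_attributes,
                n_latent_positive = sum(y),
                seed = config$seed)
  pu_dataset(cases, feature_cols = feature_cols, truth = truth)
}

# propensity e(x) of latent positives; constant c under SCAR, logistic in
# the propensity attributes under SAR with the intercept solved so that the
# mean propensity among latent positives equals c.
propensity_scores <- function(config, feats, y) {
  c_freq <- config$label_frequency
  if (config$propensity_mode == "SCAR" || c_freq %in% c(0, 1)) {
    return(rep(c_freq, nrow(feats)))
  }
  w <- config$propensity_attributes
  lin <- as.matrix(log1p(feats[, names(w), drop = FALSE])) %*% w
  lin <- as.numeric(scale(lin))
  pos <- y == 1L
  f <- function(a) mean(stats::plogis(a + lin[pos])) - c_freq
  a <- stats::uniroot(f, c(-50, 50))$root
  stats::plogis(a + lin)
}

#' Plant cohort-filter violations into a dataset
#'
#' Mutates requested fractions of cases so that each mutated case violates
#' exactly one inclusion criterion: an underage band, a missing main
#' diagnosis, a missing DRG, a missing cost cell, zero total costs, or a
#' zero-day length of stay. Used to make the cohort filters testable against
#' a known mutation log.
#'
#' @param dataset a [pu_dataset()].
#' @param fractions named numeric vector with entries among `"underage"`,
#'   `"missing_main_diagnosis"`, `"missing_drg"`, `"missing_cost"`,
#'   `"zero_total_costs"`, `"zero_los"`; each in \[0, 1\], summing to at
#'   most 1.
#' @param seed seed for choosing which cases to mutate.
#' @return A list with the mutated `dataset` and a `log` data.frame
#'   (`case_id`, `violation`).
#' @export
inject_cohort_noise <- function(dataset, fractions, seed = 1L) {
  stopifnot(inherits(dataset, "pu_dataset"))
  kinds <- c("underage", "missing_main_diagnosis", "missing_drg",
             "missing_cost", "zero_total_costs", "zero_los")
  if (is.null(names(fractions)) || !all(names(fractions) %in% kinds)) {
    stop("fractions must be named among: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  }
  if (any(fractions < 0) || any(fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(fractions) > 1 + 1e-12) {
    stop("fractions sum above 1: cases can violate at most one criterion each",
         call. = FALSE)
  }
  cases <- dataset$cases
  n <- nrow(cases)
  counts <- round(fractions * n)
  ord <- with_seed(seed, sample.int(n))
  log <- data.frame(case_id = character(), violation = character(),
                    stringsAsFactors = FALSE)
  at <- 0L
  for (kind in names(fractions)) {
    k <- counts[[kind]]
    if (k == 0L) next
    idx <- ord[(at + 1L):(at + k)]
    at <- at + k
    cases[idx, ] <- mutate_violation(cases[idx, , drop = FALSE], kind,
                                     dataset$feature_cols)
    log <- rbind(log, data.frame(case_id = cases$case_id[idx],
                                 violation = kind,
                                 stringsAsFactors = FALSE))
  }
  out <- dataset
  out$cases <- cases
  list(dataset = out, log = log)
}

mutate_violation <- function(rows, kind, feature_cols) {
  switch(kind,
    underage = { rows$age_band <- "15-19"; rows },
    missing_main_diagnosis = { rows$has_main_diagnosis <- FALSE; rows },
    missing_drg = { rows$has_drg <- FALSE; rows },
    missing_cost = {
      col <- setdiff(feature_cols, "total_costs")[1]
      if (is.na(col)) stop("no cost feature column available to blank out",
                           call. = FALSE)
      rows[[col]] <- NA_real_
      rows
    },
    zero_total_costs = { rows$total_costs <- 0; rows },
    zero_los = { rows$length_of_stay_days <- 0L; rows }
  )
}
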