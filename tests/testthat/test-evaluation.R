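test_that("cross-validation folds partition and stratify the dataset", {
  d <- generate_pu_dataset(small_generator(n = 1000, seed = 2))
  fold <- make_cv_folds(d, 5, seed = 3)
  expect_setequal(names(fold), d$cases$case_id)
  sizes <- table(fold)
  expect_lte(diff(range(sizes)), 1)
  overall <- mean(d$cases$s)
  per_fold <- tapply(d$cases$s[match(names(fold), d$cases$case_id)], fold,
                     mean)
  expect_true(all(abs(per_fold - overall) < 0.01))
  expect_identical(make_cv_folds(d, 5, seed = 3), fold)
  expect_error(make_cv_folds(d, nrow(d$cases) + 1), "folds")
  # 100 cases into 5 folds of exactly 20
  d100 <- subset(d$cases, select = c(case_id, s))[1:100, ]
  f100 <- make_cv_folds(pu_dataset(d100), 5, seed = 1)
  expect_true(all(table(f100) == 20))
})

test_that("classification uses a greater-or-equal threshold convention", {
  p <- c(a = 0.2024, b = 0.20, c = 0.9, d = 0)
  got <- classify(p, 0.2024)
  expect_equal(got, c(a = 1L, b = 0L, c = 1L, d = 0L))
  expect_true(all(classify(p, 0) == 1L))
})

test_that("recall is TP over truth positives with NA when undefined", {
  truth <- stats::setNames(c(rep(TRUE, 500), rep(FALSE, 100)),
                           sprintf("r%03d", 1:600))
  labels <- stats::setNames(c(rep(1L, 443), rep(0L, 57), rep(1L, 100)),
                            names(truth))
  expect_equal(compute_recall(labels, truth), 0.886)
  expect_equal(compute_recall(stats::setNames(rep(1L, 600), names(truth)),
                              truth), 1.0)
  expect_equal(compute_recall(stats::setNames(rep(0L, 600), names(truth)),
                              truth), 0.0)
  expect_true(is.na(compute_recall(labels, truth & FALSE)))
})

test_that("ranked metrics match the brute-force oracle on a known fixture", {
  p <- stats::setNames(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.15, 0.1, 0.05, 0.02, 0),
                       sprintf("k%02d", 1:10))
  truth <- stats::setNames(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                             FALSE, FALSE, FALSE), names(p))
  # top 30% of 10 cases = 3 cases, containing 2 truth positives of 4
  expect_equal(compute_recall_at_k(p, truth, 30), 0.5)
  expect_equal(compute_precision_at_k(p, truth, 30), 2 / 3)
  expect_equal(compute_recall_at_k(p, truth, 100), 1.0)
  # all truth positives ranked first and covered by k
  p2 <- stats::setNames(c(0.99, 0.98, 0.97, 0.96, rep(0.1, 6)), names(p))
  truth2 <- stats::setNames(c(rep(TRUE, 4), rep(FALSE, 6)), names(p))
  expect_equal(compute_recall_at_k(p2, truth2, 40), 1.0)
})

test_that("tie-breaking in ranking is by ascending case id", {
  p <- c(z9 = 0.5, a1 = 0.5, m5 = 0.5, b2 = 0.9)
  expect_equal(rank_top_ids(p, 50), c("b2", "a1"))
})

test_that("scenario predicates respect the set relations", {
  d <- generate_pu_dataset(small_generator(n = 2000, seed = 12))
  A <- scenario_truth(d, "A"); B <- scenario_truth(d, "B")
  C <- scenario_truth(d, "C"); D <- scenario_truth(d, "D")
  E <- scenario_truth(d, "E")
  expect_true(all(!E | C))  # E subset of C
  expect_true(all(!C | D))
  expect_true(all(!B | A))
  expect_true(all(!A | D))
  expect_equal(sum(D), sum(A) + sum(C) - sum(B))
  # explicit == implicit for all cases: A-D identical, E empty
  cases <- data.frame(case_id = sprintf("e%02d", 1:20),
                      s = rep(c(1L, 0L), 10))
  cases$explicit_flag <- cases$s
  cases$implicit_flag <- cases$s
  dd <- pu_dataset(cases)
  for (sc in c("B", "C", "D")) {
    expect_equal(scenario_truth(dd, sc), scenario_truth(dd, "A"))
  }
  expect_equal(sum(scenario_truth(dd, "E")), 0)
})

test_that("per-scenario truth counts match hand enumeration", {
  cases <- data.frame(
    case_id = sprintf("h%d", 1:6),
    s = c(1L, 1L, 0L, 0L, 0L, 0L),
    explicit_flag = c(1L, 1L, 0L, 0L, 0L, 0L),
    implicit_flag = c(1L, 0L, 1L, 1L, 0L, 0L))
  d <- pu_dataset(cases)
  expect_equal(sum(scenario_truth(d, "A")), 2)
  expect_equal(sum(scenario_truth(d, "B")), 1)
  expect_equal(sum(scenario_truth(d, "C")), 3)
  expect_equal(sum(scenario_truth(d, "D")), 4)
  expect_equal(sum(scenario_truth(d, "E")), 2)
})

test_that("evaluate_all reports pooled and per-fold metrics per scenario", {
  d <- generate_pu_dataset(small_generator(n = 600, seed = 23))
  fold <- make_cv_folds(d, 3, seed = 1)
  set.seed(4)
  # synthetic predictions correlated with the latent class
  p <- stats::setNames(
    stats::plogis(3 * d$cases$y - 1.5 + stats::rnorm(600)), d$cases$case_id)
  rep <- evaluate_all(p, d, fold, thresholds = rep(mean(d$cases$s), 3))
  expect_s3_class(rep, "metrics_report")
  expect_setequal(unique(rep$scenario), c("A", "B", "C", "D", "E", "latent"))
  expect_setequal(unique(rep$fold), c("pooled", "1", "2", "3"))
  # recall at k is non-decreasing in k everywhere
  expect_true(all(rep$recall_at_10 <= rep$recall_at_20 + 1e-12))
  expect_true(all(rep$recall_at_20 <= rep$recall_at_30 + 1e-12))
  expect_true(all(rep$recall >= 0 & rep$recall <= 1))
  expect_error(evaluate_all(p[-1], d, fold, 0.2), "every case")
})

test_that("missing implicit flags degrade gracefully to scenario A", {
  cases <- data.frame(case_id = sprintf("w%02d", 1:40),
                      s = rep(c(1L, 0L), 20))
  d <- pu_dataset(cases)
  p <- stats::setNames(stats::runif(40), cases$case_id)
  fold <- make_cv_folds(d, 2, seed = 2)
  expect_warning(rep <- evaluate_all(p, d, fold, 0.5), "B-E")
  expect_setequal(unique(rep$scenario), "A")
})

test_that("prediction CDF is a nondecreasing step reaching one", {
  p <- c(a = 0.1, b = 0.1, c = 0.9, d = 0.9)
  g <- c(a = "unlabeled", b = "unlabeled", c = "labeled", d = "labeled")
  cdf <- prediction_cdf(p, g)
  unl <- cdf[cdf$group == "unlabeled", ]
  expect_equal(unl$cumulative_share[unl$probability == 0.1], 1.0)
  mixed <- prediction_cdf(c(a = 0.1, b = 0.1, c = 0.9, d = 0.9),
                          c(a = "g", b = "g", c = "g", d = "g"))
  expect_equal(mixed$cumulative_share, c(0.5, 1.0))
  expect_true(all(diff(mixed$cumulative_share) >= 0))
})
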