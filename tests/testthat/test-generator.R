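test_that("a label frequency of one labels every latent positive", {
  d <- generate_pu_dataset(generator_config(n_cases = 1000,
                                            label_frequency = 1, seed = 3))
  expect_identical(d$cases$s, d$cases$y)
  se <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(mean(d$cases$s) - 0.2), 3 * se)
})

test_that("labeled fraction converges to alpha * c under SCAR", {
  fracs <- vapply(1:20, function(i) {
    d <- generate_pu_dataset(generator_config(n_cases = 50000,
                                              class_prior = 0.2,
                                              label_frequency = 0.5,
                                              seed = 100 + i))
    mean(d$cases$s)
  }, numeric(1))
  se <- sqrt(0.1 * 0.9 / (50000 * 20))
  expect_lt(abs(mean(fracs) - 0.1), 3 * se)
})

test_that("empirical label frequency among latent positives recovers c", {
  d <- generate_pu_dataset(generator_config(n_cases = 50000,
                                            label_frequency = 0.5, seed = 9))
  pos <- d$cases$y == 1L
  se <- sqrt(0.5 * 0.5 / sum(pos))
  expect_lt(abs(mean(d$cases$s[pos]) - 0.5), 3 * se)
})

test_that("PU identities hold exactly on every generated dataset", {
  for (seed in 1:5) {
    cfg <- generator_config(n_cases = 500,
                            class_prior = stats::runif(1, 0.05, 0.6),
                            label_frequency = stats::runif(1),
                            seed = seed)
    d <- generate_pu_dataset(cfg)
    expect_equal(nrow(d$cases), 500)                      # conservation
    expect_true(all(d$cases$y[d$cases$s == 1L] == 1L))    # p(y=1|s=1)=1
    expect_true(all(d$cases$s[d$cases$y == 0L] == 0L))    # p(s=1|y=0)=0
    expect_true(all(d$cases$explicit_flag[d$cases$s == 1L] == 1L))
    expect_true(all(d$cases[, d$feature_cols] >= 0))
    expect_true(all(d$cases$total_costs > 0))
  }
})

test_that("identical configs and seeds export byte-identical CSV", {
  d1 <- generate_pu_dataset(small_generator(seed = 11))
  d2 <- generate_pu_dataset(small_generator(seed = 11))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_case_table(d1, f1); write_case_table(d2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  d3 <- generate_pu_dataset(small_generator(seed = 12))
  expect_false(identical(d1$cases, d3$cases))
})

test_that("positive cases carry the configured cost shift", {
  d <- generate_pu_dataset(generator_config(n_cases = 20000, seed = 5))
  tc <- d$cases$total_costs
  ratio <- mean(tc[d$cases$y == 1L]) / mean(tc[d$cases$y == 0L])
  expect_gt(ratio, 2.5)  # labeled sepsis-like cases cost several times more
  # many exact-zero cost cells in the skewed attributes
  expect_gt(mean(d$cases$icu_overheads == 0), 0.5)
})

test_that("SAR propensity is mean-calibrated to c and attribute-dependent", {
  cfg <- generator_config(
    n_cases = 30000, label_frequency = 0.5, propensity_mode = "SAR",
    propensity_attributes = c(laboratory = 1.5), seed = 17)
  d <- generate_pu_dataset(cfg)
  pos <- d$cases$y == 1L
  se <- sqrt(0.5 * 0.5 / sum(pos))
  expect_lt(abs(mean(d$cases$s[pos]) - 0.5), 4 * se)
  # positively weighted attribute: labeled positives have higher lab costs
  lab <- d$cases$laboratory
  expect_gt(median(lab[pos & d$cases$s == 1L]),
            median(lab[pos & d$cases$s == 0L]))
})

test_that("zero label frequency flags the dataset and learners reject it", {
  d <- generate_pu_dataset(generator_config(n_cases = 200,
                                            label_frequency = 0, seed = 2))
  expect_true("no labeled positives" %in% d$flags)
  expect_error(spy_fit(d, spy_config(n_repeats = 1)), "no labeled positives")
  expect_error(ada_fit(d, ada_config()), "no labeled positives")
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(100, class_prior = 0), "class_prior")
  expect_error(generator_config(100, label_frequency = 1.2),
               "label_frequency")
  expect_error(generator_config(100, propensity_mode = "SAR"),
               "propensity_attributes")
})

test_that("cohort noise injection mutates exact counts, one violation each", {
  d <- generate_pu_dataset(small_generator(n = 100, seed = 4))
  unchanged <- inject_cohort_noise(d, c(zero_los = 0), seed = 1)
  expect_identical(unchanged$dataset$cases, d$cases)
  expect_equal(nrow(unchanged$log), 0)

  res <- inject_cohort_noise(d, c(zero_los = 0.1), seed = 1)
  expect_equal(sum(res$dataset$cases$length_of_stay_days == 0), 10)
  expect_equal(nrow(res$log), 10)

  expect_error(inject_cohort_noise(d, c(zero_los = 0.6, underage = 0.6)),
               "sum above 1")
})

test_that("filter survivors equal the hand count from the mutation log", {
  d <- generate_pu_dataset(small_generator(n = 50, seed = 8))
  res <- inject_cohort_noise(
    d, c(underage = 0.1, missing_drg = 0.1, missing_cost = 0.08,
         zero_total_costs = 0.06, zero_los = 0.04), seed = 3)
  filtered <- apply_cohort_filters(res$dataset)
  planted <- unique(res$log$case_id)
  expect_equal(filtered$report$n_output, 50 - length(planted))
  expect_false(any(planted %in% filtered$dataset$cases$case_id))
})
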