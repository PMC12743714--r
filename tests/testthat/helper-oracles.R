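# Brute-force reference implementations and small fixture builders.
# The oracles deliberately share no code with the package: plain sort,
# slice and count.

brute_top_ids <- function(p, k_percent) {
  m <- floor(k_percent * length(p) / 100)
  df <- data.frame(id = names(p), p = as.numeric(p), stringsAsFactors = FALSE)
  df <- df[order(-df$p, df$id), ]
  df$id[seq_len(m)]
}

brute_recall_at_k <- function(p, truth, k_percent) {
  top <- brute_top_ids(p, k_percent)
  sum(truth[top]) / sum(truth)
}

brute_precision_at_k <- function(p, truth, k_percent) {
  top <- brute_top_ids(p, k_percent)
  if (length(top) == 0) return(NA_real_)
  sum(truth[top]) / length(top)
}

brute_topk_threshold <- function(p, k_percent) {
  m <- floor(k_percent * length(p) / 100)
  df <- data.frame(id = names(p), p = as.numeric(p), stringsAsFactors = FALSE)
  df <- df[order(-df$p, df$id), ]
  df$p[m]
}

brute_reliable_negatives <- function(p, t) {
  out <- character()
  for (id in names(p)) if (p[[id]] < t) out <- c(out, id)
  out
}

# a random PU prediction fixture of <= 50 cases with mixed ties
random_prediction_fixture <- function(n) {
  ids <- sprintf("c%02d", sample.int(99, n))
  p <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # ties on purpose
  names(p) <- ids
  truth <- stats::setNames(sample(c(TRUE, FALSE), n, replace = TRUE), ids)
  list(p = p, truth = truth)
}

# hand-built separable PU case table: positives high on both features
separable_dataset <- function(n_pos = 30, n_neg = 70, c_freq = 1,
                              seed = 42, gap = 6) {
  set.seed(seed)
  n <- n_pos + n_neg
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  s <- as.integer(y == 1L & stats::runif(n) < c_freq)
  cases <- data.frame(
    case_id = sprintf("sep%03d", seq_len(n)),
    s = s, y = y,
    explicit_flag = s,
    implicit_flag = as.integer(y == 1L),
    f1 = stats::rnorm(n, mean = y * gap),
    f2 = stats::rnorm(n, mean = y * gap),
    stringsAsFactors = FALSE
  )
  pu_dataset(cases, feature_cols = c("f1", "f2"))
}

# a fixed deterministic linear scorer: ignores the training labels and
# scores by a frozen weight vector, so repeated fits are enumerable
fixed_linear_scorer <- function(weights, intercept = 0) {
  classifier_spec("custom",
                  fit = function(x, y, seed) list(w = weights, b = intercept),
                  predict = function(model, x) {
                    stats::plogis(as.numeric(as.matrix(x) %*% model$w) +
                                    model$b)
                  })
}

small_generator <- function(n = 800, seed = 1, c_freq = 0.5) {
  generator_config(n_cases = n, class_prior = 0.2, label_frequency = c_freq,
                   seed = seed)
}

normalize_dataset <- function(d) {
  b <- minmax_fit(d$cases[, d$feature_cols, drop = FALSE])
  d$cases[, d$feature_cols] <- minmax_apply(b, d$cases[, d$feature_cols,
                                                       drop = FALSE])
  d
}
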