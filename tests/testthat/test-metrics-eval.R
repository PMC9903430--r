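test_that("AUC matches brute-force pair counting, including ties", {
  expect_equal(compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               auc_pair_oracle(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               tolerance = 1e-15)
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(compute_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(10:200, 1)
    y <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    expect_equal(compute_auc(s, y), auc_pair_oracle(s, y),
                 tolerance = 1e-12)
  }
  expect_error(compute_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  y <- stats::rbinom(80, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- stats::rnorm(80) + y
  expect_equal(compute_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("threshold metrics agree with the confusion matrix", {
  set.seed(21)
  y <- stats::rbinom(60, 1, 0.4); y[1:2] <- c(0, 1)
  s <- stats::runif(60)
  mp <- metric_panel(s, y, threshold = 0.5)
  pred <- as.integer(s >= 0.5)
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  expect_equal(mp[["sensitivity"]], tp / (tp + fn))
  expect_equal(mp[["specificity"]], tn / (tn + fp))
  expect_equal(mp[["accuracy"]], (tp + tn) / 60)
  expect_equal(mp[["f1"]], 2 * tp / (2 * tp + fp + fn))
  # accuracy is the prevalence-weighted mix of sensitivity and specificity
  expect_equal(mp[["accuracy"]],
               (mp[["sensitivity"]] * sum(y) +
                  mp[["specificity"]] * sum(1 - y)) / 60)
})

test_that("average precision follows the threshold-sum definition", {
  # hand-traced: scores 0.9 > 0.8 > 0.7 > 0.6 with labels 1, 0, 1, 0
  # thresholds: P = 1, 1/2, 2/3, 1/2 at R = 1/2, 1/2, 1, 1
  ap <- average_precision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(ap, 0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(average_precision(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1.0)
  # all-tied scores collapse to a single threshold at the prevalence
  expect_equal(average_precision(rep(1, 10), rep(c(0, 1), 5)), 0.5)
})

test_that("stratified CV keeps fold class counts within one sample", {
  sim <- small_signal_sim(n_cases = 83, n_controls = 117, n_snps = 10)
  fold <- mlprs:::stratified_folds(sim$cohort$phenotype, 5, seed = 3)
  for (f in 1:5) {
    expect_lte(abs(sum(fold == f & sim$cohort$phenotype == 1) - 83 / 5), 1)
    expect_lte(abs(sum(fold == f & sim$cohort$phenotype == 0) - 117 / 5), 1)
  }
  expect_error(mlprs:::stratified_folds(c(1, 0, 0, 0), 3), "cv configuration")
})

test_that("every classifier separates a strong-signal cohort in CV", {
  sim <- simulate_cohort(simulation_config(
    n_cases = 200, n_controls = 400, n_snps = 9, missing_rate = 0,
    n_constant = 0, n_ld_pairs = 0, seed = 83))
  for (cl in classifier_ids()) {
    m <- evaluate_cv(sim$cohort, sim$truth$causal_ids, cl, folds = 5,
                     seed = 84)
    expect_gt(m[["auc"]], 0.9)
  }
  expect_error(evaluate_cv(sim$cohort, sim$truth$causal_ids, "mystery-model"),
               "unknown classifier")
})

test_that("a label-permuted test cohort scores near chance", {
  sim <- simulate_cohort(simulation_config(
    n_cases = 300, n_controls = 500, n_snps = 9, missing_rate = 0,
    n_constant = 0, n_ld_pairs = 0, seed = 85))
  parts <- split_samples(sim$cohort, split_spec(c(0.4, 0.6, 0, 0) / 1,
                                               seed = 86))
  test_perm <- parts$test1
  set.seed(87)
  test_perm$phenotype <- sample(test_perm$phenotype)
  m <- evaluate_test(parts$train, test_perm, sim$truth$causal_ids,
                     "random-forest", seed = 88)
  expect_gt(m[["auc"]], 0.4); expect_lt(m[["auc"]], 0.6)

  # memorising forest on train-as-test sits near the ceiling
  m2 <- evaluate_test(parts$train, parts$train, sim$truth$causal_ids,
                      "random-forest", seed = 88)
  expect_gt(m2[["auc"]], 0.95)
  # determinism under a fixed seed
  m3 <- evaluate_test(parts$train, test_perm, sim$truth$causal_ids,
                      "random-forest", seed = 88)
  expect_identical(m, m3)
})

test_that("random-panel null distribution is centred at chance", {
  sim <- simulate_cohort(simulation_config(
    n_cases = 250, n_controls = 400, n_snps = 60,
    causal_spec = data.frame(maf = numeric(0), beta = numeric(0)),
    missing_rate = 0, n_constant = 0, n_ld_pairs = 0, seed = 90))
  parts <- split_samples(sim$cohort, split_spec(c(0.65, 0.35, 0, 0),
                                               seed = 91))
  nd <- random_panel_null(parts$train, parts$test1, panel_size = 9,
                          n_iterations = 60, num_trees = 40, seed = 92)
  expect_length(nd$auc_values, 60)
  expect_true(all(nd$auc_values >= 0 & nd$auc_values <= 1))
  expect_lt(abs(mean(nd$auc_values) - 0.5), 0.05)
  expect_identical(sum(nd$histogram$count), 60L)
  # single-SNP pool: every iteration trains on the same duplicated column
  nd1 <- random_panel_null(parts$train, parts$test1,
                           pool = parts$train$snps$snp_id[1],
                           panel_size = 1, n_iterations = 3, num_trees = 20,
                           seed = 93)
  expect_equal(stats::sd(nd1$auc_values), 0)
})
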