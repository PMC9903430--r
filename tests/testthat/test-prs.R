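test_that("per-SNP logistic betas match a likelihood-maximisation oracle", {
  tabs <- list(
    matrix(c(30, 40, 20, 25, 10, 15), 2,
           dimnames = list(c("control", "case"), 0:2)),
    matrix(c(50, 10, 30, 25, 5, 40), 2,
           dimnames = list(c("control", "case"), 0:2)),
    matrix(c(80, 20, 15, 30, 2, 12), 2,
           dimnames = list(c("control", "case"), 0:2)))
  for (tab in tabs) {
    s <- table_to_samples(tab)
    co <- toy_cohort(matrix(s$g, ncol = 1), phenotype = s$y)
    eff <- estimate_effect_sizes(co, co$snps$snp_id)
    expect_lt(abs(eff$beta - logistic_table_oracle(tab)), 1e-6)
    expect_identical(eff$direction,
                     if (eff$beta < 0) "protective" else "risk")
  }
})

test_that("a phenotype-independent SNP gets a near-zero effect size", {
  set.seed(61)
  co <- toy_cohort(matrix(hwe_column(600, 0.3), ncol = 1),
                   phenotype = rep(c(0L, 1L), 300))
  eff <- estimate_effect_sizes(co, co$snps$snp_id)
  expect_lt(abs(eff$beta), 3 * eff$se)
  expect_false(eff$separation)
})

test_that("separated SNPs fall back to penalised estimates with a warning", {
  g <- c(rep(2, 50), rep(0, 50))
  y <- c(rep(1L, 50), rep(0L, 50))
  co <- toy_cohort(matrix(g, ncol = 1), phenotype = y)
  expect_warning(eff <- estimate_effect_sizes(co, co$snps$snp_id),
                 "separation")
  expect_true(eff$separation)
  expect_true(is.finite(eff$beta) && is.finite(eff$se))
  expect_gt(eff$beta, 0)
  expect_lt(abs(eff$beta), 15)
})

test_that("the PRS formula is evaluated exactly, missing-aware", {
  eff <- data.frame(snp_id = c("rs001", "rs002"), beta = c(1, -1))
  co <- toy_cohort(matrix(c(2, 2, 0, 1, NA, 0), ncol = 2),
                   phenotype = c(1L, 0L, 0L))
  prs <- compute_prs(co, eff)
  expect_equal(prs$score[1], (1 * 2 + (-1) * 1) / (2 * 2))  # = 0.25
  expect_equal(prs$score[2], (1 * 2) / (2 * 1))             # = 1.0 (M_j = 1)
  expect_equal(prs$score[3], 0)                             # all dosages 0
  expect_identical(prs$m_nonmissing, c(2, 1, 2))

  # a sample with no observed panel SNP is unscorable, never zero
  co2 <- toy_cohort(matrix(c(NA, NA, 0, 1), ncol = 2, byrow = TRUE),
                    phenotype = c(1L, 0L))
  prs2 <- compute_prs(co2, eff)
  expect_true(prs2$unscorable[1])
  expect_true(is.na(prs2$score[1]))
  expect_error(compute_prs(co2, eff, allow_missing = FALSE), "missing")
})

test_that("PRS is homogeneous in the betas and ignores zero-beta SNPs' weight", {
  sim <- small_signal_sim(n_cases = 60, n_controls = 90, n_snps = 12)
  panel <- sim$cohort$snps$snp_id[1:4]
  eff <- data.frame(snp_id = panel, beta = c(0.5, -1, 2, 0.25))
  s1 <- compute_prs(sim$cohort, eff)$score
  eff2 <- eff; eff2$beta <- eff$beta * 3
  expect_equal(compute_prs(sim$cohort, eff2)$score, 3 * s1,
               tolerance = 1e-12)
  # adding a zero-beta SNP changes scores only through M_j
  eff3 <- rbind(eff, data.frame(snp_id = sim$cohort$snps$snp_id[5], beta = 0))
  s3 <- compute_prs(sim$cohort, eff3)$score
  expect_equal(s3, s1 * 4 / 5, tolerance = 1e-12)
})

test_that("masking a zero-contribution SNP never lowers a sample's PRS", {
  eff <- data.frame(snp_id = c("a", "b", "c"), beta = c(2, -1, 1.5))
  full <- toy_cohort(matrix(c(2, 1, 0), 1), phenotype = 1L,
                     ids = c("a", "b", "c"))
  masked <- toy_cohort(matrix(c(2, 1, NA), 1), phenotype = 1L,
                       ids = c("a", "b", "c"))
  s_full <- compute_prs(full, eff)$score
  s_masked <- compute_prs(masked, eff)$score
  # the masked SNP contributed S_i * G_ij = 0; M_j drops so the magnitude
  # cannot shrink and the sign is preserved
  expect_gte(s_masked, s_full)
  expect_identical(sign(s_masked), sign(s_full))
})

test_that("PRS association: null calibration, strong signal, degenerate input", {
  # constant scores: zero slope, p = 1
  out <- test_prs_association(rep(0.2, 100), rep(c(0, 1), 50))
  expect_equal(out$slope, 0, tolerance = 1e-8)
  expect_equal(out$p_value, 1, tolerance = 1e-8)

  # null calibration: LRT p-values are uniform under independence
  set.seed(62)
  ps <- replicate(400, {
    test_prs_association(stats::rnorm(150), stats::rbinom(150, 1, 0.4))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # strong signal
  set.seed(63)
  y <- rep(c(0, 1), each = 200)
  s <- stats::rnorm(400, mean = y * 2)
  expect_lt(test_prs_association(s, y)$p_value, 1e-20)
})

test_that("PRS as sole feature: monotone-classifier AUC equals raw-score AUC", {
  sim <- simulate_cohort(simulation_config(
    n_cases = 200, n_controls = 350, n_snps = 15, missing_rate = 0,
    n_constant = 0, n_ld_pairs = 0, seed = 64))
  parts <- split_samples(sim$cohort, split_spec(c(0.6, 0.2, 0.1, 0.1),
                                               seed = 65))
  eff <- suppressWarnings(
    estimate_effect_sizes(parts$train, sim$truth$causal_ids))
  res <- evaluate_prs_as_feature(parts$train, parts[2:4], eff,
                                 classifiers = "logistic-regression",
                                 seed = 66)
  raw_auc <- compute_auc(compute_prs(parts$test1, eff)$score,
                         parts$test1$phenotype)
  got <- res$auc[res$classifier == "logistic-regression" &
                   res$dataset == "test1"]
  expect_equal(got, raw_auc, tolerance = 1e-12)
})

test_that("the risk calculator reproduces compute_prs and the logistic map", {
  sim <- small_signal_sim(n_cases = 120, n_controls = 200, n_snps = 12)
  panel <- sim$truth$causal_ids
  eff <- suppressWarnings(estimate_effect_sizes(sim$cohort, panel))
  prs <- compute_prs(sim$cohort, eff)
  assoc <- test_prs_association(prs, sim$cohort$phenotype)

  g <- sim$cohort$dosages[7, panel]
  out <- risk_calculator(g, eff, assoc$map)
  expect_equal(out$prs, prs$score[7], tolerance = 1e-12)
  expect_equal(out$probability, out$odds / (1 + out$odds), tolerance = 1e-12)

  # one missing genotype: matches compute_prs's M_j-aware score
  g2 <- g; g2[3] <- NA
  co2 <- sim$cohort[7, ]
  co2$dosages[1, panel[3]] <- NA
  expect_equal(risk_calculator(g2, eff, assoc$map)$prs,
               compute_prs(co2, eff)$score, tolerance = 1e-12)

  # all dosages zero: PRS 0, probability logistic(intercept)
  g0 <- stats::setNames(rep(0, length(panel)), panel)
  out0 <- risk_calculator(g0, eff, assoc$map)
  expect_equal(out0$prs, 0)
  expect_equal(out0$probability, stats::plogis(assoc$map$intercept))

  expect_error(risk_calculator(stats::setNames(rep(NA_real_, length(panel)),
                                               panel), eff, assoc$map),
               "unscorable")
  expect_error(risk_calculator(g[-1], eff, assoc$map), "no genotype")
})

test_that("univariate fits recover the sign of every causal effect", {
  hits <- 0L
  for (rep in 1:15) {
    sim <- simulate_cohort(simulation_config(
      n_cases = 530, n_controls = 1470, n_snps = 20, missing_rate = 0,
      n_constant = 0, n_ld_pairs = 0, seed = 700 + rep))
    eff <- suppressWarnings(
      estimate_effect_sizes(sim$cohort, sim$truth$causal_ids))
    hits <- hits + all(sign(eff$beta) == sign(sim$truth$true_betas))
  }
  expect_gte(hits, 15L * 0.95 - 1)
})

test_that("case and control PRS distributions are distinct but overlap", {
  sim <- simulate_cohort(simulation_config(
    n_cases = 300, n_controls = 700, n_snps = 20, missing_rate = 0,
    n_constant = 0, n_ld_pairs = 0, seed = 710))
  eff <- suppressWarnings(
    estimate_effect_sizes(sim$cohort, sim$truth$causal_ids))
  s <- compute_prs(sim$cohort, eff)$score
  y <- sim$cohort$phenotype
  expect_gt(mean(s[y == 1]), mean(s[y == 0]))          # distinct
  expect_gt(min(s[y == 1]), min(s[y == 0]))
  expect_lt(min(s[y == 1]), max(s[y == 0]))            # partial overlap
})

test_that("effect sizes and the risk map are functions of training data only", {
  sim <- small_signal_sim(n_cases = 150, n_controls = 250, n_snps = 10)
  parts <- split_samples(sim$cohort, split_spec(c(0.6, 0.2, 0.1, 0.1),
                                               seed = 67))
  eff <- suppressWarnings(
    estimate_effect_sizes(parts$train, sim$truth$causal_ids))
  assoc <- test_prs_association(compute_prs(parts$train, eff),
                                parts$train$phenotype)
  snap_eff <- unserialize(serialize(eff, NULL))
  snap_map <- unserialize(serialize(assoc$map, NULL))
  invisible(compute_prs(parts$test1, eff))
  invisible(evaluate_prs_as_feature(parts$train, parts[2:4], eff,
                                    classifiers = "naive-bayes"))
  expect_identical(eff, snap_eff)
  expect_identical(assoc$map, snap_map)
})
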