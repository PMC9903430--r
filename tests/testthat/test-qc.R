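test_that("exact HWE test handles modal and monomorphic configurations", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)
  expect_equal(hwe_exact_test(0, 0, 100), 1.0)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("exact HWE test agrees with full enumeration up to 200 chromosomes", {
  expect_equal(hwe_exact_test(10, 10, 10), hwe_enum_oracle(10, 10, 10),
               tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:300) {
    n <- sample(1:100, 1)               # up to 200 chromosomes
    n_aa <- sample(0:n, 1)
    n_het <- sample(0:(n - n_aa), 1)
    n_AA <- n - n_aa - n_het
    expect_equal(hwe_exact_test(n_AA, n_het, n_aa),
                 hwe_enum_oracle(n_AA, n_het, n_aa), tolerance = 1e-12)
  }
})

test_that("HWE recurrence stays finite and exact at large sample sizes", {
  # strong heterozygote excess in a big cohort: p must underflow to ~0,
  # not overflow to NaN
  p <- hwe_exact_test(0, 4000, 0)
  expect_true(is.finite(p))
  expect_lt(p, 1e-100)
  expect_equal(hwe_exact_test(1000, 2000, 1000),
               hwe_enum_oracle(1000, 2000, 1000), tolerance = 1e-12)
})

test_that("QC filters remove the planted failures, in order", {
  set.seed(19)
  n <- 200
  cols <- list(
    maf_fail1   = stats::rbinom(n, 2, 0.004),
    maf_fail2   = stats::rbinom(n, 2, 0.006),
    miss_fail1  = hwe_column(n, 0.3),
    miss_fail2  = hwe_column(n, 0.3),
    hwe_fail1   = rep(1, n),              # all heterozygous
    hwe_fail2   = rep(c(0, 1), n / 2),
    ok1 = hwe_column(n, 0.2), ok2 = hwe_column(n, 0.3),
    ok3 = hwe_column(n, 0.4), ok4 = hwe_column(n, 0.25))
  cols$hwe_fail2 <- c(rep(0, 100), rep(2, 100))  # no hets at maf 0.5
  d <- do.call(cbind, cols)
  d[sample(n, 25), "miss_fail1"] <- NA           # 12.5% missing
  d[sample(n, 23), "miss_fail2"] <- NA           # 11.5% missing
  co <- toy_cohort(d, ids = names(cols))
  res <- filter_snps(co, qc_config())
  expect_identical(res$report$removed$maf$snp_id,
                   c("maf_fail1", "maf_fail2"))
  expect_identical(res$report$removed$missingness$snp_id,
                   c("miss_fail1", "miss_fail2"))
  expect_identical(res$report$removed$hwe$snp_id,
                   c("hwe_fail1", "hwe_fail2"))
  expect_identical(res$cohort$snps$snp_id, c("ok1", "ok2", "ok3", "ok4"))
  expect_identical(res$report$counts$remaining, c(10L, 8L, 6L, 4L))
})

test_that("filters use strict inequalities at the thresholds", {
  n <- 200
  # maf exactly 0.01: 4 alt alleles in 400
  maf_edge <- c(rep(1, 4), rep(0, n - 4))
  # missingness exactly 0.10
  miss_edge <- hwe_column(n, 0.4)
  miss_edge[1:20] <- NA
  co <- toy_cohort(cbind(maf_edge = maf_edge, miss_edge = miss_edge))
  res <- filter_snps(co, qc_config())
  expect_identical(n_snps(res$cohort), 2L)   # both retained
})

test_that("near-constant rule is strict at its boundary", {
  d91 <- c(rep(0, 91), rep(1, 9))
  d90 <- c(rep(0, 90), rep(1, 10))
  dmix <- rep(c(0, 1, 2, 1), 25)
  co <- toy_cohort(cbind(a = d91, b = d90, c = dmix))
  out <- drop_near_constant(co, 0.90)
  expect_identical(out$snps$snp_id, c("b", "c"))
  expect_identical(attr(out, "dropped"), "a")
})

test_that("correlation pruning follows the greedy genomic-order scan", {
  set.seed(7)
  n <- 400
  a <- hwe_column(n, 0.4)
  flip <- function(x, k) { i <- sample(n, k); x[i] <- hwe_column(k, 0.4); x }
  b <- flip(a, 8)            # r ~ 0.97 with a
  cc <- flip(b, 8)           # r ~ 0.97 with b, lower with a
  stopifnot(abs(cor(a, b)) > 0.95, abs(cor(b, cc)) > 0.95,
            abs(cor(a, cc)) < 0.95)
  co <- toy_cohort(cbind(A = a, B = b, C = cc))
  out <- prune_correlated(co, 0.95)
  expect_identical(out$snps$snp_id, c("A", "C"))

  # exact duplicate: later copy dropped; r = 0.90 pair: both kept
  set.seed(9)
  x <- hwe_column(n, 0.3)
  y <- x
  z <- hwe_column(n, 0.3)
  co2 <- toy_cohort(cbind(X = x, Y = y, Z = z))
  out2 <- prune_correlated(co2, 0.95)
  expect_identical(out2$snps$snp_id, c("X", "Z"))

  # cross-chromosome duplicates are never pruned
  co3 <- toy_cohort(cbind(X = x, Y = y), chrom = c("1", "2"))
  expect_identical(n_snps(prune_correlated(co3, 0.95)), 2L)

  # zero-variance columns must be removed first
  co4 <- toy_cohort(cbind(X = x, K = rep(1, n)))
  expect_error(prune_correlated(co4), "zero-variance")
})

test_that("QC filters are monotone and idempotent", {
  sim <- simulate_cohort(simulation_config(
    n_cases = 150, n_controls = 350, n_snps = 60, missing_rate = 0.03,
    n_constant = 4, n_ld_pairs = 4, seed = 55))
  res <- filter_snps(sim$cohort, qc_config())
  expect_true(all(res$cohort$snps$snp_id %in% sim$cohort$snps$snp_id))
  res2 <- filter_snps(res$cohort, qc_config())
  expect_identical(res2$cohort$snps$snp_id, res$cohort$snps$snp_id)
  expect_identical(sum(vapply(res2$report$removed, nrow, integer(1))), 0L)
  co <- drop_near_constant(res$cohort)
  expect_identical(attr(drop_near_constant(co), "dropped"), character(0))
  pr <- prune_correlated(co)
  expect_identical(attr(prune_correlated(pr), "dropped"), character(0))
})

test_that("the surviving set does not depend on filter order", {
  sim <- simulate_cohort(simulation_config(
    n_cases = 150, n_controls = 350, n_snps = 80, missing_rate = 0.05,
    n_constant = 5, n_ld_pairs = 0, seed = 66))
  stats_df <- snp_statistics(sim$cohort)
  cfg <- qc_config()
  keep_spec_order <- filter_snps(sim$cohort, cfg)$cohort$snps$snp_id
  keep_direct <- stats_df$snp_id[stats_df$maf >= cfg$maf_min &
                                   stats_df$missing_rate <= cfg$missing_max &
                                   stats_df$hwe_p >= cfg$hwe_alpha]
  expect_identical(keep_spec_order, keep_direct)
})
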