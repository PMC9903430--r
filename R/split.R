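#' Specification of a fixed-proportion four-way split
#'
#' Cohorts are partitioned into one training set and three unseen test sets
#' *before* any processing, so that QC, imputation and selection never see
#' test samples. Partition sizes are the largest-remainder apportionment of
#' `fraction * N`, which conserves the total exactly; with the study-style
#' fractions `c(599, 125, 127, 127) / 978` this reproduces the partition
#' sizes (599, 125, 127, 127) for 978 cases and (1673, 349, 355, 355) for
#' 2732 controls.
#'
#' @param fractions Four non-negative proportions (train, test1, test2,
#'   test3) summing to 1 within 1e-12.
#' @param seed Integer seed for the random permutation of samples.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(fractions, seed = 1L) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 4) stop("exactly four fractions are required")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-12) {
    stop("fractions must sum to 1 (got ", format(sum(fractions), digits = 15), ")")
  }
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

#' Largest-remainder apportionment of N into integer partition sizes
#'
#' Each size is `floor(fraction * N)` plus one unit for the partitions with
#' the largest fractional remainders until the total reaches `N`. Ties are
#' broken by partition order.
#'
#' @param n Total count.
#' @param fractions Non-negative proportions summing to 1.
#' @return Integer vector of sizes summing to `n`.
#' @export
apportion_sizes <- function(n, fractions) {
  q <- fractions * n
  base <- floor(q + 1e-9)          # guard against 599/978*978 = 598.999...
  rem <- q - base
  shortfall <- n - sum(base)
  sizes <- base
  if (shortfall > 0) {
    top <- order(-rem, seq_along(rem))[seq_len(shortfall)]
    sizes[top] <- sizes[top] + 1
  }
  as.integer(sizes)
}

#' Split a cohort into train and three test partitions
#'
#' Samples are randomly permuted under the spec's seed and assigned
#' contiguously to the four partitions, separately within cases and within
#' controls so every partition keeps the cohort's case:control ratio.
#' Partitions are disjoint and exhaustive. Single-class cohorts (e.g. a
#' case-only call set split before merging) are supported.
#'
#' @param cohort A [genotype_cohort()].
#' @param spec A [split_spec()].
#' @param require_nonempty_tests If `TRUE`, a fraction implying an empty
#'   test partition is an error.
#' @return Named list of four `genotype_cohort`s: `train`, `test1`, `test2`,
#'   `test3`.
#' @export
split_samples <- function(cohort, spec, require_nonempty_tests = FALSE) {
  validate_cohort(cohort)
  stopifnot(inherits(spec, "split_spec"))
  if (length(cohort$samples) == 0) stop("cannot split an empty cohort")
  set.seed(spec$seed)
  assign_part <- rep(NA_integer_, length(cohort$samples))
  for (cls in unique(cohort$phenotype)) {
    idx <- which(cohort$phenotype == cls)
    sizes <- apportion_sizes(length(idx), spec$fractions)
    perm <- sample(idx)
    assign_part[perm] <- rep.int(1:4, sizes)
  }
  if (require_nonempty_tests && any(tabulate(assign_part, 4)[2:4] == 0)) {
    stop("degenerate split: a test partition is empty under these fractions")
  }
  parts <- lapply(1:4, function(k) cohort[which(assign_part == k), ])
  names(parts) <- c("train", "test1", "test2", "test3")
  parts
}
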