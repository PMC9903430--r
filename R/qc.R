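#' QC filter thresholds
#'
#' Defaults follow the pipeline's stated rules: drop SNPs with minor-allele
#' frequency below 1%, genotype missingness above 10%, or an exact
#' Hardy-Weinberg test p-value below 0.01; later, drop near-constant SNPs
#' (modal genotype in more than 90% of samples) and prune SNP pairs with
#' Pearson dosage correlation above 0.95 within each chromosome. All
#' comparisons are strict inequalities, so a SNP sitting exactly on a
#' threshold is retained.
#'
#' @param maf_min Minimum minor-allele frequency.
#' @param missing_max Maximum missingness fraction.
#' @param hwe_alpha Hardy-Weinberg p-value threshold.
#' @param constant_frac Near-constant modal-genotype threshold.
#' @param corr_max Correlation-pruning threshold.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.01, missing_max = 0.10, hwe_alpha = 0.01,
                      constant_frac = 0.90, corr_max = 0.95) {
  vals <- c(maf_min, missing_max, hwe_alpha, constant_frac, corr_max)
  if (any(vals <= 0 | vals >= 1)) stop("all thresholds must lie in (0, 1)")
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 hwe_alpha = hwe_alpha, constant_frac = constant_frac,
                 corr_max = corr_max), class = "qc_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on observed diploid genotype counts: conditional
#' on the observed allele counts, the probability of every feasible
#' heterozygote count is evaluated (by a numerically stable recurrence from
#' the modal configuration) and the p-value is the sum of probabilities of
#' configurations no more probable than the observed one. A monomorphic SNP
#' (minor-allele count zero) returns 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (homozygous ref, heterozygous,
#'   homozygous alt).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("at least one genotype observation is required")
  n_rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_rare == 0) return(1)
  het_obs <- n_Aa
  # feasible heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalised probabilities via the standard ratio recurrence
  #   P(h+2)/P(h) = 4 * hom_r(h) * hom_c(h) / ((h+2) * (h+1)),
  #   hom_r(h) = (n_rare - h)/2, hom_c(h) = n - h - hom_r(h),
  # anchored at the modal count and recursed outward so extreme
  # configurations underflow to zero instead of the anchor overflowing
  up_ratio <- function(h) {
    hom_r <- (n_rare - h) / 2
    4 * hom_r * (n - h - hom_r) / ((h + 2) * (h + 1))
  }
  mode_k <- 1L
  while (mode_k < length(hets) && up_ratio(hets[mode_k]) > 1) {
    mode_k <- mode_k + 1L
  }
  p <- numeric(length(hets))
  p[mode_k] <- 1
  if (mode_k < length(hets)) {
    for (k in mode_k:(length(hets) - 1L)) {
      p[k + 1] <- p[k] * up_ratio(hets[k])
    }
  }
  if (mode_k > 1) {
    for (k in mode_k:2L) {
      p[k - 1] <- p[k] / up_ratio(hets[k - 1])
    }
  }
  p <- p / sum(p)
  p_obs <- p[match(het_obs, hets)]
  if (is.na(p_obs)) stop("observed heterozygote count infeasible for allele counts")
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

#' Per-SNP summary statistics
#'
#' Computes, per SNP, the minor-allele frequency (from non-missing dosages
#' only, folded to `[0, 0.5]`), the missingness fraction, and the exact
#' Hardy-Weinberg test p-value (from integer genotype counts; `NA` for
#' columns holding fractional imputed dosages).
#'
#' @param cohort A [genotype_cohort()].
#' @return Data frame with columns `snp_id`, `maf`, `missing_rate`, `hwe_p`.
#' @export
snp_statistics <- function(cohort) {
  validate_cohort(cohort)
  d <- cohort$dosages
  n <- nrow(d)
  miss <- colMeans(is.na(d))
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.nan(maf)] <- NA_real_      # all-missing column
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[!is.na(d[, j]), j]
    if (!length(x) || any(x != round(x))) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  data.frame(snp_id = cohort$snps$snp_id, maf = maf, missing_rate = miss,
             hwe_p = hwe, row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply MAF, missingness and Hardy-Weinberg filters
#'
#' Removes, in order, SNPs with `maf < maf_min`, then (among survivors)
#' SNPs with `missing_rate > missing_max`, then SNPs with
#' `hwe_p < hwe_alpha`, all computed on the supplied (merged) cohort. The
#' order affects only which stage a doubly-failing SNP is attributed to in
#' the report, not the surviving set.
#'
#' @param cohort A [genotype_cohort()] with pre-imputation integer dosages.
#' @param config A [qc_config()].
#' @return List with elements `cohort` (filtered) and `report` (class
#'   `qc_report`): per-stage data frames of removed SNPs with the offending
#'   statistic, plus before/after counts.
#' @export
filter_snps <- function(cohort, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  stats_df <- snp_statistics(cohort)
  if (anyNA(stats_df$hwe_p)) {
    stop("filter_snps requires pre-imputation integer dosages")
  }
  keep <- rep(TRUE, nrow(stats_df))
  removed <- list()
  fail <- keep & stats_df$maf < config$maf_min
  removed$maf <- data.frame(snp_id = stats_df$snp_id[fail],
                            maf = stats_df$maf[fail])
  keep <- keep & !fail
  fail <- keep & stats_df$missing_rate > config$missing_max
  removed$missingness <- data.frame(snp_id = stats_df$snp_id[fail],
                                    missing_rate = stats_df$missing_rate[fail])
  keep <- keep & !fail
  fail <- keep & stats_df$hwe_p < config$hwe_alpha
  removed$hwe <- data.frame(snp_id = stats_df$snp_id[fail],
                            hwe_p = stats_df$hwe_p[fail])
  keep <- keep & !fail
  if (!any(keep)) stop("all SNPs removed by QC filters (empty panel)")
  report <- structure(list(
    removed = removed,
    counts = data.frame(
      stage = c("input", "maf", "missingness", "hwe"),
      removed = c(0L, vapply(removed, nrow, integer(1))),
      remaining = c(nrow(stats_df),
                    nrow(stats_df) - cumsum(vapply(removed, nrow, integer(1))))
    )), class = "qc_report")
  list(cohort = cohort[, which(keep)], report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Drop near-constant SNPs
#'
#' A SNP is removed iff its modal genotype's frequency (among non-missing
#' dosages) strictly exceeds `constant_frac`.
#'
#' @param cohort A [genotype_cohort()].
#' @param constant_frac Threshold (default 0.90).
#' @return The filtered cohort; removed ids in attribute `"dropped"`.
#' @export
drop_near_constant <- function(cohort, constant_frac = 0.90) {
  validate_cohort(cohort)
  modal_frac <- apply(cohort$dosages, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    max(table(x)) / length(x)
  })
  keep <- modal_frac <= constant_frac
  out <- cohort[, which(keep)]
  attr(out, "dropped") <- cohort$snps$snp_id[!keep]
  out
}

#' Prune highly correlated SNPs within each chromosome
#'
#' Within each chromosome, SNPs are scanned in genomic order; a SNP is
#' dropped iff its absolute Pearson dosage correlation with any
#' earlier-retained SNP on the same chromosome strictly exceeds `corr_max`
#' (so the first SNP of a correlated group, in genomic order, is the one
#' kept). Cross-chromosome pairs are never pruned. Correlations use
#' pairwise-complete observations when dosages are missing.
#'
#' @param cohort A [genotype_cohort()]; zero-variance columns must have
#'   been removed first (see [drop_near_constant()]).
#' @param corr_max Threshold (default 0.95).
#' @return The pruned cohort; removed ids in attribute `"dropped"`.
#' @export
prune_correlated <- function(cohort, corr_max = 0.95) {
  validate_cohort(cohort)
  d <- cohort$dosages
  v <- apply(d, 2, stats::var, na.rm = TRUE)
  if (any(is.na(v) | v == 0)) {
    stop("zero-variance column(s) make correlation undefined: ",
         paste(utils::head(cohort$snps$snp_id[is.na(v) | v == 0], 5),
               collapse = ", "),
         "; run drop_near_constant() first")
  }
  drop <- rep(FALSE, ncol(d))
  for (ch in unique(cohort$snps$chrom)) {
    cols <- which(cohort$snps$chrom == ch)
    cols <- cols[order(cohort$snps$pos[cols], cols)]
    retained <- integer(0)
    for (j in cols) {
      if (length(retained)) {
        r <- suppressWarnings(
          stats::cor(d[, retained, drop = FALSE], d[, j],
                     use = "pairwise.complete.obs"))
        if (any(abs(r) > corr_max, na.rm = TRUE)) {
          drop[j] <- TRUE
          next
        }
      }
      retained <- c(retained, j)
    }
  }
  out <- cohort[, which(!drop)]
  attr(out, "dropped") <- cohort$snps$snp_id[drop]
  out
}
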