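cohort_xy <- function(cohort, panel) {
  idx <- match(panel, cohort$snps$snp_id)
  if (anyNA(idx)) {
    stop("feature mismatch: SNP(s) not in cohort: ",
         paste(utils::head(panel[is.na(idx)], 5), collapse = ", "))
  }
  x <- cohort$dosages[, idx, drop = FALSE]
  if (anyNA(x)) stop("cohort has missing dosages; impute before evaluation")
  colnames(x) <- panel
  list(x = x, y = cohort$phenotype)
}

#' Stratified k-fold cross-validated metrics for one classifier
#'
#' Stratified folds preserve the case:control ratio within one sample per
#' fold. Metrics are computed on each held-out fold at the 0.5 probability
#' threshold and averaged across folds.
#'
#' @param train A fully imputed [genotype_cohort()].
#' @param panel Character vector of SNP ids used as features.
#' @param classifier One of [classifier_ids()].
#' @param folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and classifier randomness.
#' @param num_trees Trees for the random forest.
#' @return Named numeric vector of fold-averaged metrics (see
#'   [metric_panel()]).
#' @export
evaluate_cv <- function(train, panel, classifier = "random-forest",
                        folds = 5, seed = 1L, num_trees = 100) {
  stopifnot(folds >= 2)
  dat <- cohort_xy(train, panel)
  fold <- stratified_folds(dat$y, folds, seed = seed)
  per_fold <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    m <- fit_classifier(dat$x[tr, , drop = FALSE], dat$y[tr], classifier,
                        seed = seed + f, num_trees = num_trees)
    metric_panel(predict_prob(m, dat$x[!tr, , drop = FALSE]), dat$y[!tr])
  }, numeric(6))
  rowMeans(per_fold)
}

#' Train-once/test-once metrics on an unseen cohort
#'
#' The classifier is fitted on the full training cohort and the metric
#' panel is computed on the test cohort at the 0.5 threshold. The test
#' cohort influences nothing about the fit.
#'
#' @param train,test Fully imputed [genotype_cohort()]s sharing the panel.
#' @inheritParams evaluate_cv
#' @return Named numeric vector of metrics (see [metric_panel()]).
#' @export
evaluate_test <- function(train, test, panel, classifier = "random-forest",
                          seed = 1L, num_trees = 100) {
  tr <- cohort_xy(train, panel)
  te <- cohort_xy(test, panel)
  m <- fit_classifier(tr$x, tr$y, classifier, seed = seed,
                      num_trees = num_trees)
  metric_panel(predict_prob(m, te$x), te$y)
}

#' Null AUC distribution from randomly sampled SNP panels
#'
#' Each iteration samples `panel_size` SNPs *with replacement* from the
#' pool (duplicated SNPs are retained as duplicate feature columns), fits
#' the classifier on the training cohort, and records the AUC on the test
#' cohort. The resulting distribution is the reference against which the
#' selected panel's performance is judged a non-random occurrence.
#'
#' @param train,test Fully imputed [genotype_cohort()]s.
#' @param pool Character vector of candidate SNP ids (defaults to all SNPs
#'   in `train`).
#' @param panel_size SNPs drawn per iteration (default 9).
#' @param n_iterations Number of random panels (default 1000).
#' @param classifier One of [classifier_ids()].
#' @param bin_width Histogram bin width for the summary (default 0.01).
#' @param seed Integer seed.
#' @param num_trees Trees for the random forest.
#' @return Object of class `null_distribution`: `auc_values`, `histogram`
#'   (data frame of `bin_start`, `count`), `panel_size`, `n_iterations`,
#'   `bin_width`.
#' @export
random_panel_null <- function(train, test, pool = train$snps$snp_id,
                              panel_size = 9, n_iterations = 1000,
                              classifier = "random-forest",
                              bin_width = 0.01, seed = 1L, num_trees = 100) {
  if (length(pool) < panel_size) {
    stop("pool smaller than panel_size")
  }
  tr_idx <- match(pool, train$snps$snp_id)
  te_idx <- match(pool, test$snps$snp_id)
  if (anyNA(tr_idx) || anyNA(te_idx)) {
    stop("pool SNP(s) absent from train or test cohort")
  }
  Xtr <- train$dosages[, tr_idx, drop = FALSE]
  Xte <- test$dosages[, te_idx, drop = FALSE]
  if (anyNA(Xtr) || anyNA(Xte)) {
    stop("cohorts have missing dosages; impute before evaluation")
  }
  set.seed(seed)
  aucs <- vapply(seq_len(n_iterations), function(it) {
    cols <- sample.int(length(pool), panel_size, replace = TRUE)
    # classifier seed fixed across iterations: each iteration's AUC is a
    # deterministic function of the drawn panel
    m <- fit_classifier(Xtr[, cols, drop = FALSE], train$phenotype,
                        classifier, seed = seed, num_trees = num_trees)
    compute_auc(predict_prob(m, Xte[, cols, drop = FALSE]), test$phenotype)
  }, numeric(1))
  bins <- floor(aucs / bin_width) * bin_width
  hist_df <- as.data.frame(table(factor(sprintf("%.6f", bins))),
                           stringsAsFactors = FALSE)
  names(hist_df) <- c("bin_start", "count")
  hist_df$bin_start <- as.numeric(hist_df$bin_start)
  structure(list(auc_values = aucs, histogram = hist_df,
                 panel_size = panel_size, n_iterations = n_iterations,
                 bin_width = bin_width),
            class = "null_distribution")
}

#' @exportS3Method base::print
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$n_iterations, " random panels of ",
      x$panel_size, " SNPs\n", sep = "")
  cat(sprintf("  AUC mean %.3f, sd %.3f, max %.3f\n",
              mean(x$auc_values), stats::sd(x$auc_values),
              max(x$auc_values)))
  invisible(x)
}
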