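#' Plan for stratified resampled training subsets
#'
#' Feature selection is run independently on several resampled subsets of
#' the training cohort and only features selected in *every* subset are
#' kept, so that the final panel is stable against sample-size variation.
#' The default plan draws eight subsets, with replacement, stratified on
#' the phenotype, at sample fractions evenly spaced from 0.5 to 1.0 of the
#' training cohort.
#'
#' @param n_subsets Number of subsets (>= 2).
#' @param size_fractions Per-subset sample fraction of the training cohort.
#' @param stratified Stratify the draw on phenotype (default `TRUE`).
#' @param with_replacement Sample with replacement (default `TRUE`).
#' @param seed Integer seed.
#' @return An object of class `subset_plan`.
#' @export
subset_plan <- function(n_subsets = 8,
                        size_fractions = seq(0.5, 1.0,
                                             length.out = n_subsets),
                        stratified = TRUE, with_replacement = TRUE,
                        seed = 1L) {
  if (n_subsets < 2) stop("n_subsets must be at least 2")
  if (length(size_fractions) != n_subsets) {
    stop("size_fractions must have one entry per subset")
  }
  if (any(size_fractions <= 0 | size_fractions > 1)) {
    stop("size_fractions must lie in (0, 1]")
  }
  structure(list(n_subsets = as.integer(n_subsets),
                 size_fractions = size_fractions, stratified = stratified,
                 with_replacement = with_replacement,
                 seed = as.integer(seed)),
            class = "subset_plan")
}

#' Draw the resampled training subsets
#'
#' Each subset is drawn at its size fraction by stratified sampling (class
#' counts are `round(fraction * n_class)`, preserving the class proportion
#' within rounding), with replacement by default. Reproducible under the
#' plan's seed.
#'
#' @param train A [genotype_cohort()] containing both classes.
#' @param plan A [subset_plan()].
#' @return List of `genotype_cohort`s, one per subset.
#' @export
make_subsets <- function(train, plan = subset_plan()) {
  validate_cohort(train)
  stopifnot(inherits(plan, "subset_plan"))
  if (length(unique(train$phenotype)) < 2) {
    stop("training cohort must contain both classes")
  }
  set.seed(plan$seed)
  lapply(seq_len(plan$n_subsets), function(s) {
    f <- plan$size_fractions[s]
    idx <- if (plan$stratified) {
      unlist(lapply(c(1L, 0L), function(cls) {
        pool <- which(train$phenotype == cls)
        size <- round(f * length(pool))
        if (size == 0) {
          stop("degenerate subset: class ", cls, " empty at fraction ", f)
        }
        sample(pool, size, replace = plan$with_replacement)
      }))
    } else {
      size <- max(1L, round(f * length(train$samples)))
      sample(seq_along(train$samples), size,
             replace = plan$with_replacement)
    }
    sub <- train[idx, ]
    if (length(unique(sub$phenotype)) < 2) {
      stop("degenerate subset: only one class drawn")
    }
    sub
  })
}

# Recursive-elimination path: starting from all features, repeatedly drop
# the lowest-importance `step` fraction (at least one feature) down to
# `min_features`. Returns the shared grid of feature counts.
rfe_counts <- function(p, step, min_features) {
  counts <- integer(0)
  n <- p
  while (n > min_features) {
    counts <- c(counts, n)
    n <- n - max(1L, as.integer(floor(step * n)))
    if (n < min_features) n <- min_features
  }
  c(counts, min_features)
}

#' Recursive feature elimination with cross-validation (RFECV)
#'
#' A random-forest estimator is used throughout. For each cross-validation
#' fold, an elimination path is run on the fold's training part: the forest
#' is fitted, the held-out AUC is recorded at the current feature count,
#' and the lowest-importance `step` fraction of features is dropped; the
#' path continues down to `min_features`. A final elimination on the full
#' subset down to the CV-optimal count yields the selected features and
#' their impurity importances (normalised to sum to 1).
#'
#' Two rules locate the CV-optimal count. `"liberal"` (the default) picks
#' the *largest* count whose mean held-out AUC lies within one standard
#' error of the maximum: each subset's selection is deliberately
#' recall-oriented, because the final panel is the across-subset
#' intersection, which restores precision — dropping a weakly important
#' feature here is irreversible, while a noise feature admitted here still
#' has to survive every other subset. `"max"` is the classic parsimonious
#' rule: the smallest count attaining the maximal mean AUC.
#'
#' @param subset A fully imputed [genotype_cohort()] with >= 2 SNPs.
#' @param cv_folds Stratified CV folds (default 5).
#' @param step Fraction of remaining features dropped per round
#'   (default 0.1, floor of one feature).
#' @param min_features Smallest feature count on the path.
#' @param num_trees Trees per forest (default 100).
#' @param rule CV-optimum rule, `"liberal"` or `"max"` (see Details).
#' @param seed Integer seed.
#' @return List with `selected` (SNP ids, ordered by decreasing
#'   importance, ties broken by id), `importance` (named, sums to 1),
#'   `cv_curve` (data frame `n_features`, `mean_auc`), `optimal_count`.
#' @export
rfecv_select <- function(subset, cv_folds = 5, step = 0.1,
                         min_features = 1, num_trees = 100,
                         rule = c("liberal", "max"), seed = 1L) {
  rule <- match.arg(rule)
  dat <- cohort_xy(subset, subset$snps$snp_id)
  p <- ncol(dat$x)
  if (p == 1) {
    return(list(selected = colnames(dat$x),
                importance = stats::setNames(1, colnames(dat$x)),
                cv_curve = data.frame(n_features = 1L, mean_auc = NA_real_),
                optimal_count = 1L))
  }
  if (length(dat$y) < cv_folds) {
    stop("cv configuration error: fewer samples than folds")
  }
  counts <- rfe_counts(p, step, min_features)
  fold <- stratified_folds(dat$y, cv_folds, seed = seed)

  run_path <- function(x_tr, y_tr, x_te, y_te, seed_base) {
    feats <- seq_len(ncol(x_tr))
    score <- rep(NA_real_, length(counts))
    for (k in seq_along(counts)) {
      m <- ranger::ranger(x = as.data.frame(x_tr[, feats, drop = FALSE]),
                          y = factor(y_tr, levels = 0:1),
                          probability = TRUE, importance = "impurity",
                          num.trees = num_trees, seed = seed_base + k,
                          num.threads = 1)
      if (!is.null(x_te)) {
        pr <- stats::predict(
          m, data = as.data.frame(x_te[, feats, drop = FALSE]))$predictions[, "1"]
        score[k] <- compute_auc(pr, y_te)
      }
      if (k == length(counts)) break
      imp <- m$variable.importance
      keep_n <- counts[k + 1]
      ord <- order(-imp, colnames(x_tr)[feats])   # deterministic ties
      feats <- feats[ord[seq_len(keep_n)]]
    }
    list(score = score, feats = feats)
  }

  fold_scores <- vapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    run_path(dat$x[tr, , drop = FALSE], dat$y[tr],
             dat$x[!tr, , drop = FALSE], dat$y[!tr],
             seed_base = seed * 1000 + f * 100)$score
  }, numeric(length(counts)))
  mean_auc <- rowMeans(fold_scores)
  best_k <- which.max(mean_auc)
  if (rule == "max") {
    optimal <- min(counts[mean_auc >= mean_auc[best_k] - 1e-12])
  } else {
    se_best <- stats::sd(fold_scores[best_k, ]) / sqrt(cv_folds)
    optimal <- max(counts[mean_auc >= mean_auc[best_k] - se_best])
  }

  # final elimination on the full subset down to the optimal count
  feats <- seq_len(p)
  final_model <- NULL
  for (k in seq_along(counts)) {
    m <- ranger::ranger(x = as.data.frame(dat$x[, feats, drop = FALSE]),
                        y = factor(dat$y, levels = 0:1),
                        probability = TRUE, importance = "impurity",
                        num.trees = num_trees, seed = seed * 1000 + k,
                        num.threads = 1)
    if (counts[k] == optimal) { final_model <- m; break }
    imp <- m$variable.importance
    ord <- order(-imp, colnames(dat$x)[feats])
    feats <- feats[ord[seq_len(counts[k + 1])]]
  }
  imp <- final_model$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    stats::setNames(rep(1 / length(imp), length(imp)), names(imp))
  ord <- order(-imp, names(imp))
  list(selected = names(imp)[ord],
       importance = imp[ord],
       cv_curve = data.frame(n_features = counts, mean_auc = mean_auc),
       optimal_count = optimal)
}

#' Intersect per-subset selections into the stable panel
#'
#' The common panel is the exact intersection of all subsets' selected
#' sets, ordered by decreasing mean importance (averaged over all subsets;
#' every member of the intersection has an importance in every subset),
#' ties broken by SNP id. An empty intersection is a warning, not an
#' error.
#'
#' @param per_subset List (length >= 2) of character vectors of selected
#'   SNP ids.
#' @param importances List of named importance vectors, parallel to
#'   `per_subset`.
#' @return List with `common_panel` (ordered SNP ids) and
#'   `mean_importance` (named).
#' @export
intersect_selections <- function(per_subset, importances) {
  if (length(per_subset) < 2) stop("at least two subset selections required")
  common <- Reduce(intersect, per_subset)
  if (!length(common)) {
    warning("empty intersection: no SNP was selected in every subset")
    return(list(common_panel = character(0),
                mean_importance = stats::setNames(numeric(0), character(0))))
  }
  imp <- vapply(importances, function(v) unname(v[common]),
                numeric(length(common)))
  if (length(common) == 1) imp <- matrix(imp, nrow = 1)
  mean_imp <- stats::setNames(rowMeans(imp), common)
  ord <- order(-mean_imp, common)
  list(common_panel = common[ord], mean_importance = mean_imp[ord])
}

#' Run the full stability-selection pipeline
#'
#' Draws the resampled subsets, runs [rfecv_select()] on each, and
#' intersects the per-subset selections into the stable panel.
#'
#' @param train A fully imputed [genotype_cohort()].
#' @param plan A [subset_plan()].
#' @param ... Passed to [rfecv_select()] (e.g. `num_trees`, `step`).
#' @return Object of class `selection_result`: `per_subset_selected`,
#'   `per_subset_importance`, `common_panel`, `mean_importance`.
#' @export
stability_selection <- function(train, plan = subset_plan(), ...) {
  subsets <- make_subsets(train, plan)
  fits <- lapply(seq_along(subsets), function(s) {
    rfecv_select(subsets[[s]], seed = plan$seed + s, ...)
  })
  inter <- intersect_selections(lapply(fits, `[[`, "selected"),
                                lapply(fits, `[[`, "importance"))
  structure(list(per_subset_selected = lapply(fits, `[[`, "selected"),
                 per_subset_importance = lapply(fits, `[[`, "importance"),
                 common_panel = inter$common_panel,
                 mean_importance = inter$mean_importance),
            class = "selection_result")
}

#' @exportS3Method base::print
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$per_subset_selected),
      " subsets; common panel of ", length(x$common_panel), " SNPs\n",
      sep = "")
  if (length(x$common_panel)) {
    print(round(x$mean_importance, 4))
  }
  invisible(x)
}

#' Minimal panel by stepwise inclusion of ranked features
#'
#' Features are added one at a time in panel order (decreasing mean
#' importance). For each prefix of size `k`, AUC, sensitivity and
#' specificity are recorded under stratified CV on the training cohort and
#' on every test cohort. The minimal panel size is the smallest `k` at
#' which every recorded metric on every evaluation set meets or exceeds
#' its floor; if no `k` qualifies, the full panel is returned with
#' `attained = FALSE`. The deciding classifier is the random forest; the
#' curve is reported for all `k` regardless of where the floors are met.
#'
#' @param train A fully imputed [genotype_cohort()].
#' @param tests List of test `genotype_cohort`s.
#' @param ordered_panel SNP ids in decreasing importance order.
#' @param thresholds Named metric floors (default 0.9 for `auc`,
#'   `sensitivity`, `specificity`).
#' @param classifier Deciding classifier id.
#' @param folds CV folds on the training cohort.
#' @param seed Integer seed.
#' @param num_trees Trees for forest classifiers.
#' @return List with `minimal_k`, `attained`, and `curve` (data frame:
#'   `k`, `dataset`, `auc`, `sensitivity`, `specificity`).
#' @export
stepwise_minimal_panel <- function(train, tests, ordered_panel,
                                   thresholds = c(auc = 0.9,
                                                  sensitivity = 0.9,
                                                  specificity = 0.9),
                                   classifier = "random-forest", folds = 5,
                                   seed = 1L, num_trees = 100) {
  if (!length(ordered_panel)) stop("ordered_panel must be non-empty")
  if (any(thresholds < 0 | thresholds >= 1)) {
    stop("thresholds must lie in [0, 1)")
  }
  keep <- c("auc", "sensitivity", "specificity")
  rows <- list()
  ok_k <- logical(length(ordered_panel))
  for (k in seq_along(ordered_panel)) {
    panel_k <- ordered_panel[seq_len(k)]
    mets <- list(`training-cv` = evaluate_cv(train, panel_k, classifier,
                                             folds = folds, seed = seed,
                                             num_trees = num_trees)[keep])
    for (t in seq_along(tests)) {
      mets[[paste0("test", t)]] <-
        evaluate_test(train, tests[[t]], panel_k, classifier, seed = seed,
                      num_trees = num_trees)[keep]
    }
    ok_k[k] <- all(vapply(mets, function(m) {
      all(m[names(thresholds)] >= thresholds)
    }, logical(1)))
    for (nm in names(mets)) {
      rows[[length(rows) + 1]] <- data.frame(
        k = k, dataset = nm, t(mets[[nm]]), stringsAsFactors = FALSE)
    }
  }
  curve <- do.call(rbind, rows)
  attained <- any(ok_k)
  list(minimal_k = if (attained) min(which(ok_k)) else length(ordered_panel),
       attained = attained, curve = curve)
}
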