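#' Fit an iterative model-based genotype imputer on training data
#'
#' Chained-equations imputation: missing dosages are initialised at the
#' column mean, then each column in turn is regressed (ridge regression
#' with a near-zero penalty, i.e. numerically stabilised least squares) on
#' its most-correlated companion columns, and the column's missing entries
#' are replaced by the regression's predictions. The round-robin sweep is
#' repeated until the largest imputed-value change falls below `tol` or
#' `max_iter` sweeps have run. A regression model is stored for *every*
#' column, so the fitted imputer can later fill missingness anywhere in an
#' unseen cohort over the same SNP panel. The model is a plain list and is
#' serialisable with `saveRDS()`.
#'
#' Imputed values are clipped to the dosage range `[0, 2]`. Observed
#' entries are never modified.
#'
#' @param train A [genotype_cohort()] (post-filter training partition);
#'   every column must have at least one observed entry.
#' @param n_predictors Number of companion columns (ranked by absolute
#'   Pearson correlation on the mean-initialised matrix) used as regressors
#'   for each column.
#' @param max_iter Maximum round-robin sweeps.
#' @param tol Convergence tolerance on the largest absolute change of any
#'   imputed entry between sweeps.
#' @param ridge Ridge penalty added to the normal equations (kept near zero
#'   so deterministic linear relations are recovered exactly).
#' @return An object of class `imputation_model`.
#' @export
fit_imputer <- function(train, n_predictors = 20, max_iter = 10,
                        tol = 1e-3, ridge = 1e-8) {
  validate_cohort(train)
  X <- train$dosages
  p <- ncol(X)
  obs <- !is.na(X)
  if (any(colSums(obs) == 0)) {
    stop("unimputable column(s) with zero observed entries: ",
         paste(utils::head(train$snps$snp_id[colSums(obs) == 0], 5),
               collapse = ", "))
  }
  means <- colMeans(X, na.rm = TRUE)
  Xc <- X
  for (j in seq_len(p)) Xc[!obs[, j], j] <- means[j]

  k <- min(n_predictors, p - 1L)
  preds <- vector("list", p)
  if (k > 0 && p > 1) {
    cm <- suppressWarnings(stats::cor(Xc))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    for (j in seq_len(p)) {
      preds[[j]] <- order(-abs(cm[, j]), seq_len(p))[seq_len(k)]
    }
  } else {
    for (j in seq_len(p)) preds[[j]] <- integer(0)
  }

  coefs <- vector("list", p)
  has_missing <- which(colSums(!obs) > 0)
  n_sweeps <- 0L
  for (iter in seq_len(max_iter)) {
    n_sweeps <- iter
    max_change <- 0
    for (j in seq_len(p)) {
      pj <- preds[[j]]
      rows <- obs[, j]
      if (!length(pj) || sum(rows) < 2) {
        coefs[[j]] <- c(means[j], rep(0, length(pj)))
      } else {
        A <- cbind(1, Xc[rows, pj, drop = FALSE])
        y <- X[rows, j]
        AtA <- crossprod(A) + diag(c(0, rep(ridge, length(pj))))
        b <- tryCatch(solve(AtA, crossprod(A, y)),
                      error = function(e) {
                        solve(AtA + diag(1e-6, ncol(A)), crossprod(A, y))
                      })
        coefs[[j]] <- as.vector(b)
      }
      if (j %in% has_missing) {
        miss <- !obs[, j]
        fit <- coefs[[j]][1] +
          if (length(pj)) Xc[miss, pj, drop = FALSE] %*% coefs[[j]][-1] else 0
        fit <- pmin(2, pmax(0, as.vector(fit)))
        max_change <- max(max_change, abs(fit - Xc[miss, j]))
        Xc[miss, j] <- fit
      }
    }
    if (!length(has_missing) || max_change < tol) break
  }

  structure(list(snp_ids = train$snps$snp_id, means = means,
                 predictors = preds, coefs = coefs,
                 n_sweeps = n_sweeps, tol = tol),
            class = "imputation_model")
}

#' Apply a fitted imputer to a cohort
#'
#' Initialises missing entries at the training means and runs the fitted
#' per-column regressions round-robin for the same number of sweeps used in
#' fitting. No quantity is re-estimated from the target cohort: the
#' train/test firewall holds by construction. Observed entries are
#' unchanged and the result has no missing values.
#'
#' @param model An `imputation_model` from [fit_imputer()].
#' @param cohort A [genotype_cohort()] over exactly the model's SNP panel.
#' @return The cohort with all missing dosages imputed (values in `[0, 2]`,
#'   possibly fractional).
#' @export
apply_imputer <- function(model, cohort) {
  stopifnot(inherits(model, "imputation_model"))
  validate_cohort(cohort)
  if (!identical(cohort$snps$snp_id, model$snp_ids)) {
    only_model <- setdiff(model$snp_ids, cohort$snps$snp_id)
    only_cohort <- setdiff(cohort$snps$snp_id, model$snp_ids)
    if (length(only_model) || length(only_cohort)) {
      stop("feature mismatch between imputer and cohort; model-only: {",
           paste(utils::head(only_model, 5), collapse = ", "),
           "}, cohort-only: {",
           paste(utils::head(only_cohort, 5), collapse = ", "), "}")
    }
    stop("cohort SNP order differs from the imputer's training panel")
  }
  X <- cohort$dosages
  obs <- !is.na(X)
  if (all(obs)) return(cohort)
  Xc <- X
  for (j in seq_len(ncol(X))) Xc[!obs[, j], j] <- model$means[j]
  for (iter in seq_len(model$n_sweeps)) {
    for (j in which(colSums(!obs) > 0)) {
      pj <- model$predictors[[j]]
      miss <- !obs[, j]
      fit <- model$coefs[[j]][1] +
        if (length(pj)) Xc[miss, pj, drop = FALSE] %*% model$coefs[[j]][-1] else 0
      Xc[miss, j] <- pmin(2, pmax(0, as.vector(fit)))
    }
  }
  out <- cohort
  out$dosages <- Xc
  out
}
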