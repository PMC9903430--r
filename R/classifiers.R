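#' The five supported classifier identifiers
#' @return Character vector of classifier ids.
#' @export
classifier_ids <- function() {
  c("logistic-regression", "naive-bayes", "random-forest",
    "gradient-boosted-trees", "svm-rbf")
}

#' Fit one of the five supported classifiers
#'
#' A thin uniform wrapper around the engines used throughout the package:
#' `stats::glm` (L2-free logistic regression), `e1071::naiveBayes`
#' (Gaussian naive Bayes), `ranger::ranger` (probability forest, 100
#' trees), `xgboost::xgb.train` (100 rounds, depth 3, learning rate 0.3,
#' logistic objective) and `e1071::svm` (RBF kernel with the default
#' bandwidth heuristic and cross-validated probability calibration).
#' Feature columns are positional: predictions require a matrix with the
#' same columns in the same order.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Binary 0/1 labels.
#' @param classifier One of [classifier_ids()].
#' @param seed Integer seed for the stochastic engines.
#' @param num_trees Trees for the random forest.
#' @return An object of class `mlprs_model`.
#' @export
fit_classifier <- function(x, y, classifier = "random-forest", seed = 1L,
                           num_trees = 100) {
  if (!classifier %in% classifier_ids()) {
    stop("unknown classifier id '", classifier, "'; expected one of: ",
         paste(classifier_ids(), collapse = ", "))
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  features <- colnames(x)
  colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))   # duplicate-safe
  fit <- switch(
    classifier,
    "logistic-regression" = {
      df <- data.frame(.y = y, x)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    "naive-bayes" = e1071::naiveBayes(as.data.frame(x), factor(y, levels = 0:1)),
    "random-forest" = ranger::ranger(
      x = as.data.frame(x), y = factor(y, levels = 0:1), probability = TRUE,
      num.trees = num_trees, min.node.size = 1, seed = seed,
      num.threads = 1),
    "gradient-boosted-trees" = {
      set.seed(seed)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y), nrounds = 100,
        verbose = 0)
    },
    "svm-rbf" = {
      set.seed(seed)
      e1071::svm(x, factor(y, levels = 0:1), kernel = "radial",
                 probability = TRUE)
    })
  structure(list(fit = fit, classifier = classifier, features = features,
                 n_features = ncol(x)),
            class = "mlprs_model")
}

#' Predicted case probabilities from a fitted classifier
#'
#' @param model An `mlprs_model` from [fit_classifier()].
#' @param newx Feature matrix with the model's columns, in order.
#' @return Numeric vector of `P(case)` per row.
#' @export
predict_prob <- function(model, newx) {
  stopifnot(inherits(model, "mlprs_model"))
  newx <- as.matrix(newx)
  if (ncol(newx) != model$n_features) {
    stop("feature mismatch: model expects ", model$n_features,
         " columns, got ", ncol(newx))
  }
  colnames(newx) <- sprintf("f%03d", seq_len(ncol(newx)))
  switch(
    model$classifier,
    "logistic-regression" =
      as.vector(stats::predict(model$fit, newdata = as.data.frame(newx),
                               type = "response")),
    "naive-bayes" = {
      pr <- stats::predict(model$fit, as.data.frame(newx), type = "raw",
                           eps = 1e-12)
      as.vector(pr[, "1"])
    },
    "random-forest" =
      as.vector(stats::predict(model$fit,
                               data = as.data.frame(newx))$predictions[, "1"]),
    "gradient-boosted-trees" =
      as.vector(stats::predict(model$fit, xgboost::xgb.DMatrix(newx))),
    "svm-rbf" = {
      pr <- attr(stats::predict(model$fit, newx, probability = TRUE),
                 "probabilities")
      as.vector(pr[, "1"])
    })
}
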