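model_predict_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "mlprs_model")) {
    return(function(newx) predict_prob(model, newx))
  }
  stop("model must be an mlprs_model or a function(newx) -> numeric")
}

#' Exact Shapley feature attributions by coalition enumeration
#'
#' For one sample's prediction, the Shapley value of feature `i` averages
#' its marginal contribution over all `2^(k-1)` coalitions of the other
#' features. A coalition's value is the model output with in-coalition
#' features fixed at the sample's dosages and the remaining features
#' marginalised by averaging the output over the reference cohort's rows
#' (interventional expectation). The baseline is the value of the empty
#' coalition, and efficiency -- baseline plus the sum of contributions
#' equals the model's prediction for the sample -- holds to numerical
#' precision by construction.
#'
#' @param model An `mlprs_model`, or any `function(newx) -> numeric` giving
#'   model output per row of a feature matrix.
#' @param x Numeric vector: the sample's feature values (length `k <= 16`).
#' @param reference Numeric matrix (rows = background samples, `k`
#'   columns) used to marginalise absent features.
#' @return Object of class `shapley_attribution`: `contributions` (named
#'   if `x` is), `baseline`, `prediction`.
#' @export
shapley_exact <- function(model, x, reference) {
  f <- model_predict_fun(model)
  nm <- names(x)
  x <- as.numeric(unlist(x))
  names(x) <- nm
  reference <- as.matrix(reference)
  k <- length(x)
  if (ncol(reference) != k) stop("reference must have length(x) columns")
  if (k > 16) {
    stop("combinatorial limit: exact enumeration supports at most 16 ",
         "features (2^k coalitions); use a sampling approximation")
  }
  m <- nrow(reference)
  n_coal <- 2L^k
  # one prediction call over all coalitions x reference rows
  big <- matrix(0, n_coal * m, k)
  member <- matrix(FALSE, n_coal, k)
  for (s in 0:(n_coal - 1L)) {
    inset <- bitwAnd(s, bitwShiftL(1L, 0:(k - 1L))) != 0L
    member[s + 1L, ] <- inset
    block <- reference
    block[, inset] <- rep(x[inset], each = m)
    big[s * m + seq_len(m), ] <- block
  }
  v <- rowsum(f(big), rep(seq_len(n_coal), each = m)) / m
  v <- as.vector(v)

  sizes <- rowSums(member)
  w <- exp(lfactorial(0:(k - 1)) + lfactorial(k - 1 - (0:(k - 1))) -
             lfactorial(k))
  phi <- numeric(k)
  for (i in seq_len(k)) {
    without <- which(!member[, i])
    with_i <- without + bitwShiftL(1L, i - 1L)
    phi[i] <- sum(w[sizes[without] + 1] * (v[with_i] - v[without]))
  }
  names(phi) <- names(x)
  structure(list(contributions = phi, baseline = v[1],
                 prediction = v[n_coal]),
            class = "shapley_attribution")
}

#' Monte-Carlo Shapley attributions by permutation sampling
#'
#' Castro-style estimator: feature contributions are averaged marginal
#' gains along random feature orderings, with absent features marginalised
#' over the reference cohort exactly as in [shapley_exact()]. Returned
#' standard errors are per-feature across permutations. Serves as an
#' independent stochastic cross-check of the exact enumeration.
#'
#' @inheritParams shapley_exact
#' @param n_perm Number of random permutations.
#' @param seed Integer seed.
#' @return List with `contributions`, `se`, `n_perm`.
#' @export
shapley_sampling <- function(model, x, reference, n_perm = 200, seed = 1L) {
  f <- model_predict_fun(model)
  nm <- names(x)
  x <- as.numeric(unlist(x))
  names(x) <- nm
  reference <- as.matrix(reference)
  k <- length(x)
  m <- nrow(reference)
  set.seed(seed)
  gains <- matrix(0, n_perm, k)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(k)
    block <- reference
    prev <- mean(f(block))
    for (i in ord) {
      block[, i] <- x[i]
      cur <- mean(f(block))
      gains[p, i] <- cur - prev
      prev <- cur
    }
  }
  list(contributions = stats::setNames(colMeans(gains), names(x)),
       se = stats::setNames(apply(gains, 2, stats::sd) / sqrt(n_perm),
                            names(x)),
       n_perm = n_perm)
}
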