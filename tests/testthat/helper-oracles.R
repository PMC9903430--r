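# Independent oracles used to cross-check package implementations.

# Exact Hardy-Weinberg test by direct full enumeration: probabilities of
# every feasible heterozygote count from the log-factorial formula
#   P(het | n, n_rare) = n! / (hom_r! het! hom_c!) * 2^het *
#                        n_rare! (2n - n_rare)! / (2n)!
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

# AUC by exhaustive case-control pair counting (ties score 1/2)
auc_pair_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  total <- 0
  for (a in cs) for (b in ct) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(cs) * length(ct))
}

# Univariate logistic MLE from a 2x3 genotype-by-phenotype count table,
# by direct likelihood maximisation over (intercept, slope) with optim --
# independent of stats::glm's IRLS path.
logistic_table_oracle <- function(tab) {
  doses <- c(0, 1, 2)
  negll <- function(par) {
    eta <- par[1] + par[2] * doses
    -sum(tab["case", ] * stats::plogis(eta, log.p = TRUE) +
           tab["control", ] * stats::plogis(-eta, log.p = TRUE))
  }
  opt <- stats::optim(c(0, 0), negll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  opt$par[2]
}

# expand a 2x3 count table into per-sample dosage/label vectors
table_to_samples <- function(tab) {
  list(g = c(rep(c(0, 1, 2), tab["control", ]),
             rep(c(0, 1, 2), tab["case", ])),
       y = rep(c(0, 1), times = rowSums(tab)))
}
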