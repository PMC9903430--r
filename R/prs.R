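#' Univariate logistic effect sizes for a SNP panel
#'
#' One logistic regression per SNP (phenotype on alt-allele dosage, no
#' covariates, additive coding) on the training cohort, yielding the
#' per-allele log-odds used as PRS weights, with Wald standard errors and
#' p-values. A negative log-odds marks a protective allele, a positive one
#' a risk allele. Perfectly or quasi-separated SNPs (plausible at very
#' large effects) are refitted with Jeffreys-prior penalised likelihood
#' (Firth correction) and flagged, with a warning.
#'
#' @param train A fully imputed [genotype_cohort()].
#' @param panel Character vector of SNP ids.
#' @return Data frame of class `effect_size_table`: `snp_id`, `beta`,
#'   `se`, `p_value`, `direction` (`"protective"`/`"risk"`), `separation`.
#' @export
estimate_effect_sizes <- function(train, panel) {
  dat <- cohort_xy(train, panel)
  y <- dat$y
  rows <- lapply(seq_along(panel), function(j) {
    g <- dat$x[, j]
    fit <- suppressWarnings(stats::glm(y ~ g, family = stats::binomial()))
    beta <- stats::coef(fit)[["g"]]
    se <- sqrt(stats::vcov(fit)["g", "g"])
    separated <- !fit$converged || abs(beta) > 15 || se > 50 || is.na(se)
    if (separated) {
      ff <- firth_logistic(g, y)
      beta <- ff$beta; se <- ff$se
    }
    data.frame(snp_id = panel[j], beta = beta, se = se,
               p_value = 2 * stats::pnorm(-abs(beta / se)),
               direction = if (beta < 0) "protective" else "risk",
               separation = separated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$separation)) {
    warning("separation detected for SNP(s) ",
            paste(out$snp_id[out$separation], collapse = ", "),
            "; Firth penalised estimates reported")
  }
  class(out) <- c("effect_size_table", "data.frame")
  out
}

# Firth-penalised univariate logistic regression (intercept + slope):
# Newton iterations on the Jeffreys-prior-adjusted score
# U*(b) = X'(y - mu + h (1/2 - mu)), h = hat diagonal.
firth_logistic <- function(g, y, max_iter = 100, tol = 1e-10) {
  X <- cbind(1, g)
  beta <- c(stats::qlogis(mean(pmin(pmax(y, 0.05), 0.95))), 0)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    inv <- solve(info)
    h <- w * rowSums((X %*% inv) * X)
    score <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- inv %*% score
    # damped step for stability at extreme effects
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + as.vector(delta)
    if (max(abs(delta)) < tol) break
  }
  list(beta = beta[2], se = sqrt(inv[2, 2]))
}

#' Compute missingness-normalized polygenic risk scores
#'
#' For sample `j`, the score is `sum_i S_i * G_ij / (P * M_j)`: the
#' effect-size-weighted dosage sum over the *non-missing* panel SNPs,
#' divided by the ploidy (`P = 2`) times the count of non-missing panel
#' SNPs (`M_j`). Normalising by `M_j` rather than the panel size prevents
#' samples with missing genotypes from being pushed towards spuriously low
#' risk. A sample with no non-missing panel SNP is flagged unscorable
#' (`NA` score), never assigned zero.
#'
#' @param cohort A [genotype_cohort()] containing the panel SNPs.
#' @param effects An `effect_size_table` (or data frame with `snp_id`,
#'   `beta`).
#' @param allow_missing If `FALSE`, missing panel dosages are an error.
#' @param ploidy Ploidy `P` (2 for humans).
#' @return Data frame of class `prs_scores`: `sample_id`, `score`,
#'   `m_nonmissing`, `unscorable`.
#' @export
compute_prs <- function(cohort, effects, allow_missing = TRUE, ploidy = 2) {
  validate_cohort(cohort)
  idx <- match(effects$snp_id, cohort$snps$snp_id)
  if (anyNA(idx)) {
    stop("panel SNP(s) absent from cohort: ",
         paste(utils::head(effects$snp_id[is.na(idx)], 5), collapse = ", "))
  }
  G <- cohort$dosages[, idx, drop = FALSE]
  if (!allow_missing && anyNA(G)) {
    stop("missing panel dosages with allow_missing = FALSE")
  }
  m <- rowSums(!is.na(G))
  contrib <- sweep(G, 2, effects$beta, `*`)
  num <- rowSums(contrib, na.rm = TRUE)
  score <- ifelse(m > 0, num / (ploidy * m), NA_real_)
  out <- data.frame(sample_id = cohort$samples, score = score,
                    m_nonmissing = m, unscorable = m == 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("prs_scores", "data.frame")
  attr(out, "ploidy") <- ploidy
  out
}

#' Logistic association between PRS and phenotype
#'
#' Univariate logistic regression of the binary label on the score; the
#' p-value is from the likelihood-ratio test of zero slope, which stays
#' well-behaved where the Wald test degenerates under near-separation
#' (complete separation triggers a warning but the LRT value is still
#' reported).
#'
#' @param scores Numeric scores, or a `prs_scores` data frame.
#' @param labels Binary 0/1 labels.
#' @return List with `slope`, `intercept`, `p_value`, and `map` (class
#'   `prs_risk_map`): the fitted score-to-probability logistic map used by
#'   the risk calculator.
#' @export
test_prs_association <- function(scores, labels) {
  if (inherits(scores, "prs_scores")) scores <- scores$score
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  fit <- withCallingHandlers(
    stats::glm(labels ~ scores, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warning("complete or quasi-complete separation of PRS; ",
                "likelihood-ratio p-value still reported", call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  p <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                     lower.tail = FALSE)
  cf <- stats::coef(fit)
  if (is.na(cf[2])) cf[2] <- 0     # constant scores: slope inestimable
  map <- structure(list(intercept = unname(cf[1]), slope = unname(cf[2])),
                   class = "prs_risk_map")
  list(slope = unname(cf[2]), intercept = unname(cf[1]), p_value = p,
       map = map)
}

#' Evaluate the PRS as the sole classifier feature
#'
#' Effect sizes must be estimated on the training partition only; scores
#' for every partition are computed from those training-fitted weights.
#' Each classifier is evaluated with stratified CV on the training cohort
#' and train-once/test-once on every test cohort, with the single PRS
#' column as the feature.
#'
#' @param train A fully imputed training [genotype_cohort()].
#' @param tests List of test `genotype_cohort`s.
#' @param effects Training-estimated `effect_size_table`.
#' @param classifiers Character vector of classifier ids (default all
#'   five).
#' @param folds CV folds.
#' @param seed Integer seed.
#' @return Data frame: `classifier`, `dataset`, and the six metric
#'   columns of [metric_panel()].
#' @export
evaluate_prs_as_feature <- function(train, tests, effects,
                                    classifiers = classifier_ids(),
                                    folds = 5, seed = 1L) {
  # dosage containers constrain values to [0, 2]; carry the raw score in a
  # plain matrix instead
  xs <- lapply(c(list(train), tests), function(co) {
    s <- compute_prs(co, effects)
    if (any(s$unscorable)) stop("unscorable sample(s) in cohort")
    list(x = matrix(s$score, ncol = 1, dimnames = list(NULL, "PRS")),
         y = co$phenotype)
  })
  names(xs) <- c("training-cv", paste0("test", seq_along(tests)))
  rows <- list()
  for (cl in classifiers) {
    fold <- stratified_folds(xs[[1]]$y, folds, seed = seed)
    per_fold <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_classifier(xs[[1]]$x[tr, , drop = FALSE], xs[[1]]$y[tr],
                          cl, seed = seed + f)
      metric_panel(predict_prob(m, xs[[1]]$x[!tr, , drop = FALSE]),
                   xs[[1]]$y[!tr])
    }, numeric(6))
    rows[[length(rows) + 1]] <- data.frame(
      classifier = cl, dataset = "training-cv", t(rowMeans(per_fold)),
      stringsAsFactors = FALSE)
    m_full <- fit_classifier(xs[[1]]$x, xs[[1]]$y, cl, seed = seed)
    for (t in seq_along(tests)) {
      mp <- metric_panel(predict_prob(m_full, xs[[t + 1]]$x), xs[[t + 1]]$y)
      rows[[length(rows) + 1]] <- data.frame(
        classifier = cl, dataset = paste0("test", t), t(mp),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-individual risk calculator
#'
#' Computes one individual's PRS from their panel genotypes (missing
#' genotypes allowed; the missingness-normalized formula applies), then
#' maps the score to disease odds and probability through the
#' training-fitted logistic map:
#' `odds = exp(intercept + slope * PRS)`,
#' `probability = odds / (1 + odds)`.
#'
#' @param genotypes Named numeric vector of dosages in `{0, 1, 2, NA}`,
#'   names covering the panel of `effects`.
#' @param effects Training-estimated `effect_size_table`.
#' @param map A `prs_risk_map` from [test_prs_association()] on the
#'   training cohort.
#' @param ploidy Ploidy (2 for humans).
#' @return Object of class `risk_output`: `prs`, `odds`, `probability`,
#'   `contributions` (per-SNP `S_i * G_ij`), `m_nonmissing`.
#' @export
risk_calculator <- function(genotypes, effects, map, ploidy = 2) {
  stopifnot(inherits(map, "prs_risk_map"))
  if (is.null(names(genotypes))) stop("genotypes must be named by SNP id")
  missing_snps <- setdiff(effects$snp_id, names(genotypes))
  if (length(missing_snps)) {
    stop("no genotype supplied for panel SNP(s): ",
         paste(missing_snps, collapse = ", "))
  }
  g <- as.numeric(genotypes[effects$snp_id])
  if (any(!is.na(g) & !(g %in% c(0, 1, 2)))) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  m <- sum(!is.na(g))
  if (m == 0) stop("unscorable: all panel genotypes are missing")
  contrib <- effects$beta * g
  prs <- sum(contrib, na.rm = TRUE) / (ploidy * m)
  eta <- map$intercept + map$slope * prs
  structure(list(prs = prs, odds = exp(eta),
                 probability = stats::plogis(eta),
                 contributions = stats::setNames(contrib, effects$snp_id),
                 m_nonmissing = m),
            class = "risk_output")
}

#' @exportS3Method base::print
print.risk_output <- function(x, ...) {
  cat("<risk_output>\n")
  cat(sprintf("  PRS:         %.6f  (over %d non-missing SNPs)\n",
              x$prs, x$m_nonmissing))
  cat(sprintf("  odds:        %.6f\n", x$odds))
  cat(sprintf("  probability: %.6f\n", x$probability))
  invisible(x)
}
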