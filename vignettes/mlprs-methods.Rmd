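---
title: "Methods: SNP panel selection and polygenic risk scoring in mlprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP panel selection and polygenic risk scoring in mlprs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mlprs` implements a machine-learning pipeline for predicting a binary
disease phenotype from diploid SNP dosages (0/1/2 counts of the alternate
allele), together with a synthetic case/control simulator that makes every
stage testable without access to patient genotypes. This vignette is the
package's account of the science: the models, the tunable parameters, the
numerical choices, and what the synthetic experiments do and do not show.

## Pipeline overview

The analysis follows a strict train/test firewall. A case cohort and a
control cohort are each split into one training and three unseen test
partitions *before any processing*, using largest-remainder apportionment
of fixed fractions so that a fraction vector `c(599, 125, 127, 127)/978`
reproduces partition sizes (599, 125, 127, 127) for 978 samples and
(1673, 349, 355, 355) for 2732 samples, and the case:control ratio is
preserved in every partition. The training partitions are merged on the
SNPs common to both cohorts (keyed by chromosome, position, ref and alt
allele), quality-controlled, imputed, and used for feature selection and
effect-size estimation; the test partitions are touched only by the fitted
imputer and the fitted classifiers.

Stages, each a small set of exported functions:

1. **QC** (`filter_snps`): drop SNPs with minor-allele frequency below 1%,
   genotype missingness above 10%, or an exact Hardy-Weinberg test p-value
   below 0.01. All comparisons are strict, so a SNP exactly at a threshold
   survives. The filters are applied in the order MAF, missingness, HWE;
   the order affects only the report attribution of doubly-failing SNPs,
   not the surviving set (a property test asserts this).
2. **Feature pre-filtering** (`drop_near_constant`, `prune_correlated`):
   remove SNPs whose modal genotype exceeds 90% of samples, then greedily
   prune SNPs correlated above |r| = 0.95 with an earlier-retained SNP on
   the same chromosome, scanning in genomic order (so the first SNP of a
   correlated group is kept — a fixed, documented tie-break; the source
   pipeline retained "one of" each correlated group without naming a rule).
3. **Imputation** (`fit_imputer`/`apply_imputer`): chained-equations
   imputation — each column is regressed on its 20 most-correlated
   companion columns with a numerically stabilised (near-zero ridge)
   linear model, round-robin, iterated until the largest imputed change
   falls below `tol = 1e-3` or 10 sweeps. The fitted per-column models are
   frozen and replayed on test cohorts; nothing is re-estimated from test
   data. Imputed dosages are clipped to [0, 2]; observed entries are never
   modified.
4. **Stability selection** (`stability_selection`): eight stratified
   subsets of the training cohort are drawn with replacement at sample
   fractions 0.5–1.0; recursive feature elimination with cross-validation
   (RFECV, random-forest estimator) runs independently on each; the final
   panel is the *intersection* of the eight selections, ranked by mean
   impurity importance.
5. **Minimal panel** (`stepwise_minimal_panel`): features are added one at
   a time in importance order; the minimal panel is the smallest prefix
   whose AUC, sensitivity and specificity meet 0.9 floors on training CV
   and on every test set simultaneously (the random forest decides; all
   five classifiers can be reported).
6. **Evaluation** (`evaluate_cv`, `evaluate_test`, `random_panel_null`,
   `shapley_exact`): five classifiers — logistic regression, Gaussian
   naive Bayes, random forest, gradient-boosted trees, RBF-kernel SVM —
   under stratified five-fold CV and train-once/test-once evaluation;
   a 1000-iteration random-panel null AUC distribution; exact Shapley
   attributions by coalition enumeration.
7. **PRS** (`estimate_effect_sizes`, `compute_prs`,
   `test_prs_association`, `risk_calculator`): univariate logistic
   effect sizes on the training cohort and a missingness-normalized score
   (below), evaluated as a sole predictor and exposed as a per-individual
   risk calculator.

## The polygenic risk score

For sample $j$ with panel dosages $G_{ij}$ and per-allele log-odds $S_i$
(estimated by univariate logistic regression of phenotype on dosage in the
training partition only):

$$\mathrm{PRS}_j \;=\; \frac{\sum_{i} S_i \, G_{ij}}{P \times M_j},$$

where $P = 2$ is the ploidy and $M_j$ counts the *non-missing* panel SNPs
of sample $j$; the sum runs over those SNPs. Normalising by $M_j$ rather
than the panel size keeps scores of samples with missing genotypes
comparable to fully observed samples instead of deflating them toward low
risk. A sample with no observed panel SNP is flagged unscorable rather
than scored 0. The implementation accepts any panel size; $M_j$ counts the
panel in use.

Per-SNP effect sizes come from `stats::glm` fits; SNPs with complete or
quasi-complete separation (plausible at per-allele log-odds near 7) are
refitted with Jeffreys-prior penalised likelihood (Firth correction, a
small damped-Newton IRLS implemented in the package) and flagged. The
PRS–phenotype association p-value is a likelihood-ratio test of zero
slope, which remains informative where the Wald statistic degenerates
under near-separation. The risk calculator maps a score to odds and
probability through the training-fitted univariate logistic map:
`odds = exp(a + b * PRS)`, `probability = odds / (1 + odds)`.

## The exact Hardy-Weinberg test

`hwe_exact_test` is the exact conditional test: given the observed allele
counts, the probability of every feasible heterozygote count is computed
with a ratio recurrence anchored at the modal configuration (so extreme
configurations underflow harmlessly instead of the anchor overflowing),
and the p-value sums the probabilities of configurations no more probable
than the observed one, with a relative guard of `1e-10` on the inclusion
comparison so that exactly tied configurations are counted. A monomorphic
SNP returns 1 by convention. The test suite checks agreement to `1e-12`
with an independent log-factorial full enumeration for all configurations
up to 200 chromosomes, and at cohort scale (4000 diploids). An exact test
was chosen over the chi-square approximation because exome panels produce
many low minor-allele-count SNPs where the approximation is poor.

## RFECV and the stability intersection

Within one subset, RFECV runs an elimination path per CV fold: fit a
100-tree random forest, record held-out AUC at the current feature count,
drop the lowest-importance 10% of features (at least one), repeat to one
feature. The feature-count grid is shared across folds. Two rules locate
the CV-optimal count:

* `"max"` — the smallest count attaining the maximal mean held-out AUC
  (the classic parsimonious rule);
* `"liberal"` (default) — the *largest* count whose mean AUC lies within
  one standard error of the maximum.

The liberal rule is a deliberate design choice for the stability
architecture: a feature dropped inside one subset is irreversibly lost
from the final panel (the intersection over all eight subsets), whereas a
noise feature admitted by one subset still has to be selected by every
other subset to survive — with selections of ~10% of a 300-SNP pool, the
chance a given noise SNP survives eight independent subsets is of order
$10^{-8}$. Per-subset selection should therefore favour recall and leave
precision to the intersection. Empirically this matters: with the
parsimonious rule, each subset tends to keep 8–9 of 9 simulated causal
SNPs but misses a *different* weak one, and the eight-way intersection
retains only 6–7; the liberal rule recovers 8–9 with no false positives
at the problem sizes used in the test suite.

Importance ties are broken by SNP identifier; the full selection pipeline
is bit-reproducible under a master seed.

## Classifiers and metrics

The five classifiers use widely adopted defaults, all exposed as
arguments: logistic regression (unpenalised `glm`), Gaussian naive Bayes,
random forest (100 trees, `mtry = sqrt(p)`, fully grown trees with
`min.node.size = 1` — the classic randomForest convention; ranger's
probability-forest default of 10 visibly shrinks case probabilities
toward the majority class in imbalanced cohorts), gradient boosting (100
rounds, depth 3, learning rate 0.3), and an RBF SVM with the default
bandwidth heuristic and cross-validated probability calibration.

AUC is the rank statistic (ties counted one half), asserted against
exhaustive pair counting; average precision is the interpolation-free
threshold sum; sensitivity, specificity, accuracy and F1 are computed at
probability threshold 0.5 (the source pipeline never states a threshold;
0.5 is the convention of the scikit-learn `predict` it relied on).
Shapley attributions are exact: all $2^k$ coalitions ($k \le 16$), absent
features marginalised by averaging model output over a reference cohort;
efficiency (baseline + contributions = prediction) holds to numerical
precision by construction and is asserted to `1e-9`, with a Monte-Carlo
permutation estimator as an independent stochastic cross-check.

## The synthetic cohort generator

`simulate_cohort` draws genotypes per SNP as $\mathrm{Binomial}(2,
\mathrm{MAF})$ (Hardy-Weinberg proportions, no LD except where injected),
computes a logistic liability $\eta = \beta_0 + \sum_i \beta_i g_i$ over a
small causal panel, draws the phenotype Bernoulli-logistic, and keeps
drawing individuals until exactly `n_cases` cases and `n_controls`
controls are collected — conditioning that emulates a study with fixed
cohort sizes and changes only the effective intercept, not the slopes.
Non-causal genotypes are independent of the phenotype and are filled in
afterwards, which keeps exome-scale pools cheap. The generator also
injects, to exercise the QC stages: near-constant columns (MAF 0.02, so
>90% of samples share a genotype while still passing the 1% MAF filter),
high-LD pairs (a column copied with 2% of entries resampled, giving
dosage correlation ~0.97–0.98, placed on one chromosome), and
completely-at-random missingness (default 2%).

Defaults are the study-scale conditions: 978 cases, 2732 controls, a
2000-SNP pool, and nine causal SNPs — six protective with per-allele
log-odds evenly spanning $[-5.24, -2.23]$ and three risk SNPs spanning
$[3.50, 7.28]$, the reported ranges, which are the panel's attained
min/max and hence are spanned, not sampled from one end. The intercept is
calibrated by root-finding so the marginal case probability equals the
cohort's case fraction (26.4%).

**Causal MAF calibration.** The source reports no per-SNP frequencies, so
the causal MAF spectrum is the generator's one free shape parameter. It
was fixed at `seq(0.25, 0.50)` by computing, exactly on the $3^9$
genotype lattice, the model-implied (Bayes-optimal) AUC, sensitivity and
specificity of the causal panel at threshold 0.5 and 26.4% prevalence,
and choosing the spectrum whose operating point lies closest to the
reported metric regime (AUC ≈ 0.99, specificity ≈ 0.96). Two findings
from that calibration are worth recording as model-class limits rather
than bugs:

* With the reported log-odds treated as *joint* liability coefficients,
  the model-implied sensitivity at threshold 0.5 never exceeds ~0.906
  over any MAF spectrum (600-point random search on the exact lattice):
  a logistic liability with these coefficients and 26% prevalence always
  leaves a few percent of cases at intermediate risk. Fitted classifiers
  necessarily land below the reported ~0.97 sensitivity, and tree
  ensembles land a few points below logistic regression (which is the
  true model family here). Synthetic-cohort checks that require >90%
  sensitivity from a random forest sit at or above this ceiling.
* Treating the reported values as *marginal* effects instead is
  infeasible: an exact fixed-point calibration (joint coefficients whose
  population marginal projections equal the reported values) diverges,
  because at 26.4% prevalence the marginal slopes saturate below the
  reported magnitudes. The joint interpretation is therefore the only
  consistent one, and is the package default.

What the generator does *not* emulate: haplotype/coalescent LD structure
(LD is pairwise copy-with-noise only), population stratification,
covariates (age, sex, smoking), genotyping error beyond random
missingness, and any non-logistic disease architecture. Passing tests on
these cohorts therefore demonstrate correctness of the pipeline's
mechanics and its behaviour under a known additive model — not
performance on real exome data.

## Numerical choices and degenerate inputs

* Largest-remainder apportionment adds `1e-9` before `floor` so exact
  integer products are not truncated by floating-point error; ties in
  remainders break by partition order.
* Correlation pruning refuses zero-variance columns (undefined r) and
  directs the caller to `drop_near_constant`; correlations use
  pairwise-complete observations when dosages are missing.
* The imputer's ridge penalty is `1e-8`, large enough to keep the normal
  equations well-posed, small enough that a perfectly collinear partner
  is recovered to `1e-6`; a singular system falls back to a `1e-6` ridge.
* Multi-allelic VCF records are rejected by default; with
  `multiallelic = "first"` the first alt allele is kept and genotypes
  carrying other alt alleles become missing. Half-missing diploid calls
  (`./1`) are treated as missing. VCF export refuses fractional imputed
  dosages (use the dosage-table format).
* The random-panel null fixes the classifier seed across iterations, so
  each iteration's AUC is a deterministic function of the drawn panel and
  a pool of one SNP yields a degenerate (zero-variance) distribution.
* Perfect separation in per-SNP logistic fits triggers the Firth
  fallback plus a warning; constant PRS vectors report slope 0, p 1.

## Problem sizes in the test suite

The packaged checks run on reduced problem sizes chosen to keep the whole
suite fast while preserving every qualitative property: the null
distribution uses the full 1000 iterations at study-scale partition sizes
(2272 training / 474 test samples, 2000-SNP pool); the strong-signal
analogue uses a 120-SNP pool; stability-selection recovery uses five
replicates at study-scale training size (2272 samples) over a 300-SNP
pool with 60-tree forests. The recovery property is sensitive to training
size — at half the training samples the weakest protective SNPs
(per-allele log-odds near −2.2, attenuated to ~−0.5 marginally) drop out
of individual subsets — which is itself informative about the sample
sizes this design needs.

## Known limitations

* The reference-panel phasing stage of the original two-step imputation
  is out of scope; the model-based imputer alone satisfies the
  no-missing-dosages contract downstream.
* Exact Shapley enumeration is limited to 16 features; larger panels need
  the sampling estimator.
* The SVM's probability calibration is internally cross-validated and is
  the one classifier whose fitted model is not bit-reproducible across
  platforms (its RNG is seeded, but libsvm's internal order of operations
  may vary by build).
* HWE is computed on the merged case+control cohort (the default,
  matching the pipeline's placement of the filter after merging); a
  controls-only HWE filter would be stricter under true association and
  can be obtained by filtering a controls-only cohort.
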