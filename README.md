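# mlprs

Machine-learning SNP panel selection and polygenic risk scoring for
case/control cohorts.

`mlprs` is for statistical-genetics practitioners who want to go from raw
diploid genotype calls (VCF or dosage tables) for a case cohort and a
control cohort to (i) a small, stable panel of predictive SNPs, (ii) an
honest multi-classifier assessment of that panel against unseen test sets
and a random-panel null, and (iii) a per-individual polygenic risk score
with a risk calculator — with a strict train/test firewall throughout. A
synthetic cohort generator with known causal ground truth makes the whole
pipeline testable without patient data.

## The method

Samples are split into one training and three unseen test partitions
(largest-remainder apportionment of fixed fractions, stratified by
case/control status) *before* any processing. The merged training cohort is
quality-controlled (MAF < 1%, missingness > 10%, exact Hardy–Weinberg test
p < 0.01; then near-constant genotypes and per-chromosome correlation
pruning at |r| > 0.95), and missing dosages are imputed by chained ridge
regressions fitted on training data only.

The predictive panel comes from **stability selection**: recursive feature
elimination with cross-validation (RFECV, random-forest estimator) is run
independently on eight stratified bootstrap subsets of the training cohort
at sample fractions 0.5–1.0, and only SNPs selected in *every* subset are
kept, ranked by mean importance. Stepwise inclusion then locates the
smallest panel meeting AUC/sensitivity/specificity floors on training CV
and every test set. Panels are validated against a 1000-iteration null in
which equally sized SNP sets are drawn at random, and interpreted with
exact Shapley attributions.

The risk score for sample *j* over panel SNPs *i* with univariate logistic
effect sizes *Sᵢ* (training partition only) is the missingness-normalized

```
PRS_j = Σᵢ Sᵢ · G_ij / (P · M_j)
```

with ploidy *P* = 2 and *M_j* the number of non-missing panel SNPs of
sample *j*, so missing genotypes do not drag scores toward low risk. A
training-fitted logistic map converts scores to odds and probability.

## Worked example

```r
library(mlprs)

# a study-scale synthetic cohort: 978 cases / 2732 controls, 120-SNP pool,
# 9 causal SNPs with per-allele log-odds in the reported ranges
sim   <- simulate_cohort(simulation_config(n_cases = 978, n_controls = 2732,
                                           n_snps = 120, missing_rate = 0,
                                           n_constant = 0, n_ld_pairs = 0,
                                           seed = 2026))
parts <- split_samples(sim$cohort,
                       split_spec(c(599, 125, 127, 127) / 978, seed = 2027))

eff <- estimate_effect_sizes(parts$train, sim$truth$causal_ids)
eff[, c("snp_id", "beta", "se", "p_value", "direction")]
#>     snp_id   beta     se  p_value  direction
#> 1 snp00016 -0.928 0.0944 8.84e-23 protective
#> 2 snp00038 -0.988 0.0909 1.63e-27 protective
#> ...
#> 9 snp00104  1.645 0.0881 8.14e-78       risk

prs   <- compute_prs(parts$test1, eff)
assoc <- test_prs_association(compute_prs(parts$train, eff),
                              parts$train$phenotype)
compute_auc(prs$score, parts$test1$phenotype)
#> [1] 0.9902
test_prs_association(prs, parts$test1$phenotype)$p_value
#> [1] 5.98e-99

risk_calculator(parts$test1$dosages[3, sim$truth$causal_ids], eff, assoc$map)
#> <risk_output>
#>   PRS:         0.089845  (over 9 non-missing SNPs)
#>   odds:        2.474238
#>   probability: 0.712167
```

The estimated marginal effect sizes are attenuated relative to the joint
simulation coefficients (expected for univariate fits under a multi-SNP
liability model) but recover sign and ordering; the PRS built from them
separates unseen cases from controls at AUC 0.99, and the calculator turns
one individual's nine genotypes into a score, odds and case probability
under the training-fitted map.

Real data enter through `read_cohort()` (VCF or dosage table), then
`merge_on_common_snps()`, `filter_snps()`, `fit_imputer()`,
`stability_selection()`, `stepwise_minimal_panel()` and the evaluation
functions — see the methods vignette (`vignettes/mlprs-methods.Rmd`) for
the full model description, parameter meanings and design rationale. A
command-line risk calculator is installed at `inst/cli/mlprs-calc.R`.

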