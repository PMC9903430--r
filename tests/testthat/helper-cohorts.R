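# Quick in-code cohort fixtures.

toy_cohort <- function(dosages, phenotype = rep(0L, nrow(dosages)),
                       chrom = rep("1", ncol(dosages)),
                       pos = seq_len(ncol(dosages)) * 100L,
                       ids = if (!is.null(colnames(dosages))) {
                         colnames(dosages)
                       } else {
                         sprintf("rs%03d", seq_len(ncol(dosages)))
                       }) {
  genotype_cohort(
    dosages = dosages,
    snps = data.frame(snp_id = ids, chrom = chrom, pos = pos,
                      ref = rep("A", ncol(dosages)),
                      alt = rep("G", ncol(dosages)),
                      stringsAsFactors = FALSE),
    phenotype = phenotype,
    samples = sprintf("s%04d", seq_len(nrow(dosages))))
}

# HWE genotype column at a given MAF
hwe_column <- function(n, maf) stats::rbinom(n, 2, maf)

# small fully observed strong-signal cohort for evaluation tests
small_signal_sim <- function(n_cases = 150, n_controls = 350, n_snps = 30,
                             seed = 11) {
  spec <- default_causal_spec()
  spec <- spec[seq_len(min(nrow(spec), n_snps)), , drop = FALSE]
  simulate_cohort(simulation_config(
    n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
    causal_spec = spec,
    missing_rate = 0, n_constant = 0, n_ld_pairs = 0, seed = seed))
}
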