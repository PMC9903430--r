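#' Construct a genotype cohort
#'
#' A `genotype_cohort` is the central container of the package: a samples x
#' SNPs matrix of alt-allele dosages together with per-SNP metadata and a
#' binary phenotype label per sample (1 = case, 0 = control). Before
#' imputation every non-missing dosage is an integer in `{0, 1, 2}`; after
#' imputation entries may be any real value in `[0, 2]` with no missing
#' values.
#'
#' @param dosages Numeric matrix, samples in rows and SNPs in columns.
#'   Missing genotypes are `NA`. Values must lie in `[0, 2]`.
#' @param snps Data frame of SNP metadata with columns `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, one row per dosage column. `chrom`/`pos`/`ref`/
#'   `alt` may be `NA` for cohorts read from bare dosage tables.
#' @param phenotype Integer vector of 0/1 labels, one per sample.
#' @param samples Character vector of sample identifiers. Defaults to the
#'   row names of `dosages`.
#'
#' @return An object of class `genotype_cohort` with elements `samples`,
#'   `snps`, `dosages`, `phenotype`.
#' @export
genotype_cohort <- function(dosages, snps, phenotype,
                            samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(samples)) {
    samples <- sprintf("sample%04d", seq_len(nrow(dosages)))
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols)) {
    stop("snps metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  rownames(snps) <- NULL
  phenotype <- as.integer(phenotype)
  obj <- structure(
    list(samples = as.character(samples), snps = snps,
         dosages = dosages, phenotype = phenotype),
    class = "genotype_cohort"
  )
  validate_cohort(obj)
  dimnames(obj$dosages) <- list(obj$samples, obj$snps$snp_id)
  obj
}

validate_cohort <- function(x) {
  stopifnot(inherits(x, "genotype_cohort"))
  if (nrow(x$dosages) != length(x$samples)) {
    stop("dosage matrix has ", nrow(x$dosages), " rows but ",
         length(x$samples), " sample ids")
  }
  if (ncol(x$dosages) != nrow(x$snps)) {
    stop("dosage matrix has ", ncol(x$dosages), " columns but ",
         nrow(x$snps), " SNP records")
  }
  if (length(x$phenotype) != length(x$samples)) {
    stop("phenotype length does not match sample count")
  }
  if (!all(x$phenotype %in% c(0L, 1L))) {
    stop("phenotype labels must be 0 (control) or 1 (case)")
  }
  d <- x$dosages
  bad <- !is.na(d) & (d < 0 | d > 2)
  if (any(bad)) stop("dosages must lie in [0, 2]; found value outside range")
  if (anyDuplicated(x$snps$snp_id)) stop("duplicate snp_id in metadata")
  key <- snp_keys(x$snps)
  if (!all(is.na(key)) && anyDuplicated(key[!is.na(key)])) {
    stop("duplicate (chrom, pos, ref, alt) key in SNP metadata")
  }
  invisible(x)
}

# (chrom, pos, ref, alt) identity key; NA where metadata is absent
snp_keys <- function(snps) {
  has_meta <- !(is.na(snps$chrom) | is.na(snps$pos) |
                  is.na(snps$ref) | is.na(snps$alt))
  key <- rep(NA_character_, nrow(snps))
  key[has_meta] <- paste(snps$chrom[has_meta], snps$pos[has_meta],
                         snps$ref[has_meta], snps$alt[has_meta], sep = ":")
  key
}

#' @exportS3Method base::print
print.genotype_cohort <- function(x, ...) {
  cat("<genotype_cohort> ", length(x$samples), " samples x ",
      nrow(x$snps), " SNPs\n", sep = "")
  cat("  cases: ", sum(x$phenotype == 1L), "  controls: ",
      sum(x$phenotype == 0L), "\n", sep = "")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing dosages: %.2f%%", 100 * miss), "\n")
  invisible(x)
}

#' @export
dim.genotype_cohort <- function(x) c(length(x$samples), nrow(x$snps))

#' Number of samples / SNPs in a cohort
#' @param cohort A `genotype_cohort`.
#' @return Integer count.
#' @export
n_samples <- function(cohort) length(cohort$samples)

#' @rdname n_samples
#' @export
n_snps <- function(cohort) nrow(cohort$snps)

#' Subset a cohort by samples and/or SNPs
#'
#' Integer, logical or character (sample id / snp id) indices are accepted.
#' Duplicate sample indices are allowed (used by resampling with
#' replacement); duplicated sample ids are made unique.
#'
#' @param x A `genotype_cohort`.
#' @param i Sample index.
#' @param j SNP index.
#' @param ... Unused.
#' @export
`[.genotype_cohort` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$snps))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  if (anyNA(i)) stop("unknown sample id in subset")
  if (anyNA(j)) stop("unknown snp id in subset")
  samples <- make.unique(x$samples[i], sep = "_dup")
  genotype_cohort(
    dosages = x$dosages[i, j, drop = FALSE],
    snps = x$snps[j, , drop = FALSE],
    phenotype = x$phenotype[i],
    samples = samples
  )
}

#' Merge case and control cohorts on their shared SNPs
#'
#' Mirrors the merge of separately stored case and control call sets before
#' quality control: only SNPs present in both cohorts (keyed by
#' chromosome, position, ref and alt allele) are kept, samples are
#' concatenated cases-then-controls, and phenotype labels are assigned
#' 1/0 respectively.
#'
#' @param cases,controls `genotype_cohort` objects with disjoint sample ids
#'   and complete SNP metadata.
#' @return A merged `genotype_cohort`.
#' @export
merge_on_common_snps <- function(cases, controls) {
  validate_cohort(cases); validate_cohort(controls)
  if (length(intersect(cases$samples, controls$samples))) {
    stop("case and control cohorts share sample identifiers")
  }
  key_a <- snp_keys(cases$snps)
  key_b <- snp_keys(controls$snps)
  if (anyNA(key_a) || anyNA(key_b)) {
    stop("merging requires complete (chrom, pos, ref, alt) metadata")
  }
  # same (chrom, pos) with different alleles is a harmonisation failure,
  # not a disjoint site
  pos_a <- paste(cases$snps$chrom, cases$snps$pos, sep = ":")
  pos_b <- paste(controls$snps$chrom, controls$snps$pos, sep = ":")
  shared_pos <- intersect(pos_a, pos_b)
  matched_pos <- pos_a[key_a %in% key_b]
  mism <- setdiff(shared_pos, matched_pos)
  if (length(mism)) {
    stop("allele mismatch between cohorts at site(s): ",
         paste(utils::head(mism, 5), collapse = ", "))
  }
  common <- intersect(key_a, key_b)
  if (!length(common)) stop("cohorts share no SNPs (empty intersection)")
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  genotype_cohort(
    dosages = rbind(cases$dosages[, ia, drop = FALSE],
                    controls$dosages[, ib, drop = FALSE]),
    snps = cases$snps[ia, , drop = FALSE],
    phenotype = c(rep(1L, length(cases$samples)),
                  rep(0L, length(controls$samples))),
    samples = c(cases$samples, controls$samples)
  )
}
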