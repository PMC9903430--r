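#' Read a genotype cohort from disk
#'
#' Two formats are supported. `"vcf"` consumes the GT subfield of a VCF 4.x
#' file (via \pkg{vcfR}) and maps diploid calls to alt-allele dosages:
#' `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./. -> NA` (phased separators are
#' treated the same). `"dosage"` reads a tab-separated table whose header is
#' `sample_id` followed by SNP identifiers, with missing genotypes encoded
#' as `NA`; such tables carry no chromosome/position/allele metadata, so
#' those fields are `NA` in the result and the cohort cannot be merged or
#' re-exported as VCF.
#'
#' @param path File path.
#' @param format `"vcf"` or `"dosage"`.
#' @param phenotype_value Binary label (1 = case, 0 = control) assigned to
#'   every sample in the file.
#' @param multiallelic How to treat records with more than one alt allele:
#'   `"error"` (default) rejects the file, `"first"` keeps the first alt
#'   allele and treats genotypes carrying any other alt allele as missing.
#' @return A [genotype_cohort()].
#' @export
read_cohort <- function(path, format = c("vcf", "dosage"),
                        phenotype_value = 0L,
                        multiallelic = c("error", "first")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    read_cohort_vcf(path, phenotype_value, multiallelic)
  } else {
    read_cohort_dosage(path, phenotype_value)
  }
}

read_cohort_vcf <- function(path, phenotype_value, multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) {                    # single-record files
    fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  }
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- colnames(vcf@gt)[-1]
    return(genotype_cohort(
      dosages = matrix(numeric(0), nrow = length(samples), ncol = 0),
      snps = data.frame(snp_id = character(), chrom = character(),
                        pos = integer(), ref = character(),
                        alt = character()),
      phenotype = rep(as.integer(phenotype_value), length(samples)),
      samples = samples))
  }
  multi <- grepl(",", fix$ALT)
  if (any(multi) && multiallelic == "error") {
    stop("multi-allelic record(s) at line(s) for position(s): ",
         paste(utils::head(paste0(fix$CHROM[multi], ":", fix$POS[multi]), 5),
               collapse = ", "),
         "; use multiallelic = \"first\" to keep the first alt allele")
  }
  alt <- sub(",.*", "", fix$ALT)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  dos <- gt_to_dosage(gt)  # variants x samples
  id <- fix$ID
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste(fix$CHROM[no_id], fix$POS[no_id], fix$REF[no_id],
                     alt[no_id], sep = ":")
  genotype_cohort(
    dosages = t(dos),
    snps = data.frame(snp_id = id, chrom = fix$CHROM,
                      pos = as.integer(fix$POS), ref = fix$REF, alt = alt,
                      stringsAsFactors = FALSE),
    phenotype = rep(as.integer(phenotype_value), ncol(dos)),
    samples = colnames(gt)
  )
}

# GT string matrix -> numeric dosage matrix (same shape). vcfR already
# converts fully missing calls ("./.", ".|.") to NA.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  norm <- gsub("|", "/", u, fixed = TRUE)
  parts <- strsplit(norm, "/", fixed = TRUE)
  n_alleles <- lengths(parts)
  if (any(n_alleles != 2)) {
    stop("unsupported ploidy: genotype call(s) ",
         paste(utils::head(u[n_alleles != 2], 3), collapse = ", "),
         " are not diploid")
  }
  dose_of <- vapply(parts, function(a) {
    if (any(a == ".")) return(NA_real_)       # half-missing -> missing
    ia <- suppressWarnings(as.integer(a))
    if (anyNA(ia)) stop("malformed GT call in VCF")
    if (any(ia > 1)) return(NA_real_)         # non-first alt under "first"
    sum(ia)
  }, numeric(1))
  map <- c(stats::setNames(dose_of, u))
  out <- matrix(map[as.vector(gt)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

read_cohort_dosage <- function(path, phenotype_value) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (names(dt)[1] != "sample_id") {
    stop("parse error: dosage table must start with a 'sample_id' column ",
         "(line 1 of ", path, ")")
  }
  samples <- as.character(dt[[1]])
  dos <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  ids <- names(dt)[-1]
  genotype_cohort(
    dosages = dos,
    snps = data.frame(snp_id = ids, chrom = NA_character_, pos = NA_integer_,
                      ref = NA_character_, alt = NA_character_,
                      stringsAsFactors = FALSE),
    phenotype = rep(as.integer(phenotype_value), length(samples)),
    samples = samples
  )
}

#' Write a genotype cohort to disk
#'
#' VCF output carries CHROM/POS/ID/REF/ALT and one GT field per sample and
#' is only possible for integer dosages (`0/1/2/NA`); imputed fractional
#' dosages are representable only in the dosage-table format and VCF export
#' of such a cohort is an error. Output from either format is re-readable by
#' [read_cohort()] with a bit-identical dosage matrix.
#'
#' @param cohort A [genotype_cohort()].
#' @param path Output file path.
#' @param format `"vcf"` or `"dosage"`.
#' @export
write_cohort <- function(cohort, path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  validate_cohort(cohort)
  if (format == "dosage") {
    df <- data.frame(sample_id = cohort$samples,
                     cohort$dosages, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
    return(invisible(path))
  }
  d <- cohort$dosages
  if (any(!is.na(d) & d != round(d))) {
    stop("VCF cannot represent fractional (imputed) dosages; ",
         "use format = \"dosage\"")
  }
  if (anyNA(snp_keys(cohort$snps)) && nrow(cohort$snps) > 0) {
    stop("VCF export requires complete (chrom, pos, ref, alt) metadata")
  }
  gt_code <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mlprs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  body <- character(0)
  if (nrow(cohort$snps) > 0) {
    gt <- matrix("./.", nrow = nrow(cohort$snps), ncol = length(cohort$samples))
    obs <- !is.na(t(d))
    gt[obs] <- gt_code[as.character(t(d)[obs])]
    body <- paste(cohort$snps$chrom, cohort$snps$pos, cohort$snps$snp_id,
                  cohort$snps$ref, cohort$snps$alt, ".", ".", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
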