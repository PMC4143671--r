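#' Genotype matrix container
#'
#' Holds an individuals-by-SNPs minor-allele dosage matrix (entries 0, 1, 2
#' or `NA` for missing calls) alongside per-SNP metadata. Dosage counts the
#' minor allele, so 0 is major/major, 1 heterozygous and 2 minor/minor.
#'
#' @param dosages Numeric matrix, individuals in rows (rownames are the
#'   individual ids) and SNPs in columns (colnames are the SNP ids);
#'   entries in `{0, 1, 2, NA}`.
#' @param snps A data frame with one row per SNP: columns `snp_id`,
#'   `chrom`, `pos` (1-based base-pair position), `minor_allele`,
#'   `major_allele`. Allele codes are single characters, `"0"` when
#'   unobserved.
#' @param validate Set to `FALSE` to skip the entry-level checks (used
#'   internally by the simulators, which construct valid dosages by
#'   design).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snps, validate = TRUE) {
  if (!is.matrix(dosages)) stop_invalid("`dosages` must be a matrix.")
  snps <- tibble::as_tibble(snps)
  required <- c("snp_id", "chrom", "pos", "minor_allele", "major_allele")
  if (!all(required %in% names(snps))) {
    stop_invalid(paste0("`snps` must have columns: ",
                        paste(required, collapse = ", "), "."))
  }
  if (nrow(snps) != ncol(dosages)) {
    stop_invalid("`snps` must have one row per dosage column.")
  }
  if (is.null(rownames(dosages))) {
    stop_invalid("`dosages` must carry individual ids as rownames.")
  }
  snps$snp_id <- as.character(snps$snp_id)
  colnames(dosages) <- snps$snp_id
  if (validate) {
    if (anyDuplicated(rownames(dosages))) {
      stop_invalid("Individual ids must be unique.")
    }
    if (anyDuplicated(snps$snp_id)) stop_invalid("SNP ids must be unique.")
    vals <- dosages[!is.na(dosages)]
    if (length(vals) && !all(vals %in% c(0, 1, 2))) {
      stop_invalid("Dosages must be 0, 1, 2 or NA.")
    }
    if (any(!is.na(snps$pos) & snps$pos < 0)) {
      stop_invalid("Base-pair positions must be non-negative.")
    }
  }
  structure(list(dosages = dosages, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d individuals x %d SNPs, %.1f%% missing>\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g A `genotype_matrix`.
#' @export
individual_ids <- function(g) rownames(g$dosages)

#' @rdname genotype_matrix
#' @export
snp_ids <- function(g) g$snps$snp_id

#' Per-SNP summaries of a genotype matrix
#'
#' Minor allele frequency and missing-call rate per SNP. MAF is computed
#' over non-missing calls and folded onto `[0, 0.5]` (after subsetting, a
#' dosage-coded "minor" allele can drift above 50%).
#'
#' @param g A [genotype_matrix()].
#' @return A tibble with columns `snp_id`, `maf`, `missing_rate`.
#' @export
snp_summary <- function(g) {
  d <- g$dosages
  f <- colMeans(d, na.rm = TRUE) / 2
  tibble::tibble(
    snp_id = snp_ids(g),
    maf = pmin(f, 1 - f),
    missing_rate = colMeans(is.na(d))
  )
}

# subset helpers keep dosages and metadata in lockstep; `keep` may be a
# character, logical or integer index
subset_snps <- function(g, keep) {
  idx <- if (is.character(keep)) {
    match(keep, snp_ids(g))
  } else if (is.logical(keep)) which(keep) else keep
  genotype_matrix(g$dosages[, idx, drop = FALSE], g$snps[idx, , drop = FALSE],
                  validate = FALSE)
}

subset_individuals <- function(g, keep) {
  idx <- if (is.character(keep)) {
    match(keep, individual_ids(g))
  } else if (is.logical(keep)) which(keep) else keep
  genotype_matrix(g$dosages[idx, , drop = FALSE], g$snps, validate = FALSE)
}
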