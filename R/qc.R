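#' SNP-level quality control
#'
#' Two sequential filters in the conventional order: first drop SNPs with
#' a missing-call rate strictly greater than `max_missing`, then drop
#' SNPs whose minor allele frequency (computed over the remaining
#' non-missing calls) is strictly smaller than `min_maf`. Boundary values
#' are retained: a SNP with missing rate exactly `max_missing` or MAF
#' exactly `min_maf` survives.
#'
#' The filter is idempotent: re-applying it with the same thresholds
#' removes nothing further.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Maximum tolerated per-SNP missing fraction, in
#'   `[0, 1)`.
#' @param min_maf Minimum tolerated minor allele frequency, in `[0, 0.5]`.
#' @return A list with `genotypes` (the filtered matrix) and `report` (a
#'   tibble with one row per step: `step`, `threshold`, `n_removed`,
#'   `n_remaining`).
#' @export
qc_filter <- function(g, max_missing = 0.05, min_maf = 0.05) {
  if (!inherits(g, "genotype_matrix")) stop_invalid("`g` must be a genotype_matrix.")
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing >= 1) {
    stop_invalid("`max_missing` must be in [0, 1).")
  }
  if (!is.numeric(min_maf) || min_maf < 0 || min_maf > 0.5) {
    stop_invalid("`min_maf` must be in [0, 0.5].")
  }
  m0 <- ncol(g$dosages)
  miss <- colMeans(is.na(g$dosages))
  keep1 <- miss <= max_missing
  g1 <- subset_snps(g, keep1)

  f <- colMeans(g1$dosages, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep2 <- !is.na(maf) & maf >= min_maf
  g2 <- subset_snps(g1, keep2)

  report <- tibble::tibble(
    step = c("missing_rate", "maf"),
    threshold = c(max_missing, min_maf),
    n_removed = c(sum(!keep1), sum(!keep2)),
    n_remaining = c(ncol(g1$dosages), ncol(g2$dosages))
  )
  list(genotypes = g2, report = report)
}

#' Individual-level quality control
#'
#' Drops individuals on an explicit exclusion list, then individuals whose
#' genotype missing fraction strictly exceeds `max_missing`.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Maximum tolerated per-individual missing fraction.
#' @param exclude Character vector of individual ids to drop regardless of
#'   missingness (e.g. ancestry outliers flagged externally).
#' @return A list with `genotypes` and a `report` tibble.
#' @export
filter_individuals <- function(g, max_missing = 0.1, exclude = character()) {
  if (!inherits(g, "genotype_matrix")) stop_invalid("`g` must be a genotype_matrix.")
  ids <- individual_ids(g)
  keep1 <- !(ids %in% exclude)
  g1 <- subset_individuals(g, keep1)
  miss <- rowMeans(is.na(g1$dosages))
  keep2 <- miss <= max_missing
  g2 <- subset_individuals(g1, keep2)
  report <- tibble::tibble(
    step = c("exclusion_list", "individual_missing_rate"),
    threshold = c(NA_real_, max_missing),
    n_removed = c(sum(!keep1), sum(!keep2)),
    n_remaining = c(nrow(g1$dosages), nrow(g2$dosages))
  )
  list(genotypes = g2, report = report)
}

#' Merge two genotype panels on their shared SNPs
#'
#' Restricts both matrices to the intersection of their SNP ids, in the
#' first panel's order, and reconciles allele orientation: when the two
#' panels call opposite alleles "minor" for the same SNP, the second
#' panel's dosages are flipped (`2 - dosage`) so that a dosage of 2 counts
#' the same allele in both. SNPs whose allele pairs cannot be reconciled
#' (disjoint allele sets, e.g. A/G in one panel and C/T in the other) are
#' excluded with a warning.
#'
#' @param a,b Two [genotype_matrix()] objects.
#' @return A list with `a` and `b` (both restricted to the shared,
#'   reconciled SNPs in identical order), `flipped` (SNP ids whose
#'   orientation in `b` was flipped) and `excluded` (irreconcilable SNP
#'   ids).
#' @export
merge_snp_panels <- function(a, b) {
  if (!inherits(a, "genotype_matrix") || !inherits(b, "genotype_matrix")) {
    stop_invalid("Both inputs must be genotype_matrix objects.")
  }
  shared <- intersect(snp_ids(a), snp_ids(b))
  ia <- match(shared, snp_ids(a))
  ib <- match(shared, snp_ids(b))
  sa <- a$snps[ia, ]
  sb <- b$snps[ib, ]

  # per-SNP action: keep b as-is, flip b's dosage orientation, or exclude.
  # "0" marks an unobserved allele (monomorphic panel) and acts as a
  # wildcard; disjoint observed allele sets are irreconcilable.
  action <- vapply(seq_along(shared), function(k) {
    a_min <- sa$minor_allele[k]; a_maj <- sa$major_allele[k]
    b_min <- sb$minor_allele[k]; b_maj <- sb$major_allele[k]
    obs_a <- setdiff(c(a_min, a_maj), "0")
    obs_b <- setdiff(c(b_min, b_maj), "0")
    if (length(obs_a) == 0L || length(obs_b) == 0L) return("keep")
    if (!all(obs_b %in% obs_a) && !all(obs_a %in% obs_b)) return("exclude")
    if ((b_min != "0" && b_min == a_maj && a_maj != "0") ||
        (b_maj != "0" && b_maj == a_min && a_min != "0")) {
      return("flip")
    }
    "keep"
  }, character(1L))

  excluded <- shared[action == "exclude"]
  if (length(excluded)) {
    warn(sprintf("%d SNP(s) with irreconcilable allele pairs excluded: %s",
                 length(excluded),
                 paste(utils::head(excluded, 10L), collapse = ", ")))
  }

  keep <- action != "exclude"
  a2 <- subset_snps(a, ia[keep])
  b2 <- subset_snps(b, ib[keep])
  flip <- action[keep] == "flip"
  if (any(flip)) {
    b2$dosages[, flip] <- 2 - b2$dosages[, flip]
    sw <- b2$snps$minor_allele[flip]
    b2$snps$minor_allele[flip] <- b2$snps$major_allele[flip]
    b2$snps$major_allele[flip] <- sw
  }
  list(a = a2, b = b2, flipped = shared[action == "flip"], excluded = excluded)
}
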