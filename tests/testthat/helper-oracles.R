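# Independent oracles and fixture builders shared across test files.

# Literal step-up threshold rule, kept independent of the package's code
# path (which delegates to stats::p.adjust): find the largest ordered
# statistic s_(j) with s_(j) <= alpha * j / m and reject everything at or
# below that threshold. Returns a logical vector in input order.
stepup_reject_oracle <- function(s, alpha) {
  m <- length(s)
  o <- order(s)
  sorted <- s[o]
  ok <- which(sorted <= alpha * seq_len(m) / m)
  if (length(ok) == 0L) return(rep(FALSE, m))
  threshold <- sorted[max(ok)]
  s <= threshold
}

# Brute-force adjusted p-values: suffix minima of m * s_(j) / j, capped at 1.
stepup_adjust_oracle <- function(s) {
  m <- length(s)
  o <- order(s)
  vals <- m * s[o] / seq_len(m)
  adj <- rev(cummin(rev(vals)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# All sorted length-k multisets from `values` (combinations with
# repetition), as a k x n_combo matrix.
sorted_grid_vectors <- function(values, k) {
  n <- length(values)
  idx <- utils::combn(n + k - 1L, k)
  idx <- idx - (seq_len(k) - 1L)   # map strictly-increasing to non-decreasing
  matrix(values[idx], nrow = k)
}

# A small hand-checkable ped/map fixture: 5 individuals (one parent-child
# trio plus 2 singletons), 3 SNPs. SNP layout:
#   snp1: alleles A/G, G is the rarer allele
#   snp2: one missing genotype
#   snp3: monomorphic C
write_ped_fixture <- function(dir) {
  ped <- c(
    "fam1 dad 0 0 1 -9  A A  A A  C C",
    "fam1 mum 0 0 2 -9  A G  A A  C C",
    "fam1 kid dad mum 1 -9  A G  A G  C C",
    "fam2 s1  0 0 1 -9  A A  0 0  C C",
    "fam2 s2  0 0 2 -9  G G  A G  C C"
  )
  map <- c(
    "3\tsnp1\t0\t1000",
    "3\tsnp2\t0\t2000",
    "3\tsnp3\t0\t3000"
  )
  ped_path <- file.path(dir, "fix.ped")
  map_path <- file.path(dir, "fix.map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)
  list(ped = ped_path, map = map_path)
}

# Strip class/attribute decoration from a power_result for comparisons.
tidy_power <- function(x) {
  out <- as.data.frame(x)
  attr(out, "config") <- NULL
  out
}

# Restrict a genotype_matrix to named SNPs (thin wrapper over the
# package-internal subsetter).
subset_snps_for_test <- function(g, ids) {
  wfdrtrio:::subset_snps(g, ids)
}

# Random p-value table on (0, 1].
random_pvalue_tbl <- function(m, zeros = 0L) {
  p <- runif(m)
  if (zeros > 0L) p[sample.int(m, zeros)] <- 0
  data.frame(snp_id = paste0("s", seq_len(m)), p = p)
}
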