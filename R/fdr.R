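#' Bonferroni-adjusted significance threshold
#'
#' Per-test significance level controlling the family-wise error rate at
#' `alpha` over `m` tests, i.e. `alpha / m`. For a genome-wide scan of
#' 40,359 SNPs at `alpha = 0.05` this is 1.24e-6.
#'
#' @param alpha Nominal family-wise error rate, in (0, 1).
#' @param m Number of tests, a positive integer.
#' @return The per-test threshold `alpha / m`, a single number.
#' @examples
#' bonferroni_threshold(0.05, 40359)
#' @export
bonferroni_threshold <- function(alpha, m) {
  check_alpha(alpha)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 ||
      m != as.integer(m)) {
    stop_invalid("`m` must be a single positive integer.")
  }
  alpha / m
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Applies the Benjamini-Hochberg step-up procedure to per-SNP p-values:
#' with ordered p-values p_(1) <= ... <= p_(m), all hypotheses with
#' p <= T are rejected, where T is the largest p_(j) satisfying
#' p_(j) <= alpha * j / m. Adjusted p-values are the usual suffix minima
#' of m * p_(j) / j capped at 1, so `rejected` is exactly
#' `adjusted_p <= alpha`.
#'
#' @param data A data frame with columns `snp_id` (unique identifiers) and
#'   `p` (raw p-values in (0, 1]).
#' @param alpha Nominal FDR level, in (0, 1).
#' @return An `fdr_result`: a tibble with columns `snp_id`, `raw_p`,
#'   `q_stat` (`NA` for unweighted BH), `adjusted_p` and `rejected`, in the
#'   input row order, with attributes `alpha` and `method`.
#' @examples
#' bh_adjust(data.frame(snp_id = paste0("rs", 1:4),
#'                      p = c(0.005, 0.01, 0.03, 0.04)))
#' @export
bh_adjust <- function(data, alpha = 0.05) {
  check_alpha(alpha)
  pv <- check_pvalue_frame(data, zero_ok = FALSE)
  adjusted <- p.adjust(pv$p, method = "BH")
  new_fdr_result(
    snp_id = pv$snp_id, raw_p = pv$p, q_stat = rep(NA_real_, nrow(pv)),
    adjusted_p = adjusted, alpha = alpha, method = "bh"
  )
}

#' Per-SNP weights from independent population p-values
#'
#' Builds multiple-testing weights proportional to the inverse of an
#' independent population-based association p-value, normalised so the
#' weights sum to the number of SNPs m:
#' `W_j = (m / p_j) / sum_k (1 / p_k)`. A SNP with strong independent
#' evidence (small population p) receives a large weight, relaxing its
#' family-based significance threshold under the weighted BH procedure.
#'
#' Weights depend only on ratios of p-values, so rescaling all population
#' p-values by a common positive factor leaves them unchanged. The
#' population p-values must come from individuals disjoint from the trio
#' sample (e.g. an unrelated subset of the cohort); independence cannot be
#' verified from the p-values themselves and is the caller's contract.
#'
#' @param data A data frame with columns `snp_id` and `p` (population
#'   p-values in \[0, 1\]; exact zeros are permitted and handled via
#'   `floor`).
#' @param floor Values below `floor` are clamped up to it before inversion
#'   so weights stay finite; the default 1e-300 preserves the ordering of
#'   any p-value a floating-point test can produce.
#' @return A tibble with columns `snp_id` and `weight`; weights are
#'   strictly positive and sum to `nrow(data)`.
#' @examples
#' compute_weights(data.frame(snp_id = c("a", "b"), p = c(0.1, 0.2)))
#' @export
compute_weights <- function(data, floor = 1e-300) {
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) ||
      floor <= 0) {
    stop_invalid("`floor` must be a single positive number.")
  }
  pv <- check_pvalue_frame(data, zero_ok = TRUE)
  inv <- 1 / pmax(pv$p, floor)
  tibble::new_tibble(
    list(snp_id = pv$snp_id, weight = nrow(pv) * inv / sum(inv)),
    nrow = nrow(pv)
  )
}

#' Weighted Benjamini-Hochberg (WFDR) adjustment
#'
#' The weighted FDR procedure: each family-based p-value is divided by its
#' weight to form `Q_j = p_j / W_j`, and the Benjamini-Hochberg step-up
#' rule is applied to the ordered Q statistics. With weights summing to m,
#' FDR control at the nominal level is retained while SNPs with large
#' weights (strong independent evidence) are tested against a relaxed
#' threshold. With all weights equal to 1 the procedure reduces exactly to
#' ordinary BH.
#'
#' The step-up threshold comparison uses the raw Q statistic, which may
#' exceed 1; reported `adjusted_p` is capped at 1 as a probability-scale
#' summary. Weighted adjusted p-values can be smaller than the raw p-value
#' when the weight exceeds 1.
#'
#' @param p_fam A data frame with columns `snp_id` and `p`: family-based
#'   p-values in (0, 1].
#' @param weights A data frame with columns `snp_id` and `weight`
#'   (strictly positive), with `snp_id` identical to `p_fam$snp_id` in the
#'   same order. Mismatches are an error, never silently reordered; see
#'   [wfdr_pipeline()] for the merging front end.
#' @param alpha Nominal FDR level, in (0, 1).
#' @return An `fdr_result` tibble with columns `snp_id`, `raw_p`,
#'   `q_stat`, `adjusted_p`, `rejected`.
#' @seealso [compute_weights()], [bh_adjust()], [wfdr_pipeline()]
#' @examples
#' fam <- data.frame(snp_id = c("a", "b"), p = c(0.001, 0.5))
#' w <- data.frame(snp_id = c("a", "b"), weight = c(1.6, 0.4))
#' wfdr_adjust(fam, w)
#' @export
wfdr_adjust <- function(p_fam, weights, alpha = 0.05) {
  check_alpha(alpha)
  pv <- check_pvalue_frame(p_fam, zero_ok = FALSE)
  if (!is.data.frame(weights) ||
      !all(c("snp_id", "weight") %in% names(weights))) {
    stop_invalid("`weights` must be a data frame with columns `snp_id` and `weight`.")
  }
  w_id <- as.character(weights$snp_id)
  if (length(w_id) != nrow(pv) || !identical(w_id, pv$snp_id)) {
    bad <- union(setdiff(pv$snp_id, w_id), setdiff(w_id, pv$snp_id))
    if (length(bad) == 0L) bad <- pv$snp_id[pv$snp_id != w_id[seq_len(nrow(pv))]]
    stop_alignment(
      c("`p_fam` and `weights` must carry identical `snp_id` in identical order.",
        x = paste0("First offending ids: ",
                   paste(utils::head(bad, 10L), collapse = ", "))),
      offending = utils::head(bad, 10L)
    )
  }
  w <- as.numeric(weights$weight)
  if (anyNA(w) || any(w <= 0)) {
    stop_invalid("All weights must be strictly positive and non-missing.")
  }
  q <- pv$p / w
  # p.adjust("BH") sorts by raw q and caps the reported value at 1, which is
  # exactly the contract: raw Q for thresholding, probability-scale report.
  adjusted <- p.adjust(q, method = "BH")
  new_fdr_result(
    snp_id = pv$snp_id, raw_p = pv$p, q_stat = q,
    adjusted_p = adjusted, alpha = alpha, method = "wfdr"
  )
}

#' Full weighted-FDR pipeline from two p-value tables
#'
#' Convenience front end chaining [compute_weights()] and [wfdr_adjust()]:
#' merges family-based and population-based p-value tables on `snp_id`
#' (SNPs present in only one source are dropped with a warning, mirroring
#' the merge of family and population SNP panels), computes inverse-p
#' weights from the population table and applies the weighted BH
#' adjustment to the family table.
#'
#' @param p_fam Data frame with columns `snp_id`, `p`: family-based
#'   p-values in (0, 1].
#' @param p_pop Data frame with columns `snp_id`, `p`: population-based
#'   p-values in \[0, 1\], from individuals disjoint from the trio sample.
#' @inheritParams wfdr_adjust
#' @inheritParams compute_weights
#' @return An `fdr_result` tibble with columns `snp_id`, `p_fam`, `p_pop`,
#'   `weight`, `q_stat`, `adjusted_p`, `rejected`.
#' @examples
#' fam <- data.frame(snp_id = c("a", "b", "c"), p = c(1e-4, 0.2, 0.9))
#' pop <- data.frame(snp_id = c("a", "b", "c"), p = c(0.01, 0.5, 0.6))
#' wfdr_pipeline(fam, pop)
#' @export
wfdr_pipeline <- function(p_fam, p_pop, alpha = 0.05, floor = 1e-300) {
  fam <- check_pvalue_frame(p_fam, zero_ok = FALSE)
  pop <- check_pvalue_frame(p_pop, zero_ok = TRUE)
  shared <- intersect(fam$snp_id, pop$snp_id)
  dropped <- (nrow(fam) - length(shared)) + (nrow(pop) - length(shared))
  if (length(shared) == 0L) {
    stop_alignment("`p_fam` and `p_pop` share no `snp_id`.")
  }
  if (dropped > 0L) {
    warn(sprintf(
      "%d SNP(s) present in only one p-value source were dropped before weighting.",
      dropped
    ))
  }
  fam <- fam[match(shared, fam$snp_id), ]
  pop <- pop[match(shared, pop$snp_id), ]
  w <- compute_weights(pop, floor = floor)
  res <- wfdr_adjust(fam, w, alpha = alpha)
  out <- tibble::new_tibble(
    list(snp_id = res$snp_id, p_fam = res$raw_p, p_pop = pop$p,
         weight = w$weight, q_stat = res$q_stat,
         adjusted_p = res$adjusted_p, rejected = res$rejected),
    nrow = nrow(res)
  )
  class(out) <- c("fdr_result", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "method") <- "wfdr"
  out
}

# ---- fdr_result class ------------------------------------------------------

new_fdr_result <- function(snp_id, raw_p, q_stat, adjusted_p, alpha, method) {
  out <- tibble::new_tibble(
    list(snp_id = snp_id, raw_p = raw_p, q_stat = q_stat,
         adjusted_p = adjusted_p, rejected = adjusted_p <= alpha),
    nrow = length(snp_id)
  )
  class(out) <- c("fdr_result", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  out
}

#' @method tidy fdr_result
#' @export
tidy.fdr_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fdr_result")
  attr(out, "alpha") <- NULL
  attr(out, "method") <- NULL
  out
}

#' @method glance fdr_result
#' @export
glance.fdr_result <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    alpha = attr(x, "alpha"),
    m = nrow(x),
    n_rejected = sum(x$rejected)
  )
}

#' Plot an FDR adjustment result
#'
#' Ordered raw p-values (or Q statistics for the weighted procedure)
#' against rank, with the Benjamini-Hochberg step-up line
#' `alpha * rank / m`; points below the line at the largest crossing are
#' the rejections.
#'
#' @param object An `fdr_result` from [bh_adjust()], [wfdr_adjust()] or
#'   [wfdr_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fdr_result
#' @export
autoplot.fdr_result <- function(object, ...) {
  alpha <- attr(object, "alpha")
  stat <- if (identical(attr(object, "method"), "wfdr")) {
    object$q_stat
  } else if ("raw_p" %in% names(object)) object$raw_p else object$p_fam
  df <- tibble::tibble(
    rank = seq_along(stat),
    value = sort(stat),
    rejected = sort(stat) <= alpha * seq_along(stat) / length(stat)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rejected), size = 0.8) +
    ggplot2::geom_abline(slope = alpha / nrow(df), intercept = 0,
                         linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "rank", y = "ordered statistic",
      title = sprintf("%s step-up at alpha = %g", attr(object, "method"), alpha)
    )
}

#' Write an FDR adjustment result to a tab-separated file
#'
#' Plain TSV with a header row, '.' decimal separator and scientific
#' notation where R's default formatting uses it.
#'
#' @param x An `fdr_result` or any data frame.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(x)
}

# ---- shared validation -----------------------------------------------------

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop_invalid("`alpha` must be a single number strictly between 0 and 1.")
  }
  invisible(alpha)
}

# Returns a clean data.frame(snp_id = character, p = numeric); errors follow
# the shared p-value contract: (0, 1] normally, [0, 1] where zeros are
# floored downstream.
check_pvalue_frame <- function(data, zero_ok = FALSE) {
  if (!is.data.frame(data) || !all(c("snp_id", "p") %in% names(data))) {
    stop_invalid("Input must be a data frame with columns `snp_id` and `p`.")
  }
  if (nrow(data) == 0L) {
    stop_invalid("Input p-value table is empty.")
  }
  snp_id <- as.character(data$snp_id)
  if (anyDuplicated(snp_id)) {
    stop_invalid("`snp_id` values must be unique.")
  }
  p <- as.numeric(data$p)
  lo_bad <- if (zero_ok) any(p < 0) else any(p <= 0)
  if (anyNA(p) || lo_bad || any(p > 1)) {
    rng <- if (zero_ok) "[0, 1]" else "(0, 1]"
    stop_invalid(sprintf("All p-values must be in %s and non-missing.", rng))
  }
  # hand-rolled data.frame: this sits on the per-SNP hot path and
  # data.frame() overhead dominates small calls
  out <- list(snp_id = snp_id, p = p)
  attr(out, "row.names") <- .set_row_names(length(p))
  class(out) <- "data.frame"
  out
}
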