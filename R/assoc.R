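# Vectorised per-column simple linear regression with intercept.
#
# X: n x m numeric predictor matrix (NA = missing, dropped per column);
# Y: length-n response vector, or an n x m matrix giving each column its
# own response (used by the simulator, where every SNP has its own fresh
# cohort). Returns per-column slope, SE, t, p and the complete-case count.
# Slope t-tests use the t distribution with n_used - 2 degrees of freedom.
col_simple_reg <- function(X, Y) {
  n <- nrow(X)
  m <- ncol(X)
  y_is_mat <- is.matrix(Y)
  if (!anyNA(X) && !anyNA(Y)) {
    # complete-data fast path: plain cross-products
    n_used <- rep(n, m)
    sx <- colSums(X)
    sxx <- colSums(X * X)
    if (y_is_mat) {
      sy <- colSums(Y); syy <- colSums(Y * Y); sxy <- colSums(X * Y)
    } else {
      sy <- rep(sum(Y), m); syy <- rep(sum(Y * Y), m); sxy <- colSums(X * Y)
    }
  } else {
    if (!y_is_mat) Y <- matrix(Y, n, m)
    mask <- !is.na(X) & !is.na(Y)
    X0 <- ifelse(mask, X, 0)
    Y0 <- ifelse(mask, Y, 0)
    n_used <- colSums(mask)
    sx <- colSums(X0); sxx <- colSums(X0 * X0)
    sy <- colSums(Y0); syy <- colSums(Y0 * Y0)
    sxy <- colSums(X0 * Y0)
  }
  Sxx <- sxx - sx^2 / n_used
  Syy <- syy - sy^2 / n_used
  Sxy <- sxy - sx * sy / n_used
  ok_var <- is.finite(Sxx) & Sxx > 1e-12 * pmax(1, sxx)
  slope <- ifelse(ok_var, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - ifelse(ok_var, Sxy^2 / Sxx, 0), 0)
  df <- n_used - 2
  se <- ifelse(ok_var & df > 0, sqrt(rss / df / Sxx), NA_real_)
  tstat <- slope / se
  p <- 2 * pt(-abs(tstat), df)
  list(n_used = n_used, estimate = slope, se = se, statistic = tstat,
       p = p, zero_var = !ok_var)
}

assoc_tibble <- function(snp_id, fit, min_n) {
  status <- rep("ok", length(snp_id))
  status[fit$zero_var] <- "monomorphic"
  status[fit$n_used < min_n] <- "insufficient_data"
  bad <- status != "ok"
  out <- tibble::new_tibble(
    list(
      snp_id = snp_id,
      n_used = as.integer(fit$n_used),
      estimate = ifelse(bad, NA_real_, fit$estimate),
      std.error = ifelse(bad, NA_real_, fit$se),
      statistic = ifelse(bad, NA_real_, fit$statistic),
      p.value = ifelse(bad, NA_real_, fit$p),
      status = status
    ),
    nrow = length(snp_id)
  )
  out
}

#' Population-based per-SNP association scan
#'
#' For each SNP, fits an ordinary-least-squares regression of the
#' phenotype (MAP) on an intercept, the requested covariate columns and
#' the additive minor-allele dosage, and reports the two-sided t-test of
#' the dosage coefficient against zero (residual degrees of freedom).
#' Individuals missing the genotype at a given SNP, the phenotype, or any
#' covariate are dropped for that SNP only (per-SNP complete-case).
#'
#' This is the unrelated-individuals arm of the pipeline; its p-values
#' feed [compute_weights()] as the independent evidence for the weighted
#' FDR adjustment of the family-based scan. The individuals supplied here
#' must be disjoint from the trio sample for that independence to hold.
#'
#' @param g A [genotype_matrix()] of unrelated individuals.
#' @param pheno A phenotype tibble with `individual_id`, `map_value` and
#'   any covariate columns (e.g. sex, age, medication indicator,
#'   principal components).
#' @param covariates Character vector of covariate column names in
#'   `pheno`; may be empty.
#' @return A tibble with one row per SNP: `snp_id`, `n_used`, `estimate`
#'   (phenotype units per minor allele), `std.error`, `statistic`,
#'   `p.value`, `status` (`ok`, `monomorphic` when the dosage has no
#'   variance among used individuals, `insufficient_data` when fewer
#'   individuals remain than model parameters + 2).
#' @export
population_assoc <- function(g, pheno, covariates = character()) {
  if (!inherits(g, "genotype_matrix")) stop_invalid("`g` must be a genotype_matrix.")
  if (!all(c("individual_id", "map_value") %in% names(pheno))) {
    stop_invalid("`pheno` must have columns `individual_id` and `map_value`.")
  }
  missing_cov <- setdiff(covariates, names(pheno))
  if (length(missing_cov)) {
    stop_invalid(paste0("Covariate(s) not found in `pheno`: ",
                        paste(missing_cov, collapse = ", ")))
  }
  ids <- intersect(individual_ids(g), as.character(pheno$individual_id))
  if (length(ids) == 0L) {
    stop_invalid("`g` and `pheno` share no individuals.")
  }
  X <- g$dosages[ids, , drop = FALSE]
  ph <- pheno[match(ids, pheno$individual_id), ]
  y <- as.numeric(ph$map_value)

  if (length(covariates) == 0L) {
    fit <- col_simple_reg(X, y)
    return(assoc_tibble(snp_ids(g), fit, min_n = 4L))
  }

  C <- as.matrix(ph[, covariates, drop = FALSE])
  storage.mode(C) <- "double"
  n_par <- 2L + ncol(C)           # intercept + covariates + dosage
  m <- ncol(X)
  res <- list(n_used = integer(m), estimate = numeric(m), se = numeric(m),
              statistic = numeric(m), p = numeric(m), zero_var = logical(m))
  base_ok <- !is.na(y) & stats::complete.cases(C)
  for (j in seq_len(m)) {
    use <- base_ok & !is.na(X[, j])
    nj <- sum(use)
    res$n_used[j] <- nj
    if (nj < n_par + 2L) {
      res$zero_var[j] <- FALSE
      res$estimate[j] <- NA_real_
      next
    }
    xj <- X[use, j]
    if (stats::var(xj) == 0) {
      res$zero_var[j] <- TRUE
      next
    }
    mm <- cbind(1, C[use, , drop = FALSE], dosage = xj)
    fit <- stats::lm.fit(mm, y[use])
    if (any(is.na(fit$coefficients))) {      # aliased covariate
      res$zero_var[j] <- TRUE
      next
    }
    dfres <- nj - n_par
    sigma2 <- sum(fit$residuals^2) / dfres
    xtxi <- chol2inv(fit$qr$qr[seq_len(n_par), , drop = FALSE])
    se <- sqrt(sigma2 * xtxi[n_par, n_par])
    est <- fit$coefficients[[n_par]]
    res$estimate[j] <- est
    res$se[j] <- se
    res$statistic[j] <- est / se
    res$p[j] <- 2 * pt(-abs(est / se), dfres)
  }
  assoc_tibble(snp_ids(g), res, min_n = n_par + 2L)
}

#' Within-family quantitative trio association test
#'
#' A stratification-robust test for quantitative traits on parent-offspring
#' trios. For each SNP the within-family genotype component
#' `b = dosage_offspring - (dosage_father + dosage_mother) / 2`
#' is computed per trio; under Mendelian transmission `b` has mean zero
#' within every family regardless of ancestry, so regressing the offspring
#' phenotype on `b` (with intercept) is immune to population
#' stratification. The slope is tested two-sided against zero with a t
#' distribution on `n_trios - 2` degrees of freedom, or, when `n_perm > 0`,
#' with an empirical p-value from random permutations of `b` across trios
#' (under the null the within-family components are exchangeable with
#' respect to the phenotype labels).
#'
#' Trios drawn from the same extended pedigree are treated as independent;
#' this mirrors the break-into-trios simplification and slightly
#' understates the variance when many trios share parents.
#'
#' @param g A [genotype_matrix()] covering parents and offspring.
#' @param trios A `trio_set` from [extract_trios()] (or any tibble with
#'   `father`, `mother`, `offspring` id columns present in `g`).
#' @param pheno A phenotype tibble with `individual_id` and `map_value`
#'   covering every offspring.
#' @param n_perm Number of permutations; 0 (default) uses the asymptotic
#'   t test. The empirical p-value is
#'   `(1 + #{|t*| >= |t|}) / (n_perm + 1)`.
#' @return A tibble as in [population_assoc()]; `status` is
#'   `monomorphic` when a SNP has no within-family variation (all `b`
#'   equal) and `insufficient_data` when fewer than 3 trios are usable.
#' @export
trio_within_test <- function(g, trios, pheno, n_perm = 0L) {
  if (!inherits(g, "genotype_matrix")) stop_invalid("`g` must be a genotype_matrix.")
  if (!all(c("father", "mother", "offspring") %in% names(trios))) {
    stop_invalid("`trios` must have columns `father`, `mother`, `offspring`.")
  }
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 0) {
    stop_invalid("`n_perm` must be a single non-negative integer.")
  }
  ids <- individual_ids(g)
  fi <- match(trios$father, ids)
  mi <- match(trios$mother, ids)
  oi <- match(trios$offspring, ids)
  if (anyNA(fi) || anyNA(mi) || anyNA(oi)) {
    stop_invalid("Every trio member must be genotyped in `g`.")
  }
  ph <- pheno[match(trios$offspring, pheno$individual_id), ]
  if (anyNA(ph$individual_id)) {
    stop_invalid("Every offspring must appear in `pheno`.")
  }
  y <- as.numeric(ph$map_value)
  d <- g$dosages
  b <- d[oi, , drop = FALSE] - (d[fi, , drop = FALSE] + d[mi, , drop = FALSE]) / 2

  fit <- col_simple_reg(b, y)
  out <- assoc_tibble(snp_ids(g), fit, min_n = 3L)

  if (n_perm > 0L) {
    n_perm <- as.integer(n_perm)
    n <- nrow(b)
    for (j in which(out$status == "ok")) {
      use <- !is.na(b[, j]) & !is.na(y)
      bj <- b[use, j]
      nb <- length(bj)
      B <- vapply(seq_len(n_perm), function(k) bj[sample.int(nb)],
                  numeric(nb))
      pf <- col_simple_reg(B, y[use])
      t_obs <- abs(out$statistic[j])
      out$p.value[j] <- (1 + sum(abs(pf$statistic) >= t_obs, na.rm = TRUE)) /
        (n_perm + 1)
    }
  }
  out
}
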