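#' Simulation configuration
#'
#' Bundles the parameters of the generative model used by the power
#' study: trio families and an independent population cohort, with a
#' phenotype generated as `y = beta * dosage + alpha_intercept + eps`,
#' `eps ~ N(0, sigma^2)`, founder genotypes drawn from Hardy-Weinberg
#' proportions at the given minor allele frequency, and offspring
#' genotypes by Mendelian transmission.
#'
#' The reference design is 250 trio families and 250 independent
#' individuals per SNP, with 49,999 null SNPs plus 1 causal SNP and 1000
#' replications; the desk-scale defaults (`m_null = 4999`,
#' `n_reps = 200`) keep the same structure at a size a power curve can be
#' recomputed in minutes, and every field is configurable up to the
#' reference design.
#'
#' @param n_trios Number of trio families.
#' @param n_pop Number of unrelated individuals in the population cohort
#'   (a fresh cohort is drawn for every SNP, keeping SNPs independent).
#' @param m_null Number of null SNPs (no phenotype effect).
#' @param n_causal Number of causal SNPs (placed first in SNP order).
#' @param beta Causal effect size, phenotype units per minor allele.
#' @param alpha_intercept Phenotype intercept.
#' @param sigma Residual standard deviation of the phenotype.
#' @param maf Minor allele frequency of every simulated SNP, in (0, 0.5].
#' @param alpha_level Nominal FDR level for both procedures.
#' @param n_reps Replications per effect size in [power_study()].
#' @param seed Optional integer seed; when set, [run_replication()] and
#'   [power_study()] are pure functions of the configuration.
#' @param fast_null If `TRUE`, null-SNP p-values (family and population)
#'   are drawn directly from Uniform(0, 1) instead of simulating
#'   genotypes and running the tests; an approximation that makes very
#'   large `m_null` affordable. Causal SNPs are always simulated in full.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_trios = 250L, n_pop = 250L, m_null = 4999L,
                              n_causal = 1L, beta = 0.5, alpha_intercept = 0,
                              sigma = 1, maf = 0.3, alpha_level = 0.05,
                              n_reps = 200L, seed = NULL, fast_null = FALSE) {
  stopifnot_cfg <- function(ok, msg) if (!ok) stop_invalid(msg)
  stopifnot_cfg(is.numeric(n_trios) && n_trios >= 1, "`n_trios` must be >= 1.")
  stopifnot_cfg(is.numeric(n_pop) && n_pop >= 1, "`n_pop` must be >= 1.")
  stopifnot_cfg(is.numeric(m_null) && m_null >= 0, "`m_null` must be >= 0.")
  stopifnot_cfg(is.numeric(n_causal) && n_causal >= 0, "`n_causal` must be >= 0.")
  stopifnot_cfg(m_null + n_causal >= 1, "At least one SNP must be simulated.")
  stopifnot_cfg(is.numeric(beta) && is.finite(beta), "`beta` must be finite.")
  stopifnot_cfg(is.numeric(sigma) && sigma > 0, "`sigma` must be positive.")
  stopifnot_cfg(is.numeric(maf) && maf > 0 && maf <= 0.5,
                "`maf` must be in (0, 0.5].")
  check_alpha(alpha_level)
  stopifnot_cfg(is.numeric(n_reps) && n_reps >= 1, "`n_reps` must be >= 1.")
  structure(list(
    n_trios = as.integer(n_trios), n_pop = as.integer(n_pop),
    m_null = as.integer(m_null), n_causal = as.integer(n_causal),
    beta = beta, alpha_intercept = alpha_intercept, sigma = sigma,
    maf = maf, alpha_level = alpha_level, n_reps = as.integer(n_reps),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    fast_null = isTRUE(fast_null)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  for (f in setdiff(names(x), "seed")) cat(sprintf("  %-15s %s\n", f, format(x[[f]])))
  cat(sprintf("  %-15s %s\n", "seed", if (is.null(x$seed)) "<unset>" else x$seed))
  invisible(x)
}

#' Simulate trio genotypes under Hardy-Weinberg and Mendelian transmission
#'
#' Each parent's dosage at each SNP is drawn from Hardy-Weinberg
#' proportions at `maf` (Binomial(2, maf)); each offspring allele is a
#' uniform draw from the corresponding parent's two alleles, so a
#' homozygous parent transmits its allele with certainty and a
#' heterozygous parent transmits the minor allele with probability 1/2.
#' SNPs are independent (no linkage disequilibrium).
#'
#' @param n_trios Number of trio families.
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param n_snps Number of independent SNPs.
#' @return A list with `genotypes` (a [genotype_matrix()] over
#'   `3 * n_trios` individuals named `F<i>`, `M<i>`, `O<i>`) and `trios`
#'   (a `trio_set` tibble with one row per family).
#' @export
simulate_trio_genotypes <- function(n_trios, maf, n_snps = 1L) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5) {
    stop_invalid("`maf` must be in (0, 0.5].")
  }
  n_trios <- as.integer(n_trios)
  n_snps <- as.integer(n_snps)
  N <- n_trios * n_snps
  fa <- matrix(rbinom(N, 2L, maf), n_trios, n_snps)
  mo <- matrix(rbinom(N, 2L, maf), n_trios, n_snps)
  # transmitted minor-allele count is Bernoulli(dosage / 2) per parent
  off <- matrix(rbinom(N, 1L, fa / 2) + rbinom(N, 1L, mo / 2),
                n_trios, n_snps)
  idx <- seq_len(n_trios)
  d <- rbind(fa, mo, off)
  rownames(d) <- c(paste0("F", idx), paste0("M", idx), paste0("O", idx))
  snps <- tibble::new_tibble(list(
    snp_id = paste0("snp", seq_len(n_snps)),
    chrom = rep("1", n_snps),
    pos = seq_len(n_snps) * 1000,
    minor_allele = rep("A", n_snps),
    major_allele = rep("G", n_snps)
  ), nrow = n_snps)
  g <- genotype_matrix(d, snps, validate = FALSE)
  trios <- tibble::new_tibble(list(
    family_id = paste0("fam", idx),
    father = paste0("F", idx),
    mother = paste0("M", idx),
    offspring = paste0("O", idx)
  ), nrow = n_trios)
  class(trios) <- c("trio_set", class(trios))
  list(genotypes = g, trios = trios)
}

#' Simulate unrelated genotypes under Hardy-Weinberg equilibrium
#'
#' @param n Number of individuals.
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param n_snps Number of independent SNPs.
#' @return A [genotype_matrix()] with individuals named `P<i>`.
#' @export
simulate_population_genotypes <- function(n, maf, n_snps = 1L) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5) {
    stop_invalid("`maf` must be in (0, 0.5].")
  }
  n <- as.integer(n)
  n_snps <- as.integer(n_snps)
  d <- matrix(rbinom(n * n_snps, 2L, maf), n, n_snps)
  rownames(d) <- paste0("P", seq_len(n))
  snps <- tibble::new_tibble(list(
    snp_id = paste0("snp", seq_len(n_snps)),
    chrom = rep("1", n_snps),
    pos = seq_len(n_snps) * 1000,
    minor_allele = rep("A", n_snps),
    major_allele = rep("G", n_snps)
  ), nrow = n_snps)
  genotype_matrix(d, snps, validate = FALSE)
}

#' Simulate phenotypes from genotype dosages
#'
#' `y = beta * dosage + alpha_intercept + eps` with independent
#' `eps ~ N(0, sigma^2)`; vectorised over a dosage vector or matrix
#' (shape is preserved).
#'
#' @param dosages Numeric vector or matrix of minor-allele dosages.
#' @param beta Effect size, phenotype units per minor allele.
#' @param alpha_intercept Intercept.
#' @param sigma Residual standard deviation, > 0 (use a tiny value such
#'   as 1e-12 for a noise-free check).
#' @return Phenotypes with the shape of `dosages`.
#' @export
simulate_phenotypes <- function(dosages, beta, alpha_intercept = 0, sigma = 1) {
  if (!is.numeric(sigma) || sigma <= 0) stop_invalid("`sigma` must be positive.")
  y <- beta * dosages + alpha_intercept + rnorm(length(dosages), 0, sigma)
  if (is.matrix(dosages)) dim(y) <- dim(dosages)
  y
}

#' One replication of the FDR-versus-WFDR comparison
#'
#' Generates one complete dataset under the configuration — trio families
#' genotyped at `m_null + n_causal` independent SNPs with a single
#' offspring phenotype driven by the causal SNP(s), plus an independent
#' population cohort (fresh individuals per SNP) — then runs the
#' within-family trio test (asymptotic), the population regression, the
#' inverse-p weights and both the ordinary and the weighted BH adjustment
#' at `alpha_level`.
#'
#' @param cfg A [simulation_config()]. When `cfg$seed` is set the result
#'   is deterministic; leave it `NULL` to draw from the session RNG
#'   stream (as [power_study()] does internally).
#' @param beta Optional effect-size override of `cfg$beta`.
#' @return A one-row tibble: `beta`, `rejected_fdr` / `rejected_wfdr`
#'   (was every causal SNP rejected; `NA` when `n_causal = 0`),
#'   `n_fp_fdr` / `n_fp_wfdr` (null SNPs rejected), `n_rej_fdr` /
#'   `n_rej_wfdr` (total rejections).
#' @export
run_replication <- function(cfg, beta = NULL) {
  if (!inherits(cfg, "simulation_config")) {
    stop_invalid("`cfg` must be a simulation_config.")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(beta)) beta <- cfg$beta
  m <- cfg$m_null + cfg$n_causal
  causal <- seq_len(cfg$n_causal)

  if (cfg$fast_null) {
    m_sim <- cfg$n_causal
    if (m_sim == 0L) stop_invalid("`fast_null` requires at least one causal SNP.")
  } else {
    m_sim <- m
  }

  # family arm: one phenotype over the offspring, m SNPs on the same trios
  sim <- simulate_trio_genotypes(cfg$n_trios, cfg$maf, m_sim)
  off_rows <- match(sim$trios$offspring, individual_ids(sim$genotypes))
  g_off <- sim$genotypes$dosages[off_rows, causal, drop = FALSE]
  y_off <- cfg$alpha_intercept + cfg$sigma * rnorm(cfg$n_trios) +
    if (length(causal)) beta * rowSums(g_off) else 0
  pheno <- tibble::new_tibble(
    list(individual_id = sim$trios$offspring, map_value = y_off),
    nrow = cfg$n_trios
  )
  fam <- trio_within_test(sim$genotypes, sim$trios, pheno)
  p_fam_sim <- fam$p.value
  p_fam_sim[is.na(p_fam_sim)] <- 1       # monomorphic SNPs carry no evidence
  p_fam_sim <- pmax(p_fam_sim, 1e-300)   # guard against t-CDF underflow to 0

  # population arm: a fresh cohort of n_pop individuals per SNP, each with
  # its own phenotype vector, so SNPs stay mutually independent
  Gp <- matrix(rbinom(cfg$n_pop * m_sim, 2L, cfg$maf), cfg$n_pop, m_sim)
  Yp <- cfg$alpha_intercept + cfg$sigma * matrix(rnorm(cfg$n_pop * m_sim),
                                                 cfg$n_pop, m_sim)
  if (length(causal)) {
    Yp[, causal] <- Yp[, causal] + beta * Gp[, causal, drop = FALSE]
  }
  pop <- col_simple_reg(Gp, Yp)
  p_pop_sim <- pop$p
  p_pop_sim[!is.finite(p_pop_sim)] <- 1

  if (cfg$fast_null) {
    p_fam <- c(p_fam_sim, runif(cfg$m_null))
    p_pop <- c(p_pop_sim, runif(cfg$m_null))
  } else {
    p_fam <- p_fam_sim
    p_pop <- p_pop_sim
  }
  snp_id <- paste0("snp", seq_len(m))

  fam_tbl <- tibble::new_tibble(list(snp_id = snp_id, p = p_fam), nrow = m)
  pop_tbl <- tibble::new_tibble(list(snp_id = snp_id, p = p_pop), nrow = m)
  bh <- bh_adjust(fam_tbl, alpha = cfg$alpha_level)
  w <- compute_weights(pop_tbl)
  wf <- wfdr_adjust(fam_tbl, w, alpha = cfg$alpha_level)

  is_causal <- seq_len(m) %in% causal
  tibble::tibble(
    beta = beta,
    rejected_fdr = if (any(is_causal)) all(bh$rejected[is_causal]) else NA,
    rejected_wfdr = if (any(is_causal)) all(wf$rejected[is_causal]) else NA,
    n_fp_fdr = sum(bh$rejected[!is_causal]),
    n_fp_wfdr = sum(wf$rejected[!is_causal]),
    n_rej_fdr = sum(bh$rejected),
    n_rej_wfdr = sum(wf$rejected)
  )
}

#' Replication-counting power study: ordinary FDR versus weighted FDR
#'
#' For each effect size, runs `cfg$n_reps` independent replications of
#' [run_replication()] and counts in how many the causal SNP is declared
#' significant by each procedure. Empirical power is that fraction; its
#' Monte-Carlo standard error is `sqrt(p * (1 - p) / n_reps)`.
#'
#' @param cfg A [simulation_config()]; `cfg$seed`, when set, seeds the
#'   whole study once so the result is reproducible.
#' @param betas Effect sizes to scan; the default is the ten-point grid
#'   0.1, 0.3, 0.4, 0.5, 0.6, 0.8, 0.9, 1.0, 1.5, 2.0.
#' @return A `power_result` tibble: `beta`, `method` (`fdr` / `wfdr`),
#'   `n_reps`, `n_significant`, `power`, `mc_se`, plus a
#'   `mean_fdp` column (mean false-discovery proportion across
#'   replications).
#' @export
power_study <- function(cfg, betas = c(0.1, 0.3, 0.4, 0.5, 0.6, 0.8, 0.9,
                                       1.0, 1.5, 2.0)) {
  if (!inherits(cfg, "simulation_config")) {
    stop_invalid("`cfg` must be a simulation_config.")
  }
  if (length(betas) == 0L) stop_invalid("`betas` must be non-empty.")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_inner <- cfg
  cfg_inner$seed <- NULL                 # one stream for the whole study
  rows <- purrr::map(betas, function(b) {
    reps <- purrr::map(seq_len(cfg$n_reps),
                       function(i) run_replication(cfg_inner, beta = b))
    reps <- dplyr::bind_rows(reps)
    fdp <- function(n_fp, n_rej) mean(ifelse(n_rej > 0, n_fp / n_rej, 0))
    tibble::tibble(
      beta = b,
      method = c("fdr", "wfdr"),
      n_reps = cfg$n_reps,
      n_significant = c(sum(reps$rejected_fdr), sum(reps$rejected_wfdr)),
      mean_fdp = c(fdp(reps$n_fp_fdr, reps$n_rej_fdr),
                   fdp(reps$n_fp_wfdr, reps$n_rej_wfdr))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$power <- out$n_significant / out$n_reps
  out$mc_se <- sqrt(out$power * (1 - out$power) / out$n_reps)
  out <- out[, c("beta", "method", "n_reps", "n_significant", "power",
                 "mc_se", "mean_fdp")]
  class(out) <- c("power_result", class(out))
  attr(out, "config") <- cfg
  out
}

#' @method glance power_result
#' @export
glance.power_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x[, c("beta", "method", "power")],
                             names_from = "method", values_from = "power")
  tibble::tibble(
    n_betas = length(unique(x$beta)),
    n_reps = x$n_reps[1L],
    max_power_fdr = max(wide$fdr),
    max_power_wfdr = max(wide$wfdr),
    max_power_gain = max(wide$wfdr - wide$fdr)
  )
}

#' Plot an empirical power curve
#'
#' Power against effect size, one line per multiple-testing procedure,
#' with pointwise +/- 2 Monte-Carlo-standard-error ribbons.
#'
#' @param object A `power_result` from [power_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_result
#' @export
autoplot.power_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta, y = .data$power,
                                       colour = .data$method,
                                       fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$power - 2 * .data$mc_se),
                                      ymax = pmin(1, .data$power + 2 * .data$mc_se)),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "effect size (phenotype units per minor allele)",
                  y = "empirical power",
                  colour = "method", fill = "method")
}
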