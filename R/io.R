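#' Read PLINK text ped/map files
#'
#' Parses the whitespace-delimited PLINK text dialect: the map file has one
#' line per SNP with columns chromosome, SNP id, (optional genetic
#' distance,) 1-based base-pair position; the ped file has six leading
#' columns (family id, individual id, father id, mother id, sex, phenotype
#' placeholder) followed by two allele columns per SNP, with `0` as the
#' missing-allele code.
#'
#' Dosage is counted against the minor allele, determined from allele
#' counts among pedigree founders when the file contains any parent-child
#' links, otherwise among all individuals; a tie at 50% is broken so the
#' lexicographically smaller allele is called minor. A genotype with
#' either allele missing becomes a missing dosage.
#'
#' @param ped_path,map_path Paths to the ped and map files.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `pedigree` (a tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`).
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop_parse(paste0("ped file not found: ", ped_path))
  if (!file.exists(map_path)) stop_parse(paste0("map file not found: ", map_path))

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf != 3L & nf != 4L)) {
    stop_parse(sprintf("map line %d: expected 3 or 4 fields, found %d.",
                       which(nf != 3L & nf != 4L)[1L],
                       nf[which(nf != 3L & nf != 4L)[1L]]))
  }
  chrom <- vapply(map_fields, `[[`, "", 1L)
  snp_id <- vapply(map_fields, `[[`, "", 2L)
  pos <- suppressWarnings(as.numeric(vapply(map_fields, function(f) f[[length(f)]], "")))
  if (anyNA(pos)) {
    stop_parse(sprintf("map line %d: base-pair position is not numeric.",
                       which(is.na(pos))[1L]))
  }
  if (anyDuplicated(snp_id)) {
    stop_parse("map file contains duplicate SNP ids.")
  }
  m <- length(snp_id)

  ped_lines <- readLines(ped_path)
  keep <- nzchar(trimws(ped_lines))
  line_no <- which(keep)
  ped_fields <- strsplit(trimws(ped_lines[keep]), "[ \t]+")
  n <- length(ped_fields)
  if (n == 0L) stop_parse("ped file contains no individuals.")
  nf <- lengths(ped_fields)
  expected <- 6L + 2L * m
  if (any(nf != expected)) {
    bad <- which(nf != expected)[1L]
    stop_parse(sprintf(
      "ped line %d: expected %d fields (6 + 2 alleles x %d SNPs), found %d.",
      line_no[bad], expected, m, nf[bad]))
  }
  lead <- t(vapply(ped_fields, function(f) f[1:6], character(6L)))
  individual_id <- lead[, 2L]
  if (anyDuplicated(individual_id)) {
    dup <- individual_id[duplicated(individual_id)][1L]
    stop_parse(sprintf("ped line %d: duplicate individual id '%s'.",
                       line_no[which(individual_id == dup)[2L]], dup))
  }
  pedigree <- tibble::tibble(
    family_id = lead[, 1L], individual_id = individual_id,
    father_id = lead[, 3L], mother_id = lead[, 4L], sex = lead[, 5L]
  )

  # alleles: n x 2m character matrix
  al <- t(vapply(ped_fields, function(f) f[-(1:6)], character(2L * m)))
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]

  founder <- pedigree$father_id == "0" & pedigree$mother_id == "0"
  counting_set <- if (any(!founder)) founder else rep(TRUE, n)

  minor <- character(m)
  major <- character(m)
  dos <- matrix(NA_real_, n, m, dimnames = list(individual_id, snp_id))
  for (j in seq_len(m)) {
    obs <- c(a1[counting_set, j], a2[counting_set, j])
    obs <- obs[obs != "0"]
    if (length(obs) == 0L) {
      # fall back to everyone if the counting set is entirely missing
      obs <- c(a1[, j], a2[, j])
      obs <- obs[obs != "0"]
    }
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) {
      stop_parse(sprintf("SNP '%s': more than two alleles observed.", snp_id[j]))
    }
    if (length(alleles) == 0L) {
      minor[j] <- "0"; major[j] <- "0"
      next
    }
    if (length(alleles) == 1L) {
      minor[j] <- "0"; major[j] <- alleles
    } else {
      cnt <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
      # tie at 50%: lexicographically smaller allele (alleles[1]) is minor
      if (cnt[1L] <= cnt[2L]) {
        minor[j] <- alleles[1L]; major[j] <- alleles[2L]
      } else {
        minor[j] <- alleles[2L]; major[j] <- alleles[1L]
      }
    }
    ok <- a1[, j] != "0" & a2[, j] != "0"
    dos[ok, j] <- (a1[ok, j] == minor[j]) + (a2[ok, j] == minor[j])
  }

  g <- genotype_matrix(
    dos,
    tibble::tibble(snp_id = snp_id, chrom = chrom, pos = pos,
                   minor_allele = minor, major_allele = major)
  )
  list(genotypes = g, pedigree = pedigree)
}

#' Write PLINK text ped/map files
#'
#' Inverse of [read_ped_map()]: reconstructs allele pairs from minor-allele
#' dosages (0 -> major/major, 1 -> minor/major, 2 -> minor/minor, `NA` ->
#' `0 0`).
#'
#' @param g A [genotype_matrix()].
#' @param ped_path,map_path Output paths.
#' @param pedigree Optional pedigree tibble as returned by
#'   [read_ped_map()]; defaults to singleton founders (family id equal to
#'   the individual id, unknown parents, unknown sex).
#' @param phenotype Optional numeric vector (one per individual) for the
#'   ped phenotype placeholder column; defaults to `-9`.
#' @return The ped path, invisibly.
#' @export
write_ped_map <- function(g, ped_path, map_path, pedigree = NULL,
                          phenotype = NULL) {
  ids <- individual_ids(g)
  n <- length(ids)
  if (is.null(pedigree)) {
    pedigree <- tibble::tibble(family_id = ids, individual_id = ids,
                               father_id = "0", mother_id = "0", sex = "0")
  }
  pedigree <- pedigree[match(ids, pedigree$individual_id), ]
  if (anyNA(pedigree$individual_id)) {
    stop_invalid("`pedigree` must cover every genotyped individual.")
  }
  if (is.null(phenotype)) phenotype <- rep(-9, n)

  writeLines(
    paste(g$snps$chrom, g$snps$snp_id, 0, format(g$snps$pos, scientific = FALSE, trim = TRUE),
          sep = "\t"),
    map_path
  )

  d <- g$dosages
  minor <- g$snps$minor_allele
  major <- g$snps$major_allele
  rows <- character(n)
  for (i in seq_len(n)) {
    a1 <- ifelse(is.na(d[i, ]), "0", ifelse(d[i, ] >= 1, minor, major))
    a2 <- ifelse(is.na(d[i, ]), "0", ifelse(d[i, ] == 2, minor, major))
    rows[i] <- paste(c(pedigree$family_id[i], pedigree$individual_id[i],
                       pedigree$father_id[i], pedigree$mother_id[i],
                       pedigree$sex[i], phenotype[i],
                       as.vector(rbind(a1, a2))), collapse = " ")
  }
  writeLines(rows, ped_path)
  invisible(ped_path)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated file with a mandatory header. Must contain
#' `individual_id` and either `map_value` (mean arterial pressure, mmHg)
#' or both `sbp` and `dbp`, from which MAP is derived via [compute_map()].
#' All remaining columns are carried along as covariates.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `individual_id`, `map_value` and any covariate
#'   columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("phenotype file not found: ", path))
  df <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                            colClasses = NA))
  if (!"individual_id" %in% names(df)) {
    stop_parse("phenotype file must have an `individual_id` column.")
  }
  df$individual_id <- as.character(df$individual_id)
  if (anyDuplicated(df$individual_id)) {
    stop_parse("phenotype file contains duplicate individual ids.")
  }
  if (!"map_value" %in% names(df)) {
    if (!all(c("sbp", "dbp") %in% names(df))) {
      stop_parse("phenotype file must have `map_value` or both `sbp` and `dbp`.")
    }
    df$map_value <- compute_map(df$sbp, df$dbp)
  }
  df
}

#' Read a two-column SNP p-value table
#'
#' Tab-separated file with a header and columns `snp_id` and `p`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `snp_id` (character) and `p` (numeric).
#' @export
read_pvalues <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("p-value file not found: ", path))
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("snp_id", "p") %in% names(df))) {
    stop_parse("p-value file must have columns `snp_id` and `p`.")
  }
  tibble::tibble(snp_id = as.character(df$snp_id), p = as.numeric(df$p))
}
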