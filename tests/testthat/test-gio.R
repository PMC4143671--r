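test_that("compute_map evaluates the MAP formula and guards pressure ordering", {
  expect_equal(compute_map(93, 93), 93)
  expect_equal(compute_map(120, 80), (2 * 80 + 120) / 3)
  expect_equal(compute_map(100, 70), 80)
  expect_equal(compute_map(c(120, 100), c(80, 70)), c(93 + 1 / 3, 80))
  expect_error(compute_map(70, 100), class = "wfdrtrio_error_invalid")
  expect_error(compute_map(100, 0), class = "wfdrtrio_error_invalid")
})

test_that("read_ped_map parses the PLINK text dialect and calls the minor allele", {
  dir <- withr::local_tempdir()
  fx <- write_ped_fixture(dir)
  dat <- read_ped_map(fx$ped, fx$map)
  g <- dat$genotypes

  expect_identical(snp_ids(g), c("snp1", "snp2", "snp3"))
  expect_identical(individual_ids(g), c("dad", "mum", "kid", "s1", "s2"))
  expect_identical(dat$pedigree$father_id, c("0", "0", "dad", "0", "0"))

  # snp1: founders carry 3 G / 5 A, so G is minor and "G G" has dosage 2
  expect_identical(g$snps$minor_allele[1], "G")
  expect_equal(unname(g$dosages[, "snp1"]), c(0, 1, 1, 0, 2))
  # snp2: "0 0" is a missing dosage
  expect_true(is.na(g$dosages["s1", "snp2"]))
  # snp3: monomorphic, only the major allele observed
  expect_identical(g$snps$minor_allele[3], "0")
  expect_equal(unname(g$dosages[, "snp3"]), rep(0, 5))
})

test_that("a ten-allele panel with 3 G calls makes G the minor allele", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "f1 i1 0 0 1 -9 A A",
    "f1 i2 0 0 1 -9 A G",
    "f1 i3 0 0 1 -9 A A",
    "f1 i4 0 0 1 -9 A G",
    "f1 i5 0 0 1 -9 G G"
  ), file.path(dir, "x.ped"))
  writeLines("1\trs1\t0\t500", file.path(dir, "x.map"))
  dat <- read_ped_map(file.path(dir, "x.ped"), file.path(dir, "x.map"))
  expect_identical(dat$genotypes$snps$minor_allele, "G")
  expect_equal(unname(dat$genotypes$dosages[, 1]), c(0, 1, 0, 1, 2))
})

test_that("write then read of a genotype fixture is the identity", {
  dir <- withr::local_tempdir()
  fx <- write_ped_fixture(dir)
  dat <- read_ped_map(fx$ped, fx$map)
  write_ped_map(dat$genotypes, file.path(dir, "rt.ped"), file.path(dir, "rt.map"),
                pedigree = dat$pedigree)
  rt <- read_ped_map(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  expect_equal(rt$genotypes$dosages, dat$genotypes$dosages)
  expect_equal(rt$genotypes$snps, dat$genotypes$snps)
  expect_equal(rt$pedigree$individual_id, dat$pedigree$individual_id)
})

test_that("malformed ped/map files fail with a line-numbered parse error", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200"), file.path(dir, "m.map"))
  writeLines(c(
    "f1 a 0 0 1 -9 A A G G",
    "f1 b 0 0 1 -9 A A G"      # ragged: one allele short
  ), file.path(dir, "bad.ped"))
  err <- expect_error(read_ped_map(file.path(dir, "bad.ped"), file.path(dir, "m.map")),
                      class = "wfdrtrio_error_parse")
  expect_match(conditionMessage(err), "line 2")

  writeLines(c(
    "f1 a 0 0 1 -9 A A G G",
    "f1 a 0 0 1 -9 A A G G"    # duplicate id
  ), file.path(dir, "dup.ped"))
  expect_error(read_ped_map(file.path(dir, "dup.ped"), file.path(dir, "m.map")),
               class = "wfdrtrio_error_parse")
})

test_that("qc_filter drops by missingness then MAF, retaining boundary values", {
  # 10 individuals, 4 SNPs:
  #  keep1: complete, MAF 0.3; drop_miss: 60% missing;
  #  drop_maf: MAF 0.02 is impossible with n=10, use complete MAF 0 (monomorphic);
  #  boundary: exactly 5% missing is retained at max_missing = 0.05 needs n=20.
  n <- 20
  d <- cbind(
    keep1 = rep(c(0, 1, 2, 1, 0), 4),
    drop_miss = c(rep(NA, 12), rep(1, 8)),
    drop_maf = c(1, rep(0, 19)),            # MAF 0.025 < 0.05
    boundary_miss = c(NA, rep(c(0, 1), 9), 1),  # exactly 1/20 missing
    boundary_maf = c(rep(1, 2), rep(0, 18))     # MAF exactly 0.05
  )
  rownames(d) <- paste0("i", 1:n)
  g <- genotype_matrix(d, tibble::tibble(
    snp_id = colnames(d), chrom = "1", pos = 1:5, minor_allele = "A",
    major_allele = "G"
  ))
  qc <- qc_filter(g, max_missing = 0.05, min_maf = 0.05)
  expect_identical(snp_ids(qc$genotypes), c("keep1", "boundary_miss", "boundary_maf"))
  expect_equal(qc$report$n_removed, c(1, 1))
  expect_identical(qc$report$step, c("missing_rate", "maf"))

  # idempotence
  qc2 <- qc_filter(qc$genotypes, max_missing = 0.05, min_maf = 0.05)
  expect_equal(qc2$report$n_removed, c(0, 0))
  expect_identical(snp_ids(qc2$genotypes), snp_ids(qc$genotypes))
})

test_that("individual-level QC honours the exclusion list and missingness cutoff", {
  d <- rbind(good = c(0, 1, 2, 1), holey = c(NA, NA, NA, 1), out = c(0, 0, 1, 1))
  colnames(d) <- paste0("s", 1:4)
  g <- genotype_matrix(d, tibble::tibble(
    snp_id = colnames(d), chrom = "1", pos = 1:4, minor_allele = "A",
    major_allele = "G"
  ))
  res <- filter_individuals(g, max_missing = 0.5, exclude = "out")
  expect_identical(individual_ids(res$genotypes), "good")
  expect_equal(res$report$n_removed, c(1, 1))
})

test_that("extract_trios yields one trio per eligible offspring", {
  # family: 2 genotyped parents, 3 genotyped offspring, one of them
  # unphenotyped; plus a family with one ungenotyped parent
  ped <- tibble::tibble(
    family_id = c("f1", "f1", "f1", "f1", "f1", "f2", "f2", "f2"),
    individual_id = c("p1", "p2", "c1", "c2", "c3", "q1", "q2", "d1"),
    father_id = c("0", "0", "p1", "p1", "p1", "0", "0", "q1"),
    mother_id = c("0", "0", "p2", "p2", "p2", "0", "0", "q2"),
    sex = "0"
  )
  gen_ids <- c("p1", "p2", "c1", "c2", "c3", "q1", "d1")  # q2 not genotyped
  d <- matrix(0, length(gen_ids), 1, dimnames = list(gen_ids, "s1"))
  g <- genotype_matrix(d, tibble::tibble(snp_id = "s1", chrom = "1", pos = 1,
                                         minor_allele = "A", major_allele = "G"))
  pheno <- tibble::tibble(individual_id = c("c1", "c2", "c3", "d1"),
                          map_value = c(90, 85, NA, 88))  # c3 unphenotyped

  trios <- extract_trios(g, ped, pheno)
  expect_equal(nrow(trios), 2)
  expect_identical(sort(trios$offspring), c("c1", "c2"))
  # never more trios than phenotyped, genotyped non-founders
  nonfounders <- ped$individual_id[ped$father_id != "0"]
  expect_lte(nrow(trios),
             sum(nonfounders %in% gen_ids &
                   nonfounders %in% pheno$individual_id[!is.na(pheno$map_value)]))
})

test_that("pedigree validation catches dangling parents and cycles", {
  ok <- tibble::tibble(family_id = "f", individual_id = c("a", "b", "c"),
                       father_id = c("0", "0", "a"), mother_id = c("0", "0", "b"),
                       sex = "0")
  expect_silent(validate_pedigree(ok))

  bad_ref <- ok
  bad_ref$father_id[3] <- "ghost"
  expect_error(validate_pedigree(bad_ref), class = "wfdrtrio_error_invalid")

  cyc <- tibble::tibble(family_id = "f", individual_id = c("a", "b"),
                        father_id = c("b", "a"), mother_id = c("0", "0"),
                        sex = "0")
  expect_error(validate_pedigree(cyc), class = "wfdrtrio_error_invalid")
})

test_that("merge_snp_panels intersects, reorders and reconciles allele orientation", {
  mk <- function(ids, snps, d, minor, major) {
    genotype_matrix(matrix(d, length(ids), length(snps),
                           dimnames = list(ids, snps)),
                    tibble::tibble(snp_id = snps, chrom = "1",
                                   pos = seq_along(snps),
                                   minor_allele = minor, major_allele = major))
  }
  a <- mk(c("i1", "i2"), paste0("s", 1:5), rep(c(0, 1), 5),
          rep("A", 5), rep("G", 5))
  b <- mk(c("j1", "j2"), c("s2", "s4", "s5", "s9"), rep(1, 8),
          rep("A", 4), rep("G", 4))
  res <- merge_snp_panels(a, b)
  expect_identical(snp_ids(res$a), c("s2", "s4", "s5"))
  expect_identical(snp_ids(res$a), snp_ids(res$b))

  # identical panels: unchanged
  self <- merge_snp_panels(a, a)
  expect_equal(self$a$dosages, a$dosages)
  expect_equal(self$b$dosages, a$dosages)

  # swapped allele labels: dosages of b flipped so 2 counts the same allele
  b_sw <- mk(c("j1", "j2"), "s1", c(2, 0), "G", "A")
  res_sw <- merge_snp_panels(subset_snps_for_test(a, "s1"), b_sw)
  expect_identical(res_sw$flipped, "s1")
  expect_equal(unname(res_sw$b$dosages[, 1]), c(0, 2))
  expect_identical(res_sw$b$snps$minor_allele, "A")

  # irreconcilable allele pairs are excluded with a warning
  b_bad <- mk(c("j1", "j2"), "s1", c(0, 1), "C", "T")
  expect_warning(res_bad <- merge_snp_panels(subset_snps_for_test(a, "s1"), b_bad),
                 "irreconcilable")
  expect_equal(length(snp_ids(res_bad$a)), 0)
  expect_identical(res_bad$excluded, "s1")
})

test_that("read_phenotypes derives MAP from SBP/DBP when needed", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ph.tsv")
  writeLines(c("individual_id\tsbp\tdbp\tsex",
               "i1\t120\t80\t1",
               "i2\t100\t70\t2"), path)
  ph <- read_phenotypes(path)
  expect_equal(ph$map_value, c(compute_map(120, 80), 80))

  writeLines(c("individual_id\tsex", "i1\t1"), path)
  expect_error(read_phenotypes(path), class = "wfdrtrio_error_parse")
})
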