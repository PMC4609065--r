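write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("PLINK text parsing counts the minor allele and handles missing", {
  map <- write_lines_tmp("1 rs0001 0 100")
  ped <- write_lines_tmp(c("F1 S1 0 0 1 0 A A",
                           "F2 S2 0 0 1 0 A G",
                           "F3 S3 0 0 1 0 0 0"))
  ds <- read_plink_text(ped, map)
  expect_equal(unname(ds$calls[, "rs0001"]), c(0L, 1L, NA))
  expect_equal(ds$allele_labels$minor, "G")
  expect_equal(ds$allele_labels$major, "A")
  expect_true(ds$oriented)
  expect_equal(ds$positions$pos, 100L)
})

test_that("non-biallelic SNPs are rejected with the SNP named", {
  map <- write_lines_tmp(c("1 rs0001 0 100", "1 rs0002 0 200"))
  ped <- write_lines_tmp(c("F1 S1 0 0 1 0 A A C G",
                           "F2 S2 0 0 1 0 A G C T",
                           "F3 S3 0 0 1 0 A A A C"))
  expect_error(read_plink_text(ped, map), "rs0002")
})

test_that("ped/map SNP count mismatch is a format error", {
  map <- write_lines_tmp(c("1 rs0001 0 100", "1 rs0002 0 200"))
  ped <- write_lines_tmp("F1 S1 0 0 1 0 A A")
  expect_error(read_plink_text(ped, map), "mismatch")
})

test_that("minor-allele orientation: frequency, tie rule, monomorphic flag", {
  # G at frequency 0.3 is minor
  map <- write_lines_tmp("1 rs0001 0 1")
  ped <- write_lines_tmp(c("F1 S1 0 0 1 0 A A", "F2 S2 0 0 1 0 A A",
                           "F3 S3 0 0 1 0 A G", "F4 S4 0 0 1 0 G G",
                           "F5 S5 0 0 1 0 A A"))
  ds <- read_plink_text(ped, map)
  expect_equal(ds$allele_labels$minor, "G")
  expect_equal(sum(ds$calls, na.rm = TRUE), 3)

  # 50/50 tie: the lexicographically smaller nucleotide is labelled minor
  ped2 <- write_lines_tmp(c("F1 S1 0 0 1 0 A A", "F2 S2 0 0 1 0 G G"))
  ds2 <- read_plink_text(ped2, map)
  expect_equal(ds2$allele_labels$minor, "A")
  expect_equal(unname(ds2$calls[, 1]), c(2L, 0L))

  # monomorphic: all-zero calls, flag set
  ped3 <- write_lines_tmp(c("F1 S1 0 0 1 0 A A", "F2 S2 0 0 1 0 A A"))
  ds3 <- read_plink_text(ped3, map)
  expect_true(all(ds3$calls == 0))
  expect_true(ds3$monomorphic[1])
})

test_that("orientation is idempotent", {
  set.seed(42)
  calls <- matrix(sample(c(0:2, NA), 60, TRUE, prob = c(.2, .3, .45, .05)),
                  nrow = 10,
                  dimnames = list(paste0("S", 1:10), paste0("rs", 1:6)))
  ds <- genotype_dataset(calls,
                         allele_labels = tibble::tibble(
                           snp_id = paste0("rs", 1:6),
                           major = rep("A", 6), minor = rep("G", 6)))
  once <- orient_minor_allele(ds)
  twice <- orient_minor_allele(once)
  expect_identical(once$calls, twice$calls)
  expect_identical(once$allele_labels, twice$allele_labels)
  # every oriented SNP counts the less frequent allele
  freq <- colSums(once$calls, na.rm = TRUE) /
    (2 * colSums(!is.na(once$calls)))
  expect_true(all(freq <= 0.5 + 1e-12))
})

test_that("phenotype reading derives the responder grouping and validates", {
  tsv <- write_lines_tmp(c(
    "sample_id\tregimen\trecist\tcr_grade\tchem_history",
    "S1\tS-1\tPR\t0\tTRUE",
    "S2\tS-1\tNC\t1\tFALSE",
    "S3\thigh-dose 5-FU\tCR\t2\tTRUE",
    "S4\t5-FU/MTX\tPD\t0\tFALSE"))
  ph <- read_phenotypes(tsv)
  expect_equal(ph$response, c(1L, 0L, 1L, 0L))
  expect_s3_class(ph$recist, "ordered")
  expect_equal(levels(ph$recist), c("CR", "PR", "NC", "PD"))

  bad <- write_lines_tmp(c(
    "sample_id\tregimen\trecist\tcr_grade\tchem_history",
    "S1\tS-1\tXX\t0\tTRUE"))
  expect_error(read_phenotypes(bad), "RECIST")
  dup <- write_lines_tmp(c(
    "sample_id\tregimen\trecist\tcr_grade\tchem_history",
    "S1\tS-1\tPR\t0\tTRUE",
    "S1\tS-1\tNC\t0\tTRUE"))
  expect_error(read_phenotypes(dup), "duplicate")
})

test_that("dataset split nests the S-1 subset in the full cohort", {
  ph <- toy_phenotypes(rep(c(0, 1), 10), n_s1 = 8)
  sp <- split_datasets(ph)
  expect_length(sp$first, 8)
  expect_length(sp$second, 20)
  expect_true(all(sp$first %in% sp$second))

  expect_warning(split_datasets(toy_phenotypes(c(0, 1), n_s1 = 0)),
                 "empty")
  all_s1 <- split_datasets(toy_phenotypes(c(0, 1), n_s1 = 2))
  expect_identical(all_s1$first, all_s1$second)
})

test_that("genotype TSV dialect round-trips calls and missingness", {
  set.seed(7)
  calls <- matrix(sample(c(0:2, NA), 50, TRUE), nrow = 5,
                  dimnames = list(paste0("S", 1:5), paste0("rs", 1:10)))
  ds <- genotype_dataset(calls, oriented = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(ds, f)
  back <- read_genotype_tsv(f)
  expect_identical(back$calls, ds$calls)
})

test_that("annotation reading parses semicolon PubMed lists", {
  tsv <- write_lines_tmp(c(
    "snp_id\tgene\tpubmed_ids\tcancer_flag",
    "rs1\tGENE1\t123;456\tFALSE",
    "rs2\tGENE2\t\tTRUE"))
  an <- read_annotations(tsv)
  expect_equal(an$pubmed_ids[[1]], c("123", "456"))
  expect_length(an$pubmed_ids[[2]], 0)
  expect_equal(an$cancer_flag, c(FALSE, TRUE))
})
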