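test_that("genotypes follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n_samples = 10000L, n_snps = 3L, causal = NULL,
                    maf_range = c(0.2, 0.5), seed = 60)
  geno <- simulate_genotypes(cfg)
  for (j in 1:3) {
    cnt <- table(factor(geno$calls[, j], 0:2))
    q <- (cnt[2] + 2 * cnt[3]) / (2 * sum(cnt))
    expected <- sum(cnt) * c((1 - q)^2, 2 * q * (1 - q), q^2)
    gof <- sum((cnt - expected)^2 / expected)
    expect_gt(pchisq(gof, df = 1, lower.tail = FALSE), 0.001)
  }
  # MAF 0.5: heterozygote fraction near 1/2 within 3 binomial sd
  cfg5 <- sim_config(n_samples = 4000L, n_snps = 1L, causal = NULL,
                     maf_range = c(0.5, 0.5), seed = 61)
  het <- mean(simulate_genotypes(cfg5)$calls[, 1] == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("missingness and seeding behave as configured", {
  cfg0 <- sim_config(n_snps = 40L, missing_rate = 0, seed = 62)
  expect_equal(sum(is.na(simulate_genotypes(cfg0)$calls)), 0)
  cfgm <- sim_config(n_snps = 40L, missing_rate = 0.1, seed = 62)
  frac <- mean(is.na(simulate_genotypes(cfgm)$calls))
  expect_lt(abs(frac - 0.1), 0.02)
  g1 <- simulate_genotypes(cfg0)
  g2 <- simulate_genotypes(cfg0)
  expect_identical(g1$calls, g2$calls)
})

test_that("annotations drive the knowledge filter as configured", {
  cfg <- sim_config(n_snps = 400L, p_pubmed = 1, p_cancer = 0, seed = 63)
  an <- simulate_annotation(cfg)
  expect_equal(sum(knowledge_filter(an)$retained), 400)
  cfg0 <- sim_config(n_snps = 400L, p_pubmed = 0, p_cancer = 0.5,
                     seed = 63)
  expect_equal(sum(knowledge_filter(simulate_annotation(cfg0))$retained), 0)
  cfg2 <- sim_config(n_snps = 2000L, p_pubmed = 0.6, p_cancer = 0.2,
                     seed = 64)
  ret <- mean(knowledge_filter(simulate_annotation(cfg2))$retained)
  expect_lt(abs(ret - 0.6 * 0.8), 3 * sqrt(0.48 * 0.52 / 2000))
})

test_that("study fixture has the cohort shape and round-trips", {
  fx <- make_study_fixture(sim_config(n_snps = 30L, seed = 65))
  expect_length(fx$datasets$first, 58)
  expect_length(fx$datasets$second, 119)
  expect_true(all(fx$datasets$first %in% fx$datasets$second))
  scaled <- make_study_fixture(sim_config(n_samples = 60L,
                                          n_first_subset = 30L,
                                          n_snps = 10L, causal = NULL,
                                          seed = 66))
  expect_length(scaled$datasets$first, 30)
  expect_length(scaled$datasets$second, 60)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(fx$genotypes, f)
  expect_identical(read_genotype_tsv(f)$calls, fx$genotypes$calls)
})

test_that("causal effect calibration hits the target allele-model OR", {
  causal <- tibble::tibble(index = 1L, or_allele = 0.1, maf = 0.3)
  cfg <- sim_config(n_samples = 4000L, n_snps = 2L, causal = causal,
                    seed = 67)
  fx <- make_study_fixture(cfg)
  cnt <- table(factor(fx$genotypes$calls[, 1], 0:2),
               fx$phenotypes$response)
  a <- cnt[2, 2] + 2 * cnt[3, 2]; b <- 2 * cnt[1, 2] + cnt[2, 2]
  cc <- cnt[2, 1] + 2 * cnt[3, 1]; d <- 2 * cnt[1, 1] + cnt[2, 1]
  realized <- (a * d) / (b * cc)          # minor-in-responders > 1
  expect_lt(abs(log(1 / realized) - log(0.1)), 0.35)
  # marginal response rate stays at the configured 15.1%
  expect_lt(abs(mean(fx$phenotypes$response) - 0.151), 0.02)
})

test_that("infeasible effect targets error instead of silently weakening", {
  causal <- tibble::tibble(index = c(1L, 2L), or_allele = c(0.05, 0.05),
                           maf = c(0.3, 0.3))
  cfg <- sim_config(n_snps = 4L, causal = causal, seed = 68)
  expect_error(make_study_fixture(cfg), "not attainable")
})

test_that("null SNPs give conservative-to-uniform Fisher p-values", {
  cfg <- sim_config(n_snps = 500L, causal = NULL, seed = 69)
  fx <- make_study_fixture(cfg)
  sp <- stage_pvalues(fx$genotypes, fx$phenotypes)
  frac <- mean(sp$p_value <= 0.05, na.rm = TRUE)
  # the exact test is conservative, so the rejection fraction must not
  # exceed the upper binomial band around the nominal level
  expect_lte(frac, qbinom(0.975, 500, 0.05) / 500)
})

test_that("degenerate cutpoints collapse to one category with a warning", {
  cfg <- sim_config(n_snps = 4L, causal = NULL,
                    cutpoints = c(-30, -29, -28), seed = 70)
  geno <- simulate_genotypes(cfg)
  expect_warning(ph <- simulate_response(geno, cfg), "one response")
  expect_equal(unique(as.character(ph$recist)), "PD")
})

test_that("LD-coupled causal pairs keep HWE marginals and correlate", {
  causal <- tibble::tibble(index = c(1L, 2L), or_allele = c(1, 1),
                           maf = c(0.3, 0.3))
  cfg <- sim_config(n_samples = 6000L, n_snps = 3L, causal = causal,
                    causal_ld_r = 0.5, seed = 71)
  geno <- simulate_genotypes(cfg)
  d1 <- geno$calls[, 1]; d2 <- geno$calls[, 2]
  expect_lt(abs(cor(d1, d2) - 0.5), 0.05)
  expect_lt(abs(mean(d1) / 2 - 0.3), 0.02)
  cnt <- table(factor(d1, 0:2))
  q <- (cnt[2] + 2 * cnt[3]) / (2 * sum(cnt))
  expected <- sum(cnt) * c((1 - q)^2, 2 * q * (1 - q), q^2)
  gof <- sum((cnt - expected)^2 / expected)
  expect_gt(pchisq(gof, df = 1, lower.tail = FALSE), 0.001)
})
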