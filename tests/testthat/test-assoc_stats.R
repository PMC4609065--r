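test_that("genetic-model tables collapse genotype counts correctly", {
  x <- c(0, 4, 6); y <- c(10, 8, 2)
  expect_equal(unclass(build_model_table(x, y, "allele"))[, ],
               matrix(c(16, 4, 12, 28), 2, byrow = TRUE,
                      dimnames = list(c("CR+PR", "NC+PD"),
                                      c("minor", "major"))))
  expect_equal(unname(unclass(build_model_table(x, y, "dominant"))[, ]),
               matrix(c(10, 0, 10, 10), 2, byrow = TRUE))
  expect_equal(unname(unclass(build_model_table(x, y, "recessive"))[, ]),
               matrix(c(6, 4, 2, 18), 2, byrow = TRUE))
  g <- build_model_table(x, y, "genotype")
  expect_equal(dim(g), c(2L, 3L))
  expect_equal(sum(g), 30)
  expect_error(build_model_table(c(-1, 0, 0), y, "allele"), "non-negative")
  td <- tidy(build_model_table(x, y, "allele", snp_id = "rs1"))
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$count), 60)
})

test_that("two-sided Fisher 2x2 matches hand enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
               1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(1, 3, 3, 1), 2, byrow = TRUE)),
               34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)), 1)
})

test_that("Fisher 2x2 agrees with the enumeration oracle and fisher.test", {
  set.seed(1)
  for (i in 1:250) {
    tab <- random_2x2(12)
    p <- fisher_exact_2x2(tab)
    expect_equal(p, oracle_fisher_2x2(tab[1, 1], tab[1, 2],
                                      tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("Fisher p is invariant under row swap, column swap, transpose", {
  set.seed(2)
  for (i in 1:50) {
    tab <- random_2x2(15)
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(tab[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t(tab)), p, tolerance = 1e-12)
  }
})

test_that("r x c exact test: 2x2 consistency, degenerate margins, oracle", {
  set.seed(3)
  tab <- random_2x2(10)
  expect_equal(fisher_exact_rxc(tab), fisher_exact_2x2(tab),
               tolerance = 1e-12)
  expect_equal(fisher_exact_rxc(diag(1, 3)), 1, tolerance = 1e-12)
  # all-zero column is dropped without changing p
  t3 <- matrix(c(3, 0, 1, 1, 0, 4), 2, byrow = TRUE)
  expect_equal(fisher_exact_rxc(t3),
               fisher_exact_rxc(t3[, c(1, 3)]), tolerance = 1e-12)
  for (i in 1:30) {
    tab <- matrix(rpois(6, 2), 2, 3)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_rxc(tab), oracle_fisher_rxc(tab),
                 tolerance = 1e-8)
  }
  for (i in 1:10) {
    tab <- matrix(rpois(9, 1.5), 3, 3)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_rxc(tab), oracle_fisher_rxc(tab),
                 tolerance = 1e-8)
  }
  big <- matrix(50, 3, 3)
  expect_error(fisher_exact_rxc(big, enumeration_bound = 100),
               "Monte|monte")
  p_mc <- fisher_exact_rxc(big, enumeration_bound = 100,
                           monte_carlo = TRUE, replicates = 2000)
  expect_gt(p_mc, 0.5)
})

test_that("odds ratio conventions and boundary cases", {
  t1 <- matrix(c(1, 3, 3, 1), 2, byrow = TRUE)
  expect_equal(odds_ratio(t1, "sample"), 1 / 9, tolerance = 1e-12)
  expect_equal(odds_ratio(matrix(c(0, 5, 3, 4), 2, byrow = TRUE),
                          "sample"), 0)
  expect_equal(odds_ratio(matrix(c(0, 5, 3, 4), 2, byrow = TRUE),
                          "cmle"), 0)
  expect_equal(odds_ratio(matrix(c(3, 0, 4, 5), 2, byrow = TRUE),
                          "sample"), Inf)
  expect_true(is.nan(odds_ratio(matrix(c(0, 5, 0, 4), 2, byrow = TRUE))))
  # row swap inverts the OR (both conventions) when finite and nonzero
  set.seed(4)
  for (i in 1:25) {
    tab <- random_2x2(12)
    for (cv in c("sample", "cmle")) {
      or <- odds_ratio(tab, cv)
      if (is.finite(or) && or > 0) {
        expect_equal(odds_ratio(tab[2:1, ], cv), 1 / or,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("Woolf and exact OR confidence intervals", {
  ci <- or_confidence_interval(matrix(10, 2, 2), method = "woolf")
  z <- qnorm(0.975)
  expect_equal(unname(ci), c(exp(-z * sqrt(0.4)), exp(z * sqrt(0.4))),
               tolerance = 1e-10)
  ci0 <- or_confidence_interval(matrix(c(0, 5, 3, 4), 2, byrow = TRUE))
  expect_equal(unname(ci0[1]), 0)
  expect_error(or_confidence_interval(matrix(10, 2, 2), level = 1.2),
               "level")
  # interval always contains the sample OR when all cells positive
  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(sample(1:12, 4, TRUE), 2)
    or <- odds_ratio(tab, "sample")
    for (m in c("woolf", "exact")) {
      ci <- or_confidence_interval(tab, method = m)
      expect_lte(ci[["low"]], or + 1e-9)
      expect_gte(ci[["high"]], or - 1e-9)
    }
  }
})

test_that("HWE exact test matches enumeration", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(0, 2, 0), 1, tolerance = 1e-12)
  expect_equal(hwe_exact_test(25, 0, 0), 1)
  set.seed(6)
  for (i in 1:200) {
    n <- sample.int(30, 1)
    cnt <- as.integer(rmultinom(1, n, c(0.4, 0.4, 0.2)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
})

test_that("BH adjustment: worked example, edge cases, dominance over p", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.03, 0.05)),
               c(0.004, 0.02, 0.04, 0.05), tolerance = 1e-12)
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("association_table assembles per-SNP per-model statistics", {
  set.seed(8)
  calls <- matrix(sample(0:2, 80, TRUE), nrow = 20)
  geno <- toy_genotypes(calls)
  ph <- toy_phenotypes(rep(c(1, 0), each = 10))
  tab <- association_table(geno, ph)
  expect_equal(nrow(tab), 4 * 3)
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))
  one <- tab[tab$model == "allele" & tab$snp_id == "rs000001", ]
  cnt <- table(factor(calls[, 1], 0:2), rep(c(1, 0), each = 10))
  mt <- build_model_table(cnt[, "1"], cnt[, "0"], "allele")
  expect_equal(one$p_value, fisher_exact_2x2(unclass(mt)))
})
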