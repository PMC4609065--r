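test_that("intercept-only fits reproduce closed-form likelihoods", {
  d <- tibble::tibble(response = rep(c(0L, 1L), each = 50))
  f <- fit_binary_logistic(d)
  expect_equal(f$log_likelihood, 100 * log(0.5), tolerance = 1e-6)
  expect_equal(f$aic, 2 - 200 * log(0.5), tolerance = 1e-6)

  d4 <- tibble::tibble(recist = factor(rep(c("CR", "PR", "NC", "PD"), 20),
                                       levels = c("CR", "PR", "NC", "PD"),
                                       ordered = TRUE))
  fo <- fit_proportional_odds(d4)
  expect_equal(fo$log_likelihood, 80 * log(0.25), tolerance = 1e-5)
  expect_equal(fo$k, 3)
  expect_equal(fo$aic, 6 - 2 * 80 * log(0.25), tolerance = 1e-4)
  expect_equal(fo$aic, stats::AIC(fo$fit), tolerance = 1e-8)
})

test_that("independent predictors get near-zero slopes; separation flags", {
  d <- tibble::tibble(response = rep(c(0L, 1L), each = 20),
                      x = rep(c(0, 1), 20))
  f <- fit_binary_logistic(d, "x")
  expect_lt(abs(f$coefficients[["x"]]), 1e-6)
  expect_false(f$separation)

  sep <- tibble::tibble(response = rep(c(0L, 1L), each = 10),
                        x = rep(c(0, 1), each = 10))
  fs <- fit_binary_logistic(sep, "x")
  expect_true(fs$separation)
  expect_error(fit_binary_logistic(tibble::tibble(response = rep(1L, 10))),
               "constant")
})

test_that("proportional-odds degenerate and error paths", {
  d2 <- tibble::tibble(recist = factor(rep(c("PR", "NC"), each = 15),
                                       levels = c("CR", "PR", "NC", "PD"),
                                       ordered = TRUE),
                       x = rnorm(30))
  f2 <- fit_proportional_odds(d2, "x")
  expect_equal(f2$outcome, "ordinal(2)")
  expect_error(fit_proportional_odds(
    tibble::tibble(recist = factor(rep("NC", 10),
                                   levels = c("CR", "PR", "NC", "PD"),
                                   ordered = TRUE))), "levels")
})

test_that("ROC: AUC examples, tie handling and the Mann-Whitney identity", {
  # 8 of the 9 responder/non-responder pairs are concordant (only
  # 0.4 vs 0.7 is not)
  roc <- roc_curve(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                   c(1, 1, 1, 0, 0, 0))
  expect_equal(roc$auc, 8 / 9, tolerance = 1e-12)
  bc <- best_cutoff(roc)
  expect_equal(bc$cutoff, 0.8)
  expect_equal(bc$sensitivity_pct, 200 / 3, tolerance = 1e-9)
  expect_equal(bc$specificity_pct, 100)

  expect_equal(roc_curve(1:6, c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_curve(rep(1, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "positive")

  # trapezoid AUC equals the pair-counting (Mann-Whitney) AUC with ties
  set.seed(30)
  for (i in 1:20) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(1:8, 40, TRUE)  # many ties
    auc <- roc_curve(s, y)$auc
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  y <- rbinom(50, 1, 0.4)
  s <- rnorm(50)
  expect_equal(roc_curve(s, y)$auc, roc_curve(plogis(3 * s + 1), y)$auc,
               tolerance = 1e-12)
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(34)
  for (i in 1:10) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(1:10, 60, TRUE)
    ref <- suppressMessages(as.numeric(pROC::auc(y, s,
                                                 direction = "<")))
    expect_equal(roc_curve(s, y)$auc, ref, tolerance = 1e-10)
  }
})

test_that("model comparison ranks by AIC, NULL model has AUC 0.5", {
  set.seed(32)
  n <- 100
  x1 <- sample(0:2, n, TRUE); x2 <- sample(0:2, n, TRUE)
  lat <- -1.5 * x1 + rlogis(n)
  recist <- cut(lat, c(-Inf, -3, -1, 1, Inf),
                labels = c("CR", "PR", "NC", "PD"), ordered_result = TRUE)
  d <- tibble::tibble(recist = recist,
                      response = as.integer(recist %in% c("CR", "PR")),
                      rs1 = x1, rs2 = x2,
                      cr_grade = sample(0:2, n, TRUE),
                      chem_history = rbinom(n, 1, 0.5) == 1)
  cm <- compare_models(d, study_model_specs(snp1 = "rs1", snp2 = "rs2"))
  expect_equal(nrow(cm), 10)
  expect_equal(cm$aic_rank, rank(cm$aic, ties.method = "min"))
  expect_equal(cm$auc[cm$model == "NULL"], 0.5)
  # the causal single-SNP model beats NULL on strong-effect data
  expect_lt(cm$aic[cm$model == "rs1"], cm$aic[cm$model == "NULL"])
  expect_error(compare_models(d, list(a = "rs1", a = "rs2")), "duplicate")
})

test_that("nested null never exceeds the fuller model's log-likelihood", {
  set.seed(33)
  n <- 80
  x <- sample(0:2, n, TRUE)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
  d <- tibble::tibble(response = y, x = x)
  f0 <- fit_binary_logistic(d)
  f1 <- fit_binary_logistic(d, "x")
  expect_gte(f1$log_likelihood, f0$log_likelihood - 1e-8)
})

test_that("tidy and glance return broom-shaped tibbles", {
  d <- tibble::tibble(response = rep(c(0L, 1L), each = 20),
                      x = rnorm(40))
  f <- fit_binary_logistic(d, "x")
  expect_named(tidy(f), c("term", "estimate"))
  g <- glance(f)
  expect_equal(g$k, 2)
  expect_equal(g$AIC, f$aic)
  roc <- roc_curve(f$scores, f$response)
  expect_named(glance(roc),
               c("auc", "best_cutoff", "sensitivity_pct",
                 "specificity_pct", "n_pos", "n_neg"))
  expect_s3_class(autoplot(roc), "ggplot")
})
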