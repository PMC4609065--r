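#' Fit a binary logistic regression model
#'
#' Maximum-likelihood fit of the binary responder outcome (CR+PR vs
#' NC+PD) on the requested terms, on the complete-case subset. Genotype
#' terms are coded additively (minor-allele dose 0/1/2). Complete
#' separation is detected and flagged; the likelihood is still reported.
#'
#' @param data tibble holding the response and the term columns.
#' @param terms character vector of column names; `character(0)` fits the
#'   intercept-only (NULL) model.
#' @param response name of the binary 0/1 response column.
#' @return a `pgx_fit` object with coefficients, log-likelihood, AIC and
#'   per-sample fitted scores (probability of response).
#' @export
fit_binary_logistic <- function(data, terms = character(),
                                response = "response") {
  cols <- c(response, terms)
  stopifnot(all(cols %in% names(data)))
  df <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
             drop = FALSE]
  y <- df[[response]]
  if (length(unique(y)) < 2L) {
    stop("response is constant on the complete-case subset", call. = FALSE)
  }
  fml <- stats::reformulate(if (length(terms)) terms else "1",
                            response = response)
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df,
                                     control = list(epsilon = 1e-10,
                                                    maxit = 100)))
  mu <- stats::fitted(fit)
  separation <- any(mu > 1 - 1e-8 | mu < 1e-8) &&
    any(abs(stats::coef(fit)[-1]) > 10)
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit))
  structure(list(terms = terms, outcome = "binary",
                 coefficients = stats::coef(fit),
                 log_likelihood = ll, k = k, aic = 2 * k - 2 * ll,
                 scores = stats::setNames(as.numeric(mu), rownames(df)),
                 response = y, separation = separation, fit = fit),
            class = "pgx_fit")
}

#' Fit a proportional-odds (ordinal logistic) model
#'
#' Cumulative-logit fit of the ordered 4-level RECIST outcome
#' (CR < PR < NC < PD) with common slopes across the cumulative logits.
#' The free-parameter count is the number of slopes plus the number of
#' thresholds (3 for four observed levels). With only two observed
#' outcome levels the fit degenerates to binary logistic regression and
#' is handled as such.
#'
#' @param data tibble holding the outcome and term columns.
#' @param terms character vector of predictor columns.
#' @param response name of the ordered-factor outcome column.
#' @return a `pgx_fit`; `scores` hold the fitted probability of a
#'   responder outcome (CR or PR).
#' @export
fit_proportional_odds <- function(data, terms = character(),
                                  response = "recist") {
  cols <- c(response, terms)
  stopifnot(all(cols %in% names(data)))
  df <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
             drop = FALSE]
  yf <- droplevels(as.ordered(df[[response]]))
  nlev <- nlevels(yf)
  if (nlev < 2L) stop("outcome has fewer than 2 observed levels",
                      call. = FALSE)
  resp_levels <- intersect(c("CR", "PR"), levels(yf))
  if (nlev == 2L) {
    df$.bin <- as.integer(yf == levels(yf)[1L])
    out <- fit_binary_logistic(df, terms, ".bin")
    out$outcome <- "ordinal(2)"
    return(out)
  }
  df[[response]] <- yf
  fml <- stats::reformulate(if (length(terms)) terms else "1",
                            response = response)
  fit <- tryCatch(
    suppressWarnings(MASS::polr(fml, data = df, Hess = FALSE)),
    error = function(e) {
      # near-separation can defeat the default starting values; restart
      # from zero slopes and the marginal cumulative logits
      cum <- cumsum(prop.table(table(yf)))[seq_len(nlev - 1L)]
      nslope <- ncol(stats::model.matrix(fml, df)) - 1L
      suppressWarnings(MASS::polr(fml, data = df, Hess = FALSE,
                                  start = c(rep(0, nslope),
                                            stats::qlogis(cum))))
    })
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit)) + length(fit$zeta)
  pr <- stats::predict(fit, type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                     dimnames = list(NULL, levels(yf)))
  score <- rowSums(pr[, resp_levels, drop = FALSE])
  structure(list(terms = terms, outcome = "ordinal",
                 coefficients = c(stats::coef(fit), fit$zeta),
                 log_likelihood = ll, k = k, aic = 2 * k - 2 * ll,
                 scores = stats::setNames(as.numeric(score), rownames(df)),
                 response = as.integer(yf %in% resp_levels),
                 separation = NA, fit = fit),
            class = "pgx_fit")
}

#' @export
print.pgx_fit <- function(x, ...) {
  cat("<pgx_fit> outcome:", x$outcome, " terms:",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "(null)",
      "\n  logLik:", format(x$log_likelihood), " AIC:", format(x$aic), "\n")
  invisible(x)
}

#' @export
tidy.pgx_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients))
}

#' @export
glance.pgx_fit <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, k = x$k,
                 logLik = x$log_likelihood, AIC = x$aic,
                 n = length(x$scores),
                 separation = isTRUE(x$separation))
}

#' Empirical ROC curve
#'
#' Thresholds at every distinct score ("predict positive when
#' score >= cutoff"); AUC by the trapezoid rule, which equals the
#' Mann-Whitney statistic `U / (n1 * n0)` with ties counted 1/2.
#'
#' @param scores numeric prediction scores (higher = more likely
#'   responder).
#' @param binary_response 0/1 outcomes, same length.
#' @return a `pgx_roc` object: `points` tibble (cutoff, fpr, tpr), `auc`,
#'   and the Youden-optimal `best_cutoff` with `sensitivity_pct` /
#'   `specificity_pct`.
#' @export
roc_curve <- function(scores, binary_response) {
  stopifnot(length(scores) == length(binary_response))
  ok <- !is.na(scores) & !is.na(binary_response)
  scores <- scores[ok]; y <- as.integer(binary_response[ok])
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cuts, function(ct) sum(y == 1L & scores >= ct) / n1,
                numeric(1))
  fpr <- vapply(cuts, function(ct) sum(y == 0L & scores >= ct) / n0,
                numeric(1))
  pts <- tibble::tibble(cutoff = c(Inf, cuts), fpr = c(0, fpr),
                        tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  obj <- structure(list(points = pts, auc = auc, n1 = n1, n0 = n0),
                   class = "pgx_roc")
  bc <- best_cutoff(obj)
  obj$best_cutoff <- bc$cutoff
  obj$sensitivity_pct <- bc$sensitivity_pct
  obj$specificity_pct <- bc$specificity_pct
  obj
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1; ties are broken
#' by maximum specificity, then by maximum cutoff.
#'
#' @param roc a `pgx_roc` from [roc_curve()].
#' @return a one-row tibble: `cutoff`, `sensitivity_pct`,
#'   `specificity_pct`.
#' @export
best_cutoff <- function(roc) {
  stopifnot(inherits(roc, "pgx_roc"))
  pts <- roc$points[is.finite(roc$points$cutoff), ]
  sens <- pts$tpr
  spec <- 1 - pts$fpr
  j <- sens + spec - 1
  best <- which(j > max(j) - 1e-12)
  if (length(best) > 1L) {
    best <- best[spec[best] > max(spec[best]) - 1e-12]
    if (length(best) > 1L) best <- best[which.max(pts$cutoff[best])]
  }
  tibble::tibble(cutoff = pts$cutoff[best],
                 sensitivity_pct = 100 * sens[best],
                 specificity_pct = 100 * spec[best])
}

#' @export
print.pgx_roc <- function(x, ...) {
  cat("<pgx_roc> AUC:", format(x$auc),
      " best cutoff:", format(x$best_cutoff),
      sprintf(" (sens %.1f%%, spec %.1f%%)\n", x$sensitivity_pct,
              x$specificity_pct))
  invisible(x)
}

#' @export
tidy.pgx_roc <- function(x, ...) x$points

#' @export
glance.pgx_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, best_cutoff = x$best_cutoff,
                 sensitivity_pct = x$sensitivity_pct,
                 specificity_pct = x$specificity_pct,
                 n_pos = x$n1, n_neg = x$n0)
}

#' @export
autoplot.pgx_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' The ten candidate model specifications
#'
#' The named preset of regression models compared in the study: NULL,
#' each single factor, and the combinations of the two index SNPs with
#' the clinical covariates (creatinine grade, chemotherapy history).
#'
#' @param snp1,snp2 genotype column names (additive dose coding).
#' @param cr,chem clinical covariate column names.
#' @return a named list of term vectors for [compare_models()].
#' @export
study_model_specs <- function(snp1 = "rs2867461", snp2 = "rs2293347",
                              cr = "cr_grade", chem = "chem_history") {
  list(
    "NULL" = character(),
    "snp2" = snp2,
    "Cr" = cr,
    "Chem" = chem,
    "Cr+Chem" = c(cr, chem),
    "snp1" = snp1,
    "snp1+snp2" = c(snp1, snp2),
    "snp1+snp2+Cr" = c(snp1, snp2, cr),
    "snp1+snp2+Chem" = c(snp1, snp2, chem),
    "snp1+snp2+Cr+Chem" = c(snp1, snp2, cr, chem)
  ) |>
    (\(l) stats::setNames(l, c("NULL", snp2, "Cr", "Chem", "Cr+Chem", snp1,
                               paste(snp1, snp2, sep = "+"),
                               paste(snp1, snp2, "Cr", sep = "+"),
                               paste(snp1, snp2, "Chem", sep = "+"),
                               paste(snp1, snp2, "Cr+Chem", sep = "+"))))()
}

#' Compare candidate regression models by AIC and ROC
#'
#' Fits every specification (proportional-odds on the 4-level outcome by
#' default, binary logistic otherwise), computes AIC, and evaluates the
#' fitted scores against the binary responder grouping by ROC: AUC and
#' the Youden-optimal sensitivity/specificity. Rows are ranked by AIC.
#'
#' @param data tibble with outcome, response and term columns.
#' @param specs named list of term vectors, e.g. [study_model_specs()].
#' @param outcome `"ordinal"` (proportional odds on `ordinal_response`)
#'   or `"binary"` (logistic on `response`).
#' @param ordinal_response,response outcome column names.
#' @return a `pgx_model_comparison` tibble: one row per model with `k`,
#'   `logLik`, `aic`, `auc`, `best_cutoff`, `sensitivity_pct`,
#'   `specificity_pct`, `aic_rank`.
#' @export
compare_models <- function(data, specs = study_model_specs(),
                           outcome = c("ordinal", "binary"),
                           ordinal_response = "recist",
                           response = "response") {
  outcome <- match.arg(outcome)
  if (anyDuplicated(names(specs))) stop("duplicate spec names",
                                        call. = FALSE)
  rows <- purrr::imap_dfr(specs, function(terms, name) {
    fit <- if (outcome == "ordinal") {
      fit_proportional_odds(data, terms, ordinal_response)
    } else {
      fit_binary_logistic(data, terms, response)
    }
    if (length(unique(fit$scores)) == 1L) {
      # constant score (e.g. the NULL model): flat ROC
      roc <- list(auc = 0.5, best_cutoff = NA_real_,
                  sensitivity_pct = NA_real_, specificity_pct = NA_real_)
    } else {
      roc <- roc_curve(fit$scores, fit$response)
    }
    tibble::tibble(model = name,
                   terms = paste(terms, collapse = "+"),
                   k = fit$k, logLik = fit$log_likelihood, aic = fit$aic,
                   auc = roc$auc, best_cutoff = roc$best_cutoff,
                   sensitivity_pct = roc$sensitivity_pct,
                   specificity_pct = roc$specificity_pct)
  })
  rows <- dplyr::mutate(rows, aic_rank = rank(.data$aic,
                                              ties.method = "min")) |>
    dplyr::arrange(.data$aic_rank)
  class(rows) <- c("pgx_model_comparison", class(rows))
  rows
}
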