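#' Build a genetic-model contingency table from genotype counts
#'
#' Collapses responder / non-responder genotype counts (minor-allele dose
#' 0/1/2) into the 2x2 table of the requested genetic model, or the full
#' 2x3 genotype table.
#'
#' * `allele`: each subject contributes two alleles; columns (minor, major).
#' * `dominant`: carriers of at least one minor allele vs non-carriers.
#' * `recessive`: homozygous-minor subjects vs all others.
#' * `genotype`: the raw 2x3 dose table.
#'
#' @param resp_counts integer vector `(x0, x1, x2)` of responder genotype
#'   counts by minor-allele dose.
#' @param nonresp_counts integer vector `(y0, y1, y2)` for non-responders.
#' @param model one of `"allele"`, `"dominant"`, `"recessive"`, `"genotype"`.
#' @param snp_id optional SNP identifier carried as an attribute.
#' @return an integer matrix of class `model_table` with dimnames, and
#'   attributes `model` and `snp_id`.
#' @export
#' @examples
#' build_model_table(c(0, 4, 6), c(10, 8, 2), "allele")
build_model_table <- function(resp_counts, nonresp_counts,
                              model = c("allele", "dominant", "recessive",
                                        "genotype"),
                              snp_id = NA_character_) {
  model <- match.arg(model)
  x <- as.integer(resp_counts)
  y <- as.integer(nonresp_counts)
  if (length(x) != 3L || length(y) != 3L || anyNA(c(x, y)) ||
      any(c(x, y) < 0)) {
    stop("genotype counts must be two non-negative integer triples",
         call. = FALSE)
  }
  tab <- switch(model,
    allele = matrix(c(x[2] + 2L * x[3], 2L * x[1] + x[2],
                      y[2] + 2L * y[3], 2L * y[1] + y[2]),
                    nrow = 2, byrow = TRUE,
                    dimnames = list(c("CR+PR", "NC+PD"),
                                    c("minor", "major"))),
    dominant = matrix(c(x[2] + x[3], x[1], y[2] + y[3], y[1]),
                      nrow = 2, byrow = TRUE,
                      dimnames = list(c("CR+PR", "NC+PD"),
                                      c("carrier", "non-carrier"))),
    recessive = matrix(c(x[3], x[1] + x[2], y[3], y[1] + y[2]),
                       nrow = 2, byrow = TRUE,
                       dimnames = list(c("CR+PR", "NC+PD"),
                                       c("hom-minor", "other"))),
    genotype = matrix(c(x, y), nrow = 2, byrow = TRUE,
                      dimnames = list(c("CR+PR", "NC+PD"),
                                      c("0", "1", "2")))
  )
  structure(tab, model = model, snp_id = snp_id, class = c("model_table",
                                                           class(tab)))
}

#' @export
print.model_table <- function(x, ...) {
  cat("<model_table> model:", attr(x, "model"),
      if (!is.na(attr(x, "snp_id"))) paste0("snp: ", attr(x, "snp_id")),
      "\n")
  print(unclass(x))
  invisible(x)
}

#' Tidy a genetic-model contingency table
#'
#' @param x a `model_table`.
#' @param ... unused.
#' @return a tibble with one row per cell.
#' @export
tidy.model_table <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    stats::setNames(c("response", "category", "count")) |>
    dplyr::mutate(model = attr(x, "model"), snp_id = attr(x, "snp_id"))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric point probabilities,
#' at the observed margins, that do not exceed the observed table's
#' probability (with a 1e-7 relative tolerance for ties) -- the convention
#' of `stats::fisher.test()`. A table with an empty row or column margin
#' has p = 1.
#'
#' @param table a 2x2 matrix of non-negative integer counts, or a vector
#'   `c(a, b, c, d)` read row-wise.
#' @return the two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)) # 1/3
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) && length(table) == 4L) {
    table <- matrix(as.integer(table), 2, byrow = TRUE)
  }
  assert_2x2(table)
  fisher2x2_p_cpp(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
}

# vectorized backend over table cells (row-wise a, b, c, d)
fisher_2x2_vec <- function(a, b, c, d) {
  fisher2x2_p_cpp(as.integer(a), as.integer(b), as.integer(c), as.integer(d))
}

#' Fisher exact test for an r x c table
#'
#' Exact conditional p-value over all tables with the observed margins
#' (network enumeration via [stats::fisher.test()]); reduces to
#' [fisher_exact_2x2()] for 2x2 input. For totals above
#' `enumeration_bound`, set `monte_carlo = TRUE` to estimate the p-value by
#' margin-preserving simulation.
#'
#' @param table an r x c matrix of non-negative integer counts.
#' @param enumeration_bound largest table total for which exact enumeration
#'   is attempted.
#' @param monte_carlo estimate by simulation instead of enumerating.
#' @param replicates simulation replicate count when `monte_carlo = TRUE`.
#' @return the p-value in (0, 1].
#' @export
fisher_exact_rxc <- function(table, enumeration_bound = 1000L,
                             monte_carlo = FALSE, replicates = 1e5) {
  if (!is.matrix(table) || any(table < 0) || any(table != round(table))) {
    stop("expected a matrix of non-negative integer counts", call. = FALSE)
  }
  # drop all-zero rows/columns; p is invariant to them
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2L || ncol(table) < 2L) return(1)
  if (all(dim(table) == c(2L, 2L))) return(fisher_exact_2x2(table))
  if (monte_carlo) {
    return(stats::fisher.test(table, simulate.p.value = TRUE,
                              B = replicates)$p.value)
  }
  if (sum(table) > enumeration_bound) {
    stop("table total exceeds the enumeration bound; ",
         "set monte_carlo = TRUE for a simulated p-value", call. = FALSE)
  }
  stats::fisher.test(table, workspace = 2e7)$p.value
}

#' Odds ratio of a 2x2 table
#'
#' Either the sample (cross-product) estimate or the conditional
#' maximum-likelihood estimate that `stats::fisher.test()` reports.
#' Published tables formatted by standard statistical software usually
#' print the conditional MLE, under which a zero cell gives a boundary
#' estimate of exactly 0 or infinity.
#'
#' @param table a 2x2 count matrix.
#' @param convention `"cmle"` (conditional MLE, default) or `"sample"`.
#' @return the odds ratio; `0` or `Inf` at a boundary; `NaN` when both
#'   cross products are zero (undefined).
#' @export
odds_ratio <- function(table, convention = c("cmle", "sample")) {
  convention <- match.arg(convention)
  assert_2x2(table)
  num <- table[1, 1] * table[2, 2]
  den <- table[1, 2] * table[2, 1]
  if (num == 0 && den == 0) return(NaN)
  if (convention == "sample") {
    if (num == 0) return(0)
    if (den == 0) return(Inf)
    return(num / den)
  }
  if (num == 0) return(0)
  if (den == 0) return(Inf)
  unname(stats::fisher.test(table)$estimate)
}

#' Confidence interval for a 2x2 odds ratio
#'
#' @param table a 2x2 count matrix.
#' @param level confidence level in (0, 1).
#' @param method `"woolf"` for the log-OR normal interval
#'   `exp(log OR +/- z * sqrt(sum 1/cell))` (zero cells give log-limit
#'   bounds 0 / Inf), or `"exact"` for the conditional exact interval
#'   consistent with the conditional MLE.
#' @return a named numeric vector `c(low, high)`.
#' @export
or_confidence_interval <- function(table, level = 0.95,
                                   method = c("woolf", "exact")) {
  method <- match.arg(method)
  assert_2x2(table)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  if (method == "exact") {
    ci <- stats::fisher.test(table, conf.level = level)$conf.int
    return(c(low = ci[1], high = ci[2]))
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (any(table == 0)) {
    # log-limits: a zero numerator cell pins the lower bound at 0, a zero
    # denominator cell the upper at Inf; both products zero is undefined
    num <- a * d; den <- b * c
    if (num == 0 && den == 0) return(c(low = NaN, high = NaN))
    if (num == 0) return(c(low = 0, high = Inf))
    if (den == 0) return(c(low = 0, high = Inf))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  or <- (a * d) / (b * c)
  c(low = or * exp(-z * se), high = or * exp(z * se))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditions on the allele counts and sums the point probabilities of
#' heterozygote counts whose probability does not exceed the observed
#' one's (1e-7 relative tie tolerance). Monomorphic input gives p = 1.
#'
#' @param n0,n1,n2 genotype counts by minor-allele dose (vectorized).
#' @return exact p-value(s) in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(1, 0, 1) # 1/3
hwe_exact_test <- function(n0, n1, n2) {
  n0 <- as.integer(n0); n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (anyNA(c(n0, n1, n2)) || any(c(n0, n1, n2) < 0)) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  hwe_exact_p_cpp(n0, n1, n2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment
#' (`q_i = min over j >= rank(i) of p_(j) * m / j`, capped at 1), as in
#' [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-SNP, per-model association table
#'
#' Runs [build_model_table()] + [fisher_exact_2x2()] + [odds_ratio()] +
#' [or_confidence_interval()] for each SNP of an oriented genotype dataset
#' against the binary response, for one or more genetic models, and
#' BH-adjusts the p-values within each model.
#'
#' @param genotypes a [genotype_dataset].
#' @param phenotypes phenotype tibble with `sample_id` and `response`.
#' @param models character subset of allele/dominant/recessive.
#' @param sample_ids optional subset of samples to analyze.
#' @param or_convention passed to [odds_ratio()].
#' @return a tibble with one row per SNP x model: table cells, `p_value`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `q_value`.
#' @export
association_table <- function(genotypes, phenotypes,
                              models = c("allele", "dominant", "recessive"),
                              sample_ids = NULL,
                              or_convention = "cmle") {
  models <- match.arg(models, several.ok = TRUE)
  ids <- sample_ids %||% genotypes$sample_ids
  counts <- genotype_response_counts(genotypes, phenotypes, ids)
  purrr::map_dfr(models, function(mod) {
    rows <- purrr::pmap_dfr(counts, function(snp_id, x0, x1, x2, y0, y1, y2) {
      tab <- build_model_table(c(x0, x1, x2), c(y0, y1, y2), mod, snp_id)
      ci <- or_confidence_interval(tab)
      tibble::tibble(
        snp_id = snp_id, model = mod,
        n = sum(tab),
        p_value = fisher_exact_2x2(unclass(tab)),
        odds_ratio = odds_ratio(tab, or_convention),
        ci_low = ci[["low"]], ci_high = ci[["high"]]
      )
    })
    dplyr::mutate(rows, q_value = bh_adjust(.data$p_value))
  })
}

# responder/non-responder dose counts per SNP over a sample subset,
# pairwise-complete per SNP
genotype_response_counts <- function(genotypes, phenotypes, sample_ids) {
  ph <- phenotypes[match(sample_ids, phenotypes$sample_id), ]
  if (anyNA(ph$sample_id)) {
    stop("phenotypes missing for some requested samples", call. = FALSE)
  }
  calls <- genotypes$calls[sample_ids, , drop = FALSE]
  resp <- ph$response == 1L
  cnt <- function(m) {
    sapply(0:2, function(g) colSums(m == g, na.rm = TRUE))
  }
  xr <- cnt(calls[resp, , drop = FALSE])
  yr <- cnt(calls[!resp, , drop = FALSE])
  if (is.null(dim(xr))) { xr <- matrix(xr, nrow = 1); yr <- matrix(yr, nrow = 1) }
  tibble::tibble(
    snp_id = genotypes$snp_ids,
    x0 = xr[, 1], x1 = xr[, 2], x2 = xr[, 3],
    y0 = yr[, 1], y1 = yr[, 2], y2 = yr[, 3]
  )
}
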