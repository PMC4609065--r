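#' Integrated minor-allele count index
#'
#' Sums the minor-allele doses of the index SNPs per sample (range
#' 0..2 * number of SNPs). Samples missing any constituent genotype get
#' `NA`.
#'
#' @param genotypes an oriented [genotype_dataset].
#' @param snp_set character vector of index SNP ids.
#' @return a tibble with `sample_id` and `index`.
#' @export
compute_index <- function(genotypes, snp_set) {
  missing_snps <- setdiff(snp_set, genotypes$snp_ids)
  if (length(missing_snps)) {
    stop("SNPs not in dataset: ", paste(missing_snps, collapse = ", "),
         call. = FALSE)
  }
  sub <- genotypes$calls[, snp_set, drop = FALSE]
  idx <- rowSums(sub)  # NA whenever any constituent call is missing
  tibble::tibble(sample_id = genotypes$sample_ids,
                 index = as.integer(idx))
}

#' Per-level contingency analysis of an allele-count index
#'
#' Tabulates index levels against the binary responder grouping, computes
#' the response rate per level (RR = 100 * responders / total), and the
#' exact r x c Fisher p-value across levels. Samples with missing index
#' are excluded; empty levels are omitted and recorded.
#'
#' @param index tibble from [compute_index()].
#' @param phenotypes tibble with `sample_id` and binary `response`.
#' @return a `pgx_index` object: `levels` tibble
#'   (`level, n_resp, n_nonresp, n, rr_pct`), `p_levels`, `n_analyzed`,
#'   `empty_levels`.
#' @export
index_contingency <- function(index, phenotypes) {
  df <- dplyr::inner_join(index, phenotypes[, c("sample_id", "response")],
                          by = "sample_id") |>
    dplyr::filter(!is.na(.data$index))
  if (nrow(df) == 0L) stop("index is missing for every sample",
                           call. = FALSE)
  if (length(unique(df$response)) < 2L) {
    stop("both response groups must be present", call. = FALSE)
  }
  max_level <- max(df$index)
  lv <- df |>
    dplyr::count(level = .data$index, resp = .data$response) |>
    tidyr::pivot_wider(names_from = "resp", values_from = "n",
                       values_fill = 0L, names_prefix = "g")
  if (!"g1" %in% names(lv)) lv$g1 <- 0L
  if (!"g0" %in% names(lv)) lv$g0 <- 0L
  levels_tbl <- tibble::tibble(level = lv$level, n_resp = lv$g1,
                               n_nonresp = lv$g0) |>
    dplyr::arrange(.data$level) |>
    dplyr::mutate(n = .data$n_resp + .data$n_nonresp,
                  rr_pct = 100 * .data$n_resp / .data$n)
  empty <- setdiff(0:max_level, levels_tbl$level)
  tab <- as.matrix(levels_tbl[, c("n_resp", "n_nonresp")])
  rownames(tab) <- levels_tbl$level
  structure(list(levels = levels_tbl,
                 p_levels = fisher_exact_rxc(tab),
                 n_analyzed = nrow(df),
                 empty_levels = empty,
                 data = df),
            class = "pgx_index")
}

#' @export
print.pgx_index <- function(x, ...) {
  cat("<pgx_index> n =", x$n_analyzed,
      " exact p across levels =", format(x$p_levels, digits = 3), "\n")
  print(x$levels)
  if (length(x$empty_levels)) {
    cat("empty levels omitted:", paste(x$empty_levels, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
tidy.pgx_index <- function(x, ...) x$levels

#' @export
glance.pgx_index <- function(x, ...) {
  tibble::tibble(n = x$n_analyzed, p_levels = x$p_levels,
                 n_levels = nrow(x$levels))
}

#' Dichotomize an index contingency result
#'
#' Collapses the per-level table at `index >= threshold` vs
#' `index < threshold` and tests the 2x2 with the exact test. The default
#' threshold 2 pools the zero-response low levels.
#'
#' @param index_result a `pgx_index` from [index_contingency()].
#' @param threshold integer cut; must split the observed levels into two
#'   non-empty groups.
#' @return a list: 2x2 `table` (rows high/low index, columns responder /
#'   non-responder), `p_value`, `threshold`.
#' @export
dichotomize <- function(index_result, threshold = 2L) {
  stopifnot(inherits(index_result, "pgx_index"))
  lv <- index_result$levels
  hi <- lv$level >= threshold
  if (!any(hi) || all(hi)) {
    stop("threshold must split the observed index levels", call. = FALSE)
  }
  tab <- rbind(
    high = c(sum(lv$n_resp[hi]), sum(lv$n_nonresp[hi])),
    low = c(sum(lv$n_resp[!hi]), sum(lv$n_nonresp[!hi]))
  )
  colnames(tab) <- c("CR+PR", "NC+PD")
  list(table = tab, p_value = fisher_exact_2x2(tab),
       threshold = as.integer(threshold))
}

#' ROC curve of an allele-count index
#'
#' @param index tibble from [compute_index()].
#' @param phenotypes tibble with `sample_id` and `response`.
#' @return a `pgx_roc` treating the index as the prediction score.
#' @export
index_roc <- function(index, phenotypes) {
  df <- dplyr::inner_join(index, phenotypes[, c("sample_id", "response")],
                          by = "sample_id")
  roc_curve(df$index, df$response)
}

#' @export
autoplot.pgx_index <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = factor(.data$level), y = .data$rr_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$n_resp, .data$n)), vjust = -0.4) +
    ggplot2::labs(x = "index level (total minor alleles)",
                  y = "response rate (%)") +
    ggplot2::theme_minimal()
}
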