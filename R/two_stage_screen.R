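#' Permutation configuration for the two-stage screen
#'
#' @param n_perm number of permutation replicates (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param model genetic model used for screening; the allele model is the
#'   default.
#' @param stratify permute response labels within the discovery subset
#'   and its complement separately (default), holding both stage
#'   responder margins at their observed values. Required for exactness
#'   when response rates differ between regimens; `FALSE` shuffles
#'   across the whole cohort.
#' @return a `permutation_config` list.
#' @export
permutation_config <- function(n_perm = 1000L, seed = 1L,
                               model = c("allele", "dominant", "recessive"),
                               stratify = TRUE) {
  model <- match.arg(model)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 model = model, stratify = isTRUE(stratify)),
            class = "permutation_config")
}

model_code <- function(model) {
  match(model, c("allele", "dominant", "recessive")) - 1L
}

#' Per-SNP Fisher p-values in one dataset
#'
#' Builds the genetic-model 2x2 table per SNP on the requested sample
#' subset (pairwise complete per SNP) and applies the two-sided Fisher
#' exact test. A SNP with no non-missing call in the subset gets `NA`.
#'
#' @param genotypes an oriented [genotype_dataset].
#' @param phenotypes phenotype tibble with `sample_id` and `response`.
#' @param snp_set SNP ids to test (default: all).
#' @param dataset_ids sample ids of the dataset (default: all samples).
#' @param model genetic model.
#' @return a tibble with `snp_id` and `p_value`.
#' @export
stage_pvalues <- function(genotypes, phenotypes, snp_set = NULL,
                          dataset_ids = NULL,
                          model = c("allele", "dominant", "recessive")) {
  model <- match.arg(model)
  snp_set <- snp_set %||% genotypes$snp_ids
  ids <- dataset_ids %||% genotypes$sample_ids
  stopifnot(all(snp_set %in% genotypes$snp_ids),
            all(ids %in% genotypes$sample_ids))
  ph <- phenotypes[match(ids, phenotypes$sample_id), ]
  calls <- genotypes$calls[ids, snp_set, drop = FALSE]
  p <- stage_p_cpp(calls, as.integer(ph$response),
                   seq_along(ids) - 1L, model_code(model))
  tibble::tibble(snp_id = snp_set, p_value = as.numeric(p))
}

#' Permutation family-wise adjusted p-values (min-T)
#'
#' The combined statistic per SNP is `T = max(p1, p2)`, the larger of its
#' stage p-values: small only when the SNP is associated in both the
#' nested discovery subset and the full cohort. For each permutation the
#' response labels are shuffled once across the full cohort and the
#' discovery labels are the induced restriction, preserving the nesting;
#' the null distribution of the minimum `T` across SNPs gives the
#' family-wise adjusted p-value with the add-one estimator
#' `(1 + #[T*_min <= T_s]) / (n_perm + 1)`.
#'
#' @inheritParams stage_pvalues
#' @param first_ids sample ids of the nested discovery subset.
#' @param config a [permutation_config()].
#' @return a tibble with `snp_id`, `p_stage1`, `p_stage2`, `combined_t`,
#'   `perm_adjusted_p`.
#' @export
permutation_adjusted_p <- function(genotypes, phenotypes, snp_set = NULL,
                                   first_ids, config = permutation_config()) {
  snp_set <- snp_set %||% genotypes$snp_ids
  ids <- genotypes$sample_ids
  stopifnot(all(first_ids %in% ids))
  p1 <- stage_pvalues(genotypes, phenotypes, snp_set, first_ids,
                      config$model)$p_value
  p2 <- stage_pvalues(genotypes, phenotypes, snp_set, ids,
                      config$model)$p_value
  t_obs <- pmax(p1, p2)
  ph <- phenotypes[match(ids, phenotypes$sample_id), ]
  calls <- genotypes$calls[ids, snp_set, drop = FALSE]
  tmin <- withr::with_seed(
    config$seed,
    perm_min_t_cpp(calls, as.integer(ph$response),
                   match(first_ids, ids) - 1L, config$n_perm,
                   model_code(config$model), config$stratify)
  )
  adj <- vapply(t_obs, function(t) {
    if (is.na(t)) return(NA_real_)
    (1 + sum(tmin <= t)) / (config$n_perm + 1)
  }, numeric(1))
  tibble::tibble(snp_id = snp_set, p_stage1 = p1, p_stage2 = p2,
                 combined_t = t_obs, perm_adjusted_p = adj)
}

#' Two-stage candidate screening with permutation control
#'
#' Candidates must be associated in the discovery subset
#' (`p_stage1 < alpha1`), in the full cohort (`p_stage2 < alpha2`), and
#' survive the family-wise min-T permutation adjustment
#' (`perm_adjusted_p < perm_alpha`). Within the screened set, stage-1
#' p-values also receive a BH q-value.
#'
#' @inheritParams permutation_adjusted_p
#' @param alpha1,alpha2 stage significance thresholds.
#' @param perm_alpha family-wise threshold on the adjusted p.
#' @return a `pgx_screen` tibble: per-SNP stage p-values, combined
#'   statistic, permutation-adjusted p, `q_stage1` and the `candidate`
#'   flag.
#' @export
screen <- function(genotypes, phenotypes, snp_set = NULL, first_ids,
                   alpha1 = 0.05, alpha2 = 0.05, perm_alpha = 0.05,
                   config = permutation_config()) {
  snp_set <- snp_set %||% genotypes$snp_ids
  if (length(snp_set) == 0L) {
    warning("empty SNP set: nothing to screen", call. = FALSE)
    return(structure(tibble::tibble(
      snp_id = character(), p_stage1 = numeric(), p_stage2 = numeric(),
      combined_t = numeric(), perm_adjusted_p = numeric(),
      q_stage1 = numeric(), candidate = logical()
    ), class = c("pgx_screen", class(tibble::tibble()))))
  }
  res <- permutation_adjusted_p(genotypes, phenotypes, snp_set, first_ids,
                                config)
  ok <- !is.na(res$p_stage1)
  q <- rep(NA_real_, nrow(res))
  q[ok] <- bh_adjust(res$p_stage1[ok])
  res$q_stage1 <- q
  res$candidate <- !is.na(res$combined_t) &
    res$p_stage1 < alpha1 & res$p_stage2 < alpha2 &
    res$perm_adjusted_p < perm_alpha
  class(res) <- c("pgx_screen", class(res))
  res
}

#' Plot a screening result
#'
#' -log10 stage p-values per SNP with candidates highlighted.
#'
#' @param object a `pgx_screen` tibble from [screen()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pgx_screen <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(object, idx = dplyr::row_number()),
    cols = c("p_stage1", "p_stage2"),
    names_to = "stage", values_to = "p"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = -log10(.data$p),
                                   colour = .data$stage,
                                   shape = .data$candidate)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP index", y = expression(-log[10](p)),
                  colour = "dataset", shape = "candidate") +
    ggplot2::theme_minimal()
}
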