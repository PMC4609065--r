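#' Filter configuration
#'
#' Thresholds for basic genotype quality control and the knowledge-based
#' SNP filter. Defaults are conventional GWAS values: call rate >= 0.95,
#' MAF >= 0.05, HWE exact p >= 1e-6; the knowledge filter keeps
#' PubMed-linked SNPs and drops cancer-flagged ones.
#'
#' @param min_call_rate minimum fraction of non-missing calls per SNP.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_alpha SNPs with HWE exact p below this fail.
#' @param require_pubmed keep only SNPs with at least one PubMed link.
#' @param exclude_cancer drop SNPs flagged as cancer-related.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_call_rate = 0.95, min_maf = 0.05,
                          hwe_alpha = 1e-6, require_pubmed = TRUE,
                          exclude_cancer = TRUE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            hwe_alpha >= 0, hwe_alpha <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, require_pubmed = require_pubmed,
                 exclude_cancer = exclude_cancer),
            class = "filter_config")
}

#' Knowledge-based SNP filter
#'
#' Retains SNPs linked to at least one PubMed identifier and removes SNPs
#' flagged as cancer-related (each criterion switchable in the config).
#' SNPs without an annotation record count as having no links.
#'
#' @param annotations annotation tibble (see [read_annotations()]).
#' @param config a [filter_config()].
#' @param snp_ids SNPs under consideration (default: annotated SNPs).
#' @return a tibble with `snp_id`, `has_pubmed`, `cancer_flag`,
#'   `retained`.
#' @export
knowledge_filter <- function(annotations, config = filter_config(),
                             snp_ids = NULL) {
  snp_ids <- snp_ids %||% annotations$snp_id
  if (length(snp_ids) == 0L) {
    warning("empty SNP set: nothing to retain", call. = FALSE)
  }
  idx <- match(snp_ids, annotations$snp_id)
  has_pubmed <- vapply(idx, function(i) {
    !is.na(i) && length(annotations$pubmed_ids[[i]]) > 0L
  }, logical(1))
  cancer <- ifelse(is.na(idx), FALSE, annotations$cancer_flag[idx])
  retained <- rep(TRUE, length(snp_ids))
  if (config$require_pubmed) retained <- retained & has_pubmed
  if (config$exclude_cancer) retained <- retained & !cancer
  tibble::tibble(snp_id = snp_ids, has_pubmed = has_pubmed,
                 cancer_flag = cancer, retained = retained)
}

#' Basic per-SNP quality control
#'
#' Computes call rate, minor allele frequency and the HWE exact p-value
#' per SNP on the reference samples (by default the full cohort) and
#' flags passes against the config thresholds.
#'
#' @param genotypes an oriented [genotype_dataset].
#' @param config a [filter_config()].
#' @param reference_ids samples on which MAF and HWE are computed
#'   (default: all).
#' @return a tibble with per-SNP metrics, per-criterion passes and the
#'   overall `pass` (the intersection).
#' @export
basic_qc <- function(genotypes, config = filter_config(),
                     reference_ids = NULL) {
  ref <- reference_ids %||% genotypes$sample_ids
  if (length(ref) == 0L) stop("no samples", call. = FALSE)
  calls <- genotypes$calls[ref, , drop = FALSE]
  n <- nrow(calls)
  n_obs <- colSums(!is.na(calls))
  call_rate <- n_obs / n
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n0 <- n_obs - n1 - n2
  maf_num <- n1 + 2L * n2
  maf <- ifelse(n_obs > 0, pmin(maf_num, 2L * n_obs - maf_num) / (2 * n_obs),
                NA_real_)
  hwe_p <- hwe_exact_test(n0, n1, n2)
  tibble::tibble(
    snp_id = genotypes$snp_ids,
    call_rate = unname(call_rate), maf = unname(maf), hwe_p = hwe_p,
    pass_call_rate = call_rate >= config$min_call_rate,
    pass_maf = !is.na(maf) & maf >= config$min_maf,
    pass_hwe = hwe_p >= config$hwe_alpha,
    pass = .data$pass_call_rate & .data$pass_maf & .data$pass_hwe
  )
}

#' Combined QC + knowledge filtering report
#'
#' Applies [basic_qc()] and [knowledge_filter()]; the surviving set is the
#' intersection of the per-criterion passes, so the two stages commute.
#'
#' @inheritParams basic_qc
#' @param annotations annotation tibble.
#' @return a tibble joining both reports with the overall `retained`
#'   column; `attr(, "n_surviving")` holds the surviving count.
#' @export
snp_filter <- function(genotypes, annotations, config = filter_config(),
                       reference_ids = NULL) {
  qc <- basic_qc(genotypes, config, reference_ids)
  kb <- knowledge_filter(annotations, config, snp_ids = genotypes$snp_ids)
  out <- dplyr::left_join(qc, kb, by = "snp_id") |>
    dplyr::mutate(retained = .data$pass & .data$retained)
  attr(out, "n_surviving") <- sum(out$retained)
  out
}
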