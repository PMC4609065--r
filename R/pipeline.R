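#' Pipeline configuration
#'
#' Bundles the stage configurations for an end-to-end run: input data (or
#' a simulation config), filtering thresholds, permutation settings, the
#' regression-model preset and the index SNP set.
#'
#' @param fixture list with `genotypes`, `phenotypes`, `annotations`
#'   (e.g. from [make_study_fixture()]), or `NULL` to simulate from
#'   `sim`.
#' @param sim a [sim_config()] used when `fixture` is `NULL`.
#' @param filter a [filter_config()].
#' @param perm a [permutation_config()].
#' @param alpha1,alpha2,perm_alpha screening thresholds.
#' @param index_snps SNP ids for the integrated index, or `NULL` to use
#'   the top two screened candidates.
#' @param index_threshold dichotomization threshold for the index.
#' @param out_dir output directory for per-stage TSVs and the run
#'   summary, or `NULL` to skip writing.
#' @param seed master seed; propagated to every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(fixture = NULL, sim = sim_config(),
                            filter = filter_config(),
                            perm = permutation_config(),
                            alpha1 = 0.05, alpha2 = 0.05,
                            perm_alpha = 0.05,
                            index_snps = NULL, index_threshold = 2L,
                            out_dir = NULL, seed = 1L) {
  structure(list(fixture = fixture, sim = sim, filter = filter,
                 perm = perm, alpha1 = alpha1, alpha2 = alpha2,
                 perm_alpha = perm_alpha, index_snps = index_snps,
                 index_threshold = index_threshold, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Filter (QC + knowledge) -> two-stage permutation screen -> regression
#' model comparison -> integrated allele-count index, in order. Every
#' stochastic stage is a pure function of (inputs, config, seed). When
#' `out_dir` is set, per-stage TSVs, a machine-readable JSON summary and
#' a run log are written; a stage failure aborts with the stage name
#' while retaining completed outputs.
#'
#' @param config a [pipeline_config()].
#' @return a list: `filter_report`, `screen_result`, `model_comparison`,
#'   `index_result`, `dichotomized`, `candidates`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  log_lines <- c(sprintf("pgxscreen %s | seed %d | %s",
                         as.character(utils::packageVersion("pgxscreen")),
                         config$seed, format(Sys.time(), "%Y-%m-%d")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  fixture <- stage("data", {
    if (!is.null(config$fixture)) config$fixture
    else {
      sim <- config$sim
      sim$seed <- config$seed
      make_study_fixture(sim)
    }
  })
  geno <- fixture$genotypes
  if (!geno$oriented) geno <- orient_minor_allele(geno)
  pheno <- fixture$phenotypes
  datasets <- split_datasets(pheno)

  filter_report <- stage("filter", {
    snp_filter(geno, fixture$annotations, config$filter)
  })
  kept <- filter_report$snp_id[filter_report$retained]
  log_lines <- c(log_lines,
                 sprintf("filter: %d of %d SNPs retained", length(kept),
                         nrow(filter_report)))

  perm <- config$perm
  perm$seed <- config$seed
  screen_result <- stage("screen", {
    screen(geno, pheno, snp_set = kept, first_ids = datasets$first,
           alpha1 = config$alpha1, alpha2 = config$alpha2,
           perm_alpha = config$perm_alpha, config = perm)
  })
  candidates <- screen_result$snp_id[screen_result$candidate]
  log_lines <- c(log_lines,
                 sprintf("screen: %d candidate SNPs (%s)",
                         length(candidates),
                         paste(utils::head(candidates, 5), collapse = ", ")))

  index_snps <- config$index_snps %||% {
    ord <- order(screen_result$combined_t)
    utils::head(screen_result$snp_id[ord][screen_result$candidate[ord]], 2)
  }

  model_comparison <- NULL
  if (length(index_snps) >= 1) {
    mdata <- stage("model", {
      dplyr::bind_cols(
        pheno,
        tibble::as_tibble(geno$calls[pheno$sample_id, index_snps,
                                     drop = FALSE])
      )
    })
    specs <- if (length(index_snps) >= 2) {
      study_model_specs(snp1 = index_snps[1], snp2 = index_snps[2])
    } else {
      stats::setNames(list(character(), index_snps[1]),
                      c("NULL", index_snps[1]))
    }
    model_comparison <- stage("model", compare_models(mdata, specs))
  }

  index_result <- NULL
  dichotomized <- NULL
  if (length(index_snps) >= 1) {
    index_result <- stage("index", {
      index_contingency(compute_index(geno, index_snps), pheno)
    })
    dichotomized <- stage("index", {
      lv <- index_result$levels$level
      thr <- config$index_threshold
      if (any(lv >= thr) && any(lv < thr)) dichotomize(index_result, thr)
      else NULL
    })
  }

  summary <- list(
    seed = config$seed,
    n_samples = length(geno$sample_ids),
    n_first = length(datasets$first),
    n_snps_total = length(geno$snp_ids),
    n_snps_retained = length(kept),
    candidates = as.list(candidates),
    index_snps = as.list(index_snps),
    best_model = if (!is.null(model_comparison))
      model_comparison$model[1] else NULL,
    index_p_levels = if (!is.null(index_result))
      index_result$p_levels else NULL,
    index_p_dichot = if (!is.null(dichotomized))
      dichotomized$p_value else NULL
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(dplyr::select(filter_report, -dplyr::any_of("pubmed_ids")),
                     file.path(config$out_dir, "filter_report.tsv"))
    readr::write_tsv(screen_result,
                     file.path(config$out_dir, "screen_result.tsv"))
    if (!is.null(model_comparison)) {
      readr::write_tsv(model_comparison,
                       file.path(config$out_dir, "model_comparison.tsv"))
    }
    if (!is.null(index_result)) {
      readr::write_tsv(index_result$levels,
                       file.path(config$out_dir, "index_levels.tsv"))
    }
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }

  list(filter_report = filter_report, screen_result = screen_result,
       model_comparison = model_comparison, index_result = index_result,
       dichotomized = dichotomized, candidates = candidates,
       summary = summary)
}
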