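#' Genotype dataset container
#'
#' A lightweight container for a samples x SNPs matrix of minor-allele dose
#' calls (0/1/2 or `NA`) plus per-SNP metadata. Rows of `calls` are named
#' by sample, columns by SNP.
#'
#' @param calls integer matrix, samples x SNPs, values in 0/1/2 or `NA`,
#'   with row and column names.
#' @param allele_labels tibble with columns `snp_id`, `major`, `minor`
#'   (may be `NA` for dose-only sources).
#' @param positions optional tibble with `snp_id`, `chrom`, `pos`
#'   (1-based).
#' @param oriented logical: have calls been oriented to the minor allele?
#' @param monomorphic logical per SNP: no minor allele observed in the
#'   orientation reference.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(calls, allele_labels = NULL, positions = NULL,
                             oriented = FALSE, monomorphic = NULL) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)),
            !is.null(colnames(calls)))
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  snp_ids <- colnames(calls)
  if (is.null(allele_labels)) {
    allele_labels <- tibble::tibble(snp_id = snp_ids,
                                    major = NA_character_,
                                    minor = NA_character_)
  }
  if (anyDuplicated(rownames(calls))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  same <- !is.na(allele_labels$major) & !is.na(allele_labels$minor) &
    allele_labels$major == allele_labels$minor
  if (any(same)) {
    stop("allele labels must be distinct per SNP", call. = FALSE)
  }
  structure(
    list(calls = calls,
         sample_ids = rownames(calls),
         snp_ids = snp_ids,
         allele_labels = allele_labels,
         positions = positions,
         oriented = oriented,
         monomorphic = monomorphic %||% rep(FALSE, length(snp_ids))),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", length(x$sample_ids), " samples x ",
      length(x$snp_ids), " SNPs; ",
      if (x$oriented) "minor-allele oriented" else "unoriented",
      "; missing calls: ", sum(is.na(x$calls)), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.genotype_dataset <- function(x, ...) {
  tibble::as_tibble(x$calls, rownames = "sample_id")
}

#' Read PLINK text pedigree + map files
#'
#' Whitespace-delimited `.ped` (six leading columns, then two allele codes
#' per SNP; `0` = missing) and `.map` (chrom, snp id, genetic distance,
#' position). Calls are oriented to the minor allele over all samples via
#' [orient_minor_allele()].
#'
#' @param ped_source,map_source file paths (or connections readable by
#'   [readLines()]).
#' @param reference_ids samples used to define the minor allele
#'   (default: all).
#' @return a [genotype_dataset] of minor-allele dose calls.
#' @export
read_plink_text <- function(ped_source, map_source, reference_ids = NULL) {
  map <- utils::read.table(map_source, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "character", "integer"))
  if (anyDuplicated(map$snp_id)) stop("duplicate SNP ids in map",
                                      call. = FALSE)
  lines <- readLines(ped_source)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nsnp <- nrow(map)
  want <- 6L + 2L * nsnp
  lens <- lengths(toks)
  if (any(lens != want)) {
    stop("ped/map mismatch: expected ", want, " fields per ped row (",
         nsnp, " SNPs), found ", paste(unique(lens[lens != want]),
                                       collapse = ", "), call. = FALSE)
  }
  sample_ids <- vapply(toks, `[`, "", 2L)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in ped",
                                      call. = FALSE)
  al <- matrix(unlist(lapply(toks, `[`, -(1:6))), nrow = length(toks),
               byrow = TRUE)
  a1 <- al[, seq(1L, 2L * nsnp, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * nsnp, by = 2L), drop = FALSE]
  calls <- matrix(NA_integer_, nrow = length(sample_ids), ncol = nsnp,
                  dimnames = list(sample_ids, map$snp_id))
  labels <- tibble::tibble(snp_id = map$snp_id, major = NA_character_,
                           minor = NA_character_)
  for (j in seq_len(nsnp)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    seen <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(seen) > 2L) {
      stop("SNP ", map$snp_id[j], " has more than two alleles: ",
           paste(seen, collapse = "/"), call. = FALSE)
    }
    if (length(seen) == 0L) next
    ref <- seen[length(seen)]  # provisional; orientation fixes this below
    calls[!miss, j] <- (x1[!miss] == ref) + (x2[!miss] == ref)
    labels$major[j] <- seen[1L]
    labels$minor[j] <- ref
    if (length(seen) == 1L) labels$major[j] <- NA_character_
  }
  ds <- genotype_dataset(calls, labels,
                         positions = tibble::tibble(snp_id = map$snp_id,
                                                    chrom = map$chrom,
                                                    pos = map$pos))
  orient_minor_allele(ds, reference_ids)
}

#' Orient genotype calls to count the minor allele
#'
#' For each SNP the minor allele is the less frequent allele over the
#' reference samples (ties broken by labelling the lexicographically
#' smaller nucleotide minor; unlabelled dose data keeps the current
#' counted allele on a tie). Calls are re-expressed as minor-allele dose;
#' SNPs monomorphic in the reference are flagged and keep all-zero calls.
#' Idempotent.
#'
#' @param genotypes a [genotype_dataset].
#' @param reference_ids samples defining allele frequencies
#'   (default: all samples).
#' @return the re-oriented [genotype_dataset] (`oriented = TRUE`).
#' @export
orient_minor_allele <- function(genotypes, reference_ids = NULL) {
  ref <- reference_ids %||% genotypes$sample_ids
  if (length(ref) == 0L) stop("reference sample set is empty", call. = FALSE)
  calls <- genotypes$calls
  sub <- calls[ref, , drop = FALSE]
  cnt_counted <- colSums(sub, na.rm = TRUE)
  n_obs <- colSums(!is.na(sub))
  cnt_other <- 2L * n_obs - cnt_counted
  labels <- genotypes$allele_labels
  flip <- cnt_counted > cnt_other
  tie <- cnt_counted == cnt_other & n_obs > 0L
  has_lab <- !is.na(labels$major) & !is.na(labels$minor)
  # tie rule: the lexicographically smaller nucleotide is labelled minor
  flip[tie & has_lab] <- labels$minor[tie & has_lab] >
    labels$major[tie & has_lab]
  flip[tie & !has_lab] <- FALSE
  if (any(flip)) {
    calls[, flip] <- 2L - calls[, flip, drop = FALSE]
    tmp <- labels$major[flip]
    labels$major[flip] <- labels$minor[flip]
    labels$minor[flip] <- tmp
  }
  mono <- pmin(cnt_counted, cnt_other) == 0L
  genotype_dataset(calls, labels, genotypes$positions,
                   oriented = TRUE, monomorphic = unname(mono))
}

#' Read a phenotype table
#'
#' TSV with header `sample_id, regimen, recist, cr_grade, chem_history`.
#' The binary `response` column is derived: 1 for CR or PR, 0 for NC or
#' PD.
#'
#' @param tsv_source path to the TSV file.
#' @return a tibble of validated sample records with `recist` an ordered
#'   factor CR < PR < NC < PD and integer `response`.
#' @export
read_phenotypes <- function(tsv_source) {
  df <- readr::read_tsv(tsv_source, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          regimen = readr::col_character(),
                          recist = readr::col_character(),
                          cr_grade = readr::col_integer(),
                          chem_history = readr::col_logical()
                        ))
  validate_phenotypes(df)
}

#' Validate and derive phenotype records
#'
#' @param df data frame with columns `sample_id`, `regimen`, `recist`,
#'   `cr_grade`, `chem_history`.
#' @return a tibble with `recist` ordered and derived binary `response`.
#' @export
validate_phenotypes <- function(df) {
  regimens <- c("S-1", "5-FU/MTX", "high-dose 5-FU", "low-dose 5-FU")
  recist_levels <- c("CR", "PR", "NC", "PD")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in phenotype table", call. = FALSE)
  }
  bad <- setdiff(unique(df$recist), recist_levels)
  if (length(bad)) stop("unknown RECIST code: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(df$regimen), regimens)
  if (length(bad)) stop("unknown regimen: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(!df$cr_grade %in% 0:4)) {
    stop("cr_grade must be an integer grade 0-4", call. = FALSE)
  }
  df |>
    tibble::as_tibble() |>
    dplyr::mutate(
      recist = factor(.data$recist, levels = recist_levels, ordered = TRUE),
      response = as.integer(.data$recist %in% c("CR", "PR"))
    )
}

#' Split samples into the nested discovery / full datasets
#'
#' The first (discovery) dataset is the S-1-treated subset; the second is
#' every sample. The first is always nested in the second, which the
#' permutation screening relies on.
#'
#' @param records phenotype tibble with `sample_id` and `regimen`.
#' @return a list with `first` and `second` character id vectors.
#' @export
split_datasets <- function(records) {
  first <- records$sample_id[records$regimen == "S-1"]
  if (length(first) == 0L) {
    warning("no S-1-treated samples: first dataset is empty", call. = FALSE)
  }
  list(first = first, second = records$sample_id)
}

#' Write / read the genotype dose TSV dialect
#'
#' Header row `sample_id` then SNP ids; one row per sample holding
#' minor-allele dose 0/1/2 or `NA`.
#'
#' @param genotypes a [genotype_dataset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  readr::write_tsv(as_tibble(genotypes), path)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @param tsv_source path to a dose TSV.
#' @param oriented whether the file's doses already count the minor allele.
#' @export
read_genotype_tsv <- function(tsv_source, oriented = TRUE) {
  df <- readr::read_tsv(tsv_source, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          .default = readr::col_integer()))
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$sample_id
  genotype_dataset(calls, oriented = oriented)
}

#' Read a SNP annotation table
#'
#' TSV with columns `snp_id`, `gene`, `pubmed_ids`
#' (semicolon-separated, empty = no links) and `cancer_flag`.
#'
#' @param tsv_source path to the TSV.
#' @return a tibble with list-column `pubmed_ids` and logical
#'   `cancer_flag`.
#' @export
read_annotations <- function(tsv_source) {
  df <- readr::read_tsv(tsv_source, show_col_types = FALSE,
                        col_types = readr::cols(
                          snp_id = readr::col_character(),
                          gene = readr::col_character(),
                          pubmed_ids = readr::col_character(),
                          cancer_flag = readr::col_logical()))
  if (anyDuplicated(df$snp_id)) {
    stop("duplicate snp_id in annotation table", call. = FALSE)
  }
  if (anyNA(df$cancer_flag)) {
    stop("cancer_flag must be defined for every record", call. = FALSE)
  }
  df$pubmed_ids <- lapply(df$pubmed_ids, function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";")[[1]]
  })
  df
}
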