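#' Does a computed value reproduce a printed statistic?
#'
#' Publication tables print statistics at a few significant digits.
#' `match_printed()` tests whether a computed value would have been
#' printed as the target: under `mode = "round"` the significand is
#' rounded half-up to the target's precision, under `mode = "trunc"` it
#' is truncated.
#'
#' @param value computed numeric value(s).
#' @param target the printed value.
#' @param sig_digits significant digits of the printed value (>= 1).
#' @param mode `"round"` (default) or `"trunc"`.
#' @return logical vector.
#' @export
#' @examples
#' match_printed(2.4961e-5, 2.50e-5, 3) # TRUE
#' match_printed(0.0839, 0.084, 2)      # TRUE
match_printed <- function(value, target, sig_digits, mode = "round") {
  stopifnot(sig_digits >= 1)
  mode <- match.arg(mode, c("round", "trunc"))
  if (target == 0) return(!is.na(value) & value == 0)
  tol <- abs(target) * 1e-9
  out <- logical(length(value))
  ok <- !is.na(value) & is.finite(value)
  v <- value[ok]
  if (mode == "round") {
    out[ok] <- abs(signif_half_up(v, sig_digits) - target) <= tol
  } else {
    e <- floor(log10(abs(v)))
    f <- 10^(e - sig_digits + 1)
    out[ok] <- abs(sign(v) * floor(abs(v) / f) * f - target) <= tol
  }
  out
}

#' Integer count pairs reproducing a printed percentage
#'
#' Finds all (numerator, denominator) integer pairs with denominator at
#' most `max_total` whose percentage rounds half-up (one decimal) to the
#' printed value, e.g. a printed response rate.
#'
#' @param rounded_percent printed percentage with one decimal, in
#'   \[0, 100\].
#' @param max_total largest denominator to consider.
#' @return a tibble of all solutions `(numerator, denominator)` ordered
#'   by denominator; zero rows when none exists.
#' @export
#' @examples
#' solve_counts_from_rate(28.1, 119) # minimal solution 9/32
solve_counts_from_rate <- function(rounded_percent, max_total) {
  stopifnot(rounded_percent >= 0, rounded_percent <= 100, max_total >= 1)
  sols <- purrr::map_dfr(seq_len(max_total), function(d) {
    k <- 0:d
    pct <- 100 * k / d
    hit <- floor(pct * 10 + 0.5) / 10 == rounded_percent
    tibble::tibble(numerator = k[hit], denominator = d)
  })
  sols
}

#' A printed-statistic constraint on one genetic model
#'
#' @param model `"allele"`, `"dominant"` or `"recessive"`.
#' @param p printed two-sided Fisher p-value (or `NULL` to skip).
#' @param p_sig significant digits of the printed p.
#' @param or printed odds ratio (0 allowed; `NULL` to skip).
#' @param or_sig significant digits of the printed OR.
#' @param or_convention conventions to try: any of `"cmle"`, `"sample"`.
#' @return a `stat_constraint` list.
#' @export
stat_constraint <- function(model, p = NULL, p_sig = 3, or = NULL,
                            or_sig = 2, or_convention = c("cmle", "sample")) {
  model <- match.arg(model, c("allele", "dominant", "recessive"))
  structure(list(model = model, p = p, p_sig = p_sig, or = or,
                 or_sig = or_sig, or_convention = or_convention),
            class = "stat_constraint")
}

# cells of a model 2x2 from a genotype split (x = responders, y = not)
model_cells <- function(x0, x1, x2, y0, y1, y2, model) {
  switch(model,
    allele = cbind(x1 + 2 * x2, 2 * x0 + x1, y1 + 2 * y2, 2 * y0 + y1),
    dominant = cbind(x1 + x2, x0, y1 + y2, y0),
    recessive = cbind(x2, x0 + x1, y2, y0 + y1)
  )
}

# does the 2x2 (a,b,c,d) satisfy the constraint? Both row orientations
# (OR vs 1/OR) and each requested OR convention are tried; returns the
# matching annotation or NULL.
check_constraint_2x2 <- function(a, b, c, d, cs, mode = "round") {
  if (!is.null(cs$p)) {
    p <- fisher_2x2_vec(a, b, c, d)
    if (!match_printed(p, cs$p, cs$p_sig, mode)) return(NULL)
  }
  if (is.null(cs$or)) return(list(convention = NA, orientation = NA))
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  for (conv in cs$or_convention) {
    or <- odds_ratio(tab, conv)
    if (cs$or == 0) {
      if (identical(or, 0) || identical(or, Inf)) {
        return(list(convention = conv, orientation = if (or == 0) "as-is"
                    else "swapped"))
      }
      next
    }
    if (is.finite(or) && or > 0) {
      if (match_printed(or, cs$or, cs$or_sig, mode)) {
        return(list(convention = conv, orientation = "as-is"))
      }
      if (match_printed(1 / or, cs$or, cs$or_sig, mode)) {
        return(list(convention = conv, orientation = "swapped"))
      }
    }
  }
  NULL
}

#' Reconstruct genotype-by-response tables from printed statistics
#'
#' Enumerates all 2x3 genotype-by-response integer tables (rows
#' responders / non-responders, columns minor-allele dose 0/1/2) with
#' total in `n_range`, keeping those whose genetic-model statistics
#' reproduce every printed constraint at its printed precision. The
#' search is staged: the allele-model 2x2 tables are enumerated first
#' (cheap sample-OR window prefilter, then exact p), and only surviving
#' allele tables are expanded into genotype splits, against which the
#' remaining model constraints are checked.
#'
#' @param constraints list of [stat_constraint()]; must include an
#'   `"allele"` constraint with a p-value (the staging anchor).
#' @param n_range integer vector of admissible table totals (the cohort
#'   size down to plausible per-SNP missingness).
#' @param mode printed-value match mode, `"round"` or `"trunc"`.
#' @return a tibble of solutions: the genotype split
#'   `x0,x1,x2,y0,y1,y2`, `n`, responders `n_resp`, and for each genetic
#'   model its exact p and conditional-MLE and sample ORs (oriented so
#'   the allele-model OR is at most 1), plus which convention and
#'   orientation matched each constrained model.
#' @export
solve_genotype_table <- function(constraints, n_range, mode = "round") {
  stopifnot(length(n_range) >= 1)
  models <- vapply(constraints, function(cs) cs$model, "")
  if (anyDuplicated(models)) stop("one constraint per model", call. = FALSE)
  ai <- which(models == "allele")
  if (length(ai) != 1L || is.null(constraints[[ai]]$p)) {
    stop("an allele-model constraint with a p-value is required",
         call. = FALSE)
  }
  acs <- constraints[[ai]]
  rest <- constraints[-ai]

  allele_hits <- allele_stage_scan(acs, n_range, mode)
  sols <- purrr::pmap_dfr(allele_hits, function(n, n_resp, a, c) {
    expand_genotype_splits(n, n_resp, a, c, acs, rest, mode)
  })
  attr(sols, "allele_tables") <- allele_hits
  sols
}

#' Expand previously found allele-stage tables against new constraints
#'
#' Reuses the allele-model survivors of a [solve_genotype_table()] run
#' (its `"allele_tables"` attribute) and re-checks the genotype splits
#' against a different set of non-allele constraints, avoiding a second
#' full enumeration.
#'
#' @param allele_tables tibble with columns `n`, `n_resp`, `a`, `c`.
#' @param constraints list of non-allele [stat_constraint()]s.
#' @param mode printed-value match mode.
#' @return solution tibble as from [solve_genotype_table()].
#' @export
resolve_splits <- function(allele_tables, constraints, mode = "round") {
  acs <- stat_constraint("allele")
  purrr::pmap_dfr(allele_tables, function(n, n_resp, a, c) {
    expand_genotype_splits(n, n_resp, a, c, acs, constraints, mode)
  })
}

# stage 1: enumerate allele 2x2 tables (row sums 2*R, 2*(n-R)) matching
# the allele constraint
allele_stage_scan <- function(acs, n_range, mode) {
  out <- list()
  for (n in sort(unique(as.integer(n_range)))) {
    for (R in 1:(n - 1)) {
      S <- n - R
      grid <- expand.grid(a = 0:(2 * R), c = 0:(2 * S))
      a <- grid$a; c <- grid$c
      b <- 2L * R - a; d <- 2L * S - c
      if (!is.null(acs$or) && acs$or > 0) {
        # generous window on the sample OR before any exact-test work;
        # the cmle never strays far from the cross-product on tables
        # this size, so a factor-4 band is safe
        or_s <- (a * d) / (b * c)
        omin <- pmin(or_s, 1 / or_s)
        keep <- which(!is.na(omin) & omin > acs$or / 4 & omin < acs$or * 4)
      } else if (!is.null(acs$or) && acs$or == 0) {
        keep <- which(a * d == 0 | b * c == 0)
      } else {
        keep <- seq_along(a)
      }
      if (!length(keep)) next
      p <- fisher_2x2_vec(a[keep], b[keep], c[keep], d[keep])
      keep <- keep[match_printed(p, acs$p, acs$p_sig, mode)]
      for (i in keep) {
        hit <- check_constraint_2x2(a[i], b[i], c[i], d[i],
                                    # p already matched; only check OR
                                    stat_constraint("allele", p = NULL,
                                                    or = acs$or,
                                                    or_sig = acs$or_sig,
                                                    or_convention =
                                                      acs$or_convention),
                                    mode)
        if (!is.null(hit)) {
          out[[length(out) + 1]] <- tibble::tibble(n = n, n_resp = R,
                                                   a = a[i], c = c[i])
        }
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(n = integer(), n_resp = integer(), a = integer(),
                   c = integer())
  }
}

# stage 2: expand an allele table into genotype splits and check the
# remaining model constraints
expand_genotype_splits <- function(n, R, a, c, acs, rest, mode) {
  S <- n - R
  sols <- list()
  for (x2 in 0:(a %/% 2)) {
    x1 <- a - 2L * x2; x0 <- R - x1 - x2
    if (x0 < 0L) next
    for (y2 in 0:(c %/% 2)) {
      y1 <- c - 2L * y2; y0 <- S - y1 - y2
      if (y0 < 0L) next
      notes <- list()
      ok <- TRUE
      for (cs in rest) {
        cells <- model_cells(x0, x1, x2, y0, y1, y2, cs$model)
        hit <- check_constraint_2x2(cells[1], cells[2], cells[3], cells[4],
                                    cs, mode)
        if (is.null(hit)) { ok <- FALSE; break }
        notes[[cs$model]] <- hit
      }
      if (!ok) next
      sols[[length(sols) + 1]] <-
        solution_row(x0, x1, x2, y0, y1, y2, notes)
    }
  }
  if (length(sols)) dplyr::bind_rows(sols) else tibble::tibble()
}

# full statistic set for one genotype split, oriented so the allele OR
# is <= 1
solution_row <- function(x0, x1, x2, y0, y1, y2, notes) {
  stats_for <- function(model) {
    cells <- model_cells(x0, x1, x2, y0, y1, y2, model)
    tab <- matrix(cells[1, ], 2, byrow = TRUE)
    list(p = fisher_exact_2x2(tab),
         or_cmle = odds_ratio(tab, "cmle"),
         or_sample = odds_ratio(tab, "sample"))
  }
  al <- stats_for("allele")
  flip <- is.finite(al$or_cmle) && al$or_cmle > 1
  orient <- function(or) {
    if (!flip) return(or)
    if (is.nan(or)) return(or)
    if (or == 0) return(Inf)
    if (is.infinite(or)) return(0)
    1 / or
  }
  dm <- stats_for("dominant")
  rc <- stats_for("recessive")
  tibble::tibble(
    n = x0 + x1 + x2 + y0 + y1 + y2,
    n_resp = x0 + x1 + x2,
    x0 = x0, x1 = x1, x2 = x2, y0 = y0, y1 = y1, y2 = y2,
    p_allele = al$p, or_allele_cmle = orient(al$or_cmle),
    or_allele_sample = orient(al$or_sample),
    p_dominant = dm$p, or_dominant_cmle = orient(dm$or_cmle),
    or_dominant_sample = orient(dm$or_sample),
    p_recessive = rc$p, or_recessive_cmle = orient(rc$or_cmle),
    or_recessive_sample = orient(rc$or_sample),
    matched = paste(vapply(names(notes), function(nm) {
      paste0(nm, ":", notes[[nm]]$convention %||% "p-only")
    }, ""), collapse = ";")
  )
}
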