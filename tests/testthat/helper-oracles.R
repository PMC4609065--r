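# Independent brute-force oracles, deliberately written against the
# definitions rather than sharing code with the package internals.

# two-sided Fisher p for a 2x2 by explicit enumeration over the free cell
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact conditional p for an r x c table by recursive enumeration of all
# tables with the observed margins; probabilities from the
# multiple-hypergeometric formula
oracle_fisher_rxc <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  lfac <- lfactorial
  log_prob <- function(m) {
    sum(lfac(rs)) + sum(lfac(cs)) - lfac(N) - sum(lfac(m))
  }
  # enumerate row by row; the last cell of each row and the whole last
  # row are forced by the margins
  tables <- list()
  nr <- length(rs); nc <- length(cs)
  rec <- function(rows_done, col_left) {
    if (length(rows_done) == nr - 1) {
      last <- col_left
      if (all(last >= 0) && sum(last) == rs[nr]) {
        tables[[length(tables) + 1]] <<- do.call(rbind,
                                                 c(rows_done, list(last)))
      }
      return(invisible())
    }
    i <- length(rows_done) + 1
    fill <- function(prefix, j, remaining) {
      if (j == nc) {
        if (remaining <= col_left[nc]) {
          row <- c(prefix, remaining)
          rec(c(rows_done, list(row)), col_left - row)
        }
        return(invisible())
      }
      for (v in 0:min(remaining, col_left[j])) {
        fill(c(prefix, v), j + 1, remaining - v)
      }
    }
    fill(integer(), 1, rs[i])
  }
  rec(list(), cs)
  lp <- vapply(tables, log_prob, numeric(1))
  p_obs <- log_prob(tab)
  sum(exp(lp[lp <= p_obs + log1p(1e-7)]))
}

# exact HWE test by full enumeration over heterozygote counts
oracle_hwe <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(1)
  nA <- 2 * n0 + n1; na <- 2 * n2 + n1
  if (nA == 0 || na == 0) return(1)
  hs <- seq(na %% 2, min(nA, na), by = 2)
  lp <- vapply(hs, function(h) {
    lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
      lfactorial((na - h) / 2) + h * log(2) -
      (lfactorial(2 * n) - lfactorial(nA) - lfactorial(na))
  }, numeric(1))
  obs <- lp[hs == n1]
  sum(exp(lp[lp <= obs + log1p(1e-7)]))
}

# random 2x2 tables with margins bounded by mmax
random_2x2 <- function(mmax) {
  m <- sample.int(mmax, 1); n <- sample.int(mmax, 1)
  k <- sample.int(m + n, 1)
  rng <- max(0, k - n):min(k, m)
  a <- rng[sample.int(length(rng), 1)]
  matrix(c(a, m - a, k - a, n - (k - a)), 2, byrow = TRUE)
}

# tiny in-memory genotype dataset from a dose matrix
toy_genotypes <- function(calls) {
  dimnames(calls) <- list(sprintf("S%02d", seq_len(nrow(calls))),
                          sprintf("rs%06d", seq_len(ncol(calls))))
  genotype_dataset(calls, oriented = TRUE)
}

toy_phenotypes <- function(response, n_s1 = length(response)) {
  n <- length(response)
  validate_phenotypes(tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    regimen = rep(c("S-1", "high-dose 5-FU"),
                  c(n_s1, n - n_s1)),
    recist = ifelse(response == 1, "PR", "NC"),
    cr_grade = 0L,
    chem_history = FALSE
  ))
}
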