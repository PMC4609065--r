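#' Simulation configuration for study-shaped fixtures
#'
#' Defaults emulate the study cohort this package is shaped around: 119
#' fluoropyrimidine-treated patients with a nested 58-sample S-1
#' discovery subset, a ~2,000-SNP knowledge-prefiltered panel, HWE
#' genotypes with uniform MAFs, and a 4-level ordinal response from a
#' latent proportional-odds model (logistic noise, so the
#' proportional-odds fit is correctly specified).
#'
#' @param n_samples cohort size.
#' @param n_first_subset size of the nested discovery (S-1) subset.
#' @param n_snps SNP panel size.
#' @param maf_range uniform MAF bounds, in (0, 0.5].
#' @param causal tibble with columns `index` (SNP column), `or_allele`
#'   (the target allele-model contingency odds ratio of the SNP against
#'   the binary responder grouping; < 1 = minor allele protective) and
#'   optionally `maf` to pin the causal SNP's minor allele frequency.
#'   The generator back-solves the latent proportional-odds coefficient
#'   that induces this marginal allele-table OR (latent effects
#'   attenuate when the logistic noise is marginalized, so the latent
#'   coefficient is substantially stronger than `log(or_allele)`).
#'   `NULL` for a global-null panel.
#' @param beta_cr,beta_chem covariate log-odds (per creatinine grade;
#'   for prior chemotherapy) on the latent scale.
#' @param cutpoints three increasing thresholds on the latent logistic
#'   scale separating CR | PR | NC | PD, expressed for the cohort
#'   average (the generator recalibrates them so the marginal category
#'   rates stay nominal whatever the effect sizes); defaults put 3% CR,
#'   15.1% CR+PR responders and a roughly even NC/PD split.
#' @param delta_regimen latent shift added to non-S-1 patients (worse
#'   response under the non-discovery regimens). The default reproduces
#'   the study's responder split: 22.4% in the S-1 subset vs 8.2% in
#'   the remainder, 15.1% overall.
#' @param cr_probs multinomial probabilities of creatinine grades 0-4.
#' @param p_chem Bernoulli probability of prior chemotherapy.
#' @param causal_ld_r haplotype correlation (the LD measure r) between
#'   the first two causal SNPs; 0 (default) generates independent SNPs.
#'   Positive values emulate a pair of co-predictive markers whose
#'   minor alleles co-occur, which is what lets both attain strong
#'   marginal associations simultaneously.
#' @param missing_rate per-call missingness probability in \[0, 1).
#' @param p_pubmed,p_cancer annotation fractions of PubMed-linked and
#'   cancer-flagged SNPs.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 119L, n_first_subset = 58L,
                       n_snps = 2000L, maf_range = c(0.05, 0.5),
                       causal = tibble::tibble(index = c(1L, 2L),
                                               or_allele = c(0.22, 0.22)),
                       causal_ld_r = 0,
                       beta_cr = 0, beta_chem = 0,
                       cutpoints = qlogis(c(0.03, 0.151, 0.55)),
                       delta_regimen = qlogis(0.224) - qlogis(0.082),
                       cr_probs = c(0.50, 0.30, 0.15, 0.04, 0.01),
                       p_chem = 0.5,
                       missing_rate = 0, p_pubmed = 0.6, p_cancer = 0.2,
                       seed = 1L) {
  stopifnot(n_first_subset <= n_samples,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1,
            p_pubmed >= 0, p_pubmed <= 1, p_cancer >= 0, p_cancer <= 1,
            all(diff(cutpoints) > 0))
  if (!is.null(causal) && nrow(causal) > 0) {
    stopifnot(all(causal$index >= 1), all(causal$index <= n_snps),
              all(is.finite(causal$or_allele)))
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_first_subset = as.integer(n_first_subset),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 causal = causal, causal_ld_r = causal_ld_r,
                 beta_cr = beta_cr, beta_chem = beta_chem,
                 cutpoints = cutpoints, delta_regimen = delta_regimen,
                 cr_probs = cr_probs,
                 p_chem = p_chem, missing_rate = missing_rate,
                 p_pubmed = p_pubmed, p_cancer = p_cancer,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate HWE genotypes
#'
#' Draws a MAF per SNP from the configured uniform range and genotypes
#' from the Hardy-Weinberg multinomial (q^2, 2pq, p^2 with q the MAF);
#' calls are minor-allele doses by construction (sampling noise may make
#' the realized frequency exceed 0.5; [orient_minor_allele()] handles
#' that downstream). Missing calls are Bernoulli.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return a [genotype_dataset].
#' @export
simulate_genotypes <- function(config = sim_config(), seed = NULL) {
  withr::local_seed(seed %||% config$seed)
  n <- config$n_samples; m <- config$n_snps
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  if (!is.null(config$causal) && !is.null(config$causal[["maf"]])) {
    maf[config$causal$index] <- config$causal[["maf"]]
  }
  calls <- vapply(seq_len(m), function(j) {
    sample(0:2, n, replace = TRUE,
           prob = c((1 - maf[j])^2, 2 * maf[j] * (1 - maf[j]), maf[j]^2))
  }, integer(n))
  if (config$causal_ld_r != 0 && !is.null(config$causal) &&
      nrow(config$causal) >= 2) {
    # overwrite the first two causal SNPs with a haplotype-coupled pair:
    # two independent haplotypes per subject, so marginals stay HWE
    i1 <- config$causal$index[1]; i2 <- config$causal$index[2]
    hf <- haplotype_freqs(maf[i1], maf[i2], config$causal_ld_r)
    hap <- function() sample.int(4L, n, replace = TRUE, prob = hf)
    h1 <- hap(); h2 <- hap()
    carries1 <- c(0L, 0L, 1L, 1L)  # haplotypes 00, 01, 10, 11 (snp1, snp2)
    carries2 <- c(0L, 1L, 0L, 1L)
    calls[, i1] <- carries1[h1] + carries1[h2]
    calls[, i2] <- carries2[h1] + carries2[h2]
  }
  if (config$missing_rate > 0) {
    calls[runif(n * m) < config$missing_rate] <- NA_integer_
  }
  nucs <- c("A", "C", "G", "T")
  pairs <- t(vapply(seq_len(m), function(j) sample(nucs, 2), character(2)))
  dimnames(calls) <- list(sprintf("S%03d", seq_len(n)),
                          sprintf("rs%06d", seq_len(m)))
  genotype_dataset(calls,
                   allele_labels = tibble::tibble(
                     snp_id = colnames(calls),
                     major = pairs[, 1], minor = pairs[, 2]),
                   oriented = TRUE)
}

#' Simulate the ordinal response and clinical covariates
#'
#' Latent score = sum of log(or_allele) * dose over causal SNPs +
#' covariate effects + standard logistic noise; higher latent = worse
#' response. Each effect is centred at its realized cohort mean, so the
#' configured cutpoints fix the cohort-average category distribution
#' whatever the effect sizes. RECIST categories are cut at
#' `config$cutpoints` (CR best), the binary responder grouping is CR+PR,
#' and regimen labels make the first `n_first_subset` samples the S-1
#' discovery subset (the remainder split among the other study
#' regimens).
#'
#' @param genotypes a [genotype_dataset] from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @param seed overrides `config$seed + 1` when given.
#' @return a phenotype tibble (see [validate_phenotypes()]).
#' @export
simulate_response <- function(genotypes, config = sim_config(),
                              seed = NULL) {
  withr::local_seed(seed %||% (config$seed + 1L))
  n <- length(genotypes$sample_ids)
  n1 <- config$n_first_subset
  others <- c("5-FU/MTX", "high-dose 5-FU", "low-dose 5-FU")
  n_rest <- n - n1
  regimen <- c(rep("S-1", n1),
               if (n_rest > 0) others[1 + (seq_len(n_rest) %% 3L)])
  regimen <- regimen[seq_len(n)]
  reg_shift <- config$delta_regimen * (regimen != "S-1")
  offsets <- list(values = unique(reg_shift),
                  prob = as.numeric(table(factor(reg_shift,
                                                 unique(reg_shift)))) / n)

  eta <- reg_shift
  if (!is.null(config$causal) && nrow(config$causal) > 0) {
    doses <- lapply(config$causal$index, function(j) {
      d <- genotypes$calls[, j]
      d[is.na(d)] <- 0L
      d
    })
    # calibrate on the configured MAFs when pinned (stable across
    # replicates); realized frequencies otherwise
    mafs <- if (!is.null(config$causal[["maf"]])) config$causal[["maf"]] else
      vapply(doses, function(d) mean(d) / 2, numeric(1))
    dd <- causal_dose_dist(mafs, config$causal_ld_r)
    cal <- latent_betas_for_allele_or(config$causal$or_allele, dd,
                                      config$cutpoints, offsets)
    for (i in seq_along(doses)) {
      eta <- eta + cal$betas[i] * (doses[[i]] - mean(doses[[i]]))
    }
    cutpoints <- cal$cutpoints
  } else {
    cal <- latent_betas_for_allele_or(numeric(0),
                                      list(combos = matrix(0, 1, 0),
                                           prob = 1),
                                      config$cutpoints, offsets)
    cutpoints <- cal$cutpoints
  }
  cr_grade <- sample(0:4, n, replace = TRUE, prob = config$cr_probs)
  chem <- runif(n) < config$p_chem
  eta <- eta + config$beta_cr * (cr_grade - mean(cr_grade)) +
    config$beta_chem * (chem - mean(chem))
  latent <- eta + rlogis(n)
  cat_idx <- findInterval(latent, cutpoints) + 1L
  recist <- c("CR", "PR", "NC", "PD")[cat_idx]
  if (length(unique(recist)) == 1L) {
    warning("all samples fall in one response category", call. = FALSE)
  }
  validate_phenotypes(tibble::tibble(
    sample_id = genotypes$sample_ids,
    regimen = regimen,
    recist = recist,
    cr_grade = as.integer(cr_grade),
    chem_history = chem
  ))
}

#' Simulate a SNP annotation table
#'
#' Bernoulli PubMed-link and cancer flags at the configured fractions,
#' with synthetic PubMed identifiers.
#'
#' @param config a [sim_config()].
#' @param snp_ids SNP identifiers (default `rs000001...`).
#' @param seed overrides `config$seed + 2` when given.
#' @return an annotation tibble as from [read_annotations()].
#' @export
simulate_annotation <- function(config = sim_config(), snp_ids = NULL,
                                seed = NULL) {
  withr::local_seed(seed %||% (config$seed + 2L))
  snp_ids <- snp_ids %||% sprintf("rs%06d", seq_len(config$n_snps))
  m <- length(snp_ids)
  linked <- runif(m) < config$p_pubmed
  cancer <- runif(m) < config$p_cancer
  tibble::tibble(
    snp_id = snp_ids,
    gene = sprintf("GENE%04d", seq_len(m)),
    pubmed_ids = lapply(seq_len(m), function(i) {
      if (linked[i]) sprintf("%08d", sample.int(1e7, sample(1:3, 1)))
      else character()
    }),
    cancer_flag = cancer
  )
}

# Haplotype frequencies for a biallelic pair with minor-allele
# frequencies q1, q2 and LD correlation r; order (00, 01, 10, 11) where
# 1 marks carrying the minor allele at (snp1, snp2).
haplotype_freqs <- function(q1, q2, r) {
  d_max <- min(q1 * (1 - q2), (1 - q1) * q2)
  d_min <- -min(q1 * q2, (1 - q1) * (1 - q2))
  D <- r * sqrt(q1 * (1 - q1) * q2 * (1 - q2))
  if (D > d_max + 1e-12 || D < d_min - 1e-12) {
    stop("requested LD r is not attainable at these allele frequencies",
         call. = FALSE)
  }
  c(`00` = (1 - q1) * (1 - q2) + D, `01` = (1 - q1) * q2 - D,
    `10` = q1 * (1 - q2) - D, `11` = q1 * q2 + D)
}

# joint distribution of causal minor-allele doses: a (3^k x k) combo
# matrix with a probability per row; the first two causal SNPs may be
# haplotype-coupled, the rest are independent HWE
causal_dose_dist <- function(q, ld_r = 0) {
  k <- length(q)
  hwe <- function(qi) c((1 - qi)^2, 2 * qi * (1 - qi), qi^2)
  combos <- as.matrix(expand.grid(rep(list(0:2), k)))
  colnames(combos) <- NULL
  if (ld_r != 0 && k >= 2) {
    hf <- haplotype_freqs(q[1], q[2], ld_r)
    # genotype pair = two independent haplotypes
    joint12 <- matrix(0, 3, 3)
    carries <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    for (a in 1:4) for (b in 1:4) {
      d1 <- carries[a, 1] + carries[b, 1]
      d2 <- carries[a, 2] + carries[b, 2]
      joint12[d1 + 1, d2 + 1] <- joint12[d1 + 1, d2 + 1] + hf[a] * hf[b]
    }
    prob <- joint12[cbind(combos[, 1] + 1L, combos[, 2] + 1L)]
    if (k > 2) {
      for (j in 3:k) prob <- prob * hwe(q[j])[combos[, j] + 1L]
    }
  } else {
    prob <- rep(1, nrow(combos))
    for (j in seq_len(k)) prob <- prob * hwe(q[j])[combos[, j] + 1L]
  }
  list(combos = combos, prob = prob)
}

# Latent proportional-odds coefficients inducing target marginal
# allele-model ORs for the causal SNPs, together with cutpoints
# adjusted so the marginal RECIST category distribution stays at the
# configured nominal one. Each SNP's marginal association is attenuated
# both by the logistic noise and by the other causal SNPs' latent
# contributions (Jensen's inequality also shifts the marginal category
# rates), so coefficients and thresholds are solved jointly by
# fixed-point iteration, integrating exactly over the joint causal dose
# distribution. Response = latent <= cutpoints[2].
latent_betas_for_allele_or <- function(or_allele, dose_dist, cutpoints,
                                       offsets = list(values = 0,
                                                      prob = 1)) {
  k <- length(or_allele)
  combos <- dose_dist$combos
  # expand the dose grid by the fixed-offset distribution (e.g. the
  # regimen effect): every (dose combo, offset) cell with its weight
  n_off <- length(offsets$values)
  w <- rep(dose_dist$prob, times = n_off) *
    rep(offsets$prob, each = nrow(combos))
  off <- rep(offsets$values, each = nrow(combos))
  dgrid <- combos[rep(seq_len(nrow(combos)), times = n_off), , drop = FALSE]
  md <- if (k) as.numeric(t(combos) %*% dose_dist$prob) else numeric(0)
  eta_of <- function(betas) {
    base <- if (k) as.numeric(dgrid %*% betas) - sum(betas * md) else 0
    base + off
  }
  adjust_cut <- function(c_nom, eta) {
    # threshold whose marginal crossing probability matches the nominal
    target <- stats::plogis(c_nom)
    stats::uniroot(function(cc) sum(w * stats::plogis(cc - eta)) - target,
                   lower = c_nom - 200, upper = c_nom + 200,
                   tol = 1e-10)$root
  }
  log_marginal_or <- function(i, beta_i, betas, c2) {
    b <- betas; b[i] <- beta_i
    pr <- stats::plogis(c2 - eta_of(b))
    w_resp <- w * pr
    w_non <- w * (1 - pr)
    d <- dgrid[, i]
    f1 <- sum(w_resp * d) / (2 * sum(w_resp))
    f0 <- sum(w_non * d) / (2 * sum(w_non))
    log(f1 / (1 - f1)) - log(f0 / (1 - f0))
  }
  target <- log(1 / or_allele)
  residuals <- function(betas) {
    c2 <- adjust_cut(cutpoints[2], eta_of(betas))
    vapply(seq_len(k), function(i) {
      log_marginal_or(i, betas[i], betas, c2) - target[i]
    }, numeric(1))
  }
  betas <- log(or_allele)
  if (k > 0L) {
    # coordinate-wise root sweeps; fast when the causal doses are not
    # too collinear
    for (iter in seq_len(100L)) {
      prev <- betas
      c2 <- adjust_cut(cutpoints[2], eta_of(betas))
      for (i in seq_len(k)) {
        if (or_allele[i] == 1) { betas[i] <- 0; next }
        fl <- log_marginal_or(i, -60, betas, c2) - target[i]
        fh <- log_marginal_or(i, 60, betas, c2) - target[i]
        if (sign(fl) == sign(fh)) {
          stop("target allele OR ", or_allele[i], " for causal SNP ", i,
               " is not attainable: the marginal allele-model OR of ",
               "jointly acting causal SNPs is bounded by the ",
               "deterministic dose-response limit; weaken the OR, ",
               "reduce the number of causal SNPs, or couple them with ",
               "causal_ld_r", call. = FALSE)
        }
        betas[i] <- stats::uniroot(
          function(b) log_marginal_or(i, b, betas, c2) - target[i],
          lower = -60, upper = 60, tol = 1e-8)$root
      }
      if (max(abs(betas - prev)) < 1e-6) break
    }
    # collinear causal doses can make the sweeps oscillate; verify the
    # achieved marginals and fall back to a joint least-squares solve
    if (sqrt(sum(residuals(betas)^2)) > 1e-3) {
      ss <- function(b) sum(residuals(b)^2)
      if (k == 1L) {
        opt <- stats::optimize(function(b) ss(b), c(-60, 60),
                               tol = 1e-12)
        betas <- opt$minimum
      } else {
        for (start in list(betas, target, 2 * target)) {
          opt <- stats::optim(start, ss, method = "Nelder-Mead",
                              control = list(maxit = 5000,
                                             reltol = 1e-14))
          opt <- stats::optim(opt$par, ss, method = "BFGS",
                              control = list(maxit = 500, reltol = 1e-14,
                                             ndeps = rep(1e-6, k)))
          if (sqrt(opt$value) < 1e-6) break
        }
        betas <- opt$par
      }
      if (sqrt(sum(residuals(betas)^2)) > 1e-3) {
        stop("could not calibrate the latent effects to the requested ",
             "allele-model odds ratios (achieved marginals differ); ",
             "the targets may be jointly unattainable", call. = FALSE)
      }
    }
  }
  eta <- eta_of(betas)
  list(betas = betas,
       cutpoints = vapply(cutpoints, adjust_cut, numeric(1), eta = eta))
}

#' Generate a complete study-shaped fixture
#'
#' Genotypes, phenotypes and annotations in one bundle, with the nested
#' discovery/full split implied by the regimen labels.
#'
#' @param config a [sim_config()].
#' @return a list with `genotypes`, `phenotypes`, `annotations`, and
#'   `datasets` (the [split_datasets()] id lists).
#' @export
make_study_fixture <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  pheno <- simulate_response(geno, config)
  anno <- simulate_annotation(config, snp_ids = geno$snp_ids)
  list(genotypes = geno, phenotypes = pheno, annotations = anno,
       datasets = split_datasets(pheno))
}
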