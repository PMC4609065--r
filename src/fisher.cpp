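#include <Rcpp.h>
using namespace Rcpp;

// cached log-factorials, grown on demand
static std::vector<double> lfact_tab(1, 0.0);
static inline double lfact(int n) {
  if ((size_t)n >= lfact_tab.size()) {
    size_t old = lfact_tab.size();
    lfact_tab.resize(n + 1);
    for (size_t i = old; i <= (size_t)n; ++i) {
      lfact_tab[i] = lfact_tab[i - 1] + log((double)i);
    }
  }
  return lfact_tab[n];
}
static inline double lch(int n, int k) {
  return lfact(n) - lfact(k) - lfact(n - k);
}

// Two-sided Fisher exact p for a 2x2 table: sum of hypergeometric point
// probabilities not exceeding the observed one, with a 1e-7 relative tie
// tolerance. Any empty row/column margin gives p = 1 by convention.
static double fisher2x2_one(int a, int b, int c, int d) {
  int m = a + b, n = c + d, k = a + c;
  if (m == 0 || n == 0 || k == 0 || k == m + n) return 1.0;
  int lo = std::max(0, k - n), hi = std::min(k, m);
  double lden = lch(m + n, k);
  double lobs = lch(m, a) + lch(n, k - a) - lden;
  double cutoff = lobs + log1p(1e-7);
  double p = 0.0;
  for (int x = lo; x <= hi; ++x) {
    double lp = lch(m, x) + lch(n, k - x) - lden;
    if (lp <= cutoff) p += exp(lp);
  }
  return p < 1.0 ? p : 1.0;
}

// [[Rcpp::export]]
NumericVector fisher2x2_p_cpp(IntegerVector a, IntegerVector b,
                              IntegerVector c, IntegerVector d) {
  R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_INTEGER || b[i] == NA_INTEGER ||
        c[i] == NA_INTEGER || d[i] == NA_INTEGER) {
      out[i] = NA_REAL;
    } else {
      out[i] = fisher2x2_one(a[i], b[i], c[i], d[i]);
    }
  }
  return out;
}

// Exact Hardy-Weinberg test conditioning on the allele counts: p is the sum
// of point probabilities (over heterozygote counts of the right parity) not
// exceeding the observed one.
static double hwe_one(int n0, int n1, int n2) {
  int n = n0 + n1 + n2;
  if (n == 0) return 1.0;
  int nA = 2 * n0 + n1, na = 2 * n2 + n1;
  if (nA == 0 || na == 0) return 1.0;
  double denom = R::lgammafn(2.0 * n + 1.0) - R::lgammafn(nA + 1.0) -
                 R::lgammafn(na + 1.0);
  int hmax = std::min(nA, na);
  int start = na % 2;
  double lobs = R::lgammafn(n + 1.0) - R::lgammafn((nA - n1) / 2.0 + 1.0) -
                R::lgammafn(n1 + 1.0) - R::lgammafn((na - n1) / 2.0 + 1.0) +
                n1 * M_LN2 - denom;
  double cutoff = lobs + log1p(1e-7);
  double p = 0.0;
  for (int h = start; h <= hmax; h += 2) {
    double lp = R::lgammafn(n + 1.0) - R::lgammafn((nA - h) / 2.0 + 1.0) -
                R::lgammafn(h + 1.0) - R::lgammafn((na - h) / 2.0 + 1.0) +
                h * M_LN2 - denom;
    if (lp <= cutoff) p += exp(lp);
  }
  return p < 1.0 ? p : 1.0;
}

// [[Rcpp::export]]
NumericVector hwe_exact_p_cpp(IntegerVector n0, IntegerVector n1,
                              IntegerVector n2) {
  R_xlen_t n = n0.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = hwe_one(n0[i], n1[i], n2[i]);
  return out;
}

// model: 0 = allele, 1 = dominant, 2 = recessive
static double model_p(int r0, int r1, int r2, int s0, int s1, int s2,
                      int model) {
  switch (model) {
  case 0:
    return fisher2x2_one(r1 + 2 * r2, 2 * r0 + r1, s1 + 2 * s2, 2 * s0 + s1);
  case 1:
    return fisher2x2_one(r1 + r2, r0, s1 + s2, s0);
  default:
    return fisher2x2_one(r2, r0 + r1, s2, s0 + s1);
  }
}

// Per-SNP p-values for one sample subset under a genetic model.
// doses: samples x snps, NA allowed; resp: 0/1 per sample; idx0: 0-based
// subset indices. A SNP with no non-missing call in the subset gets NA.
// [[Rcpp::export]]
NumericVector stage_p_cpp(IntegerMatrix doses, IntegerVector resp,
                          IntegerVector idx0, int model) {
  int m = doses.ncol();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    int cnt[2][3] = {{0, 0, 0}, {0, 0, 0}};
    int seen = 0;
    for (int ii = 0; ii < idx0.size(); ++ii) {
      int i = idx0[ii];
      int g = doses(i, j);
      if (g == NA_INTEGER) continue;
      cnt[resp[i]][g]++;
      seen++;
    }
    out[j] = seen == 0 ? NA_REAL
                       : model_p(cnt[1][0], cnt[1][1], cnt[1][2], cnt[0][0],
                                 cnt[0][1], cnt[0][2], model);
  }
  return out;
}

// Min over SNPs of max(stage1 p, stage2 p) for n_perm permutations of the
// response labels; the stage-1 labels are the induced restriction,
// preserving the nesting of the two datasets. With stratify = true the
// labels are shuffled within the discovery subset and within its
// complement separately, so both stage responder margins are held at
// their observed values (required for exactness when response depends on
// regimen). Uses R's RNG so set.seed() makes runs reproducible. SNPs
// with no data in a stage are skipped in the min.
// [[Rcpp::export]]
NumericVector perm_min_t_cpp(IntegerMatrix doses, IntegerVector resp,
                             IntegerVector first_idx0, int n_perm,
                             int model, bool stratify) {
  int n = doses.nrow(), m = doses.ncol();
  std::vector<int> z(resp.begin(), resp.end());
  std::vector<char> in_first(n, 0);
  for (int ii = 0; ii < first_idx0.size(); ++ii) in_first[first_idx0[ii]] = 1;
  std::vector<int> stratum1, stratum2;
  for (int i = 0; i < n; ++i) {
    if (in_first[i]) stratum1.push_back(i); else stratum2.push_back(i);
  }
  NumericVector out(n_perm);
  for (int b = 0; b < n_perm; ++b) {
    if (stratify) {
      for (size_t s = 0; s < 2; ++s) {
        std::vector<int> &st = s == 0 ? stratum1 : stratum2;
        for (int i = (int)st.size() - 1; i > 0; --i) {
          int jj = (int)floor(unif_rand() * (i + 1));
          if (jj > i) jj = i;
          std::swap(z[st[i]], z[st[jj]]);
        }
      }
    } else {
      // Fisher-Yates shuffle of the response labels over the full cohort
      for (int i = n - 1; i > 0; --i) {
        int jj = (int)floor(unif_rand() * (i + 1));
        if (jj > i) jj = i;
        std::swap(z[i], z[jj]);
      }
    }
    double tmin = R_PosInf;
    for (int j = 0; j < m; ++j) {
      int c1[2][3] = {{0, 0, 0}, {0, 0, 0}};  // stage 1 (subset)
      int c2[2][3] = {{0, 0, 0}, {0, 0, 0}};  // stage 2 (all)
      int seen1 = 0, seen2 = 0;
      for (int i = 0; i < n; ++i) {
        int g = doses(i, j);
        if (g == NA_INTEGER) continue;
        c2[z[i]][g]++;
        seen2++;
        if (in_first[i]) {
          c1[z[i]][g]++;
          seen1++;
        }
      }
      if (seen1 == 0 || seen2 == 0) continue;
      double p1 = model_p(c1[1][0], c1[1][1], c1[1][2], c1[0][0], c1[0][1],
                          c1[0][2], model);
      double p2 = model_p(c2[1][0], c2[1][1], c2[1][2], c2[0][0], c2[0][1],
                          c2[0][2], model);
      double t = p1 > p2 ? p1 : p2;
      if (t < tmin) tmin = t;
    }
    out[b] = tmin;
  }
  return out;
}
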