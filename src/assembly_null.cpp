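#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Nearest-taxon distances under a tip permutation.
// M is otus x samples (flat, column-major): M[s*n_otu + i] = min over taxa j
// present in sample s of d(perm[i], perm[j]).  perm relabels tips on the
// patristic matrix (the taxa-shuffle null); the identity gives the observed
// value.  d must be symmetric, so a column of d doubles as a row.
static void ntd_matrix(const std::vector< std::vector<int> >& pres,
                       const NumericMatrix& d, const int* perm,
                       int n_otu, int n_samp, std::vector<double>& M) {
  const double* dp = &d[0];
  for (int s = 0; s < n_samp; ++s) {
    const std::vector<int>& P = pres[s];
    double* Ms = &M[(size_t)s * n_otu];
    for (int i = 0; i < n_otu; ++i) {
      const double* drow = dp + (size_t)perm[i] * n_otu;
      double mn = R_PosInf;
      for (size_t k = 0; k < P.size(); ++k) {
        double v = drow[perm[P[k]]];
        if (v < mn) mn = v;
      }
      Ms[i] = mn;
    }
  }
}

// Abundance-weighted beta mean nearest taxon distance for all sample pairs.
// bmntd(a,b) = 0.5 * ( sum_{i in a} f_ai * ntd(i -> b) +
//                      sum_{j in b} f_bj * ntd(j -> a) )
static void bmntd_all(const NumericMatrix& freq,
                      const std::vector< std::vector<int> >& pres,
                      const std::vector<double>& M,
                      int n_otu, int n_samp, std::vector<double>& out) {
  std::fill(out.begin(), out.end(), 0.0);
  for (int a = 0; a < n_samp; ++a) {
    for (int b = 0; b < n_samp; ++b) {
      if (a == b) continue;
      const std::vector<int>& P = pres[a];
      const double* Mb = &M[(size_t)b * n_otu];
      double acc = 0.0;
      for (size_t k = 0; k < P.size(); ++k) {
        int i = P[k];
        acc += freq(a, i) * Mb[i];
      }
      out[(size_t)b * n_samp + a] += 0.5 * acc;
      out[(size_t)a * n_samp + b] += 0.5 * acc;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_bmntd(NumericMatrix freq, NumericMatrix d) {
  int n_samp = freq.nrow(), n_otu = freq.ncol();
  std::vector< std::vector<int> > pres(n_samp);
  for (int s = 0; s < n_samp; ++s)
    for (int i = 0; i < n_otu; ++i)
      if (freq(s, i) > 0) pres[s].push_back(i);
  std::vector<int> ident(n_otu);
  for (int i = 0; i < n_otu; ++i) ident[i] = i;
  std::vector<double> M((size_t)n_otu * n_samp);
  ntd_matrix(pres, d, ident.data(), n_otu, n_samp, M);
  std::vector<double> out((size_t)n_samp * n_samp);
  bmntd_all(freq, pres, M, n_otu, n_samp, out);
  NumericMatrix res(n_samp, n_samp);
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// Observed beta MNTD plus null mean and sd over tip permutations.
// perms: n_null x n_otu, 0-based, generated (seeded) on the R side.
// [[Rcpp::export]]
List cpp_bnti_null(NumericMatrix freq, NumericMatrix d, IntegerMatrix perms) {
  int n_samp = freq.nrow(), n_otu = freq.ncol(), n_null = perms.nrow();
  std::vector< std::vector<int> > pres(n_samp);
  for (int s = 0; s < n_samp; ++s)
    for (int i = 0; i < n_otu; ++i)
      if (freq(s, i) > 0) pres[s].push_back(i);

  std::vector<int> ident(n_otu);
  for (int i = 0; i < n_otu; ++i) ident[i] = i;
  std::vector<double> M((size_t)n_otu * n_samp);
  std::vector<double> cur((size_t)n_samp * n_samp);

  ntd_matrix(pres, d, ident.data(), n_otu, n_samp, M);
  bmntd_all(freq, pres, M, n_otu, n_samp, cur);
  NumericMatrix obs(n_samp, n_samp);
  std::copy(cur.begin(), cur.end(), obs.begin());

  std::vector<double> sum((size_t)n_samp * n_samp, 0.0);
  std::vector<double> sumsq((size_t)n_samp * n_samp, 0.0);
  std::vector<int> perm(n_otu);
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < n_otu; ++i) perm[i] = perms(r, i);
    ntd_matrix(pres, d, perm.data(), n_otu, n_samp, M);
    bmntd_all(freq, pres, M, n_otu, n_samp, cur);
    for (size_t k = 0; k < cur.size(); ++k) {
      sum[k] += cur[k];
      sumsq[k] += cur[k] * cur[k];
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix mean_(n_samp, n_samp), sd_(n_samp, n_samp);
  for (size_t k = 0; k < sum.size(); ++k) {
    double m = sum[k] / n_null;
    double v = (sumsq[k] - n_null * m * m) / (n_null - 1.0);
    mean_[k] = m;
    sd_[k] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return List::create(_["obs"] = obs, _["null_mean"] = mean_,
                      _["null_sd"] = sd_);
}

// Raup-Crick null for shared-species counts.  Each replicate draws one null
// assemblage per sample (richness preserved, OTUs drawn without replacement
// with probability proportional to w) and the shared count is read off for
// every pair, so all pairs see a consistent null.  Weighted sampling without
// replacement uses exponential keys (Efraimidis-Spirakis); RNG is R's, so
// set.seed() on the R side makes this reproducible.
// [[Rcpp::export]]
List cpp_raup_crick(LogicalMatrix pres, NumericVector w, int n_null) {
  int n_samp = pres.nrow(), n_otu = pres.ncol();
  int n_words = (n_otu + 63) / 64;

  std::vector<int> pool;
  for (int i = 0; i < n_otu; ++i)
    if (w[i] > 0) pool.push_back(i);
  int pool_size = (int)pool.size();

  std::vector<int> rich(n_samp, 0);
  std::vector<uint64_t> obs_bits((size_t)n_samp * n_words, 0);
  for (int s = 0; s < n_samp; ++s)
    for (int i = 0; i < n_otu; ++i)
      if (pres(s, i)) {
        rich[s]++;
        obs_bits[(size_t)s * n_words + (i >> 6)] |= (uint64_t)1 << (i & 63);
      }
  for (int s = 0; s < n_samp; ++s)
    if (rich[s] > pool_size)
      stop("sample richness exceeds the null pool size");

  IntegerMatrix ss_obs(n_samp, n_samp);
  for (int a = 0; a < n_samp; ++a)
    for (int b = a + 1; b < n_samp; ++b) {
      int sh = 0;
      for (int wd = 0; wd < n_words; ++wd)
        sh += __builtin_popcountll(obs_bits[(size_t)a * n_words + wd] &
                                   obs_bits[(size_t)b * n_words + wd]);
      ss_obs(a, b) = sh;
      ss_obs(b, a) = sh;
    }

  std::vector<int> n_gt((size_t)n_samp * n_samp, 0);
  std::vector<int> n_eq((size_t)n_samp * n_samp, 0);
  std::vector<uint64_t> null_bits((size_t)n_samp * n_words);
  std::vector<double> key(pool_size);
  std::vector<int> idx(pool_size);

  for (int r = 0; r < n_null; ++r) {
    std::fill(null_bits.begin(), null_bits.end(), 0);
    for (int s = 0; s < n_samp; ++s) {
      int k = rich[s];
      for (int t = 0; t < pool_size; ++t) {
        key[t] = R::exp_rand() / w[pool[t]];
        idx[t] = t;
      }
      std::nth_element(idx.begin(), idx.begin() + k, idx.end(),
                       [&](int x, int y) { return key[x] < key[y]; });
      uint64_t* bits = &null_bits[(size_t)s * n_words];
      for (int t = 0; t < k; ++t) {
        int otu = pool[idx[t]];
        bits[otu >> 6] |= (uint64_t)1 << (otu & 63);
      }
    }
    for (int a = 0; a < n_samp; ++a)
      for (int b = a + 1; b < n_samp; ++b) {
        int sh = 0;
        for (int wd = 0; wd < n_words; ++wd)
          sh += __builtin_popcountll(null_bits[(size_t)a * n_words + wd] &
                                     null_bits[(size_t)b * n_words + wd]);
        int o = ss_obs(a, b);
        if (sh > o) n_gt[(size_t)b * n_samp + a]++;
        else if (sh == o) n_eq[(size_t)b * n_samp + a]++;
      }
    if (r % 128 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix brc(n_samp, n_samp);
  for (int a = 0; a < n_samp; ++a)
    for (int b = a + 1; b < n_samp; ++b) {
      double p = (n_gt[(size_t)b * n_samp + a] +
                  0.5 * n_eq[(size_t)b * n_samp + a]) / (double)n_null;
      double v = 2.0 * (p - 0.5);
      brc(a, b) = v;
      brc(b, a) = v;
    }
  return List::create(_["brc"] = brc, _["ss_obs"] = ss_obs);
}
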