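#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Permutation engine for correlation significance over short vectors
// (group-mean vectors of length 8 in the motivating design).
//
// The statistic is the Pearson correlation r, computed as the dot product
// of the two vectors after centering and scaling to unit norm; permuting
// the entries of x permutes its standardized values identically, so each
// permutation costs one length-n dot product.
//
// Counting is strictly-greater ("higher correlation"): a permutation ties
// with the observed statistic only through exact symmetry, and ties never
// count toward the exceedance. A tolerance of 1e-12 keeps the identity
// rearrangement (and symmetric duplicates) from counting via round-off.

static const double TIE_EPS = 1e-12;

// -- seeded RNG: splitmix64 seeding a xorshift64* stream -------------------
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) {
    uint64_t sm = seed;
    s = splitmix64(sm);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  inline uint64_t next() {
    uint64_t x = s;
    x ^= x >> 12;
    x ^= x << 25;
    x ^= x >> 27;
    s = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  inline int bounded(int n) { return (int)(next() % (uint64_t)n); }
};

static inline uint64_t fnv1a(const char *str) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (const char *p = str; *p; ++p) {
    h ^= (uint64_t)(unsigned char)(*p);
    h *= 0x100000001B3ULL;
  }
  return h;
}

// standardize to zero mean, unit L2 norm; returns false if constant
static bool standardize(const double *x, int n, std::vector<double> &out) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) {
    out[i] = x[i] - m;
    ss += out[i] * out[i];
  }
  if (ss <= 0.0) return false;
  double inv = 1.0 / std::sqrt(ss);
  for (int i = 0; i < n; ++i) out[i] *= inv;
  return true;
}

static inline double dot(const std::vector<double> &a,
                         const std::vector<double> &b, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

// exhaustive scan over all n! rearrangements of xs against fixed ys;
// returns number of permutations whose statistic strictly exceeds stat_obs
static long exhaustive_count(const std::vector<double> &xs,
                             const std::vector<double> &ys, int n,
                             bool absolute, double stat_obs, long &n_perms) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  long exceed = 0, total = 0;
  do {
    double r = 0.0;
    for (int i = 0; i < n; ++i) r += xs[idx[i]] * ys[i];
    double stat = absolute ? std::fabs(r) : r;
    if (stat > stat_obs + TIE_EPS) ++exceed;
    ++total;
  } while (std::next_permutation(idx.begin(), idx.end()));
  n_perms = total;
  return exceed;
}

static long monte_carlo_count(const std::vector<double> &xs,
                              const std::vector<double> &ys, int n,
                              bool absolute, double stat_obs, int n_perms,
                              uint64_t seed) {
  XRng rng(seed);
  std::vector<double> perm(xs);
  long exceed = 0;
  for (int b = 0; b < n_perms; ++b) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = rng.bounded(i + 1);
      std::swap(perm[i], perm[j]);
    }
    double r = dot(perm, ys, n);
    double stat = absolute ? std::fabs(r) : r;
    if (stat > stat_obs + TIE_EPS) ++exceed;
  }
  return exceed;
}

// [[Rcpp::export]]
List cpp_perm_exhaustive(NumericVector x, NumericVector y, bool absolute) {
  int n = x.size();
  std::vector<double> xs(n), ys(n);
  if (!standardize(REAL(x), n, xs))
    stop("`x` is constant; correlation is undefined");
  if (!standardize(REAL(y), n, ys))
    stop("`y` is constant; correlation is undefined");
  double r_obs = dot(xs, ys, n);
  double stat_obs = absolute ? std::fabs(r_obs) : r_obs;
  long n_perms = 0;
  long exceed = exhaustive_count(xs, ys, n, absolute, stat_obs, n_perms);
  return List::create(_["r_observed"] = r_obs, _["n_exceeding"] = (double)exceed,
                      _["n_perms"] = (double)n_perms);
}

// [[Rcpp::export]]
List cpp_perm_montecarlo(NumericVector x, NumericVector y, int n_perms,
                         bool absolute, double seed) {
  int n = x.size();
  std::vector<double> xs(n), ys(n);
  if (!standardize(REAL(x), n, xs))
    stop("`x` is constant; correlation is undefined");
  if (!standardize(REAL(y), n, ys))
    stop("`y` is constant; correlation is undefined");
  double r_obs = dot(xs, ys, n);
  double stat_obs = absolute ? std::fabs(r_obs) : r_obs;
  long exceed = monte_carlo_count(xs, ys, n, absolute, stat_obs, n_perms,
                                  (uint64_t)seed);
  return List::create(_["r_observed"] = r_obs, _["n_exceeding"] = (double)exceed,
                      _["n_perms"] = (double)n_perms);
}

// All-pairs scan: rows of `lnc` against rows of `mrna` (columns = groups).
// Per-pair RNG substreams are derived from (seed, lnc_id, mrna_id) so the
// result is independent of iteration order. skip: 0 ok, 1 constant lnc,
// 2 constant mrna.
// [[Rcpp::export]]
List cpp_correlate_pairs(NumericMatrix lnc, NumericMatrix mrna,
                         CharacterVector lnc_ids, CharacterVector mrna_ids,
                         int n_perms, bool absolute, bool exhaustive,
                         double seed) {
  int nl = lnc.nrow(), nm = mrna.nrow(), n = lnc.ncol();
  if (mrna.ncol() != n) stop("group dimension mismatch");
  long npair = (long)nl * nm;

  std::vector<std::vector<double>> lstd(nl, std::vector<double>(n));
  std::vector<std::vector<double>> mstd(nm, std::vector<double>(n));
  std::vector<char> lok(nl), mok(nm);
  std::vector<uint64_t> lh(nl), mh(nm);
  for (int i = 0; i < nl; ++i) {
    NumericMatrix::Row row = lnc(i, _);
    std::vector<double> tmp(row.begin(), row.end());
    lok[i] = standardize(tmp.data(), n, lstd[i]) ? 1 : 0;
    lh[i] = fnv1a(CHAR(STRING_ELT(lnc_ids, i)));
  }
  for (int j = 0; j < nm; ++j) {
    NumericMatrix::Row row = mrna(j, _);
    std::vector<double> tmp(row.begin(), row.end());
    mok[j] = standardize(tmp.data(), n, mstd[j]) ? 1 : 0;
    mh[j] = fnv1a(CHAR(STRING_ELT(mrna_ids, j)));
  }

  IntegerVector li(npair), mj(npair), skip(npair);
  NumericVector r(npair), nexc(npair), nper(npair);
  uint64_t base = (uint64_t)seed;

  long k = 0;
  for (int i = 0; i < nl; ++i) {
    for (int j = 0; j < nm; ++j, ++k) {
      li[k] = i + 1;
      mj[k] = j + 1;
      if (!lok[i] || !mok[j]) {
        skip[k] = lok[i] ? 2 : 1;
        r[k] = NA_REAL;
        nexc[k] = NA_REAL;
        nper[k] = NA_REAL;
        continue;
      }
      double r_obs = dot(lstd[i], mstd[j], n);
      double stat_obs = absolute ? std::fabs(r_obs) : r_obs;
      long exceed, total;
      if (exhaustive) {
        exceed = exhaustive_count(lstd[i], mstd[j], n, absolute, stat_obs,
                                  total);
      } else {
        // mix the base seed with both probe-id hashes
        uint64_t mix = base ^ (lh[i] * 0x9E3779B97F4A7C15ULL) ^
                       (mh[j] + 0xD1B54A32D192ED03ULL);
        uint64_t sm = mix;
        exceed = monte_carlo_count(lstd[i], mstd[j], n, absolute, stat_obs,
                                   n_perms, splitmix64(sm));
        total = n_perms;
      }
      skip[k] = 0;
      r[k] = r_obs;
      nexc[k] = (double)exceed;
      nper[k] = (double)total;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["lnc_index"] = li, _["mrna_index"] = mj, _["r"] = r,
                      _["n_exceeding"] = nexc, _["n_perms"] = nper,
                      _["skip"] = skip);
}

// Batch exhaustive p-values for a list of (x, y) pairs stacked as matrix
// rows: pairs x (2*n). Used for calibration scans where thousands of exact
// small-n p-values are needed.
// [[Rcpp::export]]
List cpp_perm_exhaustive_batch(NumericMatrix xs, NumericMatrix ys,
                               bool absolute) {
  int npair = xs.nrow(), n = xs.ncol();
  if (ys.nrow() != npair || ys.ncol() != n) stop("dimension mismatch");
  NumericVector r(npair), nexc(npair), nper(npair);
  LogicalVector ok(npair);
  std::vector<double> xv(n), yv(n);
  for (int k = 0; k < npair; ++k) {
    NumericMatrix::Row xr = xs(k, _), yr = ys(k, _);
    std::vector<double> xt(xr.begin(), xr.end()), yt(yr.begin(), yr.end());
    bool okx = standardize(xt.data(), n, xv);
    bool oky = standardize(yt.data(), n, yv);
    if (!okx || !oky) {
      ok[k] = false;
      r[k] = NA_REAL;
      nexc[k] = NA_REAL;
      nper[k] = NA_REAL;
      continue;
    }
    double r_obs = dot(xv, yv, n);
    double stat_obs = absolute ? std::fabs(r_obs) : r_obs;
    long total;
    long exceed = exhaustive_count(xv, yv, n, absolute, stat_obs, total);
    ok[k] = true;
    r[k] = r_obs;
    nexc[k] = (double)exceed;
    nper[k] = (double)total;
    if ((k & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["ok"] = ok, _["r"] = r, _["n_exceeding"] = nexc,
                      _["n_perms"] = nper);
}
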