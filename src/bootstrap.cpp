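// Bootstrap / permutation significance of pairwise Pearson correlations.
//
// Each unordered cell pair gets its own deterministic RNG substream derived
// from (seed, pair index) by a splitmix64 counter hash, so results are
// reproducible across platforms and independent of R's global RNG, and the
// exact resampling indices of any pair can be regenerated for auditing
// (see boot_replicate_indices on the R side).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double unif01(uint64_t &state) {
  return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0); // 2^-53
}

// one uniform integer in [0, n)
static inline int unif_int(uint64_t &state, int n) {
  int k = (int)(unif01(state) * n);
  return k >= n ? n - 1 : k;
}

// Initial state for the substream of pair k (0-based, upper-triangle
// row-major order): hash the seed and counter through the splitmix64
// finaliser twice to decorrelate nearby counters.
static inline uint64_t pair_state(uint64_t seed, uint64_t k) {
  uint64_t s = seed ^ (0xD1B54A32D192ED03ULL * (k + 1));
  splitmix64(s);
  splitmix64(s);
  return s;
}

enum Method { PAIRS = 1, BLOCK = 2, PERM = 3 };

// Fill idx[0..n) with one replicate's (0-based) frame indices.
static void draw_replicate(uint64_t &state, int method, int n, int block_len,
                           std::vector<int> &idx) {
  if (method == PAIRS) {
    for (int f = 0; f < n; ++f) idx[f] = unif_int(state, n);
  } else if (method == BLOCK) {
    int pos = 0;
    int nstart = n - block_len + 1;
    while (pos < n) {
      int start = unif_int(state, nstart);
      int len = std::min(block_len, n - pos);
      for (int f = 0; f < len; ++f) idx[pos + f] = start + f;
      pos += len;
    }
  } else { // PERM: a permutation of 0..n-1 (Fisher-Yates)
    for (int f = 0; f < n; ++f) idx[f] = f;
    for (int i = n - 1; i > 0; --i) {
      int j = unif_int(state, i + 1);
      std::swap(idx[i], idx[j]);
    }
  }
}

struct CorAcc {
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
};

// Pearson r of (x[idx], y[idy]) over n frames; returns false if either
// resampled series is (numerically) constant.
static inline bool resampled_r(const double *x, const double *y,
                               const std::vector<int> &idx,
                               const std::vector<int> &idy, int n,
                               double &r_out) {
  CorAcc a;
  for (int f = 0; f < n; ++f) {
    double xv = x[idx[f]], yv = y[idy[f]];
    a.sx += xv; a.sy += yv;
    a.sxx += xv * xv; a.syy += yv * yv; a.sxy += xv * yv;
  }
  double dn = (double)n;
  double vx = dn * a.sxx - a.sx * a.sx;
  double vy = dn * a.syy - a.sy * a.sy;
  double eps_x = 1e-12 * std::max(1.0, dn * a.sxx);
  double eps_y = 1e-12 * std::max(1.0, dn * a.syy);
  if (vx <= eps_x || vy <= eps_y) return false;
  r_out = (dn * a.sxy - a.sx * a.sy) / std::sqrt(vx * vy);
  return true;
}

// [[Rcpp::export(name = ".boot_pvalues_cpp")]]
List boot_pvalues_cpp(NumericMatrix X, NumericMatrix Robs, int n_boot,
                      int method, int block_len, double seed) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (method == BLOCK && (block_len < 1 || block_len > n))
    stop("block_len must lie in [1, n_frames]");
  NumericMatrix P(p, p);
  IntegerMatrix discarded(p, p);
  LogicalMatrix failed(p, p);
  std::fill(P.begin(), P.end(), NA_REAL);
  const uint64_t useed = (uint64_t)(int64_t)seed;
  std::vector<int> idx(n), idy_buf(n);
  std::vector<int> ident(n);
  for (int f = 0; f < n; ++f) ident[f] = f;
  const int max_discard = n_boot / 10;
  uint64_t k = 0;
  for (int i = 0; i < p - 1; ++i) {
    Rcpp::checkUserInterrupt();
    const double *x = &X(0, i);
    for (int j = i + 1; j < p; ++j, ++k) {
      const double *y = &X(0, j);
      uint64_t state = pair_state(useed, k);
      const double robs = Robs(i, j);
      int count = 0, ndisc = 0, done = 0;
      bool fail = false;
      while (done < n_boot) {
        draw_replicate(state, method, n, block_len, idx);
        double r;
        bool ok;
        if (method == PERM) {
          // permute only the second member; the first keeps frame order
          ok = resampled_r(x, y, ident, idx, n, r);
        } else {
          ok = resampled_r(x, y, idx, idx, n, r);
        }
        if (!ok) {
          if (++ndisc > max_discard) { fail = true; break; }
          continue; // redraw from the same substream
        }
        if (method == PERM) {
          if (r >= robs) ++count;
        } else {
          if (r <= 0.0) ++count;
        }
        ++done;
      }
      discarded(i, j) = discarded(j, i) = ndisc;
      failed(i, j) = failed(j, i) = fail;
      if (!fail) {
        double pv = (1.0 + count) / (n_boot + 1.0);
        P(i, j) = P(j, i) = pv;
      }
    }
  }
  return List::create(_["P"] = P, _["discarded"] = discarded,
                      _["failed"] = failed);
}

// [[Rcpp::export(name = ".boot_indices_cpp")]]
IntegerMatrix boot_indices_cpp(double seed, double pair_index, int n_frames,
                               int n_boot, int method, int block_len) {
  if (method == BLOCK && (block_len < 1 || block_len > n_frames))
    stop("block_len must lie in [1, n_frames]");
  const uint64_t useed = (uint64_t)(int64_t)seed;
  uint64_t state = pair_state(useed, (uint64_t)pair_index);
  IntegerMatrix out(n_frames, n_boot);
  std::vector<int> idx(n_frames);
  for (int b = 0; b < n_boot; ++b) {
    draw_replicate(state, method, n_frames, block_len, idx);
    for (int f = 0; f < n_frames; ++f) out(f, b) = idx[f] + 1; // 1-based
  }
  return out;
}
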