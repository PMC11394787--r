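#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

// Local duplex pseudo-energy between a lncRNA (5'->3') and a target read
// 3'->5' (the caller passes the reversed target). Watson-Crick pairs and
// G.U wobbles are rewarded, mismatches and gaps penalized; the empty
// duplex scores 0, so the minimum is always <= 0.

static inline double pair_score(char a, char b, double wc, double wobble,
                                double mismatch) {
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
      (a == 'C' && b == 'G') || (a == 'G' && b == 'C')) return wc;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return wobble;
  return mismatch;
}

// [[Rcpp::export]]
double duplex_energy_cpp(std::string a, std::string b, double wc,
                         double wobble, double mismatch, double gap) {
  const int m = a.size(), n = b.size();
  std::vector<double> prev(n + 1, 0.0), cur(n + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      double e = prev[j - 1] + pair_score(a[i - 1], b[j - 1], wc, wobble, mismatch);
      e = std::min(e, prev[j] + gap);
      e = std::min(e, cur[j - 1] + gap);
      e = std::min(e, 0.0);
      cur[j] = e;
      if (e < best) best = e;
    }
    std::swap(prev, cur);
  }
  return best;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

// Seed-and-extend screen: find exact complementary k-mers between `a` and
// `b` (b already reversed by the caller), then run the local DP only on a
// window around each seed hit. Returns 0 when no seed exists. Used for
// batch screening of co-expressed pairs; the full DP above is the exact
// reference.
// [[Rcpp::export]]
double duplex_energy_seeded_cpp(std::string a, std::string b, int seed_len,
                                int window, double wc, double wobble,
                                double mismatch, double gap) {
  const int m = a.size(), n = b.size();
  if (m < seed_len || n < seed_len) return 0.0;
  const uint64_t mask = (seed_len >= 32) ? ~0ULL
                                         : ((1ULL << (2 * seed_len)) - 1);
  // hash complementary k-mers of b: complement each base so equality with
  // an a k-mer hash means elementwise Watson-Crick pairing
  std::unordered_multimap<uint64_t, int> index;
  uint64_t h = 0;
  int run = 0;
  for (int j = 0; j < n; ++j) {
    int c = base_code(b[j]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)(3 - c)) & mask;  // complemented base
    if (++run >= seed_len) index.emplace(h, j - seed_len + 1);
  }
  double best = 0.0;
  h = 0; run = 0;
  std::vector<double> prev, cur;
  for (int i = 0; i < m; ++i) {
    int c = base_code(a[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run < seed_len) continue;
    auto range = index.equal_range(h);
    for (auto it = range.first; it != range.second; ++it) {
      const int i0 = std::max(0, i - seed_len + 1 - window);
      const int i1 = std::min(m, i + 1 + window);
      const int j0 = std::max(0, it->second - window);
      const int j1 = std::min(n, it->second + seed_len + window);
      const int nn = j1 - j0;
      prev.assign(nn + 1, 0.0);
      cur.assign(nn + 1, 0.0);
      for (int ii = i0 + 1; ii <= i1; ++ii) {
        cur[0] = 0.0;
        for (int jj = 1; jj <= nn; ++jj) {
          double e = prev[jj - 1] +
            pair_score(a[ii - 1], b[j0 + jj - 1], wc, wobble, mismatch);
          e = std::min(e, prev[jj] + gap);
          e = std::min(e, cur[jj - 1] + gap);
          e = std::min(e, 0.0);
          cur[jj] = e;
          if (e < best) best = e;
        }
        std::swap(prev, cur);
      }
    }
  }
  return best;
}
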