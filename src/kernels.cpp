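#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Internal representation: groups as 1-based integer member vectors,
// sample_of_group 1-based. All RNG draws go through R's generator so that
// set.seed() in R gives reproducible chains.

static inline int runif_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static bool contains(const std::vector<int>& g, int v) {
  for (int x : g) if (x == v) return true;
  return false;
}

// One checkerboard swap: pick a sample with >=2 groups, two groups g,h in
// it, i in g not in h, j in h not in g (i != j); exchange them. Up to
// max_tries proposals; returns false (no-op) if none succeeds.
static bool try_flip(std::vector<std::vector<int>>& groups,
                     const std::vector<std::vector<int>>& by_sample,
                     const std::vector<int>& swappable, int max_tries) {
  if (swappable.empty()) return false;
  for (int t = 0; t < max_tries; ++t) {
    int s = swappable[runif_int((int)swappable.size())];
    const std::vector<int>& gl = by_sample[s];
    int a = runif_int((int)gl.size());
    int b = runif_int((int)gl.size() - 1);
    if (b >= a) ++b;
    std::vector<int>& g = groups[gl[a]];
    std::vector<int>& h = groups[gl[b]];
    int pi = runif_int((int)g.size());
    int pj = runif_int((int)h.size());
    int i = g[pi], j = h[pj];
    if (i == j) continue;
    if (contains(h, i) || contains(g, j)) continue;
    g[pi] = j;
    h[pj] = i;
    return true;
  }
  return false;
}

static void build_structures(const List& groups_in, const IntegerVector& sample_of_group,
                             int n_samples,
                             std::vector<std::vector<int>>& groups,
                             std::vector<std::vector<int>>& by_sample,
                             std::vector<int>& swappable) {
  int K = groups_in.size();
  groups.resize(K);
  by_sample.assign(n_samples, {});
  for (int k = 0; k < K; ++k) {
    IntegerVector g = groups_in[k];
    groups[k] = as<std::vector<int>>(g);
    by_sample[sample_of_group[k] - 1].push_back(k);
  }
  swappable.clear();
  for (int s = 0; s < n_samples; ++s)
    if (by_sample[s].size() >= 2) swappable.push_back(s);
}

// [[Rcpp::export]]
List cpp_permute_groups(List groups_in, IntegerVector sample_of_group,
                        int n_samples, int n_flips, int max_tries) {
  std::vector<std::vector<int>> groups, by_sample;
  std::vector<int> swappable;
  build_structures(groups_in, sample_of_group, n_samples, groups, by_sample,
                   swappable);
  int done = 0;
  for (int f = 0; f < n_flips; ++f)
    if (try_flip(groups, by_sample, swappable, max_tries)) ++done;
  List out(groups.size());
  for (size_t k = 0; k < groups.size(); ++k) out[k] = wrap(groups[k]);
  return List::create(_["groups"] = out, _["n_swapped"] = done);
}

// Number of sampling periods in which each (unordered) dyad co-occurred in
// at least one group of the period.
static void x_matrix_fill(const std::vector<std::vector<int>>& groups,
                          const std::vector<std::vector<int>>& by_sample,
                          int n_ind, std::vector<int>& x) {
  std::fill(x.begin(), x.end(), 0);
  std::vector<uint8_t> pair_seen((size_t)n_ind * n_ind, 0);
  std::vector<std::pair<int,int>> marked;
  for (const auto& gl : by_sample) {
    marked.clear();
    for (int k : gl) {
      const std::vector<int>& g = groups[k];
      for (size_t a = 0; a + 1 < g.size(); ++a)
        for (size_t b = a + 1; b < g.size(); ++b) {
          int i = g[a] - 1, j = g[b] - 1;
          if (i > j) std::swap(i, j);
          size_t pos = (size_t)i * n_ind + j;
          if (!pair_seen[pos]) {
            pair_seen[pos] = 1;
            marked.push_back({i, j});
          }
        }
    }
    for (auto& p : marked) {
      x[(size_t)p.first * n_ind + p.second] += 1;
      pair_seen[(size_t)p.first * n_ind + p.second] = 0;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_x_matrix(List groups_in, IntegerVector sample_of_group,
                           int n_ind, int n_samples) {
  std::vector<std::vector<int>> groups, by_sample;
  std::vector<int> swappable;
  build_structures(groups_in, sample_of_group, n_samples, groups, by_sample,
                   swappable);
  std::vector<int> x((size_t)n_ind * n_ind, 0);
  x_matrix_fill(groups, by_sample, n_ind, x);
  IntegerMatrix out(n_ind, n_ind);
  for (int i = 0; i < n_ind; ++i)
    for (int j = i + 1; j < n_ind; ++j) {
      out(i, j) = x[(size_t)i * n_ind + j];
      out(j, i) = out(i, j);
    }
  return out;
}

// CV (sample SD / mean) of the off-diagonal dyadic index values.
// index 0 = HWI, 1 = HWIG. n_seen = per-individual period counts (fixed
// under flips). Returns NaN when the mean is 0.
static double index_cv(const std::vector<int>& x, const IntegerVector& n_seen,
                       int n_ind, int hwig, std::vector<double>& hwi_buf) {
  // HWI_ab = x / (x + y_ab + (y_a+y_b)/2) = 2x/(n_a+n_b)
  for (int i = 0; i < n_ind; ++i)
    for (int j = i + 1; j < n_ind; ++j) {
      double denom = (double)n_seen[i] + n_seen[j];
      double v = denom > 0 ? 2.0 * x[(size_t)i * n_ind + j] / denom : 0.0;
      hwi_buf[(size_t)i * n_ind + j] = v;
      hwi_buf[(size_t)j * n_ind + i] = v;
    }
  double s = 0.0, ss = 0.0;
  long n_dyads = (long)n_ind * (n_ind - 1) / 2;
  if (!hwig) {
    for (int i = 0; i < n_ind; ++i)
      for (int j = i + 1; j < n_ind; ++j) {
        double v = hwi_buf[(size_t)i * n_ind + j];
        s += v; ss += v * v;
      }
  } else {
    std::vector<double> rs(n_ind, 0.0);
    double tot = 0.0;
    for (int i = 0; i < n_ind; ++i) {
      double r = 0.0;
      for (int j = 0; j < n_ind; ++j)
        if (j != i) r += hwi_buf[(size_t)i * n_ind + j];
      rs[i] = r; tot += r;
    }
    for (int i = 0; i < n_ind; ++i)
      for (int j = i + 1; j < n_ind; ++j) {
        double v = 0.0;
        if (rs[i] > 0 && rs[j] > 0)
          v = hwi_buf[(size_t)i * n_ind + j] * tot / (rs[i] * rs[j]);
        s += v; ss += v * v;
      }
  }
  double mean = s / n_dyads;
  if (mean <= 0) return R_NaN;
  double var = (ss - s * s / n_dyads) / (n_dyads - 1);
  if (var < 0) var = 0;
  return std::sqrt(var) / mean;
}

// Sequential permutation chain: starting from the observed grouping, apply
// `flips` checkerboard swaps, recompute the index matrix, record its CV;
// repeat n_perm times. Chain state carries over between permutations.
// [[Rcpp::export]]
List cpp_cv_chain(List groups_in, IntegerVector sample_of_group,
                  IntegerVector n_seen, int n_ind, int n_samples,
                  int n_perm, int flips, int burn_in, int max_tries,
                  int hwig) {
  std::vector<std::vector<int>> groups, by_sample;
  std::vector<int> swappable;
  build_structures(groups_in, sample_of_group, n_samples, groups, by_sample,
                   swappable);
  std::vector<int> x((size_t)n_ind * n_ind, 0);
  std::vector<double> hwi_buf((size_t)n_ind * n_ind, 0.0);

  x_matrix_fill(groups, by_sample, n_ind, x);
  double observed = index_cv(x, n_seen, n_ind, hwig, hwi_buf);

  long total_swaps = 0;
  for (int f = 0; f < burn_in; ++f)
    if (try_flip(groups, by_sample, swappable, max_tries)) ++total_swaps;

  NumericVector null_cvs(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    for (int f = 0; f < flips; ++f)
      if (try_flip(groups, by_sample, swappable, max_tries)) ++total_swaps;
    x_matrix_fill(groups, by_sample, n_ind, x);
    null_cvs[p] = index_cv(x, n_seen, n_ind, hwig, hwi_buf);
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["observed_cv"] = observed,
                      _["null_cvs"] = null_cvs,
                      _["n_swapped"] = (double)total_swaps,
                      _["degenerate"] = swappable.empty());
}

// Standardized lagged association rate tallies with per-block bookkeeping
// for the delete-one-block jackknife.
//
// adj: per period, per subset member, bitset of subset associates.
// present: per period, bitset of subset members identified in the period.
// For every ordered period pair (t1 < t2), lag = time[t2]-time[t1] binned by
// `edges`; for each i associated at t1:
//   num += popcount(adj1[i] & adj2[i])         (ordered pairs (i, j))
//   den += deg1[i] * deg2[i]   if i present at t2
// Tallies are accumulated per (bin, block(t1), block(t2)).
// [[Rcpp::export]]
List cpp_slar_tallies(List period_members, List period_groups,
                      NumericVector times, int n_sub,
                      NumericVector edges, IntegerVector block_of_period) {
  int P = period_members.size();
  int nb = edges.size() - 1;
  int B = 0;
  for (int p = 0; p < P; ++p) B = std::max(B, block_of_period[p]);
  int W = (n_sub + 63) / 64;

  // build per-period adjacency bitsets and degrees
  std::vector<std::vector<uint64_t>> adj(P);
  std::vector<std::vector<int>> deg(P), members(P);
  for (int p = 0; p < P; ++p) {
    adj[p].assign((size_t)n_sub * W, 0);
    deg[p].assign(n_sub, 0);
    IntegerVector mem = period_members[p];
    members[p] = as<std::vector<int>>(mem);
    List gl = period_groups[p];
    for (int k = 0; k < gl.size(); ++k) {
      IntegerVector g = gl[k];
      for (int a = 0; a < g.size(); ++a)
        for (int b = 0; b < g.size(); ++b) {
          if (a == b) continue;
          int i = g[a] - 1, j = g[b] - 1;
          size_t pos = (size_t)i * W + (j >> 6);
          uint64_t bit = 1ULL << (j & 63);
          if (!(adj[p][pos] & bit)) {
            adj[p][pos] |= bit;
            deg[p][i] += 1;
          }
        }
    }
  }
  std::vector<std::vector<uint8_t>> present(P);
  for (int p = 0; p < P; ++p) {
    present[p].assign(n_sub, 0);
    for (int i : members[p]) present[p][i - 1] = 1;
  }

  std::vector<double> num((size_t)nb * B * B, 0.0), den((size_t)nb * B * B, 0.0);
  for (int t1 = 0; t1 < P; ++t1) {
    for (int t2 = t1 + 1; t2 < P; ++t2) {
      double lag = times[t2] - times[t1];
      if (lag < edges[0] || lag > edges[nb]) continue;
      int bin = (int)(std::upper_bound(edges.begin(), edges.end(), lag) -
                      edges.begin()) - 1;
      if (bin >= nb) bin = nb - 1;
      if (bin < 0) bin = 0;
      // column-major layout matching R's array(dim = c(nb, B, B))
      size_t cell = (size_t)bin +
                    (size_t)nb * (block_of_period[t1] - 1) +
                    (size_t)nb * B * (block_of_period[t2] - 1);
      double nsum = 0.0, dsum = 0.0;
      for (int i1 : members[t1]) {
        int i = i1 - 1;
        int d1 = deg[t1][i];
        if (d1 == 0) continue;
        if (!present[t2][i]) continue;
        const uint64_t* a1 = &adj[t1][(size_t)i * W];
        const uint64_t* a2 = &adj[t2][(size_t)i * W];
        int ov = 0; // ordered pairs (i, j) associated at both periods
        for (int w = 0; w < W; ++w)
          ov += __builtin_popcountll(a1[w] & a2[w]);
        nsum += ov;
        dsum += (double)d1 * deg[t2][i];
      }
      num[cell] += nsum;
      den[cell] += dsum;
    }
    if (t1 % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["num"] = NumericVector(num.begin(), num.end()),
                      _["den"] = NumericVector(den.begin(), den.end()),
                      _["n_bins"] = nb, _["n_blocks"] = B);
}
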