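#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy Louvain maximisation of Tr[H^T B H] = sum_{i,j : l_i = l_j} B_ij
// for a dense symmetric matrix B (a generalized modularity / stability
// matrix).  Node-moving sweeps to a local optimum, then community
// aggregation, repeated until no gain.  Visit order is shuffled by a
// seeded mt19937 so identical seeds give identical partitions.  Moves
// require a strict gain above EPS (B is pre-scaled to max|B| = 1 by the
// caller-facing wrapper); ties keep the incumbent, and among improving
// communities the lowest id wins at equal weight.

static const double EPS_GAIN = 1e-10;
static const int MAX_PASSES = 100;

static bool move_phase(const std::vector<double>& B, int n,
                       std::vector<int>& lab, std::mt19937& rng) {
  bool any_move = false;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> w(n);
  bool improved = true;
  int pass = 0;
  while (improved && pass < MAX_PASSES) {
    improved = false;
    ++pass;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      const int i = order[oi];
      std::fill(w.begin(), w.end(), 0.0);
      const double* row = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j)
        if (j != i) w[lab[j]] += row[j];
      const int cur = lab[i];
      int best = cur;
      double bestw = w[cur];
      for (int c = 0; c < n; ++c) {
        if (w[c] > bestw + EPS_GAIN) {
          best = c;
          bestw = w[c];
        }
      }
      if (best != cur) {
        lab[i] = best;
        improved = true;
        any_move = true;
      }
    }
  }
  return any_move;
}

static int relabel_contiguous(std::vector<int>& lab) {
  std::vector<int> map(lab.size(), -1);
  int next = 0;
  for (size_t i = 0; i < lab.size(); ++i) {
    if (map[lab[i]] < 0) map[lab[i]] = next++;
    lab[i] = map[lab[i]];
  }
  return next;
}

// [[Rcpp::export]]
IntegerVector louvain_dense_impl(NumericMatrix B, int seed) {
  const int n0 = B.nrow();
  std::mt19937 rng((unsigned)seed);

  std::vector<double> curB((size_t)n0 * n0);
  for (int i = 0; i < n0; ++i)
    for (int j = 0; j < n0; ++j) curB[(size_t)i * n0 + j] = B(i, j);
  int n = n0;

  std::vector<int> assign(n0);  // original node -> current super-node
  for (int i = 0; i < n0; ++i) assign[i] = i;

  while (true) {
    std::vector<int> lab(n);
    for (int i = 0; i < n; ++i) lab[i] = i;
    const bool moved = move_phase(curB, n, lab, rng);
    const int nc = relabel_contiguous(lab);
    for (int i = 0; i < n0; ++i) assign[i] = lab[assign[i]];
    if (!moved || nc == n) break;
    // aggregate: B'[a][b] = sum of B over node pairs with labels (a, b)
    std::vector<double> aggB((size_t)nc * nc, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        aggB[(size_t)lab[i] * nc + lab[j]] += curB[(size_t)i * n + j];
    curB.swap(aggB);
    n = nc;
  }

  // canonical labels: order of first appearance
  std::vector<int> map(n0, -1);
  int next = 0;
  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) {
    if (map[assign[i]] < 0) map[assign[i]] = next++;
    out[i] = map[assign[i]] + 1;  // 1-based for R
  }
  return out;
}

// Tr[H^T B H]: sum of B over same-community pairs (diagonal included).
// [[Rcpp::export]]
double trace_block_sum(NumericMatrix B, IntegerVector lab) {
  const int n = B.nrow();
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (lab[i] == lab[j]) s += B(i, j);
  return s;
}
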