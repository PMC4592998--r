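#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Kingman coalescent simulation kernels used for null distributions:
// genealogies are simulated tip-down (at k lineages the waiting time is
// exponential with rate k(k-1)/2, a uniformly chosen pair merges) and a
// fixed number S of infinite-sites mutations is placed on branches with
// probability proportional to branch length (Hudson-style conditioning on
// S). Only the derived-count spectrum is needed for the statistics, so no
// haplotype matrices are built. R's RNG is used throughout, so results are
// reproducible under set.seed().

namespace {

struct SpectrumSim {
  int n;
  std::vector<double> len;   // branch length above each node (root = 0)
  std::vector<int> size;     // tips subtended by each node
  std::vector<double> cum;   // cumulative branch lengths for placement
  std::vector<int> active;

  explicit SpectrumSim(int n_) : n(n_) {
    int m = 2 * n - 1;
    len.resize(m);
    size.resize(m);
    cum.resize(m - 1);
    active.resize(n);
  }

  void simulate_tree() {
    int m = 2 * n - 1;
    std::fill(len.begin(), len.end(), 0.0);
    for (int v = 0; v < m; ++v) size[v] = 1;
    for (int i = 0; i < n; ++i) active[i] = i;
    int next = n;
    for (int k = n; k > 1; --k) {
      double t = exp_rand() / (k * (k - 1) / 2.0);
      for (int i = 0; i < k; ++i) len[active[i]] += t;
      int i = (int)(unif_rand() * k);
      if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1));
      if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = active[i], b = active[j];
      size[next] = size[a] + size[b];
      int lo = std::min(i, j), hi = std::max(i, j);
      active[lo] = next;
      active[hi] = active[k - 1];
      ++next;
    }
    // cumulative lengths over non-root nodes (root = index 2n-2, len 0)
    double tot = 0.0;
    for (int v = 0; v < m - 1; ++v) {
      tot += len[v];
      cum[v] = tot;
    }
  }

  // derived count of one mutation dropped uniformly on total length
  int drop_one() const {
    double u = unif_rand() * cum.back();
    int lo = 0, hi = (int)cum.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return size[lo];
  }
};

struct StatConsts {
  double a1, a2, e1, e2;     // Tajima
  double an, ud, vd;         // Fu & Li (polarized)
  int n;
};

StatConsts make_consts(int n) {
  StatConsts k;
  k.n = n;
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i <= n - 1; ++i) {
    a1 += 1.0 / i;
    a2 += 1.0 / ((double)i * i);
  }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * (double)n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  k.a1 = a1;
  k.a2 = a2;
  k.e1 = c1 / a1;
  k.e2 = c2 / (a1 * a1 + a2);
  double cn = (n > 2)
    ? 2.0 * (n * a1 - 2.0 * (n - 1.0)) / ((n - 1.0) * (n - 2.0)) : 1.0;
  double vd = 1.0 + a1 * a1 / (a2 + a1 * a1) * (cn - (n + 1.0) / (n - 1.0));
  k.an = a1;
  k.vd = vd;
  k.ud = a1 - 1.0 - vd;
  return k;
}

double tajima_d_from_xi(const std::vector<int>& xi, int S,
                        const StatConsts& k) {
  int n = k.n;
  double pi = 0.0;
  for (int i = 1; i <= n - 1; ++i) {
    pi += xi[i] * 2.0 * i * (n - i);
  }
  pi /= n * (n - 1.0);
  return (pi - S / k.a1) / std::sqrt(k.e1 * S + k.e2 * S * (S - 1.0));
}

} // namespace

// Simulate the joint null distribution of (Tajima's D, Fu & Li's D,
// Fay & Wu's H) for samples of size n conditioned on S segregating sites.
// Returns a reps x 3 matrix.
// [[Rcpp::export]]
NumericMatrix cpp_null_stats(int n, int S, int reps) {
  if (n < 2) stop("n must be >= 2");
  if (S < 1) stop("S must be >= 1");
  StatConsts k = make_consts(n);
  SpectrumSim sim(n);
  NumericMatrix out(reps, 3);
  std::vector<int> xi(n);
  for (int r = 0; r < reps; ++r) {
    sim.simulate_tree();
    std::fill(xi.begin(), xi.end(), 0);
    for (int s = 0; s < S; ++s) xi[sim.drop_one()]++;
    double pi = 0.0, th = 0.0;
    for (int i = 1; i <= n - 1; ++i) {
      pi += xi[i] * 2.0 * i * (n - i);
      th += xi[i] * 2.0 * (double)i * i;
    }
    pi /= n * (n - 1.0);
    th /= n * (n - 1.0);
    out(r, 0) = tajima_d_from_xi(xi, S, k);
    out(r, 1) = (S - k.an * xi[1]) / std::sqrt(k.ud * S + k.vd * S * S);
    out(r, 2) = pi - th;
  }
  colnames(out) = CharacterVector::create("tajima_d", "fu_li_d",
                                          "fay_wu_h");
  return out;
}

// Null distribution of the difference in Tajima's D between two mutation
// classes. With shared = true (the default reading of the heterogeneity
// test), both classes are dropped on one genealogy per replicate and the
// class labels are randomly assigned; with shared = false each class gets
// its own genealogy. Returns delta = D_class2 - D_class1 per replicate.
// [[Rcpp::export]]
NumericVector cpp_delta_tajima(int n, int S1, int S2, int reps,
                               bool shared) {
  if (n < 2) stop("n must be >= 2");
  if (S1 < 1 || S2 < 1) stop("both classes need S >= 1");
  StatConsts k = make_consts(n);
  SpectrumSim sim(n);
  NumericVector out(reps);
  std::vector<int> xi1(n), xi2(n);
  for (int r = 0; r < reps; ++r) {
    sim.simulate_tree();
    std::fill(xi1.begin(), xi1.end(), 0);
    std::fill(xi2.begin(), xi2.end(), 0);
    // placements are i.i.d. given the tree, so dropping S1 then S2 on the
    // shared genealogy is equivalent to random labelling of S1+S2 drops
    for (int s = 0; s < S1; ++s) xi1[sim.drop_one()]++;
    if (!shared) sim.simulate_tree();
    for (int s = 0; s < S2; ++s) xi2[sim.drop_one()]++;
    out[r] = tajima_d_from_xi(xi2, S2, k) - tajima_d_from_xi(xi1, S1, k);
  }
  return out;
}
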