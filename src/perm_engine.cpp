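#include <Rcpp.h>
using namespace Rcpp;

// Internal engine for cluster-based max-statistic permutation inference.
// Voxel t statistics, connected components over a precomputed neighbor
// list, cluster measures (size / maximum / mass) and per-permutation
// maxima are computed here; the user-facing clustering path and all test
// oracles live in R.

// t statistics for one permutation.
// X: nVox x nObs. Unpaired: assign = 0/1 group labels. Paired: X holds
// per-pair differences and assign = +1/-1 sign flips.
static void tstats(const NumericMatrix& X, const IntegerVector& assign,
                   bool paired, std::vector<double>& t) {
  const int nv = X.nrow(), n = X.ncol();
  if (paired) {
    for (int v = 0; v < nv; ++v) {
      double s = 0, ss = 0;
      for (int i = 0; i < n; ++i) {
        double x = X(v, i) * assign[i];
        s += x; ss += x * x;
      }
      double m = s / n;
      double var = (ss - n * m * m) / (n - 1);
      t[v] = m / std::sqrt(var / n);
    }
  } else {
    int n1 = 0;
    for (int i = 0; i < n; ++i) n1 += assign[i];
    const int n2 = n - n1;
    for (int v = 0; v < nv; ++v) {
      double s1 = 0, s2 = 0, ss1 = 0, ss2 = 0;
      for (int i = 0; i < n; ++i) {
        double x = X(v, i);
        if (assign[i]) { s1 += x; ss1 += x * x; }
        else { s2 += x; ss2 += x * x; }
      }
      double m1 = s1 / n1, m2 = s2 / n2;
      double sp2 = ((ss1 - n1 * m1 * m1) + (ss2 - n2 * m2 * m2)) /
                   (n1 + n2 - 2);
      t[v] = (m1 - m2) / std::sqrt(sp2 * (1.0 / n1 + 1.0 / n2));
    }
  }
}

// Flood-fill clusters of active voxels (same excursion sign joins) and
// write the chosen measure of each cluster into out[voxel] (signed mass,
// positive size/maximum); inactive voxels get 0. Returns max |measure|.
// tail: 0 = two-sided, 1 = positive, 2 = negative. measure: 0 size,
// 1 maximum, 2 mass.
static double clusterFill(const std::vector<double>& t, double tthresh,
                          int tail, int measure, const List& nbr,
                          std::vector<double>* out) {
  const int nv = t.size();
  std::vector<signed char> state(nv, 0); // 0 inactive, 1 active, 2 visited
  for (int v = 0; v < nv; ++v) {
    bool act = false;
    if (tail == 0) act = std::fabs(t[v]) > tthresh;
    else if (tail == 1) act = t[v] > tthresh;
    else act = t[v] < -tthresh;
    state[v] = act ? 1 : 0;
  }
  if (out) std::fill(out->begin(), out->end(), 0.0);
  double best = 0;
  std::vector<int> stack, members;
  for (int v0 = 0; v0 < nv; ++v0) {
    if (state[v0] != 1) continue;
    const bool pos = t[v0] > 0;
    stack.clear(); members.clear();
    stack.push_back(v0); state[v0] = 2;
    double size = 0, mx = 0, mass = 0;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      members.push_back(v);
      size += 1; mass += t[v];
      if (std::fabs(t[v]) > mx) mx = std::fabs(t[v]);
      IntegerVector nb = nbr[v];
      for (int k = 0; k < nb.size(); ++k) {
        int w = nb[k] - 1;
        if (state[w] == 1 && ((t[w] > 0) == pos)) {
          state[w] = 2;
          stack.push_back(w);
        }
      }
    }
    double val = measure == 0 ? size : (measure == 1 ? mx : mass);
    if (out)
      for (size_t k = 0; k < members.size(); ++k) (*out)[members[k]] = val;
    if (std::fabs(val) > best) best = std::fabs(val);
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_cluster_map(NumericVector t, double tthresh, int tail,
                              int measure, List nbr) {
  std::vector<double> tv(t.begin(), t.end());
  std::vector<double> out(tv.size(), 0.0);
  clusterFill(tv, tthresh, tail, measure, nbr, &out);
  return wrap(out);
}

// Max cluster measure per permutation (single threshold).
// [[Rcpp::export]]
NumericVector cpp_null_max(NumericMatrix X, IntegerMatrix assign,
                           bool paired, double tthresh, int tail,
                           int measure, List nbr) {
  const int nPerm = assign.nrow();
  const int nv = X.nrow();
  NumericVector out(nPerm);
  std::vector<double> t(nv);
  for (int p = 0; p < nPerm; ++p) {
    IntegerVector a = assign(p, _);
    tstats(X, a, paired, t);
    out[p] = clusterFill(t, tthresh, tail, measure, nbr, nullptr);
  }
  return out;
}

// Max |threshold-averaged cluster-value| per permutation: for each
// permutation, cluster-value maps are computed at every threshold in the
// grid, averaged voxel-wise, and the maximum absolute averaged value is
// returned.
// [[Rcpp::export]]
NumericVector cpp_uce_null_max(NumericMatrix X, IntegerMatrix assign,
                               bool paired, NumericVector tthresh, int tail,
                               int measure, List nbr) {
  const int nPerm = assign.nrow();
  const int nv = X.nrow();
  const int ng = tthresh.size();
  NumericVector out(nPerm);
  std::vector<double> t(nv), acc(nv), map(nv);
  for (int p = 0; p < nPerm; ++p) {
    IntegerVector a = assign(p, _);
    tstats(X, a, paired, t);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int g = 0; g < ng; ++g) {
      clusterFill(t, tthresh[g], tail, measure, nbr, &map);
      for (int v = 0; v < nv; ++v) acc[v] += map[v];
    }
    double best = 0;
    for (int v = 0; v < nv; ++v) {
      double m = std::fabs(acc[v]) / ng;
      if (m > best) best = m;
    }
    out[p] = best;
  }
  return out;
}

// Voxel t statistics for the observed labeling (used by statMap).
// [[Rcpp::export]]
NumericVector cpp_tstats(NumericMatrix X, IntegerVector assign,
                         bool paired) {
  std::vector<double> t(X.nrow());
  tstats(X, assign, paired, t);
  return wrap(t);
}
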