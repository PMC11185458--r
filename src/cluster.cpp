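// Spatio-temporal cluster permutation core.
//
// Points are (channel, sample) pairs flattened channel-fastest:
//   point = s * n_ch + c.
// Two points are adjacent iff same channel & |ds| == 1, or same sample &
// channels are neighbours.  Clusters are sign-homogeneous connected
// components of supra-threshold |t| values; cluster mass is
// sum(|t|^eta) over members.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

namespace {

// paired t statistic per point for sign-flipped differences.
// D: n_subj x n_points (column-major), SS: per-point sum of squares
// (invariant under sign flips), s: +/-1 per subject.
inline void tmap_signed(const NumericMatrix &D, const std::vector<double> &SS,
                        const int *s, std::vector<double> &t) {
  int n = D.nrow(), p = D.ncol();
  for (int j = 0; j < p; ++j) {
    const double *col = &D[(R_xlen_t)j * n];
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += s[i] * col[i];
    double mean = m / n;
    double var = (SS[j] - n * mean * mean) / (n - 1);
    double se = std::sqrt(var / n);
    t[j] = (se > 0) ? mean / se : (mean == 0 ? 0.0 : (mean > 0 ? R_PosInf : R_NegInf));
  }
}

// label sign-homogeneous supra-threshold clusters; returns number of
// clusters, fills labels (0 = subthreshold) and masses (|t|^eta sums)
int find_clusters(const std::vector<double> &t, double tcrit, double eta,
                  int n_ch, int n_s, const std::vector<std::vector<int>> &adj,
                  std::vector<int> &labels, std::vector<double> &masses) {
  int np = n_ch * n_s;
  labels.assign(np, 0);
  masses.clear();
  int next = 0;
  std::queue<int> q;
  for (int start = 0; start < np; ++start) {
    if (labels[start] != 0 || !(std::fabs(t[start]) > tcrit)) continue;
    ++next;
    bool pos = t[start] > 0;
    double mass = 0.0;
    labels[start] = next;
    q.push(start);
    while (!q.empty()) {
      int p0 = q.front(); q.pop();
      mass += std::pow(std::fabs(t[p0]), eta);
      int c = p0 % n_ch, s = p0 / n_ch;
      // temporal neighbours
      for (int ds = -1; ds <= 1; ds += 2) {
        int s2 = s + ds;
        if (s2 < 0 || s2 >= n_s) continue;
        int p2 = s2 * n_ch + c;
        if (labels[p2] == 0 && std::fabs(t[p2]) > tcrit && (t[p2] > 0) == pos) {
          labels[p2] = next; q.push(p2);
        }
      }
      // spatial neighbours
      for (int c2 : adj[c]) {
        int p2 = s * n_ch + c2;
        if (labels[p2] == 0 && std::fabs(t[p2]) > tcrit && (t[p2] > 0) == pos) {
          labels[p2] = next; q.push(p2);
        }
      }
    }
    masses.push_back(mass);
  }
  return next;
}

std::vector<std::vector<int>> adj_to_vec(const List &chan_adj) {
  int n_ch = chan_adj.size();
  std::vector<std::vector<int>> adj(n_ch);
  for (int c = 0; c < n_ch; ++c) {
    IntegerVector v = chan_adj[c];  // 0-based neighbour indices
    adj[c] = std::vector<int>(v.begin(), v.end());
  }
  return adj;
}

} // namespace

// Observed clusters plus permutation null of the maximum cluster mass.
// D: n_subj x (n_ch * n_s) paired differences (points channel-fastest);
// signs: n_perm x n_subj matrix of +/-1.
// [[Rcpp::export(name = ".cluster_perm")]]
List cluster_perm(NumericMatrix D, int n_ch, int n_s, List chan_adj,
                  double tcrit, double eta, IntegerMatrix signs) {
  int n_subj = D.nrow(), np = D.ncol();
  if (np != n_ch * n_s) stop("D has wrong number of columns");
  std::vector<std::vector<int>> adj = adj_to_vec(chan_adj);
  std::vector<double> SS(np);
  for (int j = 0; j < np; ++j) {
    const double *col = &D[(R_xlen_t)j * n_subj];
    double ss = 0.0;
    for (int i = 0; i < n_subj; ++i) ss += col[i] * col[i];
    SS[j] = ss;
  }
  std::vector<double> t(np);
  std::vector<int> ones(n_subj, 1), labels;
  std::vector<double> masses;
  tmap_signed(D, SS, ones.data(), t);
  find_clusters(t, tcrit, eta, n_ch, n_s, adj, labels, masses);
  NumericVector tmap(np);
  IntegerVector lab(np);
  for (int j = 0; j < np; ++j) { tmap[j] = t[j]; lab[j] = labels[j]; }

  int n_perm = signs.nrow();
  NumericVector null_max(n_perm);
  std::vector<int> srow(n_subj);
  std::vector<int> plab;
  std::vector<double> pmass, pt(np);
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < n_subj; ++i) srow[i] = signs(p, i);
    tmap_signed(D, SS, srow.data(), pt);
    find_clusters(pt, tcrit, eta, n_ch, n_s, adj, plab, pmass);
    double mx = 0.0;
    for (double m : pmass) if (m > mx) mx = m;
    null_max[p] = mx;
  }
  return List::create(_["tmap"] = tmap, _["labels"] = lab,
                      _["masses"] = NumericVector(masses.begin(), masses.end()),
                      _["null_max"] = null_max);
}
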