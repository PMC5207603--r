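#include "core.h"

using namespace Rcpp;

namespace ffl {

namespace {
int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}
}  // namespace

std::vector<int> group_labels(const std::vector<double>& x,
                              const std::vector<double>& y, double d) {
  int n = (int)x.size();
  double d2 = d * d;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy < d2) {
        int ri = uf_find(parent, i), rj = uf_find(parent, j);
        if (ri != rj) parent[ri] = rj;
      }
    }
  }
  std::vector<int> label(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    if (label[r] < 0) label[r] = next++;
    label[i] = label[r];
  }
  return label;
}

}  // namespace ffl

// [[Rcpp::export]]
IntegerVector cpp_group_labels(NumericVector x, NumericVector y, double d) {
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  std::vector<int> lab = ffl::group_labels(xs, ys, d);
  IntegerVector out(lab.size());
  for (size_t i = 0; i < lab.size(); ++i) out[i] = lab[i] + 1;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_neighbour_counts(NumericVector x, NumericVector y, double r) {
  int n = x.size();
  double r2 = r * r;
  IntegerVector cnt(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy < r2) {
        cnt[i]++;
        cnt[j]++;
      }
    }
  }
  return cnt;
}

// Weighted draws of an interaction partner: conspecifics within `perception`
// of focal agent i (1-based) with weight 1 / max(distance, eps); 0 if none.
// [[Rcpp::export]]
IntegerVector cpp_sample_partner(int i, NumericVector x, NumericVector y,
                                 double perception, double eps, int ndraws) {
  int n = x.size(), focal = i - 1;
  double p2 = perception * perception;
  std::vector<int> cand;
  std::vector<double> w;
  double total = 0;
  for (int j = 0; j < n; ++j) {
    if (j == focal) continue;
    double dx = x[j] - x[focal], dy = y[j] - y[focal];
    double d2 = dx * dx + dy * dy;
    if (d2 < p2) {
      double d = std::sqrt(d2);
      double wj = 1.0 / (d > eps ? d : eps);
      cand.push_back(j);
      w.push_back(wj);
      total += wj;
    }
  }
  IntegerVector out(ndraws);
  if (cand.empty()) {
    std::fill(out.begin(), out.end(), 0);
    return out;
  }
  for (int t = 0; t < ndraws; ++t) {
    double u = unif_rand() * total, acc = 0;
    int pick = cand.back();
    for (size_t k = 0; k < cand.size(); ++k) {
      acc += w[k];
      if (u < acc) { pick = cand[k]; break; }
    }
    out[t] = pick + 1;
  }
  return out;
}
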