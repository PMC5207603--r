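#include "core.h"

using namespace Rcpp;

namespace ffl {

int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

Rule random_rule(int ant_max) {
  Rule r;
  r.fill(-1);
  int k = 1 + runif_int(ant_max);
  // distinct variables via partial Fisher-Yates
  int pool[N_VARS];
  for (int i = 0; i < N_VARS; ++i) pool[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + runif_int(N_VARS - i);
    std::swap(pool[i], pool[j]);
    r[2 * i] = pool[i];
    r[2 * i + 1] = runif_int(n_values(pool[i]));
  }
  r[8] = runif_int(N_OUT);
  return r;
}

RuleBase random_rulebase(int cap, int ant_max) {
  int len = 1 + runif_int(cap);
  RuleBase rb(len);
  for (int i = 0; i < len; ++i) rb[i] = random_rule(ant_max);
  return rb;
}

RuleBase crossover(const RuleBase& a, const RuleBase& b, int cap) {
  int joint = (int)(a.size() + b.size());
  int maxlen = joint < cap ? joint : cap;
  int len = 1 + runif_int(maxlen);
  std::vector<int> idx(joint);
  for (int i = 0; i < joint; ++i) idx[i] = i;
  RuleBase child(len);
  for (int i = 0; i < len; ++i) {
    int j = i + runif_int(joint - i);
    std::swap(idx[i], idx[j]);
    int k = idx[i];
    child[i] = k < (int)a.size() ? a[k] : b[k - a.size()];
  }
  return child;
}

RuleBase mutate(const RuleBase& rb, double p, int add_max, int rem_max,
                int cap, int ant_max) {
  if (unif_rand() >= p) return rb;
  RuleBase out = rb;
  if (unif_rand() < 0.5) {  // add fresh random rules, truncated at cap
    int k = 1 + runif_int(add_max);
    for (int i = 0; i < k && (int)out.size() < cap; ++i)
      out.push_back(random_rule(ant_max));
  } else {  // remove uniformly chosen rules, never dropping below one
    int k = 1 + runif_int(rem_max);
    int n = (int)out.size();
    if (k > n - 1) k = n - 1;
    if (k <= 0) return out;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < k; ++i) {
      int j = i + runif_int(n - i);
      std::swap(idx[i], idx[j]);
    }
    std::vector<bool> drop(n, false);
    for (int i = 0; i < k; ++i) drop[idx[i]] = true;
    RuleBase kept;
    kept.reserve(n - k);
    for (int i = 0; i < n; ++i)
      if (!drop[i]) kept.push_back(out[i]);
    out = kept;
  }
  return out;
}

std::pair<int, int> select_parents(const std::vector<double>& energy) {
  int n = (int)energy.size();
  double total = 0;
  for (double e : energy) total += e;
  double u = unif_rand() * total;
  int first = n - 1;
  double acc = 0;
  for (int i = 0; i < n; ++i) {
    acc += energy[i];
    if (u < acc) { first = i; break; }
  }
  double total2 = total - energy[first];
  double u2 = unif_rand() * total2;
  int second = -1;
  acc = 0;
  for (int i = 0; i < n; ++i) {
    if (i == first) continue;
    acc += energy[i];
    if (u2 < acc) { second = i; break; }
  }
  if (second < 0) second = (first == n - 1) ? n - 2 : n - 1;
  return {first, second};
}

}  // namespace ffl

// [[Rcpp::export]]
IntegerMatrix cpp_random_rule(int ant_max) {
  ffl::RuleBase rb{ffl::random_rule(ant_max)};
  return ffl::encode_rb(rb);
}

// [[Rcpp::export]]
IntegerMatrix cpp_random_rulebase(int cap, int ant_max) {
  return ffl::encode_rb(ffl::random_rulebase(cap, ant_max));
}

// [[Rcpp::export]]
IntegerMatrix cpp_crossover(IntegerMatrix a, IntegerMatrix b, int cap) {
  return ffl::encode_rb(
      ffl::crossover(ffl::decode_rb(a), ffl::decode_rb(b), cap));
}

// [[Rcpp::export]]
IntegerMatrix cpp_mutate(IntegerMatrix rb, double p, int add_max, int rem_max,
                         int cap, int ant_max) {
  return ffl::encode_rb(
      ffl::mutate(ffl::decode_rb(rb), p, add_max, rem_max, cap, ant_max));
}

// [[Rcpp::export]]
IntegerVector cpp_select_parents(NumericVector energy) {
  std::vector<double> e(energy.begin(), energy.end());
  auto pr = ffl::select_parents(e);
  return IntegerVector::create(pr.first + 1, pr.second + 1);
}
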