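#include "core.h"

using namespace Rcpp;

namespace ffl {

// Table of linguistic values.  Distance variables share one set of five
// values, bearing/heading variables one set of four (the fourth, behind /
// opposite, is periodic with period 360).
static const FValue DIST_VALUES[5] = {
    {0, 0, 10, false},    // next
    {0, 15, 40, false},   // close
    {20, 40, 60, false},  // near
    {50, 60, 100, false}, // away
    {60, 100, 100, false} // far
};
static const FValue ANGLE_VALUES[4] = {
    {-180, -90, 0, false},  // left
    {-90, 0, 90, false},    // in front / same
    {0, 90, 180, false},    // right
    {90, 180, -90, true}    // behind / opposite
};
static const FValue OUT_VALUES[N_OUT] = {
    {-180, -180, -90, false},  // hard left
    {-180, -90, 0, false},     // left
    {-90, 0, 90, false},       // none
    {0, 90, 180, false},       // right
    {90, 180, 180, false}      // hard right
};

bool is_distance_var(int var) { return var == 0 || var == 3 || var == 6; }

int n_values(int var) { return is_distance_var(var) ? 5 : 4; }

const FValue& db_value(int var, int idx) {
  return is_distance_var(var) ? DIST_VALUES[idx] : ANGLE_VALUES[idx];
}

const FValue& out_value(int idx) { return OUT_VALUES[idx]; }

double posmod(double a, double c) {
  double r = a - std::floor(a / c) * c;
  if (r < 0) r += c;
  if (r >= c) r -= c;
  return r;
}

double wrap180(double a) {
  double r = posmod(a, 360.0);
  if (r > 180.0) r -= 360.0;
  return r;
}

double heading_of(double vx, double vy) {
  return wrap180(std::atan2(-vy, vx) * 180.0 / M_PI);
}

double bearing_from(double x, double y, double heading, double tx, double ty) {
  return wrap180(heading_of(tx - x, ty - y) - heading);
}

// Triangular membership.  A zero-width side is a crisp shoulder: membership
// is 1 at the peak and on the degenerate side's boundary.
double tri_mf(double x, double l, double m, double r) {
  double left = (m > l) ? (x - l) / (m - l) : (x >= m ? 2.0 : -1.0);
  double right = (r > m) ? (r - x) / (r - m) : (x <= m ? 2.0 : -1.0);
  double v = left < right ? left : right;
  if (v < 0.0) return 0.0;
  if (v > 1.0) return 1.0;
  return v;
}

// Periodic triangular membership: unwrap x (and the peak/right shoulder)
// into the period frame anchored at l, then evaluate the plain triangle.
double ptri_mf(double x, double l, double m, double r, double c) {
  double mm = l + posmod(m - l, c);
  double rr = mm + posmod(r - m, c);
  double xx = l + posmod(x - l, c);
  return tri_mf(xx, l, mm, rr);
}

double membership(int var, int idx, double x) {
  if (is_distance_var(var)) {
    if (x < 0.0) x = 0.0;
    if (x > DIST_MAX) x = DIST_MAX;
  }
  const FValue& f = db_value(var, idx);
  return f.periodic ? ptri_mf(x, f.l, f.m, f.r, PERIOD) : tri_mf(x, f.l, f.m, f.r);
}

RuleBase decode_rb(const IntegerMatrix& m) {
  RuleBase rb(m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < RULE_COLS; ++j) rb[i][j] = m(i, j);
  return rb;
}

Rcpp::IntegerMatrix encode_rb(const RuleBase& rb) {
  IntegerMatrix m(rb.size(), RULE_COLS);
  for (size_t i = 0; i < rb.size(); ++i)
    for (int j = 0; j < RULE_COLS; ++j) m(i, j) = rb[i][j];
  return m;
}

Grid::Grid(double res_) : res(res_) {
  n = (int)std::lround(360.0 / res) + 1;
  x.resize(n);
  for (int j = 0; j < n; ++j) x[j] = -180.0 + j * res;
  outmf.assign(N_OUT, std::vector<double>(n));
  sup_lo.resize(N_OUT);
  sup_hi.resize(N_OUT);
  out_centroid.resize(N_OUT);
  for (int v = 0; v < N_OUT; ++v) {
    const FValue& f = OUT_VALUES[v];
    for (int j = 0; j < n; ++j) outmf[v][j] = tri_mf(x[j], f.l, f.m, f.r);
    int lo = (int)std::floor((f.l + 180.0) / res);
    int hi = (int)std::ceil((f.r + 180.0) / res);
    sup_lo[v] = lo < 0 ? 0 : lo;
    sup_hi[v] = hi > n - 1 ? n - 1 : hi;
    // centroid of the unscaled value (scale cancels in centre of gravity)
    double num = 0, den = 0;
    for (int j = 0; j < n; ++j) {
      double w = (j == 0 || j == n - 1) ? 0.5 : 1.0;
      num += w * x[j] * outmf[v][j];
      den += w * outmf[v][j];
    }
    out_centroid[v] = den > 0 ? num / den : 0.0;
  }
}

double rule_activation(const Rule& rule, const double* in8) {
  double a = 1.0;
  for (int k = 0; k < 4; ++k) {
    int var = rule[2 * k];
    if (var < 0) continue;
    double xv = in8[var];
    if (std::isnan(xv)) return 0.0;  // null variable: the rule does not fire
    a *= membership(var, rule[2 * k + 1], xv);
    if (a <= 0.0) return 0.0;
  }
  return a;
}

bool aggregate_rb(const RuleBase& rb, const double* in8, const Grid& g,
                  std::vector<double>& S) {
  // Probabilistic sum of product-scaled consequents:
  //   S(x) = 1 - prod_i (1 - a_i * T_i(x))
  S.assign(g.n, 1.0);
  bool fired = false;
  for (const Rule& rule : rb) {
    double a = rule_activation(rule, in8);
    if (a <= 0.0) continue;
    fired = true;
    int v = rule[8];
    const double* t = g.outmf[v].data();
    for (int j = g.sup_lo[v]; j <= g.sup_hi[v]; ++j) S[j] *= 1.0 - a * t[j];
  }
  if (!fired) {
    S.assign(g.n, 0.0);
    return false;
  }
  for (int j = 0; j < g.n; ++j) S[j] = 1.0 - S[j];
  return true;
}

double centroid_of(const std::vector<double>& S, const Grid& g) {
  double num = 0, den = 0;
  for (int j = 0; j < g.n; ++j) {
    double w = (j == 0 || j == g.n - 1) ? 0.5 : 1.0;
    num += w * g.x[j] * S[j];
    den += w * S[j];
  }
  if (den < 1e-12) return 0.0;
  return num / den;
}

double infer(const RuleBase& rb, const double* in8, const Grid& g) {
  // Fast paths: no rule fires -> 0; a single firing rule -> the consequent's
  // centroid (product implication rescales, which cancels in the centroid).
  int fired = 0, last_v = -1;
  for (const Rule& rule : rb) {
    if (rule_activation(rule, in8) > 0.0) {
      if (++fired > 1) break;
      last_v = rule[8];
    }
  }
  if (fired == 0) return 0.0;
  if (fired == 1) return g.out_centroid[last_v];
  std::vector<double> S;
  aggregate_rb(rb, in8, g, S);
  return centroid_of(S, g);
}

const RuleBase& predator_rules() {
  // Minimal preset pursuit controller over the target's relative bearing
  // (variable slot 4): left -> left, in front -> none, right -> right,
  // behind -> hard right (breaks the rear dead-lock).
  static const RuleBase rb = {
      Rule{4, 0, -1, -1, -1, -1, -1, -1, 1},
      Rule{4, 1, -1, -1, -1, -1, -1, -1, 2},
      Rule{4, 2, -1, -1, -1, -1, -1, -1, 3},
      Rule{4, 3, -1, -1, -1, -1, -1, -1, 4}};
  return rb;
}

}  // namespace ffl

// ---------------------------------------------------------------------------
// Exported wrappers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_tri_mf(NumericVector x, double l, double m, double r) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = ffl::tri_mf(x[i], l, m, r);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ptri_mf(NumericVector x, double l, double m, double r,
                          double c) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = ffl::ptri_mf(x[i], l, m, r, c);
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_database() {
  std::vector<std::string> var, val;
  std::vector<double> l, m, r;
  std::vector<bool> periodic;
  static const char* var_names[ffl::N_VARS] = {
      "interaction.distance", "interaction.relative_bearing",
      "interaction.relative_heading", "predator.distance",
      "predator.relative_bearing", "predator.relative_heading",
      "living_area.distance", "living_area.relative_bearing"};
  static const char* dist_names[5] = {"next", "close", "near", "away", "far"};
  static const char* bear_names[4] = {"left", "in front", "right", "behind"};
  static const char* head_names[4] = {"left", "same", "right", "opposite"};
  static const char* out_names[ffl::N_OUT] = {"hard left", "left", "none",
                                              "right", "hard right"};
  for (int v = 0; v < ffl::N_VARS; ++v) {
    bool heading_var = (v == 2 || v == 5);
    for (int i = 0; i < ffl::n_values(v); ++i) {
      const ffl::FValue& f = ffl::db_value(v, i);
      var.push_back(var_names[v]);
      val.push_back(ffl::is_distance_var(v)
                        ? dist_names[i]
                        : (heading_var ? head_names[i] : bear_names[i]));
      l.push_back(f.l);
      m.push_back(f.m);
      r.push_back(f.r);
      periodic.push_back(f.periodic);
    }
  }
  for (int i = 0; i < ffl::N_OUT; ++i) {
    const ffl::FValue& f = ffl::out_value(i);
    var.push_back("action.heading_change");
    val.push_back(out_names[i]);
    l.push_back(f.l);
    m.push_back(f.m);
    r.push_back(f.r);
    periodic.push_back(false);
  }
  return DataFrame::create(_["variable"] = var, _["value"] = val, _["l"] = l,
                           _["m"] = m, _["r"] = r, _["periodic"] = periodic,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
NumericVector cpp_activations(IntegerMatrix rb, NumericVector inputs) {
  ffl::RuleBase r = ffl::decode_rb(rb);
  double in8[ffl::N_VARS];
  for (int i = 0; i < ffl::N_VARS; ++i)
    in8[i] = NumericVector::is_na(inputs[i]) ? NAN : inputs[i];
  NumericVector out(r.size());
  for (size_t i = 0; i < r.size(); ++i) out[i] = ffl::rule_activation(r[i], in8);
  return out;
}

// [[Rcpp::export]]
List cpp_aggregate(NumericVector activations, IntegerVector consequents,
                   double resolution) {
  ffl::Grid g(resolution);
  std::vector<double> S(g.n, 1.0);
  bool fired = false;
  for (int i = 0; i < activations.size(); ++i) {
    double a = activations[i];
    if (a <= 0.0) continue;
    fired = true;
    int v = consequents[i];
    for (int j = g.sup_lo[v]; j <= g.sup_hi[v]; ++j)
      S[j] *= 1.0 - a * g.outmf[v][j];
  }
  NumericVector x(g.n), mu(g.n);
  for (int j = 0; j < g.n; ++j) {
    x[j] = g.x[j];
    mu[j] = fired ? 1.0 - S[j] : 0.0;
  }
  return List::create(_["x"] = x, _["mu"] = mu);
}

// [[Rcpp::export]]
double cpp_infer(IntegerMatrix rb, NumericVector inputs, double resolution) {
  ffl::Grid g(resolution);
  ffl::RuleBase r = ffl::decode_rb(rb);
  double in8[ffl::N_VARS];
  for (int i = 0; i < ffl::N_VARS; ++i)
    in8[i] = NumericVector::is_na(inputs[i]) ? NAN : inputs[i];
  return ffl::infer(r, in8, g);
}

// [[Rcpp::export]]
IntegerMatrix cpp_predator_rules() { return ffl::encode_rb(ffl::predator_rules()); }

// [[Rcpp::export]]
double cpp_predator_heading_change(double bearing, double resolution) {
  ffl::Grid g(resolution);
  double in8[ffl::N_VARS];
  for (int i = 0; i < ffl::N_VARS; ++i) in8[i] = NAN;
  in8[4] = bearing;
  return ffl::infer(ffl::predator_rules(), in8, g);
}
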