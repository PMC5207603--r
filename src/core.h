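#pragma once

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <vector>

// Shared core for the fuzzy inference engine, the genetic operators and the
// world simulation.  All randomness goes through R's RNG (unif_rand), so a
// single set.seed() on the R side makes every run reproducible.

namespace ffl {

// ---------------------------------------------------------------------------
// Fuzzy data base (fixed): 8 input variables, 1 output variable.
// Variable indices:
//   0 interaction.distance          (5 values)
//   1 interaction.relative_bearing  (4)
//   2 interaction.relative_heading  (4)
//   3 predator.distance             (5)
//   4 predator.relative_bearing     (4)
//   5 predator.relative_heading     (4)
//   6 living_area.distance          (5)
//   7 living_area.relative_bearing  (4)
// Output: action.heading_change     (5 values)
// ---------------------------------------------------------------------------

struct FValue {
  double l, m, r;
  bool periodic;  // period 360 when true
};

constexpr int N_VARS = 8;
constexpr int N_OUT = 5;
constexpr double PERIOD = 360.0;
constexpr double DIST_MAX = 100.0;  // distance universes are clamped to [0, 100]

int n_values(int var);
const FValue& db_value(int var, int idx);
const FValue& out_value(int idx);
bool is_distance_var(int var);

// ---------------------------------------------------------------------------
// Angles and geometry.  Headings are stored in degrees with a clockwise-
// positive convention: heading 0 points along +x and the movement direction
// of heading h is (cos h, -sin h).  Relative bearings are then negative when
// the target lies on the agent's left and positive on its right.
// ---------------------------------------------------------------------------

double wrap180(double a);                    // to (-180, 180]
double posmod(double a, double c);           // non-negative modulus
double heading_of(double vx, double vy);     // heading whose direction is (vx, vy)
double bearing_from(double x, double y, double heading, double tx, double ty);

// ---------------------------------------------------------------------------
// Membership and inference
// ---------------------------------------------------------------------------

double tri_mf(double x, double l, double m, double r);
double ptri_mf(double x, double l, double m, double r, double c);
double membership(int var, int idx, double x);  // clamps distance inputs

// Rules are encoded as 9 ints: 4 (variable, value) antecedent slots (-1 when
// empty) followed by the consequent value index.
constexpr int RULE_COLS = 9;
using Rule = std::array<int, RULE_COLS>;
using RuleBase = std::vector<Rule>;

RuleBase decode_rb(const Rcpp::IntegerMatrix& m);
Rcpp::IntegerMatrix encode_rb(const RuleBase& rb);

// Uniform grid over [-180, 180] with precomputed output-value membership.
struct Grid {
  double res;
  int n;
  std::vector<double> x;
  std::vector<std::vector<double>> outmf;  // N_OUT x n
  std::vector<int> sup_lo, sup_hi;         // support index range per output value
  std::vector<double> out_centroid;        // centroid of each unscaled output value
  explicit Grid(double res);
};

// Activation of one rule for 8 crisp inputs (NaN = null variable).
double rule_activation(const Rule& rule, const double* in8);

// Aggregated output curve; returns false when no rule fires (S untouched).
bool aggregate_rb(const RuleBase& rb, const double* in8, const Grid& g,
                  std::vector<double>& S);

double centroid_of(const std::vector<double>& S, const Grid& g);
double infer(const RuleBase& rb, const double* in8, const Grid& g);

const RuleBase& predator_rules();  // preset pursuit controller

// ---------------------------------------------------------------------------
// Genetic operators (R RNG must be active via RNGScope)
// ---------------------------------------------------------------------------

int runif_int(int n);  // uniform on {0, ..., n-1}
Rule random_rule(int ant_max);
RuleBase random_rulebase(int cap, int ant_max);
RuleBase crossover(const RuleBase& a, const RuleBase& b, int cap);
RuleBase mutate(const RuleBase& rb, double p, int add_max, int rem_max,
                int cap, int ant_max);
// Fitness-proportional draw of two distinct indices (0-based).
std::pair<int, int> select_parents(const std::vector<double>& energy);

// ---------------------------------------------------------------------------
// Metrics helpers
// ---------------------------------------------------------------------------

// Connected components of the graph linking points at distance < d.
// Returns 0-based component labels.
std::vector<int> group_labels(const std::vector<double>& x,
                              const std::vector<double>& y, double d);

}  // namespace ffl
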