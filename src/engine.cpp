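#include "core.h"

using namespace Rcpp;

namespace ffl {
namespace {

const double DEG = M_PI / 180.0;

struct WCfg {
  int n_prey;
  double spawn_radius, living_area_side, prey_size, prey_speed,
      prey_perception, initial_energy, foraging_gain, collision_penalty,
      wandering_penalty;
  int n_predators;
  double ambush_distance;
  int reenter_min, reenter_max, hunt_duration;
  double st_speed, st_perception, st_catch;
  double hda_speed, hda_perception, hda_catch;
  double resolution, eps;
};

WCfg read_cfg(const List& wc) {
  WCfg c;
  c.n_prey = as<int>(wc["n_prey"]);
  c.spawn_radius = as<double>(wc["spawn_radius"]);
  c.living_area_side = as<double>(wc["living_area_side"]);
  c.prey_size = as<double>(wc["prey_size"]);
  c.prey_speed = as<double>(wc["prey_speed"]);
  c.prey_perception = as<double>(wc["prey_perception"]);
  c.initial_energy = as<double>(wc["initial_energy"]);
  c.foraging_gain = as<double>(wc["foraging_gain"]);
  c.collision_penalty = as<double>(wc["collision_penalty"]);
  c.wandering_penalty = as<double>(wc["wandering_penalty"]);
  c.n_predators = as<int>(wc["n_predators"]);
  c.ambush_distance = as<double>(wc["ambush_distance"]);
  c.reenter_min = as<int>(wc["reenter_min"]);
  c.reenter_max = as<int>(wc["reenter_max"]);
  c.hunt_duration = as<int>(wc["hunt_duration"]);
  c.st_speed = as<double>(wc["st_speed"]);
  c.st_perception = as<double>(wc["st_perception"]);
  c.st_catch = as<double>(wc["st_catch"]);
  c.hda_speed = as<double>(wc["hda_speed"]);
  c.hda_perception = as<double>(wc["hda_perception"]);
  c.hda_catch = as<double>(wc["hda_catch"]);
  c.resolution = as<double>(wc["resolution"]);
  c.eps = as<double>(wc["eps"]);
  return c;
}

struct Pred {
  bool active = false;
  double x = 0, y = 0, h = 0;
  int tactic = 0;       // 0 nearest, 1 most_isolated, 2 most_central, 3 hda
  int target = -1;      // prey slot (0-based), ST only
  int hunt_left = 0;
  double next_entry = 0;
};

// Single-target selection among live prey within `perception` of (px, py).
// Returns prey slot or -1.  Ties break to the lowest slot index.
int select_target_st(int tactic, double px, double py,
                     const std::vector<double>& x, const std::vector<double>& y,
                     const std::vector<bool>& dead, double perception) {
  int n = (int)x.size();
  double p2 = perception * perception;
  std::vector<int> cand;
  for (int j = 0; j < n; ++j) {
    if (dead[j]) continue;
    double dx = x[j] - px, dy = y[j] - py;
    if (dx * dx + dy * dy < p2) cand.push_back(j);
  }
  if (cand.empty()) return -1;
  if (tactic == 0) {  // nearest
    int best = -1;
    double bd = R_PosInf;
    for (int j : cand) {
      double dx = x[j] - px, dy = y[j] - py, d2 = dx * dx + dy * dy;
      if (d2 < bd) { bd = d2; best = j; }
    }
    return best;
  }
  if (tactic == 1) {  // most isolated: largest nearest-conspecific distance
    int best = -1;
    double bd = -1;
    for (int j : cand) {
      double nn = R_PosInf;
      for (int k = 0; k < n; ++k) {
        if (k == j || dead[k]) continue;
        double dx = x[k] - x[j], dy = y[k] - y[j], d2 = dx * dx + dy * dy;
        if (d2 < nn) nn = d2;
      }
      if (nn > bd) { bd = nn; best = j; }
    }
    return best;
  }
  // most central: closest to the centroid of all perceived prey
  double cx = 0, cy = 0;
  for (int j : cand) { cx += x[j]; cy += y[j]; }
  cx /= cand.size();
  cy /= cand.size();
  int best = -1;
  double bd = R_PosInf;
  for (int j : cand) {
    double dx = x[j] - cx, dy = y[j] - cy, d2 = dx * dx + dy * dy;
    if (d2 < bd) { bd = d2; best = j; }
  }
  return best;
}

// High-density-area target point: position of the perceived prey with the
// most conspecifics within `catchd`.  Returns false when no prey perceived.
bool hda_target(double px, double py, const std::vector<double>& x,
                const std::vector<double>& y, const std::vector<bool>& dead,
                double perception, double catchd, double* tx, double* ty) {
  int n = (int)x.size();
  double p2 = perception * perception, c2 = catchd * catchd;
  int best = -1, bestcnt = -1;
  for (int j = 0; j < n; ++j) {
    if (dead[j]) continue;
    double dx = x[j] - px, dy = y[j] - py;
    if (dx * dx + dy * dy >= p2) continue;
    int cnt = 0;
    for (int k = 0; k < n; ++k) {
      if (k == j || dead[k]) continue;
      double ex = x[k] - x[j], ey = y[k] - y[j];
      if (ex * ex + ey * ey < c2) cnt++;
    }
    if (cnt > bestcnt) { bestcnt = cnt; best = j; }
  }
  if (best < 0) return false;
  *tx = x[best];
  *ty = y[best];
  return true;
}

// Nearest point on the axis-aligned square of side `side` centred at the
// origin, valid inside and outside; centre ties break to the +x edge.
void border_point(double x, double y, double side, double* bx, double* by,
                  double* dist) {
  double half = side / 2.0;
  if (std::abs(x) <= half && std::abs(y) <= half) {
    double dr = half - x, dl = x + half, dt = half - y, db = y + half;
    double dmin = dr;
    int which = 0;
    if (dl < dmin) { dmin = dl; which = 1; }
    if (dt < dmin) { dmin = dt; which = 2; }
    if (db < dmin) { dmin = db; which = 3; }
    switch (which) {
      case 0: *bx = half;  *by = y;     break;
      case 1: *bx = -half; *by = y;     break;
      case 2: *bx = x;     *by = half;  break;
      default: *bx = x;    *by = -half; break;
    }
    *dist = dmin;
  } else {
    double cx = x < -half ? -half : (x > half ? half : x);
    double cy = y < -half ? -half : (y > half ? half : y);
    *bx = cx;
    *by = cy;
    *dist = std::sqrt((x - cx) * (x - cx) + (y - cy) * (y - cy));
  }
}

// Perception of prey slot i against the pre-step world; fills in8 (NaN=null).
void perceive(int i, const std::vector<double>& x, const std::vector<double>& y,
              const std::vector<double>& h, const std::vector<Pred>& preds,
              const WCfg& c, double* in8) {
  for (int k = 0; k < N_VARS; ++k) in8[k] = NAN;
  // a) interacting conspecific: weight 1/max(d, eps) among those in range
  double p2 = c.prey_perception * c.prey_perception;
  int n = (int)x.size();
  std::vector<int> cand;
  std::vector<double> w;
  double total = 0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = x[j] - x[i], dy = y[j] - y[i], d2 = dx * dx + dy * dy;
    if (d2 < p2) {
      double d = std::sqrt(d2);
      double wj = 1.0 / (d > c.eps ? d : c.eps);
      cand.push_back(j);
      w.push_back(wj);
      total += wj;
    }
  }
  if (!cand.empty()) {
    double u = unif_rand() * total, acc = 0;
    int pick = cand.back();
    for (size_t k = 0; k < cand.size(); ++k) {
      acc += w[k];
      if (u < acc) { pick = cand[k]; break; }
    }
    {
      double ddx = x[pick] - x[i], ddy = y[pick] - y[i];
      in8[0] = std::sqrt(ddx * ddx + ddy * ddy);
    }
    in8[1] = bearing_from(x[i], y[i], h[i], x[pick], y[pick]);
    in8[2] = wrap180(h[pick] - h[i]);
  }
  // b) nearest on-world predator
  int bp = -1;
  double bd = R_PosInf;
  for (size_t k = 0; k < preds.size(); ++k) {
    if (!preds[k].active) continue;
    double dx = preds[k].x - x[i], dy = preds[k].y - y[i], d2 = dx * dx + dy * dy;
    if (d2 < bd) { bd = d2; bp = (int)k; }
  }
  if (bp >= 0 && bd < p2) {
    in8[3] = std::sqrt(bd);
    in8[4] = bearing_from(x[i], y[i], h[i], preds[bp].x, preds[bp].y);
    in8[5] = wrap180(preds[bp].h - h[i]);
  }
  // c) closest living-area border point
  double bx, by, bdist;
  border_point(x[i], y[i], c.living_area_side, &bx, &by, &bdist);
  if (bdist < c.prey_perception) {
    in8[6] = bdist;
    in8[7] = bearing_from(x[i], y[i], h[i], bx, by);
  }
}

void spawn_predator(Pred& p, const WCfg& c, int fixed_tactic, int step,
                    const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<bool>& dead) {
  double phi = unif_rand() * 2.0 * M_PI;
  p.x = c.ambush_distance * std::cos(phi);
  p.y = c.ambush_distance * std::sin(phi);
  p.h = heading_of(-p.x, -p.y);
  p.tactic = fixed_tactic >= 0 ? fixed_tactic : runif_int(4);
  p.hunt_left = c.hunt_duration;
  p.active = true;
  p.target = -1;
  if (p.tactic < 3)
    p.target = select_target_st(p.tactic, p.x, p.y, x, y, dead, c.st_perception);
  (void)step;
}

}  // namespace
}  // namespace ffl

using namespace ffl;

// [[Rcpp::export]]
List cpp_simulate(List wc, List run) {
  WCfg c = read_cfg(wc);
  Grid grid(c.resolution);
  int steps = as<int>(run["steps"]);
  int mode = as<int>(run["mode"]);  // 0 evolve, 1 frozen
  int start_step = as<int>(run["start_step"]);
  int fixed_tactic = as<int>(run["fixed_tactic"]);
  int record_every = as<int>(run["record_every"]);
  int record_start = as<int>(run["record_start"]);
  bool record_events = as<bool>(run["record_events"]);
  double mut_p = as<double>(run["mutation_probability"]);
  int add_max = as<int>(run["add_max"]);
  int rem_max = as<int>(run["rem_max"]);
  int rb_cap = as<int>(run["rulebase_cap"]);
  int ant_cap = as<int>(run["antecedent_cap"]);

  int n = c.n_prey;
  std::vector<double> x = as<std::vector<double>>(run["px"]);
  std::vector<double> y = as<std::vector<double>>(run["py"]);
  std::vector<double> h = as<std::vector<double>>(run["heading"]);
  std::vector<double> e = as<std::vector<double>>(run["energy"]);
  std::vector<double> birth = as<std::vector<double>>(run["birth"]);
  std::vector<double> id = as<std::vector<double>>(run["id"]);
  double next_id = as<double>(run["next_id"]);

  List rbs_in = run["rule_bases"];
  std::vector<RuleBase> rbs(n);
  for (int i = 0; i < n; ++i) rbs[i] = decode_rb(rbs_in[i]);

  List pool_in = run["pool"];
  std::vector<RuleBase> pool(pool_in.size());
  for (int i = 0; i < pool_in.size(); ++i) pool[i] = decode_rb(pool_in[i]);

  List pd = run["predators"];
  int npred = c.n_predators;
  std::vector<Pred> preds(npred);
  {
    LogicalVector pa = pd["active"];
    NumericVector px_ = pd["x"], py_ = pd["y"], ph_ = pd["heading"],
                  pne = pd["next_entry"];
    IntegerVector pt = pd["tactic"], ptar = pd["target"], phl = pd["hunt_left"];
    for (int k = 0; k < npred; ++k) {
      preds[k].active = pa[k];
      preds[k].x = px_[k];
      preds[k].y = py_[k];
      preds[k].h = ph_[k];
      preds[k].tactic = pt[k];
      preds[k].target = ptar[k] - 1;  // R side is 1-based, 0 = none
      preds[k].hunt_left = phl[k];
      preds[k].next_entry = pne[k];
    }
  }

  // counters and logs
  double n_captures = 0, n_collisions = 0, n_wanders = 0, n_energy_deaths = 0,
         n_births = 0;
  std::vector<int> ev_step, ev_type;
  std::vector<double> ev_id;
  auto log_event = [&](int step, int type, double who) {
    if (record_events) {
      ev_step.push_back(step);
      ev_type.push_back(type);
      ev_id.push_back(who);
    }
  };

  std::vector<int> snap_steps;
  std::vector<NumericMatrix> snap_prey, snap_pred;
  auto take_snapshot = [&](int step) {
    NumericMatrix sp(n, 5);
    for (int i = 0; i < n; ++i) {
      sp(i, 0) = id[i];
      sp(i, 1) = x[i];
      sp(i, 2) = y[i];
      sp(i, 3) = h[i];
      sp(i, 4) = e[i];
    }
    NumericMatrix sq(npred, 6);
    for (int k = 0; k < npred; ++k) {
      sq(k, 0) = preds[k].active ? 1 : 0;
      sq(k, 1) = preds[k].x;
      sq(k, 2) = preds[k].y;
      sq(k, 3) = preds[k].h;
      sq(k, 4) = preds[k].tactic;
      sq(k, 5) = preds[k].hunt_left;
    }
    snap_steps.push_back(step);
    snap_prey.push_back(sp);
    snap_pred.push_back(sq);
  };
  auto should_record = [&](int step) {
    return record_every > 0 && step >= record_start &&
           (step - record_start) % record_every == 0;
  };
  if (should_record(start_step)) take_snapshot(start_step);

  std::vector<bool> dead(n, false);
  std::vector<double> dh(n), xin(n), yin(n), hin(n);
  std::vector<double> pdh(npred);
  double in8[N_VARS];
  double half = c.living_area_side / 2.0;
  std::vector<bool> no_dead(n, false);

  for (int t = start_step + 1; t <= start_step + steps; ++t) {
    // -- predator entries -------------------------------------------------
    for (int k = 0; k < npred; ++k) {
      if (!preds[k].active && t >= preds[k].next_entry)
        spawn_predator(preds[k], c, fixed_tactic, t, x, y, no_dead);
    }
    // -- perception and decisions on the pre-step state -------------------
    xin = x; yin = y; hin = h;
    for (int i = 0; i < n; ++i) {
      perceive(i, xin, yin, hin, preds, c, in8);
      dh[i] = infer(rbs[i], in8, grid);
    }
    for (int k = 0; k < npred; ++k) {
      pdh[k] = 0;
      if (!preds[k].active) continue;
      Pred& p = preds[k];
      double tx = NAN, ty = NAN;
      if (p.tactic < 3) {
        if (p.target < 0)
          p.target = select_target_st(p.tactic, p.x, p.y, xin, yin, no_dead,
                                      c.st_perception);
        if (p.target >= 0) { tx = xin[p.target]; ty = yin[p.target]; }
      } else {
        hda_target(p.x, p.y, xin, yin, no_dead, c.hda_perception, c.hda_catch,
                   &tx, &ty);
      }
      if (!std::isnan(tx)) {
        double b = bearing_from(p.x, p.y, p.h, tx, ty);
        for (int q = 0; q < N_VARS; ++q) in8[q] = NAN;
        in8[4] = b;
        pdh[k] = infer(predator_rules(), in8, grid);
      }
    }
    // -- synchronous movement ---------------------------------------------
    for (int i = 0; i < n; ++i) {
      h[i] = wrap180(h[i] + dh[i]);
      x[i] += c.prey_speed * std::cos(h[i] * DEG);
      y[i] -= c.prey_speed * std::sin(h[i] * DEG);
    }
    for (int k = 0; k < npred; ++k) {
      if (!preds[k].active) continue;
      Pred& p = preds[k];
      p.h = wrap180(p.h + pdh[k]);
      double sp = p.tactic < 3 ? c.st_speed : c.hda_speed;
      p.x += sp * std::cos(p.h * DEG);
      p.y -= sp * std::sin(p.h * DEG);
    }
    // -- energy ------------------------------------------------------------
    double csum2 = 4.0 * c.prey_size * c.prey_size;  // (2 * size)^2
    std::vector<bool> hit(n, false);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j];
        if (dx * dx + dy * dy < csum2) { hit[i] = true; hit[j] = true; }
      }
    }
    for (int i = 0; i < n; ++i) {
      e[i] += c.foraging_gain;
      if (hit[i]) {
        e[i] += c.collision_penalty;
        n_collisions++;
        log_event(t, 2, id[i]);
      }
      if (std::abs(x[i]) > half || std::abs(y[i]) > half) {
        e[i] += c.wandering_penalty;
        n_wanders++;
        log_event(t, 3, id[i]);
      }
    }
    // -- captures ----------------------------------------------------------
    std::fill(dead.begin(), dead.end(), false);
    for (int k = 0; k < npred; ++k) {
      if (!preds[k].active) continue;
      Pred& p = preds[k];
      if (p.tactic < 3) {
        if (p.target >= 0 && !dead[p.target]) {
          double dx = x[p.target] - p.x, dy = y[p.target] - p.y;
          if (dx * dx + dy * dy < c.st_catch * c.st_catch) {
            dead[p.target] = true;
            n_captures++;
            log_event(t, 1, id[p.target]);
            p.target = select_target_st(p.tactic, p.x, p.y, x, y, dead,
                                        c.st_perception);
          }
        }
      } else {
        double c2 = c.hda_catch * c.hda_catch;
        for (int i = 0; i < n; ++i) {
          if (dead[i]) continue;
          double dx = x[i] - p.x, dy = y[i] - p.y;
          if (dx * dx + dy * dy < c2) {
            dead[i] = true;
            n_captures++;
            log_event(t, 1, id[i]);
          }
        }
      }
    }
    // -- deaths and replacement (population size is conserved) -------------
    for (int i = 0; i < n; ++i) {
      if (!dead[i] && e[i] <= 0) {
        dead[i] = true;
        n_energy_deaths++;
        log_event(t, 4, id[i]);
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!dead[i]) continue;
      if (mode == 0) {
        // steady-state genetic replacement: fitness-proportional parents
        // among survivors, joint-set crossover, then mutation
        std::vector<int> live;
        std::vector<double> fit;
        for (int j = 0; j < n; ++j) {
          if (!dead[j]) { live.push_back(j); fit.push_back(e[j]); }
        }
        if (live.size() >= 2) {
          auto pr = select_parents(fit);
          rbs[i] = mutate(crossover(rbs[live[pr.first]], rbs[live[pr.second]],
                                    rb_cap),
                          mut_p, add_max, rem_max, rb_cap, ant_cap);
        } else {
          rbs[i] = random_rulebase(rb_cap, ant_cap);
        }
      } else {
        rbs[i] = pool[runif_int((int)pool.size())];
      }
      double rr = c.spawn_radius * std::sqrt(unif_rand());
      double phi = unif_rand() * 2.0 * M_PI;
      x[i] = rr * std::cos(phi);
      y[i] = rr * std::sin(phi);
      h[i] = wrap180(unif_rand() * 360.0 - 180.0);
      e[i] = c.initial_energy;
      birth[i] = t;
      id[i] = next_id;
      next_id += 1;
      n_births++;
      log_event(t, 5, id[i]);
      dead[i] = false;
      for (int k = 0; k < npred; ++k)
        if (preds[k].target == i) preds[k].target = -1;  // target died
    }
    // -- predator hunt/re-enter scheduling ---------------------------------
    for (int k = 0; k < npred; ++k) {
      if (!preds[k].active) continue;
      if (--preds[k].hunt_left <= 0) {
        preds[k].active = false;
        preds[k].target = -1;
        preds[k].next_entry =
            t + c.reenter_min + runif_int(c.reenter_max - c.reenter_min + 1);
      }
    }
    if (should_record(t)) take_snapshot(t);
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  // -- pack results ---------------------------------------------------------
  List rbs_out(n);
  for (int i = 0; i < n; ++i) rbs_out[i] = encode_rb(rbs[i]);
  LogicalVector pa(npred);
  NumericVector ppx(npred), ppy(npred), pph(npred), pne(npred);
  IntegerVector pt(npred), ptar(npred), phl(npred);
  for (int k = 0; k < npred; ++k) {
    pa[k] = preds[k].active;
    ppx[k] = preds[k].x;
    ppy[k] = preds[k].y;
    pph[k] = preds[k].h;
    pt[k] = preds[k].tactic;
    ptar[k] = preds[k].target + 1;
    phl[k] = preds[k].hunt_left;
    pne[k] = preds[k].next_entry;
  }
  List state = List::create(
      _["step"] = start_step + steps, _["px"] = x, _["py"] = y,
      _["heading"] = h, _["energy"] = e, _["birth"] = birth, _["id"] = id,
      _["next_id"] = next_id, _["rule_bases"] = rbs_out,
      _["predators"] = List::create(
          _["active"] = pa, _["x"] = ppx, _["y"] = ppy, _["heading"] = pph,
          _["tactic"] = pt, _["target"] = ptar, _["hunt_left"] = phl,
          _["next_entry"] = pne));
  List snaps = List::create(
      _["step"] = wrap(snap_steps),
      _["prey"] = wrap(snap_prey),
      _["predators"] = wrap(snap_pred));
  NumericVector counts = NumericVector::create(
      _["captures"] = n_captures, _["collisions"] = n_collisions,
      _["wanders"] = n_wanders, _["energy_deaths"] = n_energy_deaths,
      _["births"] = n_births);
  List events = R_NilValue;
  if (record_events)
    events = List::create(_["step"] = wrap(ev_step), _["type"] = wrap(ev_type),
                          _["id"] = wrap(ev_id));
  return List::create(_["state"] = state, _["snapshots"] = snaps,
                      _["counts"] = counts, _["events"] = events);
}

// [[Rcpp::export]]
NumericVector cpp_perceive(int i, NumericVector px, NumericVector py,
                           NumericVector ph, List predators, List wc) {
  WCfg c = read_cfg(wc);
  std::vector<double> x(px.begin(), px.end()), y(py.begin(), py.end()),
      h(ph.begin(), ph.end());
  LogicalVector pa = predators["active"];
  NumericVector qx = predators["x"], qy = predators["y"], qh = predators["heading"];
  std::vector<Pred> preds(pa.size());
  for (int k = 0; k < pa.size(); ++k) {
    preds[k].active = pa[k];
    preds[k].x = qx[k];
    preds[k].y = qy[k];
    preds[k].h = qh[k];
  }
  double in8[N_VARS];
  perceive(i - 1, x, y, h, preds, c, in8);
  NumericVector out(N_VARS);
  for (int k = 0; k < N_VARS; ++k)
    out[k] = std::isnan(in8[k]) ? NA_REAL : in8[k];
  return out;
}

// [[Rcpp::export]]
List cpp_select_target(int tactic, double px, double py, NumericVector x,
                       NumericVector y, double perception, double catchd) {
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  std::vector<bool> dead(xs.size(), false);
  if (tactic < 3) {
    int tgt = select_target_st(tactic, px, py, xs, ys, dead, perception);
    return List::create(_["target"] = tgt + 1, _["point"] = R_NilValue);
  }
  double tx, ty;
  if (hda_target(px, py, xs, ys, dead, perception, catchd, &tx, &ty))
    return List::create(_["target"] = 0,
                        _["point"] = NumericVector::create(tx, ty));
  return List::create(_["target"] = 0, _["point"] = R_NilValue);
}

// [[Rcpp::export]]
List cpp_border_point(double x, double y, double side) {
  double bx, by, d;
  border_point(x, y, side, &bx, &by, &d);
  return List::create(_["point"] = NumericVector::create(bx, by),
                      _["distance"] = d);
}

// [[Rcpp::export]]
double cpp_bearing(double x, double y, double heading, double tx, double ty) {
  return bearing_from(x, y, heading, tx, ty);
}

// [[Rcpp::export]]
double cpp_wrap180(double a) { return wrap180(a); }
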