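# The 2D artificial world: configuration, geometry, perception, predator
# tactics and the synchronous update loop (C++ engine behind the scenes).

#' World configuration
#'
#' All parameters of the predator and prey agents, with the model's default
#' values.  Distances and times are in arbitrary units.  The living area is
#' an axis-aligned square centred at the origin; newborn prey spawn on a
#' closed disc centred at the origin (whose radius deliberately exceeds the
#' living-area half-side, so newborns may legally appear outside the
#' square).  `resolution` is the defuzzification grid spacing shared by all
#' agents.
#'
#' @param n_prey number of prey agents (constant through time).
#' @param spawn_radius radius of the spawn disc.
#' @param living_area_side side length of the square living area.
#' @param prey_size prey body radius; two prey collide when their centre
#'   distance is below the sum of their sizes.
#' @param prey_speed constant prey speed per update step.
#' @param prey_perception prey perception distance.
#' @param initial_energy energy assigned at birth.
#' @param foraging_gain energy gained per step for living.
#' @param collision_penalty energy change per step spent in collision
#'   (negative).
#' @param wandering_penalty energy change per step spent outside the living
#'   area (negative).
#' @param n_predators number of predator slots (on-world or waiting).
#' @param ambush_distance distance from the origin at which predators enter.
#' @param reenter_min,reenter_max bounds of the uniform re-enter interval
#'   (update steps).
#' @param hunt_duration steps a predator stays on-world per hunt.
#' @param st_size,st_speed,st_perception,st_catch single-target predator
#'   parameters (tactics nearest / most isolated / most central).
#' @param hda_size,hda_speed,hda_perception,hda_catch high-density-area
#'   predator parameters.
#' @param resolution defuzzification grid spacing in degrees.
#' @param eps distance floor for inverse-distance interaction weights.
#' @return A `world_config` list.
#' @export
world_config <- function(n_prey = 100, spawn_radius = 325,
                         living_area_side = 375, prey_size = 1,
                         prey_speed = 2, prey_perception = 100,
                         initial_energy = 1000, foraging_gain = 1,
                         collision_penalty = -10, wandering_penalty = -10,
                         n_predators = 16, ambush_distance = 400,
                         reenter_min = 600, reenter_max = 1200,
                         hunt_duration = 600,
                         st_size = 6, st_speed = 3, st_perception = 500,
                         st_catch = 6,
                         hda_size = 12, hda_speed = 1.5,
                         hda_perception = 500, hda_catch = 12,
                         resolution = 0.25, eps = 1e-6) {
  cfg <- as.list(environment())
  pos <- c("n_prey", "spawn_radius", "living_area_side", "prey_size",
           "prey_speed", "prey_perception", "initial_energy", "foraging_gain",
           "ambush_distance", "hunt_duration", "st_size", "st_speed",
           "st_perception", "st_catch", "hda_size", "hda_speed",
           "hda_perception", "hda_catch", "resolution", "eps")
  for (p in pos) if (cfg[[p]] <= 0) stop(p, " must be positive", call. = FALSE)
  if (cfg$n_predators < 0) stop("n_predators must be >= 0", call. = FALSE)
  if (cfg$collision_penalty > 0 || cfg$wandering_penalty > 0)
    stop("penalties must be non-positive", call. = FALSE)
  if (cfg$reenter_min > cfg$reenter_max)
    stop("reenter_min must not exceed reenter_max", call. = FALSE)
  structure(cfg, class = "world_config")
}

#' Relative bearing of a target point
#'
#' Signed angle from an agent's heading to the direction of a target point:
#' 0 means dead ahead, negative values lie on the agent's left, positive on
#' its right, and +/-180 directly behind.
#'
#' @param pos agent position, numeric `c(x, y)`.
#' @param heading agent heading in degrees.
#' @param target target position, numeric `c(x, y)`.
#' @return Bearing in degrees in `(-180, 180]`.
#' @export
relative_bearing <- function(pos, heading, target) {
  if (sqrt(sum((target - pos)^2)) < 1e-12)
    stop("target coincides with the agent position", call. = FALSE)
  cpp_bearing(pos[1], pos[2], heading, target[1], target[2])
}

#' Relative heading between two agents
#'
#' Wrapped signed heading difference `other - own`: 0 when the agents move
#' in the same direction, +/-180 when opposite.
#'
#' @param own,other headings in degrees.
#' @return Degrees in `(-180, 180]`, vectorized.
#' @export
relative_heading <- function(own, other) {
  .wrap180(other - own)
}

#' Closest point on the living-area border
#'
#' Euclidean nearest point on the perimeter of the axis-aligned square of
#' side `side` centred at the origin, valid for positions inside or outside
#' the square.  Exact centre ties break towards the +x edge.
#'
#' @param pos position, numeric `c(x, y)`.
#' @param side side length of the square.
#' @return List with `point` (numeric `c(x, y)`) and `distance`.
#' @export
#' @examples
#' closest_border_point(c(100, 0), 375) # point (187.5, 0), distance 87.5
closest_border_point <- function(pos, side) {
  stopifnot(side > 0)
  cpp_border_point(pos[1], pos[2], side)
}

#' Sample an interaction partner
#'
#' Draws one conspecific among those within the perception distance of the
#' focal agent, with probability inversely proportional to distance
#' (weight `1 / max(d, eps)`).  Returns `NA` when no conspecific is in
#' range.
#'
#' @param focal index of the focal agent (row of `positions`).
#' @param positions n x 2 matrix of agent positions.
#' @param perception perception distance.
#' @param eps distance floor for the weights.
#' @param draws number of independent draws to return.
#' @return Integer vector of partner indices (`NA` when none in range).
#' @export
sample_interaction_partner <- function(focal, positions, perception = 100,
                                       eps = 1e-6, draws = 1) {
  out <- cpp_sample_partner(focal, positions[, 1], positions[, 2],
                            perception, eps, as.integer(draws))
  out[out == 0L] <- NA_integer_
  out
}

#' Build the perception snapshot of a prey agent
#'
#' The eight nullable crisp inputs of one prey agent against a world state:
#' a sampled interacting conspecific, the nearest on-world predator and the
#' closest living-area border point, each gated by the prey perception
#' distance (no occlusion, no blind angle).
#'
#' @param focal index of the focal prey.
#' @param state a `world_state` (see [init_world()]).
#' @param cfg a [world_config()].
#' @return A [perception_input()] vector.
#' @export
build_perception <- function(focal, state, cfg) {
  out <- cpp_perceive(focal, state$px, state$py, state$heading,
                      state$predators, cfg)
  names(out) <- .input_vars
  out
}

#' Predator target selection
#'
#' Single-target tactics pick one prey among those within the predator's
#' perception distance: `nearest` minimizes distance to the predator,
#' `most_isolated` maximizes the prey's own nearest-conspecific distance,
#' `most_central` minimizes distance to the centroid of all perceived prey.
#' The `hda` tactic returns a point: the position of the perceived prey
#' with the most conspecifics within the predator's catch radius (ties go
#' to the lowest index).
#'
#' @param tactic one of `"nearest"`, `"most_isolated"`, `"most_central"`,
#'   `"hda"`.
#' @param predator_pos predator position, numeric `c(x, y)`.
#' @param positions n x 2 matrix of prey positions.
#' @param perception predator perception distance.
#' @param catch predator catch distance (used by `hda`).
#' @return List with `target` (prey index or `NA`) and `point` (for `hda`).
#' @export
select_target <- function(tactic = .tactics, predator_pos, positions,
                          perception = 500, catch = 12) {
  tactic <- match.arg(tactic)
  ti <- match(tactic, .tactics) - 1L
  out <- cpp_select_target(ti, predator_pos[1], predator_pos[2],
                           positions[, 1], positions[, 2], perception, catch)
  if (out$target == 0L) out$target <- NA_integer_
  out
}

#' Preset predator pursuit controller
#'
#' The predator's drives are a fixed linguistic rule base over the target's
#' relative bearing, run through the same inference engine as the prey:
#' left turns left, in front holds, right turns right, behind turns hard
#' right (breaking the rear dead-lock).
#'
#' @param bearing relative bearing of the target in degrees.
#' @param resolution defuzzification grid spacing.
#' @return `predator_heading_change`: desired heading change in degrees;
#'   `predator_rule_base`: the controller as a `fuzzy_rulebase`.
#' @export
predator_heading_change <- function(bearing, resolution = 0.25) {
  vapply(bearing, cpp_predator_heading_change, numeric(1),
         resolution = resolution)
}

#' @rdname predator_heading_change
#' @export
predator_rule_base <- function() {
  .rb_decode(cpp_predator_rules())
}

# ---- world state ----------------------------------------------------------

#' Initialize a world state
#'
#' Places `n_prey` prey uniformly on the spawn disc with uniform random
#' headings and full initial energy, assigns rule bases (fresh random ones,
#' or draws from `pool`), and schedules the predators off-world with their
#' initial random re-enter countdowns.
#'
#' @param cfg a [world_config()].
#' @param evo_cfg an [evolution_config()] (bounds for random rule bases).
#' @param pool optional list of `fuzzy_rulebase` to assign instead of random
#'   behaviour: assigned 1:1 when sizes match, sampled without replacement
#'   when the pool is larger, with replacement when smaller.
#' @param positions,headings optional explicit initial placement.
#' @param predator_start step from which predators may enter (default 0).
#' @param predator_immediate if `TRUE` the predators enter exactly at
#'   `predator_start` instead of after a random initial interval.
#' @return A `world_state` list.
#' @export
init_world <- function(cfg = world_config(), evo_cfg = evolution_config(),
                       pool = NULL, positions = NULL, headings = NULL,
                       predator_start = 0, predator_immediate = FALSE) {
  n <- cfg$n_prey
  if (is.null(positions)) {
    r <- cfg$spawn_radius * sqrt(runif(n))
    phi <- runif(n) * 2 * pi
    positions <- cbind(r * cos(phi), r * sin(phi))
  }
  if (is.null(headings)) headings <- runif(n, -180, 180)
  if (is.null(pool)) {
    rbs <- replicate(n, random_rule_base(evo_cfg), simplify = FALSE)
  } else {
    idx <- if (length(pool) == n) seq_len(n)
           else sample.int(length(pool), n, replace = length(pool) < n)
    rbs <- pool[idx]
  }
  np <- cfg$n_predators
  entries <- if (np == 0) numeric(0)
             else if (predator_immediate) rep(predator_start, np)
             else predator_start +
               sample(seq(cfg$reenter_min, cfg$reenter_max), np, replace = TRUE)
  structure(list(
    step = 0L,
    px = positions[, 1], py = positions[, 2],
    heading = .wrap180(headings),
    energy = rep(cfg$initial_energy, n),
    birth = rep(0, n),
    id = as.numeric(seq_len(n)),
    next_id = n + 1,
    rule_bases = rbs,
    predators = list(
      active = rep(FALSE, np), x = rep(0, np), y = rep(0, np),
      heading = rep(0, np), tactic = rep(0L, np), target = rep(0L, np),
      hunt_left = rep(0L, np), next_entry = entries
    )
  ), class = "world_state")
}

.run_args <- function(steps, mode, state, pool, evo_cfg, record_every,
                      record_start, record_events, fixed_tactic) {
  list(
    steps = as.integer(steps),
    mode = if (mode == "evolve") 0L else 1L,
    start_step = as.integer(state$step),
    px = state$px, py = state$py, heading = state$heading,
    energy = state$energy, birth = state$birth, id = state$id,
    next_id = state$next_id,
    rule_bases = lapply(state$rule_bases, .rb_encode),
    pool = lapply(pool, .rb_encode),
    predators = state$predators,
    fixed_tactic = if (is.null(fixed_tactic)) -1L
                   else as.integer(fixed_tactic),
    mutation_probability = evo_cfg$mutation_probability,
    add_max = evo_cfg$add_rules_upper_bound,
    rem_max = evo_cfg$remove_rules_upper_bound,
    rulebase_cap = evo_cfg$rule_base_upper_bound,
    antecedent_cap = evo_cfg$antecedents_upper_bound,
    record_every = as.integer(record_every),
    record_start = as.integer(record_start),
    record_events = isTRUE(record_events)
  )
}

.decode_state <- function(st) {
  st$rule_bases <- lapply(st$rule_bases, .rb_decode)
  class(st) <- "world_state"
  st
}

#' Run the world simulation
#'
#' Advances a world state by `steps` synchronous updates.  Each step: (1)
#' every agent perceives the pre-step world and computes its desired heading
#' change by fuzzy inference; (2) headings are updated by the full
#' defuzzified change and positions advance at constant speed; (3) energy is
#' updated (foraging gain, collision and wandering penalties); (4) predators
#' attempt captures; (5) dead prey are replaced so the population size is
#' conserved -- by genetic offspring (`mode = "evolve"`) or by a uniform
#' draw from `pool` (`mode = "frozen"`); (6) predator hunt and re-enter
#' timers advance.
#'
#' @param cfg a [world_config()].
#' @param steps number of update steps.
#' @param mode `"evolve"` (steady-state genetic replacement) or `"frozen"`
#'   (replacement from a fixed pool; evolution disabled).
#' @param evo_cfg an [evolution_config()].
#' @param pool list of `fuzzy_rulebase` (required in frozen mode).
#' @param state optional `world_state` to continue from; a fresh one is
#'   initialized otherwise.
#' @param record_every snapshot interval in steps (0 = none).
#' @param record_start first step eligible for snapshots.
#' @param record_events if `TRUE`, keep a per-event log (capture,
#'   collision, wander, death, birth) with step and agent id.
#' @param predator_start,predator_immediate,fixed_tactic initial predator
#'   scheduling, see [init_world()]; `fixed_tactic` (0-3 or a name from
#'   `"nearest"`, `"most_isolated"`, `"most_central"`, `"hda"`) pins every
#'   predator entry to one tactic.
#' @return A `flock_sim` list: final `state`, `snapshots`, event `counts`,
#'   optional `events` data frame, and the configurations used.
#' @export
simulate_world <- function(cfg = world_config(), steps,
                           mode = c("evolve", "frozen"),
                           evo_cfg = evolution_config(), pool = NULL,
                           state = NULL, record_every = 0, record_start = 0,
                           record_events = FALSE, predator_start = 0,
                           predator_immediate = FALSE, fixed_tactic = NULL) {
  mode <- match.arg(mode)
  if (mode == "frozen" && (is.null(pool) || length(pool) == 0))
    stop("frozen mode requires a non-empty pool", call. = FALSE)
  if (is.character(fixed_tactic))
    fixed_tactic <- match(match.arg(fixed_tactic, .tactics), .tactics) - 1L
  if (is.null(state))
    state <- init_world(cfg, evo_cfg, pool = pool,
                        predator_start = predator_start,
                        predator_immediate = predator_immediate)
  if (is.null(pool)) pool <- list()
  run <- .run_args(steps, mode, state, pool, evo_cfg, record_every,
                   record_start, record_events, fixed_tactic)
  out <- cpp_simulate(cfg, run)
  events <- NULL
  if (record_events) {
    ev <- out$events
    events <- data.frame(
      step = ev$step,
      event = c("capture", "collision", "wander", "death", "birth")[ev$type],
      id = ev$id
    )
  }
  structure(list(
    state = .decode_state(out$state),
    snapshots = out$snapshots,
    counts = out$counts,
    events = events,
    cfg = cfg, evo_cfg = evo_cfg, mode = mode
  ), class = "flock_sim")
}

#' Advance a world state by one (or a few) steps
#'
#' Thin wrapper around [simulate_world()] that returns only the updated
#' state; useful for stepping a scripted scene through the full update
#' rule.
#'
#' @param state a `world_state`.
#' @param cfg a [world_config()].
#' @param steps number of steps (default 1).
#' @param ... further arguments passed to [simulate_world()].
#' @return The updated `world_state`.
#' @export
step_world <- function(state, cfg = world_config(), steps = 1, ...) {
  simulate_world(cfg, steps = steps, state = state, ...)$state
}

#' @export
print.flock_sim <- function(x, ...) {
  cat(sprintf("<flock_sim: %s, %d prey, step %d>\n", x$mode,
              length(x$state$px), x$state$step))
  cat("counts:", paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Convert recorded snapshots to a trajectory table
#'
#' One row per agent per recorded step, in the common trajectory CSV
#' dialect: `step, id, kind, tactic, x, y, heading, energy`.
#'
#' @param sim a `flock_sim` with recorded snapshots.
#' @return A data frame.
#' @export
as_trajectory <- function(sim) {
  sn <- sim$snapshots
  out <- vector("list", length(sn$step))
  for (k in seq_along(sn$step)) {
    p <- sn$prey[[k]]
    prey <- data.frame(step = sn$step[k], id = p[, 1], kind = "prey",
                       tactic = NA_character_, x = p[, 2], y = p[, 3],
                       heading = p[, 4], energy = p[, 5])
    q <- sn$predators[[k]]
    act <- q[, 1] > 0
    if (any(act)) {
      pred <- data.frame(step = sn$step[k], id = -seq_len(nrow(q))[act],
                         kind = "predator",
                         tactic = .tactics[q[act, 5] + 1],
                         x = q[act, 2], y = q[act, 3], heading = q[act, 4],
                         energy = NA_real_)
      prey <- rbind(prey, pred)
    }
    out[[k]] <- prey
  }
  do.call(rbind, out)
}
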