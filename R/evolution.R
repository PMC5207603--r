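# Open-ended, steady-state genetic evolution of prey rule bases
# (Pittsburgh coding: the chromosome is the whole variable-length rule
# base).  The operators are shared with the C++ engine.

#' Evolutionary process configuration
#'
#' @param total_steps default length of an evolutionary run in update
#'   steps.
#' @param rule_base_upper_bound maximum number of rules per rule base.
#' @param antecedents_upper_bound maximum antecedents per rule.
#' @param mutation_probability per-offspring probability that a mutation
#'   (rule addition or removal, equally likely) occurs.
#' @param add_rules_upper_bound maximum rules added by one add-mutation.
#' @param remove_rules_upper_bound maximum rules removed by one
#'   remove-mutation.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(total_steps = 1e7, rule_base_upper_bound = 50,
                             antecedents_upper_bound = 4,
                             mutation_probability = 0.02,
                             add_rules_upper_bound = 3,
                             remove_rules_upper_bound = 3) {
  stopifnot(total_steps > 0, rule_base_upper_bound >= 1,
            antecedents_upper_bound >= 1,
            mutation_probability >= 0, mutation_probability <= 1,
            add_rules_upper_bound >= 1, remove_rules_upper_bound >= 1)
  structure(as.list(environment()), class = "evolution_config")
}

#' Generate a random fuzzy rule
#'
#' Antecedent count uniform on 1..`antecedents_upper_bound`; variables
#' sampled uniformly without replacement from the 8 input variables; one
#' value per variable uniform over that variable's linguistic values;
#' consequent uniform over the 5 heading-change values.
#'
#' @param evo_cfg an [evolution_config()].
#' @return A `fuzzy_rule`.
#' @export
random_rule <- function(evo_cfg = evolution_config()) {
  .rule_decode(cpp_random_rule(evo_cfg$antecedents_upper_bound)[1, ])
}

#' Generate a random rule base
#'
#' Length uniform on 1..`rule_base_upper_bound`; rules i.i.d. from
#' [random_rule()].
#'
#' @param evo_cfg an [evolution_config()].
#' @return A `fuzzy_rulebase`.
#' @export
random_rule_base <- function(evo_cfg = evolution_config()) {
  .rb_decode(cpp_random_rulebase(evo_cfg$rule_base_upper_bound,
                                 evo_cfg$antecedents_upper_bound))
}

#' Fitness-proportional parent selection
#'
#' Draws two distinct indices with probability proportional to energy
#' (fitness is survivability, assessed via the current energy level); the
#' second draw excludes the first.
#'
#' @param energies positive numeric vector of current energy levels.
#' @return Integer vector of two distinct indices.
#' @export
select_parents <- function(energies) {
  if (length(energies) < 2)
    stop("parent selection needs at least two live agents", call. = FALSE)
  if (any(energies <= 0))
    stop("energies must be positive", call. = FALSE)
  cpp_select_parents(as.numeric(energies))
}

#' Joint-set crossover of two rule bases
#'
#' The offspring length is uniform on 1..`min(|a| + |b|, cap)` and its
#' rules are sampled uniformly without replacement from the joint multiset
#' of the parents' rules.
#'
#' @param a,b parent `fuzzy_rulebase` objects.
#' @param cap rule-base upper bound.
#' @return An offspring `fuzzy_rulebase`.
#' @export
crossover_rule_bases <- function(a, b, cap = 50) {
  .rb_decode(cpp_crossover(.rb_encode(a), .rb_encode(b), cap))
}

#' Mutate a rule base
#'
#' With probability `mutation_probability`, either adds 1..`add` fresh
#' random rules (truncated at `cap` rules) or removes 1..`remove`
#' uniformly chosen rules (never dropping below one rule); the branch is
#' chosen with equal probability.  Otherwise the rule base is returned
#' unchanged.
#'
#' @param rb a `fuzzy_rulebase`.
#' @param evo_cfg an [evolution_config()].
#' @return A `fuzzy_rulebase`.
#' @export
mutate_rule_base <- function(rb, evo_cfg = evolution_config()) {
  .rb_decode(cpp_mutate(.rb_encode(rb), evo_cfg$mutation_probability,
                        evo_cfg$add_rules_upper_bound,
                        evo_cfg$remove_rules_upper_bound,
                        evo_cfg$rule_base_upper_bound,
                        evo_cfg$antecedents_upper_bound))
}

#' Run an open-ended evolutionary simulation
#'
#' Initializes `n_prey` agents with random rule bases at uniform random
#' points on the spawn disc, then runs the world with steady-state genetic
#' replacement: every dead prey (captured or out of energy) is replaced by
#' the mutated joint-set crossover of two energy-proportionally selected
#' live parents.  The end-of-run pool of rule bases is the evolved
#' behaviour.
#'
#' @param cfg a [world_config()].
#' @param evo_cfg an [evolution_config()].
#' @param steps run length (defaults to `evo_cfg$total_steps`).
#' @param record_every snapshot interval for the periodic metric log.
#' @param record_events keep the per-event log (memory-heavy on long runs).
#' @return A `flock_evolution` list: `pool` (the n_prey evolved rule
#'   bases), the final `state`, `snapshots`, `counts` and configurations.
#' @export
run_evolution <- function(cfg = world_config(),
                          evo_cfg = evolution_config(),
                          steps = evo_cfg$total_steps,
                          record_every = max(1, floor(steps / 200)),
                          record_events = FALSE) {
  sim <- simulate_world(cfg, steps = steps, mode = "evolve",
                        evo_cfg = evo_cfg, record_every = record_every,
                        record_events = record_events)
  structure(list(pool = sim$state$rule_bases, state = sim$state,
                 snapshots = sim$snapshots, counts = sim$counts,
                 events = sim$events, cfg = cfg, evo_cfg = evo_cfg,
                 steps = steps),
            class = "flock_evolution")
}

#' @export
print.flock_evolution <- function(x, ...) {
  sizes <- lengths(x$pool)
  cat(sprintf("<flock_evolution: %d steps, pool of %d rule bases>\n",
              x$steps, length(x$pool)))
  cat(sprintf("rule-base sizes: min %d / median %g / max %d\n",
              min(sizes), median(sizes), max(sizes)))
  cat("counts:", paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
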