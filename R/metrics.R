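# Order parameters for collective motion, interaction-graph grouping,
# state classification, time-in-state accounting, local density, bootstrap
# CIs, and the validation protocol.

.unit_velocities <- function(headings) {
  cbind(cos(headings * pi / 180), -sin(headings * pi / 180))
}

#' Polarization order parameter
#'
#' Norm of the mean unit direction vector of a group,
#' `p = |1/n * sum(v_i)|`: 1 when all individuals are aligned, near 0 for
#' incoherent headings.
#'
#' @param headings numeric vector of headings in degrees.
#' @return Polarization in `[0, 1]`.
#' @export
polarization <- function(headings) {
  v <- .unit_velocities(headings)
  sqrt(sum(colMeans(v)^2))
}

#' Rotation (milling) order parameter
#'
#' Absolute value of the mean cross product of the unit vector from the
#' group centroid to each agent with the agent's unit velocity,
#' `m = |1/n * sum(c_i x v_i)|`: 1 for a perfect mill, near 0 otherwise.
#' An agent exactly on the centroid contributes 0.
#'
#' @param positions n x 2 matrix of positions.
#' @param headings numeric vector of headings in degrees.
#' @return Rotation in `[0, 1]`.
#' @export
rotation <- function(positions, headings) {
  v <- .unit_velocities(headings)
  ctr <- colMeans(positions)
  cx <- positions[, 1] - ctr[1]
  cy <- positions[, 2] - ctr[2]
  nrm <- sqrt(cx^2 + cy^2)
  ok <- nrm > 1e-12
  cross <- numeric(length(nrm))
  cross[ok] <- (cx[ok] * v[ok, 2] - cy[ok] * v[ok, 1]) / nrm[ok]
  abs(mean(cross))
}

#' Partition prey into interaction groups
#'
#' Groups are the connected components of the graph linking prey whose
#' distance is strictly below the perception distance: agents that can
#' influence each other directly or indirectly belong to the same group.
#' Singleton components are stragglers, excluded from local-scale
#' analysis.
#'
#' @param positions n x 2 matrix of prey positions.
#' @param perception perception distance.
#' @return A `group_partition`: list with `membership` (component label per
#'   agent), `groups` (list of index vectors, size >= 2) and `stragglers`
#'   (index vector).
#' @export
find_groups <- function(positions, perception = 100) {
  lab <- cpp_group_labels(positions[, 1], positions[, 2], perception)
  comp <- split(seq_along(lab), lab)
  sizes <- lengths(comp)
  structure(list(
    membership = lab,
    groups = unname(comp[sizes >= 2]),
    stragglers = unlist(unname(comp[sizes == 1]), use.names = FALSE)
  ), class = "group_partition")
}

#' Classify a group's collective state
#'
#' Threshold classification on (polarization, rotation): polar `"P"` when
#' `p > 0.65` and `m < 0.35`; milling `"M"` when `p < 0.35` and
#' `m > 0.65`; swarm `"S"` when both are below 0.35; transition `"T"`
#' otherwise.
#'
#' @param p polarization in `[0, 1]` (vectorized).
#' @param m rotation in `[0, 1]`.
#' @return Character vector over `"P"`, `"M"`, `"S"`, `"T"`.
#' @export
classify_state <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), all(m >= 0 & m <= 1))
  out <- rep("T", length(p))
  out[p > 0.65 & m < 0.35] <- "P"
  out[p < 0.35 & m > 0.65] <- "M"
  out[p < 0.35 & m < 0.35] <- "S"
  out
}

#' Local density
#'
#' Per-agent count of conspecifics within `radius` (default: the prey
#' perception distance) and the population mean.  The measure is a simple
#' neighbour count; pass any function of `positions` via `measure` to plug
#' in an alternative.
#'
#' @param positions n x 2 matrix of positions.
#' @param radius neighbourhood radius.
#' @param measure optional replacement: a function `(positions, radius)`
#'   returning per-agent densities.
#' @return List with `counts` (per agent) and `mean`.
#' @export
local_density <- function(positions, radius = 100, measure = NULL) {
  counts <- if (is.null(measure)) {
    cpp_neighbour_counts(positions[, 1], positions[, 2], radius)
  } else {
    measure(positions, radius)
  }
  list(counts = counts, mean = mean(counts))
}

#' Time spent in each collective state
#'
#' Each update step contributes a total weight of 1, split equally across
#' the groups present at that step (three groups: one third each); steps
#' with no groups are dropped from the denominator.
#'
#' @param states_by_step list with one character vector of group state
#'   labels (`"P"`, `"M"`, `"S"`, `"T"`) per step.
#' @return Named numeric vector of fractions over P, M, S, T (sums to 1).
#' @export
state_time_proportions <- function(states_by_step) {
  acc <- c(P = 0, M = 0, S = 0, T = 0)
  counted <- 0
  for (st in states_by_step) {
    k <- length(st)
    if (k == 0) next
    counted <- counted + 1
    for (s in st) acc[s] <- acc[s] + 1 / k
  }
  if (counted == 0) stop("no step with at least one group", call. = FALSE)
  acc / counted
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param x numeric sample.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param conf confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(x, n_boot = 10000, conf = 0.95) {
  stopifnot(length(x) >= 1)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(x[sample.int(length(x), replace = TRUE)]),
                  numeric(1))
  alpha <- (1 - conf) / 2
  unname(quantile(means, c(alpha, 1 - alpha)))
}

# Per-snapshot metric rows: one GLOBAL row plus one row per group.
.snapshot_metrics <- function(positions, headings, perception, step,
                              replicate = NA_integer_) {
  gp <- find_groups(positions, perception)
  ld <- local_density(positions, perception)
  ngr <- length(gp$groups)
  gp_rows <- lapply(seq_len(ngr), function(g) {
    idx <- gp$groups[[g]]
    p <- polarization(headings[idx])
    m <- rotation(positions[idx, , drop = FALSE], headings[idx])
    data.frame(replicate = replicate, step = step, group_id = as.character(g),
               n_members = length(idx), polarization = p, rotation = m,
               state = classify_state(p, m), mean_local_density = ld$mean,
               n_groups = ngr)
  })
  p <- polarization(headings)
  m <- rotation(positions, headings)
  glob <- data.frame(replicate = replicate, step = step, group_id = "GLOBAL",
                     n_members = nrow(positions), polarization = p,
                     rotation = m, state = classify_state(p, m),
                     mean_local_density = ld$mean, n_groups = ngr)
  do.call(rbind, c(list(glob), gp_rows))
}

#' Per-step collective-motion metrics from recorded snapshots
#'
#' For every recorded step: global polarization/rotation/state (all prey as
#' one group, stragglers included), per-group metrics for each interaction
#' group, mean local density and the group count.
#'
#' @param sim a `flock_sim` (or `flock_evolution`) with recorded snapshots.
#' @param perception grouping/density radius (default: prey perception of
#'   the run's configuration).
#' @param replicate replicate label attached to every row.
#' @return A data frame with columns `replicate, step, group_id, n_members,
#'   polarization, rotation, state, mean_local_density, n_groups`.
#' @export
trajectory_metrics <- function(sim, perception = sim$cfg$prey_perception,
                               replicate = NA_integer_) {
  sn <- sim$snapshots
  rows <- lapply(seq_along(sn$step), function(k) {
    p <- sn$prey[[k]]
    .snapshot_metrics(p[, 2:3, drop = FALSE], p[, 4], perception,
                      sn$step[k], replicate)
  })
  do.call(rbind, rows)
}

#' Validation protocol configuration
#'
#' @param replicates number of validation replicates.
#' @param stabilisation steps before recording starts.
#' @param predator_introduction step at which the predator enters.
#' @param total total run length in steps.
#' @return A `validation_config` list.
#' @export
validation_config <- function(replicates = 20, stabilisation = 900,
                              predator_introduction = 1800, total = 3600) {
  stopifnot(replicates >= 1, stabilisation < predator_introduction,
            predator_introduction < total)
  structure(as.list(environment()), class = "validation_config")
}

#' Validate an evolved behaviour pool
#'
#' Runs `replicates` independent simulations of a frozen pool: prey are
#' placed at random on the spawn disc with random headings, evolution is
#' disabled (dead prey draw a rule base uniformly from the pool), metrics
#' are recorded from the end of the stabilisation period, and a single
#' predator (tactic drawn uniformly per replicate unless pinned) enters at
#' the introduction step.
#'
#' @param pool list of `fuzzy_rulebase` (an evolved pool).
#' @param cfg a [world_config()]; the predator complement is reduced to
#'   one.
#' @param val_cfg a [validation_config()].
#' @param fixed_tactic optionally pin the predator tactic (name or 0-3).
#' @param init optional list with `positions` and `headings` to override
#'   the random placement (applied to every replicate).
#' @return A `flock_validation` list: `metrics` (per-step data frame over
#'   all replicates, with `phase` pre/post predator) and `summary` (means,
#'   bootstrap CIs, state-time proportions per phase, behaviour class).
#' @export
run_validation <- function(pool, cfg = world_config(),
                           val_cfg = validation_config(),
                           fixed_tactic = NULL, init = NULL) {
  stopifnot(length(pool) >= 1)
  cfg$n_predators <- 1L
  all_rows <- vector("list", val_cfg$replicates)
  for (r in seq_len(val_cfg$replicates)) {
    tactic <- if (is.null(fixed_tactic)) sample(0:3, 1) else fixed_tactic
    state <- init_world(cfg, pool = pool, positions = init$positions,
                        headings = init$headings,
                        predator_start = val_cfg$predator_introduction,
                        predator_immediate = TRUE)
    sim <- simulate_world(cfg, steps = val_cfg$total, mode = "frozen",
                          pool = pool, state = state, record_every = 1,
                          record_start = val_cfg$stabilisation,
                          fixed_tactic = tactic)
    all_rows[[r]] <- trajectory_metrics(sim, replicate = r)
  }
  metrics <- do.call(rbind, all_rows)
  metrics$phase <- ifelse(metrics$step < val_cfg$predator_introduction,
                          "no_predator", "predator")
  summary <- .validation_summary(metrics)
  structure(list(metrics = metrics, summary = summary, cfg = cfg,
                 val_cfg = val_cfg),
            class = "flock_validation")
}

.phase_summary <- function(mm) {
  glob <- mm[mm$group_id == "GLOBAL", ]
  by_step <- glob[!duplicated(glob[c("replicate", "step")]), ]
  states <- split(mm$state[mm$group_id != "GLOBAL"],
                  interaction(mm$replicate[mm$group_id != "GLOBAL"],
                              mm$step[mm$group_id != "GLOBAL"], drop = TRUE))
  props <- tryCatch(state_time_proportions(states),
                    error = function(e) c(P = NA, M = NA, S = NA, T = NA))
  list(
    mean_local_density = mean(by_step$mean_local_density),
    local_density_ci = bootstrap_ci(by_step$mean_local_density, 1000),
    mean_n_groups = mean(by_step$n_groups),
    n_groups_ci = bootstrap_ci(by_step$n_groups, 1000),
    state_time = props
  )
}

.validation_summary <- function(metrics) {
  phases <- lapply(split(metrics, metrics$phase), .phase_summary)
  cls <- NA_character_
  pre <- phases[["no_predator"]]
  if (!is.null(pre) && !anyNA(pre$state_time)) {
    top <- names(which.max(pre$state_time))
    cls <- if (top == "T") "D" else top
  }
  c(phases, list(behaviour_class = cls))
}

#' @export
print.flock_validation <- function(x, ...) {
  s <- x$summary
  cat("<flock_validation>\n")
  for (ph in setdiff(names(s), "behaviour_class")) {
    cat(sprintf(
      "  %s: local density %.2f [%.2f, %.2f], groups %.2f, state time P=%.2f M=%.2f S=%.2f T=%.2f\n",
      ph, s[[ph]]$mean_local_density, s[[ph]]$local_density_ci[1],
      s[[ph]]$local_density_ci[2], s[[ph]]$mean_n_groups,
      s[[ph]]$state_time["P"], s[[ph]]$state_time["M"],
      s[[ph]]$state_time["S"], s[[ph]]$state_time["T"]))
  }
  cat("  behaviour class:", s$behaviour_class, "\n")
  invisible(x)
}

#' Group-size experiment
#'
#' Relationship between group size and behaviour stability: for each size,
#' runs predator-free replicates whose rule bases are drawn at random from
#' the pool, and records global polarization and rotation over the
#' post-stabilisation window.
#'
#' @param pool list of `fuzzy_rulebase`.
#' @param sizes numbers of prey agents to test.
#' @param replicates replicates per size.
#' @param cfg a [world_config()].
#' @param steps run length per replicate.
#' @param record_start first recorded step.
#' @return A data frame `size, replicate, step, polarization, rotation`.
#' @export
group_size_experiment <- function(pool, sizes = c(30, 70, 150, 300),
                                  replicates = 20, cfg = world_config(),
                                  steps = 1800, record_start = 900) {
  rows <- list()
  for (n in sizes) {
    wc <- cfg
    wc$n_prey <- as.integer(n)
    wc$n_predators <- 0L
    for (r in seq_len(replicates)) {
      sim <- simulate_world(wc, steps = steps, mode = "frozen", pool = pool,
                            record_every = 1, record_start = record_start)
      sn <- sim$snapshots
      p <- vapply(sn$prey, function(m) polarization(m[, 4]), numeric(1))
      m <- vapply(sn$prey, function(mm)
        rotation(mm[, 2:3, drop = FALSE], mm[, 4]), numeric(1))
      rows[[length(rows) + 1]] <-
        data.frame(size = n, replicate = r, step = sn$step,
                   polarization = p, rotation = m)
    }
  }
  do.call(rbind, rows)
}
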