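# Scripted scenes: geometric fixtures exercising the metrics and the
# inference engine without running evolution.

.new_scene <- function(positions, headings, predator = NULL,
                       rule_base = NULL) {
  stopifnot(nrow(positions) == length(headings),
            all(is.finite(positions)), all(is.finite(headings)))
  structure(list(positions = positions, headings = .wrap180(headings),
                 predator = predator, rule_base = rule_base),
            class = "scripted_scene")
}

#' Scripted scene: parallel lane
#'
#' A square-ish lattice of agents with identical headings -- the polarized
#' (P) regime: polarization 1, rotation ~ 0.
#'
#' @param n number of agents (>= 2).
#' @param spacing lattice spacing.
#' @param heading shared heading in degrees.
#' @return A `scripted_scene`.
#' @export
make_parallel <- function(n, spacing = 10, heading = 0) {
  stopifnot(n >= 2)
  ncol <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1
  pos <- cbind((idx %% ncol) * spacing, (idx %/% ncol) * spacing)
  .new_scene(pos, rep(heading, n))
}

#' Scripted scene: tangential ring (mill)
#'
#' Agents evenly spaced on a circle with tangential headings of a common
#' sense -- the milling (M) regime: rotation 1, polarization 0 (the
#' tangential unit vectors cancel).
#'
#' @param n number of agents (>= 3).
#' @param radius ring radius.
#' @param sense +1 or -1, the milling direction.
#' @return A `scripted_scene`.
#' @export
make_mill <- function(n, radius = 50, sense = 1) {
  stopifnot(n >= 3, sense %in% c(-1, 1))
  phi <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(radius * cos(phi), radius * sin(phi))
  vx <- -sin(phi) * sense
  vy <- cos(phi) * sense
  headings <- .wrap180(atan2(-vy, vx) * 180 / pi)
  .new_scene(pos, headings)
}

#' Scripted scene: random blob (swarm)
#'
#' Agents uniform on a disc with i.i.d. uniform headings -- the swarm (S)
#' regime: both order parameters shrink as `1/sqrt(n)`.
#'
#' @param n number of agents (>= 2).
#' @param radius disc radius.
#' @return A `scripted_scene`.
#' @export
make_swarm <- function(n, radius = 100) {
  stopifnot(n >= 2)
  r <- radius * sqrt(runif(n))
  phi <- runif(n) * 2 * pi
  pos <- cbind(r * cos(phi), r * sin(phi))
  .new_scene(pos, runif(n, -180, 180))
}

#' Scripted scene: single prey with a pursuing predator
#'
#' One prey at the origin heading along +x, one predator placed so that
#' its relative bearing from the prey is exactly `bearing` (default -126,
#' rearward left) at the given distance, plus the two-rule escape base
#' {predator bearing left -> turn right; predator bearing behind -> no
#' turn} whose inference on the default scene defuzzifies to 54.375
#' degrees.
#'
#' @param bearing predator relative bearing in degrees.
#' @param distance predator distance (must be below the prey perception
#'   distance to be perceived).
#' @return A `scripted_scene` with a `predator` pose and a `rule_base`.
#' @export
make_pursuit_scene <- function(bearing = -126, distance = 50) {
  phi <- -bearing * pi / 180  # clockwise bearing -> math angle
  pos <- distance * c(cos(phi), sin(phi))
  predator <- list(x = pos[1], y = pos[2],
                   heading = .wrap180(atan2(-(-pos[2]), -pos[1]) * 180 / pi))
  rb <- rule_base(list(
    fuzzy_rule(c(predator.relative_bearing = "left"), "right"),
    fuzzy_rule(c(predator.relative_bearing = "behind"), "none")
  ))
  .new_scene(matrix(0, 1, 2), 0, predator = predator, rule_base = rb)
}

#' Convert a scripted scene to a world state
#'
#' Embeds the scene in a full `world_state` (all agents at full energy,
#' shared rule base if the scene carries one) so it can be stepped through
#' the simulator or analysed with the metric tools.
#'
#' @param scene a `scripted_scene`.
#' @param cfg a [world_config()]; `n_prey` is overridden by the scene
#'   size.
#' @param rule_base rule base assigned to every agent (defaults to the
#'   scene's own, or a single no-turn rule).
#' @return A list with the adjusted `cfg` and the `world_state`.
#' @export
scene_to_state <- function(scene, cfg = world_config(), rule_base = NULL) {
  n <- nrow(scene$positions)
  cfg$n_prey <- n
  rb <- rule_base %||% scene$rule_base %||%
    rule_base(fuzzy_rule(c(interaction.distance = "far"), "none"))
  state <- init_world(cfg, pool = rep(list(rb), n),
                      positions = scene$positions,
                      headings = scene$headings)
  if (!is.null(scene$predator) && cfg$n_predators > 0) {
    np <- cfg$n_predators
    state$predators$active[1] <- TRUE
    state$predators$x[1] <- scene$predator$x
    state$predators$y[1] <- scene$predator$y
    state$predators$heading[1] <- scene$predator$heading
    state$predators$hunt_left[1] <- cfg$hunt_duration
    state$predators$next_entry <- rep(Inf, np)
    state$predators$next_entry[1] <- 0
  }
  list(cfg = cfg, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a scripted scene to a trajectory table
#'
#' Emits the same trajectory dialect as the simulator, so the metric tools
#' are agnostic to data origin.
#'
#' @param scene a `scripted_scene`.
#' @param step step label for all rows.
#' @return A data frame `step, id, kind, tactic, x, y, heading, energy`.
#' @export
scene_to_trajectory <- function(scene, step = 0) {
  n <- nrow(scene$positions)
  df <- data.frame(step = step, id = seq_len(n), kind = "prey",
                   tactic = NA_character_, x = scene$positions[, 1],
                   y = scene$positions[, 2], heading = scene$headings,
                   energy = NA_real_)
  if (!is.null(scene$predator)) {
    df <- rbind(df, data.frame(step = step, id = -1L, kind = "predator",
                               tactic = NA_character_, x = scene$predator$x,
                               y = scene$predator$y,
                               heading = scene$predator$heading,
                               energy = NA_real_))
  }
  df
}

#' Write / read a trajectory CSV
#'
#' Plain CSV with columns `step, id, kind, tactic, x, y, heading, energy`,
#' one row per agent per recorded step.
#'
#' @param traj a trajectory data frame.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the data frame.
#' @export
write_trajectory <- function(traj, path) {
  num <- vapply(traj, is.numeric, logical(1))
  traj[num] <- lapply(traj[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 17, scientific = FALSE,
                                trim = TRUE))
  })
  write.csv(traj, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("step", "id", "kind", "tactic", "x", "y", "heading", "energy")
  if (!all(need %in% names(df)))
    stop("not a trajectory CSV: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df[need]
}
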