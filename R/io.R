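# Run configuration, manifests and snapshot plotting.

#' Assemble a full run configuration
#'
#' Bundles the world, evolution and validation configurations with the run
#' seed and output sampling interval.  The defaults reproduce the model's
#' standard parameterization; any field can be overridden.
#'
#' @param world a [world_config()].
#' @param evolution an [evolution_config()].
#' @param validation a [validation_config()].
#' @param seed integer RNG seed for the run.
#' @param record_every snapshot sampling interval in steps.
#' @return A `run_config` list.
#' @export
run_config <- function(world = world_config(),
                       evolution = evolution_config(),
                       validation = validation_config(),
                       seed = 1L, record_every = 1000L) {
  structure(list(world = world, evolution = evolution,
                 validation = validation, seed = as.integer(seed),
                 record_every = as.integer(record_every)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' The load -> dump -> load round trip is lossless; unknown fields are
#' rejected so that typos in hand-edited configs fail loudly, with the
#' offending field path in the message.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(lapply(config, unclass)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(section, ctor, where) {
    known <- names(formals(ctor))
    extra <- setdiff(names(section), known)
    if (length(extra) > 0)
      stop("unknown config field: ", where, "$", extra[1], call. = FALSE)
    do.call(ctor, section)
  }
  run_config(
    world = build(obj$world, world_config, "world"),
    evolution = build(obj$evolution, evolution_config, "evolution"),
    validation = build(obj$validation, validation_config, "validation"),
    seed = obj$seed %||% 1L,
    record_every = obj$record_every %||% 1000L
  )
}

#' Hash a configuration for provenance manifests
#'
#' 64-bit FNV-1a hash of the JSON serialization, printed as hex.  Stable
#' across sessions, used to tie artifacts (pools, metric tables) back to
#' the exact configuration that produced them.
#'
#' @param config any jsonlite-serializable object.
#' @return A 16-character hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(lapply(config, unclass)), auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s)) %% 256
  # 32-bit FNV-1a carried in doubles (exact below 2^53); the xor only
  # touches the low byte, the multiply is split into 16-bit halves
  fnv32 <- function(seed) {
    h <- seed
    for (b in bytes) {
      low <- h %% 256
      h <- h - low + bitwXor(as.integer(low), as.integer(b))
      h <- (h %% 65536) * 16777619 +
        (((h %/% 65536) * 16777619) %% 65536) * 65536
      h <- h %% 4294967296
    }
    h
  }
  word <- function(v) sprintf("%04x%04x", v %/% 65536, v %% 65536)
  paste0(word(fnv32(2166136261)), word(fnv32(2654435769)))
}

#' Write a run manifest
#'
#' Records the seed, step count, configuration hash and package version
#' next to a produced artifact, making it traceable.
#'
#' @param path file path for the manifest JSON.
#' @param config the [run_config()] used.
#' @param steps steps actually run.
#' @param extra named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, steps, extra = list()) {
  obj <- c(list(seed = config$seed, steps = steps,
                config_hash = config_hash(config),
                package = as.character(packageVersion("fuzzyflock")),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot one recorded step of a trajectory
#'
#' 2D scatter of all agents with heading quivers, the living-area square,
#' and prey coloured by interaction group (stragglers grey); predators are
#' drawn as red triangles.  Requires ggplot2.
#'
#' @param traj a trajectory data frame ([as_trajectory()],
#'   [read_trajectory()]).
#' @param step the step to plot (must be present in `traj`).
#' @param perception grouping radius for the colour coding.
#' @param living_area_side side of the living-area square to draw.
#' @param quiver_length arrow length in world units.
#' @return A ggplot object.
#' @export
plot_snapshot <- function(traj, step, perception = 100,
                          living_area_side = 375, quiver_length = 8) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_snapshot requires the ggplot2 package", call. = FALSE)
  rows <- traj[traj$step == step, ]
  if (nrow(rows) == 0)
    stop("step ", step, " not present; available: ",
         paste(range(traj$step), collapse = "-"), call. = FALSE)
  prey <- rows[rows$kind == "prey", ]
  pred <- rows[rows$kind == "predator", ]
  gp <- find_groups(as.matrix(prey[, c("x", "y")]), perception)
  grp <- as.character(gp$membership)
  grp[gp$stragglers] <- "straggler"
  prey$group <- grp
  half <- living_area_side / 2
  square <- data.frame(x = c(-half, half, half, -half, -half),
                       y = c(-half, -half, half, half, -half))
  rad <- pi / 180
  prey$xend <- prey$x + quiver_length * cos(prey$heading * rad)
  prey$yend <- prey$y - quiver_length * sin(prey$heading * rad)
  gg <- ggplot2::ggplot(prey, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = square, colour = "grey40",
                       inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$xend, yend = .data$yend,
                                       colour = .data$group),
                          linewidth = 0.3,
                          arrow = grid::arrow(length = grid::unit(3, "pt"))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("step %d", step), x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (nrow(pred) > 0)
    gg <- gg + ggplot2::geom_point(data = pred, colour = "red", shape = 17,
                                   size = 2, inherit.aes = FALSE,
                                   ggplot2::aes(x = .data$x, y = .data$y))
  gg
}
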