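# Plain-text import/export: delimited grids with JSON sidecars, trajectory
# CSVs, and key-value (YAML/JSON) run configurations.

#' Write / read a payoff grid as CSV plus JSON sidecar
#'
#' The payoff matrix is written as a headerless CSV (one grid row per line);
#' generation metadata (kind, seed, dimensions) goes to `<path>.json`.
#'
#' @param grid A `payoff_grid`.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `write_landscape` returns `path` invisibly; `read_landscape`
#'   returns a `payoff_grid`.
#' @export
write_landscape <- function(grid, path) {
  stopifnot(inherits(grid, "payoff_grid"))
  utils::write.table(grid$payoff, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(type = "payoff_grid", kind = grid$kind, width = grid$width,
               height = grid$height, seed = grid$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  new_payoff_grid(m,
                  kind = if (is.null(meta$kind)) "complex" else meta$kind,
                  seed = meta$seed)
}

#' Write / read a skill grid as CSV plus JSON sidecar
#'
#' @param skills A `skill_grid`.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `write_skill_grid` returns `path` invisibly; `read_skill_grid`
#'   returns a `skill_grid`.
#' @export
write_skill_grid <- function(skills, path) {
  stopifnot(inherits(skills, "skill_grid"))
  utils::write.table(skills$skill, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(type = "skill_grid", s = skills$s, width = skills$width,
               height = skills$height, seed = skills$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_skill_grid
#' @export
read_skill_grid <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  s <- if (is.null(meta$s)) max(m) else meta$s
  structure(list(skill = m, width = ncol(m), height = nrow(m),
                 s = as.integer(s), seed = meta$seed),
            class = "skill_grid")
}

#' Export a trajectory as a long CSV
#'
#' Columns: `run_id`, `step`, `agent_id`, `payoff`, and `row`/`col` when the
#' run recorded positions.
#'
#' @param traj A `trajectory`.
#' @param path Output CSV path.
#' @param run_id Identifier written to the `run_id` column.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, run_id = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  steps <- nrow(traj$payoffs)
  n <- ncol(traj$payoffs)
  df <- data.frame(
    run_id = run_id,
    step = rep(0:(steps - 1L), times = n),
    agent_id = rep(seq_len(n), each = steps),
    payoff = as.vector(traj$payoffs)
  )
  if (!is.null(traj$positions)) {
    df$row <- as.vector(traj$positions$row)
    df$col <- as.vector(traj$positions$col)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

config_to_list <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sched <- unclass(config$schedule)
  list(
    n = config$n, s = config$s, r = config$params$r,
    width = config$width, height = config$height,
    landscape_kind = config$landscape_kind,
    network = config$network, density = config$density,
    schedule = sched,
    max_steps = config$max_steps, horizon = config$horizon,
    noise = unclass(config$noise), signal_variance = config$signal_variance,
    record_positions = config$record_positions, seed = config$seed
  )
}

config_from_list <- function(x) {
  sched <- x$schedule
  schedule <- if (is.null(sched)) {
    mode_schedule("constant_p", p = 0.5)
  } else if (identical(sched$kind, "phase")) {
    mode_schedule("phase", k = sched$k,
                  total_rounds = if (is.null(sched$total_rounds)) 10L
                                 else sched$total_rounds)
  } else {
    mode_schedule("constant_p", p = sched$p)
  }
  args <- list(
    schedule = schedule,
    noise = if (is.null(x$noise)) noise_spec() else do.call(noise_spec, x$noise)
  )
  for (f in c("n", "s", "r", "width", "height", "landscape_kind", "network",
              "density", "max_steps", "horizon", "signal_variance",
              "record_positions", "seed")) {
    if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  }
  do.call(simulation_config, args)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Top-level keys mirror [simulation_config()] arguments; the schedule is a
#' nested mapping, e.g. `schedule: {kind: constant_p, p: 0.5}` or
#' `schedule: {kind: phase, k: 3, total_rounds: 10}`.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop_param("config file must be .json, .yaml or .yml")
  )
  config_from_list(x)
}

#' Write a simulation configuration to a YAML or JSON file
#'
#' @param config A [simulation_config()].
#' @param path Destination ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- config_to_list(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null"),
    yaml = ,
    yml = yaml::write_yaml(x, path),
    stop_param("config file must be .json, .yaml or .yml")
  )
  invisible(path)
}
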