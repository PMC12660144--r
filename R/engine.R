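# Asynchronous update dynamics.
#
# Each time step draws a fresh uniform permutation of the agents and updates
# them sequentially, so later agents see the new positions of earlier ones.
# When an agent updates it either collaborates (probability p, or during the
# first k rounds of a phase schedule) or copies. It then moves to the
# highest-payoff cell of its candidate set if — and only if — that payoff
# strictly exceeds its current one; ties among maxima are broken uniformly
# at random. A constant-p run terminates after the first step in which no
# agent moves; a phase run lasts exactly `total_rounds` steps.
#
# RNG contract (what the dynamics stream is consumed for, in order): one
# permutation per step; for constant_p schedules one uniform per agent
# update (drawn even when p is 0 or 1, so trajectories for different p are
# comparable under matched seeds); one extra draw per update only when an
# improving move has 2+ distinct tied maxima (picked uniformly from the
# tied cells sorted by column-major linear index, so the choice does not
# depend on candidate enumeration order). Reference implementations must
# follow the same order to reproduce trajectories.

#' Mode schedule: constant collaboration rate or collaborate-then-copy
#'
#' `constant_p` draws the communication mode independently at every agent
#' update: collaborate with probability `p`, copy with probability `1 - p`.
#' `phase` is deterministic: all agents collaborate for the first `k` rounds
#' and copy for the remaining `total_rounds - k` rounds.
#'
#' @param kind `"constant_p"` or `"phase"`.
#' @param p Collaboration probability in `[0, 1]` (constant_p).
#' @param k Number of collaboration rounds (phase), `0 <= k <= total_rounds`.
#' @param total_rounds Fixed horizon of a phase run (default 10).
#' @return An object of class `mode_schedule`.
#' @export
#' @examples
#' mode_schedule("constant_p", p = 0.5)
#' mode_schedule("phase", k = 3)
mode_schedule <- function(kind = c("constant_p", "phase"), p = NULL, k = NULL,
                          total_rounds = 10L) {
  kind <- match.arg(kind)
  if (kind == "constant_p") {
    if (is.null(p)) stop_param("constant_p schedule requires `p`")
    p <- check_prob(p, "p")
    sched <- list(kind = kind, p = p)
  } else {
    if (is.null(k)) stop_param("phase schedule requires `k`")
    total_rounds <- check_count(total_rounds, "total_rounds", min = 1L)
    k <- check_count(k, "k", min = 0L)
    if (k > total_rounds) stop_param("`k` must not exceed `total_rounds`")
    sched <- list(kind = kind, k = k, total_rounds = total_rounds)
  }
  structure(sched, class = "mode_schedule")
}

#' Simulation configuration
#'
#' Bundles every model parameter of a single run. Defaults are the headline
#' parameterization: 16 agents with 100 skill types and perception radius 6
#' searching a complex 100 x 100 landscape.
#'
#' @param n Group size (default 16).
#' @param s Number of skill types (default 100).
#' @param r Perception radius (default 6).
#' @param width,height Grid dimensions (default 100 x 100).
#' @param landscape_kind `"complex"` (signal + Perlin noise) or `"simple"`
#'   (single Gaussian bump).
#' @param network `"path"`, `"complete"`, `"edgeless"` (individual
#'   baseline), or `"density"` (path randomly densified to `density`).
#' @param density Target density when `network = "density"`.
#' @param schedule A [mode_schedule()].
#' @param max_steps Safety cap on steps for constant_p runs (default 1000;
#'   strict-improvement moves guarantee termination long before this).
#' @param horizon Reporting horizon: per-step summaries are padded with
#'   final values up to this step so runs of different lengths average
#'   cleanly (default 50).
#' @param noise A [noise_spec()] for complex landscapes.
#' @param signal_variance Gaussian signal variance for complex landscapes
#'   (default 3).
#' @param record_positions Keep the full position history in the trajectory.
#' @param seed Master seed; spawns independent substreams for the
#'   landscape, skill grid, network, agent initialization and dynamics.
#'   `NULL` draws a master seed from the current RNG.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n = 16L, s = 100L, r = 6, width = 100L,
                              height = 100L,
                              landscape_kind = c("complex", "simple"),
                              network = c("path", "complete", "edgeless", "density"),
                              density = NULL,
                              schedule = mode_schedule("constant_p", p = 0.5),
                              max_steps = 1000L, horizon = 50L,
                              noise = noise_spec(), signal_variance = 3,
                              record_positions = FALSE, seed = NULL) {
  landscape_kind <- match.arg(landscape_kind)
  network <- match.arg(network)
  n <- check_count(n, "n", min = 1L)
  s <- check_count(s, "s", min = 1L)
  if (network %in% c("path", "complete", "density") && n < 2L) {
    stop_param("connected networks need n >= 2")
  }
  if (network == "density") {
    if (is.null(density)) stop_param("network = \"density\" requires `density`")
    density <- check_prob(density, "density")
    if (density < 2 / n) stop_param("`density` below the path network's 2/n")
  }
  stopifnot(inherits(schedule, "mode_schedule"))
  structure(
    list(n = n, s = s, params = perception_params(r),
         width = check_count(width, "width", min = 3L),
         height = check_count(height, "height", min = 3L),
         landscape_kind = landscape_kind, network = network, density = density,
         schedule = schedule,
         max_steps = check_count(max_steps, "max_steps"),
         horizon = check_count(horizon, "horizon"),
         noise = noise, signal_variance = signal_variance,
         record_positions = isTRUE(record_positions),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "simulation_config"
  )
}

build_network <- function(config, seed) {
  switch(config$network,
    path = path_network(config$n),
    complete = complete_network(config$n),
    edgeless = edgeless_network(config$n),
    density = densify(path_network(config$n), config$density, seed = seed)
  )
}

#' Initialize a simulation run
#'
#' Generates a fresh landscape and skill grid, builds the interaction
#' network, and places `n` agents with i.i.d. uniform skills and positions.
#' The master seed is split into one substream per component, so the same
#' configuration and seed always reproduce the identical starting state.
#'
#' @param config A [simulation_config()].
#' @return A list with `instance` ([problem_instance()]), `network`,
#'   `state` (a `population_state`: vectors `row`, `col`, `skill`, `payoff`,
#'   plus `step` and `moved_last_step`), and `seeds` (the named substream
#'   seeds; `seeds["dynamics"]` drives the update loop).
#' @export
initialize_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  master <- if (is.null(config$seed)) sample.int(.MAX_SEED, 1L) else config$seed
  seeds <- derive_seeds(master, 5L,
                        c("landscape", "skills", "network", "init", "dynamics"))

  payoffs <- if (config$landscape_kind == "complex") {
    generate_complex_landscape(config$width, config$height,
                               config$signal_variance, config$noise,
                               seed = seeds[["landscape"]])
  } else {
    generate_simple_landscape(config$width, config$height,
                              seed = seeds[["landscape"]])
  }
  skills <- assign_skills(config$width, config$height, config$s,
                          seed = seeds[["skills"]])
  instance <- problem_instance(payoffs, skills)
  net <- build_network(config, seeds[["network"]])

  state <- withr::with_seed(seeds[["init"]], {
    row <- sample.int(config$height, config$n, replace = TRUE)
    col <- sample.int(config$width, config$n, replace = TRUE)
    skill <- sample.int(config$s, config$n, replace = TRUE)
    list(row = row, col = col, skill = skill)
  })
  state$payoff <- payoffs$payoff[cbind(state$row, state$col)]
  state$step <- 0L
  state$moved_last_step <- NA
  class(state) <- "population_state"

  list(instance = instance, network = net, state = state, seeds = seeds)
}

#' Draw the communication mode for one agent update
#'
#' Constant-p schedules flip an independent coin per update (consuming one
#' uniform from the current RNG stream even when `p` is 0 or 1); phase
#' schedules collaborate deterministically on steps `1..k` and copy after.
#'
#' @param schedule A [mode_schedule()].
#' @param step Current time step (>= 1).
#' @return `"collaborate"` or `"copy"`.
#' @export
select_mode <- function(schedule, step) {
  stopifnot(inherits(schedule, "mode_schedule"), step >= 1)
  if (schedule$kind == "constant_p") {
    if (stats::runif(1) < schedule$p) "collaborate" else "copy"
  } else {
    if (step <= schedule$k) "collaborate" else "copy"
  }
}

# Fast single-agent move decision on raw state vectors. Returns the linear
# index of the destination cell (== current cell when no strict improvement
# exists). Consumes one RNG draw only to break a tie among 2+ maxima.
best_move_idx <- function(i, state, mode, payoff_mat, skill_mat, h, w, r,
                          collab_ok, own_ok, nbrs) {
  ok <- if (mode == "collaborate") collab_ok else own_ok
  idx <- visible_indices(state$row[i], state$col[i], ok, skill_mat, h, w, r)
  if (mode == "copy" && length(nbrs)) {
    idx <- c(idx, (state$col[nbrs] - 1L) * h + state$row[nbrs])
  }
  pays <- payoff_mat[idx]
  top <- max(pays)
  cur_idx <- (state$col[i] - 1L) * h + state$row[i]
  if (top <= payoff_mat[cur_idx]) return(cur_idx)
  # ties are resolved over the sorted distinct tied cells, so the outcome
  # (and RNG consumption) is independent of candidate enumeration order
  ties <- unique(idx[pays == top])
  if (length(ties) > 1L) ties <- sort(ties)[sample.int(length(ties), 1L)]
  ties
}

agent_skill_lookups <- function(state, net, s) {
  n <- length(state$skill)
  own <- lapply(seq_len(n), function(i) skill_lookup(s, state$skill[i]))
  collab <- lapply(seq_len(n), function(i) {
    skill_lookup(s, c(state$skill[i], state$skill[net$adj[[i]]]))
  })
  list(own = own, collab = collab)
}

#' Update a single agent
#'
#' Computes the agent's candidate set for the given mode (collaboration uses
#' the network neighbors' skills, copying their current positions), and
#' returns the position of the highest-payoff candidate if it strictly beats
#' the agent's current payoff — otherwise the current position. Ties among
#' maxima are broken uniformly at random using the current RNG stream.
#'
#' @param state A `population_state` from [initialize_simulation()].
#' @param i Index of the agent to update.
#' @param mode `"collaborate"` or `"copy"`.
#' @param instance A [problem_instance()].
#' @param net An `interaction_network`.
#' @param params A [perception_params()].
#' @return Integer vector `c(row, col)` of the chosen position.
#' @export
update_agent <- function(state, i, mode = c("collaborate", "copy"),
                         instance, net, params = perception_params()) {
  mode <- match.arg(mode)
  lk <- agent_skill_lookups(state, net, instance$s)
  idx <- best_move_idx(i, state, mode, instance$payoffs$payoff,
                       instance$skills$skill, instance$height, instance$width,
                       params$r, lk$collab[[i]], lk$own[[i]], net$adj[[i]])
  c(row = ((idx - 1L) %% instance$height) + 1L,
    col = ((idx - 1L) %/% instance$height) + 1L)
}

#' Advance the population by one time step
#'
#' Draws a fresh uniform permutation of the agents and updates them one by
#' one in that order (asynchronously: each agent sees the already-updated
#' positions of agents earlier in the permutation). Uses the current RNG
#' stream; see the package RNG contract in `run_simulation`'s details.
#'
#' @inheritParams update_agent
#' @param schedule A [mode_schedule()].
#' @return The updated `population_state`, with `step` incremented and
#'   `moved_last_step` set to whether any agent changed position.
#' @export
advance_step <- function(state, instance, net, schedule,
                         params = perception_params()) {
  lk <- agent_skill_lookups(state, net, instance$s)
  advance_step_fast(state, instance$payoffs$payoff, instance$skills$skill,
                    instance$height, instance$width, params$r, net, schedule,
                    lk)
}

advance_step_fast <- function(state, payoff_mat, skill_mat, h, w, r, net,
                              schedule, lk) {
  n <- length(state$row)
  step <- state$step + 1L
  ord <- sample.int(n)
  moved <- FALSE
  for (i in ord) {
    mode <- select_mode(schedule, step)
    idx <- best_move_idx(i, state, mode, payoff_mat, skill_mat, h, w, r,
                         lk$collab[[i]], lk$own[[i]], net$adj[[i]])
    new_row <- ((idx - 1L) %% h) + 1L
    new_col <- ((idx - 1L) %/% h) + 1L
    if (new_row != state$row[i] || new_col != state$col[i]) {
      moved <- TRUE
      state$row[i] <- new_row
      state$col[i] <- new_col
      state$payoff[i] <- payoff_mat[idx]
    }
  }
  state$step <- step
  state$moved_last_step <- moved
  state
}

#' Run a full simulation
#'
#' Initializes a problem instance, network and population from the config's
#' master seed, then iterates time steps. Constant-p runs stop after the
#' first step in which no agent moves (capped at `max_steps`, which the
#' strict-improvement rule makes unreachable in practice); phase runs last
#' exactly `schedule$total_rounds` steps regardless of movement.
#'
#' @param config A [simulation_config()].
#' @return A `trajectory`: list with `payoffs` (a `(steps + 1) x n` matrix,
#'   row 1 = initial state), `n_steps`, `terminated` (did a no-movement step
#'   occur), `positions` (list of `row`/`col` matrices if
#'   `record_positions`), `seeds`, and `config`.
#' @export
#' @examples
#' traj <- run_simulation(simulation_config(
#'   n = 4, s = 5, width = 20, height = 20,
#'   schedule = mode_schedule("constant_p", p = 1), seed = 42))
#' payoff_summary(final_payoffs(traj))
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  init <- initialize_simulation(config)
  state <- init$state
  instance <- init$instance
  net <- init$network
  h <- instance$height; w <- instance$width
  payoff_mat <- instance$payoffs$payoff
  skill_mat <- instance$skills$skill
  r <- config$params$r
  schedule <- config$schedule
  lk <- agent_skill_lookups(state, net, config$s)

  phase <- schedule$kind == "phase"
  limit <- if (phase) schedule$total_rounds else config$max_steps
  pay_hist <- vector("list", limit + 1L)
  pay_hist[[1L]] <- state$payoff
  pos_hist <- if (config$record_positions) {
    list(row = list(state$row), col = list(state$col))
  }

  terminated <- FALSE
  withr::local_seed(init$seeds[["dynamics"]])
  t <- 0L
  while (t < limit) {
    state <- advance_step_fast(state, payoff_mat, skill_mat, h, w, r, net,
                               schedule, lk)
    t <- t + 1L
    pay_hist[[t + 1L]] <- state$payoff
    if (!is.null(pos_hist)) {
      pos_hist$row[[t + 1L]] <- state$row
      pos_hist$col[[t + 1L]] <- state$col
    }
    if (!phase && !state$moved_last_step) {
      terminated <- TRUE
      break
    }
  }
  if (!phase && !terminated) {
    warning("run hit max_steps without a no-movement step", call. = FALSE)
  }

  structure(
    list(payoffs = do.call(rbind, pay_hist[seq_len(t + 1L)]),
         n_steps = t,
         terminated = if (phase) NA else terminated,
         positions = if (!is.null(pos_hist)) {
           list(row = do.call(rbind, pos_hist$row),
                col = do.call(rbind, pos_hist$col))
         },
         seeds = init$seeds, config = config),
    class = "trajectory"
  )
}

#' Final per-agent payoffs of a trajectory
#'
#' @param traj A `trajectory`.
#' @return Numeric vector of length `n`.
#' @export
final_payoffs <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$payoffs[nrow(traj$payoffs), ]
}

#' Pad a trajectory's payoff history to a common horizon
#'
#' Runs terminate at different steps; padding each agent's payoff series
#' with its final value up to `horizon` makes per-step means across runs
#' well defined.
#'
#' @param traj A `trajectory`.
#' @param horizon Number of steps to pad to (default the config's horizon).
#' @return A `(horizon + 1) x n` matrix; row `t + 1` is the state after
#'   step `t`.
#' @export
pad_payoffs <- function(traj, horizon = traj$config$horizon) {
  stopifnot(inherits(traj, "trajectory"))
  horizon <- check_count(horizon, "horizon")
  m <- traj$payoffs
  if (nrow(m) >= horizon + 1L) return(m[seq_len(horizon + 1L), , drop = FALSE])
  pad <- matrix(m[nrow(m), ], horizon + 1L - nrow(m), ncol(m), byrow = TRUE)
  rbind(m, pad)
}

#' @export
print.simulation_config <- function(x, ...) {
  sched <- if (x$schedule$kind == "constant_p") {
    sprintf("constant p = %g", x$schedule$p)
  } else {
    sprintf("phase k = %d of %d rounds", x$schedule$k, x$schedule$total_rounds)
  }
  cat(sprintf(
    "<simulation_config> n = %d, s = %d, r = %g, %d x %d %s landscape,\n  network = %s%s, schedule = %s, seed = %s\n",
    x$n, x$s, x$params$r, x$width, x$height, x$landscape_kind, x$network,
    if (!is.null(x$density)) sprintf(" (density %g)", x$density) else "",
    sched, if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  fp <- final_payoffs(x)
  cat(sprintf(
    "<trajectory> %d agents, %d steps%s; final max/mean/min = %.3f/%.3f/%.3f\n",
    ncol(x$payoffs), x$n_steps,
    if (isTRUE(x$terminated)) " (terminated)" else "",
    max(fp), mean(fp), min(fp)))
  invisible(x)
}
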