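# Monte-Carlo experiment harness.
#
# Every protocol is a grid of conditions; each condition is replicated with
# independent runs (fresh landscape, skill grid, network randomization and
# agent initialization per run) and summarized by the mean and standard
# error of the group outcomes across runs.

#' Run a batch of independent replicate simulations
#'
#' Derives one child seed per run from the master seed (all children are
#' drawn up front, so run `i`'s results do not depend on whether run `j` is
#' executed) and runs each replicate with a fresh landscape, skill grid,
#' network and population.
#'
#' @param config A [simulation_config()]; its own `seed` field is ignored.
#' @param n_runs Number of replicates (>= 1).
#' @param seed Master seed for the batch.
#' @return List of `trajectory` objects, one per run.
#' @export
run_batch <- function(config, n_runs, seed) {
  stopifnot(inherits(config, "simulation_config"))
  n_runs <- check_count(n_runs, "n_runs")
  run_seeds <- derive_seeds(seed, n_runs)
  lapply(seq_len(n_runs), function(i) {
    cfg <- config
    cfg$seed <- run_seeds[i]
    run_simulation(cfg)
  })
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Summarize a batch of trajectories
#'
#' Computes the group outcomes (max, mean, min payoff and Gini coefficient)
#' either from each run's final state or per time step (runs padded with
#' final values up to `horizon`), then averages across runs.
#'
#' @param trajectories List of `trajectory` objects (>= 2 for a finite SEM).
#' @param at `"final"` or `"per_step"`.
#' @param horizon Padding horizon for `at = "per_step"` (default the first
#'   trajectory's configured horizon).
#' @return A data.frame with columns `outcome`, `mean`, `sem`, `n_runs`
#'   (plus `step` for `at = "per_step"`).
#' @export
summarize_runs <- function(trajectories, at = c("final", "per_step"),
                           horizon = NULL) {
  at <- match.arg(at)
  stopifnot(length(trajectories) >= 1L,
            all(vapply(trajectories, inherits, logical(1), "trajectory")))
  if (length(trajectories) < 2L) {
    stop_param("need >= 2 trajectories to estimate a standard error")
  }
  outcomes <- c("max_payoff", "mean_payoff", "min_payoff", "gini")
  n_runs <- length(trajectories)

  if (at == "final") {
    vals <- t(vapply(trajectories, function(tr) payoff_summary(final_payoffs(tr)),
                     numeric(4)))
    return(data.frame(
      outcome = outcomes,
      mean = colMeans(vals),
      sem = apply(vals, 2, sem),
      n_runs = n_runs,
      row.names = NULL
    ))
  }

  if (is.null(horizon)) horizon <- trajectories[[1]]$config$horizon
  horizon <- check_count(horizon, "horizon")
  # per run: (horizon + 1) x 4 summary matrix
  per_run <- lapply(trajectories, function(tr) {
    m <- pad_payoffs(tr, horizon)
    t(apply(m, 1, payoff_summary))
  })
  arr <- simplify2array(per_run)  # (horizon+1) x 4 x n_runs
  mean_mat <- apply(arr, c(1, 2), mean)
  sem_mat <- apply(arr, c(1, 2), sem)
  data.frame(
    step = rep(0:horizon, times = 4L),
    outcome = rep(outcomes, each = horizon + 1L),
    mean = as.vector(mean_mat),
    sem = as.vector(sem_mat),
    n_runs = n_runs,
    row.names = NULL
  )
}

#' Define an experimental protocol
#'
#' Four named designs:
#' \describe{
#'   \item{timeseries}{Per-step best/average payoff for collaboration rates
#'     `p_values` on the complete network plus the individual (edgeless)
#'     baseline, on both simple and complex landscapes.}
#'   \item{p_sweep}{Final outcomes as a function of `p` on the path and
#'     complete networks.}
#'   \item{density_sweep}{Final outcomes over network density (path network
#'     randomly densified) at `p = 0` and `p = 1`.}
#'   \item{phase_sweep}{Final outcomes of collaborate-for-`k`-rounds /
#'     copy-for-`total_rounds - k` schedules over `k`, on both networks.}
#' }
#'
#' @param name Protocol name.
#' @param base A [simulation_config()] supplying the fixed parameters.
#' @param n_runs Replicates per condition (default 1000, matching the
#'   headline experiments; use ~200 for desk-scale runs).
#' @param seed Master seed; each condition gets an independent child seed.
#' @param p_grid Collaboration rates for `p_sweep`.
#' @param p_values Collaboration rates for `timeseries`.
#' @param density_grid Densities for `density_sweep`.
#' @param k_grid Collaboration-round counts for `phase_sweep`.
#' @param networks Networks compared in `p_sweep` / `phase_sweep`.
#' @return An object of class `protocol`.
#' @export
protocol <- function(name = c("timeseries", "p_sweep", "density_sweep", "phase_sweep"),
                     base = simulation_config(), n_runs = 1000L, seed = 1L,
                     p_grid = seq(0, 1, by = 0.1),
                     p_values = c(0, 0.1, 0.9, 1),
                     density_grid = c(0.125, 0.25, 0.5, 0.75, 1),
                     k_grid = 0:10,
                     networks = c("path", "complete")) {
  name <- match.arg(name)
  stopifnot(inherits(base, "simulation_config"))
  n_runs <- check_count(n_runs, "n_runs")
  if (any(p_grid < 0 | p_grid > 1) || any(p_values < 0 | p_values > 1)) {
    stop_param("collaboration rates must lie in [0, 1]")
  }
  if (name == "density_sweep" &&
      any(density_grid < 2 / base$n | density_grid > 1)) {
    stop_param("densities must lie in [2/n, 1]")
  }
  if (any(k_grid < 0)) stop_param("k values must be >= 0")
  structure(
    list(name = name, base = base, n_runs = n_runs, seed = as.integer(seed),
         p_grid = p_grid, p_values = p_values, density_grid = density_grid,
         k_grid = k_grid, networks = match.arg(networks, several.ok = TRUE)),
    class = "protocol"
  )
}

protocol_conditions <- function(proto) {
  base <- proto$base
  cond <- switch(proto$name,
    timeseries = {
      g <- expand.grid(landscape = c("simple", "complex"),
                       network = c("edgeless", "complete"),
                       p = proto$p_values, stringsAsFactors = FALSE)
      # the individual baseline is p-invariant; keep a single p for it
      g <- g[g$network == "complete" | g$p == proto$p_values[1], ]
      g$p[g$network == "edgeless"] <- NA
      g$density <- NA_real_
      g$k <- NA_integer_
      g
    },
    p_sweep = {
      g <- expand.grid(network = proto$networks, p = proto$p_grid,
                       stringsAsFactors = FALSE)
      g$landscape <- base$landscape_kind
      g$density <- NA_real_
      g$k <- NA_integer_
      g
    },
    density_sweep = {
      g <- expand.grid(density = proto$density_grid, p = c(0, 1))
      g$network <- "density"
      g$landscape <- base$landscape_kind
      g$k <- NA_integer_
      g
    },
    phase_sweep = {
      g <- expand.grid(network = proto$networks, k = proto$k_grid,
                       stringsAsFactors = FALSE)
      g$landscape <- base$landscape_kind
      g$p <- NA_real_
      g$density <- NA_real_
      g
    }
  )
  rownames(cond) <- NULL
  cond[, c("landscape", "network", "p", "density", "k")]
}

condition_config <- function(proto, cond_row) {
  cfg <- proto$base
  cfg$landscape_kind <- cond_row$landscape
  cfg$network <- cond_row$network
  cfg$density <- if (is.na(cond_row$density)) NULL else cond_row$density
  cfg$schedule <- if (!is.na(cond_row$k)) {
    mode_schedule("phase", k = cond_row$k)
  } else if (is.na(cond_row$p)) {
    # individual baseline: p is irrelevant (and provably has no effect)
    mode_schedule("constant_p", p = 0)
  } else {
    mode_schedule("constant_p", p = cond_row$p)
  }
  cfg
}

#' Run an experimental protocol
#'
#' Executes every condition of the protocol with `n_runs` replicates each
#' and returns a tidy results table (one row per condition x outcome, or per
#' condition x outcome x step for the timeseries protocol). Optionally
#' writes the table and a JSON manifest of the full parameterization.
#'
#' @param proto A [protocol()].
#' @param out Optional output directory; writes `results.csv` and
#'   `manifest.json` there.
#' @param verbose Print per-condition progress.
#' @return The results data.frame, invisibly carrying the protocol as
#'   attribute `"protocol"`.
#' @export
run_protocol <- function(proto, out = NULL, verbose = FALSE) {
  stopifnot(inherits(proto, "protocol"))
  cond <- protocol_conditions(proto)
  cond_seeds <- derive_seeds(proto$seed, nrow(cond))
  at <- if (proto$name == "timeseries") "per_step" else "final"

  rows <- lapply(seq_len(nrow(cond)), function(ci) {
    cfg <- condition_config(proto, cond[ci, ])
    if (verbose) {
      message(sprintf("[%s] condition %d/%d: %s", proto$name, ci, nrow(cond),
                      paste(names(cond), unlist(cond[ci, ]), sep = "=",
                            collapse = " ")))
    }
    trajs <- run_batch(cfg, proto$n_runs, cond_seeds[ci])
    smry <- summarize_runs(trajs, at = at)
    cbind(cond[ci, ], smry, row.names = NULL)
  })
  res <- do.call(rbind, rows)
  res <- cbind(protocol = proto$name, res)
  attr(res, "protocol") <- proto

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out, "results.csv"), row.names = FALSE)
    manifest <- list(
      protocol = proto$name, n_runs = proto$n_runs, seed = proto$seed,
      base = config_to_list(proto$base),
      grids = list(p_grid = proto$p_grid, p_values = proto$p_values,
                   density_grid = proto$density_grid, k_grid = proto$k_grid,
                   networks = proto$networks),
      package_version = as.character(utils::packageVersion("skillscape"))
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res)
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %s: %d conditions x %d runs, seed = %d\n",
              x$name, nrow(protocol_conditions(x)), x$n_runs, x$seed))
  invisible(x)
}
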