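# Independent brute-force oracles. These deliberately use naive double loops
# over all grid cells and a literal transcription of the update rules, and
# share nothing with the package implementation except the documented
# contracts (candidate definitions, update order, RNG consumption).

oracle_gini <- function(x) {
  n <- length(x)
  if (mean(x) == 0) return(0)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(x[i] - x[j])
  tot / (2 * n^2 * mean(x))
}

oracle_local_optima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  cnt <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      is_opt <- TRUE
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && m[ii, jj] > m[i, j]) {
            is_opt <- FALSE
          }
        }
      }
      if (is_opt) cnt <- cnt + 1L
    }
  }
  cnt
}

# Visible cells by scanning every grid cell. skill_set: admissible labels.
oracle_visible <- function(row, col, skill_set, instance, r) {
  h <- instance$height; w <- instance$width
  out <- NULL
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      cheb <- max(abs(i - row), abs(j - col))
      d2 <- (i - row)^2 + (j - col)^2
      vis <- cheb <= 1 ||
        (d2 <= r^2 && instance$skills$skill[i, j] %in% skill_set)
      if (vis) out <- rbind(out, c(i, j))
    }
  }
  out
}

oracle_candidate_idx <- function(i, st, mode, instance, net, r) {
  h <- instance$height
  skill_set <- if (mode == "collaborate") {
    c(st$skill[i], st$skill[net$adj[[i]]])
  } else {
    st$skill[i]
  }
  pos <- oracle_visible(st$row[i], st$col[i], skill_set, instance, r)
  idx <- (pos[, 2] - 1L) * h + pos[, 1]
  if (mode == "copy" && length(net$adj[[i]])) {
    nb <- net$adj[[i]]
    idx <- c(idx, (st$col[nb] - 1L) * h + st$row[nb])
  }
  idx
}

# Full reference simulation of the dynamics, given an already-initialized
# world. Mirrors the documented RNG contract: per step one permutation; per
# update one uniform for constant_p mode choice; one draw among the sorted
# distinct tied maxima only when an improving move ties.
oracle_run <- function(instance, net, state, schedule, r, dyn_seed,
                       max_steps = 1000L) {
  h <- instance$height
  pay <- instance$payoffs$payoff
  n <- length(state$row)
  st <- state
  hist_pay <- list(st$payoff)
  hist_row <- list(st$row)
  hist_col <- list(st$col)
  phase <- schedule$kind == "phase"
  limit <- if (phase) schedule$total_rounds else max_steps

  withr::with_seed(dyn_seed, {
    t <- 0L
    repeat {
      if (t >= limit) break
      step <- t + 1L
      ord <- sample.int(n)
      moved <- FALSE
      for (i in ord) {
        mode <- if (phase) {
          if (step <= schedule$k) "collaborate" else "copy"
        } else {
          if (runif(1) < schedule$p) "collaborate" else "copy"
        }
        idx <- oracle_candidate_idx(i, st, mode, instance, net, r)
        pays <- pay[idx]
        top <- max(pays)
        if (top > st$payoff[i]) {
          ties <- sort(unique(idx[pays == top]))
          pick <- if (length(ties) > 1L) ties[sample.int(length(ties), 1L)] else ties
          st$row[i] <- ((pick - 1L) %% h) + 1L
          st$col[i] <- ((pick - 1L) %/% h) + 1L
          st$payoff[i] <- pay[pick]
          moved <- TRUE
        }
      }
      t <- t + 1L
      hist_pay[[t + 1L]] <- st$payoff
      hist_row[[t + 1L]] <- st$row
      hist_col[[t + 1L]] <- st$col
      if (!phase && !moved) break
    }
  })
  list(payoffs = do.call(rbind, hist_pay),
       row = do.call(rbind, hist_row),
       col = do.call(rbind, hist_col))
}

# Small-world end-to-end comparison helper: run the package engine and the
# oracle from the identical initialized world and dynamics seed.
compare_with_oracle <- function(config) {
  init <- initialize_simulation(config)
  traj <- run_simulation(config)
  ref <- oracle_run(init$instance, init$network, init$state, config$schedule,
                    config$params$r, init$seeds[["dynamics"]],
                    max_steps = config$max_steps)
  list(traj = traj, ref = ref)
}

small_config <- function(seed, p = NULL, k = NULL, n = 3L, s = 4L,
                         side = 6L, r = 2 * sqrt(2), network = "path") {
  schedule <- if (!is.null(k)) {
    mode_schedule("phase", k = k, total_rounds = 6L)
  } else {
    mode_schedule("constant_p", p = p)
  }
  simulation_config(n = n, s = s, r = r, width = side, height = side,
                    network = network, schedule = schedule,
                    landscape_kind = "complex",
                    noise = noise_spec(octaves = 2, base_period = 4),
                    record_positions = TRUE, seed = seed)
}
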