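test_that("initialization is deterministic and respects the config", {
  cfg <- simulation_config(seed = 123)
  init1 <- initialize_simulation(cfg)
  init2 <- initialize_simulation(cfg)
  expect_identical(init1$instance$payoffs$payoff, init2$instance$payoffs$payoff)
  expect_identical(init1$state, init2$state)

  st <- init1$state
  expect_length(st$row, 16L)
  expect_true(all(st$skill >= 1L & st$skill <= 100L))
  expect_true(all(st$row >= 1L & st$row <= 100L & st$col >= 1L & st$col <= 100L))
  expect_equal(st$payoff,
               init1$instance$payoffs$payoff[cbind(st$row, st$col)])

  # single-agent population is valid
  tiny <- simulation_config(n = 1, s = 3, width = 10, height = 10,
                            network = "edgeless", seed = 4)
  expect_length(initialize_simulation(tiny)$state$row, 1L)
  expect_error(simulation_config(n = 1, network = "path"), "n >= 2")
})

test_that("select_mode honors constant_p and phase schedules", {
  expect_true(all(replicate(20, select_mode(mode_schedule("constant_p", p = 1), 1))
                  == "collaborate"))
  expect_true(all(replicate(20, select_mode(mode_schedule("constant_p", p = 0), 1))
                  == "copy"))

  ph <- mode_schedule("phase", k = 3)
  expect_identical(select_mode(ph, 3), "collaborate")
  expect_identical(select_mode(ph, 4), "copy")
  expect_identical(select_mode(ph, 10), "copy")

  draws <- withr::with_seed(42, replicate(10000,
    select_mode(mode_schedule("constant_p", p = 0.5), 1)))
  frac <- mean(draws == "collaborate")
  bounds <- stats::qbinom(c(5e-4, 1 - 5e-4), 10000, 0.5) / 10000
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])

  expect_error(mode_schedule("constant_p", p = 1.2), "`p`")
  expect_error(mode_schedule("phase", k = 11, total_rounds = 10), "total_rounds")
})

test_that("update_agent moves to the best strict improvement, else stays", {
  pay <- matrix(0.1, 5, 5)
  pay[3, 3] <- 0.4   # agent 1
  pay[1, 1] <- 0.9   # unique best, occupied by the neighbor
  pay[5, 5] <- 0.3   # worse than agent 1's cell
  inst <- make_instance(pay, matrix(1L, 5, 5), s = 2)
  net <- complete_network(2)

  # neighbor sits on the unique best cell, outside r: copy reaches it
  st <- make_state(inst, row = c(3, 1), col = c(3, 1), skill = c(2, 2))
  expect_equal(update_agent(st, 1, "copy", inst, net, perception_params(2)),
               c(row = 1, col = 1))
  # collaborating instead: nothing within r beats 0.4
  expect_equal(update_agent(st, 1, "collaborate", inst, net,
                            perception_params(2)),
               c(row = 3, col = 3))

  # agent on the global optimum stays
  st2 <- make_state(inst, row = c(1, 5), col = c(1, 5), skill = c(2, 2))
  expect_equal(update_agent(st2, 1, "copy", inst, net, perception_params(2)),
               c(row = 1, col = 1))
  # all considered payoffs <= current: stays
  expect_equal(update_agent(st2, 2, "copy", inst,
                            edgeless_network(2), perception_params(1)),
               c(row = 5, col = 5))
})

test_that("a population at a fixed point reports no movement", {
  pay <- matrix(0.2, 4, 4)
  pay[2, 2] <- 1
  inst <- make_instance(pay, matrix(1L, 4, 4), s = 1)
  st <- make_state(inst, row = c(2, 2, 2), col = c(2, 2, 2), skill = c(1, 1, 1))
  out <- withr::with_seed(1, advance_step(st, inst, complete_network(3),
                                          mode_schedule("constant_p", p = 0.5),
                                          perception_params(2)))
  expect_false(out$moved_last_step)
  expect_identical(out$row, st$row)
  expect_equal(out$step, 1L)
})

test_that("updates are sequential: later agents see earlier agents' new positions", {
  pay <- matrix(c(0.3, 0.1, 0.2,
                  0.1, 0.1, 0.4,
                  0.1, 0.2, 0.9), 3, 3, byrow = TRUE)
  inst <- make_instance(pay, matrix(1L, 3, 3), s = 1)
  net <- complete_network(2)
  sched <- mode_schedule("constant_p", p = 0)  # copy only
  pp <- perception_params(0)  # Moore-only individual vision
  # agent 1 ("X") at (1,1) has no individual improvement; agent 2 ("Y") at
  # (2,3) climbs to (3,3). X's outcome reveals whose position it copied.
  seed_for_first <- function(first) {
    for (s in 1:50) {
      if (withr::with_seed(s, sample.int(2))[1] == first) return(s)
    }
  }
  st <- make_state(inst, row = c(1, 2), col = c(1, 3), skill = c(1, 1))

  s_y_first <- seed_for_first(2)
  out1 <- withr::with_seed(s_y_first, advance_step(st, inst, net, sched, pp))
  expect_equal(c(out1$row[1], out1$col[1]), c(3, 3))  # copied Y's NEW cell

  s_x_first <- seed_for_first(1)
  out2 <- withr::with_seed(s_x_first, advance_step(st, inst, net, sched, pp))
  expect_equal(c(out2$row[1], out2$col[1]), c(2, 3))  # copied Y's OLD cell
  expect_equal(c(out2$row[2], out2$col[2]), c(3, 3))
})

test_that("full trajectories match the brute-force reference", {
  specs <- list(list(p = 0), list(p = 1), list(p = 0.4), list(k = 2),
                list(p = 0.7), list(k = 4))
  for (seed in 1:12) {
    sp <- specs[[(seed - 1) %% length(specs) + 1]]
    cfg <- small_config(seed = 1000 + seed, p = sp$p, k = sp$k,
                        n = 2 + seed %% 3, side = 5 + seed %% 4,
                        network = c("path", "complete")[1 + seed %% 2])
    cmp <- compare_with_oracle(cfg)
    expect_identical(cmp$traj$payoffs, cmp$ref$payoffs)
    expect_identical(cmp$traj$positions$row, cmp$ref$row)
    expect_identical(cmp$traj$positions$col, cmp$ref$col)
  }
})

test_that("per-agent payoffs are non-decreasing and runs terminate", {
  for (seed in 1:10) {
    cfg <- small_config(seed = 300 + seed,
                        p = c(0, 0.5, 1)[1 + seed %% 3],
                        n = 4, side = 8, network = "complete")
    traj <- run_simulation(cfg)
    expect_true(all(apply(traj$payoffs, 2, function(x) all(diff(x) >= 0))))
    expect_true(traj$terminated)
    # last step is the no-movement step: state unchanged from the one before
    expect_identical(traj$payoffs[traj$n_steps + 1L, ],
                     traj$payoffs[traj$n_steps, ])
  }
})

test_that("phase schedules run exactly total_rounds steps", {
  cfg <- small_config(seed = 77, k = 3, n = 3, side = 6)
  traj <- run_simulation(cfg)
  expect_equal(traj$n_steps, 6L)  # small_config uses total_rounds = 6
  expect_equal(nrow(traj$payoffs), 7L)
  expect_true(is.na(traj$terminated))
})

test_that("empty network makes p irrelevant (matched seeds)", {
  for (p in c(0, 0.6, 1)) {
    cfg <- simulation_config(n = 5, s = 6, r = 3, width = 15, height = 15,
                             network = "edgeless",
                             schedule = mode_schedule("constant_p", p = p),
                             record_positions = TRUE, seed = 555)
    traj <- run_simulation(cfg)
    if (p == 0) {
      ref <- traj
    } else {
      expect_identical(traj$payoffs, ref$payoffs)
      expect_identical(traj$positions, ref$positions)
    }
  }
})

test_that("with a single skill type, collaboration equals individual search", {
  base <- list(n = 5, s = 1, r = 3, width = 15, height = 15,
               schedule = mode_schedule("constant_p", p = 1),
               record_positions = TRUE, seed = 808)
  collab <- run_simulation(do.call(simulation_config,
                                   c(base, network = "complete")))
  solo <- run_simulation(do.call(simulation_config,
                                 c(base, network = "edgeless")))
  expect_identical(collab$payoffs, solo$payoffs)
  expect_identical(collab$positions, solo$positions)
})

test_that("one copy round on the complete network lifts everyone to the start maximum", {
  for (seed in c(21, 22, 23)) {
    cfg <- simulation_config(n = 8, s = 10, r = 4, width = 30, height = 30,
                             network = "complete",
                             schedule = mode_schedule("constant_p", p = 0),
                             seed = seed)
    init <- initialize_simulation(cfg)
    start_max <- max(init$state$payoff)
    out <- withr::with_seed(init$seeds[["dynamics"]],
      advance_step(init$state, init$instance, init$network, cfg$schedule,
                   cfg$params))
    expect_true(all(out$payoff >= start_max))
  }
})

test_that("trajectory padding reaches the horizon with final values", {
  cfg <- small_config(seed = 31, p = 0.5, n = 3, side = 6)
  traj <- run_simulation(cfg)
  padded <- pad_payoffs(traj, 40)
  expect_equal(dim(padded), c(41L, 3L))
  expect_equal(padded[41, ], final_payoffs(traj))
  expect_identical(padded[seq_len(nrow(traj$payoffs)), ], traj$payoffs)
})

test_that("hitting max_steps without convergence warns", {
  cfg <- simulation_config(n = 8, s = 5, r = 3, width = 30, height = 30,
                           network = "complete", max_steps = 1,
                           schedule = mode_schedule("constant_p", p = 0.5),
                           seed = 9)
  expect_warning(run_simulation(cfg), "max_steps")
})
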