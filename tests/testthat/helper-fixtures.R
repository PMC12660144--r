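# Fixture builders: construct problem instances directly from matrices,
# bypassing the generators.

make_payoff_grid <- function(m, kind = "complex") {
  structure(
    list(payoff = m, width = ncol(m), height = nrow(m), kind = kind,
         seed = NULL),
    class = "payoff_grid"
  )
}

make_skill_grid <- function(m, s = max(m)) {
  storage.mode(m) <- "integer"
  structure(
    list(skill = m, width = ncol(m), height = nrow(m), s = as.integer(s),
         seed = NULL),
    class = "skill_grid"
  )
}

make_instance <- function(payoff, skill, s = max(skill)) {
  problem_instance(make_payoff_grid(payoff), make_skill_grid(skill, s))
}

random_instance <- function(h, w, s, seed) {
  withr::with_seed(seed, {
    make_instance(matrix(runif(h * w), h, w),
                  matrix(sample.int(s, h * w, replace = TRUE), h, w), s = s)
  })
}

# population_state from explicit vectors
make_state <- function(instance, row, col, skill) {
  structure(
    list(row = as.integer(row), col = as.integer(col),
         skill = as.integer(skill),
         payoff = instance$payoffs$payoff[cbind(row, col)],
         step = 0L, moved_last_step = NA),
    class = "population_state"
  )
}

positions_as_key <- function(m) {
  paste(m[, 1], m[, 2], sep = ",")
}
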