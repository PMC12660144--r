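r22 <- 2 * sqrt(2)

test_that("individual visible set: self, Moore ring, and skill matches", {
  # skill-mismatched surroundings: agent sees exactly self + 8 adjacent
  inst <- make_instance(matrix(runif(49), 7, 7), matrix(1L, 7, 7), s = 2)
  a <- agent(1, skill = 2, row = 4, col = 4)
  vis <- individual_visible_set(a, inst, perception_params(r22))
  expect_equal(nrow(vis), 9L)
  expect_true("4,4" %in% positions_as_key(vis))
  expect_true(all(abs(vis[, "row"] - 4) <= 1 & abs(vis[, "col"] - 4) <= 1))

  # s = 1: everything within the disk matches; r = 2*sqrt(2) reaches all
  # offsets with dx^2 + dy^2 <= 8, i.e. the full 5x5 square
  inst1 <- make_instance(matrix(runif(49), 7, 7), matrix(1L, 7, 7), s = 1)
  a1 <- agent(1, skill = 1, row = 4, col = 4)
  expect_equal(nrow(individual_visible_set(a1, inst1, perception_params(r22))),
               25L)

  # corner, own skill absent within r: self + 3 clipped neighbors
  ac <- agent(1, skill = 2, row = 1, col = 1)
  corner <- individual_visible_set(ac, inst, perception_params(r22))
  expect_equal(nrow(corner), 4L)
})

test_that("collaborative set extends by neighbor skills only", {
  inst <- make_instance(matrix(runif(49), 7, 7), matrix(1L, 7, 7), s = 3)
  a <- agent(1, skill = 2, row = 4, col = 4)
  ind <- individual_visible_set(a, inst, perception_params(r22))

  expect_identical(collaborative_visible_set(a, 2L, inst, perception_params(r22)),
                   ind)
  expect_identical(collaborative_visible_set(a, integer(0), inst,
                                             perception_params(r22)),
                   ind)

  # checkerboard with two types partitions the whole disk
  chk <- matrix(1L + (row(matrix(0, 7, 7)) + col(matrix(0, 7, 7))) %% 2L, 7, 7)
  inst2 <- make_instance(matrix(runif(49), 7, 7), chk, s = 2)
  a2 <- agent(1, skill = chk[4, 4], row = 4, col = 4)
  other <- 3L - chk[4, 4]
  expect_equal(
    nrow(collaborative_visible_set(a2, other, inst2, perception_params(r22))),
    25L)
})

test_that("copy candidate set unions in neighbor positions", {
  inst <- make_instance(matrix(runif(25), 5, 5), matrix(1L, 5, 5), s = 2)
  a <- agent(1, skill = 2, row = 3, col = 3)
  pp <- perception_params(2)
  ind <- copy_candidate_set(a, NULL, inst, pp)
  expect_identical(ind, individual_visible_set(a, inst, pp))

  # neighbor already inside the set: unchanged
  expect_identical(copy_candidate_set(a, rbind(c(3, 4)), inst, pp), ind)

  # neighbor outside r: exactly one extra cell
  with_far <- copy_candidate_set(a, rbind(c(1, 1)), inst, pp)
  expect_equal(nrow(with_far), nrow(ind) + 1L)
  expect_setequal(positions_as_key(with_far),
                  c(positions_as_key(ind), "1,1"))
})

test_that("visible sets satisfy nesting, bounds and radius monotonicity, and match the oracle", {
  for (seed in 1:6) {
    inst <- random_instance(10, 10, s = 4, seed = seed)
    pos <- withr::with_seed(seed + 50, c(sample.int(10, 1), sample.int(10, 1)))
    a <- agent(1, skill = ((seed - 1) %% 4) + 1, row = pos[1], col = pos[2])
    nb_sk <- withr::with_seed(seed + 90, sample.int(4, 2))

    prev_n <- 0L
    for (r in c(1.5, r22, 4, 6)) {
      pp <- perception_params(r)
      ind <- individual_visible_set(a, inst, pp)
      col <- collaborative_visible_set(a, nb_sk, inst, pp)
      cpy <- copy_candidate_set(a, rbind(c(1, 10)), inst, pp)

      # oracle agreement
      expect_setequal(positions_as_key(ind),
                      positions_as_key(oracle_visible(a$row, a$col, a$skill,
                                                      inst, r)))
      expect_setequal(positions_as_key(col),
                      positions_as_key(oracle_visible(a$row, a$col,
                                                      c(a$skill, nb_sk),
                                                      inst, r)))
      # nesting and self-containment
      expect_true(all(positions_as_key(ind) %in% positions_as_key(col)))
      expect_true(all(positions_as_key(ind) %in% positions_as_key(cpy)))
      expect_true(paste(a$row, a$col, sep = ",") %in% positions_as_key(ind))
      # bounds
      expect_true(all(ind >= 1 & ind <= 10))
      # radius monotonicity
      expect_gte(nrow(ind), prev_n)
      prev_n <- nrow(ind)
    }
  }
})

test_that("s = 1 degeneracy: collaboration adds nothing", {
  inst <- random_instance(8, 8, s = 1, seed = 4)
  a <- agent(1, skill = 1, row = 5, col = 2)
  for (nb in list(integer(0), 1L, rep(1L, 5))) {
    expect_identical(
      collaborative_visible_set(a, nb, inst, perception_params(3)),
      individual_visible_set(a, inst, perception_params(3)))
  }
})

test_that("perception validates inputs", {
  inst <- random_instance(5, 5, s = 2, seed = 1)
  expect_error(individual_visible_set(agent(1, 1, 6, 1), inst), "bounds")
  expect_error(individual_visible_set(agent(1, 3, 2, 2), inst), "skill")
  expect_error(perception_params(-1), "`r`")
})
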