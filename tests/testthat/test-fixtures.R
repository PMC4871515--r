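test_that("action enabling and renormalization follow the narrative", {
  s0 <- toy_initial_state()
  a0 <- enabled_actions(s0)
  expect_length(a0, 1L)
  expect_identical(a0[[1]]$action, "assimilate")
  expect_identical(c(a0[[1]]$num, a0[[1]]$den), c(1L, 1L))

  # energized cell in a corner: two in-bounds move targets at 1/2 each
  s2 <- toy_state(c(2L, 2L), {
    m <- matrix(1L, 2, 2); m[2, 2] <- 0L; m
  }, 0L, 1L)
  a2 <- enabled_actions(s2)
  expect_length(a2, 2L)
  expect_true(all(vapply(a2, `[[`, character(1), "action") == "move"))
  expect_true(all(vapply(a2, function(a) a$num / a$den, numeric(1)) == 0.5))

  # exhausted state is terminal
  dormant <- toy_state(c(1L, 1L), matrix(0L, 2, 2), 0L, 0L)
  expect_length(enabled_actions(dormant), 0L)

  # a hypothetical state with several enabled actions renormalizes weights
  rich <- toy_state(c(1L, 1L), matrix(1L, 2, 2), 1L, 1L)
  ar <- enabled_actions(rich)
  expect_equal(sum(vapply(ar, function(a) a$num / a$den, numeric(1))), 1)
  probs <- vapply(ar, function(a) a$num / a$den, numeric(1))
  names(probs) <- vapply(ar, function(a)
    if (a$action == "move") paste0("move", paste(a$target, collapse = "")) else
      a$action, character(1))
  expect_equal(unname(probs[c("assimilate", "convert")]), c(0.5, 0.3))
})

test_that("the enumerated state space matches the published chain exactly", {
  ts <- enumerate_toy_state_space()
  ref <- reference_toy_chain()

  expect_length(ts$states, 27L)
  expect_identical(sum(ts$terminal), 6L)
  expect_identical(nrow(ts$edges), 28L)

  # every published state is reachable; map published labels to BFS indices
  idx <- vapply(ref$states, function(s) toy_state_index(ts, s), integer(1))
  expect_false(anyNA(idx))
  expect_identical(anyDuplicated(idx), 0L)

  # every published transition probability is reproduced exactly
  for (k in seq_len(nrow(ref$edges))) {
    from <- idx[ref$edges$from[k] + 1L]
    to <- idx[ref$edges$to[k] + 1L]
    hit <- ts$edges$from == from & ts$edges$to == to
    expect_true(any(hit), label = sprintf("edge S%d -> S%d present",
                                          ref$edges$from[k], ref$edges$to[k]))
    expect_identical(ts$edges$num[hit] / ts$edges$den[hit], ref$edges$prob[k])
  }
  # and no transitions beyond the published ones
  expect_identical(nrow(ts$edges), nrow(ref$edges))
  # the published terminal states are exactly the enumerator's
  expect_setequal(idx[ref$terminal + 1L], which(ts$terminal))

  # stochasticity: outgoing probabilities sum to exactly one
  for (i in which(!ts$terminal)) {
    e <- ts$edges[ts$edges$from == i, ]
    expect_identical(sum(e$num / e$den), 1)
  }
})

test_that("path probabilities multiply along printed prefixes", {
  ts <- enumerate_toy_state_space()
  ref <- reference_toy_chain()
  idx <- vapply(ref$states, function(s) toy_state_index(ts, s), integer(1))

  # S0 S1 S2 S3 S5 S7 S10: product 1 * 1 * 1/2 * 1 * 1 * 1/2
  path <- idx[c(0, 1, 2, 3, 5, 7, 10) + 1L]
  pp <- toy_path_probability(ts, path)
  expect_identical(as.numeric(pp), 0.25)
  expect_identical(attr(pp, "num") / attr(pp, "den"), 0.25)

  expect_identical(as.numeric(toy_path_probability(ts, idx[1])), 1)
  expect_error(toy_path_probability(ts, idx[c(1, 4)]),
               class = "mstmc_error_path")

  # conservation: one-step extensions of a prefix sum to its probability
  prefix <- idx[c(0, 1, 2) + 1L]
  p_prefix <- as.numeric(toy_path_probability(ts, prefix))
  succ <- ts$edges[ts$edges$from == prefix[length(prefix)], ]
  ext <- sum(vapply(succ$to, function(j)
    as.numeric(toy_path_probability(ts, c(prefix, j))), numeric(1)))
  expect_identical(ext, p_prefix)
})

test_that("the simulator is sound and statistically consistent", {
  ts <- enumerate_toy_state_space()
  # every simulated path stays inside the reachable set, along real edges
  for (seed in 1:20) {
    tr <- simulate_toy(seed = seed, max_steps = 20)
    states <- attr(tr, "states")
    idx <- vapply(states, function(s) toy_state_index(ts, s), integer(1))
    expect_false(anyNA(idx))
    for (k in seq_len(length(idx) - 1L))
      expect_true(any(ts$edges$from == idx[k] & ts$edges$to == idx[k + 1L]))
  }
  # initial observations: zero intracellular A and energy, cell lower-right
  tr <- simulate_toy(seed = 1)
  tp0 <- tr$timepoints[[1]]
  vals <- vapply(tp0$numeric, `[[`, numeric(1), "value")
  names(vals) <- vapply(tp0$numeric, `[[`, character(1), "name")
  expect_identical(unname(vals[c("A_intracellular", "Energy")]), c(0, 0))
  grids <- attr(tr, "grids")[[1]]
  expect_identical(grids[[1]]$values[2, 2], 1)
  expect_identical(sum(grids[[1]]$values), 1)
  expect_true(all(grids[[2]]$values == 1))

  # empirical split of the first move (state S2) is ~50/50
  n <- 4000L
  firsts <- vapply(seq_len(n), function(i) {
    tr <- simulate_toy(seed = 10000L + i, max_steps = 3)
    attr(tr, "states")[[4]]$pos[1]   # row of position after the first move
  }, integer(1))
  frac_up <- mean(firsts == 1L)
  # 3 sigma binomial band around 1/2
  expect_lt(abs(frac_up - 0.5), 3 * sqrt(0.25 / n))
})

test_that("simulated traces survive MSTML round trips and satisfy the energy property", {
  g <- toy_ma_graph()
  q <- parse_query(paste0(
    "P > 0.9 [F[0,3] ({Energy}(scaleAndSubsystem = ",
    "Intracellular.EnergyProductionReactionNetwork) > 0)]"), g)
  for (seed in 1:10) {
    tr <- simulate_toy(seed = seed, max_steps = 10)
    path <- withr::local_tempfile(fileext = ".xml")
    write_mstml(tr, path)
    tr2 <- read_mstml(path)
    expect_true(evaluate_query_on_trace(q, tr2, g))
  }
})

test_that("shape grids provide exact ground truth and reject overlap", {
  gs <- make_shape_grid(list(list(type = "rect", row = 2, col = 3,
                                  height = 3, width = 5)), 12, 12)
  gt <- attr(gs, "ground_truth")
  expect_identical(gt$area, 15L)
  expect_identical(gt$centroid_row, 2)
  expect_identical(gt$centroid_col, 4)

  empty <- make_shape_grid(list(), 5, 5)
  expect_true(all(empty$values == 0))

  expect_error(make_shape_grid(list(
    list(type = "rect", row = 1, col = 1, height = 3, width = 3),
    list(type = "rect", row = 2, col = 2, height = 3, width = 3)), 10, 10),
    class = "mstmc_error_spec")
  expect_error(make_shape_grid(list(
    list(type = "rect", row = 9, col = 9, height = 5, width = 5)), 10, 10),
    class = "mstmc_error_spec")
})

test_that("Bernoulli streams are reproducible with the stated moments", {
  expect_true(all(bernoulli_outcomes(1, 50, seed = 1)))
  expect_false(any(bernoulli_outcomes(0, 50, seed = 1)))
  b1 <- bernoulli_outcomes(0.7, 1000, seed = 42)
  b2 <- bernoulli_outcomes(0.7, 1000, seed = 42)
  expect_identical(b1, b2)
  big <- bernoulli_outcomes(0.7, 1e5, seed = 7)
  expect_lt(abs(mean(big) - 0.7), 0.01)
  expect_error(bernoulli_outcomes(1.2, 10), class = "mstmc_error_parameter")
})
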