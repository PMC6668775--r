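test_that("conditional probabilities are weighted co-occurrence ratios", {
  ev <- event_table(list("A"), list("O"))
  cp <- conditional_probs(ev)
  expect_equal(cp$cue_outcome["A", "O"], 1)
  expect_equal(cp$cue_cue["A", "A"], 1)

  ev2 <- event_table(list("A", c("A", "B")), list("O", "O"), c(1, 3))
  cp2 <- conditional_probs(ev2)
  expect_equal(cp2$cue_cue["A", "B"], 0.75)
  expect_equal(cp2$cue_cue["B", "A"], 1)

  ev3 <- event_table(list("A", "B"), list("O", "P"))
  expect_equal(conditional_probs(ev3)$cue_cue["A", "B"], 0)
})

test_that("a single always-predictive cue reaches the asymptote", {
  V <- solve_equilibrium(event_table(list("A"), list("O"), 5))
  expect_equal(V["A", "O"], 1)
})

test_that("blocking yields V_A = 1 and V_B = 0 for arbitrary weights", {
  for (w in list(c(1, 1), c(2, 5), c(10, 1), c(3, 300))) {
    V <- solve_equilibrium(event_table(list("A", c("A", "B")),
                                       list("O", "O"), w))
    expect_equal(V["A", "O"], 1, tolerance = 1e-10)
    expect_equal(V["B", "O"], 0, tolerance = 1e-10)
  }
})

test_that("the equilibrium is invariant to rescaling all event weights", {
  ev1 <- random_event_table(3)
  ev2 <- event_table(ev1$cues, ev1$outcomes, ev1$weights * 7)
  expect_equal(solve_equilibrium(ev1), solve_equilibrium(ev2),
               tolerance = 1e-12)
})

test_that("outcomes are learned independently of one another", {
  ev <- random_event_table(5)
  base <- solve_equilibrium(ev)
  # add an unrelated outcome to every event
  aug <- event_table(ev$cues,
                     lapply(ev$outcomes, c, "ZZZ"),
                     ev$weights)
  V <- solve_equilibrium(aug)
  expect_equal(V[, colnames(base)], base[, colnames(base)],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("equilibrium residuals vanish on seeded full-rank systems", {
  for (s in 1:10) {
    V <- solve_equilibrium(random_full_rank_table(s))
    expect_lt(attr(V, "residual"), 1e-8)
  }
})

test_that("the discrete update follows the learning rule case by case", {
  W <- matrix(0, 2, 1, dimnames = list(c("A", "B"), "O"))
  p <- rw_params(beta1 = 0.1)
  # cue present, outcome present, V = 0: delta = alpha * beta1 * lambda
  W1 <- rw_update(W, "A", "O", p)
  expect_equal(W1["A", "O"], 0.1)
  # absent cue unchanged
  expect_equal(W1["B", "O"], 0)
  # outcome absent: delta = alpha * beta2 * (0 - sum V)
  W2 <- matrix(c(0.5, 0), 2, 1, dimnames = list(c("A", "B"), "O"))
  W3 <- rw_update(W2, "A", character(0), rw_params(beta1 = 0.1, beta2 = 0.1))
  expect_equal(W3["A", "O"], 0.45)
  expect_error(rw_update(W, "C", "O"), "not indexed")
})

test_that("iterative learning is seeded, convergent and side-effect free", {
  ev <- event_table(list("A"), list("O"))
  expect_equal(simulate_learning(ev, n_trials = 0)["A", "O"], 0)

  V <- simulate_learning(ev, rw_params(beta1 = 0.1), n_trials = 500, seed = 2)
  expect_equal(V["A", "O"], 1, tolerance = 1e-3)

  ev2 <- random_event_table(11)
  a <- simulate_learning(ev2, n_trials = 200, seed = 42)
  b <- simulate_learning(ev2, n_trials = 200, seed = 42)
  expect_identical(a, b)

  set.seed(123)
  before <- .Random.seed
  invisible(simulate_learning(ev2, n_trials = 50, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("activation sums weights over known active cues plus back-off", {
  V <- solve_equilibrium(event_table(list("A", c("A", "B")),
                                     list("O", "O"), c(2, 3)))
  expect_equal(activation(V, "B")[["O"]], 0.01, tolerance = 1e-9)
  expect_equal(activation(V, c("A", "B"))[["O"]], 1.01, tolerance = 1e-9)
  # unknown cues contribute nothing
  expect_equal(activation(V, c("X", "Y"))[["O"]], 0.01)
  expect_equal(activation(V, "A", backoff = 0)[["O"]], 1, tolerance = 1e-9)
})
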