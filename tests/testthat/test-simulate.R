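test_that("parameter container enforces the ten positive parameters", {
  p <- ndra_params()
  expect_equal(p$w1, 1.270)
  expect_equal(p$w7, 450)
  expect_equal(p$w_lex, 4.700)
  expect_equal(p$backoff, 0.01)
  expect_equal(p$n_neighbors, 20)
  expect_length(unclass(p), 10L)
  expect_error(ndra_params(w2 = -1), "positive")
  expect_error(ndra_params(backoff = 0), "positive")
})

test_that("lexeme activation adds the back-off and floors at it", {
  model <- suppressWarnings(ndra_train(toy_lexicon("bear", "b8R")))
  la <- lexeme_activations(model, "bear", target = "BEAR")
  expect_equal(la$act_lexeme, 1.01, tolerance = 1e-9)
  # items without a lexical representation sit exactly at the back-off
  expect_equal(lexeme_activations(model, "bozz")$act_lexeme, 0.01)
  expect_error(lexeme_activations(model, "bozz", target = "BOZZ"),
               "not in the trained network")
})

test_that("neighbour ranking excludes the target and breaks ties stably", {
  acts <- c(APE = 0.5, BAT = 0.2, CAT = 0.2, DOG = -0.1)
  nb <- top_neighbors(acts, target = "APE", n = 20)
  expect_equal(nrow(nb), 3L)
  expect_equal(nb$lexeme, c("BAT", "CAT", "DOG"))  # tie: lexicographic
  expect_equal(nb$weight, c(0.2, 0.2, 0))          # floored at zero
  expect_equal(nrow(top_neighbors(acts, NULL, n = 2)), 2L)
})

test_that("demi-syllable activation follows the weighted-neighbour formula", {
  model <- suppressWarnings(ndra_train(toy_lexicon("bear", "b8R")))
  none <- data.frame(lexeme = character(0), activation = numeric(0),
                     weight = numeric(0))
  ap <- demisyllable_activations(model, c("b8", "8R"), "BEAR", none)
  expect_equal(ap, rep(4.700 * 0.5 + 0.01, 2), tolerance = 1e-9)
  # a non-word with no active neighbours bottoms out at the back-off
  ap0 <- demisyllable_activations(model, c("b8", "8R"), NULL, none)
  expect_equal(ap0, c(0.01, 0.01))
  expect_warning(
    apx <- demisyllable_activations(model, "zz", "BEAR", none),
    "not in the phonology network"
  )
  expect_equal(apx, 0.01)
})

test_that("selection entropy behaves like a two-outcome Shannon entropy", {
  expect_equal(demi_entropy(0.7, 0.7), 1)
  expect_equal(demi_entropy(0.8, 0.2), 0.7219, tolerance = 1e-4)
  expect_lt(demi_entropy(1e-6, 1), 1e-4)
  expect_error(demi_entropy(0, 1), "positive")
})

test_that("total activation integrates multiplicatively", {
  p <- ndra_params()
  expect_equal(total_activation(1, 1, 1, 1, 1, p), 1)
  base <- total_activation(100, 1, 2, 2, 0.9, p)
  expect_equal(total_activation(100, 2, 2, 2, 0.9, p) / base, 2^(-p$w2),
               tolerance = 1e-12)
  # entropy is floored at the back-off rather than zeroing the latency
  expect_gt(total_activation(100, 1, 2, 2, 0, p), 0)
})

test_that("latencies are a linear transform of activation", {
  expect_equal(simulate_rt(0), 450)
  expect_equal(simulate_rt(1000), 505)
  p <- ndra_params()
  a <- 123.4
  expect_equal(simulate_rt(2 * a, p) - simulate_rt(a, p), p$w6 * a)
})

test_that("batch simulation is deterministic and complete", {
  fx <- cached_fixture()
  items <- fx$lexicon$orthography[1:8]
  p1 <- ndra_simulate(fx$model, items)
  p2 <- ndra_simulate(fx$model, items)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 8L)
  expect_false(any(p1$failed))
  expect_true(all(p1$ActLexeme >= 0.01))
  expect_true(all(p1$H >= 0 & p1$H <= 1))
  expect_equal(p1$RT, 0.055 * p1$Act + 450)
  expect_equal(nrow(ndra_simulate(fx$model, character(0))), 0L)
})

test_that("sub-lexical measures are reported but never enter Act", {
  fx <- cached_fixture()
  items <- fx$lexicon$orthography[1:5]
  plain <- ndra_simulate(fx$model, items)
  subl <- ndra_simulate(fx$model, items, sublexical = TRUE)
  expect_true(all(c("ActPhonSub1", "ActPhonSub2", "HSub") %in% names(subl)))
  expect_equal(subl$Act, plain$Act)
  no_sub <- suppressWarnings(ndra_train(toy_lexicon("bear", "b8R")))
  expect_error(ndra_simulate(no_sub, "bear", sublexical = TRUE),
               "without a sub-lexical")
})

test_that("unsimulatable items come back as failed rows", {
  fx <- cached_fixture()
  out <- ndra_simulate(fx$model, c(fx$lexicon$orthography[1L], "qqqq"))
  expect_false(out$failed[1L])
  expect_true(out$failed[2L])
  expect_true(is.na(out$RT[2L]))
})
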