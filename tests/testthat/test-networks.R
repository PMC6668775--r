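test_that("a one-word lexicon learns its lexeme at the asymptote", {
  lex <- toy_lexicon("bear", "b8R", 20000)
  V <- build_o2l(lex)
  cues <- extract_cues("bear")
  expect_equal(sum(V[cues, "BEAR"]), 1, tolerance = 1e-10)
  expect_equal(unname(activation(V, cues, backoff = 0)["BEAR"]), 1,
               tolerance = 1e-10)
})

test_that("orthographically disjoint words do not interact", {
  lex <- toy_lexicon(c("bim", "zog"), c("bIm", "zQg"))
  V <- build_o2l(lex)
  expect_equal(max(abs(V[extract_cues("bim"), "ZOG"])), 0, tolerance = 1e-10)
  expect_equal(max(abs(V[extract_cues("zog"), "BIM"])), 0, tolerance = 1e-10)
})

test_that("a unique phonology splits its weight evenly over both halves", {
  V <- build_p2l(toy_lexicon("bear", "b8R"))
  expect_equal(unname(V["b8", "BEAR"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(V["8R", "BEAR"]), 0.5, tolerance = 1e-10)
})

test_that("sharing a demi-syllable dilutes its association to each lexeme", {
  # a phonological neighbour (hair) lowers BEAR -> 8R; this is the
  # mechanism behind inhibitory phonological neighbourhood effects
  alone <- build_p2l(toy_lexicon("bear", "b8R"))
  crowd <- build_p2l(toy_lexicon(c("bear", "hair"), c("b8R", "h8R")))
  expect_lt(crowd["8R", "BEAR"], alone["8R", "BEAR"])
  expect_equal(unname(crowd["8R", "BEAR"]), 1 / 3, tolerance = 1e-10)
})

test_that("the sub-lexical network activates both halves at the asymptote", {
  V <- build_sublexical(toy_lexicon("bear", "b8R"))
  a <- activation(V, extract_cues("bear"), backoff = 0)
  expect_equal(unname(a[c("b8", "8R")]), c(1, 1), tolerance = 1e-10)
})

test_that("raising a word's frequency never lowers its own cue weights", {
  lo <- build_o2l(toy_lexicon(c("bat", "cat"), c("b{t", "k{t"), c(10, 10)))
  hi <- build_o2l(toy_lexicon(c("bat", "cat"), c("b{t", "k{t"), c(100, 10)))
  cues <- extract_cues("bat")
  expect_true(all(hi[cues, "BAT"] >= lo[cues, "BAT"] - 1e-12))
})

test_that("training is deterministic given the lexicon", {
  lex <- generate_lexicon(fixture_config(seed = 3, n_words = 60,
                                         n_bodies = 20))
  m1 <- suppressWarnings(ndra_train(lex))
  m2 <- suppressWarnings(ndra_train(lex))
  expect_equal(m1$o2l, m2$o2l, tolerance = 1e-12)
  expect_equal(m1$p2l, m2$p2l, tolerance = 1e-12)
})

test_that("the transpose contract holds in demi-syllable activation", {
  fx <- cached_fixture()
  model <- fx$model
  entry <- model$training[1L, ]
  neighbors <- data.frame(lexeme = character(0), activation = numeric(0),
                          weight = numeric(0))
  ap <- demisyllable_activations(model, c(entry$demi1, entry$demi2),
                                 target = entry$lexeme, neighbors = neighbors)
  b <- model$params$backoff
  wl <- model$params$w_lex
  expect_equal(ap[1L],
               max(wl * model$p2l[entry$demi1, entry$lexeme] + b, b))
  expect_equal(ap[2L],
               max(wl * model$p2l[entry$demi2, entry$lexeme] + b, b))
})

test_that("non-word entries only enter training when asked", {
  lex <- toy_lexicon(c("bim", "zog", "fap"), c("bIm", "zQg", "f{p"),
                     nonword = c(FALSE, FALSE, TRUE))
  m_off <- ndra_train(lex)
  m_on <- ndra_train(lex, include_nonwords = TRUE)
  expect_false("FAP" %in% colnames(m_off$o2l))
  expect_true("FAP" %in% colnames(m_on$o2l))
})

test_that("training refuses an empty lexicon", {
  empty <- as_lexicon(data.frame(orthography = character(),
                                 disc = character(),
                                 frequency = numeric()))
  expect_error(build_p2l(empty), "no trainable")
})
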