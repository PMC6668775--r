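# A small lexicon with the candidate structure of the bap example: words
# sharing the orthographic onset+vowel provide the first demi-syllable,
# words sharing the rhyme provide the second.
bap_lexicon <- function() {
  toy_lexicon(
    c("back", "ball", "bat", "chap", "lap", "map", "cat", "call"),
    c("b{k", "b$l", "b{t", "J{p", "l{p", "m{p", "k{t", "k$l"),
    c(300, 200, 150, 120, 260, 80, 90, 70)
  )
}

test_that("assembly joins the halves over the shared nucleus", {
  expect_equal(assemble("b8", "8R"), "b8R")
  expect_equal(assemble("b{", "{p"), "b{p")
  expect_equal(assemble("8", "8R"), "8R")
  expect_error(assemble("b8", "{nd"), "mismatch")
})

test_that("vowel conflicts defer to the second demi-syllable", {
  cand <- c(b8 = 0.9, "b{" = 0.4)
  # nuclei agree: top candidate kept
  expect_equal(resolve_vowel_conflict(cand, "8R")$demi, "b8")
  # conflict: highest candidate with the second half's nucleus
  res <- resolve_vowel_conflict(cand, "{nd")
  expect_equal(res$demi, "b{")
  expect_false(res$synthesized)
  # no matching candidate: synthesize onset + nucleus, flagged
  res2 <- resolve_vowel_conflict(c(b8 = 0.9), "{nd")
  expect_equal(res2$demi, "b{")
  expect_true(res2$synthesized)
})

test_that("words are pronounced through their own lexeme", {
  model <- suppressWarnings(ndra_train(bap_lexicon()))
  r <- pronounce_word(model, "back")
  expect_false(r$failed)
  expect_equal(r$assembled, "b{k")
  expect_equal(r$route, "word-target")
  expect_equal(r$assembled, assemble(r$first, r$second))
  # single-word lexicon reproduces its own transcription
  solo <- suppressWarnings(ndra_train(toy_lexicon("bear", "b8R")))
  expect_equal(pronounce_word(solo, "bear")$assembled, "b8R")
  expect_error(pronounce_word(solo, "fear"), "no lexeme")
})

test_that("homophone spellings receive identical pronunciations", {
  lex <- toy_lexicon(
    c("meet", "meat", "heat", "heet", "bean", "been"),
    c("mit", "mit", "hit", "hit", "bin", "bin"),
    c(100, 90, 80, 70, 60, 50)
  )
  model <- suppressWarnings(ndra_train(lex))
  expect_equal(pronounce_word(model, "meet")$assembled,
               pronounce_word(model, "meat")$assembled)
})

test_that("non-words are assembled from onset+vowel and rhyme sharers", {
  model <- suppressWarnings(ndra_train(bap_lexicon()))
  r <- pronounce_nonword(model, "bap")
  expect_false(r$failed)
  expect_equal(r$first, "b{")
  expect_equal(r$second, "{p")
  expect_equal(r$assembled, "b{p")
  expect_equal(r$route, "nonword-neighbors")
})

test_that("missing onset+vowel sharers trigger the onset-only fallback", {
  model <- suppressWarnings(ndra_train(bap_lexicon()))
  r <- pronounce_nonword(model, "bip")  # no b+i word in the lexicon
  expect_equal(r$route, "fallback-onset")
  expect_false(r$failed)
  # entirely alien material cannot be pronounced
  r2 <- pronounce_nonword(model, "vun")
  expect_true(r2$failed)
})

test_that("non-word output only ever uses attested demi-syllables", {
  fx <- cached_fixture()
  nw <- generate_nonwords(fx$lexicon, seed = 77, n = 60)
  pr <- pronounce(fx$model, nw$orthography, nonword = TRUE)
  ok <- !pr$failed
  expect_true(all(pr$first[ok] %in% fx$model$demis1))
  expect_true(all(pr$second[ok] %in% fx$model$demis2))
})

test_that("tie handling is deterministic and falls back gracefully", {
  model <- suppressWarnings(ndra_train(bap_lexicon()))
  # no tie: candidate returned unchanged
  expect_equal(tie_fallback(model, "bap", "b{", 1L), "b{")
  # forced artificial tie resolves deterministically
  w <- pmax(activation(model$o2l, extract_cues("bap"), 0), 0)
  r1 <- tie_fallback(model, "bap", c("b{", "b$"), 1L, w)
  r2 <- tie_fallback(model, "bap", c("b{", "b$"), 1L, w)
  expect_identical(r1, r2)
  expect_true(r1 %in% c("b{", "b$"))
})

test_that("batch pronunciation returns one row per item", {
  fx <- cached_fixture()
  items <- fx$lexicon$orthography[1:6]
  out <- pronounce(fx$model, items)
  expect_equal(out$item, items)
  expect_false(any(out$failed))
  expect_equal(out$assembled,
               fx$lexicon$disc[match(items, fx$lexicon$orthography)])
  # results and traces are reproducible
  expect_identical(out, pronounce(fx$model, items))
})
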