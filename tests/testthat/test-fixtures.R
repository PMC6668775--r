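test_that("lexicon generation is deterministic and valid by construction", {
  cfg <- fixture_config(seed = 11, n_words = 120, n_bodies = 40)
  l1 <- generate_lexicon(cfg)
  l2 <- generate_lexicon(cfg)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  expect_s3_class(l1, "ndra_lexicon")
  expect_equal(nrow(l1), 120L)
  expect_false(anyDuplicated(l1$orthography) > 0)
  expect_true(all(l1$frequency >= 1))
  expect_true(all(nchar(l1$orthography) >= 3L))
})

test_that("a fully consistent lexicon maps each body to one rime", {
  lex <- generate_lexicon(fixture_config(seed = 5, n_words = 200,
                                         n_bodies = 50,
                                         consistency_mix = 0))
  rime_of <- function(d) split_demisyllables(d)$second
  rimes_per_body <- tapply(vapply(lex$disc, rime_of, ""), lex$body,
                           function(x) length(unique(x)))
  expect_true(all(rimes_per_body == 1L))
})

test_that("inconsistent bodies carry a second, minority pronunciation", {
  lex <- generate_lexicon(fixture_config(seed = 5, n_words = 200,
                                         n_bodies = 50,
                                         consistency_mix = 0.5))
  rime_of <- function(d) split_demisyllables(d)$second
  rimes <- vapply(lex$disc, rime_of, "")
  n_rimes <- tapply(rimes, lex$body, function(x) length(unique(x)))
  incons <- unique(lex$body[!lex$consistent])
  expect_true(all(n_rimes[incons] == 2L))
  expect_true(all(n_rimes[setdiff(names(n_rimes), incons)] == 1L))
  # the alternative pronunciation sits on the lower-frequency members
  for (b in incons[1:5]) {
    fam <- lex[lex$body == b, ]
    fam_rime <- vapply(fam$disc, rime_of, "")
    lower <- fam$frequency < stats::median(fam$frequency)
    expect_length(unique(fam_rime[lower]), 1L)
    expect_length(unique(fam_rime[!lower]), 1L)
    expect_false(unique(fam_rime[lower]) == unique(fam_rime[!lower]))
  }
})

test_that("family sizes follow the configured word/body ratio", {
  lex <- generate_lexicon(fixture_config(seed = 2, n_words = 50,
                                         n_bodies = 10))
  expect_equal(mean(table(lex$body)), 5)
})

test_that("token frequencies follow the configured Zipf law", {
  for (s in c(1, 9)) {
    lex <- generate_lexicon(fixture_config(seed = s, n_words = 300,
                                           n_bodies = 75))
    f <- sort(lex$frequency, decreasing = TRUE)
    slope <- unname(coef(lm(log(f) ~ log(seq_along(f))))[2L])
    expect_lt(abs(slope + 1), 0.2)
  }
})

test_that("impossible configurations are rejected", {
  inv <- fixture_inventories()
  expect_error(generate_lexicon(fixture_config(seed = 1, n_words = 4000,
                                               n_bodies = 4000)),
               "inventory too small")
  expect_error(generate_lexicon(fixture_config(seed = 1, n_words = 60,
                                               n_bodies = 2)),
               "inventory too small")
})

test_that("generated non-words are novel recombinations of attested parts", {
  fx <- cached_fixture()
  nw <- generate_nonwords(fx$lexicon, seed = 13, n = 80)
  expect_equal(nrow(nw), 80L)
  expect_false(any(nw$orthography %in% fx$lexicon$orthography))
  word_parts <- lapply(fx$lexicon$orthography, orthographic_parts)
  onsets <- unique(vapply(word_parts, `[[`, "", "onset"))
  rhymes <- unique(vapply(word_parts, `[[`, "", "rhyme"))
  nw_parts <- lapply(nw$orthography, orthographic_parts)
  expect_true(all(vapply(nw_parts, `[[`, "", "onset") %in% onsets))
  expect_true(all(vapply(nw_parts, `[[`, "", "rhyme") %in% rhymes))
  # both candidate demi-syllables are attested in the lexicon phonology
  demi1 <- vapply(nw$disc_candidate,
                  function(d) split_demisyllables(d)$first, "")
  demi2 <- vapply(nw$disc_candidate,
                  function(d) split_demisyllables(d)$second, "")
  expect_true(all(demi1 %in% fx$model$demis1))
  expect_true(all(demi2 %in% fx$model$demis2))
  # pseudo-homophones are exactly the items sounding like real words
  expect_equal(nw$pseudo_homophone, nw$disc_candidate %in% fx$lexicon$disc)
})

test_that("exhausting the combination space warns and returns fewer", {
  lex <- toy_lexicon(c("bat", "cat", "bap", "cap"),
                     c("b{t", "k{t", "b{p", "k{p"))
  expect_warning(nw <- generate_nonwords(lex, seed = 1, n = 50), "requested")
  expect_lt(nrow(nw), 50L)
})

test_that("the matched designs deliver the advertised controls", {
  d <- generate_neighborhood_design(seed = 4, n_units = 30)
  expect_equal(nrow(d$targets), 30L)
  lex <- d$lexicon
  idx <- function(w) match(w, lex$orthography)
  # frequency and length matched within units; rimes phonologically shared
  expect_equal(lex$frequency[idx(d$targets$dense)],
               lex$frequency[idx(d$targets$sparse)])
  expect_equal(nchar(d$targets$dense), nchar(d$targets$sparse))
  rime2 <- function(w) split_demisyllables(lex$disc[idx(w)])$second
  expect_equal(vapply(d$targets$dense, rime2, ""),
               vapply(d$targets$sparse, rime2, ""),
               ignore_attr = TRUE)

  dc <- generate_consistency_design(seed = 4, n_units = 30)
  lex2 <- dc$lexicon
  idx2 <- function(w) match(w, lex2$orthography)
  expect_equal(lex2$frequency[idx2(dc$targets$consistent)],
               lex2$frequency[idx2(dc$targets$inconsistent)])
  expect_equal(nchar(dc$targets$consistent), nchar(dc$targets$inconsistent))
  expect_equal(lex2$disc[idx2(dc$targets$consistent)],
               lex2$disc[idx2(dc$targets$inconsistent)])
})
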