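# Shared fixtures: all built in code, deterministically.

# Random small event table; cue and outcome coverage by rejection.
random_event_table <- function(seed, max_cues = 6L, max_outcomes = 4L) {
  for (try in 0:99) {
    set.seed(seed * 1000L + try)
    nc <- sample(2:max_cues, 1L)
    nk <- sample(1:max_outcomes, 1L)
    ne <- sample(4:10, 1L)
    cues <- lapply(seq_len(ne), function(i) {
      sample(letters[1:nc], sample(1:min(3L, nc), 1L))
    })
    outs <- lapply(seq_len(ne), function(i) {
      sample(LETTERS[1:nk], sample(1:min(2L, nk), 1L))
    })
    if (length(unique(unlist(cues))) == nc &&
        length(unique(unlist(outs))) == nk) {
      return(event_table(cues, outs, sample(1:5, ne, replace = TRUE)))
    }
  }
  stop("could not build a covered event table for seed ", seed)
}

# Like random_event_table but only full-rank cue systems.
random_full_rank_table <- function(seed) {
  for (bump in 0:99) {
    ev <- random_event_table(seed + 7919L * bump)
    C <- conditional_probs(ev)$cue_cue
    if (qr(C)$rank == ncol(C)) return(ev)
  }
  stop("no full-rank table found for seed ", seed)
}

toy_lexicon <- function(orth, disc, freq = rep(10, length(orth)),
                        nonword = FALSE) {
  as_lexicon(data.frame(orthography = orth, disc = disc, frequency = freq,
                        is_nonword = nonword))
}

# One shared small trained model for read-mostly tests.
.test_cache <- new.env(parent = emptyenv())
cached_fixture <- function() {
  if (is.null(.test_cache$fixture)) {
    lex <- generate_lexicon(fixture_config(seed = 7, n_words = 300,
                                           n_bodies = 90,
                                           consistency_mix = 0))
    .test_cache$fixture <- list(
      lexicon = lex,
      model = suppressWarnings(ndra_train(lex, sublexical = TRUE))
    )
  }
  .test_cache$fixture
}
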