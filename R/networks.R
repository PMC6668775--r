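# Construction of the model's trained networks from a lexicon:
# orthography -> lexeme, demi-syllable -> lexeme (read transposed at run
# time), and the optional sub-lexical orthography -> demi-syllable network.

lexeme_of <- function(orthography) toupper(orthography)

# Entries that enter training: words by default, plus flagged non-words on
# request; 1-2 letter entries are excluded (they would favour the bigram
# coding scheme) with a warning.
.training_entries <- function(lexicon, include_nonwords = FALSE) {
  stopifnot(inherits(lexicon, "ndra_lexicon"))
  keep <- if (include_nonwords) rep(TRUE, nrow(lexicon)) else !lexicon$is_nonword
  entries <- lexicon[keep, , drop = FALSE]
  short <- nchar(entries$orthography) < 3L
  if (any(short)) {
    warning(sum(short), " entr(ies) shorter than 3 letters excluded from training",
            call. = FALSE)
    entries <- entries[!short, , drop = FALSE]
  }
  if (nrow(entries) == 0L) stop("no trainable lexicon entries", call. = FALSE)
  entries
}

#' Train the orthography-to-lexeme network
#'
#' One learning event per lexicon entry: the entry's letter and bigram cues
#' predict its lexeme (uppercase orthography), weighted by token frequency.
#' Solved with the equilibrium equations.
#'
#' @param lexicon An `ndra_lexicon`.
#' @param include_nonwords Include entries flagged `is_nonword` in training
#'   (used to study frequency effects for non-words; off by default).
#' @return Cue x lexeme weight matrix.
#' @export
build_o2l <- function(lexicon, include_nonwords = FALSE) {
  entries <- .training_entries(lexicon, include_nonwords)
  ev <- event_table(
    cues = lapply(entries$orthography, extract_cues),
    outcomes = as.list(lexeme_of(entries$orthography)),
    weights = entries$frequency
  )
  solve_equilibrium(ev)
}

#' Train the phonology network (demi-syllables as cues, lexemes as outcomes)
#'
#' Although activation at run time flows from lexemes to demi-syllables, the
#' network is trained in the reverse direction -- demi-syllables as cues and
#' lexemes as outcomes -- because a one-to-many mapping is learned more
#' discriminatively than a many-to-one mapping, and because perception
#' precedes production in acquisition. Run-time lexeme-to-demi-syllable flow
#' reads the transpose: the weight from lexeme L to demi-syllable D is
#' exactly `V[D, L]`.
#'
#' @inheritParams build_o2l
#' @param nuclei DISC nucleus inventory used to split transcriptions.
#' @return Demi-syllable x lexeme weight matrix.
#' @export
build_p2l <- function(lexicon, include_nonwords = FALSE, nuclei = disc_nuclei()) {
  entries <- .training_entries(lexicon, include_nonwords)
  demis <- lapply(entries$disc, function(p) {
    unlist(split_demisyllables(p, nuclei), use.names = FALSE)
  })
  ev <- event_table(
    cues = demis,
    outcomes = as.list(lexeme_of(entries$orthography)),
    weights = entries$frequency
  )
  solve_equilibrium(ev)
}

#' Train the sub-lexical orthography-to-phonology network
#'
#' A direct Rescorla-Wagner mapping from letter/bigram cues to demi-syllable
#' outcomes, trained on the same events as the lexical networks. Its
#' activations are reported alongside the lexical measures for dual-route
#' comparisons; they are never integrated into the simulated latency.
#'
#' @inheritParams build_p2l
#' @return Cue x demi-syllable weight matrix.
#' @export
build_sublexical <- function(lexicon, include_nonwords = FALSE,
                             nuclei = disc_nuclei()) {
  entries <- .training_entries(lexicon, include_nonwords)
  demis <- lapply(entries$disc, function(p) {
    unlist(split_demisyllables(p, nuclei), use.names = FALSE)
  })
  ev <- event_table(
    cues = lapply(entries$orthography, extract_cues),
    outcomes = demis,
    weights = entries$frequency
  )
  solve_equilibrium(ev)
}

#' Train a complete reading-aloud model
#'
#' Builds the orthography-to-lexeme and phonology networks (and optionally
#' the sub-lexical network) from a lexicon and packages them together with
#' the letter-complexity table and the simulation parameters.
#'
#' @inheritParams build_p2l
#' @param sublexical Also train the sub-lexical network.
#' @param params Simulation parameters, see [ndra_params()].
#' @param glyphs Glyph set for the visual front end.
#' @return An object of class `ndra_model`.
#' @export
#' @examples
#' lex <- generate_lexicon(fixture_config(seed = 1, n_words = 60, n_bodies = 20))
#' model <- ndra_train(lex)
#' model
ndra_train <- function(lexicon, sublexical = FALSE, include_nonwords = FALSE,
                       params = ndra_params(), glyphs = load_fixture_glyphs(),
                       nuclei = disc_nuclei()) {
  entries <- .training_entries(lexicon, include_nonwords)
  splits <- lapply(entries$disc, split_demisyllables, nuclei = nuclei)
  parts <- lapply(entries$orthography, orthographic_parts)
  training <- data.frame(
    orthography = entries$orthography,
    disc = entries$disc,
    frequency = entries$frequency,
    is_nonword = entries$is_nonword,
    lexeme = lexeme_of(entries$orthography),
    demi1 = vapply(splits, `[[`, "", "first"),
    demi2 = vapply(splits, `[[`, "", "second"),
    onset = vapply(parts, `[[`, "", "onset"),
    vowel = vapply(parts, `[[`, "", "vowel"),
    coda = vapply(parts, `[[`, "", "coda"),
    rhyme = vapply(parts, `[[`, "", "rhyme"),
    stringsAsFactors = FALSE
  )
  model <- structure(
    list(
      o2l = build_o2l(lexicon, include_nonwords),
      p2l = build_p2l(lexicon, include_nonwords, nuclei),
      sublex = if (sublexical) build_sublexical(lexicon, include_nonwords, nuclei),
      lexicon = lexicon,
      training = training,
      demis1 = sort(unique(training$demi1), method = "radix"),
      demis2 = sort(unique(training$demi2), method = "radix"),
      params = params,
      nuclei = nuclei,
      complexity = letter_complexity(glyphs)
    ),
    class = "ndra_model"
  )
  model
}

#' @export
print.ndra_model <- function(x, ...) {
  cat("<ndra_model>\n")
  cat("  orthography -> lexeme: ", nrow(x$o2l), " cues x ", ncol(x$o2l),
      " lexemes\n", sep = "")
  cat("  demi-syllable network: ", nrow(x$p2l), " demi-syllables x ",
      ncol(x$p2l), " lexemes\n", sep = "")
  if (!is.null(x$sublex)) {
    cat("  sub-lexical network:   ", nrow(x$sublex), " cues x ",
        ncol(x$sublex), " demi-syllables\n", sep = "")
  }
  cat("  trained on ", nrow(x$training), " lexicon entries\n", sep = "")
  invisible(x)
}
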