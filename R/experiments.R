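# Canned simulation experiments on synthetic lexica: the benchmark effects
# from the reading aloud literature, each as a seeded, self-contained
# procedure returning the group means and the significance of the contrast.

#' Orthographic neighbourhood density (Coltheart's N)
#'
#' Number of same-length words differing from the target in exactly one
#' letter position.
#'
#' @param words Character vector of word forms.
#' @param against Vocabulary to count neighbours in (defaults to `words`).
#' @return Integer vector of neighbourhood sizes.
#' @export
coltheart_neighbors <- function(words, against = words) {
  chars <- strsplit(against, "", fixed = TRUE)
  lens <- nchar(against)
  vapply(words, function(w) {
    cw <- strsplit(w, "", fixed = TRUE)[[1L]]
    same_len <- which(lens == length(cw) & against != w)
    sum(vapply(same_len, function(i) {
      sum(chars[[i]] != cw) == 1L
    }, TRUE))
  }, 0L, USE.NAMES = FALSE)
}

#' Word versus non-word naming latencies
#'
#' Trains a model on a synthetic lexicon, simulates naming latencies for
#' the words and for non-words recombining attested onsets and bodies, and
#' tests whether non-words are named slower.
#'
#' @param seed Integer seed.
#' @param n_items Words and non-words per group.
#' @param config Lexicon configuration (defaults to [fixture_config()]
#'   with this seed).
#' @return List with the group mean latencies, their difference and the
#'   one-sided p-value of the contrast.
#' @export
experiment_lexicality <- function(seed = 1L, n_items = 200L, config = NULL) {
  if (is.null(config)) config <- fixture_config(seed = seed)
  lex <- generate_lexicon(config)
  model <- suppressWarnings(ndra_train(lex))
  nw <- generate_nonwords(lex, seed = seed + 1L, n = n_items)
  words <- .with_seed(seed + 2L, sample(lex$orthography, n_items))
  pw <- ndra_simulate(model, words)
  pn <- ndra_simulate(model, nw$orthography)
  tt <- stats::t.test(pn$RT, pw$RT, alternative = "greater")
  list(
    mean_rt_words = mean(pw$RT, na.rm = TRUE),
    mean_rt_nonwords = mean(pn$RT, na.rm = TRUE),
    difference = mean(pn$RT, na.rm = TRUE) - mean(pw$RT, na.rm = TRUE),
    p_value = tt$p.value,
    n = n_items
  )
}

#' Orthographic neighbourhood density effect
#'
#' Simulates latencies for every word of a synthetic lexicon, splits the
#' items at the median neighbourhood density, and tests whether
#' dense-neighbourhood words are named faster. The scaled linear effect of
#' the density predictor is reported alongside.
#'
#' @inheritParams experiment_lexicality
#' @return List with group means, mean difference (sparse minus dense),
#'   one-sided p-value, and the standardized regression slope `beta`.
#' @export
experiment_neighborhood <- function(seed = 1L, config = NULL) {
  if (is.null(config)) config <- fixture_config(seed = seed)
  lex <- generate_lexicon(config)
  model <- suppressWarnings(ndra_train(lex))
  prof <- ndra_simulate(model, lex$orthography)
  n_density <- coltheart_neighbors(lex$orthography)
  dense <- n_density > stats::median(n_density)
  tt <- stats::t.test(prof$RT[!dense], prof$RT[dense], alternative = "greater")
  eff <- linear_effect(n_density, prof$RT, "orthographic_N")
  list(
    mean_rt_dense = mean(prof$RT[dense], na.rm = TRUE),
    mean_rt_sparse = mean(prof$RT[!dense], na.rm = TRUE),
    difference = mean(prof$RT[!dense], na.rm = TRUE) -
      mean(prof$RT[dense], na.rm = TRUE),
    p_value = tt$p.value,
    beta = eff$beta,
    t = eff$t,
    n = nrow(prof)
  )
}

#' Spelling-to-sound consistency effect
#'
#' Runs matched-pair consistency designs (see
#' [generate_consistency_design()]): each unit pairs a fully consistent
#' target with an inconsistent target that shares rime, onset,
#' word-initial demi-syllable, frequency and family structure, and differs
#' only in how many of its body neighbours support the target rime.
#' Several replicate designs are pooled and the paired latency difference
#' is tested; the default of five 150-unit replicates reflects the power
#' needed to detect the expected ~2 ms paired contrast against ~13 ms of
#' between-unit equilibrium noise.
#'
#' @param seed Integer seed.
#' @param n_units Units per replicate design.
#' @param replicates Number of independent replicate designs.
#' @param family_size,n_enemies Family structure per unit.
#' @return List with pooled means, mean paired difference (inconsistent
#'   minus consistent) and its one-sided p-value.
#' @export
experiment_consistency <- function(seed = 1L, n_units = 150L,
                                   replicates = 5L, family_size = 6L,
                                   n_enemies = 3L) {
  diffs <- numeric(0)
  cons <- incons <- numeric(0)
  for (r in seq_len(replicates)) {
    d <- generate_consistency_design(seed = seed + 101L * r,
                                     n_units = n_units,
                                     family_size = family_size,
                                     n_enemies = n_enemies)
    model <- suppressWarnings(ndra_train(d$lexicon))
    pc <- ndra_simulate(model, d$targets$consistent)
    pi_ <- ndra_simulate(model, d$targets$inconsistent)
    diffs <- c(diffs, pi_$RT - pc$RT)
    cons <- c(cons, pc$RT)
    incons <- c(incons, pi_$RT)
  }
  tt <- stats::t.test(diffs, alternative = "greater")
  list(
    mean_rt_consistent = mean(cons, na.rm = TRUE),
    mean_rt_inconsistent = mean(incons, na.rm = TRUE),
    difference = mean(diffs, na.rm = TRUE),
    p_value = tt$p.value,
    n = length(diffs)
  )
}

#' Non-word frequency effect after retraining
#'
#' Adds non-words to the training lexicon at two token-frequency tiers
#' (scaled to the synthetic corpus: the high tier sits at the level of a
#' low-frequency word, the low tier far below the corpus inclusion
#' threshold), retrains the model with unchanged parameters, and simulates
#' the retrained non-words through their newly acquired lexical
#' representations. A crossover design (each item high in one retraining
#' and low in the other) gives a within-item contrast.
#'
#' @param seed Integer seed.
#' @param n_items Number of non-words.
#' @param high_frequency,low_frequency Token frequencies of the two tiers.
#' @param config Base lexicon configuration.
#' @return List with tier means, mean within-item difference (low minus
#'   high) and its one-sided p-value.
#' @export
experiment_nonword_frequency <- function(seed = 1L, n_items = 200L,
                                         high_frequency = 4600,
                                         low_frequency = 5,
                                         config = NULL) {
  if (is.null(config)) config <- fixture_config(seed = seed)
  lex <- generate_lexicon(config)
  nw <- generate_nonwords(lex, seed = seed + 1L, n = n_items)
  half <- nrow(nw) %/% 2L
  hi_first <- .with_seed(seed + 2L, sort(sample(nrow(nw), half)))
  tier_hi <- seq_len(nrow(nw)) %in% hi_first
  rt <- matrix(NA_real_, nrow(nw), 2L)
  base <- as.data.frame(lex)[, c("orthography", "disc", "frequency",
                                 "is_nonword")]
  for (phase in 1:2) {
    f <- ifelse(tier_hi == (phase == 1L), high_frequency, low_frequency)
    full <- as_lexicon(rbind(base, data.frame(
      orthography = nw$orthography, disc = nw$disc_candidate,
      frequency = f, is_nonword = TRUE
    )))
    model <- suppressWarnings(ndra_train(full, include_nonwords = TRUE))
    rt[, phase] <- ndra_simulate(model, nw$orthography, nonword = FALSE)$RT
  }
  rt_hi <- ifelse(tier_hi, rt[, 1L], rt[, 2L])
  rt_lo <- ifelse(tier_hi, rt[, 2L], rt[, 1L])
  tt <- stats::t.test(rt_lo - rt_hi, alternative = "greater")
  list(
    mean_rt_high = mean(rt_hi, na.rm = TRUE),
    mean_rt_low = mean(rt_lo, na.rm = TRUE),
    difference = mean(rt_lo - rt_hi, na.rm = TRUE),
    p_value = tt$p.value,
    n = nrow(nw)
  )
}
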