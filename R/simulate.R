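# Per-item activation profiles and simulated naming latencies.

#' Simulation parameters
#'
#' The model's ten free parameters. `w1`-`w5` are the exponents of the
#' multiplicative integration of visual complexity, lexeme activation, the
#' two demi-syllable activations and their entropy; `w6` (slope, ms per
#' activation unit) and `w7` (intercept, ms) map total activation onto a
#' simulated naming latency; `w_lex` is the relative weight of the target
#' lexeme against co-activated orthographic neighbours in demi-syllable
#' activation; `backoff` is the additive floor applied to all activations
#' (it prevents division by zero in the latency formula); `n_neighbors` is
#' the number of co-activated lexemes taken into account.
#'
#' @param w1 Exponent of visual complexity (facilitates longer latencies).
#' @param w2 Exponent of lexeme activation.
#' @param w3 Exponent of the first demi-syllable activation.
#' @param w4 Exponent of the second demi-syllable activation.
#' @param w5 Exponent of the demi-syllable entropy.
#' @param w6 Latency slope in ms per activation unit.
#' @param w7 Latency intercept in ms.
#' @param w_lex Weight of the target lexeme in demi-syllable activation.
#' @param backoff Back-off constant added to activations.
#' @param n_neighbors Number of co-activated orthographic neighbours.
#' @return List of class `ndra_params`.
#' @export
ndra_params <- function(w1 = 1.270, w2 = 0.200, w3 = 0.050, w4 = 0.098,
                        w5 = 0.152, w6 = 0.055, w7 = 450, w_lex = 4.700,
                        backoff = 0.01, n_neighbors = 20) {
  p <- list(w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5, w6 = w6, w7 = w7,
            w_lex = w_lex, backoff = backoff, n_neighbors = n_neighbors)
  if (any(vapply(p, length, 1L) != 1L) || any(unlist(p) <= 0)) {
    stop("all simulation parameters must be positive scalars", call. = FALSE)
  }
  structure(p, class = "ndra_params")
}

#' Lexeme activations for an orthographic input
#'
#' Sums the orthography-to-lexeme weights over the active letter and bigram
#' cues for every lexeme (raw, without back-off) and derives the target
#' lexeme activation `ActLexeme`: the target's raw activation (floored at 0)
#' plus the back-off constant for words, and exactly the back-off constant
#' for items without a lexical representation (non-words).
#'
#' @param model A trained `ndra_model`.
#' @param orthography Item to present.
#' @param target Target lexeme, or `NULL` for a non-word.
#' @return List with `activations` (raw named vector) and `act_lexeme`.
#' @export
lexeme_activations <- function(model, orthography, target = NULL) {
  b <- model$params$backoff
  acts <- activation(model$o2l, extract_cues(orthography), backoff = 0)
  act_lexeme <- if (is.null(target)) {
    b
  } else {
    if (!target %in% names(acts)) {
      stop("target lexeme ", sQuote(target), " is not in the trained network",
           call. = FALSE)
    }
    max(acts[[target]], 0) + b
  }
  list(activations = acts, act_lexeme = act_lexeme)
}

#' Top co-activated orthographic neighbours
#'
#' Ranks lexemes by their raw orthographic activation, excludes the target
#' (when given), and returns the `n` most activated ones. Neighbour weights
#' are the raw activations floored at zero. Ties are broken
#' lexicographically so results are stable across runs and platforms.
#'
#' @param activations Named activation vector from [lexeme_activations()].
#' @param target Target lexeme to exclude, or `NULL`.
#' @param n Number of neighbours (fewer are returned in a small lexicon).
#' @return Data frame with columns `lexeme`, `activation` and `weight`.
#' @export
top_neighbors <- function(activations, target = NULL, n = 20) {
  stopifnot(n >= 1)
  if (!is.null(target)) {
    activations <- activations[setdiff(names(activations), target)]
  }
  ord <- order(-activations, names(activations), method = "radix")
  keep <- ord[seq_len(min(n, length(ord)))]
  data.frame(
    lexeme = names(activations)[keep],
    activation = unname(activations[keep]),
    weight = pmax(unname(activations[keep]), 0),
    stringsAsFactors = FALSE
  )
}

#' Demi-syllable activations for a target pair
#'
#' The activation of demi-syllable `k` is
#' `ActPhon_k = w_lex * a_t + sum_i w_i * a_i + b`,
#' where `a_t` is the (transposed) phonology-network weight from the target
#' lexeme to the demi-syllable, the `a_i` are the weights from the
#' co-activated neighbour lexemes, and the `w_i` are the neighbours'
#' orthographic activations. For non-words the target term is omitted:
#' activation comes exclusively from the lexical representations of
#' orthographic neighbours. Raw sums below the back-off constant are floored
#' at it (association weights can be negative; positivity is required
#' downstream by the entropy and the multiplicative latency formula). A
#' demi-syllable absent from the network contributes nothing and triggers a
#' warning.
#'
#' @param model A trained `ndra_model`.
#' @param demis Character vector of (typically two) demi-syllables.
#' @param target Target lexeme, or `NULL` for non-words.
#' @param neighbors Neighbour table from [top_neighbors()].
#' @return Numeric vector of activations, one per demi-syllable.
#' @export
demisyllable_activations <- function(model, demis, target = NULL, neighbors) {
  p <- model$params
  b <- p$backoff
  vapply(demis, function(d) {
    if (!d %in% rownames(model$p2l)) {
      warning("demi-syllable ", sQuote(d), " is not in the phonology network",
              call. = FALSE)
      return(b)
    }
    raw <- 0
    if (!is.null(target)) raw <- raw + p$w_lex * model$p2l[d, target]
    if (nrow(neighbors)) {
      raw <- raw + sum(neighbors$weight * model$p2l[d, neighbors$lexeme])
    }
    max(raw + b, b)
  }, 1, USE.NAMES = FALSE)
}

#' Shannon entropy over two demi-syllable activations
#'
#' Activations are normalized into probabilities
#' `p_k = ActPhon_k / (ActPhon_1 + ActPhon_2)` and the entropy
#' `H = -sum p_k log2 p_k` (in bits, in `[0, 1]` for two outcomes)
#' quantifies how hard it is to produce the right demi-syllable at the
#' right time: similar activations (high H) mean more competition at
#' response selection.
#'
#' @param act1,act2 Strictly positive activations.
#' @return Entropy in bits.
#' @export
demi_entropy <- function(act1, act2) {
  if (!(act1 > 0 && act2 > 0)) {
    stop("demi-syllable activations must be strictly positive", call. = FALSE)
  }
  p <- c(act1, act2) / (act1 + act2)
  -sum(p * log2(p))
}

#' Multiplicative integration into total activation
#'
#' `Act = Complexity^w1 * H^w5 / (ActLexeme^w2 * ActPhon_1^w3 * ActPhon_2^w4)`.
#' Bottom-up support (lexeme and demi-syllable activations) shortens
#' latencies and therefore divides; visual complexity and response-selection
#' entropy lengthen them and multiply. The back-off floor on all activations
#' keeps the denominator away from zero; the entropy is floored at the same
#' constant so that a vanishing H cannot zero out the latency.
#'
#' @param complexity Visual complexity of the item.
#' @param act_lexeme Target lexeme activation.
#' @param act_phon1,act_phon2 Demi-syllable activations.
#' @param entropy Demi-syllable entropy in bits.
#' @param params An [ndra_params()] object.
#' @return Total activation (non-negative scalar).
#' @export
total_activation <- function(complexity, act_lexeme, act_phon1, act_phon2,
                             entropy, params = ndra_params()) {
  h <- max(entropy, params$backoff)
  complexity^params$w1 * h^params$w5 /
    (act_lexeme^params$w2 * act_phon1^params$w3 * act_phon2^params$w4)
}

#' Linear transformation from activation to latency
#'
#' `RT = w6 * Act + w7`, in milliseconds. The intercept absorbs processes
#' outside the discriminative core (response execution, voice-key
#' sensitivity, fatigue).
#'
#' @param act Total activation.
#' @param params An [ndra_params()] object.
#' @return Simulated naming latency in ms.
#' @export
simulate_rt <- function(act, params = ndra_params()) {
  params$w6 * act + params$w7
}

# Decide which items count as words: present in the trained lexicon and not
# flagged as non-words.
.default_nonword <- function(model, items) {
  lex <- model$training
  word_orths <- lex$orthography[!lex$is_nonword]
  !(items %in% word_orths)
}

#' Simulate activation profiles and naming latencies for a batch of items
#'
#' For each item the full activation profile is computed: visual complexity,
#' lexeme activation, the activations of the first and second demi-syllable,
#' their entropy, the total activation and the simulated latency. Words use
#' the demi-syllables of their lexicon transcription; non-words use the pair
#' selected by the pronunciation checking mechanism (see
#' [pronounce_nonword()]). When the model carries a sub-lexical network and
#' `sublexical = TRUE`, the analogous sub-lexical measures (`ActPhonSub1`,
#' `ActPhonSub2`, `HSub`) are reported alongside; they never enter `Act`.
#'
#' @param model A trained `ndra_model`.
#' @param items Character vector of orthographic items.
#' @param nonword Logical vector flagging non-words; defaults to items
#'   without a (word) entry in the trained lexicon.
#' @param sublexical Report sub-lexical measures (requires a model trained
#'   with `sublexical = TRUE`).
#' @param params Simulation parameters; defaults to the model's.
#' @return Data frame with one row per item. Items whose pronunciation (and
#'   hence target demi-syllable pair) cannot be derived are recorded as
#'   failed rows with `NA` measures.
#' @export
ndra_simulate <- function(model, items, nonword = NULL, sublexical = FALSE,
                          params = model$params) {
  stopifnot(inherits(model, "ndra_model"))
  if (is.null(nonword)) nonword <- .default_nonword(model, items)
  nonword <- rep_len(nonword, length(items))
  if (sublexical && is.null(model$sublex)) {
    stop("model was trained without a sub-lexical network", call. = FALSE)
  }
  rows <- lapply(seq_along(items), function(i) {
    .simulate_one(model, items[i], nonword[i], sublexical, params)
  })
  if (!length(rows)) {
    out <- .simulate_one(model, "x", TRUE, sublexical, params)[0L, ]
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

.simulate_one <- function(model, item, nonword, sublexical, params) {
  b <- params$backoff
  na_row <- data.frame(
    item = item, nonword = nonword, first = NA_character_,
    second = NA_character_, Complexity = NA_real_, ActLexeme = NA_real_,
    ActPhon1 = NA_real_, ActPhon2 = NA_real_, H = NA_real_, Act = NA_real_,
    RT = NA_real_, failed = TRUE, stringsAsFactors = FALSE
  )
  res <- tryCatch({
    complexity <- word_complexity(item, model$complexity)
    target <- if (nonword) NULL else lexeme_of(item)
    lex_act <- lexeme_activations(model, item, target)
    neighbors <- top_neighbors(lex_act$activations, target,
                               n = params$n_neighbors)
    if (nonword) {
      pron <- pronounce_nonword(model, item, params)
      if (pron$failed) return(na_row)
      demis <- c(pron$first, pron$second)
    } else {
      # prefer the word entry; a retrained non-word entry is simulated
      # lexically through its own trained representation
      entry <- model$training[model$training$lexeme == target, , drop = FALSE]
      if (nrow(entry) > 1L && any(!entry$is_nonword)) {
        entry <- entry[!entry$is_nonword, , drop = FALSE]
      }
      demis <- c(entry$demi1[1L], entry$demi2[1L])
    }
    ap <- demisyllable_activations(model, demis, target, neighbors)
    h <- demi_entropy(ap[1L], ap[2L])
    act <- total_activation(complexity, lex_act$act_lexeme, ap[1L], ap[2L],
                            h, params)
    out <- data.frame(
      item = item, nonword = nonword, first = demis[1L], second = demis[2L],
      Complexity = complexity, ActLexeme = lex_act$act_lexeme,
      ActPhon1 = ap[1L], ActPhon2 = ap[2L], H = h, Act = act,
      RT = simulate_rt(act, params), failed = FALSE, stringsAsFactors = FALSE
    )
    if (sublexical) {
      sacts <- activation(model$sublex, extract_cues(item), backoff = 0)
      sub <- vapply(demis, function(d) {
        if (d %in% names(sacts)) max(sacts[[d]], 0) + b else b
      }, 1, USE.NAMES = FALSE)
      out$ActPhonSub1 <- sub[1L]
      out$ActPhonSub2 <- sub[2L]
      out$HSub <- demi_entropy(sub[1L], sub[2L])
    }
    out
  }, error = function(e) NULL)
  if (is.null(res)) {
    if (sublexical) {
      na_row$ActPhonSub1 <- NA_real_
      na_row$ActPhonSub2 <- NA_real_
      na_row$HSub <- NA_real_
    }
    return(na_row)
  }
  res
}
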