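# Top-down checking mechanism: turns network activations into an actual
# DISC pronunciation for words and non-words.
#
# The discriminative core models response times; selecting what to say is a
# response-conflict resolution problem. The checking mechanism filters the
# lexemes that are allowed to activate demi-syllables down to those that
# share orthographic features with the presented item, picks the most
# active word-initial and word-final demi-syllable, resolves vowel
# conflicts in favour of the second demi-syllable, and assembles the two
# halves into a single transcription.

.demi_parts <- function(demi, nuclei) {
  run <- .nucleus_run(demi, nuclei, what = "demi-syllable")
  list(
    onset = if (run[1L] > 1L) substr(demi, 1L, run[1L] - 1L) else "",
    nucleus = substr(demi, run[1L], run[2L]),
    coda = if (run[2L] < nchar(demi)) {
      substr(demi, run[2L] + 1L, nchar(demi))
    } else {
      ""
    }
  )
}

# Indices of candidates whose score is (numerically) maximal.
.which_top <- function(scores, tol = 1e-9) {
  which(scores >= max(scores) - tol)
}

#' Assemble two demi-syllables into a DISC transcription
#'
#' The two halves must agree on the nucleus (the vowel is represented in
#' both); the assembled form is the first half's onset, the shared nucleus
#' once, and the second half's coda.
#'
#' @param first Word-initial demi-syllable (onset + nucleus).
#' @param second Word-final demi-syllable (nucleus + coda).
#' @param nuclei DISC nucleus inventory.
#' @return The assembled DISC string.
#' @export
#' @examples
#' assemble("b8", "8R")  # "b8R"
assemble <- function(first, second, nuclei = disc_nuclei()) {
  p1 <- .demi_parts(first, nuclei)
  p2 <- .demi_parts(second, nuclei)
  if (!identical(p1$nucleus, p2$nucleus)) {
    stop("nucleus mismatch between demi-syllables ", sQuote(first), " and ",
         sQuote(second), " (resolve the vowel conflict first)", call. = FALSE)
  }
  paste0(p1$onset, p1$nucleus, p2$coda)
}

#' Resolve a vowel conflict between the two selected demi-syllables
#'
#' When the most active word-initial and word-final demi-syllables disagree
#' on the vowel, preference goes to the vowel of the second demi-syllable
#' (its activation carries more weight in the latency model, and rhymes are
#' perceptually more prominent than onset-plus-vowel sequences). The first
#' demi-syllable is re-selected as the most active word-initial candidate
#' whose nucleus matches the second's; when no such candidate exists, a
#' first demi-syllable is synthesized from the top candidate's onset and
#' the second's nucleus (flagged in the result).
#'
#' @param first_candidates Named numeric vector of word-initial candidate
#'   scores (names are demi-syllables).
#' @param second The chosen word-final demi-syllable.
#' @param nuclei DISC nucleus inventory.
#' @return List with `demi` (the resolved first demi-syllable) and
#'   `synthesized` (logical).
#' @export
resolve_vowel_conflict <- function(first_candidates, second,
                                   nuclei = disc_nuclei()) {
  stopifnot(length(first_candidates) >= 1L, !is.null(names(first_candidates)))
  ord <- order(-first_candidates, names(first_candidates), method = "radix")
  first_candidates <- first_candidates[ord]
  target_nuc <- .demi_parts(second, nuclei)$nucleus
  top <- names(first_candidates)[1L]
  if (identical(.demi_parts(top, nuclei)$nucleus, target_nuc)) {
    return(list(demi = top, synthesized = FALSE))
  }
  nucs <- vapply(names(first_candidates), function(d) {
    .demi_parts(d, nuclei)$nucleus
  }, "")
  match_idx <- which(nucs == target_nuc)
  if (length(match_idx)) {
    return(list(demi = names(first_candidates)[match_idx[1L]],
                synthesized = FALSE))
  }
  list(demi = paste0(.demi_parts(top, nuclei)$onset, target_nuc),
       synthesized = TRUE)
}

# Activation-weighted vote of a lexeme set over a demi-syllable set:
# score(d) = sum_L w_L * V[d, L], considering only demi-syllables that
# receive positive weight from at least one voting lexeme.
.demi_vote <- function(model, demis, lexemes, weights) {
  lexemes <- intersect(lexemes, colnames(model$p2l))
  demis <- intersect(demis, rownames(model$p2l))
  if (!length(lexemes) || !length(demis)) return(numeric(0))
  sub <- model$p2l[demis, lexemes, drop = FALSE]
  supported <- rowSums(sub > 0) > 0
  if (!any(supported)) return(numeric(0))
  sub <- sub[supported, , drop = FALSE]
  scores <- as.vector(sub %*% weights[lexemes])
  names(scores) <- rownames(sub)
  scores
}

# Word entries of the trained lexicon (non-word training entries never vote
# in the checking mechanism).
.word_entries <- function(model) {
  model$training[!model$training$is_nonword, , drop = FALSE]
}

#' Tie resolution by coarser orthographic sharing
#'
#' When two or more demi-syllables remain equally active, the checking
#' mechanism re-votes with the lexemes that share only the orthographic
#' onset (for the first position) or only the orthographic coda (for the
#' second position) with the presented item. The re-vote considers only
#' demi-syllables phonologically compatible with the tie: those sharing the
#' phonological onset (first position) or coda (second position) with one
#' of the tied demi-syllables. Residual ties are broken lexicographically.
#'
#' @param model A trained `ndra_model`.
#' @param orthography The presented item.
#' @param tied Character vector of tied demi-syllables (>= 2, but a single
#'   candidate is returned unchanged).
#' @param position 1 (word-initial) or 2 (word-final).
#' @param weights Named lexeme weight vector (raw orthographic activations
#'   floored at 0); computed from the model when omitted.
#' @return A single demi-syllable.
#' @export
tie_fallback <- function(model, orthography, tied, position, weights = NULL) {
  stopifnot(position %in% c(1L, 2L))
  if (length(tied) <= 1L) return(tied)
  if (is.null(weights)) {
    weights <- pmax(activation(model$o2l, extract_cues(orthography), 0), 0)
  }
  parts <- orthographic_parts(orthography)
  words <- .word_entries(model)
  sharers <- if (position == 1L) {
    words$lexeme[words$onset == parts$onset]
  } else {
    words$lexeme[words$coda == parts$coda]
  }
  pool <- if (position == 1L) model$demis1 else model$demis2
  tied_feat <- unique(vapply(tied, function(d) {
    p <- .demi_parts(d, model$nuclei)
    if (position == 1L) p$onset else p$coda
  }, ""))
  compatible <- pool[vapply(pool, function(d) {
    p <- .demi_parts(d, model$nuclei)
    (if (position == 1L) p$onset else p$coda) %in% tied_feat
  }, TRUE)]
  scores <- .demi_vote(model, compatible, sharers, weights)
  if (length(scores)) {
    top <- names(scores)[.which_top(scores)]
    return(sort(top, method = "radix")[1L])
  }
  sort(tied, method = "radix")[1L]
}

.pron_result <- function(item, first = NA_character_, second = NA_character_,
                         assembled = NA_character_, route = NA_character_,
                         failed = FALSE, trace = list()) {
  structure(
    list(item = item, first = first, second = second, assembled = assembled,
         route = route, failed = failed, trace = trace),
    class = "ndra_pronunciation"
  )
}

#' @export
print.ndra_pronunciation <- function(x, ...) {
  if (x$failed) {
    cat("<ndra_pronunciation> ", x$item, ": FAILED\n", sep = "")
  } else {
    cat("<ndra_pronunciation> ", x$item, " -> ", x$assembled,
        "  (", x$first, " + ", x$second, ", route: ", x$route, ")\n",
        sep = "")
  }
  invisible(x)
}

# Shared selection step: pick the winner among scored candidates,
# delegating ties to a ladder of increasingly coarse votes: (1) the
# activation-weighted vote of the orthographically sharing lexemes,
# (2) the same vote unweighted (engaged when orthographic activations
# carry no signal, e.g. for exactly blocked neighbours), (3) the
# onset-/coda-only fallback vote, (4) lexicographic order.
.select_demi <- function(model, orthography, scores, position, weights,
                         trace, vote_sets = NULL) {
  top <- names(scores)[.which_top(scores)]
  if (length(top) == 1L) return(list(demi = top, trace = trace))
  trace <- c(trace, list(list(step = "tie", position = position,
                              candidates = sort(top, method = "radix"))))
  if (!is.null(vote_sets) && length(vote_sets)) {
    vs <- .demi_vote(model, top, vote_sets, weights)
    if (length(vs)) {
      vtop <- names(vs)[.which_top(vs)]
      if (length(vtop) == 1L) {
        return(list(demi = vtop, trace = trace))
      }
      top <- vtop
    }
    uniform <- stats::setNames(rep(1, length(vote_sets)), vote_sets)
    vs <- .demi_vote(model, top, vote_sets, uniform)
    if (length(vs)) {
      vtop <- names(vs)[.which_top(vs)]
      if (length(vtop) == 1L) {
        trace <- c(trace, list(list(step = "unweighted_vote",
                                    position = position, winner = vtop)))
        return(list(demi = vtop, trace = trace))
      }
      top <- vtop
    }
  }
  demi <- tie_fallback(model, orthography, top, position, weights)
  trace <- c(trace, list(list(step = "tie_fallback", position = position,
                              winner = demi)))
  list(demi = demi, trace = trace)
}

#' Pronounce a word through the target-lexeme filter
#'
#' For words, response conflict is resolved by restricting demi-syllable
#' activation to the units activated by the target lexeme itself: the
#' word-initial and word-final demi-syllables with the largest (positive)
#' transposed phonology-network weight from the target are selected. Ties
#' are resolved by the same neighbour-vote procedure used for non-words,
#' vowel conflicts in favour of the second demi-syllable.
#'
#' @param model A trained `ndra_model`.
#' @param word Orthography of a word with a lexeme in the model.
#' @param params Simulation parameters; defaults to the model's.
#' @return An `ndra_pronunciation` object.
#' @export
pronounce_word <- function(model, word, params = model$params) {
  target <- lexeme_of(word)
  if (!target %in% colnames(model$p2l)) {
    stop("word ", sQuote(word), " has no lexeme in the model", call. = FALSE)
  }
  v <- model$p2l[, target]
  trace <- list()
  weights <- pmax(activation(model$o2l, extract_cues(word), 0), 0)
  parts <- tryCatch(orthographic_parts(word), error = function(e) NULL)
  words <- .word_entries(model)

  pick <- vector("list", 2L)
  for (pos in 1:2) {
    pool <- if (pos == 1L) model$demis1 else model$demis2
    cand <- v[pool[v[pool] > 0]]
    if (!length(cand)) {
      return(.pron_result(word, failed = TRUE, route = "word-target",
                          trace = c(trace, list(list(
                            step = "failure", position = pos,
                            reason = "no positively weighted demi-syllable")))))
    }
    trace <- c(trace, list(list(step = "candidates", position = pos,
                                candidates = sort(names(cand), method = "radix"))))
    vote_sets <- if (!is.null(parts)) {
      if (pos == 1L) {
        words$lexeme[words$onset == parts$onset & words$vowel == parts$vowel]
      } else {
        words$lexeme[words$rhyme == parts$rhyme]
      }
    }
    sel <- .select_demi(model, word, cand, pos, weights, trace, vote_sets)
    trace <- sel$trace
    pick[[pos]] <- list(demi = sel$demi, candidates = cand)
  }

  first <- pick[[1L]]$demi
  second <- pick[[2L]]$demi
  n1 <- .demi_parts(first, model$nuclei)$nucleus
  n2 <- .demi_parts(second, model$nuclei)$nucleus
  if (!identical(n1, n2)) {
    res <- resolve_vowel_conflict(pick[[1L]]$candidates, second, model$nuclei)
    trace <- c(trace, list(list(step = "vowel_conflict", from = first,
                                to = res$demi, synthesized = res$synthesized)))
    first <- res$demi
  }
  .pron_result(word, first, second, assemble(first, second, model$nuclei),
               route = "word-target", trace = trace)
}

#' Pronounce a non-word through orthographic-neighbour co-activation
#'
#' Non-words have no lexeme, so the checking mechanism varies the set of
#' voting lexemes serially: the word-initial demi-syllable is chosen by an
#' activation-weighted vote among the demi-syllables supported by lexemes
#' sharing the orthographic onset and vowel with the item, the word-final
#' one by the lexemes sharing the orthographic rhyme (vowel plus coda).
#' Each lexeme's vote is weighted by the orthographic activation it
#' receives from the item. When no lexeme shares the onset-plus-vowel
#' (respectively the rhyme), the mechanism falls back to onset-only
#' (coda-only) sharers. Only attested demi-syllables can ever be produced.
#'
#' @param model A trained `ndra_model`.
#' @param orthography The non-word to pronounce.
#' @param params Simulation parameters; defaults to the model's.
#' @return An `ndra_pronunciation` object.
#' @export
pronounce_nonword <- function(model, orthography, params = model$params) {
  parts <- orthographic_parts(orthography)
  weights <- pmax(activation(model$o2l, extract_cues(orthography), 0), 0)
  words <- .word_entries(model)
  trace <- list()
  route <- "nonword-neighbors"

  pick <- vector("list", 2L)
  for (pos in 1:2) {
    sharers <- if (pos == 1L) {
      words$lexeme[words$onset == parts$onset & words$vowel == parts$vowel]
    } else {
      words$lexeme[words$rhyme == parts$rhyme]
    }
    used_fallback <- FALSE
    if (!length(sharers)) {
      sharers <- if (pos == 1L) {
        words$lexeme[words$onset == parts$onset]
      } else {
        words$lexeme[words$coda == parts$coda]
      }
      used_fallback <- TRUE
      if (route == "nonword-neighbors") {
        route <- if (pos == 1L) "fallback-onset" else "fallback-coda"
      }
      trace <- c(trace, list(list(step = "fallback", position = pos)))
    }
    pool <- if (pos == 1L) model$demis1 else model$demis2
    scores <- .demi_vote(model, pool, sharers, weights)
    if (!length(scores)) {
      return(.pron_result(orthography, failed = TRUE, route = route,
                          trace = c(trace, list(list(
                            step = "failure", position = pos,
                            reason = "empty candidate set")))))
    }
    trace <- c(trace, list(list(step = "candidates", position = pos,
                                candidates = sort(names(scores), method = "radix"),
                                fallback = used_fallback)))
    sel <- .select_demi(model, orthography, scores, pos, weights, trace,
                        vote_sets = sharers)
    trace <- sel$trace
    pick[[pos]] <- list(demi = sel$demi, candidates = scores)
  }

  first <- pick[[1L]]$demi
  second <- pick[[2L]]$demi
  n1 <- .demi_parts(first, model$nuclei)$nucleus
  n2 <- .demi_parts(second, model$nuclei)$nucleus
  if (!identical(n1, n2)) {
    res <- resolve_vowel_conflict(pick[[1L]]$candidates, second, model$nuclei)
    trace <- c(trace, list(list(step = "vowel_conflict", from = first,
                                to = res$demi, synthesized = res$synthesized)))
    first <- res$demi
  }
  .pron_result(orthography, first, second,
               assemble(first, second, model$nuclei),
               route = route, trace = trace)
}

#' Pronounce a batch of items
#'
#' Dispatches each item to [pronounce_word()] or [pronounce_nonword()] and
#' collects the results in a data frame.
#'
#' @param model A trained `ndra_model`.
#' @param items Character vector of items.
#' @param nonword Logical vector; defaults to items without a word entry in
#'   the trained lexicon.
#' @param params Simulation parameters; defaults to the model's.
#' @return Data frame with columns `item`, `first`, `second`, `assembled`,
#'   `route` and `failed`.
#' @export
pronounce <- function(model, items, nonword = NULL, params = model$params) {
  if (is.null(nonword)) nonword <- .default_nonword(model, items)
  nonword <- rep_len(nonword, length(items))
  rows <- lapply(seq_along(items), function(i) {
    r <- if (nonword[i]) {
      pronounce_nonword(model, items[i], params)
    } else {
      pronounce_word(model, items[i], params)
    }
    data.frame(item = r$item, first = r$first, second = r$second,
               assembled = r$assembled, route = r$route, failed = r$failed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
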