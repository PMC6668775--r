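# Synthetic-lexicon and non-word generation. The generators emulate the
# structure of monomorphemic monosyllabic CVC-style training data: Zipfian
# token frequencies, orthographic body families with controllable
# spelling-to-sound consistency, and non-words recombining attested onsets
# and bodies.

# Split values by key with groups in locale-independent (radix) key
# order, deduplicated; keeps generation identical across platforms.
.radix_split <- function(values, keys) {
  out <- split(values, keys)
  out <- out[sort(names(out), method = "radix")]
  lapply(out, unique)
}

# Evaluate `expr` under a fixed seed, leaving the caller's RNG state alone.
.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Paired orthography/DISC inventories for the synthetic lexicon
#'
#' Onsets, nuclei and codas with jointly plausible orthographic and DISC
#' forms (e.g. onset `b`/`b`, nucleus `ea`/`i` with alternative `E`, coda
#' `nd`/`nd`), so that generated entries are consistent in both codes
#' without requiring any external lexical database. Each nucleus carries an
#' alternative DISC realisation (`alt`) used for inconsistent bodies, in
#' the way English `ea` is mostly /i/ (bead) but sometimes /E/ (dead).
#'
#' @return List of data frames `onsets`, `nuclei` (columns `orth`, `disc`,
#'   `alt`) and `codas`.
#' @export
fixture_inventories <- function() {
  list(
    onsets = data.frame(
      orth = c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r", "s",
               "t", "v", "w", "z", "sh", "ch", "th", "st", "sk", "pl", "br",
               "gr"),
      disc = c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r", "s",
               "t", "v", "w", "z", "S", "J", "T", "st", "sk", "pl", "br",
               "gr"),
      stringsAsFactors = FALSE
    ),
    nuclei = data.frame(
      orth = c("a", "e", "i", "o", "u", "ee", "oo", "ea", "ai", "oa", "ay",
               "oy", "ou", "ie", "ei", "oe", "ue"),
      disc = c("{", "E", "I", "Q", "V", "i", "u", "i", "1", "5", "1", "4",
               "6", "2", "1", "5", "u"),
      alt = c("1", "i", "2", "5", "u", "E", "U", "E", "{", "Q", "2", "2",
              "u", "i", "i", "u", "2"),
      stringsAsFactors = FALSE
    ),
    codas = data.frame(
      orth = c("", "p", "t", "k", "d", "g", "m", "n", "l", "s", "b", "ck",
               "st", "nd", "mp", "nt", "ng", "ld", "ft", "sh", "ch", "ss",
               "lt", "nk", "x",
               # silent-e spellings (made/maid-style homographs of the
               # bare-consonant codas)
               "be", "de", "ke", "le", "me", "ne", "pe", "se", "te", "ve",
               "ze",
               # doubled-consonant spellings (inn/add/mitt-style)
               "f", "ff", "tt", "dd", "nn", "ll", "pp", "gg", "mm", "zz"),
      disc = c("", "p", "t", "k", "d", "g", "m", "n", "l", "s", "b", "k",
               "st", "nd", "mp", "nt", "N", "ld", "ft", "S", "J", "s",
               "lt", "Nk", "ks",
               "b", "d", "k", "l", "m", "n", "p", "s", "t", "v", "z",
               "f", "f", "t", "d", "n", "l", "p", "g", "m", "z"),
      stringsAsFactors = FALSE
    )
  )
}

#' Configuration for the synthetic lexicon generator
#'
#' @param seed Integer seed; identical configurations generate identical
#'   lexica.
#' @param n_words Number of words to generate.
#' @param zipf_exponent Exponent of the Zipfian rank-frequency law.
#' @param n_bodies Number of orthographic bodies (rime families); family
#'   size is `n_words / n_bodies` on average.
#' @param consistency_mix Fraction of bodies carrying a second,
#'   inconsistent rime pronunciation (0 = fully consistent lexicon).
#' @param inventories Onset/nucleus/coda inventories, see
#'   [fixture_inventories()].
#' @return List of class `ndra_fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_words = 500L, zipf_exponent = 1.0,
                           n_bodies = 125L, consistency_mix = 0.25,
                           inventories = fixture_inventories()) {
  stopifnot(n_words >= 1, n_bodies >= 1, n_bodies <= n_words,
            consistency_mix >= 0, consistency_mix <= 1,
            zipf_exponent > 0,
            nrow(inventories$onsets) > 0, nrow(inventories$nuclei) > 0,
            nrow(inventories$codas) > 0)
  structure(
    list(seed = as.integer(seed), n_words = as.integer(n_words),
         zipf_exponent = zipf_exponent, n_bodies = as.integer(n_bodies),
         consistency_mix = consistency_mix, inventories = inventories),
    class = "ndra_fixture_config"
  )
}

# Break exact cue exchangeability in the draft lexicon. Two demi-syllable
# cues whose sets of co-occurring partner demi-syllables are identical are
# exchangeable for the equilibrium solver: their association weights to
# every lexeme coincide exactly, which makes pronunciations for the
# affected families undecidable in principle. Real lexica essentially never
# contain such exact duplicates; the generator removes them by swapping
# onsets between words of the same vowel group (which preserves every
# onset-vowel usage count) until all partner sets are distinct.
.break_exchangeable <- function(lex, inv, max_iter = 300L) {
  body_onsets <- function() split(lex$onset_idx, lex$body_idx)
  for (iter in seq_len(max_iter)) {
    d1 <- paste0(inv$onsets$disc[lex$onset_idx], lex$nucleus_disc)
    d2 <- paste0(lex$nucleus_disc, lex$coda_disc)
    set1 <- tapply(d2, d1, function(x) paste(sort(unique(x)), collapse = "|"))
    set2 <- tapply(d1, d2, function(x) paste(sort(unique(x)), collapse = "|"))
    dup1 <- names(set1)[duplicated(set1) | duplicated(set1, fromLast = TRUE)]
    dup2 <- names(set2)[duplicated(set2) | duplicated(set2, fromLast = TRUE)]
    offending <- which(d1 %in% dup1 | d2 %in% dup2)
    if (!length(offending)) break
    bo <- body_onsets()
    i <- offending[sample.int(length(offending), 1L)]
    cand <- which(lex$vowel == lex$vowel[i] &
                    lex$body_idx != lex$body_idx[i] &
                    lex$onset_idx != lex$onset_idx[i])
    cand <- cand[!vapply(cand, function(j) {
      lex$onset_idx[j] %in% bo[[as.character(lex$body_idx[i])]] ||
        lex$onset_idx[i] %in% bo[[as.character(lex$body_idx[j])]]
    }, TRUE)]
    if (!length(cand)) next
    j <- cand[sample.int(length(cand), 1L)]
    tmp <- lex$onset_idx[i]
    lex$onset_idx[i] <- lex$onset_idx[j]
    lex$onset_idx[j] <- tmp
  }
  lex
}

# All usable bodies: nucleus x coda combinations with at least 2 letters
# (so that 1-letter onsets still give >= 3-letter words) and unique
# orthography.
.candidate_bodies <- function(inv) {
  grid <- expand.grid(ni = seq_len(nrow(inv$nuclei)),
                      ci = seq_len(nrow(inv$codas)))
  bodies <- data.frame(
    orth = paste0(inv$nuclei$orth[grid$ni], inv$codas$orth[grid$ci]),
    vowel = inv$nuclei$orth[grid$ni],
    coda_orth = inv$codas$orth[grid$ci],
    nucleus_disc = inv$nuclei$disc[grid$ni],
    nucleus_alt = inv$nuclei$alt[grid$ni],
    coda_disc = inv$codas$disc[grid$ci],
    stringsAsFactors = FALSE
  )
  bodies <- bodies[nchar(bodies$orth) >= 2L, , drop = FALSE]
  bodies[!duplicated(bodies$orth), , drop = FALSE]
}

#' Generate a synthetic lexicon
#'
#' Words are built as onset + body (vowel cluster + coda) from the paired
#' inventories, grouped into body families that share the orthographic
#' rime. Token frequencies follow a Zipfian rank-frequency law with the
#' configured exponent (ranks randomly assigned to words). A configurable
#' fraction of bodies is inconsistent: within those families, the members
#' below the family's median frequency receive the body's alternative rime
#' pronunciation, mimicking lower-frequency "enemy" spellings.
#'
#' @param config An [fixture_config()] object.
#' @return An `ndra_lexicon` with extra columns `body` (orthographic rime)
#'   and `consistent` (body-level flag).
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "ndra_fixture_config"))
  inv <- config$inventories
  .with_seed(config$seed, {
    bodies <- .candidate_bodies(inv)
    if (config$n_bodies > nrow(bodies)) {
      stop("inventory too small: ", config$n_bodies, " bodies requested, ",
           nrow(bodies), " available", call. = FALSE)
    }
    bodies <- bodies[sample.int(nrow(bodies), config$n_bodies), , drop = FALSE]

    # distribute words over bodies as evenly as possible
    sizes <- rep(config$n_words %/% config$n_bodies, config$n_bodies)
    extra <- config$n_words %% config$n_bodies
    if (extra > 0) {
      sizes[sample.int(config$n_bodies, extra)] <- sizes[1L] + 1L
    }
    if (max(sizes) > nrow(inv$onsets)) {
      stop("inventory too small: family of ", max(sizes),
           " words needs as many onsets, only ", nrow(inv$onsets),
           " available", call. = FALSE)
    }

    # Assign onsets per vowel group from a pooled, cycled onset list so that
    # every onset-vowel combination is used by at least two words wherever
    # the group is large enough. This keeps the lexicon in the shared-cue
    # regime of large-scale training data: a word with a cue unique to
    # itself would block all co-activation of its orthographic neighbours
    # at equilibrium, which small random lexica would otherwise do
    # pervasively and full-scale lexica essentially never do.
    onset_rows <- vector("list", config$n_bodies)
    for (v in unique(bodies$vowel)) {
      bidx <- which(bodies$vowel == v)
      sz <- sizes[bidx]
      m <- sum(sz)
      if (m == 0L) next
      p <- min(max(max(sz), m %/% 2L), nrow(inv$onsets))
      pool <- sample.int(nrow(inv$onsets), p)
      counts <- rep(m %/% p, p)
      rem <- m %% p
      if (rem > 0L) counts[sample.int(p, rem)] <- counts[1L] + 1L
      multiset <- rep(pool, counts)
      # deal the multiset randomly over the bodies, repairing within-body
      # duplicates; random (rather than cyclic) dealing avoids onsets with
      # identical rime-partner sets, which would make their demi-syllables
      # exchangeable for the equilibrium solver
      dealt <- NULL
      for (attempt in 1:25) {
        ms <- sample(multiset)
        cand <- split(ms, rep.int(seq_along(sz), sz))
        if (!any(vapply(cand, anyDuplicated, 1L) > 0L)) {
          dealt <- cand
          break
        }
      }
      if (is.null(dealt)) {
        dealt <- split(ms, rep.int(seq_along(sz), sz))
        for (i in seq_along(dealt)) {
          while (anyDuplicated(dealt[[i]])) {
            dup_pos <- which(duplicated(dealt[[i]]))[1L]
            j <- sample(setdiff(seq_along(dealt), i), 1L)
            k <- sample(seq_along(dealt[[j]]), 1L)
            if (!(dealt[[j]][k] %in% dealt[[i]]) &&
                !(dealt[[i]][dup_pos] %in% dealt[[j]][-k])) {
              tmp <- dealt[[i]][dup_pos]
              dealt[[i]][dup_pos] <- dealt[[j]][k]
              dealt[[j]][k] <- tmp
            }
          }
        }
      }
      for (i in seq_along(bidx)) onset_rows[[bidx[i]]] <- dealt[[i]]
    }

    rows <- vector("list", config$n_bodies)
    for (bi in seq_len(config$n_bodies)) {
      if (sizes[bi] == 0L) next
      oi <- onset_rows[[bi]]
      rows[[bi]] <- data.frame(
        onset_idx = oi,
        body_idx = bi,
        vowel = bodies$vowel[bi],
        body = bodies$orth[bi],
        nucleus_disc = bodies$nucleus_disc[bi],
        nucleus_alt = bodies$nucleus_alt[bi],
        coda_disc = bodies$coda_disc[bi],
        stringsAsFactors = FALSE
      )
    }
    lex <- do.call(rbind, rows)
    lex <- .break_exchangeable(lex, inv)
    lex$orthography <- paste0(inv$onsets$orth[lex$onset_idx], lex$body)
    lex$onset_disc <- inv$onsets$disc[lex$onset_idx]
    stopifnot(!anyDuplicated(lex$orthography))

    # Zipfian token frequencies over randomly assigned ranks
    rank <- sample.int(nrow(lex))
    lex$frequency <- pmax(1, round(1e6 * rank^(-config$zipf_exponent)))

    # inconsistent bodies: members below the family median frequency get
    # the alternative rime pronunciation
    fam_sizes <- table(lex$body)
    eligible <- names(fam_sizes)[fam_sizes >= 2L]
    n_inconsistent <- min(length(eligible),
                          floor(config$consistency_mix * config$n_bodies))
    inconsistent <- if (n_inconsistent > 0) {
      sample(eligible, n_inconsistent)
    } else {
      character(0)
    }
    lex$consistent <- !(lex$body %in% inconsistent)
    use_alt <- rep(FALSE, nrow(lex))
    for (b in inconsistent) {
      idx <- which(lex$body == b)
      minority <- idx[lex$frequency[idx] < stats::median(lex$frequency[idx])]
      if (!length(minority)) minority <- idx[which.min(lex$frequency[idx])]
      use_alt[minority] <- TRUE
    }
    nucleus <- ifelse(use_alt, lex$nucleus_alt, lex$nucleus_disc)
    lex$disc <- paste0(lex$onset_disc, nucleus, lex$coda_disc)

    out <- data.frame(
      orthography = lex$orthography,
      disc = lex$disc,
      frequency = lex$frequency,
      is_nonword = FALSE,
      body = lex$body,
      consistent = lex$consistent,
      stringsAsFactors = FALSE
    )
    as_lexicon(out)
  })
}

#' Generate non-words from attested onsets and bodies
#'
#' Recombines orthographic onsets and bodies observed in the lexicon into
#' novel strings, keeping only combinations whose two candidate
#' demi-syllables (onset + nucleus, nucleus + coda, using each body's
#' majority pronunciation) are attested in the lexicon's phonology -- so
#' every generated non-word is in principle pronounceable by the model.
#' Items whose candidate pronunciation coincides with an existing word's
#' phonology are flagged as pseudo-homophones.
#'
#' @param lexicon An `ndra_lexicon` of words.
#' @param seed Integer seed.
#' @param n Number of non-words requested; fewer are returned (with a
#'   warning) when the combination space is exhausted.
#' @param nuclei DISC nucleus inventory.
#' @return Data frame with columns `orthography`, `disc_candidate` and
#'   `pseudo_homophone`.
#' @export
generate_nonwords <- function(lexicon, seed = 1L, n = 100L,
                              nuclei = disc_nuclei()) {
  stopifnot(inherits(lexicon, "ndra_lexicon"), nrow(lexicon) > 0)
  words <- lexicon[!lexicon$is_nonword, , drop = FALSE]
  parts <- lapply(words$orthography, orthographic_parts)
  splits <- lapply(words$disc, split_demisyllables, nuclei = nuclei)
  onset_orth <- vapply(parts, `[[`, "", "onset")
  rhyme_orth <- vapply(parts, `[[`, "", "rhyme")
  demi1 <- vapply(splits, `[[`, "", "first")
  demi2 <- vapply(splits, `[[`, "", "second")
  nucleus <- vapply(demi2, function(d) .demi_parts(d, nuclei)$nucleus, "")
  onset_disc <- substr(demi1, 1L, nchar(demi1) - nchar(nucleus))

  # onset orthography -> most frequent DISC onset; body -> majority rime
  onset_map <- .majority_map(onset_orth, onset_disc, words$frequency)
  body_map <- .majority_map(rhyme_orth, demi2, words$frequency)
  vowel_orth <- vapply(parts, `[[`, "", "vowel")
  vowel_of_rhyme <- vapply(split(vowel_orth, rhyme_orth), `[`, "", 1L)

  attested1 <- unique(demi1)
  attested2 <- unique(demi2)
  attested_combos <- unique(paste0(onset_orth, vowel_orth))

  grid <- expand.grid(o = names(onset_map), b = names(body_map),
                      stringsAsFactors = FALSE)
  grid <- grid[nzchar(grid$o), , drop = FALSE]
  # only onset-vowel junctions attested in real words: the recombined item
  # then introduces no letter bigram of its own, mirroring non-word sets
  # built from existing orthographic components
  grid <- grid[paste0(grid$o, vowel_of_rhyme[grid$b]) %in% attested_combos, ,
               drop = FALSE]
  orth <- paste0(grid$o, grid$b)
  keep <- !(orth %in% words$orthography) & !duplicated(orth)
  grid <- grid[keep, , drop = FALSE]
  orth <- orth[keep]

  d2 <- unname(body_map[grid$b])
  nuc <- vapply(d2, function(d) .demi_parts(d, nuclei)$nucleus, "")
  d1 <- paste0(unname(onset_map[grid$o]), nuc)
  ok <- d1 %in% attested1 & d2 %in% attested2
  orth <- orth[ok]
  cand_disc <- paste0(unname(onset_map[grid$o[ok]]), nuc[ok],
                      substring(d2[ok], nchar(nuc[ok]) + 1L))

  .with_seed(seed, {
    if (length(orth) < n) {
      warning("only ", length(orth), " of ", n,
              " requested non-words could be generated", call. = FALSE)
      take <- sample.int(length(orth), length(orth))
    } else {
      take <- sample.int(length(orth), n)
    }
    data.frame(
      orthography = orth[take],
      disc_candidate = cand_disc[take],
      pseudo_homophone = cand_disc[take] %in% words$disc,
      stringsAsFactors = FALSE
    )
  })
}

# frequency-weighted majority mapping key -> value (radix key order, so
# downstream sampling is identical across platforms and locales)
.majority_map <- function(keys, values, weights) {
  uk <- sort(unique(keys), method = "radix")
  out <- vapply(uk, function(k) {
    idx <- which(keys == k)
    tab <- tapply(weights[idx], values[idx], sum)
    names(tab)[which.max(tab)]
  }, "")
  names(out) <- uk
  out
}

#' Family design for the orthographic-neighbourhood contrast
#'
#' Builds a lexicon of matched units in which orthographic and phonological
#' neighbourhood are decoupled. Each unit has one phonological rime
#' realised by two different spellings: a dense family (a target plus
#' `family_size - 1` orthographic body neighbours) and a sparse target
#' whose body is unique, so its rime sharers are phonological neighbours
#' only. Dense and sparse targets are frequency matched within each unit,
#' and both have exactly the same number of demi-syllable sharers; they
#' differ only in whether those sharers are co-activated orthographically.
#'
#' @param seed Integer seed.
#' @param n_units Number of matched units (2 targets each).
#' @param family_size Words in the dense family, target included.
#' @return List with `lexicon` and a data frame `targets` (columns `dense`,
#'   `sparse`).
#' @export
generate_neighborhood_design <- function(seed = 1L, n_units = 100L,
                                         family_size = 7L) {
  inv <- fixture_inventories()
  stopifnot(family_size >= 2L, family_size + 1L <= nrow(inv$onsets))
  .with_seed(seed, {
    # spelling alternatives per nucleus DISC (main or alternative
    # realisation) and per coda DISC: the design needs rimes that sound
    # identical but are spelled with disjoint letter material (maid/made)
    nspell <- .radix_split(c(inv$nuclei$orth, inv$nuclei$orth),
                           c(inv$nuclei$disc, inv$nuclei$alt))
    cpool <- inv$codas[nzchar(inv$codas$orth), , drop = FALSE]
    cspell <- .radix_split(cpool$orth, cpool$disc)
    has_junction_partner <- function(c2) {
      any(substr(cpool$orth, 1L, 1L) == substr(c2, 1L, 1L) &
            cpool$orth != c2)
    }

    used_bodies <- character(0)
    units <- list()
    cells <- expand.grid(
      nu = names(nspell)[vapply(nspell, length, 1L) >= 2L],
      ka = names(cspell)[vapply(cspell, length, 1L) >= 2L],
      stringsAsFactors = FALSE
    )
    cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
    more <- TRUE
    while (length(units) < n_units && more) {
      more <- FALSE
      for (ci in seq_len(nrow(cells))) {
        if (length(units) >= n_units) break
        vs <- sample(nspell[[cells$nu[ci]]])
        cs <- sample(cspell[[cells$ka[ci]]])
        if (length(vs) < 2L || length(cs) < 2L) next
        cand <- expand.grid(v1 = vs, c1 = cs, v2 = vs, c2 = cs,
                            stringsAsFactors = FALSE)
        # the two spellings must differ in both components, have equal
        # length (so visual complexity is matched within the unit), and the
        # sparse-side coda must admit a junction filler
        cand <- cand[cand$v1 != cand$v2 & cand$c1 != cand$c2 &
                       nchar(cand$v1) + nchar(cand$c1) ==
                         nchar(cand$v2) + nchar(cand$c2) &
                       vapply(cand$c2, has_junction_partner, TRUE), ,
                     drop = FALSE]
        if (!nrow(cand)) next
        cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
        for (ri in seq_len(nrow(cand))) {
          b1 <- paste0(cand$v1[ri], cand$c1[ri])
          b2 <- paste0(cand$v2[ri], cand$c2[ri])
          if (b1 %in% used_bodies || b2 %in% used_bodies || b1 == b2) next
          used_bodies <- c(used_bodies, b1, b2)
          units[[length(units) + 1L]] <- list(
            nu = cells$nu[ci], v1 = cand$v1[ri], v2 = cand$v2[ri],
            c1 = cand$c1[ri], c2 = cand$c2[ri], kdisc = cells$ka[ci]
          )
          more <- TRUE
          break
        }
      }
    }
    if (length(units) < n_units) {
      stop("inventory too small for ", n_units, " units (",
           length(units), " available)", call. = FALSE)
    }

    rows <- list()
    targets <- data.frame(dense = character(n_units),
                          sparse = character(n_units),
                          stringsAsFactors = FALSE)
    onset_disc <- stats::setNames(inv$onsets$disc, inv$onsets$orth)
    coda_disc <- stats::setNames(inv$codas$disc, inv$codas$orth)
    rfreq <- function(m) pmax(1, round(1e6 / sample.int(2000L, m,
                                                        replace = TRUE)))
    for (u in seq_len(n_units)) {
      un <- units[[u]]
      nuc <- un$nu
      # the two targets take equal-length onsets so the conditions are
      # matched on visual complexity and word length
      len1 <- nchar(sample(inv$onsets$orth, 1L))
      same_len <- inv$onsets$orth[nchar(inv$onsets$orth) == len1]
      tpair <- sample(same_len, 2L)
      others <- sample(setdiff(inv$onsets$orth, tpair), family_size + 1L)
      ons <- c(tpair[1L], others[seq_len(family_size - 1L)], tpair[2L],
               others[family_size:(family_size + 1L)])
      target_freq <- rfreq(1L)
      buddy_freq <- rfreq(1L)

      # dense family: target plus (family_size - 1) body neighbours
      dense_orth <- paste0(ons[seq_len(family_size)], un$v1, un$c1)
      # sparse target: same rime DISC, disjoint spelling, no body neighbour
      sparse_orth <- paste0(ons[family_size + 1L], un$v2, un$c2)
      # onset-vowel buddy per target: same onset and vowel spelling,
      # different coda, same nucleus DISC; prevents either target from
      # carrying a cue unique to itself (which would block co-activation)
      bcs <- sample(setdiff(cpool$orth, c(un$c1, un$c2)), 2L)
      dense_buddy <- paste0(ons[1L], un$v1, bcs[1L])
      sparse_buddy <- paste0(ons[family_size + 1L], un$v2, bcs[2L])
      # junction filler for the sparse side: shares the vowel spelling and
      # the vowel-coda junction bigram with the sparse target without being
      # an orthographic neighbour or a rime sharer
      cj <- sample(cpool$orth[substr(cpool$orth, 1L, 1L) ==
                                substr(un$c2, 1L, 1L) &
                                cpool$orth != un$c2], 1L)
      filler <- paste0(ons[family_size + 2L], un$v2, cj)

      orths <- c(dense_orth, sparse_orth, dense_buddy, sparse_buddy, filler)
      discs <- c(
        paste0(onset_disc[ons[seq_len(family_size)]], nuc, coda_disc[un$c1]),
        paste0(onset_disc[ons[family_size + 1L]], nuc, coda_disc[un$c2]),
        paste0(onset_disc[ons[1L]], nuc, coda_disc[bcs[1L]]),
        paste0(onset_disc[ons[family_size + 1L]], nuc, coda_disc[bcs[2L]]),
        paste0(onset_disc[ons[family_size + 2L]], nuc, coda_disc[cj])
      )
      freqs <- c(target_freq, rfreq(family_size - 1L), target_freq,
                 buddy_freq, buddy_freq, rfreq(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        orthography = orths, disc = discs, frequency = freqs,
        is_nonword = FALSE, stringsAsFactors = FALSE
      )
      targets$dense[u] <- dense_orth[1L]
      targets$sparse[u] <- sparse_orth
    }
    lex <- do.call(rbind, rows)
    lex <- lex[!duplicated(lex$orthography), , drop = FALSE]
    targets <- targets[targets$dense %in% lex$orthography &
                         targets$sparse %in% lex$orthography, , drop = FALSE]
    list(lexicon = as_lexicon(lex), targets = targets)
  })
}

#' Family design for the consistency contrast
#'
#' Each unit realises one phonological rime with two equal-length
#' spellings: a fully consistent family (target plus `family_size - 1`
#' friends) and an inconsistent family of the same size, built from the
#' same onsets and frequencies, in which the `n_enemies` highest-frequency
#' non-target members take an alternative rime pronunciation. Both targets
#' share the rime, the word-initial demi-syllable, the onset spelling and
#' the frequency, so they face identical phonological competition and
#' differ only in how many of their orthographic body neighbours support
#' the target rime.
#'
#' @param seed Integer seed.
#' @param n_units Number of matched units (2 targets each).
#' @param family_size Words per family, target included.
#' @param n_enemies Enemies within the inconsistent family.
#' @return List with `lexicon` and a data frame `targets` (columns
#'   `consistent`, `inconsistent`).
#' @export
generate_consistency_design <- function(seed = 1L, n_units = 100L,
                                        family_size = 6L, n_enemies = 2L) {
  inv <- fixture_inventories()
  stopifnot(family_size >= 2L, n_enemies >= 1L, n_enemies < family_size,
            family_size <= nrow(inv$onsets))
  .with_seed(seed, {
    nspell <- .radix_split(c(inv$nuclei$orth, inv$nuclei$orth),
                           c(inv$nuclei$disc, inv$nuclei$alt))
    cpool <- inv$codas[nzchar(inv$codas$orth), , drop = FALSE]
    cspell <- .radix_split(cpool$orth, cpool$disc)
    all_nuc <- unique(c(inv$nuclei$disc, inv$nuclei$alt))

    # units are built from cells of same-sounding rime spellings: the two
    # target bodies must be spelled differently but with the same number of
    # letters, so that visual complexity is matched within a unit; a third
    # spelling hosts the filler words
    used_bodies <- character(0)
    units <- list()
    cells <- expand.grid(
      nu = names(nspell)[vapply(nspell, length, 1L) >= 2L],
      ka = names(cspell)[vapply(cspell, length, 1L) >= 2L],
      stringsAsFactors = FALSE
    )
    cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
    more <- TRUE
    while (length(units) < n_units && more) {
      more <- FALSE
      for (ci in seq_len(nrow(cells))) {
        if (length(units) >= n_units) break
        vs <- sample(nspell[[cells$nu[ci]]])
        cs <- sample(cspell[[cells$ka[ci]]])
        if (length(vs) < 2L || length(cs) < 2L) next
        cand <- expand.grid(v1 = vs, c1 = cs, v2 = vs, c2 = cs,
                            stringsAsFactors = FALSE)
        # equal length and shared initial letters in both components keep
        # the two spellings visually close, so the paired contrast is not
        # swamped by letter-identity differences
        cand <- cand[paste0(cand$v1, cand$c1) != paste0(cand$v2, cand$c2) &
                       nchar(cand$v1) + nchar(cand$c1) ==
                         nchar(cand$v2) + nchar(cand$c2) &
                       substr(cand$v1, 1L, 1L) == substr(cand$v2, 1L, 1L) &
                       substr(cand$c1, 1L, 1L) == substr(cand$c2, 1L, 1L), ,
                     drop = FALSE]
        if (!nrow(cand)) next
        cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
        for (ri in seq_len(nrow(cand))) {
          b1 <- paste0(cand$v1[ri], cand$c1[ri])
          b2 <- paste0(cand$v2[ri], cand$c2[ri])
          if (b1 %in% used_bodies || b2 %in% used_bodies) next
          used_bodies <- c(used_bodies, b1, b2)
          units[[length(units) + 1L]] <- list(
            nu = cells$nu[ci], b1 = b1, b2 = b2,
            v1 = cand$v1[ri], v2 = cand$v2[ri],
            c1 = cand$c1[ri], c2 = cand$c2[ri],
            kdisc = cells$ka[ci]
          )
          more <- TRUE
          break
        }
      }
    }
    if (length(units) < n_units) {
      stop("inventory too small for ", n_units, " units (",
           length(units), " available)", call. = FALSE)
    }

    onset_disc <- stats::setNames(inv$onsets$disc, inv$onsets$orth)
    coda_disc <- stats::setNames(inv$codas$disc, inv$codas$orth)
    rfreq <- function(m) pmax(1, round(1e6 / sample.int(2000L, m,
                                                        replace = TRUE)))
    rows <- list()
    targets <- data.frame(consistent = character(n_units),
                          inconsistent = character(n_units),
                          stringsAsFactors = FALSE)
    for (u in seq_len(n_units)) {
      un <- units[[u]]
      nuc <- un$nu
      alt <- sample(setdiff(all_nuc, nuc), 1L)
      target_freq <- rfreq(1L)
      # both targets take the same onset (matched visual complexity and a
      # shared word-initial demi-syllable); the rest of each family gets
      # its own onsets but one shared frequency vector
      o_t <- sample(inv$onsets$orth, 1L)
      oi1 <- c(o_t, sample(setdiff(inv$onsets$orth, o_t), family_size - 1L))
      oi2 <- oi1
      fam_freq <- rfreq(family_size - 1L)

      # consistent family: every member of body 1 takes the unit rime
      fam1 <- data.frame(
        orthography = paste0(oi1, un$b1),
        disc = paste0(onset_disc[oi1], nuc, coda_disc[un$c1]),
        frequency = c(target_freq, fam_freq),
        is_nonword = FALSE, stringsAsFactors = FALSE
      )
      # inconsistent family: the n_enemies highest-frequency non-target
      # members of body 2 take an alternative nucleus, so the target's
      # spelling-to-sound mapping loses its token-weighted majority
      enemy_pos <- 1L + order(fam_freq, decreasing = TRUE)[seq_len(n_enemies)]
      nuc2 <- rep(nuc, family_size)
      nuc2[enemy_pos] <- alt
      fam2 <- data.frame(
        orthography = paste0(oi2, un$b2),
        disc = paste0(onset_disc[oi2], nuc2, coda_disc[un$c2]),
        frequency = c(target_freq, fam_freq),
        is_nonword = FALSE, stringsAsFactors = FALSE
      )
      # one onset-vowel buddy per target (same onset and vowel, different
      # coda, identical frequency in both conditions) so that neither
      # target carries a cue unique to itself
      bcs <- sample(setdiff(cpool$orth, c(un$c1, un$c2)), 2L)
      buddy_freq <- rfreq(1L)
      buddies <- data.frame(
        orthography = c(paste0(oi1[1L], un$v1, bcs[1L]),
                        paste0(oi2[1L], un$v2, bcs[2L])),
        disc = c(paste0(onset_disc[oi1[1L]], nuc, coda_disc[bcs[1L]]),
                 paste0(onset_disc[oi2[1L]], nuc, coda_disc[bcs[2L]])),
        frequency = rep(buddy_freq, 2L),
        is_nonword = FALSE, stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- rbind(fam1, fam2, buddies)
      targets$consistent[u] <- fam1$orthography[1L]
      targets$inconsistent[u] <- fam2$orthography[1L]
    }
    lex <- do.call(rbind, rows)
    lex <- lex[!duplicated(lex$orthography), , drop = FALSE]
    targets <- targets[targets$consistent %in% lex$orthography &
                         targets$inconsistent %in% lex$orthography, ,
                       drop = FALSE]
    list(lexicon = as_lexicon(lex), targets = targets)
  })
}
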