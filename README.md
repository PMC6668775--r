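# ndra — Naive Discriminative Reading Aloud

`ndra` is an R implementation of a single-route discriminative-learning
model of response times in the reading aloud task. It is aimed at
psycholinguists who study visual word recognition and speech production
and want a fully scripted, deterministic simulator for naming latencies
of words *and* non-words that does not rely on grapheme-to-phoneme
conversion rules or a separate sub-lexical route.

## The model in brief

Reading aloud is modelled in three stages:

1. **Visual decoding.** Each letter has a complexity
   `C_i = sqrt( Σ_j Σ_k |B_ik − B_jk| )`, the (root) summed city-block
   distance between its 20×20 bitmap and those of the other letters; word
   complexity is the sum over letters.
2. **Orthography → lexemes.** Letters and boundary-marked letter bigrams
   (`bear` → `b, e, a, r, #b, be, ea, ar, r#`) are cues to lexical
   outcomes in a Rescorla–Wagner network solved at equilibrium
   (`Pr(O|C_i) − Σ_j Pr(C_j|C_i) V_ji = 0`), a parameter-free system
   determined entirely by the distributional properties of the training
   lexicon. The input co-activates orthographic neighbours along with the
   target — the model's only route to non-word phonology.
3. **Lexemes → phonology.** Demi-syllables (DISC notation, the nucleus
   in both halves: `b8R` → `b8`, `8R`) are linked to lexemes by a second
   equilibrium network, read in transposition at run time:
   `ActPhon_k = w_lex·a_t + Σ_i w_i·a_i + b`, with neighbour votes `w_i`
   given by orthographic activation. The entropy `H` over the two
   demi-syllable activations measures response-selection conflict.

Latencies integrate these multiplicatively,

```
Act = Complexity^w1 · H^w5 / (ActLexeme^w2 · ActPhon1^w3 · ActPhon2^w4)
RT  = w6 · Act + w7        (ms)
```

with the published default parameters (`w1 = 1.270 … w7 = 450`,
`w_lex = 4.700`, back-off `b = 0.01`, 20 neighbours) exposed through
`ndra_params()`. A top-down checking mechanism turns activations into
actual DISC pronunciations for words (via the target lexeme) and
non-words (via onset+vowel- and rhyme-sharing lexemes), with explicit tie
and vowel-conflict resolution.

Everything runs on synthetic lexica from the built-in generator (Zipfian
frequencies, orthographic body families, controllable spelling-to-sound
consistency), so no external lexical databases are needed.

## Worked example

```r
library(ndra)

lex   <- generate_lexicon(fixture_config(seed = 42, n_words = 500,
                                         n_bodies = 125,
                                         consistency_mix = 0))
model <- ndra_train(lex)
model
#> <ndra_model>
#>   orthography -> lexeme: 232 cues x 500 lexemes
#>   demi-syllable network: 313 demi-syllables x 500 lexemes
#>   trained on 500 lexicon entries

nw   <- generate_nonwords(lex, seed = 43, n = 3)
prof <- ndra_simulate(model, c(lex$orthography[1:3], nw$orthography))
prof[, c("item", "nonword", "first", "second", "ActLexeme",
         "ActPhon1", "ActPhon2", "H", "RT")]
#>    item nonword first second ActLexeme ActPhon1 ActPhon2     H  RT
#> 1  hute   FALSE    hV     Vt     0.839    2.517    1.907 0.986 504
#> 2 grute   FALSE   grV     Vt     0.626    2.778    1.387 0.918 528
#> 3  kute   FALSE    kV     Vt     0.207    1.927    0.905 0.904 529
#> 4  gouf    TRUE    g6     6f     0.010    0.106    0.271 0.858 639
#> 5 heass    TRUE    hi     is     0.010    0.156    0.105 0.973 710
#> 6  koup    TRUE    k6     6p     0.010    0.162    0.290 0.942 632

pronounce(model, c("hute", nw$orthography[1]))
#>   item first second assembled             route failed
#> 1 hute    hV     Vt       hVt       word-target  FALSE
#> 2 gouf    g6     6f       g6f nonword-neighbors  FALSE
```

The words are read through their own lexical representations
(high `ActLexeme`, strong demi-syllable support, latencies near 500 ms);
the non-words have no lexeme (`ActLexeme` pinned at the 0.01 back-off),
draw phonology from co-activated neighbours only, and come out over
100 ms slower — the non-word naming disadvantage. The pronunciations are
assembled from attested demi-syllables selected by the checking
mechanism.

Higher-level experiment wrappers reproduce the benchmark effects of the
naming literature on seeded synthetic data: `experiment_lexicality()`,
`experiment_neighborhood()`, `experiment_consistency()` and
`experiment_nonword_frequency()`. A command-line front end for the
generate/train/simulate/pronounce/evaluate pipeline lives in
`inst/cli/ndra.R`.

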