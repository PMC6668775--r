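---
title: "A discriminative-learning model of reading aloud: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discriminative-learning model of reading aloud: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndra)
```

## The model

`ndra` implements a single-route model of response times in the reading
aloud task. Reading aloud is modelled in three stages: a visual front end
that decodes letters, and two associative networks — orthography to
lexical representations (*lexemes*), and lexemes to phonological output
units — trained with the Rescorla–Wagner learning rule. There is no
separate grapheme-to-phoneme rule system: non-words are read through the
co-activation of orthographically similar words in the same lexical
network that reads words.

### Equilibrium Rescorla–Wagner learning

On a learning event, the association $V_{ik}$ from each present cue $C_i$
to an outcome $O_k$ changes by $\alpha\beta_1(\lambda - \sum_j V_{jk})$
when the outcome is present and $\alpha\beta_2(0 - \sum_j V_{jk})$ when it
is absent, the sum running over the present cues. Rather than simulating a
developmental trajectory, the package models the stable adult state as the
solution of the equilibrium equations

$$\Pr(O_k \mid C_i) - \sum_j \Pr(C_j \mid C_i)\, V_{jk} = 0,$$

which is parameter-free: it depends only on the conditional co-occurrence
probabilities of cues and outcomes in the (frequency-weighted) training
events. Outcomes are solved independently of one another — the "naive"
independence assumption. `solve_equilibrium()` is the implementation;
`simulate_learning()` provides the trial-level process as an independent
check (with a small constant learning rate the trajectory fluctuates
around the equilibrium; since the update is linear in the weights, the
stationary mean *is* the equilibrium, so the tail-averaged trajectory is
an unbiased, variance-reduced estimate of it).

Two numerical points deserve mention.

* **Rank deficiency is the rule, not the exception.** Whenever cues are
  perfectly correlated the system is singular; we then take the
  minimum-norm least-squares solution (Moore–Penrose pseudoinverse),
  which is deterministic and invariant to cue order. In the phonology
  network singularity is even *structural*: with exactly two demi-syllable
  cues per word, the vector that is $+1$ on all word-initial and $-1$ on
  all word-final demi-syllables of a connected component is always a null
  vector of the cue co-occurrence system.
* **Residual tolerance.** On full-rank systems the solver verifies a
  maximum residual of $10^{-8}$ and aborts otherwise; in practice
  residuals sit at the $10^{-15}$ level.

### From letters to latencies

Orthographic cues are the letters of a word plus its letter bigrams with a
boundary marker (`bear` → `b, e, a, r, #b, be, ea, ar, r#`); cue presence
is binary. The activation of an outcome is the sum of the weights from the
active cues plus a small back-off constant $b = 0.01$ that keeps all
activations positive.

Phonology uses *demi-syllables* in CELEX DISC notation, with the nucleus
represented in both halves (`b8R` → `b8` and `8R`). The phonology network
is trained with demi-syllables as cues and lexemes as outcomes (one-to-many
mappings are learned more discriminatively, and perception precedes
production); at run time the flow is reversed by reading the transpose.
The activation of demi-syllable $k$ is

$$\mathrm{ActPhon}_k = w_{lex}\, a_t + \sum_i w_i\, a_i + b,$$

where $a_t$ is the transposed weight from the target lexeme, the $a_i$
are the weights from the co-activated orthographic neighbours (the 20 most
activated lexemes other than the target), and each neighbour's vote $w_i$
is its own orthographic activation (raw, floored at zero). For non-words
the target term is absent. Competition at response selection is the
Shannon entropy $H$ over the two demi-syllable activations transformed
into probabilities.

The five measures combine multiplicatively into total activation

$$\mathrm{Act} =
\frac{\mathrm{Complexity}^{w_1}\, H^{w_5}}
     {\mathrm{ActLexeme}^{w_2}\, \mathrm{ActPhon}_1^{w_3}\,
      \mathrm{ActPhon}_2^{w_4}},$$

and a simulated latency $RT = w_6\,\mathrm{Act} + w_7$ in milliseconds.
We place the facilitatory measures in the denominator: the back-off
constant is motivated throughout as preventing division by zero, and only
this placement yields the observed signs (more bottom-up support → shorter
latencies). Activations entering $H$ and the ratio are floored at $b$
(association sums can be negative), and $H$ itself is floored at $b$ so a
degenerate entropy cannot zero out the latency.

The ten parameters, all exposed via `ndra_params()`:

| parameter | default | role |
|---|---|---|
| $w_1$ | 1.270 | visual complexity exponent |
| $w_2$ | 0.200 | lexeme activation exponent |
| $w_3$ | 0.050 | first demi-syllable exponent |
| $w_4$ | 0.098 | second demi-syllable exponent |
| $w_5$ | 0.152 | entropy exponent |
| $w_6$ | 0.055 | latency slope (ms per activation unit) |
| $w_7$ | 450 | latency intercept (ms) |
| $w_{lex}$ | 4.700 | target-lexeme weight in demi-syllable activation |
| $b$ | 0.01 | back-off constant |
| $n$ | 20 | co-activated neighbours considered |

### The visual front end

Letter complexity is the summed city-block distance between a letter's
20×20 binary bitmap and the bitmaps of the other 25 letters; by default
the square root of the sum is taken (the bare sum is available via
`use_sqrt = FALSE`, since the two variants both appear in descriptions of
this family of measures). Word complexity is the sum over letter
occurrences. The package ships a deterministic synthetic monospaced glyph
set (`inst/extdata/glyphs_synthetic_mono_20x20.pbm`, upscaled from a 5×7
bitmap font) instead of rasterizing a system font: rasterization is
platform-dependent and would make complexity values irreproducible. Only
ordinal properties are meaningful for this fixture — visually prototypical
letters such as *o* and *c* score low, atypical ones such as *w* and *y*
score high — and only such properties are asserted in the tests.

### Generating pronunciations

The discriminative core yields activations, not utterances. A top-down
checking mechanism selects what to say:

* **Words.** Demi-syllable selection is restricted to the units activated
  by the target lexeme itself; the most strongly connected word-initial
  and word-final demi-syllables are chosen.
* **Non-words.** The voting lexemes vary serially with reading position:
  the word-initial demi-syllable is chosen by an activation-weighted vote
  of the lexemes sharing the orthographic onset and vowel with the item,
  the word-final one by the lexemes sharing the orthographic rhyme. When
  no lexeme shares the onset-plus-vowel (rhyme), the mechanism falls back
  to onset-only (coda-only) sharers. Only attested demi-syllables can be
  produced; items without any sharers fail explicitly rather than being
  patched.
* **Ties** are resolved by a ladder: (1) the activation-weighted vote of
  the orthographically sharing lexemes, restricted to the tied units;
  (2) the same vote unweighted — engaged when the orthographic activations
  carry no signal, which happens at small scale when the equilibrium
  blocks neighbours exactly; (3) a re-vote by onset-only/coda-only
  sharers over units phonologically compatible with the tie (our reading
  of an ambiguous procedural clause: compatibility means sharing the
  phonological onset for word-initial units and the phonological coda for
  word-final units); (4) lexicographic order, which also makes results
  platform-independent.
* **Vowel conflicts** (the two selected halves disagreeing on the
  nucleus) are resolved in favour of the second demi-syllable, whose
  activation carries the larger exponent and whose rhyme is perceptually
  more prominent; the first half is re-selected among candidates with the
  matching nucleus, or, if none exists, synthesized from the winning
  onset and the second half's nucleus (flagged in the trace).

For naming latencies of non-words, the demi-syllable pair entering
$\mathrm{ActPhon}_k$ is the pair selected by this mechanism: no canonical
transcription is available for an item that has never been heard.

## The synthetic lexicon generator

All tests and the acceptance script run on synthetic lexica built by
`generate_lexicon()` from paired orthography/DISC inventories of onsets,
nuclei and codas (including silent-e and doubled-consonant coda spellings,
so that the same rime can be written in several ways, as in *maid/made*).
The generator emulates the structural properties of monomorphemic,
monosyllabic training data:

* **Zipfian token frequencies** (exponent 1.0 by default, maximum
  1,000,000), assigned to random ranks;
* **body families**: words sharing an orthographic rime (125 bodies for
  500 words by default, i.e. a mean family size of 4);
* **controllable consistency**: a configurable fraction of bodies
  (default 0.25, a rough reflection of how common inconsistent bodies are
  in English) carries a second rime pronunciation assigned to the members
  below the family's median frequency;
* **the shared-cue regime**: onsets are dealt per vowel group so that
  every onset–vowel combination occurs in at least two words. This is the
  single most important structural property. In a network trained on
  hundreds of thousands of words with only a few hundred cues, no word
  has a cue unique to itself; in a small random lexicon most words would.
  A unique cue makes the equilibrium *block* all co-activation of the
  word's orthographic neighbours exactly — the two-word example
  *bear/fear* already shows it: presenting *bear* activates FEAR at
  exactly zero, because bear's unique cues compensate the shared ones.
  Since every neighbourhood phenomenon in this architecture flows through
  co-activation, the fixture must avoid the unique-cue regime to be
  representative of scale.
* **no exchangeable cues**: two demi-syllables whose sets of co-occurring
  partner units coincide exactly are *exchangeable* for the equilibrium —
  their weights to every lexeme are identical, and no mechanism can
  recover which of them belongs to which word. Real lexica essentially
  never contain exact duplicates, but regular synthetic ones do; the
  generator breaks them by swapping onsets between same-vowel words
  (which preserves all combination counts).

`generate_nonwords()` recombines attested onsets and bodies into novel
strings whose candidate demi-syllables are attested and whose onset–vowel
junction occurs in some word, and flags pseudo-homophones.

What the generator does **not** emulate: real English letter statistics,
morphological structure, polysyllables, age-of-acquisition or semantic
correlates. Passing tests on these fixtures therefore show that the
mechanisms work and point in the documented directions at desk scale; they
do not certify quantitative fits to human data, which require the full
training resources.

## The benchmark contrasts

Four latency contrasts from the experimental literature are packaged as
seeded experiments (`experiment_*()`), each reporting group means and a
one-sided test.

**Lexicality.** Words versus matched non-words on the default lexicon.
Non-words lack a lexeme (ActLexeme is pinned at $b$) and lack the target
term in demi-syllable activation, so they come out 25–30% slower — the
direction and rough magnitude observed in naming studies.

**Orthographic neighbourhood density.** Measured as reading research
measures it: across the heterogeneous items of a lexicon, latencies are
regressed on Coltheart's N (and median-split for a mean contrast). The
effect is robustly facilitatory on the fixture. A caveat worth recording:
in a *minimal* matched design that holds length, frequency and the number
of phonological rime-sharers constant (`generate_neighborhood_design()`),
the model's own arithmetic predicts a small net *inhibition* with the
default parameters, because the dilution of the target's own lexeme
activation by cue-sharing neighbours (exponent $w_2 = 0.200$) outweighs
the extra demi-syllable support those neighbours send (exponents
$w_3 + w_4 = 0.148$ applied to small relative gains). The headline
facilitation across unmatched items rides substantially on the covariation
of density with word length, which the model expresses through visual
complexity. The matched design is exported precisely so that users can
inspect this decomposition.

**Consistency.** `generate_consistency_design()` pairs, within each unit,
a fully consistent target with an inconsistent one matched on rime,
onset, word-initial demi-syllable, body length, family onsets and all
frequencies; the inconsistent family's highest-frequency non-target
members take an alternative nucleus, so the target's mapping loses its
token-weighted majority. Both targets face identical phonological
competition; they differ only in how many co-activated body neighbours
support the target rime. The paired contrast is about 2 ms against about
13 ms of between-unit equilibrium noise, so the packaged experiment pools
five replicate designs of 150 units (750 pairs) to test it with adequate
power.

**Non-word frequency.** Non-words demonstrably carry token frequencies in
web-scale corpora at the level of low-frequency words. The experiment adds
generated non-words to the training lexicon at two frequency tiers —
scaled to the synthetic corpus so that the high tier sits about an order
of magnitude above the corpus inclusion threshold and the low tier far
below it — retrains with unchanged parameters, and simulates the
retrained items through their newly acquired lexical representations:
once an item has been learned, the word/non-word distinction is graded,
not categorical, which is the point of the manipulation. A crossover
(each item high in one retraining, low in the other) turns this into a
within-item contrast; the high tier is named on the order of 100 ms
faster.

## Problem sizes and reproducibility

Default study sizes: 500-word lexica with 125 bodies; 200 items per group
in the lexicality and non-word frequency experiments; 750 matched pairs
for consistency; 50 random event tables for the solver residual check and
20 tables of $2\times10^5$ trials for the trial-level oracle. All
randomness is seed-derived; character orderings use radix sorting
throughout so that generation and tie-breaking are identical across
platforms and locales.

## Known limitations

* Monosyllabic, monomorphemic vocabulary only; one nucleus run per
  transcription.
* Homographs collapse onto a single lexeme (identified with the uppercase
  orthography).
* The checking mechanism cannot produce unattested demi-syllables; items
  whose parts are entirely unknown fail explicitly.
* Sub-lexical (direct orthography-to-phonology) activations are computed
  and reported for dual-route comparisons but never enter the simulated
  latency; in the reference analyses they add nothing once the lexical
  measures are in place.
* At desk scale, exact blocking and exchangeability are real properties
  of the equilibrium that full-scale training data do not exhibit; the
  generator works around them, and the vignette sections above record
  where this matters.
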