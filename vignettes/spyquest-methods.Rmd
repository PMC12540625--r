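---
title: "spyquest: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spyquest: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spyquest)
```

spyquest simulates and scores a suspect-elimination question game: one of
`N` visually distinct suspects (default 50) is a hidden spy; a player asks
an agent yes/no questions about the spy's visible attributes, crosses out
ruled-out suspects, and has a budget of 5 guesses. This vignette documents
the model behind each stage, the tunable parameters, and the design
decisions taken where the design was genuinely open.

## The room model

A room is a draw of `size` pairwise-distinct attribute vectors from the
product space of a finite schema, plus a uniformly chosen spy. The packaged
default schema has six properties:

```{r}
default_schema()
```

The full attribute table of the original 50-character game scene is not
published anywhere, so this schema is a reconstruction: it spans every
property and example value the game's documentation names (gender, hair
length and colour, face accessories such as glasses and scars, clothing
type and colour) and its 1,800-cell product space comfortably exceeds the
50 distinct suspects a room needs. Suspects are sampled *without
replacement* — characters in the game visibly differ from each other, so
duplicate attribute vectors are disallowed (and `generate_room()` refuses
schemas too small for the requested size). A single seed drives each room;
the suspect sample is consumed from the seeded stream first and the spy
draw last, so a `(schema, size, seed)` triple is a complete, bit-identical
description of a room. Screen coordinates are optional cosmetic metadata
and never enter scoring or the room checksum.

## Question classification

Free-text questions are mapped to `(property, value)` labels by keyword
pattern matching:

1. tokenize: lowercase, drop apostrophes, split hyphens, strip punctuation;
2. if a colour word is present, consult **property–colour pairs**: a colour
   plus a cue word ("hair", "wearing", "shirt", …) labels the matching
   colour property — so "Does the target have grey hair?" is a hair-colour
   question even though "grey" alone names no property;
3. otherwise, if exactly one value keyword matches, return its pair;
4. everything else is `UNCLASSIFIED` — a value, not an error.

Three rules are deliberate choices rather than forced by the scheme:

* **Whole-word, phrase-aware matching.** Keywords match whole tokens only
  ("scarf" never fires "scar"), and multi-word keywords suppress their
  embedded words ("t-shirt" does not degrade to "shirt"). No stemming: the
  scheme's strength is its transparency.
* **Conjunctions are unclassifiable.** A question carrying two distinct
  non-colour keywords ("a woman wearing glasses") cannot be represented by
  a single-label scheme; forcing a choice would silently misscore it.
* **Negation is classified as if positive by default.** "Not wearing
  glasses" keys on "glasses"; the `reject_negation` flag routes such
  questions to `UNCLASSIFIED` instead for users who prefer to drop them.

```{r}
lex <- build_default_lexicon(default_schema())
classify_question("Is it a boy?", lex)
classify_question("Does the target have grey hair?", lex)
classify_question("Is the spy a woman wearing glasses?", lex)
```

## The answer oracle

The oracle reproduces the chatbot's three-way contract — `"Affirmative
agent"`, `"Negative agent"`, `"I cannot give the answer to that question"`
— plus a deflection for questions addressed to the agent itself ("Are you
wearing glasses?"). Unlike a live language model it is never wrong; an
optional `oracle_error_rate` flips truthful yes/no answers with the given
probability (seeded) to study how an unreliable answerer degrades play and
scoring. Refusals and deflections are distinguished in logs but both carry
zero attribute information, so both are excluded from ground-truth
scoring and score zero eliminations.

## Scoring

With `n` questions on a room of `N` suspects:

* **QEM**: per-question score `eliminated_i / N` with the denominator fixed
  at the room size, totalled as `Σ (1/i) · score_i`. Every question is
  included; no classification is needed. Player eliminations occurring
  between question `i` and question `i+1` (or game end) are attributed to
  question `i` — the attribution window is not otherwise specified by the
  game's log format.
* **Effective QEM**: a ground-truth replay. Each question is re-classified
  from its text; unclassifiable questions leave the sequence; each included
  question scores `potential_i / remaining_i` where `remaining_i` counts
  suspects consistent with all previous included answers and `potential_i`
  is the drop in that count.

Two numerical decisions matter:

* **No division by zero.** The consistent count includes the spy, so it is
  at least 1 by construction; questions asked after the field collapses to
  one suspect ("overshooting") score 0. A replayed answer chain that would
  empty the set entirely — possible only when answers were not truthful —
  retains one suspect (the spy when still present) and raises a `clamped`
  flag rather than failing, so external logs always score.
* **Index shifting.** Excluded questions do not consume a `1/i` slot by
  default; the alternative reading (weights keyed to original transcript
  positions) is available as `keep_original_index = TRUE`. The two agree
  whenever nothing is excluded, and the first included question's score is
  the "first-question effective QEM" either way.

Scores are per-question bounded in `[0, 1]`, totals bounded by the harmonic
number `H_n`, and — because weights decrease — a fixed multiset of
per-question scores attains its maximal total exactly when delivered in
descending order: front-loading informative questions is rewarded.

## Simulated players

`propose_question()` implements the strategy taxonomy from the
question-asking literature over `(property, value)` pairs:
*constraint-seeking* picks the pair whose holder fraction among remaining
suspects is closest to 1/2; *hypothesis-scanning* picks the pair held by
the fewest (but at least one); *random* draws uniformly from unasked
pairs. Ties break by schema order, then value order, keeping play
deterministic under the seed.

`run_game()` wraps a proposal rule with human-like noise:

| knob | meaning | default |
|---|---|---|
| `lapse_rate` | probability a turn asks a uniformly random question | 0 |
| `elimination_compliance` | probability the player crosses out what an answer justifies | 1 |
| `guess_threshold` | guess when the believed remaining set is this small | 1 |
| `premature_guess_rate` | probability of guessing early on any turn | 0 |

The player's *believed* set (ground truth filtered by the eliminations they
actually recorded) drives both question choice and guessing — guesses are
uniform over it, modelling imperfect bookkeeping. Wrong guesses eliminate
the guessed suspect and spend budget; the spy is never eliminated from
either set. Questions are rendered through canonical templates covered by
the lexicon, so every emitted question classifies back to its generating
pair (a `free_text` mode injects paraphrases to stress the classifier).

The `noisy_human` policy bundles the canonical noise preset (lapse 0.2,
compliance 0.6, premature rate 0.05, threshold 3). Measured over seeded
batches it wins almost always — noise at that level mostly slows play
rather than losing games. Because an engaging difficulty level for human
players sits at a 60–80 % success rate, we ran a one-off sweep over the
four knobs (150 games per cell, seed 11) and packaged the selected cell as
`noisy_human_presets()$calibrated`: lapse 0.2, compliance 0.4, threshold 8,
premature rate 0.05. That preset plays in the band (win rates around 0.75
across seeds) at roughly 8–9 questions per game, and reproduces the
qualitative elimination phenotypes of human play: winners with near-total
elimination, a loser tail with very few eliminations (low compliance), and
occasional lucky early winners.

### What the simulator does and does not emulate

The generator reproduces the *structure* of human sessions — question
sequences with varying informativeness, incomplete crossing-out, premature
and repeated guesses, 60–80 % win rates — which is what the scoring and
analysis stages consume. It does not model natural-language variety beyond
the paraphrase templates, question complexity, learning within a session,
or answer latencies (times are drawn from a fixed lognormal and are
metadata only). Tests passing on simulated data therefore validate the
measurement pipeline, not claims about human cognition.

## Outcome analysis

Win/loss prediction from session measures follows the standard recipe for
imbalanced outcomes: stratified 80/20 split (seeded), SMOTE on the
*training fold only* (oversampling the test fold would leak synthetic
copies of test information), logistic regression, evaluation at threshold
0.5. SMOTE uses `k = 5` nearest minority neighbours (the canonical
choice) under Euclidean distance on SD-standardized features; each
synthetic point is a convex combination of two real minority points. The
default model uses the single feature `n_player_eliminated`, matching the
observation that elimination thoroughness is the dominant predictor of
winning; arbitrary feature subsets are accepted.

The fit itself is ordinary maximum likelihood via `stats::glm` (IRLS,
tolerance 1e-8, 100 iterations). Perfect separation — easy to produce
here, since "eliminated > 40 ⇒ win" patterns separate cleanly — is
detected and flagged, and the model refits with a tiny ridge penalty
(λ = 1e-6, intercept unpenalized) so coefficients stay finite while
predictions are unchanged for practical purposes.

## Numerical and interface choices

* Randomness: every public entry point that draws takes an explicit
  integer seed; batches derive distinct per-game seeds from a master seed.
* Rooms are identified in transcripts by an FNV-1a 32-bit checksum of the
  canonical attribute table plus spy id; scorers refuse a mismatched room.
* Transcripts are JSON Lines with a schema-versioned header (streamable,
  append-safe); session tables are CSV with doubles printed at 17
  significant digits so they round-trip bit-for-bit.
* Degenerate inputs: empty transcripts score 0; sessions without questions
  or without classifiable questions are flagged (`excluded_reason`), never
  dropped; malformed records report their line number.

The test suite exercises the engine at the scales the checks need:
1,000 replayed games against a brute-force consistency oracle, 10,000
fuzzed games (room sizes 20–50, all policies) for the no-overshoot
guarantee, 500 games per policy for the strategy ordering
(constraint-seeking < hypothesis-scanning < random in mean questions, at
95 % bootstrap confidence), and closed-form three-question fixtures checked
to 1e-12.

## Known limitations

* The default schema is a reconstruction, not the original art's attribute
  table; absolute score levels on simulated rooms need not match scores on
  the original scene, though all scoring properties are schema-agnostic.
* The classifier is English-only and keyword-bound; paraphrases outside
  the lexicon are `UNCLASSIFIED` (excluded from effective QEM), which
  mirrors the original measurement procedure's blind spot.
* Policies are memoryless heuristics, not cognitive models; they bound and
  order strategy performance but do not explain it.
* Effective QEM conditions on the answers actually given. With a noisy
  oracle the replayed "ground truth" inherits the noise; the `clamped`
  flag marks the resulting inconsistencies but cannot repair them.
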