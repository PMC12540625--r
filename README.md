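# spyquest

A deterministic, seedable research engine for studying **yes/no
question-asking strategies** in suspect-elimination games — the
"20 questions" / "Guess Who?" family, here in the form of a hidden-object
game: one of 50 visually distinct suspects in a room is a spy, and a player
narrows the field by asking an agent yes/no questions about the spy's
visible attributes (gender, hair, accessories, clothing), visually crossing
out ruled-out suspects, and spending up to 5 guesses.

The package replaces every component that normally needs human subjects or
a live language model with a reproducible counterpart:

| Stage | spyquest component |
|---|---|
| Room of 50 distinct characters, one random spy | `default_schema()`, `generate_room()` |
| GPT-style chatbot answering "Affirmative agent" / "Negative agent" / "I cannot give the answer to that question" | `answer_question()` — a truthful oracle, with an optional error rate |
| Keyword pattern-matching of free-text questions to (property, value) labels | `build_default_lexicon()`, `classify_question()` |
| Human players | `run_game()` / `run_batch()` with constraint-seeking, hypothesis-scanning, random and noisy-human policies |
| Question-effectiveness scoring | `qem()`, `effective_qem()`, `first_question_effective_qem()` |
| Game logs and session measures | JSONL transcripts + CSV session tables (`write_transcripts()`, `summarize_sessions()`) |
| Win/loss outcome analysis on imbalanced data | `smote_oversample()` + `fit_winloss_model()` (`analyze_outcomes()`) |

## The scoring model

For a game with questions \(q_1, \dots, q_n\) on a room of \(N\) suspects
(by default \(N = 50\)):

**QEM** (question effectiveness measure) scores what the player actually
did. Each question is credited with the fraction of the *full room* the
player crossed out after its answer, and the per-question scores are summed
with harmonic weights so that early questions dominate:

```
QEM(q_i) = eliminated_i / N,          QEM = Σ_{i=1..n} (1/i) · QEM(q_i)
```

**Effective QEM** scores what the questions *could* have achieved,
replaying the transcript against the room's ground truth and ignoring the
player's crossing-out behaviour. Each classifiable question's potential
eliminations are counted against the suspects still consistent with all
previous answers:

```
eQEM(q_i) = potential_i / remaining_i,  eQEM = Σ_{i=1..n} (1/i) · eQEM(q_i)
```

Questions that cannot be mapped to a (property, value) label are excluded
from the sequence (the harmonic index runs over included questions;
`keep_original_index = TRUE` keeps transcript positions). The consistent
count always retains the spy, so the denominator never reaches zero:
"overshooting" questions asked after the field is resolved score 0 instead
of dividing by zero.

## Worked example

```r
library(spyquest)
schema <- default_schema()
room   <- generate_room(schema, 50, seed = 1)
lex    <- build_default_lexicon(schema)

tr <- run_game(room, noisy_human_presets()$calibrated, game_config(), seed = 42)
tr$turns[, c("i", "question_text", "answer", "remaining_before",
             "potential_eliminations", "player_eliminations")]
#>   i                 question_text      answer remaining_before
#> 1 1             Is the spy a man?    NEGATIVE               50
#> 2 2  Does the spy have long hair? AFFIRMATIVE               21
#> 3 3 Does the spy have blond hair?    NEGATIVE               10
#> 4 4     Does the spy have a scar?    NEGATIVE                6
#>   potential_eliminations player_eliminations
#> 1                     29                  29
#> 2                     11                  11
#> 3                      4                   0
#> 4                      2                   4

qem(tr)                      # <spy_scores> total 0.7100 over 4 questions
effective_qem(tr, room, lex) # <spy_scores> total 1.0586 over 4 questions
first_question_effective_qem(tr, room, lex)  # 0.58
```

The four questions came from a noisy constraint-seeking player: question 1
splits the room 29/21 (score 29/50 = 0.58); on question 3 the player
"forgot" to cross anyone out (`player_eliminations = 0`), which QEM
penalizes but effective QEM does not — that gap between the two scores is
exactly what the ground-truth replay isolates.

Scaling up and analysing outcomes:

```r
batch <- run_batch(200, policy = noisy_human_presets()$calibrated, master_seed = 7)
tab   <- summarize_sessions(batch, lexicon = lex)
session_aggregates(tab)
#> win_rate 0.735, mean_questions 8.54 (sd 4.61), mean_guesses_winners 2.96

analyze_outcomes(tab, seed = 3)$report
#> <spy_classifier_report> accuracy 0.750 on n = 40
#>  class precision    recall        f1 support
#>   LOSS 0.5384615 0.6363636 0.5833333      11
#>    WIN 0.8518519 0.7931034 0.8214286      29
```

The calibrated noisy-human preset plays inside the 60–80 % win-rate band
with roughly 8–9 questions per game; wins are predicted from the number of
suspects a player eliminated, after SMOTE-balancing the training fold.

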