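lex <- build_default_lexicon(default_schema())

test_that("QEM evaluates the harmonic-weighted elimination fractions", {
  room <- fixture_room_3q()
  tr <- fixture_transcript_3q(room)
  br <- qem(tr, total_suspects = 50)
  # 25/50 + (1/2)(12/50) + (1/3)(6/50)
  expect_equal(br$total, 0.66, tolerance = 1e-12)
  expect_equal(br$per_question$weight, 1 / (1:3))
  expect_false(br$clamped)

  zero <- tr
  zero$turns$player_eliminations <- c(0L, 0L, 0L)
  expect_equal(qem(zero)$total, 0)

  one <- tr
  one$turns <- one$turns[1, ]
  one$turns$player_eliminations <- 49L
  expect_equal(qem(one)$per_question$score, 0.98, tolerance = 1e-12)

  bad <- tr
  bad$turns$player_eliminations[2] <- -1L
  expect_error(qem(bad), class = "spyquest_negative_elimination")
})

test_that("effective QEM replays ground truth with shifting denominators", {
  room <- fixture_room_3q()
  tr <- fixture_transcript_3q(room)
  br <- effective_qem(tr, room, lex)
  # 25/50 + (1/2)(12/25) + (1/3)(6/13)
  expect_equal(br$total, 0.5 + 0.24 + 2 / 13, tolerance = 1e-12)
  expect_identical(br$per_question$potential_eliminations, c(25L, 12L, 6L))
  expect_identical(br$per_question$remaining_before, c(50L, 25L, 13L))
  expect_length(br$excluded_indices, 0)
  expect_false(br$clamped)
})

test_that("unclassifiable questions are excluded and indices shift", {
  room <- fixture_room_3q()
  tr <- fixture_transcript_3q(room)
  tr$turns$question_text[1] <- "Is the spy happy?"
  tr$turns$answer[1] <- "CANNOT_ANSWER"
  br <- effective_qem(tr, room, lex)
  expect_identical(br$excluded_indices, 1L)
  # the long-hair question is now included question 1: weight 1, 21/50
  expect_equal(br$per_question$weight[1], 1)
  expect_equal(br$per_question$score[1],
               sum(room$suspects$hair_length == "long") / 50)

  keep <- effective_qem(tr, room, lex, keep_original_index = TRUE)
  expect_equal(keep$per_question$weight, 1 / tr$turns$i[-1])

  allbad <- tr
  allbad$turns$question_text <- rep("Is the spy happy?", 3)
  allbad$turns$answer <- rep("CANNOT_ANSWER", 3)
  br0 <- effective_qem(allbad, room, lex)
  expect_equal(br0$total, 0)
  expect_identical(br0$excluded_indices, 1:3)
  expect_error(first_question_effective_qem(allbad, room, lex),
               class = "spyquest_no_classifiable_question")
})

test_that("first-question effective QEM handles even splits and unique values", {
  room <- fixture_room_3q()
  tr <- fixture_transcript_3q(room)
  expect_equal(first_question_effective_qem(tr, room, lex), 0.5)

  # first question unclassifiable: score comes from the next included one
  shifted <- tr
  shifted$turns$question_text[1] <- "Is the spy happy?"
  shifted$turns$answer[1] <- "CANNOT_ANSWER"
  expect_equal(first_question_effective_qem(shifted, room, lex),
               sum(room$suspects$hair_length == "long") / 50)

  # affirmative answer on a value only the spy holds: 49 of 50 eliminated
  uroom <- fixture_room_unique_scar()
  utr <- spy_transcript(
    session_id = "unique", room = uroom,
    turns = data.frame(i = 1L, question_text = "Does the spy have a scar?",
                       property = "face_accessory", value = "scar",
                       answer = "AFFIRMATIVE", player_eliminations = 49L,
                       remaining_before = 50L, potential_eliminations = 49L,
                       elapsed_s = 5, stringsAsFactors = FALSE),
    guesses = data.frame(suspect_id = 50L, correct = TRUE, elapsed_s = 2),
    outcome = "WIN")
  expect_equal(first_question_effective_qem(utr, uroom, lex), 0.98,
               tolerance = 1e-12)
})

test_that("questions after the field is resolved score zero, never divide by zero", {
  room <- fixture_room_unique_scar()
  turns <- data.frame(
    i = 1:3,
    question_text = c("Does the spy have a scar?", "Is the spy a man?",
                      "Is the spy a woman?"),
    property = NA_character_, value = NA_character_,
    answer = c("AFFIRMATIVE",
               if (room$suspects$gender[50] == "male") "AFFIRMATIVE" else "NEGATIVE",
               if (room$suspects$gender[50] == "female") "AFFIRMATIVE" else "NEGATIVE"),
    player_eliminations = c(49L, 0L, 0L), remaining_before = c(50L, 1L, 1L),
    potential_eliminations = c(49L, 0L, 0L), elapsed_s = 1,
    stringsAsFactors = FALSE)
  tr <- spy_transcript("overshoot", room, turns,
                       data.frame(suspect_id = 50L, correct = TRUE,
                                  elapsed_s = 1), "WIN")
  br <- effective_qem(tr, room, lex)
  expect_equal(br$per_question$score, c(0.98, 0, 0))
  expect_equal(br$per_question$remaining_before, c(50L, 1L, 1L))
  expect_false(br$clamped)
})

test_that("an answer chain that empties the room is clamped, not an error", {
  room <- fixture_room_unique_scar()
  # lie: nobody (not even the spy) survives 'scar AFFIRMATIVE then NEGATIVE gender twice'
  turns <- data.frame(
    i = 1:2,
    question_text = c("Is the spy a man?", "Is the spy a woman?"),
    property = NA_character_, value = NA_character_,
    answer = c("NEGATIVE", "NEGATIVE"),
    player_eliminations = c(0L, 0L), remaining_before = c(50L, NA),
    potential_eliminations = c(NA_integer_, NA_integer_), elapsed_s = 1,
    stringsAsFactors = FALSE)
  tr <- spy_transcript("liar", room, turns, empty_guesses_df(), "LOSS")
  br <- effective_qem(tr, room, lex)
  expect_true(br$clamped)
  expect_true(all(br$per_question$score >= 0 & br$per_question$score <= 1))
  expect_true(all(br$per_question$remaining_before >= 1))
})

test_that("QEM equals effective QEM when eliminations track ground truth exactly", {
  room <- fixture_room_3q()
  # one informative question, then one that eliminates nobody (no remaining
  # female wears white clothes), with the player crossing out exactly the
  # ground-truth eliminations
  turns <- data.frame(
    i = 1:2,
    question_text = c("Is the spy a man?", "Is the spy wearing white clothes?"),
    property = c("gender", "clothing_color"), value = c("male", "white"),
    answer = c("NEGATIVE", "NEGATIVE"),
    player_eliminations = c(25L, 0L), remaining_before = c(50L, 25L),
    potential_eliminations = c(25L, 0L), elapsed_s = 1,
    stringsAsFactors = FALSE)
  tr <- spy_transcript("track", room, turns,
                       data.frame(suspect_id = 44L, correct = TRUE,
                                  elapsed_s = 1), "WIN")
  expect_equal(qem(tr, 50)$total, effective_qem(tr, room, lex)$total,
               tolerance = 1e-12)
})

test_that("scores stay within bounds on simulated transcripts", {
  batch <- run_batch(40, policy = noisy_human_presets()$calibrated,
                     master_seed = 31)
  for (g in seq_along(batch$transcripts)) {
    tr <- batch$transcripts[[g]]
    room <- batch$rooms[[tr$room_checksum]]
    n <- nrow(tr$turns)
    if (!n) next
    qb <- qem(tr)
    eb <- effective_qem(tr, room, lex)
    expect_true(all(qb$per_question$score >= 0 & qb$per_question$score <= 1))
    expect_true(all(eb$per_question$score >= 0 & eb$per_question$score <= 1))
    expect_lte(qb$total, sum(1 / seq_len(n)) + 1e-12)
    expect_lte(eb$total, sum(1 / seq_len(n)) + 1e-12)
  }
})

test_that("a transcript scored against the wrong room is refused", {
  room <- fixture_room_3q()
  other <- generate_room(default_schema(), 50, seed = 99)
  tr <- fixture_transcript_3q(room)
  expect_error(effective_qem(tr, other, lex), class = "spyquest_room_mismatch")
})
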