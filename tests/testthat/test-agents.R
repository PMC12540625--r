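lex <- build_default_lexicon(default_schema())

test_that("proposal rules pick the documented questions", {
  room <- fixture_room_3q()  # gender splits 25/25
  q <- propose_question(policy_config("constraint_seeking"), room$suspects,
                        room$schema)
  expect_identical(q$property, "gender")

  # hypothesis scanning goes for the rarest held value: a unique scar
  uroom <- fixture_room_unique_scar()
  q2 <- propose_question(policy_config("hypothesis_scanning"), uroom$suspects,
                         uroom$schema)
  expect_identical(c(q2$property, q2$value), c("face_accessory", "scar"))

  # two remaining suspects differing in one property: both isolate the spy
  two <- room$suspects[room$suspects$gender == "female" &
                         room$suspects$hair_length == "long", ][1:2, ]
  stopifnot(nrow(two) == 2)
  diff_props <- names(which(vapply(
    c("hair_color", "face_accessory", "clothing_type", "clothing_color"),
    function(p) two[[p]][1] != two[[p]][2], logical(1))))
  for (pol in c("constraint_seeking", "hypothesis_scanning")) {
    qq <- propose_question(policy_config(pol), two, room$schema)
    expect_true(qq$property %in% diff_props)
  }
})

test_that("degenerate candidate sets raise NoInformativeQuestion", {
  room <- fixture_room_3q()
  same <- room$suspects[room$suspects$gender == "male", ][1:3, ]
  asked <- spyquest:::schema_pairs(room$schema)
  expect_error(propose_question(policy_config("random"), same, room$schema,
                                asked = asked),
               class = "spyquest_no_informative_question")
})

test_that("noiseless constraint seeking always wins with one guess", {
  for (seed in 1:25) {
    room <- generate_room(default_schema(), 50, seed = seed,
                          screen_positions = FALSE)
    tr <- run_game(room, policy_config("constraint_seeking"), game_config(),
                   seed = 100 + seed)
    expect_identical(tr$outcome, "WIN")
    expect_identical(nrow(tr$guesses), 1L)
    expect_true(tr$guesses$correct)
    # ground-truth remaining trace strictly decreasing
    expect_true(all(diff(tr$turns$remaining_before) < 0))
    expect_true(all(tr$turns$potential_eliminations >= 1))
  }
})

test_that("games are deterministic under the seed", {
  room <- generate_room(default_schema(), 50, seed = 5)
  a <- run_game(room, policy_config("random"), game_config(), seed = 9)
  b <- run_game(room, policy_config("random"), game_config(), seed = 9)
  expect_identical(a, b)
  c <- run_game(room, policy_config("random"), game_config(), seed = 10)
  expect_false(identical(a$turns, c$turns))
})

test_that("zero elimination compliance yields unmarked boards but positive effective QEM", {
  room <- generate_room(default_schema(), 50, seed = 21)
  pol <- policy_config("constraint_seeking", elimination_compliance = 0,
                       guess_threshold = 1)
  tr <- run_game(room, pol, game_config(), seed = 22)
  expect_true(all(tr$turns$player_eliminations == 0))
  expect_equal(qem(tr)$total, 0)
  expect_gt(effective_qem(tr, room, lex)$total, 0)
})

test_that("emitted questions classify back to their generating pair", {
  batch <- run_batch(20, policy = policy_config("random"), master_seed = 17)
  for (tr in batch$transcripts) {
    for (t in seq_len(nrow(tr$turns))) {
      cq <- classify_question(tr$turns$question_text[t], lex)
      expect_identical(c(cq$property, cq$value),
                       c(tr$turns$property[t], tr$turns$value[t]))
    }
  }
})

test_that("the spy survives every simulated game", {
  batch <- run_batch(60, policy = noisy_human_presets()$calibrated,
                     master_seed = 23)
  for (tr in batch$transcripts) {
    room <- batch$rooms[[tr$room_checksum]]
    expect_true(all(tr$turns$potential_eliminations <=
                      tr$turns$remaining_before - 1L))
    cls <- tr$turns[!is.na(tr$turns$property), ]
    if (nrow(cls)) {
      final <- consistent_suspects(room, data.frame(
        property = cls$property, value = cls$value, answer = cls$answer))
      expect_true(room$spy_id %in% final)
    }
  }
})

test_that("batches derive reproducible per-game seeds from the master seed", {
  b1 <- run_batch(5, policy = policy_config("random"), master_seed = 3)
  b2 <- run_batch(5, policy = policy_config("random"), master_seed = 3)
  expect_identical(b1$transcripts, b2$transcripts)
  expect_length(b1$transcripts, 5)
  seeds <- vapply(b1$transcripts, function(t) t$seed, integer(1))
  expect_identical(anyDuplicated(seeds), 0L)

  single <- run_batch(1, policy = policy_config("random"), master_seed = 3)
  room <- single$rooms[[1]]
  again <- run_game(room, policy_config("random"), game_config(),
                    seed = single$transcripts[[1]]$seed,
                    session_id = single$transcripts[[1]]$session_id)
  expect_identical(single$transcripts[[1]], again)
})

test_that("the calibrated noisy-human preset wins in the engagement band", {
  batch <- run_batch(300, policy = noisy_human_presets()$calibrated,
                     master_seed = 41)
  wins <- vapply(batch$transcripts, function(t) t$outcome == "WIN", logical(1))
  expect_gte(mean(wins), 0.60)
  expect_lte(mean(wins), 0.80)
})

test_that("noiseless constraint seeking sits between the entropy and greedy bounds", {
  batch <- run_batch(200, policy = policy_config("constraint_seeking"),
                     master_seed = 47)
  mean_q <- mean(vapply(batch$transcripts, function(t) nrow(t$turns), numeric(1)))

  # independent greedy oracle: repeatedly apply the best balanced split by
  # direct data.frame filtering, for every possible spy in sampled rooms
  greedy_len <- function(room, spy_id) {
    pairs <- spyquest:::schema_pairs(room$schema)
    remaining <- room$suspects
    spy <- room$suspects[room$suspects$suspect_id == spy_id, ]
    n_q <- 0L
    asked <- rep(FALSE, nrow(pairs))
    while (nrow(remaining) > 1L) {
      counts <- vapply(seq_len(nrow(pairs)), function(k) {
        sum(remaining[[pairs$property[k]]] == pairs$value[k])
      }, numeric(1))
      ok <- !asked & counts > 0 & counts < nrow(remaining)
      k <- which(ok)[which.min(abs(counts[ok] / nrow(remaining) - 0.5))]
      asked[k] <- TRUE
      n_q <- n_q + 1L
      holds <- remaining[[pairs$property[k]]] == pairs$value[k]
      spy_holds <- spy[[pairs$property[k]]] == pairs$value[k]
      remaining <- remaining[holds == spy_holds, , drop = FALSE]
    }
    n_q
  }
  worst <- 0L
  for (seed in c(61, 62, 63)) {
    room <- generate_room(default_schema(), 50, seed = seed,
                          screen_positions = FALSE)
    for (sid in room$suspects$suspect_id) {
      worst <- max(worst, greedy_len(room, sid))
    }
  }
  expect_gte(mean_q, log2(50) * 0.95)
  expect_lte(mean_q, worst)
})
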