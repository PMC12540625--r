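# Fixtures are built in code, never stored.

default_grid <- function() {
  s <- default_schema()
  grid <- expand.grid(lapply(s$properties, function(p) p$domain),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- vapply(s$properties, function(p) p$name, character(1))
  grid
}

# 50-suspect room engineered so the three-question chain
#   "Is the spy a man?"            NEGATIVE  eliminates 25 of 50
#   "Does the spy have long hair?" NEGATIVE  eliminates 12 of 25
#   "Is the spy wearing glasses?"  NEGATIVE  eliminates  6 of 13
# leaves 7 suspects including the spy (#44). No remaining female wears
# white clothes, so a white-clothes question afterwards eliminates nobody.
fixture_room_3q <- function() {
  grid <- default_grid()
  take <- function(cond, n) { d <- grid[cond, , drop = FALSE]; d[seq_len(n), ] }
  A <- take(grid$gender == "male", 25)
  B1 <- take(grid$gender == "female" & grid$hair_length == "long" &
               grid$clothing_color != "white", 12)
  B2 <- take(grid$gender == "female" & grid$hair_length != "long" &
               grid$face_accessory == "glasses" & grid$clothing_color != "white", 6)
  B3 <- take(grid$gender == "female" & grid$hair_length != "long" &
               grid$face_accessory != "glasses" & grid$clothing_color != "white", 7)
  suspects <- rbind(A, B1, B2, B3)
  rownames(suspects) <- NULL
  make_room(default_schema(), suspects, spy_id = 44L)
}

fixture_transcript_3q <- function(room = fixture_room_3q()) {
  spy_transcript(
    session_id = "fixture3q", room = room,
    turns = data.frame(
      i = 1:3,
      question_text = c("Is the spy a man?", "Does the spy have long hair?",
                        "Is the spy wearing glasses?"),
      property = c("gender", "hair_length", "face_accessory"),
      value = c("male", "long", "glasses"),
      answer = c("NEGATIVE", "NEGATIVE", "NEGATIVE"),
      player_eliminations = c(25L, 12L, 6L),
      remaining_before = c(50L, 25L, 13L),
      potential_eliminations = c(25L, 12L, 6L),
      elapsed_s = c(10, 8, 6),
      stringsAsFactors = FALSE),
    guesses = data.frame(suspect_id = 44L, correct = TRUE, elapsed_s = 4),
    outcome = "WIN")
}

# 50-suspect room where the spy (#50) is the only scar-bearer.
fixture_room_unique_scar <- function() {
  grid <- default_grid()
  others <- grid[grid$face_accessory != "scar", , drop = FALSE][1:49, ]
  spy <- grid[grid$face_accessory == "scar", , drop = FALSE][1, ]
  suspects <- rbind(others, spy)
  rownames(suspects) <- NULL
  make_room(default_schema(), suspects, spy_id = 50L)
}

empty_guesses_df <- function() spyquest:::empty_guesses()

# Independent oracle: per-suspect predicate loop, no set arithmetic shared
# with consistent_suspects().
brute_force_consistent <- function(room, constraints) {
  out <- integer(0)
  for (r in seq_len(nrow(room$suspects))) {
    ok <- TRUE
    if (!is.null(constraints) && nrow(constraints)) {
      for (k in seq_len(nrow(constraints))) {
        holds <- room$suspects[[constraints$property[k]]][r] == constraints$value[k]
        want <- constraints$answer[k] == "AFFIRMATIVE"
        if (holds != want) { ok <- FALSE; break }
      }
    }
    if (ok) out <- c(out, room$suspects$suspect_id[r])
  }
  out
}

# Independent replay of a transcript's potential-elimination counts:
# accumulate constraints and recount the consistent set from scratch with
# the brute-force predicate loop at every step.
brute_force_replay <- function(transcript, room, lexicon) {
  chain <- NULL
  before <- counts <- integer(0)
  for (t in seq_len(nrow(transcript$turns))) {
    cq <- classify_question(transcript$turns$question_text[t], lexicon)
    ans <- transcript$turns$answer[t]
    if (!is_classified(cq) || !ans %in% c("AFFIRMATIVE", "NEGATIVE")) next
    n_before <- length(brute_force_consistent(room, chain))
    chain <- rbind(chain, data.frame(property = cq$property, value = cq$value,
                                     answer = ans, stringsAsFactors = FALSE))
    n_after <- length(brute_force_consistent(room, chain))
    before <- c(before, n_before)
    counts <- c(counts, n_before - n_after)
  }
  list(remaining_before = before, potential_eliminations = counts)
}

random_truthful_chain <- function(room, n_constraints) {
  pairs <- spyquest:::schema_pairs(room$schema)
  spy <- room$suspects[room$suspects$suspect_id == room$spy_id, ]
  ks <- sample.int(nrow(pairs), n_constraints)
  data.frame(
    property = pairs$property[ks], value = pairs$value[ks],
    answer = ifelse(
      mapply(function(p, v) spy[[p]] == v, pairs$property[ks], pairs$value[ks]),
      "AFFIRMATIVE", "NEGATIVE"),
    stringsAsFactors = FALSE)
}
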