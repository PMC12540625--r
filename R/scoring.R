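#' Construct a game transcript
#'
#' The unit every scorer consumes: the ordered question/answer turns, the
#' guesses, and the outcome of one game session.
#'
#' @param session_id Identifier string.
#' @param room The `spy_room` the game was played on (only its checksum is
#'   stored), or an 8-hex-digit checksum string.
#' @param turns data.frame with columns `i` (1-based question index),
#'   `question_text`, `property`, `value` (`NA` when unclassified),
#'   `answer`, `player_eliminations`, `remaining_before`,
#'   `potential_eliminations`, `elapsed_s`.
#' @param guesses data.frame with columns `suspect_id`, `correct`,
#'   `elapsed_s` (possibly zero rows).
#' @param outcome `"WIN"` or `"LOSS"`.
#' @param policy,seed Optional provenance metadata.
#' @param extra Named list of additional fields, preserved through I/O.
#' @return A `spy_transcript`.
#' @export
spy_transcript <- function(session_id, room, turns, guesses = empty_guesses(),
                           outcome, policy = NA_character_, seed = NA_integer_,
                           extra = list()) {
  checksum <- if (inherits(room, "spy_room")) room_checksum(room) else
    as.character(room)
  if (!outcome %in% c("WIN", "LOSS")) {
    spy_abort("outcome must be WIN or LOSS", "spyquest_malformed_record")
  }
  if (nrow(guesses)) {
    if (sum(guesses$correct) > 1L ||
        xor(outcome == "WIN", guesses$correct[nrow(guesses)])) {
      spy_abort("WIN iff the last guess is the single correct one",
                "spyquest_malformed_record")
    }
  } else if (outcome == "WIN") {
    spy_abort("a WIN needs a correct guess", "spyquest_malformed_record")
  }
  structure(list(session_id = session_id, room_checksum = checksum,
                 turns = turns, guesses = guesses, outcome = outcome,
                 policy = policy, seed = seed, extra = extra),
            class = "spy_transcript")
}

empty_turns <- function() {
  data.frame(i = integer(0), question_text = character(0),
             property = character(0), value = character(0),
             answer = character(0), player_eliminations = integer(0),
             remaining_before = integer(0), potential_eliminations = integer(0),
             elapsed_s = numeric(0), stringsAsFactors = FALSE)
}

empty_guesses <- function() {
  data.frame(suspect_id = integer(0), correct = logical(0),
             elapsed_s = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.spy_transcript <- function(x, ...) {
  cat(sprintf("<spy_transcript> %s: %d questions, %d guesses, %s\n",
              x$session_id, nrow(x$turns), nrow(x$guesses), x$outcome))
  invisible(x)
}

new_score_breakdown <- function(per_question, excluded_indices, clamped) {
  total <- if (nrow(per_question)) sum(per_question$weight * per_question$score) else 0
  structure(list(per_question = per_question, total = total,
                 excluded_indices = as.integer(excluded_indices),
                 clamped = clamped),
            class = "spy_scores")
}

#' @export
print.spy_scores <- function(x, ...) {
  cat(sprintf("<spy_scores> total %.4f over %d questions (%d excluded)%s\n",
              x$total, nrow(x$per_question), length(x$excluded_indices),
              if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Question Effectiveness Measure (QEM)
#'
#' Scores each question by the fraction of the full room the player
#' visually eliminated after it, `eliminated / total_suspects`, then sums
#' with harmonic weights `1/i` over question positions, so early questions
#' dominate. The denominator is fixed at the room size for every question;
#' every question is included — no classification is involved.
#'
#' @param transcript A `spy_transcript`.
#' @param total_suspects Fixed denominator (default 50, the standard room).
#' @return A `spy_scores` breakdown: `per_question` (index, weight, score),
#'   `total`, `excluded_indices` (always empty here), `clamped` (set when a
#'   log claims more eliminations than the room holds; scores are capped
#'   at 1).
#' @examples
#' # three questions eliminating 25, 12 and 6 of 50 suspects
#' tr <- spy_transcript("demo", "00000000",
#'   turns = data.frame(i = 1:3, question_text = "", property = NA, value = NA,
#'                      answer = "NEGATIVE", player_eliminations = c(25, 12, 6),
#'                      remaining_before = c(50, 25, 13),
#'                      potential_eliminations = c(25, 12, 6), elapsed_s = NA),
#'   guesses = data.frame(suspect_id = 1, correct = TRUE, elapsed_s = NA),
#'   outcome = "WIN")
#' qem(tr, 50)$total  # 0.66
#' @export
qem <- function(transcript, total_suspects = 50L) {
  stopifnot(inherits(transcript, "spy_transcript"), total_suspects >= 1)
  turns <- transcript$turns
  if (!nrow(turns)) {
    return(new_score_breakdown(
      data.frame(i = integer(0), weight = numeric(0), score = numeric(0)),
      integer(0), FALSE))
  }
  pe <- turns$player_eliminations
  if (anyNA(pe) || any(pe < 0)) {
    spy_abort("negative or missing player elimination counts",
              "spyquest_negative_elimination")
  }
  clamped <- any(pe > total_suspects) || sum(pe) > total_suspects - 1L
  score <- pmin(pe / total_suspects, 1)
  idx <- seq_along(score)
  new_score_breakdown(
    data.frame(i = idx, weight = 1 / idx, score = score),
    integer(0), clamped)
}

#' Effective QEM: ground-truth replay scoring
#'
#' Replays a transcript against the room's ground truth, ignoring the
#' player's actual crossing-out: each question is re-classified from its
#' text; unclassifiable questions (and turns answered with a refusal or
#' deflection, which carry no attribute information) are excluded from the
#' sequence; for each included question the potential eliminations are the
#' drop in the consistent-suspect count after applying its
#' `(property, value, answer)` constraint, scored against the suspects
#' remaining *before* it. Harmonic weights `1/i` run over included
#' questions (set `keep_original_index = TRUE` to weight by original
#' transcript position instead).
#'
#' The consistent count always includes the spy, so the denominator never
#' reaches zero: questions asked after the field collapses to one suspect
#' score 0 rather than dividing by zero. A replayed answer that would empty
#' the consistent set (possible only for logs whose answers were not
#' truthful) retains a single suspect and raises the `clamped` flag.
#'
#' @param transcript A `spy_transcript`.
#' @param room The `spy_room` it was played on; its checksum must match the
#'   transcript's `room_checksum`.
#' @param lexicon A `spy_lexicon` for re-classification.
#' @param keep_original_index Weight by original question position rather
#'   than position among included questions.
#' @param reject_negation Passed to [classify_question()].
#' @return A `spy_scores` breakdown; `per_question` also carries
#'   `orig_index`, `remaining_before` and `potential_eliminations` for each
#'   included question.
#' @export
effective_qem <- function(transcript, room, lexicon,
                          keep_original_index = FALSE,
                          reject_negation = FALSE) {
  stopifnot(inherits(transcript, "spy_transcript"), inherits(room, "spy_room"),
            inherits(lexicon, "spy_lexicon"))
  if (!is.na(transcript$room_checksum) &&
      !identical(transcript$room_checksum, room_checksum(room))) {
    spy_abort("transcript room checksum does not match the supplied room",
              "spyquest_room_mismatch")
  }
  turns <- transcript$turns
  n_room <- nrow(room$suspects)
  remaining <- rep(TRUE, n_room)
  spy_row <- which(room$suspects$suspect_id == room$spy_id)

  rows <- list()
  excluded <- integer(0)
  clamped <- FALSE
  j <- 0L
  for (t in seq_len(nrow(turns))) {
    cq <- classify_question(turns$question_text[t], lexicon,
                            reject_negation = reject_negation)
    ans <- turns$answer[t]
    if (!is_classified(cq) || !ans %in% c("AFFIRMATIVE", "NEGATIVE")) {
      excluded <- c(excluded, turns$i[t])
      next
    }
    before <- sum(remaining)
    holds <- room$suspects[[cq$property]] == cq$value
    after <- remaining & (if (ans == "AFFIRMATIVE") holds else !holds)
    if (!any(after)) {
      clamped <- TRUE
      keep_row <- if (remaining[spy_row]) spy_row else which(remaining)[1]
      after <- rep(FALSE, n_room)
      after[keep_row] <- TRUE
    }
    potential <- before - sum(after)
    remaining <- after
    j <- j + 1L
    wi <- if (keep_original_index) turns$i[t] else j
    rows[[j]] <- data.frame(i = wi, orig_index = turns$i[t], weight = 1 / wi,
                            score = potential / before,
                            remaining_before = before,
                            potential_eliminations = potential)
  }
  if (sum(turns$player_eliminations, na.rm = TRUE) > n_room - 1L) {
    clamped <- TRUE
  }
  per_question <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(0), orig_index = integer(0), weight = numeric(0),
               score = numeric(0), remaining_before = integer(0),
               potential_eliminations = integer(0))
  new_score_breakdown(per_question, excluded, clamped)
}

#' Effective QEM of the first classifiable question
#'
#' The unweighted per-question score of the first included question in the
#' ground-truth replay (the harmonic weight is 1 there, so weighted and
#' bare values coincide).
#'
#' @inheritParams effective_qem
#' @return A number in `[0, 1]`.
#' @export
first_question_effective_qem <- function(transcript, room, lexicon, ...) {
  br <- effective_qem(transcript, room, lexicon, ...)
  if (!nrow(br$per_question)) {
    spy_abort("transcript has no classifiable question",
              "spyquest_no_classifiable_question")
  }
  br$per_question$score[1]
}
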