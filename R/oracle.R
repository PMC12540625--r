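#' Answer labels and their canonical surface strings
#'
#' The chatbot contract allows exactly three responses to a question about
#' the spy — affirmative, negative, or a refusal when a yes/no answer is not
#' applicable — plus a deflection when the player addresses the agent
#' itself.
#'
#' @format Named character vector mapping label to surface string.
#' @export
answer_strings <- c(
  AFFIRMATIVE = "Affirmative agent",
  NEGATIVE = "Negative agent",
  CANNOT_ANSWER = "I cannot give the answer to that question",
  SELF_DEFLECTION = "I am not the spy, so that's not relevant. What do you want to know about the spy?"
)

#' Detect questions addressed to the agent rather than the spy
#'
#' Second-person cues ("you", "yourself") address the agent; "your" does too
#' unless it modifies the spy/target ("Is your spy a woman?" asks about the
#' spy).
#'
#' @param text Question text.
#' @return `TRUE` when the question is about the agent itself.
#' @examples
#' detect_self_reference("Are you wearing glasses?")
#' detect_self_reference("Is your spy a woman?")
#' @export
detect_self_reference <- function(text) {
  tokens <- tokenize_question(text)
  if (any(tokens %in% c("you", "yourself", "yours"))) return(TRUE)
  idx <- which(tokens == "your")
  for (i in idx) {
    nxt <- if (i < length(tokens)) tokens[i + 1L] else ""
    if (!nxt %in% c("spy", "target", "suspect", "suspects")) return(TRUE)
  }
  FALSE
}

#' Answer a classified question about the spy
#'
#' Deterministic stand-in for the game's chatbot: self-referential questions
#' get the deflection sentence, unclassifiable questions the refusal, and
#' labelled questions are answered truthfully from the spy's ground-truth
#' attributes. With `error_rate > 0` the truthful AFFIRMATIVE/NEGATIVE
#' answer is flipped with that probability (drawn from the current RNG
#' stream), emulating an unreliable chatbot.
#'
#' @param cq A `spy_question` from [classify_question()].
#' @param room A `spy_room`.
#' @param error_rate Probability of flipping a truthful yes/no answer
#'   (default 0: the oracle is never wrong).
#' @return One of `"AFFIRMATIVE"`, `"NEGATIVE"`, `"CANNOT_ANSWER"`,
#'   `"SELF_DEFLECTION"`. Surface strings live in [answer_strings].
#' @export
answer_question <- function(cq, room, error_rate = 0) {
  stopifnot(inherits(cq, "spy_question"), inherits(room, "spy_room"))
  if (isTRUE(cq$self_referential)) return("SELF_DEFLECTION")
  if (!is_classified(cq)) return("CANNOT_ANSWER")
  spy <- spy_attributes(room)
  if (!cq$property %in% names(spy)) return("CANNOT_ANSWER")
  ans <- if (identical(spy[[cq$property]], cq$value)) "AFFIRMATIVE" else "NEGATIVE"
  if (error_rate > 0 && stats::runif(1) < error_rate) {
    ans <- if (ans == "AFFIRMATIVE") "NEGATIVE" else "AFFIRMATIVE"
  }
  ans
}
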