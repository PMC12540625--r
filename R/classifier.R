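# Tokenization: lowercase; apostrophes removed (so "isn't" -> "isnt");
# hyphens become spaces (so "t-shirt" -> "t shirt"); remaining punctuation
# stripped; split on whitespace. Matching is whole-word on these tokens —
# "scarf" never matches "scar".
tokenize_question <- function(text) {
  x <- tolower(text)
  x <- gsub("[’']", "", x)
  x <- gsub("-", " ", x, fixed = TRUE)
  x <- gsub("[^a-z0-9 ]", " ", x)
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

# All keyword matches as token spans (keywords may be multi-word phrases).
# A match wholly contained in a longer match is suppressed, so "t shirt"
# beats its embedded "shirt".
match_spans <- function(tokens, keys) {
  if (!length(tokens) || !length(keys)) return(NULL)
  lens <- lengths(strsplit(keys, " ", fixed = TRUE))
  out <- list()
  for (j in seq_along(keys)) {
    L <- lens[j]
    if (L > length(tokens)) next
    for (start in seq_len(length(tokens) - L + 1L)) {
      phrase <- paste(tokens[start:(start + L - 1L)], collapse = " ")
      if (phrase == keys[j]) {
        out[[length(out) + 1L]] <- list(key = keys[j], start = start, len = L)
      }
    }
  }
  if (!length(out)) return(NULL)
  keep <- vapply(out, function(m) {
    !any(vapply(out, function(o) {
      o$len > m$len && o$start <= m$start &&
        (o$start + o$len) >= (m$start + m$len)
    }, logical(1)))
  }, logical(1))
  out[keep]
}

#' Classify a free-text yes/no question by keyword pattern matching
#'
#' Mirrors the pattern-matching scheme used to label game questions: if the
#' question contains a colour word, property-colour pairs are checked first
#' (a colour plus a cue word like "hair" or "wearing" labels the matching
#' colour property); otherwise, if exactly one value keyword matches, its
#' `(property, value)` is returned; anything else — no keyword, conflicting
#' keywords, a colour with no (or an ambiguous) cue — is `UNCLASSIFIED`.
#' `UNCLASSIFIED` is a value, not an error.
#'
#' @param text The question (non-empty string).
#' @param lexicon A `spy_lexicon` from [build_default_lexicon()].
#' @param reject_negation If `TRUE`, questions containing a negator token
#'   ("not", "isnt", "without", ...) are routed to `UNCLASSIFIED` instead of
#'   being classified by their keywords as if phrased positively.
#' @return A `spy_question`: `raw_text`, `property`/`value` (`NA` when
#'   unclassified), `matched_keywords`, `self_referential`.
#' @examples
#' lex <- build_default_lexicon(default_schema())
#' classify_question("Is it a boy?", lex)
#' classify_question("Does the target have grey hair?", lex)
#' @export
classify_question <- function(text, lexicon, reject_negation = FALSE) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  tokens <- tokenize_question(text)
  self_ref <- detect_self_reference(text)

  unclassified <- function(matched = character(0)) {
    new_spy_question(text, NA_character_, NA_character_, matched, self_ref)
  }

  if (reject_negation) {
    negators <- c("not", "isnt", "doesnt", "dont", "arent", "wasnt",
                  "werent", "didnt", "without", "never")
    if (any(tokens %in% negators)) return(unclassified(intersect(tokens, negators)))
  }

  color_hits <- match_spans(tokens, names(lexicon$color_keywords))
  if (!is.null(color_hits)) {
    color_words <- unique(vapply(color_hits, `[[`, character(1), "key"))
    colors <- unique(unname(lexicon$color_keywords[color_words]))
    cue_hits <- match_spans(tokens, names(lexicon$color_cues))
    cue_words <- if (is.null(cue_hits)) character(0) else
      unique(vapply(cue_hits, `[[`, character(1), "key"))
    cue_props <- unique(unname(lexicon$color_cues[cue_words]))
    matched <- c(cue_words, color_words)
    if (length(colors) == 1L && length(cue_props) == 1L) {
      prop <- get_property(lexicon$schema, cue_props)
      if (colors %in% prop$domain) {
        return(new_spy_question(text, cue_props, colors, matched, self_ref))
      }
    }
    return(unclassified(matched))
  }

  hits <- match_spans(tokens, names(lexicon$keyword_to_property_value))
  if (is.null(hits)) return(unclassified())
  words <- unique(vapply(hits, `[[`, character(1), "key"))
  targets <- unique(vapply(words, function(w) {
    paste(lexicon$keyword_to_property_value[[w]], collapse = "\r")
  }, character(1)))
  if (length(targets) != 1L) return(unclassified(words))
  pv <- strsplit(targets, "\r", fixed = TRUE)[[1]]
  new_spy_question(text, pv[1], pv[2], words, self_ref)
}

new_spy_question <- function(raw_text, property, value, matched_keywords,
                             self_referential) {
  structure(list(raw_text = raw_text, property = property, value = value,
                 matched_keywords = matched_keywords,
                 self_referential = self_referential),
            class = "spy_question")
}

#' Is a classified question labelled?
#'
#' @param cq A `spy_question`.
#' @return `TRUE` when the question carries a `(property, value)` label.
#' @export
is_classified <- function(cq) {
  !is.na(cq$property)
}

#' @export
print.spy_question <- function(x, ...) {
  lab <- if (is_classified(x)) sprintf("(%s, %s)", x$property, x$value)
         else "UNCLASSIFIED"
  cat(sprintf("<spy_question> %s -> %s%s\n", dQuote(x$raw_text), lab,
              if (x$self_referential) " [self-referential]" else ""))
  invisible(x)
}
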