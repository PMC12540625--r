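TRANSCRIPT_FORMAT <- "spyquest-transcripts"
TRANSCRIPT_VERSION <- 1L

transcript_to_list <- function(tr) {
  out <- list(session_id = tr$session_id, room_checksum = tr$room_checksum,
              outcome = tr$outcome, policy = tr$policy, seed = tr$seed,
              turns = df_to_rows(tr$turns), guesses = df_to_rows(tr$guesses))
  c(out, tr$extra)
}

df_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

rows_to_df <- function(rows, template) {
  if (!length(rows)) return(template)
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  # JSON numbers lose the integer/double distinction; restore the
  # template's column types so round-trips are lossless.
  for (col in intersect(names(df), names(template))) {
    df[[col]] <- switch(class(template[[col]])[1],
                        integer = as.integer(df[[col]]),
                        numeric = as.numeric(df[[col]]),
                        logical = as.logical(df[[col]]),
                        character = as.character(df[[col]]),
                        df[[col]])
  }
  df
}

required_turn_fields <- c("i", "question_text", "answer", "player_eliminations")

transcript_from_list <- function(rec, line = NA_integer_) {
  malformed <- function(what) {
    spy_abort(sprintf("malformed transcript record at line %s: %s",
                      format(line), what), "spyquest_malformed_record")
  }
  for (f in c("session_id", "outcome", "turns", "guesses")) {
    if (is.null(rec[[f]])) malformed(sprintf("missing field '%s'", f))
  }
  for (j in seq_along(rec$turns)) {
    miss <- setdiff(required_turn_fields, names(rec$turns[[j]]))
    if (length(miss)) {
      malformed(sprintf("turn %d missing field '%s'", j, miss[1]))
    }
  }
  known <- c("session_id", "room_checksum", "outcome", "policy", "seed",
             "turns", "guesses")
  extra <- rec[setdiff(names(rec), known)]
  if (!length(extra)) extra <- list()
  turns <- rows_to_df(rec$turns, empty_turns())
  for (col in setdiff(names(empty_turns()), names(turns))) turns[[col]] <- NA
  spy_transcript(
    session_id = rec$session_id,
    room = if (is.null(rec$room_checksum)) NA_character_ else rec$room_checksum,
    turns = turns,
    guesses = rows_to_df(rec$guesses, empty_guesses()),
    outcome = rec$outcome,
    policy = if (is.null(rec$policy)) NA_character_ else rec$policy,
    seed = if (is.null(rec$seed)) NA_integer_ else as.integer(rec$seed),
    extra = extra)
}

#' Write / read game transcripts as JSON Lines
#'
#' One game per line, preceded by a schema-versioned header line.
#' Round-trips are lossless; unknown fields in externally produced records
#' are preserved under `$extra` and written back out.
#'
#' @param x A `spy_batch` or list of `spy_transcript` objects.
#' @param path Output file.
#' @return `read_transcripts()` returns a list of `spy_transcript`.
#'   Malformed lines raise a `spyquest_malformed_record` error carrying the
#'   line number; a foreign or future schema version raises
#'   `spyquest_schema_version_mismatch`.
#' @export
write_transcripts <- function(x, path) {
  transcripts <- if (inherits(x, "spy_batch")) x$transcripts else x
  header <- jsonlite::toJSON(list(format = TRANSCRIPT_FORMAT,
                                  schema_version = TRANSCRIPT_VERSION),
                             auto_unbox = TRUE)
  lines <- vapply(transcripts, function(tr) {
    as.character(jsonlite::toJSON(transcript_to_list(tr), auto_unbox = TRUE,
                                  digits = NA, na = "null"))
  }, character(1))
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(list())
  header <- tryCatch(jsonlite::fromJSON(lines[1], simplifyVector = FALSE),
                     error = function(e) NULL)
  if (is.null(header) || !identical(header$format, TRANSCRIPT_FORMAT)) {
    spy_abort("missing or foreign transcript header line",
              "spyquest_schema_version_mismatch")
  }
  if (!identical(as.integer(header$schema_version), TRANSCRIPT_VERSION)) {
    spy_abort(sprintf("transcript schema version %s, expected %d",
                      format(header$schema_version), TRANSCRIPT_VERSION),
              "spyquest_schema_version_mismatch")
  }
  body <- lines[-1]
  body_idx <- which(nzchar(trimws(body)))
  lapply(body_idx, function(i) {
    rec <- tryCatch(jsonlite::fromJSON(body[i], simplifyVector = FALSE),
                    error = function(e) {
                      spy_abort(sprintf("unparseable JSON at line %d", i + 1L),
                                "spyquest_malformed_record")
                    })
    transcript_from_list(rec, line = i + 1L)
  })
}

session_columns <- c("session_id", "won", "n_questions", "n_guesses",
                     "n_player_eliminated", "qem", "effective_qem",
                     "first_q_eqem", "mean_question_time_s",
                     "n_excluded_questions", "clamped", "excluded_reason")

#' Summarize transcripts into a session table
#'
#' One row per game with both effectiveness scores computed, the input the
#' outcome-analysis stage consumes. Sessions that cannot be scored (no
#' questions, no classifiable questions, or a scoring error) are flagged in
#' `excluded_reason`, never dropped.
#'
#' @param transcripts List of `spy_transcript` (or a `spy_batch`).
#' @param rooms Named list of rooms keyed by checksum (as in a
#'   `spy_batch`), or a single `spy_room` shared by all transcripts.
#' @param lexicon A `spy_lexicon`.
#' @param keep_original_index Forwarded to [effective_qem()].
#' @return data.frame with fixed column order: `session_id`, `won`,
#'   `n_questions`, `n_guesses`, `n_player_eliminated`, `qem`,
#'   `effective_qem`, `first_q_eqem`, `mean_question_time_s`,
#'   `n_excluded_questions`, `clamped`, `excluded_reason`. Use
#'   [session_aggregates()] for the aggregate block.
#' @export
summarize_sessions <- function(transcripts, rooms, lexicon,
                               keep_original_index = FALSE) {
  if (inherits(transcripts, "spy_batch")) {
    if (missing(rooms)) rooms <- transcripts$rooms
    transcripts <- transcripts$transcripts
  }
  if (inherits(rooms, "spy_room")) {
    rooms <- stats::setNames(list(rooms), room_checksum(rooms))
  }
  rows <- lapply(transcripts, function(tr) {
    room <- rooms[[tr$room_checksum]]
    if (is.null(room)) {
      spy_abort(sprintf("no room with checksum %s for session %s",
                        tr$room_checksum, tr$session_id),
                "spyquest_room_mismatch")
    }
    n_q <- nrow(tr$turns)
    reason <- NA_character_
    q <- eq <- fq <- NA_real_
    nexcl <- NA_integer_
    clamped <- NA
    if (n_q == 0L) {
      reason <- "no_questions"
      q <- eq <- 0
      nexcl <- 0L
      clamped <- FALSE
    } else {
      res <- tryCatch({
        qb <- qem(tr, total_suspects = nrow(room$suspects))
        eb <- effective_qem(tr, room, lexicon,
                            keep_original_index = keep_original_index)
        list(q = qb$total, eq = eb$total,
             fq = if (nrow(eb$per_question)) eb$per_question$score[1] else NA_real_,
             nexcl = length(eb$excluded_indices),
             clamped = qb$clamped || eb$clamped,
             reason = if (!nrow(eb$per_question)) "no_classifiable_questions"
                      else NA_character_)
      }, spyquest_error = function(e) list(q = NA_real_, eq = NA_real_,
                                           fq = NA_real_, nexcl = NA_integer_,
                                           clamped = NA,
                                           reason = conditionMessage(e)))
      q <- res$q; eq <- res$eq; fq <- res$fq
      nexcl <- res$nexcl; clamped <- res$clamped; reason <- res$reason
    }
    data.frame(
      session_id = tr$session_id,
      won = tr$outcome == "WIN",
      n_questions = n_q,
      n_guesses = nrow(tr$guesses),
      n_player_eliminated = if (n_q) sum(tr$turns$player_eliminations) else 0L,
      qem = q, effective_qem = eq, first_q_eqem = fq,
      mean_question_time_s = if (n_q) mean(tr$turns$elapsed_s) else NA_real_,
      n_excluded_questions = nexcl,
      clamped = clamped,
      excluded_reason = reason,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(rep(list(logical(0)), length(session_columns))),
                    session_columns)
  out[session_columns]
}

#' Aggregate block over a session table
#'
#' Computed from the table's columns only, so re-reading a written CSV
#' reproduces the aggregates exactly.
#'
#' @param sessions A session table from [summarize_sessions()] (possibly
#'   re-read from CSV).
#' @param room_size Room size used for the elimination histogram bins.
#' @return List: `n_sessions`, `win_rate`, `mean_questions`,
#'   `sd_questions`, `mean_guesses_winners`, `sd_guesses_winners`,
#'   `elimination_hist` (named counts). All `NA` for an empty table.
#' @export
session_aggregates <- function(sessions, room_size = 50L) {
  if (!nrow(sessions)) {
    return(list(n_sessions = 0L, win_rate = NA_real_,
                mean_questions = NA_real_, sd_questions = NA_real_,
                mean_guesses_winners = NA_real_, sd_guesses_winners = NA_real_,
                elimination_hist = NULL))
  }
  winners <- sessions[sessions$won, , drop = FALSE]
  breaks <- unique(c(seq(0L, room_size, by = 10L), room_size))
  hist <- table(cut(sessions$n_player_eliminated, breaks = breaks,
                    include.lowest = TRUE, right = FALSE))
  list(
    n_sessions = nrow(sessions),
    win_rate = mean(sessions$won),
    mean_questions = mean(sessions$n_questions),
    sd_questions = stats::sd(sessions$n_questions),
    mean_guesses_winners = if (nrow(winners)) mean(winners$n_guesses) else NA_real_,
    sd_guesses_winners = if (nrow(winners) > 1L) stats::sd(winners$n_guesses) else NA_real_,
    elimination_hist = c(hist)
  )
}

#' Write / read session tables as CSV
#'
#' Column order is fixed ([summarize_sessions()] documents it); numeric
#' columns are written with 17 significant digits so doubles round-trip
#' bit-for-bit.
#'
#' @param sessions Session table.
#' @param path File path.
#' @return `read_session_table()` returns the table with original column
#'   types.
#' @export
write_session_table <- function(sessions, path) {
  out <- sessions
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_session_table
#' @export
read_session_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(session_id = "character"))
  if ("excluded_reason" %in% names(df)) {
    df$excluded_reason <- as.character(df$excluded_reason)
  }
  for (col in c("qem", "effective_qem", "first_q_eqem", "mean_question_time_s")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  df
}
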