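#' Generate a room of distinct suspects
#'
#' Samples `size` pairwise-distinct attribute vectors without replacement
#' from the schema's product space and marks one suspect, chosen uniformly,
#' as the spy. A single seed drives the whole draw; the suspect sample is
#' consumed first and the spy draw last, so identical `(schema, size, seed)`
#' always yields a bit-identical room.
#'
#' @param schema A `spy_schema`, e.g. [default_schema()].
#' @param size Number of suspects (default 50).
#' @param seed Integer seed.
#' @param screen_positions If `TRUE`, attach arbitrary-unit screen
#'   coordinates to each suspect (cosmetic metadata; never used by scoring).
#' @return A `spy_room`: list with `schema`, `suspects` (data.frame with
#'   `suspect_id` and one column per property), `spy_id`, `seed`.
#' @examples
#' room <- generate_room(default_schema(), 50, seed = 1)
#' room$spy_id
#' @export
generate_room <- function(schema, size = 50L, seed, screen_positions = TRUE) {
  stopifnot(inherits(schema, "spy_schema"))
  size <- as.integer(size)
  if (size < 2L) spy_abort("room size must be >= 2", "spyquest_bad_config")
  space <- schema_space_size(schema)
  if (space < size) {
    spy_abort(sprintf("schema supports only %d distinct suspects, %d requested",
                      space, size), "spyquest_schema_too_small")
  }
  set.seed(seed)
  # sample cell indices of the product space, then decode them mixed-radix
  # (first property varies fastest, as in expand.grid)
  domains <- lapply(schema$properties, function(p) p$domain)
  sizes <- lengths(domains)
  cells <- sample.int(space, size, replace = FALSE) - 1L
  suspects <- data.frame(suspect_id = seq_len(size))
  for (j in seq_along(domains)) {
    suspects[[property_names(schema)[j]]] <- domains[[j]][cells %% sizes[j] + 1L]
    cells <- cells %/% sizes[j]
  }
  if (screen_positions) {
    suspects$screen_x <- round(stats::runif(size, 0, 100), 2)
    suspects$screen_y <- round(stats::runif(size, 0, 100), 2)
  }
  spy_id <- sample.int(size, 1L)
  new_room(schema, suspects, spy_id, seed = as.integer(seed))
}

#' Assemble a room from explicit suspects
#'
#' Used for hand-built fixtures and for replaying externally supplied logs
#' where the suspect table is part of the record.
#'
#' @param schema A `spy_schema`.
#' @param suspects data.frame with one column per schema property (a
#'   `suspect_id` column is added when absent).
#' @param spy_id Suspect id of the spy.
#' @param seed Optional provenance seed (not re-used).
#' @return A `spy_room`.
#' @export
make_room <- function(schema, suspects, spy_id, seed = NA_integer_) {
  props <- property_names(schema)
  missing <- setdiff(props, names(suspects))
  if (length(missing)) {
    spy_abort(paste("suspects lack properties:", paste(missing, collapse = ", ")),
              "spyquest_bad_room")
  }
  if (!"suspect_id" %in% names(suspects)) {
    suspects <- cbind(data.frame(suspect_id = seq_len(nrow(suspects))), suspects)
  }
  new_room(schema, suspects, spy_id, seed)
}

new_room <- function(schema, suspects, spy_id, seed) {
  props <- property_names(schema)
  for (p in schema$properties) {
    bad <- !suspects[[p$name]] %in% p$domain
    if (any(bad)) {
      spy_abort(sprintf("out-of-domain value '%s' for property '%s'",
                        suspects[[p$name]][bad][1], p$name),
                "spyquest_unknown_value")
    }
  }
  key <- do.call(paste, c(suspects[props], sep = "\r"))
  if (anyDuplicated(key)) {
    spy_abort("suspects are not pairwise distinct", "spyquest_bad_room")
  }
  spy_id <- as.integer(spy_id)
  if (!spy_id %in% suspects$suspect_id) {
    spy_abort("spy_id is not a suspect_id", "spyquest_bad_room")
  }
  room <- structure(list(schema = schema, suspects = suspects, spy_id = spy_id,
                         seed = seed),
                    class = "spy_room")
  room$checksum <- compute_room_checksum(room)
  room
}

#' @export
print.spy_room <- function(x, ...) {
  cat(sprintf("<spy_room> %d suspects, spy #%d, seed %s, checksum %s\n",
              nrow(x$suspects), x$spy_id, format(x$seed), room_checksum(x)))
  invisible(x)
}

spy_attributes <- function(room) {
  s <- room$suspects
  as.list(s[s$suspect_id == room$spy_id, property_names(room$schema)])
}

#' Filter suspects consistent with answered constraints
#'
#' Each constraint is a `(property, value, answer)` triple where the answer
#' is `"AFFIRMATIVE"` (the spy's attribute equals the value) or `"NEGATIVE"`
#' (it differs). When constraints come from truthful answers about the spy,
#' the spy is always in the result, so the consistent set never empties.
#'
#' @param room A `spy_room`.
#' @param constraints data.frame with columns `property`, `value`, `answer`,
#'   or a list of such triples. Empty input returns every suspect.
#' @return Integer vector of consistent `suspect_id`s.
#' @examples
#' room <- generate_room(default_schema(), 50, seed = 1)
#' cs <- data.frame(property = "face_accessory", value = "glasses",
#'                  answer = "AFFIRMATIVE")
#' consistent_suspects(room, cs)
#' @export
consistent_suspects <- function(room, constraints = NULL) {
  keep <- rep(TRUE, nrow(room$suspects))
  constraints <- as_constraints(constraints)
  if (!is.null(constraints) && nrow(constraints)) {
    for (k in seq_len(nrow(constraints))) {
      prop <- constraints$property[k]
      val <- constraints$value[k]
      ans <- constraints$answer[k]
      p <- get_property(room$schema, prop)
      if (!val %in% p$domain) {
        spy_abort(sprintf("value '%s' not in domain of '%s'", val, prop),
                  "spyquest_unknown_value")
      }
      if (!ans %in% c("AFFIRMATIVE", "NEGATIVE")) {
        spy_abort("constraint answers must be AFFIRMATIVE or NEGATIVE",
                  "spyquest_bad_constraint")
      }
      holds <- room$suspects[[prop]] == val
      keep <- keep & if (ans == "AFFIRMATIVE") holds else !holds
    }
  }
  room$suspects$suspect_id[keep]
}

as_constraints <- function(x) {
  if (is.null(x) || (is.data.frame(x) && !nrow(x))) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.list(x) && !length(x)) return(NULL)
  do.call(rbind, lapply(x, function(tr) {
    data.frame(property = tr[[1]], value = tr[[2]], answer = tr[[3]],
               stringsAsFactors = FALSE)
  }))
}

# ---- checksums & serialization ------------------------------------------

# FNV-1a 32-bit over a canonical attribute string; identifies a room inside
# transcripts without embedding it. Pure R with 16-bit limb arithmetic so
# the 32-bit multiply never loses precision in doubles.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b %% 256))
    mid <- (hi * 403 + lo * 256) %% 65536
    h <- (mid * 65536 + lo * 403) %% 4294967296
  }
  lo <- h %% 65536
  hi <- (h - lo) / 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(lo))
}

#' Checksum identifying a room's ground truth
#'
#' Hash of the canonical attribute table plus spy id. Transcripts carry this
#' value so scorers can verify they are replaying against the right room.
#'
#' @param room A `spy_room`.
#' @return 8-hex-digit string.
#' @export
room_checksum <- function(room) {
  room$checksum %||% compute_room_checksum(room)
}

# Canonical form: per suspect, its id and the domain index of each
# attribute (so screen positions and other cosmetic metadata never enter
# the hash), then the spy id.
compute_room_checksum <- function(room) {
  codes <- vapply(room$schema$properties, function(p) {
    match(room$suspects[[p$name]], p$domain)
  }, integer(nrow(room$suspects)))
  canon <- paste(
    paste(room$suspects$suspect_id,
          apply(codes, 1, paste, collapse = ","), sep = ":", collapse = ";"),
    room$spy_id, sep = "|")
  fnv1a32(canon)
}

schema_to_list <- function(schema) {
  list(properties = lapply(schema$properties, function(p) {
    list(name = p$name, domain = as.list(p$domain), is_color = p$is_color,
         keywords = lapply(p$keywords, as.list))
  }))
}

schema_from_list <- function(x) {
  attribute_schema(lapply(x$properties, function(p) {
    property_spec(p$name, unlist(p$domain), isTRUE(p$is_color),
                  lapply(p$keywords, unlist))
  }))
}

room_to_list <- function(room) {
  list(schema = schema_to_list(room$schema),
       suspects = room$suspects,
       spy_id = room$spy_id,
       seed = room$seed,
       checksum = room_checksum(room))
}

room_from_list <- function(x) {
  schema <- schema_from_list(x$schema)
  if (is.data.frame(x$suspects)) {
    suspects <- x$suspects
  } else {
    suspects <- do.call(rbind, lapply(x$suspects, function(r) {
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)
    }))
  }
  seed <- if (is.null(x$seed) || is.na(x$seed)) NA_integer_ else as.integer(x$seed)
  room <- make_room(schema, suspects, x$spy_id, seed)
  if (!is.null(x$checksum) && !identical(x$checksum, room_checksum(room))) {
    spy_abort("room checksum mismatch on load", "spyquest_room_mismatch")
  }
  room
}

#' Write / read rooms as JSON
#'
#' Rooms round-trip losslessly; a stored checksum is verified on read.
#'
#' @param room A `spy_room` (or list of rooms for the plural forms).
#' @param path File path.
#' @return `read_room()` returns a `spy_room`; `read_rooms()` a list of
#'   rooms named by checksum.
#' @export
write_room <- function(room, path) {
  jsonlite::write_json(room_to_list(room), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_room
#' @export
read_room <- function(path) {
  room_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname write_room
#' @param rooms List of `spy_room` objects.
#' @export
write_rooms <- function(rooms, path) {
  jsonlite::write_json(lapply(rooms, room_to_list), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_room
#' @export
read_rooms <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rooms <- lapply(raw, room_from_list)
  names(rooms) <- vapply(rooms, room_checksum, character(1))
  rooms
}
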