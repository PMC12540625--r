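#' Build the default keyword lexicon for a schema
#'
#' Collects every value keyword declared in the schema into a flat
#' keyword -> (property, value) map, defines the colour vocabulary
#' (with spelling variants such as "gray" and "blonde"), and binds
#' property-colour pairs: a colour word co-occurring with a cue word for a
#' colour-bearing property ("hair", "wearing", "shirt", ...) labels that
#' property. Pairs take precedence over single keywords, which is what lets
#' "red dress" mean clothing colour while "dress" alone means clothing type.
#'
#' @param schema A `spy_schema`; colour-bearing properties must be flagged
#'   `is_color`.
#' @return A `spy_lexicon`: `keyword_to_property_value` (named list of
#'   `c(property, value)`), `color_keywords` (named character vector mapping
#'   surface colour words to canonical values), `color_cues` (named character
#'   vector mapping cue words to colour-property names).
#' @examples
#' lex <- build_default_lexicon(default_schema())
#' lex$keyword_to_property_value[["boy"]]
#' @export
build_default_lexicon <- function(schema) {
  k2pv <- list()
  for (p in schema$properties) {
    for (val in names(p$keywords)) {
      if (!val %in% p$domain) {
        spy_abort(sprintf("keyword target (%s, %s) not in domain", p$name, val),
                  "spyquest_bad_lexicon")
      }
      for (kw in p$keywords[[val]]) {
        kw <- tolower(kw)
        if (!is.null(k2pv[[kw]])) {
          spy_abort(sprintf("keyword '%s' maps to two targets", kw),
                    "spyquest_bad_lexicon")
        }
        k2pv[[kw]] <- c(property = p$name, value = val)
      }
    }
  }

  # surface colour word -> canonical colour value
  color_keywords <- c(
    black = "black", brown = "brown", grey = "grey", gray = "grey",
    red = "red", blond = "blond", blonde = "blond", blue = "blue",
    green = "green", white = "white"
  )

  # cue word -> which colour-bearing property the colour applies to
  color_cues <- c(
    hair = "hair_color", haired = "hair_color",
    wearing = "clothing_color", wears = "clothing_color",
    clothes = "clothing_color", clothing = "clothing_color",
    outfit = "clothing_color", dressed = "clothing_color",
    shirt = "clothing_color", "t shirt" = "clothing_color",
    tshirt = "clothing_color", tee = "clothing_color",
    dress = "clothing_color", jacket = "clothing_color",
    coat = "clothing_color"
  )
  present <- property_names(schema)
  color_cues <- color_cues[color_cues %in% present]

  structure(list(keyword_to_property_value = k2pv,
                 color_keywords = color_keywords,
                 color_cues = color_cues,
                 schema = schema),
            class = "spy_lexicon")
}

#' @export
print.spy_lexicon <- function(x, ...) {
  cat(sprintf("<spy_lexicon> %d value keywords, %d color words, %d color cues\n",
              length(x$keyword_to_property_value), length(x$color_keywords),
              length(x$color_cues)))
  invisible(x)
}

#' Write / read a lexicon as JSON
#'
#' @param lexicon A `spy_lexicon`.
#' @param path File path.
#' @return `read_lexicon()` returns a `spy_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  jsonlite::write_json(
    list(keyword_to_property_value = lapply(lexicon$keyword_to_property_value, as.list),
         color_keywords = as.list(lexicon$color_keywords),
         color_cues = as.list(lexicon$color_cues),
         schema = schema_to_list(lexicon$schema)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(
    keyword_to_property_value = lapply(raw$keyword_to_property_value, unlist),
    color_keywords = unlist(raw$color_keywords),
    color_cues = unlist(raw$color_cues),
    schema = schema_from_list(raw$schema)
  ), class = "spy_lexicon")
}
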