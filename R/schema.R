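#' Define a suspect attribute property
#'
#' A property is one visual feature a suspect can have (gender, hair colour,
#' ...), with a finite domain of mutually exclusive values. Colour-bearing
#' properties (`is_color = TRUE`) are classified through property-colour
#' pairs rather than bare keywords, because colour words alone do not say
#' *which* feature carries the colour.
#'
#' @param name Property name (unique within a schema).
#' @param domain Character vector of at least two distinct values.
#' @param is_color Whether the domain consists of colour words.
#' @param keywords Named list mapping each domain value to the keyword
#'   strings (lowercase; multi-word phrases allowed) that identify it in
#'   free-text questions. Values of colour properties may have no direct
#'   keywords; they are reached via property-colour pairs instead.
#' @return A `spy_property` list.
#' @export
property_spec <- function(name, domain, is_color = FALSE, keywords = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  domain <- as.character(domain)
  if (length(domain) < 2L || anyDuplicated(domain)) {
    spy_abort(sprintf("property '%s' needs >= 2 distinct domain values", name),
              "spyquest_bad_schema")
  }
  structure(
    list(name = name, domain = domain, is_color = isTRUE(is_color),
         keywords = keywords),
    class = "spy_property"
  )
}

#' Build an attribute schema
#'
#' @param properties List of [property_spec()] objects, in display order.
#'   The order is meaningful: simulated policies break ties by schema order.
#' @return A `spy_schema` object.
#' @export
attribute_schema <- function(properties) {
  nms <- vapply(properties, function(p) p$name, character(1))
  if (anyDuplicated(nms)) spy_abort("duplicate property names", "spyquest_bad_schema")
  structure(list(properties = properties), class = "spy_schema")
}

#' @export
print.spy_schema <- function(x, ...) {
  cat(sprintf("<spy_schema> %d properties, %s distinct suspects\n",
              length(x$properties),
              format(schema_space_size(x), big.mark = ",")))
  for (p in x$properties) {
    cat(sprintf("  %s%s: %s\n", p$name, if (p$is_color) " [color]" else "",
                paste(p$domain, collapse = ", ")))
  }
  invisible(x)
}

property_names <- function(schema) {
  vapply(schema$properties, function(p) p$name, character(1))
}

get_property <- function(schema, name) {
  for (p in schema$properties) if (p$name == name) return(p)
  spy_abort(sprintf("unknown property '%s'", name), "spyquest_unknown_property")
}

#' Size of the attribute product space
#'
#' @param schema A `spy_schema`.
#' @return Number of distinct attribute combinations the schema supports.
#' @export
schema_space_size <- function(schema) {
  prod(vapply(schema$properties, function(p) length(p$domain), numeric(1)))
}

#' The packaged default schema
#'
#' Six visual properties spanning gender, hair (length and colour), face
#' accessories and clothing (type and colour). The product space holds 1,800
#' distinct suspects, comfortably above the default room size of 50. Keyword
#' lists cover common phrasings ("boy", "woman", "glasses", "t-shirt", ...);
#' colour values are reached through property-colour pairs built by
#' [build_default_lexicon()].
#'
#' @return A `spy_schema` with properties `gender`, `hair_length`,
#'   `hair_color`, `face_accessory`, `clothing_type`, `clothing_color`.
#' @examples
#' s <- default_schema()
#' schema_space_size(s)
#' @export
default_schema <- function() {
  attribute_schema(list(
    property_spec("gender", c("male", "female"), keywords = list(
      male   = c("man", "boy", "male", "guy", "gentleman"),
      female = c("woman", "girl", "female", "lady")
    )),
    property_spec("hair_length", c("bald", "short", "long"), keywords = list(
      bald  = c("bald"),
      short = c("short"),
      long  = c("long")
    )),
    property_spec("hair_color", c("black", "brown", "grey", "red", "blond"),
                  is_color = TRUE),
    property_spec("face_accessory", c("none", "glasses", "scar"), keywords = list(
      none    = c("no accessory", "no accessories"),
      glasses = c("glasses", "spectacles", "eyeglasses"),
      scar    = c("scar", "scarred")
    )),
    property_spec("clothing_type", c("t-shirt", "shirt", "dress", "jacket"),
                  keywords = list(
      "t-shirt" = c("t shirt", "tshirt", "tee"),
      shirt     = c("shirt"),
      dress     = c("dress"),
      jacket    = c("jacket", "coat")
    )),
    property_spec("clothing_color", c("black", "red", "blue", "green", "white"),
                  is_color = TRUE)
  ))
}

# All (property, value) pairs of a schema as a data.frame in schema order.
schema_pairs <- function(schema) {
  do.call(rbind, lapply(schema$properties, function(p) {
    data.frame(property = p$name, value = p$domain, stringsAsFactors = FALSE)
  }))
}
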