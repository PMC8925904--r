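#' @title HED annotation strings
#' @description
#' A HED string is a comma-separated sequence of tags and arbitrarily nested
#' parenthesized tag groups, e.g. `"Sensory-event, (Index-finger, (Press,
#' Keyboard-key))"`.  Tags may be written in short form (`Circle`), in long
#' form (`Item/Object/Geometric-object/2D-shape/Ellipse/Circle`), or with a
#' value suffix on a takes-value term (`Item-count/2`, `Def/Face-image`).
#' Parsing resolves every tag against a [HedSchema][load_hed_schema] and
#' validates long paths component by component.
#' @name hedstring
NULL

new_hed_tag <- function(name, value = NULL, source = NULL) {
  structure(list(name = name, value = value,
                 source = source %||% name),
            class = "hed_tag")
}

new_hed_group <- function(items) {
  structure(list(items = items), class = "hed_group")
}

new_hed_string <- function(items) {
  structure(list(items = items), class = "hed_string")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_hed_tag <- function(x) inherits(x, "hed_tag")
is_hed_group <- function(x) inherits(x, "hed_group")

#' Parse a HED annotation string
#'
#' @param text Annotation text.  `#` is accepted as a placeholder tag (used
#'   in sidecar value templates and placeholder definitions).
#' @param schema A `HedSchema` to resolve tags against.
#' @return A `hed_string` object: an ordered list of `hed_tag` and
#'   `hed_group` items mirroring the parenthesization.
#' @examples
#' parse_hed("(Index-finger, (Press, Keyboard-key))", hed_schema())
#' @export
parse_hed <- function(text, schema) {
  stopifnot(inherits(schema, "HedSchema"))
  text <- trimws(text)
  if (!nzchar(text)) return(new_hed_string(list()))
  toks <- tokenize_hed(text)
  st <- parse_items(toks, 1L, schema, depth = 0L)
  if (st$pos <= length(toks)) {
    stop(sprintf("parse error: unbalanced parenthesis near '%s'",
                 toks[[st$pos]]$text), call. = FALSE)
  }
  new_hed_string(st$items)
}

tokenize_hed <- function(text) {
  toks <- list()
  buf <- ""
  flush <- function() {
    b <- trimws(buf)
    if (nzchar(b)) toks[[length(toks) + 1L]] <<- list(type = "tag", text = b)
    buf <<- ""
  }
  for (ch in strsplit(text, "", fixed = TRUE)[[1]]) {
    if (ch == "(") { flush(); toks[[length(toks) + 1L]] <- list(type = "open", text = "(") }
    else if (ch == ")") { flush(); toks[[length(toks) + 1L]] <- list(type = "close", text = ")") }
    else if (ch == ",") { flush(); toks[[length(toks) + 1L]] <- list(type = "comma", text = ",") }
    else buf <- paste0(buf, ch)
  }
  flush()
  toks
}

parse_items <- function(toks, pos, schema, depth) {
  items <- list()
  while (pos <= length(toks)) {
    tok <- toks[[pos]]
    if (tok$type == "tag") {
      items[[length(items) + 1L]] <- parse_tag_text(tok$text, schema)
      pos <- pos + 1L
    } else if (tok$type == "open") {
      st <- parse_items(toks, pos + 1L, schema, depth + 1L)
      if (st$pos > length(toks) || toks[[st$pos]]$type != "close") {
        stop("parse error: unbalanced parenthesis (missing ')')", call. = FALSE)
      }
      if (length(st$items) == 0L) {
        stop("parse error: empty group '()'", call. = FALSE)
      }
      items[[length(items) + 1L]] <- new_hed_group(st$items)
      pos <- st$pos + 1L
    } else if (tok$type == "close") {
      if (depth == 0L) {
        stop("parse error: unbalanced parenthesis (unexpected ')')", call. = FALSE)
      }
      return(list(items = items, pos = pos))
    } else { # comma
      pos <- pos + 1L
    }
  }
  if (depth > 0L) {
    stop("parse error: unbalanced parenthesis (missing ')')", call. = FALSE)
  }
  list(items = items, pos = pos)
}

# Resolve one tag text against the schema.  Walk down the hierarchy as far as
# component names match parent->child edges; any remainder is a value suffix
# and is only legal on a takes-value node.
parse_tag_text <- function(text, schema) {
  if (text == "#") {
    return(structure(list(name = "#", value = NULL, source = "#"),
                     class = "hed_tag"))
  }
  comps <- strsplit(text, "/", fixed = TRUE)[[1]]
  if (length(comps) == 0L || !nzchar(comps[[1]])) {
    stop(sprintf("parse error: malformed tag '%s'", text), call. = FALSE)
  }
  node <- resolve_node(schema, comps[[1]])
  i <- 2L
  while (i <= length(comps)) {
    child_canon <- index_lookup(schema, comps[[i]])
    if (!is.null(child_canon) && child_canon %in% node$children) {
      node <- schema$nodes[[child_canon]]
      i <- i + 1L
    } else break
  }
  value <- NULL
  if (i <= length(comps)) {
    value <- paste(comps[i:length(comps)], collapse = "/")
    if (!node$takes_value) {
      stop(sprintf(
        "validation error in '%s': node '%s' does not take a value ('%s')",
        text, node$name, value), call. = FALSE)
    }
    if (!nzchar(trimws(value))) {
      stop(sprintf("parse error: empty value in tag '%s'", text), call. = FALSE)
    }
  }
  new_hed_tag(node$name, value, source = text)
}

#' Serialize a HED string
#'
#' @param hs A `hed_string` (or `hed_group`/`hed_tag`).
#' @param form `"short"` (canonical term names) or `"long"` (full schema
#'   paths; a value is appended after the final slash).
#' @param schema Schema used for long-form expansion; defaults to the
#'   packaged one.
#' @return A single character string; groups are parenthesized and items are
#'   separated by `", "`.
#' @examples
#' hs <- parse_hed("Item-count/2, (Press, Keyboard-key)", hed_schema())
#' hed_to_string(hs, form = "long")
#' @export
hed_to_string <- function(hs, form = c("short", "long"), schema = hed_schema()) {
  form <- match.arg(form)
  serialize_item <- function(x) {
    if (is_hed_tag(x)) {
      if (x$name == "#") return("#")
      base <- if (form == "long") hed_long_path(schema, x$name) else x$name
      if (!is.null(x$value)) paste0(base, "/", x$value) else base
    } else if (is_hed_group(x)) {
      paste0("(", paste(vapply(x$items, serialize_item, character(1)),
                        collapse = ", "), ")")
    } else {
      stop("internal: unknown HED item type", call. = FALSE)
    }
  }
  items <- if (inherits(hs, "hed_string")) hs$items else list(hs)
  paste(vapply(items, serialize_item, character(1)), collapse = ", ")
}

#' @export
format.hed_string <- function(x, ...) hed_to_string(x)

#' @export
print.hed_string <- function(x, ...) {
  cat("<hed_string> ", hed_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.hed_group <- function(x, ...) hed_to_string(new_hed_string(list(x)))

#' @export
print.hed_group <- function(x, ...) {
  cat("<hed_group> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.hed_tag <- function(x, ...) {
  if (!is.null(x$value)) paste0(x$name, "/", x$value) else x$name
}

#' @export
print.hed_tag <- function(x, ...) {
  cat("<hed_tag> ", format(x), "\n", sep = "")
  invisible(x)
}

# depth-first walk over tags; f(tag, path) where path is an integer vector of
# item positions from the top level
walk_tags <- function(hs, f) {
  recurse <- function(items, prefix) {
    for (i in seq_along(items)) {
      it <- items[[i]]
      if (is_hed_tag(it)) f(it, c(prefix, i))
      else recurse(it$items, c(prefix, i))
    }
  }
  items <- if (inherits(hs, "hed_string")) hs$items else hs$items
  recurse(items, integer())
  invisible(NULL)
}

#' Search a HED string for tags subsumed by a query term
#'
#' Finds every tag (recursing into groups) whose schema node is the query
#' node or one of its descendants, implementing generalization search: a
#' query for `2D-shape` matches a `Circle` tag.
#'
#' @param hs A `hed_string`.
#' @param query A term name resolving in `schema`.
#' @param schema A `HedSchema`.
#' @return A list of matches, each `list(tag = <hed_tag>, path = <integer
#'   positions from the top level>)`.
#' @export
hed_search <- function(hs, query, schema = hed_schema()) {
  resolve_node(schema, query) # unknown query -> error
  out <- list()
  walk_tags(hs, function(tag, path) {
    if (tag$name != "#" && hed_subsumes(schema, query, tag$name)) {
      out[[length(out) + 1L]] <<- list(tag = tag, path = path)
    }
  })
  out
}

# canonical form used for order-insensitive structural equality: sort the
# serialized items at each nesting level
canonical_key <- function(x) {
  if (is_hed_tag(x)) {
    paste0("t:", tolower(format(x)))
  } else {
    keys <- sort(vapply(x$items, canonical_key, character(1)))
    paste0("g:(", paste(keys, collapse = ","), ")")
  }
}

#' Order-insensitive structural equality of HED strings
#'
#' Equality is multiset comparison at each nesting level: the order in which
#' tags and groups are written (or concatenated during assembly) is
#' presentational and does not affect meaning.  Comparison is
#' case-insensitive.
#'
#' @param a,b `hed_string` objects.
#' @return Logical scalar.
#' @export
hed_equal <- function(a, b) {
  ka <- sort(vapply(a$items, canonical_key, character(1)))
  kb <- sort(vapply(b$items, canonical_key, character(1)))
  identical(ka, kb)
}

# number of tags (recursive)
hed_n_tags <- function(hs) {
  n <- 0L
  walk_tags(hs, function(tag, path) n <<- n + 1L)
  n
}

# concatenate hed_strings preserving item order
hed_concat <- function(strings) {
  items <- list()
  for (s in strings) items <- c(items, s$items)
  new_hed_string(items)
}
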