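#' Load a HED mini-schema document
#'
#' Reads a hierarchical controlled vocabulary from an indentation-based text
#' document: one node per line, two spaces of indentation per level, an
#' optional description after `" ; "`, and a lone `#` child marking the parent
#' as a node that admits a `/value` suffix.  Every term name must be unique
#' across the whole forest -- this uniqueness is what makes short-form
#' annotation unambiguous and is enforced at load time.
#'
#' @param path Path to the schema document (UTF-8 text).  The default is the
#'   mini vocabulary packaged with hedlite.
#' @return An object of class `HedSchema`: a rooted forest with a
#'   case-insensitive name index.  Canonical capitalization is the one
#'   declared in the document.
#' @examples
#' sch <- load_hed_schema()
#' length(sch$roots)
#' hed_long_path(sch, "Circle")
#' @export
load_hed_schema <- function(path = hedlite_schema_path()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # comment lines start with "#" in column 1; an indented lone "#" is a
  # takes-value marker, so only column-1 "#" lines are dropped
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    stop("schema parse error: document contains no nodes", call. = FALSE)
  }

  nodes <- list()
  index <- character() # lower-case name -> canonical name
  roots <- character()
  stack <- character() # canonical names, one per depth level

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    indent <- nchar(line) - nchar(sub("^ *", "", line))
    if (indent %% 2L != 0L) {
      stop(sprintf("schema parse error at line %d: odd indentation", lineno[i]),
           call. = FALSE)
    }
    depth <- indent %/% 2L
    body <- trimws(line)
    if (depth > length(stack)) {
      stop(sprintf("schema parse error at line %d: indentation jumps a level",
                   lineno[i]), call. = FALSE)
    }

    if (body == "#") {
      if (depth == 0L) {
        stop(sprintf("schema parse error at line %d: '#' marker at top level",
                     lineno[i]), call. = FALSE)
      }
      parent <- stack[[depth]]
      if (length(nodes[[parent]]$children) > 0L) {
        stop(sprintf(
          "schema-invalid: node '%s' has both children and a '#' value marker",
          parent), call. = FALSE)
      }
      nodes[[parent]]$takes_value <- TRUE
      next
    }

    parts <- strsplit(body, " ; ", fixed = TRUE)[[1]]
    name <- trimws(parts[[1]])
    descr <- if (length(parts) > 1L) trimws(paste(parts[-1], collapse = " ; ")) else ""
    if (grepl("[[:space:]]", name)) {
      stop(sprintf("schema parse error at line %d: name '%s' contains whitespace",
                   lineno[i], name), call. = FALSE)
    }
    key <- tolower(name)
    if (key %in% names(index)) {
      other <- nodes[[index[[key]]]]
      parent_here <- if (depth == 0L) "<root>" else stack[[depth]]
      stop(sprintf(
        "schema-invalid: duplicate node name '%s' (already at '%s', again under '%s')",
        name, other$long_path, parent_here), call. = FALSE)
    }

    parent <- if (depth == 0L) NA_character_ else stack[[depth]]
    long_components <- if (depth == 0L) name else
      c(nodes[[parent]]$long_components, name)
    nodes[[name]] <- list(
      name = name, parent = parent, children = character(),
      takes_value = FALSE, description = descr,
      long_components = long_components,
      long_path = paste(long_components, collapse = "/"),
      depth = depth
    )
    if (depth == 0L) {
      roots <- c(roots, name)
    } else {
      if (nodes[[parent]]$takes_value) {
        stop(sprintf(
          "schema-invalid: takes-value node '%s' cannot have child '%s'",
          parent, name), call. = FALSE)
      }
      nodes[[parent]]$children <- c(nodes[[parent]]$children, name)
    }
    index[[key]] <- name
    stack <- c(stack[seq_len(depth)], name)
  }

  structure(
    list(nodes = nodes, index = index, roots = roots, source = path),
    class = "HedSchema"
  )
}

#' Path of the packaged mini-schema fixture
#' @return File path of the vocabulary document shipped with the package.
#' @export
hedlite_schema_path <- function() {
  system.file("extdata", "hed_mini_schema.txt", package = "hedlite",
              mustWork = TRUE)
}

schema_cache <- new.env(parent = emptyenv())

#' The packaged mini-schema (memoized)
#'
#' Convenience accessor used as the default vocabulary throughout the
#' package; loads the packaged fixture once per session.
#' @return A `HedSchema`.
#' @export
hed_schema <- function() {
  if (is.null(schema_cache$default)) {
    schema_cache$default <- load_hed_schema()
  }
  schema_cache$default
}

index_lookup <- function(schema, name) {
  canonical <- unname(schema$index[tolower(name)])
  if (length(canonical) != 1L || is.na(canonical)) NULL else canonical
}

resolve_node <- function(schema, name) {
  canonical <- index_lookup(schema, name)
  if (is.null(canonical)) {
    stop(sprintf("unknown tag: '%s' does not resolve in the schema", name),
         call. = FALSE)
  }
  schema$nodes[[canonical]]
}

hed_node_exists <- function(schema, name) {
  !is.null(index_lookup(schema, name))
}

#' Long-form path of a term
#'
#' @param schema A `HedSchema`.
#' @param short_name A term name (case-insensitive).
#' @return The slash-joined root-to-node path in canonical capitalization.
#' @examples
#' hed_long_path(hed_schema(), "circle")
#' @export
hed_long_path <- function(schema, short_name) {
  resolve_node(schema, short_name)$long_path
}

#' Subsumption test between two terms
#'
#' `TRUE` iff the descendant's long path has the ancestor's long path as a
#' prefix on component boundaries, i.e. the ancestor is the same term or a
#' more general one on the same branch.
#'
#' @param schema A `HedSchema`.
#' @param ancestor_name,descendant_name Term names (case-insensitive).
#' @return Logical scalar.
#' @examples
#' hed_subsumes(hed_schema(), "2D-shape", "Circle")
#' @export
hed_subsumes <- function(schema, ancestor_name, descendant_name) {
  anc <- resolve_node(schema, ancestor_name)
  dec <- resolve_node(schema, descendant_name)
  n <- length(anc$long_components)
  if (n > length(dec$long_components)) return(FALSE)
  identical(anc$long_components, dec$long_components[seq_len(n)])
}

#' @export
print.HedSchema <- function(x, ...) {
  cat(sprintf("HedSchema: %d roots, %d nodes (%d take values)\n",
              length(x$roots), length(x$nodes),
              sum(vapply(x$nodes, `[[`, logical(1), "takes_value"))))
  cat("roots:", paste(x$roots, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.HedSchema <- function(x, ...) {
  sprintf("HedSchema<%d roots, %d nodes>", length(x$roots), length(x$nodes))
}
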