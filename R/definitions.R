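#' @title Named definitions (Definition / Def / Def-expand)
#' @description
#' A definition names a tag group once -- `(Definition/Face-image,
#' (Visual-presentation, (Image, Face), (White, Cross)))` -- so annotations
#' can reference it compactly as `Def/Face-image`.  At analysis time `Def`
#' references are expanded into `(Def-expand/Name, <body>)` groups so the
#' defined tags are available for search.  To avoid circularities,
#' definition bodies may not themselves contain `Definition`, `Def` or
#' `Def-expand` tags.  A placeholder definition carries exactly one `#` in
#' its body, substituted from a `Def/Name/value` reference.
#' @name definitions
NULL

new_definition <- function(name, body_items, takes_placeholder, provenance) {
  structure(list(name = name, body_items = body_items,
                 takes_placeholder = takes_placeholder,
                 provenance = provenance),
            class = "hed_definition")
}

def_group_name <- function(group) {
  # a definition group is one whose first item is a Definition/<name> tag
  if (!is_hed_group(group) || length(group$items) == 0L) return(NULL)
  first <- group$items[[1L]]
  if (!is_hed_tag(first) || tolower(first$name) != "definition" ||
      is.null(first$value)) {
    return(NULL)
  }
  strsplit(first$value, "/", fixed = TRUE)[[1]][[1]]
}

count_placeholders <- function(items) {
  n <- 0L
  walk_tags(new_hed_string(items), function(tag, path) {
    if (tag$name == "#" || (!is.null(tag$value) && grepl("(^|/)#($|/)", tag$value))) {
      n <<- n + 1L
    }
  })
  n
}

#' Collect definitions from parsed HED strings
#'
#' Registers every group whose first tag is `Definition/Name`.  Registration
#' is idempotent: encountering a structurally identical definition twice is
#' fine, but two definitions sharing a name with different bodies are a hard
#' conflict, since definitions anchor temporal scoping and design
#' extraction.
#'
#' @param strings A list of `hed_string` objects (or a single one), already
#'   parsed against the schema.
#' @param provenance Optional character vector (recycled) recording where
#'   each string came from.
#' @return A `DefinitionRegistry`.
#' @export
extract_definitions <- function(strings, provenance = NULL) {
  if (inherits(strings, "hed_string")) strings <- list(strings)
  if (is.null(provenance)) provenance <- rep("<input>", length(strings))
  provenance <- rep_len(provenance, length(strings))
  reg <- structure(list(entries = list()), class = "DefinitionRegistry")
  for (i in seq_along(strings)) {
    reg <- harvest_definitions(reg, strings[[i]], provenance[[i]])
  }
  reg
}

harvest_definitions <- function(reg, hs, provenance) {
  scan <- function(items, at_top) {
    for (it in items) {
      if (is_hed_tag(it)) {
        if (tolower(it$name) == "definition") {
          stop(sprintf(
            "structural error: Definition tag outside a group (%s)", provenance),
            call. = FALSE)
        }
      } else {
        nm <- def_group_name(it)
        if (!is.null(nm)) {
          reg <<- register_definition(reg, it, nm, provenance)
        } else {
          scan(it$items, FALSE)
        }
      }
    }
  }
  scan(hs$items, TRUE)
  reg
}

register_definition <- function(reg, group, name, provenance) {
  first <- group$items[[1L]]
  body_items <- group$items[-1L]
  declared_placeholder <- grepl("/#$", first$value)
  n_hash <- count_placeholders(body_items)
  entry <- new_definition(name, body_items,
                          takes_placeholder = declared_placeholder || n_hash > 0L,
                          provenance = provenance)
  key <- tolower(name)
  existing <- reg$entries[[key]]
  if (!is.null(existing)) {
    same <- hed_equal(new_hed_string(existing$body_items),
                      new_hed_string(body_items))
    if (!same) {
      stop(sprintf(
        "definition conflict: '%s' defined with different bodies (%s vs %s)",
        name, existing$provenance, provenance), call. = FALSE)
    }
    return(reg)
  }
  reg$entries[[key]] <- entry
  reg
}

#' @export
print.DefinitionRegistry <- function(x, ...) {
  cat(sprintf("DefinitionRegistry: %d definitions\n", length(x$entries)))
  for (e in x$entries) {
    cat(sprintf("  %s%s: %s\n", e$name,
                if (e$takes_placeholder) " (#)" else "",
                hed_to_string(new_hed_string(e$body_items))))
  }
  invisible(x)
}

lookup_definition <- function(reg, name) reg$entries[[tolower(name)]]

#' Lint a definition registry
#'
#' Returns issues rather than raising errors: nesting violations (a body
#' containing `Definition`, `Def` or `Def-expand`), and placeholder arity
#' violations (a placeholder definition must contain exactly one `#`).
#'
#' @param reg A `DefinitionRegistry`.
#' @return A data frame with columns `code`, `name`, `message` (zero rows
#'   when clean).
#' @export
validate_definitions <- function(reg) {
  issues <- empty_issues(c("code", "name", "message"))
  for (e in reg$entries) {
    nested <- character()
    walk_tags(new_hed_string(e$body_items), function(tag, path) {
      if (tolower(tag$name) %in% c("definition", "def", "def-expand")) {
        nested <<- c(nested, format(tag))
      }
    })
    for (nm in nested) {
      issues <- add_issue(issues, code = "nested-definition", name = e$name,
                          message = sprintf(
                            "definition '%s' contains '%s'; definitions cannot be nested",
                            e$name, nm))
    }
    n_hash <- count_placeholders(e$body_items)
    if (e$takes_placeholder && n_hash != 1L) {
      issues <- add_issue(issues, code = "placeholder-arity", name = e$name,
                          message = sprintf(
                            "placeholder definition '%s' contains %d '#' placeholders (expected 1)",
                            e$name, n_hash))
    }
    if (!e$takes_placeholder && n_hash > 0L) {
      issues <- add_issue(issues, code = "placeholder-arity", name = e$name,
                          message = sprintf(
                            "definition '%s' contains unexpected '#'", e$name))
    }
  }
  issues
}

substitute_placeholder <- function(items, value) {
  subst <- function(x) {
    if (is_hed_tag(x)) {
      if (x$name == "#") return(new_hed_tag_value_only(value))
      if (!is.null(x$value) && grepl("(^|/)#($|/)", x$value)) {
        x$value <- sub("#", value, x$value, fixed = TRUE)
        x$source <- format(x)
      }
      x
    } else {
      new_hed_group(lapply(x$items, subst))
    }
  }
  lapply(items, subst)
}

# a bare "#" substituted by a literal value becomes a value-only tag; this
# only occurs in sidecar value templates, where the template supplies the
# enclosing takes-value tag, so a bare # replacement is kept as plain text
new_hed_tag_value_only <- function(value) {
  structure(list(name = value, value = NULL, source = value),
            class = "hed_tag")
}

#' Expand Def references
#'
#' Replaces every `Def/Name` tag (wherever it is nested) by the group
#' `(Def-expand/Name, <body>)`, substituting the `#` placeholder when the
#' reference supplies a value (`Def/Name/value`).  Idempotent on its own
#' output: the result contains no `Def` tags.
#'
#' @param hs A `hed_string`.
#' @param reg A `DefinitionRegistry`.
#' @return A `hed_string` with all references expanded.
#' @export
expand_defs <- function(hs, reg) {
  expand_item <- function(x) {
    if (is_hed_tag(x)) {
      if (tolower(x$name) == "def") {
        if (is.null(x$value)) {
          stop("validation error: bare Def tag without a definition name",
               call. = FALSE)
        }
        comps <- strsplit(x$value, "/", fixed = TRUE)[[1]]
        name <- comps[[1]]
        supplied <- if (length(comps) > 1L)
          paste(comps[-1L], collapse = "/") else NULL
        entry <- lookup_definition(reg, name)
        if (is.null(entry)) {
          stop(sprintf("unknown definition: Def/%s is not registered", name),
               call. = FALSE)
        }
        if (!is.null(supplied) && !entry$takes_placeholder) {
          stop(sprintf(
            "validation error: value '%s' supplied to non-placeholder definition '%s'",
            supplied, entry$name), call. = FALSE)
        }
        if (is.null(supplied) && entry$takes_placeholder) {
          stop(sprintf(
            "validation error: placeholder definition '%s' referenced without a value",
            entry$name), call. = FALSE)
        }
        body <- entry$body_items
        expand_tag_value <- entry$name
        if (!is.null(supplied)) {
          body <- substitute_placeholder(body, supplied)
          expand_tag_value <- paste0(entry$name, "/", supplied)
        }
        return(new_hed_group(c(list(new_hed_tag("Def-expand", expand_tag_value)),
                               body)))
      }
      x
    } else {
      new_hed_group(lapply(x$items, expand_item))
    }
  }
  new_hed_string(lapply(hs$items, expand_item))
}

# inverse of expand_defs: collapse (Def-expand/Name, ...) groups back to
# Def/Name references; used for round-trip checking
contract_defs <- function(hs) {
  contract_item <- function(x) {
    if (is_hed_tag(x)) return(x)
    if (length(x$items) >= 1L && is_hed_tag(x$items[[1L]]) &&
        tolower(x$items[[1L]]$name) == "def-expand") {
      return(new_hed_tag("Def", x$items[[1L]]$value))
    }
    new_hed_group(lapply(x$items, contract_item))
  }
  new_hed_string(lapply(hs$items, contract_item))
}

# strip definition groups from a string (definitions are declarations, not
# annotation payload)
strip_definition_groups <- function(hs) {
  keep <- Filter(function(it) is.null(def_group_name(it)), hs$items)
  new_hed_string(keep)
}
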