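#' @title Experimental design extraction
#' @description
#' A design factor is declared by giving each of its levels a definition
#' whose body carries a `Condition-variable/Factor-name` tag; the
#' definition name is the level name.  Levels referenced from event-file
#' columns (`Def/Famous-face-cond`) are column-encoded; levels opened as
#' processes by meta-events (`(Def/Left-sym-cond, Onset)`) are row-encoded
#' and apply to every event within the process interval.
#' @name design
NULL

#' Extract condition variables from a definition registry
#'
#' Every definition whose body contains `Condition-variable/F` contributes
#' its name as a level of factor `F`; a bare `Condition-variable` (no
#' value) makes the definition name its own singleton factor.  Factor names
#' are matched case-insensitively; the first capitalization seen is kept
#' for output.
#'
#' @param reg A `DefinitionRegistry`.
#' @return A list of `ConditionVariable` objects (`factor_name`, `levels`,
#'   `encoding`; encoding is resolved by [design_matrix()]).
#' @export
extract_condition_variables <- function(reg) {
  factors <- list() # lower(factor name) -> list(factor_name, levels)
  for (e in reg$entries) {
    cv_values <- list()
    walk_tags(new_hed_string(e$body_items), function(tag, path) {
      if (tolower(tag$name) == "condition-variable") {
        # wrap so a NULL value (bare Condition-variable) still appends
        cv_values[[length(cv_values) + 1L]] <<- list(value = tag$value)
      }
    })
    for (v in cv_values) {
      fname <- if (is.null(v$value)) e$name else v$value
      key <- tolower(fname)
      if (is.null(factors[[key]])) {
        factors[[key]] <- list(factor_name = fname, levels = character())
      }
      factors[[key]]$levels <- union(factors[[key]]$levels, e$name)
    }
  }
  unname(lapply(factors, function(f) {
    structure(list(factor_name = f$factor_name, levels = f$levels,
                   encoding = NA_character_),
              class = "ConditionVariable")
  }))
}

# definition names referenced by Def / Def-expand tags anywhere in a string
referenced_def_names <- function(hs) {
  out <- character()
  walk_tags(hs, function(tag, path) {
    if (tolower(tag$name) %in% c("def", "def-expand") && !is.null(tag$value)) {
      out <<- c(out, strsplit(tag$value, "/", fixed = TRUE)[[1]][[1]])
    }
  })
  unique(out)
}

#' Per-event design matrix
#'
#' Assigns each event a level of each factor.  Column-encoded levels are
#' assigned where the event's annotation references the level definition;
#' row-encoded levels (those that open timeline processes) are assigned to
#' every event within the closed process interval, so a setup meta-event at
#' the first sample scopes the whole recording including its own marker and
#' the final one.  An event referencing two levels of one factor yields a
#' conflict issue (the first level is kept so summaries still print).
#'
#' @param events A list of assembled events or a `hed_assembly`.
#' @param timeline A `hed_timeline` from [resolve_processes()].
#' @param factors Condition variables from [extract_condition_variables()].
#' @return A `hed_design`: `$assignments` (data frame, one row per event,
#'   one column per factor plus `onset`), `$factors` (with `encoding`
#'   resolved to `"column"` or `"row"`), `$issues`.
#' @export
design_matrix <- function(events, timeline, factors) {
  if (inherits(events, "hed_assembly")) events <- events$events
  pr <- timeline$processes
  proc_defs <- tolower(unique(pr$definition))
  factors <- lapply(factors, function(f) {
    f$encoding <- if (any(tolower(f$levels) %in% proc_defs)) "row" else "column"
    f
  })
  onsets <- vapply(events, `[[`, numeric(1), "onset")
  assignments <- data.frame(onset = onsets, stringsAsFactors = FALSE)
  issues <- empty_issues(c("row", "factor", "code", "message"))

  refs <- lapply(events, function(ev) tolower(referenced_def_names(ev$hed)))

  for (f in factors) {
    col <- rep(NA_character_, length(events))
    lv_low <- tolower(f$levels)
    for (i in seq_along(events)) {
      hits <- character()
      if (f$encoding == "column") {
        hits <- f$levels[lv_low %in% refs[[i]]]
      } else {
        t <- onsets[[i]]
        for (j in seq_along(f$levels)) {
          rows <- pr$definition[tolower(pr$definition) == lv_low[[j]] &
                                  pr$onset <= t & t <= pr$offset]
          if (length(rows) > 0L) hits <- c(hits, f$levels[[j]])
        }
      }
      hits <- unique(hits)
      if (length(hits) > 1L) {
        issues <- add_issue(issues, row = i, factor = f$factor_name,
                            code = "level-conflict",
                            message = sprintf(
                              "event %d carries levels %s of factor '%s'",
                              i, paste(hits, collapse = "+"), f$factor_name))
      }
      if (length(hits) >= 1L) col[[i]] <- hits[[1L]]
    }
    assignments[[f$factor_name]] <- col
  }
  structure(list(assignments = assignments, factors = factors,
                 issues = issues),
            class = "hed_design")
}

#' @export
print.hed_design <- function(x, ...) {
  cat(sprintf("hed_design: %d events x %d factors (%s), %d issues\n",
              nrow(x$assignments), length(x$factors),
              paste(vapply(x$factors, function(f)
                sprintf("%s[%s]", f$factor_name, f$encoding), character(1)),
                collapse = ", "),
              nrow(x$issues)))
  invisible(x)
}

#' Summarize a design matrix
#'
#' @param dm A `hed_design`.
#' @return A `hed_design_summary`: `$factors` (factor, encoding, n_levels),
#'   `$level_counts` (per-level event counts), `$cells` (a named list of
#'   crossed-factor contingency tables for every factor pair).
#' @export
summarize_design <- function(dm) {
  stopifnot(inherits(dm, "hed_design"))
  fnames <- vapply(dm$factors, `[[`, character(1), "factor_name")
  factors <- data.frame(
    factor = fnames,
    encoding = vapply(dm$factors, `[[`, character(1), "encoding"),
    n_levels = vapply(dm$factors, function(f) length(f$levels), integer(1)),
    stringsAsFactors = FALSE)
  level_counts <- do.call(rbind, lapply(dm$factors, function(f) {
    col <- dm$assignments[[f$factor_name]]
    data.frame(factor = f$factor_name, level = f$levels,
               n_events = vapply(f$levels, function(lv)
                 sum(!is.na(col) & col == lv), integer(1)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(level_counts)) {
    level_counts <- data.frame(factor = character(), level = character(),
                               n_events = integer(), stringsAsFactors = FALSE)
  }
  rownames(level_counts) <- NULL
  cells <- list()
  if (length(fnames) >= 2L) {
    combos <- utils::combn(fnames, 2L, simplify = FALSE)
    for (cb in combos) {
      a <- dm$assignments[[cb[[1]]]]
      b <- dm$assignments[[cb[[2]]]]
      f_a <- dm$factors[[match(cb[[1]], fnames)]]
      f_b <- dm$factors[[match(cb[[2]], fnames)]]
      cells[[paste(cb, collapse = " x ")]] <-
        table(factor(a, levels = f_a$levels), factor(b, levels = f_b$levels),
              dnn = cb)
    }
  }
  structure(list(factors = factors, level_counts = level_counts,
                 cells = cells),
            class = "hed_design_summary")
}

#' @export
print.hed_design_summary <- function(x, ...) {
  cat("Design factors:\n"); print(x$factors)
  cat("\nLevel counts:\n"); print(x$level_counts)
  for (nm in names(x$cells)) {
    cat(sprintf("\nCell counts (%s):\n", nm)); print(x$cells[[nm]])
  }
  invisible(x)
}
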