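#' @title Temporal scope resolution
#' @description
#' A tag group pairing a `Def/Name` reference with an `Onset` tag marks the
#' start of an event process named by the definition; the process stays in
#' effect until the next event whose annotation groups the same definition
#' with an `Onset` or an `Offset` tag (both close it; a re-`Onset` also
#' opens a new process).  Intervals are half-open `[onset, offset)`.
#' Processes still open at the last event marker are closed there and
#' flagged via `closed_by = "end-of-record"`.
#' @name temporal
NULL

# Find (definition name, marker) pairs in an assembled annotation: any group
# whose direct items include a Def (or expanded Def-expand group) together
# with an Onset or Offset tag.
temporal_groups <- function(hs) {
  out <- list()
  scan <- function(items) {
    for (it in items) {
      if (!is_hed_group(it)) next
      def_name <- NULL
      marker <- NULL
      for (sub in it$items) {
        if (is_hed_tag(sub)) {
          low <- tolower(sub$name)
          if (low == "def" && !is.null(sub$value)) {
            def_name <- strsplit(sub$value, "/", fixed = TRUE)[[1]][[1]]
          } else if (low %in% c("onset", "offset")) {
            marker <- low
          }
        } else if (length(sub$items) >= 1L && is_hed_tag(sub$items[[1L]]) &&
                   tolower(sub$items[[1L]]$name) == "def-expand") {
          def_name <- strsplit(sub$items[[1L]]$value, "/", fixed = TRUE)[[1]][[1]]
        }
      }
      if (!is.null(def_name) && !is.null(marker)) {
        out[[length(out) + 1L]] <<- list(definition = def_name, marker = marker)
      } else {
        scan(it$items)
      }
    }
  }
  scan(hs$items)
  out
}

#' Resolve Onset/Offset groups into event processes
#'
#' @param events A list of assembled events (see [assemble_events()]),
#'   sorted by onset time (they are sorted defensively).
#' @return A `hed_timeline`: `$processes` is a data frame with columns
#'   `definition`, `onset`, `offset`, `duration`, `closed_by`
#'   (`"explicit-offset"`, `"next-onset"` or `"end-of-record"`);
#'   `$instantaneous` lists `(time, hed)` for events with no Onset/Offset
#'   grouping; `$issues` collects unmatched Offsets.
#' @export
resolve_processes <- function(events) {
  if (inherits(events, "hed_assembly")) events <- events$events
  times <- vapply(events, `[[`, numeric(1), "onset")
  events <- events[order(times)]
  times <- sort(times)

  open <- list() # lower(def name) -> list(definition, onset)
  proc_def <- character(); proc_on <- numeric(); proc_off <- numeric()
  proc_by <- character()
  issues <- empty_issues()
  instantaneous <- list()

  close_process <- function(key, offset, how) {
    p <- open[[key]]
    proc_def[[length(proc_def) + 1L]] <<- p$definition
    proc_on[[length(proc_on) + 1L]] <<- p$onset
    proc_off[[length(proc_off) + 1L]] <<- offset
    proc_by[[length(proc_by) + 1L]] <<- how
    open[[key]] <<- NULL
  }

  for (i in seq_along(events)) {
    ev <- events[[i]]
    t <- ev$onset
    tg <- temporal_groups(ev$hed)
    if (length(tg) == 0L) {
      if (length(ev$hed$items) > 0L) {
        instantaneous[[length(instantaneous) + 1L]] <-
          list(time = t, hed = ev$hed)
      }
      next
    }
    # offsets first so an event may close and reopen the same definition
    ord <- order(vapply(tg, function(g) g$marker != "offset", logical(1)))
    for (g in tg[ord]) {
      key <- tolower(g$definition)
      if (g$marker == "offset") {
        if (is.null(open[[key]])) {
          issues <- add_issue(issues, row = ev$row, code = "unmatched-offset",
                              message = sprintf(
                                "Offset for '%s' at %.3f s with no open process",
                                g$definition, t))
        } else {
          close_process(key, t, "explicit-offset")
        }
      } else {
        if (!is.null(open[[key]])) close_process(key, t, "next-onset")
        open[[key]] <- list(definition = g$definition, onset = t)
      }
    }
  }

  if (length(events) > 0L) {
    end_time <- times[[length(times)]]
    for (key in names(open)) close_process(key, end_time, "end-of-record")
  }

  processes <- data.frame(definition = proc_def, onset = proc_on,
                          offset = proc_off, duration = proc_off - proc_on,
                          closed_by = proc_by, stringsAsFactors = FALSE)
  processes <- processes[order(processes$onset, processes$definition), ,
                         drop = FALSE]
  rownames(processes) <- NULL
  structure(list(processes = processes, instantaneous = instantaneous,
                 issues = issues),
            class = "hed_timeline")
}

#' @export
print.hed_timeline <- function(x, ...) {
  cat(sprintf("hed_timeline: %d processes, %d instantaneous events, %d issues\n",
              nrow(x$processes), length(x$instantaneous), nrow(x$issues)))
  if (nrow(x$processes) > 0L) print(utils::head(x$processes, 10L))
  invisible(x)
}

#' @export
as.data.frame.hed_timeline <- function(x, ...) x$processes

#' Insert Event-context groups into concurrent events
#'
#' Each event whose time lies strictly inside a process interval (the
#' process's own boundary markers are excluded) gains an `(Event-context,
#' Def/P, ...)` group naming every such ongoing process.  Process
#' boundaries are never modified, and removing the inserted groups recovers
#' the original annotations exactly.
#'
#' @param events A list of assembled events or a `hed_assembly`.
#' @param timeline The `hed_timeline` from [resolve_processes()].
#' @return The events with context groups appended where applicable.
#' @export
insert_context <- function(events, timeline) {
  asm <- NULL
  if (inherits(events, "hed_assembly")) { asm <- events; events <- events$events }
  pr <- timeline$processes
  out <- lapply(events, function(ev) {
    t <- ev$onset
    inside <- pr$onset < t & t < pr$offset
    if (any(inside)) {
      defs <- unique(pr$definition[inside])
      ctx <- new_hed_group(c(
        list(new_hed_tag("Event-context")),
        lapply(defs, function(d) new_hed_tag("Def", d))))
      ev$hed <- new_hed_string(c(ev$hed$items, list(ctx)))
    }
    ev
  })
  if (!is.null(asm)) { asm$events <- out; return(asm) }
  out
}

# drop Event-context groups (inverse of insert_context)
strip_context <- function(events) {
  if (inherits(events, "hed_assembly")) events <- events$events
  lapply(events, function(ev) {
    keep <- Filter(function(it) {
      !(is_hed_group(it) && length(it$items) >= 1L &&
          is_hed_tag(it$items[[1L]]) &&
          tolower(it$items[[1L]]$name) == "event-context")
    }, ev$hed$items)
    ev$hed <- new_hed_string(keep)
    ev
  })
}
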