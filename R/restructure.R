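#' @title By-trial to by-event conversion
#' @description
#' Many shared datasets store one row per trial, with the other trial
#' events embedded as delays relative to an anchor event (and not always
#' with consistent signs -- a cross shown *before* the anchor may be stored
#' as a positive duration).  Best practice is one event marker per line, so
#' these tables are exploded using an explicit mapping that states, for
#' every derived event, which column holds the delay and whether it lies
#' before or after the anchor.  The reference point is never inferred.
#' @name restructure
NULL

#' Build a trial mapping specification
#'
#' @param anchor_column Column holding the trial anchor onset (usually
#'   `onset`).
#' @param derived_events A list of entries
#'   `list(event_name=, source_column=, sign=, role=)`: `sign` is
#'   `"before"` or `"after"` the anchor; `role` is `"anchor"` (the anchor
#'   row itself, `source_column` ignored), `"onset-delta"` (the stored
#'   value is a delay to the event onset) or `"duration-from-anchor"` (the
#'   stored value is a duration whose end marks the event).  The two delta
#'   roles share the arithmetic `onset = anchor +/- value`; they differ in
#'   intent and are kept apart for auditability.
#' @param pass_through Columns copied verbatim onto every emitted row.
#' @param anchor_event Event name given to the anchor row when no explicit
#'   `"anchor"` entry names it.
#' @return A `TrialMappingSpec`.
#' @export
trial_mapping_spec <- function(anchor_column, derived_events,
                               pass_through = character(),
                               anchor_event = "anchor") {
  for (d in derived_events) {
    stopifnot(!is.null(d$event_name), !is.null(d$role))
    if (!d$role %in% c("anchor", "onset-delta", "duration-from-anchor")) {
      stop(sprintf("invalid role '%s' in trial mapping", d$role), call. = FALSE)
    }
    if (d$role != "anchor" && is.null(d$source_column)) {
      stop(sprintf("derived event '%s' needs a source_column", d$event_name),
           call. = FALSE)
    }
  }
  structure(list(anchor_column = anchor_column,
                 derived_events = derived_events,
                 pass_through = pass_through,
                 anchor_event = anchor_event),
            class = "TrialMappingSpec")
}

#' Read a trial mapping specification from JSON
#' @param path Path to a JSON mapping file.
#' @return A `TrialMappingSpec`.
#' @export
read_mapping_spec <- function(path) {
  json <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  trial_mapping_spec(
    anchor_column = json$anchor_column,
    derived_events = json$derived_events,
    pass_through = unlist(json$pass_through) %||% character(),
    anchor_event = json$anchor_event %||% "anchor")
}

fmt_num <- function(x) sprintf("%g", x)

#' Explode a by-trial table into a by-event table
#'
#' Each trial row emits one row per derived event whose source cell is
#' present; missing (`"n/a"`) cells skip that event.  Output rows carry the
#' event name in an `event_type` column, a `trial` index, and the
#' pass-through columns; they are sorted by onset.  Negative onsets are
#' allowed but flagged with a warning.
#'
#' @param tab A by-trial `EventTable`.
#' @param spec A `TrialMappingSpec`.
#' @return A by-event `EventTable`.
#' @export
explode_trials <- function(tab, spec) {
  stopifnot(inherits(tab, "EventTable"), inherits(spec, "TrialMappingSpec"))
  data <- tab$data
  needed <- c(spec$anchor_column,
              unlist(lapply(spec$derived_events, `[[`, "source_column")),
              spec$pass_through)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop(sprintf("trial mapping references missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  rows <- list()
  for (r in seq_len(nrow(data))) {
    anchor <- as.numeric(data[r, spec$anchor_column])
    for (d in spec$derived_events) {
      if (d$role == "anchor") {
        onset <- anchor
      } else {
        cell <- data[r, d$source_column]
        if (is.na(cell)) next
        v <- as.numeric(cell)
        onset <- if (identical(d$sign, "before")) anchor - v else anchor + v
      }
      row <- c(list(onset = fmt_num(onset), duration = "n/a",
                    event_type = d$event_name, trial = as.character(r)),
               stats::setNames(as.list(as.character(data[r, spec$pass_through])),
                               spec$pass_through))
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(onset = character(), duration = character(),
                      event_type = character(), trial = character(),
                      stringsAsFactors = FALSE)
    for (nm in spec$pass_through) out[[nm]] <- character()
    return(event_table(out))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  ord <- order(as.numeric(out$onset), match(out$event_type,
                                            vapply(spec$derived_events, `[[`,
                                                   character(1), "event_name")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (any(as.numeric(out$onset) < 0)) {
    warning(sprintf("%d exploded event(s) have negative onsets",
                    sum(as.numeric(out$onset) < 0)), call. = FALSE)
  }
  event_table(out)
}

#' Re-fold a by-event table into by-trial form
#'
#' Inverse of [explode_trials()] given the same mapping; exact on tables
#' with no missing source cells.
#'
#' @param tab A by-event `EventTable` produced by [explode_trials()].
#' @param spec The `TrialMappingSpec` used to explode.
#' @return A by-trial `EventTable` with the anchor, delay and pass-through
#'   columns reconstructed.
#' @export
fold_trials <- function(tab, spec) {
  stopifnot(inherits(tab, "EventTable"), inherits(spec, "TrialMappingSpec"))
  data <- tab$data
  trials <- sort(unique(as.integer(data$trial)))
  out_rows <- list()
  for (tr in trials) {
    sub <- data[as.integer(data$trial) == tr, , drop = FALSE]
    anchor_name <- spec$anchor_event
    for (d in spec$derived_events) {
      if (d$role == "anchor") anchor_name <- d$event_name
    }
    anchor_row <- sub[sub$event_type == anchor_name, , drop = FALSE][1, ]
    anchor <- as.numeric(anchor_row$onset)
    row <- stats::setNames(list(fmt_num(anchor)), spec$anchor_column)
    for (d in spec$derived_events) {
      if (d$role == "anchor") next
      ev <- sub[sub$event_type == d$event_name, , drop = FALSE]
      if (nrow(ev) == 0L) {
        row[[d$source_column]] <- NA_character_
        next
      }
      delta <- as.numeric(ev$onset[[1]]) - anchor
      if (identical(d$sign, "before")) delta <- -delta
      row[[d$source_column]] <- fmt_num(delta)
    }
    for (nm in spec$pass_through) row[[nm]] <- anchor_row[[nm]]
    out_rows[[length(out_rows) + 1L]] <- row
  }
  out <- do.call(rbind, lapply(out_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (!"duration" %in% names(out)) {
    # reconstructed by-trial tables carry their durations in named delay
    # columns; BIDS still requires the column to exist
    dur_src <- Filter(function(d) identical(d$role, "duration-from-anchor"),
                      spec$derived_events)
    out$duration <- if (length(dur_src) > 0L)
      out[[dur_src[[1]]$source_column]] else "n/a"
    out <- out[, c(spec$anchor_column, "duration",
                   setdiff(names(out), c(spec$anchor_column, "duration"))),
               drop = FALSE]
  }
  event_table(out)
}
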