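# Shared fixtures and independent oracles for the hedlite suite.

wh_sidecar <- function() read_sidecar(hedlite_wh_sidecar_path())
wh_table <- function() read_events_tsv(hedlite_wh_events_path())
wh_assembly <- function(expand = FALSE) {
  assemble_events(wh_table(), wh_sidecar(), expand = expand)
}
wh_fmri_dir <- function() {
  system.file("extdata", "wh_fmri", package = "hedlite", mustWork = TRUE)
}

# The six design-encoding definitions exactly as printed in the source
# table (face type and repetition status factors, three levels each).
design_definition_texts <- c(
  "(Definition/Famous-face-cond, (Condition-variable/Face-type, (Image, (Face, Famous))))",
  "(Definition/Unfamiliar-face-cond, (Condition-variable/Face-type, (Image, (Face, Unfamiliar))))",
  "(Definition/Scrambled-face-cond, (Condition-variable/Face-type, (Image, (Face, Disordered))))",
  "(Definition/First-show-cond, (Condition-variable/Repetition-status, Item-count/1))",
  "(Definition/Immediate-repeat-cond, (Condition-variable/Repetition-status, Item-count/2, Item-interval/1))",
  "(Definition/Delayed-repeat-cond, (Condition-variable/Repetition-status, Item-count/2))"
)

session_face_counts <- function(ses) {
  vapply(ses$runs, function(r)
    sum(r$data$event_type %in% c("show_face", "show_face_initial")),
    integer(1))
}

# ---- random HED tree generation (plain vocabulary, no Def machinery) ----

plain_vocab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sch <- hed_schema()
      special <- c("definition", "def", "def-expand", "event-context")
      nms <- names(sch$nodes)
      cache <<- nms[!(tolower(nms) %in% special)]
    }
    cache
  }
})

random_hed_tag <- function(sch) {
  nm <- sample(plain_vocab(), 1L)
  node <- sch$nodes[[nm]]
  if (node$takes_value) {
    hedlite:::new_hed_tag(nm, as.character(sample(1:99, 1L)))
  } else {
    hedlite:::new_hed_tag(nm)
  }
}

random_hed_items <- function(sch, n_items, depth = 0L) {
  lapply(seq_len(n_items), function(i) {
    if (depth < 3L && stats::runif(1) < 0.3) {
      hedlite:::new_hed_group(
        random_hed_items(sch, sample(1:3, 1L), depth + 1L))
    } else {
      random_hed_tag(sch)
    }
  })
}

random_hed_string <- function(sch, n_items = sample(1:8, 1L)) {
  hedlite:::new_hed_string(random_hed_items(sch, n_items))
}

# ---- independent search oracle: long-path string prefix test ----

flatten_tags_oracle <- function(x) {
  out <- list()
  grab <- function(items) {
    for (it in items) {
      if (inherits(it, "hed_tag")) out[[length(out) + 1L]] <<- it
      else grab(it$items)
    }
  }
  grab(x$items)
  out
}

search_oracle <- function(hs, query, sch) {
  qpath <- tolower(hed_long_path(sch, query))
  hits <- 0L
  for (tag in flatten_tags_oracle(hs)) {
    tpath <- tolower(hed_long_path(sch, tag$name))
    if (tpath == qpath || startsWith(tpath, paste0(qpath, "/"))) {
      hits <- hits + 1L
    }
  }
  hits
}

# ---- independent temporal oracle: per-definition left-to-right sweep ----

# stream: data.frame(time, def, marker) with marker in onset/offset/none
sweep_oracle <- function(stream) {
  stream <- stream[order(stream$time), , drop = FALSE]
  end_time <- max(stream$time)
  rows <- list()
  for (d in unique(stream$def[stream$marker != "none"])) {
    sub <- stream[stream$def == d & stream$marker != "none", , drop = FALSE]
    open <- NA_real_
    for (i in seq_len(nrow(sub))) {
      t <- sub$time[i]
      if (sub$marker[i] == "onset") {
        if (!is.na(open)) {
          rows[[length(rows) + 1L]] <- data.frame(
            definition = d, onset = open, offset = t, closed_by = "next-onset")
        }
        open <- t
      } else {
        if (!is.na(open)) {
          rows[[length(rows) + 1L]] <- data.frame(
            definition = d, onset = open, offset = t,
            closed_by = "explicit-offset")
          open <- NA_real_
        }
      }
    }
    if (!is.na(open)) {
      rows[[length(rows) + 1L]] <- data.frame(
        definition = d, onset = open, offset = end_time,
        closed_by = "end-of-record")
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(definition = character(), onset = numeric(),
               offset = numeric(), closed_by = character())
  out$duration <- out$offset - out$onset
  out <- out[order(out$onset, out$definition), c("definition", "onset",
                                                 "offset", "duration",
                                                 "closed_by")]
  rownames(out) <- NULL
  out
}

# build an assembled-event list from a marker stream so resolve_processes
# can consume it
stream_to_events <- function(stream) {
  times <- sort(unique(stream$time))
  lapply(times, function(t) {
    sub <- stream[stream$time == t, , drop = FALSE]
    items <- list()
    for (i in seq_len(nrow(sub))) {
      if (sub$marker[i] == "none") {
        items[[length(items) + 1L]] <- hedlite:::new_hed_tag("Sensory-event")
      } else {
        items[[length(items) + 1L]] <- hedlite:::new_hed_group(list(
          hedlite:::new_hed_tag("Def", sub$def[i]),
          hedlite:::new_hed_tag(
            if (sub$marker[i] == "onset") "Onset" else "Offset")))
      }
    }
    structure(list(onset = t, sample = NA_real_, row = NA_integer_,
                   hed = hedlite:::new_hed_string(items),
                   contributions = list()),
              class = "AssembledEvent")
  })
}

random_stream <- function(n_markers = 50L, n_defs = 5L) {
  defs <- paste0("Proc-", seq_len(n_defs))
  # unique times so marker ordering at a time point is never ambiguous
  data.frame(
    time = sort(sample(seq(0.001, 100, by = 0.001), n_markers)),
    def = sample(defs, n_markers, replace = TRUE),
    marker = sample(c("onset", "offset", "none"), n_markers,
                    replace = TRUE, prob = c(0.45, 0.35, 0.2)),
    stringsAsFactors = FALSE)
}

# drop unmatched-offset markers so oracle comparisons are on clean streams
# when a test wants zero issues
write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
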