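#' @title BIDS event tables and sidecars
#' @description
#' Event files are tab-separated tables with required `onset` and `duration`
#' columns (seconds), an optional `sample` column, and arbitrary user
#' columns; `"n/a"` denotes a missing cell.  A JSON sidecar annotates
#' columns by name: a `HED` entry that is a mapping makes the column
#' categorical (one annotation per level), a `HED` entry that is a single
#' string containing one `#` makes it a value column (the cell text is
#' substituted for the `#`), and entries without a `HED` key are
#' unannotated.  Cells are kept as the text found in the file, so writing a
#' table back reproduces the original content.
#' @name bids_events
NULL

#' Construct an event table
#'
#' @param data A data frame; all cells are stored as character (numbers are
#'   kept exactly as formatted).  Must contain `onset` and `duration`
#'   columns.  `NA` represents `"n/a"`.
#' @param path Optional provenance path.
#' @return An `EventTable`.
#' @export
event_table <- function(data, path = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(data)) data[[nm]] <- as.character(data[[nm]])
  if (!all(c("onset", "duration") %in% names(data))) {
    stop(sprintf("format error: event table %smust have onset and duration columns",
                 if (is.null(path)) "" else paste0("'", path, "' ")),
         call. = FALSE)
  }
  on <- suppressWarnings(as.numeric(data$onset))
  if (anyNA(on) && nrow(data) > 0L) {
    stop("format error: non-numeric onset values", call. = FALSE)
  }
  if (is.unsorted(on)) {
    warning(sprintf("event table %shas non-monotone onsets",
                    if (is.null(path)) "" else paste0("'", path, "' ")),
            call. = FALSE)
  }
  rownames(data) <- NULL
  structure(list(data = data, path = path), class = "EventTable")
}

#' Read a BIDS events.tsv file
#'
#' @param path File path; first line must be a header.
#' @return An `EventTable`; `"n/a"` cells become `NA`.
#' @export
read_events_tsv <- function(path) {
  data <- utils::read.delim(path, sep = "\t", colClasses = "character",
                            na.strings = "n/a", check.names = FALSE,
                            quote = "", comment.char = "")
  event_table(data, path = path)
}

#' Write a BIDS events.tsv file
#'
#' Content round-trips: `read_events_tsv(write_events_tsv(tab, f))` has
#' identical cells, with missing values written as `"n/a"`.
#'
#' @param tab An `EventTable`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(tab, path) {
  stopifnot(inherits(tab, "EventTable"))
  utils::write.table(tab$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a", eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.EventTable <- function(x, ...) {
  cat(sprintf("EventTable: %d events, %d columns (%s)\n",
              nrow(x$data), ncol(x$data),
              paste(names(x$data), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.EventTable <- function(x, ...) x$data

#' Numeric onsets of an event table
#' @param tab An `EventTable`.
#' @return Numeric vector of onset times in seconds.
#' @export
event_onsets <- function(tab) as.numeric(tab$data$onset)

new_column_annotation <- function(kind, levels = NULL, template = NULL,
                                  level_descriptions = NULL, description = NULL) {
  structure(list(kind = kind, levels = levels, template = template,
                 level_descriptions = level_descriptions,
                 description = description),
            class = "ColumnAnnotation")
}

empty_sidecar <- function(source = "<none>") {
  structure(list(columns = list(), definitions = extract_definitions(list()),
                 definition_strings = list(), unannotated = character(),
                 issues = empty_issues(), source = source),
            class = "Sidecar")
}

#' Read a BIDS events.json sidecar
#'
#' Classifies each annotated column as categorical or value from the shape
#' of its `HED` entry alone, harvests `Definition` groups (both from
#' dedicated definition keys and from column annotations) into a
#' [DefinitionRegistry][extract_definitions], and records keys without a
#' `HED` entry as unannotated.  Malformed entries and unknown tags are
#' collected as issues in `$issues`, not raised.
#'
#' @param path Path to a JSON sidecar.
#' @param schema A `HedSchema`.
#' @return A `Sidecar`.
#' @export
read_sidecar <- function(path, schema = hed_schema()) {
  json <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sidecar_from_list(json, schema, source = path)
}

sidecar_from_list <- function(json, schema, source = "<list>") {
  sc <- empty_sidecar(source)
  def_strings <- list()
  def_provenance <- character()

  for (key in names(json)) {
    entry <- json[[key]]
    if (!is.list(entry) || is.null(entry$HED)) {
      if (key != "comment") sc$unannotated <- c(sc$unannotated, key)
      next
    }
    hed <- entry$HED
    descr <- if (!is.null(entry$Description)) entry$Description else NULL

    if (is.list(hed)) {
      levels <- list()
      level_ok <- TRUE
      all_definition_groups <- TRUE
      for (lv in names(hed)) {
        txt <- hed[[lv]]
        if (!is.character(txt) || length(txt) != 1L) {
          sc$issues <- add_issue(sc$issues, file = source, column = key,
                                 code = "sidecar-format",
                                 message = sprintf(
                                   "level '%s' of '%s' is not a single annotation text",
                                   lv, key))
          level_ok <- FALSE
          next
        }
        hs <- tryCatch(parse_hed(txt, schema), error = function(e) e)
        if (inherits(hs, "error")) {
          sc$issues <- add_issue(sc$issues, file = source, column = key,
                                 code = issue_code_for(hs),
                                 message = sprintf("in '%s'/'%s': %s",
                                                   key, lv, conditionMessage(hs)))
          next
        }
        levels[[lv]] <- hs
        if (!all(vapply(hs$items,
                        function(it) !is.null(def_group_name(it)),
                        logical(1))) || length(hs$items) == 0L) {
          all_definition_groups <- FALSE
        }
      }
      if (length(levels) > 0L && all_definition_groups) {
        # a key containing only Definition groups is a definition store,
        # not a column annotation
        for (lv in names(levels)) {
          def_strings[[length(def_strings) + 1L]] <- levels[[lv]]
          def_provenance <- c(def_provenance,
                              sprintf("%s:%s/%s", source, key, lv))
        }
        next
      }
      # definitions embedded in ordinary annotations are harvested too,
      # and stripped from the payload used downstream
      for (lv in names(levels)) {
        if (length(hed_search_defs(levels[[lv]])) > 0L) {
          def_strings[[length(def_strings) + 1L]] <- levels[[lv]]
          def_provenance <- c(def_provenance,
                              sprintf("%s:%s/%s", source, key, lv))
          levels[[lv]] <- strip_definition_groups(levels[[lv]])
        }
      }
      sc$columns[[key]] <- new_column_annotation(
        "categorical", levels = levels,
        level_descriptions = entry$Levels, description = descr)
    } else if (is.character(hed) && length(hed) == 1L) {
      n_hash <- lengths(regmatches(hed, gregexpr("#", hed, fixed = TRUE)))
      if (n_hash != 1L) {
        sc$issues <- add_issue(sc$issues, file = source, column = key,
                               code = "sidecar-format",
                               message = sprintf(
                                 "value annotation for '%s' contains %d '#' placeholders (expected 1)",
                                 key, n_hash))
        next
      }
      hs <- tryCatch(parse_hed(hed, schema), error = function(e) e)
      if (inherits(hs, "error")) {
        sc$issues <- add_issue(sc$issues, file = source, column = key,
                               code = issue_code_for(hs),
                               message = sprintf("in '%s': %s", key,
                                                 conditionMessage(hs)))
        next
      }
      sc$columns[[key]] <- new_column_annotation("value", template = hs,
                                                 description = descr)
    } else {
      sc$issues <- add_issue(sc$issues, file = source, column = key,
                             code = "sidecar-format",
                             message = sprintf(
                               "HED entry for '%s' is neither a mapping nor a single text",
                               key))
    }
  }

  sc$definition_strings <- def_strings
  reg <- tryCatch(extract_definitions(def_strings, def_provenance),
                  error = function(e) e)
  if (inherits(reg, "error")) {
    sc$issues <- add_issue(sc$issues, file = source,
                           code = "definition-conflict",
                           message = conditionMessage(reg))
    reg <- extract_definitions(list())
  }
  sc$definitions <- reg
  def_issues <- validate_definitions(reg)
  if (nrow(def_issues) > 0L) {
    for (i in seq_len(nrow(def_issues))) {
      sc$issues <- add_issue(sc$issues, file = source,
                             code = def_issues$code[i],
                             message = def_issues$message[i])
    }
  }
  sc
}

issue_code_for <- function(e) {
  msg <- conditionMessage(e)
  if (grepl("^unknown tag", msg)) "unknown-tag" else "annotation-parse"
}

hed_search_defs <- function(hs) {
  found <- list()
  for (it in hs$items) {
    if (!is.null(def_group_name(it))) found[[length(found) + 1L]] <- it
  }
  found
}

#' @export
print.Sidecar <- function(x, ...) {
  kinds <- vapply(x$columns, `[[`, character(1), "kind")
  cat(sprintf("Sidecar (%s): %d annotated columns (%s), %d unannotated, %d definitions, %d issues\n",
              x$source, length(x$columns),
              paste(sprintf("%s=%s", names(kinds), kinds), collapse = ", "),
              length(x$unannotated), length(x$definitions$entries),
              nrow(x$issues)))
  invisible(x)
}

#' Write a sidecar back to JSON
#'
#' Serializes column annotations and definition strings into the BIDS
#' sidecar layout (definitions under a dedicated `hed_defs` key).
#'
#' @param sc A `Sidecar`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(sc, path) {
  stopifnot(inherits(sc, "Sidecar"))
  out <- list()
  for (key in names(sc$columns)) {
    ann <- sc$columns[[key]]
    entry <- list()
    if (!is.null(ann$description)) entry$Description <- ann$description
    if (!is.null(ann$level_descriptions)) entry$Levels <- ann$level_descriptions
    if (ann$kind == "categorical") {
      entry$HED <- lapply(ann$levels, hed_to_string)
    } else {
      entry$HED <- hed_to_string(ann$template)
    }
    out[[key]] <- entry
  }
  if (length(sc$definitions$entries) > 0L) {
    defs <- lapply(sc$definitions$entries, function(e) {
      body <- hed_to_string(new_hed_string(e$body_items))
      nm <- if (e$takes_placeholder) paste0(e$name, "/#") else e$name
      sprintf("(Definition/%s, %s)", nm, body)
    })
    names(defs) <- paste0(tolower(names(defs)), "_def")
    out[["hed_defs"]] <- list(
      Description = "HED definitions used by the annotations.",
      HED = defs)
  }
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE), path,
             useBytes = TRUE)
  invisible(path)
}

#' Merge all sidecars applicable to an events file
#'
#' Walks from the dataset root down to the directory of the events file,
#' merging every `*events.json` found on the way; deeper files override
#' shallower ones per top-level key (the BIDS inheritance principle).
#'
#' @param root Dataset root directory.
#' @param events_path Path of the events.tsv file (inside `root`).
#' @param schema A `HedSchema`.
#' @return A merged `Sidecar`; empty (with a warning) when none is found.
#' @export
gather_sidecars <- function(root, events_path, schema = hed_schema()) {
  root <- normalizePath(root)
  ev <- normalizePath(events_path)
  rel <- sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", root), "/?"),
             "", dirname(ev))
  dirs <- root
  if (nzchar(rel) && rel != ".") {
    parts <- strsplit(rel, "/", fixed = TRUE)[[1]]
    for (i in seq_along(parts)) {
      dirs <- c(dirs, file.path(root, paste(parts[seq_len(i)], collapse = "/")))
    }
  }
  merged <- list()
  found <- FALSE
  for (d in dirs) {
    files <- sort(list.files(d, pattern = "events\\.json$", full.names = TRUE))
    for (f in files) {
      found <- TRUE
      json <- jsonlite::fromJSON(f, simplifyVector = FALSE)
      for (key in names(json)) merged[[key]] <- json[[key]] # deeper wins
    }
  }
  if (!found) {
    warning(sprintf("no events.json sidecar found for '%s'", events_path),
            call. = FALSE)
    return(empty_sidecar(source = sprintf("<empty merge for %s>", events_path)))
  }
  sidecar_from_list(merged, schema,
                    source = sprintf("<merged for %s>", basename(events_path)))
}

#' Assemble per-event HED annotations
#'
#' For each row of the event table, fragments are gathered in column order:
#' a categorical column contributes the annotation of the cell's level, a
#' value column contributes its template with the cell text substituted for
#' `#` (inserted exactly as written, so `"1"` stays `"1"`), missing
#' (`"n/a"`) cells and unannotated columns contribute nothing.  Fragments
#' are concatenated with commas into one HED string per event.
#'
#' @param tab An `EventTable`.
#' @param sidecar A `Sidecar`.
#' @param expand If `TRUE`, `Def` references are expanded to `Def-expand`
#'   groups using the sidecar's definitions.
#' @return A `hed_assembly`: `$events` is a list of assembled events
#'   (`onset`, `sample`, `row`, `hed`, `contributions`), `$issues` collects
#'   missing-level findings (assembly continues past them).
#' @export
assemble_events <- function(tab, sidecar, expand = FALSE) {
  stopifnot(inherits(tab, "EventTable"), inherits(sidecar, "Sidecar"))
  data <- tab$data
  ann_cols <- intersect(names(data), names(sidecar$columns))
  issues <- empty_issues()
  events <- vector("list", nrow(data))
  file <- tab$path %||% "<table>"
  for (r in seq_len(nrow(data))) {
    frags <- list()
    for (col in ann_cols) {
      cell <- data[r, col]
      if (is.na(cell)) next
      ann <- sidecar$columns[[col]]
      if (ann$kind == "categorical") {
        hs <- ann$levels[[cell]]
        if (is.null(hs)) {
          issues <- add_issue(issues, file = file, row = r, column = col,
                              code = "missing-level",
                              message = sprintf(
                                "value '%s' in categorical column '%s' has no annotation",
                                cell, col))
          next
        }
        frags[[col]] <- hs
      } else {
        frags[[col]] <- new_hed_string(
          substitute_placeholder(ann$template$items, cell))
      }
    }
    hed <- hed_concat(frags)
    if (expand) hed <- expand_defs(hed, sidecar$definitions)
    events[[r]] <- structure(
      list(onset = as.numeric(data$onset[r]),
           sample = if ("sample" %in% names(data))
             suppressWarnings(as.numeric(data$sample[r])) else NA_real_,
           row = r,
           hed = hed,
           contributions = frags),
      class = "AssembledEvent")
  }
  structure(list(events = events, issues = issues, path = tab$path),
            class = "hed_assembly")
}

#' @export
print.hed_assembly <- function(x, ...) {
  cat(sprintf("hed_assembly: %d events, %d issues\n",
              length(x$events), nrow(x$issues)))
  invisible(x)
}

#' @export
print.AssembledEvent <- function(x, ...) {
  cat(sprintf("AssembledEvent @ %.3f s: %s\n", x$onset, hed_to_string(x$hed)))
  invisible(x)
}

#' @export
as.data.frame.hed_assembly <- function(x, ...) {
  data.frame(
    onset = vapply(x$events, `[[`, numeric(1), "onset"),
    hed = vapply(x$events, function(e) hed_to_string(e$hed), character(1)),
    stringsAsFactors = FALSE)
}

#' Validate a BIDS-like dataset
#'
#' Runs the whole pipeline over every `*events.tsv` under `root` and
#' aggregates findings as data: sidecar format problems, unknown tags,
#' definition conflicts and arity problems, missing categorical levels, and
#' unmatched Offsets from temporal resolution.  Processes left open at the
#' end of a recording are closed there and are not issues.
#'
#' @param root Dataset root directory.
#' @param schema A `HedSchema`.
#' @return Issue data frame with columns `file`, `row`, `column`, `code`,
#'   `message`; zero rows for a clean dataset.
#' @export
validate_dataset <- function(root, schema = hed_schema()) {
  files <- sort(list.files(root, pattern = "_events\\.tsv$", recursive = TRUE,
                           full.names = TRUE))
  issues <- empty_issues()
  for (f in files) {
    tab <- tryCatch(read_events_tsv(f), error = function(e) e)
    if (inherits(tab, "error")) {
      issues <- add_issue(issues, file = f, code = "format-error",
                          message = conditionMessage(tab))
      next
    }
    sc <- suppressWarnings(gather_sidecars(root, f, schema))
    issues <- bind_issues(issues, sc$issues)
    asm <- assemble_events(tab, sc)
    issues <- bind_issues(issues, asm$issues)
    tl <- resolve_processes(asm$events)
    if (nrow(tl$issues) > 0L) {
      tl$issues$file <- f
      issues <- bind_issues(issues, tl$issues)
    }
  }
  issues
}
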