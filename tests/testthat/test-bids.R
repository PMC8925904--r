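test_that("the fixture events excerpt reads with typed onsets and n/a handling", {
  tab <- wh_table()
  expect_s3_class(tab, "EventTable")
  expect_identical(nrow(tab$data), 8L)
  expect_identical(names(tab$data)[1:4],
                   c("onset", "duration", "sample", "event_type"))
  expect_identical(event_onsets(tab)[1], 0.400)
  expect_true(all(is.na(tab$data$duration)))      # every duration is n/a
  expect_identical(tab$data$rep_lag[6], "1")
  expect_identical(tab$data$stim_file[2], "f032.bmp")
  expect_false(is.unsorted(event_onsets(tab)))
})

test_that("tables without onset/duration or with unsorted onsets are flagged", {
  bad <- write_lines_tmp(c("time\tevent", "1.0\tx"), ext = ".tsv")
  expect_error(read_events_tsv(bad), "onset and duration")
  unsorted <- write_lines_tmp(
    c("onset\tduration", "2.0\tn/a", "1.0\tn/a"), ext = ".tsv")
  expect_warning(read_events_tsv(unsorted), "non-monotone")
})

test_that("sidecar classification is driven by entry shape alone", {
  sc <- wh_sidecar()
  kinds <- vapply(sc$columns, `[[`, character(1), "kind")
  expect_identical(kinds[["event_type"]], "categorical")
  expect_identical(kinds[["face_type"]], "categorical")
  expect_identical(kinds[["rep_status"]], "categorical")
  expect_identical(kinds[["rep_lag"]], "value")
  expect_identical(kinds[["stim_file"]], "value")
  expect_true(all(c("onset", "duration", "sample", "value") %in% sc$unannotated))
  expect_length(sc$definitions$entries, 15L)
  expect_identical(nrow(sc$issues), 0L)

  bad <- write_lines_tmp(
    '{"x": {"HED": "(Image, Pathname)"}, "y": {"HED": "(Label/#, ID/#)"}}',
    ext = ".json")
  sc2 <- read_sidecar(bad)
  expect_true(all(sc2$issues$code == "sidecar-format"))
  expect_identical(nrow(sc2$issues), 2L)

  misspelled <- write_lines_tmp(
    '{"x": {"HED": {"a": "Sensory-evnt"}}}', ext = ".json")
  sc3 <- read_sidecar(misspelled)
  expect_identical(sc3$issues$code, "unknown-tag")
})

test_that("sidecar inheritance merges per top-level key, deeper wins", {
  root <- tempfile("ds")
  dir.create(file.path(root, "sub-01"), recursive = TRUE)
  file.copy(hedlite_wh_sidecar_path(),
            file.path(root, "task-FacePerception_events.json"))
  ev <- file.path(root, "sub-01", "sub-01_task-FacePerception_run-1_events.tsv")
  file.copy(hedlite_wh_events_path(), ev)

  merged <- gather_sidecars(root, ev)
  expect_identical(merged$columns[["rep_status"]]$kind, "categorical")
  expect_length(merged$definitions$entries, 15L)

  # run-level override of one key
  writeLines('{"rep_status": {"HED": {"first_show": "Sensory-event"}}}',
             file.path(root, "sub-01", "sub-01_task-FacePerception_run-1_events.json"))
  merged2 <- gather_sidecars(root, ev)
  expect_identical(names(merged2$columns[["rep_status"]]$levels), "first_show")
  expect_identical(merged2$columns[["face_type"]]$kind, "categorical") # untouched

  empty_root <- tempfile("empty")
  dir.create(empty_root)
  ev2 <- file.path(empty_root, "x_events.tsv")
  file.copy(hedlite_wh_events_path(), ev2)
  expect_warning(sc <- gather_sidecars(empty_root, ev2), "no events.json")
  expect_length(sc$columns, 0L)
})

test_that("assembly reproduces the printed worked example", {
  asm <- wh_assembly()
  ev <- asm$events[[6]] # the bold row at onset 26.940
  expect_identical(ev$onset, 26.940)
  expected <- paste(
    "Sensory-event, Experimental-stimulus,",
    "(Def/Face-image, Onset), (Def/Blink-inhibition, Onset),",
    "(Def/Cross-only, Offset),",
    "Def/Famous-face-cond, Def/Immediate-repeat-cond,",
    "(Face, Item-interval/1), (Image, Pathname/f032.bmp)")
  expect_true(hed_equal(ev$hed, parse_hed(expected, hed_schema())))
  expect_setequal(names(ev$contributions),
                  c("event_type", "face_type", "rep_status", "rep_lag",
                    "stim_file"))

  press <- asm$events[[3]] # left press at 24.081: only event_type contributes
  expect_true(hed_equal(
    press$hed,
    parse_hed("Agent-action, Participant-response, Def/Press-left-finger",
              hed_schema())))
  expect_identical(names(press$contributions), "event_type")
})

test_that("value substitutions keep the cell text verbatim", {
  sch <- hed_schema()
  sc <- read_sidecar(write_lines_tmp(
    '{"amount": {"HED": "(Item-count/#)"}}', ext = ".json"))
  tab <- event_table(data.frame(onset = c("1.0", "2.0"),
                                duration = c("n/a", "n/a"),
                                amount = c("1", "1.0")))
  asm <- assemble_events(tab, sc)
  expect_identical(hed_to_string(asm$events[[1]]$hed), "(Item-count/1)")
  expect_identical(hed_to_string(asm$events[[2]]$hed), "(Item-count/1.0)")
})

test_that("assembly skips missing cells, flags missing levels, and is per-row", {
  sc <- wh_sidecar()
  tab <- wh_table()

  # unannotated table -> empty annotations
  bare <- event_table(tab$data[, c("onset", "duration")])
  asm0 <- assemble_events(bare, sc)
  expect_true(all(vapply(asm0$events, function(e)
    length(e$hed$items) == 0L, logical(1))))

  # unknown categorical level is an issue, not an error
  mut <- tab
  mut$data$event_type[3] <- "no_such_level"
  asm1 <- assemble_events(mut, sc)
  expect_identical(asm1$issues$code, "missing-level")
  expect_length(asm1$events, 8L)

  # per-row independence: permuting rows permutes assemblies identically
  perm <- c(3L, 1L, 2L, 6L, 5L, 4L, 8L, 7L)
  shuffled <- suppressWarnings(event_table(tab$data[perm, ]))
  asm_p <- assemble_events(shuffled, sc)
  asm <- assemble_events(tab, sc)
  for (i in seq_along(perm)) {
    expect_true(hed_equal(asm_p$events[[i]]$hed, asm$events[[perm[i]]]$hed))
  }

  # every assembled annotation re-parses to the same structure
  for (ev in asm$events) {
    expect_true(hed_equal(parse_hed(hed_to_string(ev$hed), hed_schema()),
                          ev$hed))
  }
})

test_that("events.tsv writing round-trips byte-for-byte", {
  tab <- wh_table()
  out <- tempfile(fileext = ".tsv")
  write_events_tsv(tab, out)
  expect_identical(readLines(out), readLines(hedlite_wh_events_path()))

  empty <- event_table(data.frame(onset = character(),
                                  duration = character()))
  out2 <- tempfile(fileext = ".tsv")
  write_events_tsv(empty, out2)
  expect_identical(readLines(out2), "onset\tduration")
})

test_that("sidecar writing preserves annotations through a round trip", {
  sc <- wh_sidecar()
  out <- tempfile(fileext = ".json")
  write_sidecar(sc, out)
  sc2 <- read_sidecar(out)
  expect_setequal(names(sc2$columns), names(sc$columns))
  expect_length(sc2$definitions$entries, length(sc$definitions$entries))
  for (lv in names(sc$columns$event_type$levels)) {
    expect_true(hed_equal(sc2$columns$event_type$levels[[lv]],
                          sc$columns$event_type$levels[[lv]]))
  }
})

test_that("dataset validation is clean on the fixture and catches mutations", {
  expect_identical(nrow(validate_dataset(hedlite_wh_root())), 0L)

  # mutated copy: drop one categorical level from the sidecar
  root <- tempfile("mut")
  dir.create(file.path(root, "sub-002"), recursive = TRUE)
  file.copy(hedlite_wh_events_path(),
            file.path(root, "sub-002", basename(hedlite_wh_events_path())))
  sidecar <- jsonlite::fromJSON(hedlite_wh_sidecar_path(),
                                simplifyVector = FALSE)
  sidecar$rep_status$HED$first_show <- NULL
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE),
             file.path(root, "task-FacePerception_events.json"))
  iss <- validate_dataset(root)
  expect_identical(iss$code, "missing-level")

  # mutated copy: misspell a tag
  sidecar2 <- jsonlite::fromJSON(hedlite_wh_sidecar_path(),
                                 simplifyVector = FALSE)
  sidecar2$face_type$HED$famous_face <- "Def/Famous-face-cond, Sensry-event"
  writeLines(jsonlite::toJSON(sidecar2, auto_unbox = TRUE),
             file.path(root, "task-FacePerception_events.json"))
  iss2 <- validate_dataset(root)
  expect_true("unknown-tag" %in% iss2$code)
})
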