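test_that("the fixture face-image process lasts 0.88 s", {
  tl <- resolve_processes(wh_assembly())
  fi <- tl$processes[tl$processes$definition == "Face-image", ]
  first <- fi[fi$onset == 23.870, ]
  expect_identical(nrow(first), 1L)
  expect_equal(first$offset, 24.750)
  expect_equal(first$duration, 0.88)
  expect_identical(first$closed_by, "explicit-offset")

  # the setup process spans the record and closes at the last marker
  ks <- tl$processes[tl$processes$definition == "Left-sym-cond", ]
  expect_identical(ks$closed_by, "end-of-record")
  expect_equal(ks$offset, 27.990)
  expect_identical(nrow(tl$issues), 0L)
})

test_that("re-onset closes the running process; lone offsets are issues", {
  stream <- data.frame(time = c(1, 2, 3),
                       def = "Proc-1",
                       marker = c("onset", "onset", "none"))
  tl <- resolve_processes(stream_to_events(stream))
  expect_identical(tl$processes$closed_by, c("next-onset", "end-of-record"))
  expect_equal(tl$processes$onset, c(1, 2))
  expect_equal(tl$processes$offset, c(2, 3))

  lone <- data.frame(time = c(1, 2), def = "Proc-1",
                     marker = c("none", "offset"))
  tl2 <- resolve_processes(stream_to_events(lone))
  expect_identical(nrow(tl2$processes), 0L)
  expect_identical(tl2$issues$code, "unmatched-offset")
})

test_that("an event can close and reopen the same definition", {
  sch <- hed_schema()
  mk <- function(t, txt) {
    structure(list(onset = t, sample = NA_real_, row = NA_integer_,
                   hed = parse_hed(txt, sch), contributions = list()),
              class = "AssembledEvent")
  }
  evs <- list(
    mk(1, "(Def/Cross-only, Onset)"),
    mk(2, "(Def/Cross-only, Offset), (Def/Cross-only, Onset)"),
    mk(3, "(Def/Cross-only, Offset)"))
  tl <- resolve_processes(evs)
  expect_identical(nrow(tl$processes), 2L)
  expect_identical(tl$processes$closed_by,
                   c("explicit-offset", "explicit-offset"))
  expect_identical(nrow(tl$issues), 0L)
})

test_that("event context lists strictly enclosing processes only", {
  asm <- wh_assembly()
  tl <- resolve_processes(asm)
  ctx <- insert_context(asm, tl)

  # the left press at 24.081 is inside Face-image [23.870, 24.750)
  press <- ctx$events[[3]]
  ctx_group <- Filter(function(it)
    inherits(it, "hed_group") && tolower(it$items[[1]]$name) == "event-context",
    press$hed$items)
  expect_length(ctx_group, 1L)
  in_ctx <- vapply(ctx_group[[1]]$items[-1], `[[`, character(1), "value")
  expect_true(all(c("Face-image", "Blink-inhibition", "Fixation-task",
                    "Left-sym-cond") %in% in_ctx))

  # boundary exclusion: the 26.940 event closes Cross-only and opens
  # Face-image; neither belongs to its own context
  face <- ctx$events[[6]]
  g <- Filter(function(it)
    inherits(it, "hed_group") && tolower(it$items[[1]]$name) == "event-context",
    face$hed$items)
  in_ctx6 <- vapply(g[[1]]$items[-1], `[[`, character(1), "value")
  expect_false("Cross-only" %in% in_ctx6)
  expect_false("Face-image" %in% in_ctx6)
  expect_true("Fixation-task" %in% in_ctx6)

  # events with no enclosing process gain nothing: the setup event at 0.400
  setup <- ctx$events[[1]]
  expect_true(hed_equal(setup$hed, asm$events[[1]]$hed))

  # context insertion is reversible and does not move process boundaries
  stripped <- hedlite:::strip_context(ctx)
  for (i in seq_along(asm$events)) {
    expect_identical(hed_to_string(stripped[[i]]$hed),
                     hed_to_string(asm$events[[i]]$hed))
  }
  tl2 <- resolve_processes(ctx)
  expect_equal(tl2$processes[c("definition", "onset", "offset")],
               tl$processes[c("definition", "onset", "offset")])
})

test_that("the resolver matches the brute-force sweep oracle", {
  set.seed(303)
  for (i in 1:20) {
    stream <- random_stream(n_markers = sample(20:200, 1L),
                            n_defs = sample(2:10, 1L))
    tl <- resolve_processes(stream_to_events(stream))
    oracle <- sweep_oracle(stream)
    got <- tl$processes
    rownames(got) <- NULL
    expect_equal(got, oracle, label = sprintf("stream %d", i))
    # unmatched offsets agree too
    n_unmatched <- 0L
    for (d in unique(stream$def)) {
      sub <- stream[stream$def == d & stream$marker != "none", , drop = FALSE]
      open <- FALSE
      for (m in sub$marker[order(sub$time)]) {
        if (m == "onset") open <- TRUE
        else { if (!open) n_unmatched <- n_unmatched + 1L; open <- FALSE }
      }
    }
    expect_identical(nrow(tl$issues), n_unmatched)
  }
})

test_that("instantaneous events do not change covered durations", {
  set.seed(404)
  stream <- random_stream(n_markers = 80, n_defs = 4)
  stream <- stream[stream$marker != "none", ]
  base <- resolve_processes(stream_to_events(stream))
  covered <- function(tl) tapply(tl$processes$duration,
                                 tl$processes$definition, sum)
  extra <- rbind(stream,
                 data.frame(time = round(runif(30, min(stream$time),
                                               max(stream$time)), 3),
                            def = "ignored", marker = "none"))
  with_inst <- resolve_processes(stream_to_events(extra))
  expect_equal(covered(with_inst), covered(base))
})
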