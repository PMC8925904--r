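test_that("the printed design definitions yield two factors of three levels", {
  sch <- hed_schema()
  reg <- extract_definitions(lapply(design_definition_texts, parse_hed,
                                    schema = sch))
  factors <- extract_condition_variables(reg)
  expect_length(factors, 2L)
  byname <- setNames(factors, vapply(factors, `[[`, character(1), "factor_name"))
  expect_setequal(names(byname), c("Face-type", "Repetition-status"))
  expect_setequal(byname[["Face-type"]]$levels,
                  c("Famous-face-cond", "Unfamiliar-face-cond",
                    "Scrambled-face-cond"))
  expect_length(byname[["Repetition-status"]]$levels, 3L)
})

test_that("extraction covers setup factors and is event-order independent", {
  reg <- wh_sidecar()$definitions
  factors <- extract_condition_variables(reg)
  fnames <- vapply(factors, `[[`, character(1), "factor_name")
  expect_setequal(fnames, c("Face-type", "Repetition-status", "Key-assignment"))
  ka <- factors[[match("Key-assignment", fnames)]]
  expect_setequal(ka$levels, c("Left-sym-cond", "Right-sym-cond"))

  # bare Condition-variable: the definition is its own singleton factor
  sch <- hed_schema()
  reg2 <- extract_definitions(list(parse_hed(
    "(Definition/Lone-cond, (Condition-variable, Circle))", sch)))
  f2 <- extract_condition_variables(reg2)
  expect_length(f2, 1L)
  expect_identical(f2[[1]]$factor_name, "Lone-cond")
  expect_identical(f2[[1]]$levels, "Lone-cond")

  expect_length(extract_condition_variables(
    extract_definitions(list())), 0L)
})

test_that("the fixture design matrix assigns column and row factors", {
  asm <- wh_assembly()
  sc <- wh_sidecar()
  tl <- resolve_processes(asm)
  factors <- extract_condition_variables(sc$definitions)
  dm <- design_matrix(asm, tl, factors)

  enc <- setNames(vapply(dm$factors, `[[`, character(1), "encoding"),
                  vapply(dm$factors, `[[`, character(1), "factor_name"))
  expect_identical(enc[["Face-type"]], "column")
  expect_identical(enc[["Repetition-status"]], "column")
  expect_identical(enc[["Key-assignment"]], "row")

  a <- dm$assignments
  row6 <- a[a$onset == 26.940, ]
  expect_identical(row6[["Face-type"]], "Famous-face-cond")
  expect_identical(row6[["Repetition-status"]], "Immediate-repeat-cond")

  # the row-encoded setup factor spans every event of the recording
  expect_identical(a[["Key-assignment"]], rep("Left-sym-cond", 8L))

  # events without level references have missing cells
  circles <- a[c(4, 7), ]
  expect_true(all(is.na(circles[["Face-type"]])))
  expect_identical(nrow(dm$issues), 0L)

  # every assigned level resolves to a definition carrying the factor tag
  for (f in dm$factors) {
    assigned <- unique(stats::na.omit(a[[f$factor_name]]))
    expect_true(all(assigned %in% f$levels))
  }
})

test_that("column and row encodings of a condition agree", {
  # rebuild the fixture with key assignment as a column instead of a
  # setup meta-event and compare the extracted assignment
  sch <- hed_schema()
  tab <- wh_table()
  data <- tab$data[-1, ] # drop the setup meta-event
  data$key_assignment <- "left_sym"
  col_tab <- event_table(data)

  sidecar <- jsonlite::fromJSON(hedlite_wh_sidecar_path(),
                                simplifyVector = FALSE)
  sidecar$event_type$HED$setup_left_sym <- NULL
  sidecar$event_type$HED$setup_right_sym <- NULL
  sidecar$key_assignment <- list(HED = list(
    left_sym = "Def/Left-sym-cond", right_sym = "Def/Right-sym-cond"))
  sc2 <- hedlite:::sidecar_from_list(sidecar, sch)

  asm2 <- assemble_events(col_tab, sc2)
  tl2 <- resolve_processes(asm2)
  dm2 <- design_matrix(asm2, tl2,
                       extract_condition_variables(sc2$definitions))

  asm1 <- wh_assembly()
  dm1 <- design_matrix(asm1, resolve_processes(asm1),
                       extract_condition_variables(wh_sidecar()$definitions))

  # same events (minus the setup row), same Key-assignment level everywhere
  a1 <- dm1$assignments[-1, ]
  a2 <- dm2$assignments
  expect_identical(a2[["Key-assignment"]], a1[["Key-assignment"]])
  expect_identical(a2[["Face-type"]], a1[["Face-type"]])
  enc2 <- vapply(dm2$factors, `[[`, character(1), "encoding")
  expect_true("column" %in% enc2)
})

test_that("level conflicts are issues, not errors", {
  sch <- hed_schema()
  sc <- wh_sidecar()
  conflict <- structure(list(
    onset = 1, sample = NA_real_, row = 1L,
    hed = parse_hed("Def/Famous-face-cond, Def/Unfamiliar-face-cond", sch),
    contributions = list()), class = "AssembledEvent")
  tl <- resolve_processes(list(conflict))
  dm <- design_matrix(list(conflict), tl,
                      extract_condition_variables(sc$definitions))
  expect_identical(dm$issues$code, "level-conflict")
  expect_false(is.na(dm$assignments[["Face-type"]][1]))
})

test_that("summaries report levels, counts and crossed cells", {
  asm <- wh_assembly()
  sc <- wh_sidecar()
  dm <- design_matrix(asm, resolve_processes(asm),
                      extract_condition_variables(sc$definitions))
  s <- summarize_design(dm)
  expect_identical(sort(s$factors$n_levels), c(2L, 3L, 3L))
  cell <- s$cells[["Face-type x Repetition-status"]]
  expect_identical(dim(cell), c(3L, 3L))
  expect_identical(sum(cell), 2L) # two face presentations in the excerpt
  expect_identical(cell["Famous-face-cond", "Immediate-repeat-cond"], 1L)

  empty <- design_matrix(list(), resolve_processes(list()), list())
  s0 <- summarize_design(empty)
  expect_identical(nrow(s0$factors), 0L)
  expect_identical(nrow(s0$level_counts), 0L)
})
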