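# Lint-style issue collection: issues are data, not conditions, so
# validation can aggregate across files and keep going.

empty_issues <- function(cols = c("file", "row", "column", "code", "message")) {
  out <- stats::setNames(rep(list(character()), length(cols)), cols)
  as.data.frame(out, stringsAsFactors = FALSE)
}

add_issue <- function(issues, ...) {
  vals <- list(...)
  row <- stats::setNames(as.list(rep(NA_character_, ncol(issues))),
                         names(issues))
  for (nm in names(vals)) row[[nm]] <- as.character(vals[[nm]])
  rbind(issues, as.data.frame(row, stringsAsFactors = FALSE))
}

bind_issues <- function(...) {
  dfs <- Filter(Negate(is.null), list(...))
  dfs <- Filter(function(d) is.data.frame(d), dfs)
  if (length(dfs) == 0L) return(empty_issues())
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA_character_
    d[, cols, drop = FALSE]
  })
  do.call(rbind, dfs)
}
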