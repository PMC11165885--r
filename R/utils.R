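# Internal helpers shared across pipeline stages.

# Validation findings are collected in a flat data frame rather than raised,
# so a whole intake file can be checked in one pass and reported to the
# workshop moderator at once.
new_report <- function() {
  data.frame(
    severity = character(0), stage = character(0), id = character(0),
    message = character(0), stringsAsFactors = FALSE
  )
}

report_add <- function(report, severity, stage, id, message) {
  rbind(report, data.frame(
    severity = severity, stage = stage, id = id, message = message,
    stringsAsFactors = FALSE
  ))
}

report_merge <- function(...) do.call(rbind, list(...))

#' Extract the errors from a validation report
#'
#' @param report A validation report data frame as returned by
#'   [validate_workshop()], [validate_criteria()] or [validate_scores()].
#' @return The subset of rows with `severity == "error"`.
#' @export
report_errors <- function(report) {
  report[report$severity == "error", , drop = FALSE]
}

stop_if_report_errors <- function(report, context) {
  errs <- report_errors(report)
  if (nrow(errs) > 0L) {
    stop(context, ": ", paste(errs$message, collapse = "; "), call. = FALSE)
  }
  invisible(report)
}

# Deterministic full-precision text round-trip for doubles: 17 significant
# digits round-trip IEEE doubles exactly through read.csv.
fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- NA_character_
  gsub(" ", "", out, fixed = TRUE)
}

write_workshop_table <- function(df, path) {
  out <- df
  quoted <- which(vapply(out, is.character, logical(1)))
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = unname(quoted), na = "")
  invisible(path)
}

read_workshop_table <- function(path, required_cols, file_label = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop(
      file_label, ": missing required column(s): ",
      paste(missing, collapse = ", "), call. = FALSE
    )
  }
  df
}

# Judgment values travel through files as "4" or "1/4"; parse and format
# without ever round-tripping a reciprocal through a truncated decimal.
parse_judgment_value <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  frac <- grepl("^1\\s*/\\s*[0-9]+$", x)
  out[frac] <- 1 / as.numeric(sub("^1\\s*/\\s*", "", x[frac]))
  plain <- !frac & grepl("^[0-9.]+$", x)
  out[plain] <- suppressWarnings(as.numeric(x[plain]))
  out
}

format_judgment_value <- function(v) {
  ifelse(v >= 1, as.character(round(v)), paste0("1/", round(1 / v)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
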