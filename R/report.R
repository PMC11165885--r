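#' Render the end-of-workshop summary report
#'
#' Compiles the findings of all groups into one human-readable summary: the
#' top-ranked items per stream by combined rank, every group's criterion
#' weights with consistency-ratio flags, the ties that still require
#' stakeholder consensus, and any degenerate groups (all composites equal).
#' Sections with nothing to report state "none" explicitly.
#'
#' @param bundle An `oh_bundle` whose ranking stage has completed.
#' @param top_n How many top-ranked items to list per stream.
#' @return An object of class `oh_report`: a list with `text` and `html`
#'   character vectors (one element per line).
#' @seealso [write_report()]
#' @export
render_report <- function(bundle, top_n = 5L) {
  if (length(bundle$rankings) == 0L) {
    stop("cannot render report: ranking stage has not run", call. = FALSE)
  }
  lines <- c(
    "One Health prioritisation workshop — summary report",
    strrep("=", 51),
    sprintf("Groups: %s", paste(bundle$config$groups, collapse = ", ")),
    sprintf("Combined rank method: %s (engine default; the cross-group rule is a documented choice)",
      bundle$config$combined_rank_method),
    ""
  )

  for (s in names(bundle$rankings)) {
    tab <- bundle$rankings[[s]]
    lines <- c(lines, sprintf("Stream: %s", s), strrep("-", 20))

    lines <- c(lines, sprintf("Top %d by combined rank:", top_n))
    head_tab <- utils::head(tab, top_n)
    tie_lab <- head_tab$tie_group
    tie_lab[is.na(tie_lab)] <- ""
    lines <- c(lines, sprintf(
      "  %2d. %-20s combined score %.4f%s",
      head_tab$combined_rank, head_tab$item, head_tab$combined_score,
      ifelse(nzchar(tie_lab), paste0("  [tie ", tie_lab, "]"), "")
    ))

    if (!is.null(bundle$weights)) {
      ws <- bundle$weights[bundle$weights$stream == s, , drop = FALSE]
      lines <- c(lines, "Criterion weights per group:")
      for (g in unique(ws$group)) {
        wg <- ws[ws$group == g, , drop = FALSE]
        flag <- if (any(wg$cr_flag)) "  ** CR > 0.10 — judgments inconsistent, review with the group **" else ""
        lines <- c(lines, sprintf(
          "  %s: %s  (CR = %.3f)%s", g,
          paste(sprintf("%s = %.4f", wg$criterion, wg$weight), collapse = ", "),
          wg$cr[1L], flag
        ))
      }
    }

    # reconstruct from the table columns when the ranking was reloaded from
    # disk and the in-memory attributes are gone
    ties <- attr(tab, "tie_sets") %||%
      unname(Filter(function(v) length(v) > 1L, split(tab$item, tab$combined_rank)))
    lines <- c(lines, "Ties requiring consensus:")
    lines <- c(lines, if (length(ties) == 0L) "  none" else
      vapply(ties, function(t) paste0("  { ", paste(t, collapse = ", "), " }"), character(1)))

    dg <- attr(tab, "degenerate_groups") %||%
      Filter(nzchar, strsplit(as.character(tab$degenerate_groups[1L] %||% ""), ";")[[1L]])
    if (length(dg) == 1L && is.na(dg)) dg <- character(0)
    lines <- c(lines, "Degenerate groups (all composites equal; normalised scores are all 0):")
    lines <- c(lines, if (length(dg) == 0L) "  none" else paste0("  ", dg))
    lines <- c(lines, "")
  }

  html <- c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    "<title>One Health prioritisation report</title></head><body>",
    "<pre>", escape_html(lines), "</pre>", "</body></html>"
  )
  structure(list(text = lines, html = html), class = "oh_report")
}

escape_html <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' @export
print.oh_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' @rdname render_report
#' @param report An `oh_report` object.
#' @param dir Directory to write `report.txt` and `report.html` into.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report$text, file.path(dir, BUNDLE_FILES$report_txt))
  writeLines(report$html, file.path(dir, BUNDLE_FILES$report_html))
  invisible(dir)
}
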