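#' Tally inclusion votes
#'
#' Step 1 of the workflow is an individual activity: every participant marks
#' each candidate risk factor or disease for inclusion in the prioritisation
#' exercise or not. Votes are tallied by summing the inclusion marks per item;
#' an item a participant never voted on counts as an exclusion, and all votes
#' carry equal weight regardless of the voter's sector.
#'
#' @param votes Data frame with columns `participant`, `stream`, `item`,
#'   `include` (logical or 0/1). At most one record per (participant, item).
#' @param catalogue Candidate catalogue data frame (`stream`, `id`, `label`).
#' @return A data frame with columns `stream`, `item`, `votes`, covering every
#'   catalogue item (zero counts included), sorted by stream, votes
#'   descending, then item id ascending.
#' @examples
#' cat <- data.frame(stream = "risk", id = c("a", "b"), label = c("A", "B"))
#' v <- data.frame(
#'   participant = c("p1", "p2", "p3", "p1"), stream = "risk",
#'   item = c("a", "a", "a", "b"), include = c(1, 1, 1, 1)
#' )
#' tally_votes(v, cat)
#' @export
tally_votes <- function(votes, catalogue) {
  unknown <- setdiff(unique(votes$item), catalogue$id)
  if (length(unknown) > 0L) {
    stop("vote(s) reference unknown item id(s): ",
      paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- paste(votes$participant, votes$item, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- votes$item[duplicated(key)]
    stop("duplicate vote record(s) for item(s): ",
      paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  inc <- votes[as.logical(votes$include), , drop = FALSE]
  counts <- table(factor(inc$item, levels = catalogue$id))
  out <- data.frame(
    stream = catalogue$stream,
    item = catalogue$id,
    votes = as.integer(counts[catalogue$id]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$stream, -out$votes, out$item), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the shortlist from vote counts
#'
#' Keeps every item whose vote count strictly exceeds the k-th largest count,
#' plus *all* items tied at the k-th count — a tied candidate is never
#' silently dropped, because resolving the final list is a stakeholder
#' decision, not the engine's. The shortlist may therefore exceed `k`; when it
#' does, `tie_at_cutoff` is set. Items with zero votes are never shortlisted;
#' if fewer than `k` items received any vote, all voted items are returned
#' with a warning in the attached report.
#'
#' @param counts Either a named integer vector (item -> votes) or a data frame
#'   with columns `item` and `votes` for a single stream.
#' @param k Requested shortlist size (>= 1).
#' @return An object of class `oh_shortlist`: a data frame (`item`, `votes`)
#'   sorted by votes descending then item ascending, with attributes `cutoff`
#'   (`k`), `tie_at_cutoff` (logical) and `report` (warnings, if any).
#' @examples
#' sl <- select_top(c(A = 5, B = 3, C = 3, D = 1), k = 2)
#' sl$item                  # A, B, C: the tie at 3 votes is kept whole
#' attr(sl, "tie_at_cutoff")
#' @export
select_top <- function(counts, k) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(as.integer(counts$votes), counts$item)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)

  report <- new_report()
  voted <- counts[counts >= 1L]
  if (length(voted) == 0L) {
    sel <- voted
    report <- report_add(report, "warning", "selection", "k",
      "no item received any inclusion vote; shortlist is empty")
  } else if (k > length(voted)) {
    sel <- voted
    report <- report_add(report, "warning", "selection", "k",
      sprintf(
        "requested shortlist size %d exceeds the %d item(s) with votes; keeping all voted items",
        k, length(voted)
      ))
  } else {
    cutoff_count <- sort(voted, decreasing = TRUE)[k]
    sel <- voted[voted >= cutoff_count]
  }

  out <- data.frame(
    item = names(sel), votes = as.integer(sel),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$votes, out$item), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    cutoff = k,
    tie_at_cutoff = nrow(out) > k,
    report = report,
    class = c("oh_shortlist", "data.frame")
  )
}

#' @export
print.oh_shortlist <- function(x, ...) {
  cat(sprintf(
    "Shortlist: %d item(s) (requested k = %d%s)\n",
    nrow(x), attr(x, "cutoff"),
    if (isTRUE(attr(x, "tie_at_cutoff"))) ", enlarged by a tie at the cutoff" else ""
  ))
  print.data.frame(x, ...)
  rep <- attr(x, "report")
  if (!is.null(rep) && nrow(rep) > 0L) {
    cat("Notes:\n")
    for (m in rep$message) cat("  -", m, "\n")
  }
  invisible(x)
}
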