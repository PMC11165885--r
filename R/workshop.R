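#' Workshop configuration
#'
#' Bundles the structural parameters of a prioritisation workshop: the group
#' ids, the target number of participants per group, the requested shortlist
#' sizes per stream, and the candidate-catalogue cap. The design constraints
#' are those of the co-creation workshop format: at most 50 candidate risk
#' factors and 50 candidate diseases, at most five scoring groups, groups of
#' roughly five to seven participants.
#'
#' @param groups Character vector of group ids (1-5 groups).
#' @param participants_per_group Target participants per group.
#' @param shortlist_size_risk,shortlist_size_disease Requested shortlist sizes
#'   (`k`) per stream; ties at the cutoff may enlarge the actual shortlist.
#' @param catalogue_limit Maximum number of candidates per stream (default 50).
#' @param tie_policy How rank ties are handled downstream: `"report"` leaves
#'   them annotated for consensus; `"manual-override"` signals that an
#'   override file will be applied.
#' @param combined_rank_method Cross-group combination rule; currently
#'   `"mean-normalised"` (mean of per-group normalised scores).
#' @return An object of class `oh_config` (a named list).
#' @examples
#' cfg <- workshop_config(groups = c("G1", "G2", "G3"))
#' cfg$catalogue_limit
#' @export
workshop_config <- function(groups = c("G1", "G2", "G3", "G4"),
                            participants_per_group = 6L,
                            shortlist_size_risk = 10L,
                            shortlist_size_disease = 10L,
                            catalogue_limit = 50L,
                            tie_policy = c("report", "manual-override"),
                            combined_rank_method = "mean-normalised") {
  tie_policy <- match.arg(tie_policy)
  structure(
    list(
      groups = as.character(groups),
      participants_per_group = as.integer(participants_per_group),
      shortlist_size_risk = as.integer(shortlist_size_risk),
      shortlist_size_disease = as.integer(shortlist_size_disease),
      catalogue_limit = as.integer(catalogue_limit),
      tie_policy = tie_policy,
      combined_rank_method = combined_rank_method
    ),
    class = "oh_config"
  )
}

#' @export
print.oh_config <- function(x, ...) {
  cat("Workshop configuration\n")
  cat("  groups:           ", paste(x$groups, collapse = ", "), "\n")
  cat("  participants/grp: ", x$participants_per_group, "\n")
  cat("  shortlist k:      ", x$shortlist_size_risk, "(risk),",
      x$shortlist_size_disease, "(disease)\n")
  cat("  catalogue limit:  ", x$catalogue_limit, "per stream\n")
  cat("  combined rank:    ", x$combined_rank_method, "\n")
  invisible(x)
}

#' Validate workshop intake
#'
#' Side-effect-free structural validation of the workshop setup. Violations of
#' hard design constraints (more than five groups, more than
#' `catalogue_limit` candidates in a stream, malformed criteria, duplicate
#' candidate ids) are errors. Group sizes outside the 5-7 participant band are
#' reported as warnings only, since the workshop format tolerates some
#' variation in panel size.
#'
#' @param config An [workshop_config()] object.
#' @param criteria A criterion catalogue data frame.
#' @param catalogue Candidate catalogue data frame with columns `stream`,
#'   `id`, `label` (and optionally `source`, `"catalogue"` or
#'   `"participant-added"`).
#' @param enforce_criteria_counts Passed to [validate_criteria()].
#' @return A validation report data frame (`severity`, `stage`, `id`,
#'   `message`). An empty error subset means all invariants hold.
#' @examples
#' cfg <- workshop_config(groups = c("G1", "G2"))
#' cat50 <- data.frame(
#'   stream = "risk", id = sprintf("rf%02d", 1:50),
#'   label = sprintf("Risk factor %02d", 1:50)
#' )
#' nrow(report_errors(validate_workshop(cfg, default_criteria(), cat50)))
#' @export
validate_workshop <- function(config, criteria, catalogue,
                              enforce_criteria_counts = TRUE) {
  report <- validate_criteria(criteria, enforce_counts = enforce_criteria_counts)

  n_groups <- length(config$groups)
  if (n_groups < 1L || n_groups > 5L) {
    report <- report_add(report, "error", "config",
      paste(config$groups, collapse = ","),
      sprintf("group count must be 1-5, found %d", n_groups))
  }
  if (anyDuplicated(config$groups)) {
    dup <- unique(config$groups[duplicated(config$groups)])
    report <- report_add(report, "error", "config", paste(dup, collapse = ","),
      sprintf("duplicate group id(s): %s", paste(dup, collapse = ", ")))
  }
  if (config$participants_per_group < 5L || config$participants_per_group > 7L) {
    report <- report_add(report, "warning", "config", "participants_per_group",
      sprintf(
        "participants per group is %d; the workshop format targets 5-7",
        config$participants_per_group
      ))
  }

  for (s in unique(catalogue$stream)) {
    cs <- catalogue[catalogue$stream == s, , drop = FALSE]
    if (nrow(cs) > config$catalogue_limit) {
      report <- report_add(report, "error", "catalogue", s,
        sprintf(
          "stream %s: %d candidates exceed the catalogue limit of %d",
          s, nrow(cs), config$catalogue_limit
        ))
    }
    dup <- unique(cs$id[duplicated(cs$id)])
    for (d in dup) {
      report <- report_add(report, "error", "catalogue", d,
        sprintf("duplicate candidate id '%s' in stream %s", d, s))
    }
    blank <- cs$id[is.na(cs$id) | !nzchar(trimws(cs$id))]
    if (length(blank) > 0L) {
      report <- report_add(report, "error", "catalogue", s,
        sprintf("stream %s: %d candidate(s) with empty id", s, length(blank)))
    }
  }
  report
}
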