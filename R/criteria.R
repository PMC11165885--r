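#' Criterion catalogues
#'
#' A criterion catalogue defines, for each prioritisation stream, the scoring
#' dimensions of the workshop. The risk stream combines three weighted
#' likelihood criteria (scope of exposure, frequency of exposure, mitigation
#' strategy) with one unweighted multiplier, the potential for outbreak. The
#' disease stream combines four weighted threat criteria (severity,
#' prevalence, transmissibility, preventive and control strategy) with the
#' disease-burden multiplier. Each criterion carries a three-level ordinal
#' rubric mapped to scores 1, 2, 3.
#'
#' Note the deliberate directionality of the two strategy criteria: score 3
#' means *no* strategy is available, so a larger score is always the riskier
#' (worse) situation on every criterion.
#'
#' @param path Path to a criteria catalogue in YAML form. `default_criteria()`
#'   reads the catalogue shipped with the package.
#' @return A data frame with one row per criterion and columns `stream`
#'   (`"risk"` or `"disease"`), `id`, `label`, `role` (`"weighted"` or
#'   `"multiplier"`), `question` and `level_1`, `level_2`, `level_3` (the
#'   rubric descriptions for scores 1-3).
#' @examples
#' crit <- default_criteria()
#' subset(crit, stream == "risk")$id
#' @seealso [validate_criteria()]
#' @export
default_criteria <- function() {
  read_criteria(system.file("extdata", "default_criteria.yml",
    package = "ohrank", mustWork = TRUE
  ))
}

#' @rdname default_criteria
#' @export
read_criteria <- function(path) {
  raw <- yaml::read_yaml(path)
  streams <- intersect(c("risk", "disease"), names(raw))
  if (length(streams) == 0L) {
    stop("criteria file has no 'risk' or 'disease' section: ", path, call. = FALSE)
  }
  rows <- lapply(streams, function(s) {
    do.call(rbind, lapply(raw[[s]], function(cr) {
      rub <- as.character(cr$rubric %||% character(0))
      length(rub) <- 3L
      data.frame(
        stream = s,
        id = as.character(cr$id %||% NA_character_),
        label = as.character(cr$label %||% cr$id %||% NA_character_),
        role = as.character(cr$role %||% "weighted"),
        question = as.character(cr$question %||% ""),
        level_1 = rub[1L], level_2 = rub[2L], level_3 = rub[3L],
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate a criterion catalogue
#'
#' Checks the structural invariants of a criterion catalogue: every rubric has
#' exactly three non-empty levels, each stream has exactly one multiplier
#' criterion, and (unless `enforce_counts = FALSE`, for locally adapted
#' criterion sets) the risk stream has exactly 3 and the disease stream
#' exactly 4 weighted criteria.
#'
#' @param criteria A criterion catalogue data frame (see [default_criteria()]).
#' @param enforce_counts Enforce the default 3+1 / 4+1 stream structure.
#' @return A validation report data frame with columns `severity`, `stage`,
#'   `id`, `message`; empty when all invariants hold.
#' @export
validate_criteria <- function(criteria, enforce_counts = TRUE) {
  report <- new_report()
  for (s in unique(criteria$stream)) {
    cs <- criteria[criteria$stream == s, , drop = FALSE]
    dup <- unique(cs$id[duplicated(cs$id)])
    for (d in dup) {
      report <- report_add(report, "error", "criteria", d,
        sprintf("duplicate criterion id '%s' in stream %s", d, s))
    }
    bad_role <- cs$id[!cs$role %in% c("weighted", "multiplier")]
    for (b in bad_role) {
      report <- report_add(report, "error", "criteria", b,
        sprintf("criterion '%s': role must be 'weighted' or 'multiplier'", b))
    }
    levels <- as.matrix(cs[, c("level_1", "level_2", "level_3")])
    incomplete <- cs$id[apply(levels, 1L, function(r) any(is.na(r) | !nzchar(trimws(r))))]
    for (b in incomplete) {
      report <- report_add(report, "error", "criteria", b,
        sprintf("criterion '%s': rubric must have exactly 3 non-empty levels", b))
    }
    n_mult <- sum(cs$role == "multiplier")
    if (n_mult != 1L) {
      report <- report_add(report, "error", "criteria", s,
        sprintf("stream %s: expected exactly 1 multiplier criterion, found %d", s, n_mult))
    }
    if (enforce_counts) {
      want <- if (s == "risk") 3L else 4L
      n_w <- sum(cs$role == "weighted")
      if (n_w != want) {
        report <- report_add(report, "error", "criteria", s,
          sprintf("stream %s: expected %d weighted criteria, found %d", s, want, n_w))
      }
    }
  }
  report
}

#' Criterion ids by role
#'
#' `weighted_criteria()` returns the ids of a stream's weighted criteria in
#' catalogue order (the order pairwise judgments are elicited in);
#' `multiplier_criterion()` returns the stream's single unweighted multiplier
#' criterion.
#'
#' @param criteria A criterion catalogue data frame.
#' @param stream `"risk"` or `"disease"`.
#' @return Character vector of criterion ids.
#' @export
weighted_criteria <- function(criteria, stream) {
  criteria$id[criteria$stream == stream & criteria$role == "weighted"]
}

#' @rdname weighted_criteria
#' @export
multiplier_criterion <- function(criteria, stream) {
  criteria$id[criteria$stream == stream & criteria$role == "multiplier"]
}
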