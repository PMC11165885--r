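#' Validate an ordinal score sheet
#'
#' Every group must score every shortlisted item of a stream on every
#' criterion of that stream (weighted criteria and the multiplier), with one
#' integer score in {1, 2, 3} per cell. Missing cells, out-of-range or
#' non-integer values, scores for items not on the shortlist, unknown
#' criteria and duplicate cells are all reported as errors; nothing is
#' imputed — scoring discrepancies are resolved by group consensus, not by
#' the engine.
#'
#' @param scores Data frame with columns `group`, `stream`, `item`,
#'   `criterion`, `value`.
#' @param shortlists Named list of shortlists per stream (each a data frame
#'   with an `item` column, e.g. from [select_top()]).
#' @param criteria Criterion catalogue data frame.
#' @param groups Character vector of group ids expected to have scored.
#' @return A validation report data frame (`severity`, `stage`, `id`,
#'   `message`); empty when the sheet is complete and valid.
#' @export
validate_scores <- function(scores, shortlists, criteria, groups) {
  report <- new_report()
  for (s in names(shortlists)) {
    items <- shortlists[[s]]$item
    crits <- criteria$id[criteria$stream == s]
    ss <- scores[scores$stream == s, , drop = FALSE]

    extra_item <- setdiff(unique(ss$item), items)
    for (it in extra_item) {
      report <- report_add(report, "error", "scores", it,
        sprintf("stream %s: score present for item '%s' not on the shortlist", s, it))
    }
    extra_crit <- setdiff(unique(ss$criterion), crits)
    for (cr in extra_crit) {
      report <- report_add(report, "error", "scores", cr,
        sprintf("stream %s: score uses unknown criterion '%s'", s, cr))
    }
    extra_grp <- setdiff(unique(ss$group), groups)
    for (g in extra_grp) {
      report <- report_add(report, "error", "scores", g,
        sprintf("stream %s: score from unknown group '%s'", s, g))
    }

    bad <- which(!(ss$value %in% c(1L, 2L, 3L)) | ss$value != round(ss$value))
    for (i in bad) {
      report <- report_add(report, "error", "scores", ss$item[i],
        sprintf(
          "stream %s: invalid score %s for item '%s', criterion '%s', group %s (must be 1, 2 or 3)",
          s, as.character(ss$value[i]), ss$item[i], ss$criterion[i], ss$group[i]
        ))
    }

    key <- paste(ss$group, ss$item, ss$criterion, sep = "\r")
    dup <- which(duplicated(key))
    for (i in dup) {
      report <- report_add(report, "error", "scores", ss$item[i],
        sprintf(
          "stream %s: duplicate score for item '%s', criterion '%s', group %s",
          s, ss$item[i], ss$criterion[i], ss$group[i]
        ))
    }

    want <- expand.grid(
      group = groups, item = items, criterion = crits,
      stringsAsFactors = FALSE
    )
    want_key <- paste(want$group, want$item, want$criterion, sep = "\r")
    miss <- want[!(want_key %in% key), , drop = FALSE]
    for (i in seq_len(nrow(miss))) {
      report <- report_add(report, "error", "scores", miss$item[i],
        sprintf(
          "stream %s: missing score for item '%s', criterion '%s', group %s",
          s, miss$item[i], miss$criterion[i], miss$group[i]
        ))
    }
  }
  report
}

# Shared core of both composite scores: weighted sum of the ordinal criterion
# scores times the raw (unweighted) 1-3 multiplier. With weights summing to 1
# and scores in [1,3] the composite lies in [1,9].
composite_value <- function(scores, weights, multiplier, n_expected, what) {
  if (inherits(weights, "oh_weights")) weights <- weights$weights
  if (length(weights) != n_expected) {
    stop(what, ": expected ", n_expected, " weighted criteria, got ",
      length(weights), " weights", call. = FALSE)
  }
  if (!is.null(names(scores)) && !is.null(names(weights))) {
    if (!setequal(names(scores), names(weights))) {
      stop(what, ": criterion mismatch between scores (",
        paste(names(scores), collapse = ","), ") and weights (",
        paste(names(weights), collapse = ","), ")", call. = FALSE)
    }
    scores <- scores[names(weights)]
  } else if (length(scores) != length(weights)) {
    stop(what, ": ", length(scores), " scores for ", length(weights),
      " weights", call. = FALSE)
  }
  if (any(!(scores %in% c(1L, 2L, 3L)))) {
    stop(what, ": criterion scores must be integers in {1,2,3}", call. = FALSE)
  }
  if (!(multiplier %in% c(1L, 2L, 3L))) {
    stop(what, ": multiplier score must be an integer in {1,2,3}", call. = FALSE)
  }
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-9) {
    stop(what, ": weights must be positive and sum to 1", call. = FALSE)
  }
  ws <- sum(as.numeric(scores) * as.numeric(weights))
  list(
    weighted_sum = ws,
    multiplier = as.integer(multiplier),
    value = ws * multiplier
  )
}

#' Composite risk-impact score for one risk factor
#'
#' The three weighted likelihood scores (scope of exposure, frequency of
#' exposure, mitigation strategy) are each multiplied by their group's AHP
#' weight, summed, and the sum is multiplied by the raw 1-3 potential-for-
#' outbreak score. The multiplier is deliberately unweighted and takes no
#' part in the AHP. The result lies in \[1, 9\].
#'
#' @param scores Named numeric vector of the three likelihood criterion
#'   scores (values in {1,2,3}); names must match the weight names when both
#'   are named.
#' @param weights The group's risk-stream weights: a named numeric vector
#'   summing to 1, or an `oh_weights` object.
#' @param outbreak_potential The impact-criterion score, an integer in
#'   {1,2,3}.
#' @return List with `weighted_sum`, `multiplier` and `value`
#'   (= weighted_sum x multiplier), all at full precision.
#' @examples
#' risk_impact_score(c(scope = 2, frequency = 3, mitigation = 1),
#'   weights = c(scope = 0.5, frequency = 0.3, mitigation = 0.2),
#'   outbreak_potential = 2
#' )$value # 4.2
#' @export
risk_impact_score <- function(scores, weights, outbreak_potential) {
  composite_value(scores, weights, outbreak_potential, 3L, "risk impact score")
}

#' Composite disease-burden score for one disease
#'
#' The four weighted threat scores (severity, prevalence, transmissibility,
#' preventive and control strategy) are each multiplied by their group's AHP
#' weight, summed, and the sum is multiplied by the raw 1-3 disease-burden
#' outcome score. The result lies in \[1, 9\].
#'
#' @param scores Named numeric vector of the four threat criterion scores.
#' @param weights The group's disease-stream weights (named vector summing to
#'   1, or an `oh_weights` object).
#' @param burden The disease-burden outcome score, an integer in {1,2,3}.
#' @return List with `weighted_sum`, `multiplier` and `value`.
#' @examples
#' disease_burden_score(
#'   c(severity = 3, prevalence = 1, transmissibility = 2, strategy = 2),
#'   weights = c(
#'     severity = 0.4, prevalence = 0.3,
#'     transmissibility = 0.2, strategy = 0.1
#'   ),
#'   burden = 2
#' )$value # 4.2
#' @export
disease_burden_score <- function(scores, weights, burden) {
  composite_value(scores, weights, burden, 4L, "disease burden score")
}

#' Composite scores for every (group, item) of both streams
#'
#' Applies [risk_impact_score()] / [disease_burden_score()] across a full
#' validated score sheet using each group's own stream weights. Values are
#' kept at full precision; rounding happens only at presentation.
#'
#' @param scores Validated score-sheet data frame (`group`, `stream`, `item`,
#'   `criterion`, `value`).
#' @param weights Weights table from [ahp_weights()].
#' @param criteria Criterion catalogue data frame.
#' @return Data frame with columns `group`, `stream`, `item`, `weighted_sum`,
#'   `multiplier`, `value`, sorted by stream, group, item.
#' @export
composite_scores <- function(scores, weights, criteria) {
  out <- list()
  for (s in unique(scores$stream)) {
    wc <- weighted_criteria(criteria, s)
    mc <- multiplier_criterion(criteria, s)
    n_exp <- length(wc)
    ss <- scores[scores$stream == s, , drop = FALSE]
    for (g in unique(ss$group)) {
      wg <- weights[weights$stream == s & weights$group == g, , drop = FALSE]
      if (nrow(wg) == 0L) {
        stop("no ", s, "-stream weights available for group ", g, call. = FALSE)
      }
      w <- stats::setNames(wg$weight, wg$criterion)
      sg <- ss[ss$group == g, , drop = FALSE]
      for (it in unique(sg$item)) {
        si <- sg[sg$item == it, , drop = FALSE]
        crit_scores <- stats::setNames(si$value[match(wc, si$criterion)], wc)
        mult <- si$value[si$criterion == mc]
        if (anyNA(crit_scores) || length(mult) != 1L) {
          stop(sprintf(
            "incomplete scores for item '%s', group %s, stream %s (validate the sheet first)",
            it, g, s
          ), call. = FALSE)
        }
        cv <- composite_value(crit_scores, w, mult, n_exp, paste0(s, " composite"))
        out[[length(out) + 1L]] <- data.frame(
          group = g, stream = s, item = it,
          weighted_sum = cv$weighted_sum, multiplier = cv$multiplier,
          value = cv$value, stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$stream, res$group, res$item), , drop = FALSE]
  rownames(res) <- NULL
  res
}
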