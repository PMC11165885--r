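#' Min-max normalise composite scores within one group
#'
#' `(value - min) / (max - min)` over the group's shortlisted items, so the
#' top item scores 1 and the bottom item 0. When every composite in the group
#' is equal (including a single-item group) the denominator vanishes; all
#' scores are then set to 0 and the group is flagged degenerate — in that
#' case 0 does *not* mean lowest priority, and the flag is surfaced in the
#' ranking table and report.
#'
#' @param values Named numeric vector, item -> composite value (>= 1 item).
#' @return Named numeric vector of normalised scores in \[0, 1\], with
#'   attribute `degenerate` (logical).
#' @examples
#' normalise_scores(c(A = 2, B = 5, C = 9)) # A = 0, B = 3/7, C = 1
#' @export
normalise_scores <- function(values) {
  if (length(values) == 0L) stop("cannot normalise an empty group", call. = FALSE)
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    out <- stats::setNames(rep(0, length(values)), names(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (values - rng[1L]) / (rng[2L] - rng[1L])
  attr(out, "degenerate") <- FALSE
  out
}

# Ties are defined by equality after rounding to 9 decimals: composites are
# short products of small rationals, so 1e-9 cannot conflate genuinely
# different score combinations, while guarding against float noise.
TIE_DECIMALS <- 9L

#' Competition-rank normalised scores
#'
#' Descending competition ranking ("1, 1, 3"): tied items share the best
#' applicable rank and the next rank is skipped. Ties are detected at
#' 9-decimal rounding and reported as explicit tie sets — they are never
#' averaged away, because resolving them is a stakeholder consensus decision.
#'
#' @param normalised Named numeric vector of normalised scores.
#' @return List with `rank` (named integer vector) and `ties` (list of
#'   character vectors, one per tie set of size >= 2, in rank order).
#' @examples
#' rank_scores(c(A = 1, B = 1, C = 0.2))$rank # A = 1, B = 1, C = 3
#' @export
rank_scores <- function(normalised) {
  r <- round(as.numeric(normalised), TIE_DECIMALS)
  rk <- stats::setNames(
    vapply(r, function(v) 1L + sum(r > v), integer(1)),
    names(normalised)
  )
  tie_ranks <- sort(unique(rk[duplicated(rk) | duplicated(rk, fromLast = TRUE)]))
  ties <- lapply(tie_ranks, function(tr) sort(names(rk)[rk == tr]))
  list(rank = rk, ties = ties)
}

#' Build the full ranking table for one stream
#'
#' Normalises each group's composite scores, ranks items within each group,
#' averages the per-group normalised scores into a combined score (the
#' default cross-group combination rule), and competition-ranks the combined
#' scores. Every shortlisted item must have a composite in every group.
#'
#' @param composites Composite-score data frame (from [composite_scores()]),
#'   single stream or filtered to one via `stream`.
#' @param stream Stream to tabulate (`"risk"` or `"disease"`).
#' @param method Cross-group combination rule; only `"mean-normalised"` is
#'   currently implemented.
#' @return An object of class `oh_ranking`: a data frame with columns
#'   `stream`, `item`, then per group `composite_<g>`, `normalised_<g>`,
#'   `rank_<g>`, then `combined_score`, `combined_rank`, `tie_group` (id of
#'   the combined-rank tie set, or `""`), `override` and `note`; sorted by
#'   combined rank then item. Attributes: `groups`, `method`, `tie_sets`
#'   (combined), `group_ties` (per group), `degenerate_groups`.
#' @export
ranking_table <- function(composites, stream, method = "mean-normalised") {
  if (method != "mean-normalised") {
    stop("unsupported combined-rank method: ", method, call. = FALSE)
  }
  comp <- composites[composites$stream == stream, , drop = FALSE]
  if (nrow(comp) == 0L) stop("no composite scores for stream ", stream, call. = FALSE)
  groups <- sort(unique(comp$group))
  items <- sort(unique(comp$item))

  cmat <- matrix(NA_real_, length(items), length(groups),
    dimnames = list(items, groups)
  )
  idx <- cbind(match(comp$item, items), match(comp$group, groups))
  cmat[idx] <- comp$value
  if (anyNA(cmat)) {
    miss <- which(is.na(cmat), arr.ind = TRUE)
    stop("item(s) missing a composite score in some group(s): ",
      paste(sprintf("(%s, %s)", items[miss[, 1L]], groups[miss[, 2L]]),
        collapse = ", "), call. = FALSE)
  }

  nmat <- cmat
  degenerate <- character(0)
  group_ranks <- cmat
  group_ties <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    norm <- normalise_scores(cmat[, g])
    if (isTRUE(attr(norm, "degenerate"))) degenerate <- c(degenerate, g)
    nmat[, g] <- as.numeric(norm)
    rs <- rank_scores(stats::setNames(nmat[, g], items))
    group_ranks[, g] <- rs$rank
    group_ties[[g]] <- rs$ties
  }

  combined <- rowMeans(nmat)
  crs <- rank_scores(combined)

  tie_group <- stats::setNames(rep("", length(items)), items)
  for (i in seq_along(crs$ties)) {
    tie_group[crs$ties[[i]]] <- sprintf("T%d", i)
  }

  out <- data.frame(
    stream = stream, item = items, stringsAsFactors = FALSE
  )
  for (g in groups) {
    out[[paste0("composite_", g)]] <- cmat[, g]
    out[[paste0("normalised_", g)]] <- nmat[, g]
    out[[paste0("rank_", g)]] <- as.integer(group_ranks[, g])
  }
  out$combined_score <- combined
  out$combined_rank <- as.integer(crs$rank[items])
  out$tie_group <- tie_group[items]
  out$degenerate_groups <- paste(degenerate, collapse = ";")
  out$override <- FALSE
  out$note <- ""
  out <- out[order(out$combined_rank, out$item), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    groups = groups, method = method, tie_sets = crs$ties,
    group_ties = group_ties, degenerate_groups = degenerate,
    class = c("oh_ranking", "data.frame")
  )
}

#' @export
print.oh_ranking <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Ranking table: stream %s, %d item(s), %d group(s); combined rank = %s\n",
    x$stream[1L], nrow(x), length(attr(x, "groups")), attr(x, "method")
  ))
  show <- x[, c("item", "combined_score", "combined_rank", "tie_group"), drop = FALSE]
  show$combined_score <- round(show$combined_score, digits)
  print.data.frame(show, ...)
  ties <- attr(x, "tie_sets")
  if (length(ties) > 0L) {
    cat("Combined-rank ties requiring consensus:\n")
    for (t in ties) cat("  {", paste(t, collapse = ", "), "}\n")
  }
  dg <- attr(x, "degenerate_groups")
  if (length(dg) > 0L) {
    cat("Degenerate group(s) (all composites equal; normalised scores forced to 0):",
      paste(dg, collapse = ", "), "\n")
  }
  invisible(x)
}

# A rank multiset is a valid competition ranking iff each distinct rank
# equals 1 + the number of items strictly above it.
is_competition_ranking <- function(ranks) {
  tab <- table(ranks)
  r <- as.integer(names(tab))
  all(vapply(seq_along(r), function(i) r[i] == 1L + sum(tab[r < r[i]]), logical(1)))
}

#' Apply stakeholder tie-break overrides to a ranking table
#'
#' Workshop stakeholders may resolve combined-rank ties by consensus. An
#' override may only touch items inside a reported tie set, and the full set
#' of combined ranks after the override must still be a valid competition
#' ranking; anything else is rejected. Overridden rows carry an audit note.
#'
#' @param table An `oh_ranking` table.
#' @param overrides Named integer vector (item -> new combined rank) or a
#'   data frame with columns `item`, `rank`.
#' @return A new `oh_ranking` table with overrides applied, re-sorted, and
#'   audit annotations in `override` / `note`.
#' @export
apply_overrides <- function(table, overrides) {
  if (is.data.frame(overrides)) {
    overrides <- stats::setNames(as.integer(overrides$rank), overrides$item)
  }
  tied_items <- unlist(attr(table, "tie_sets"), use.names = FALSE)
  bad <- setdiff(names(overrides), tied_items)
  if (length(bad) > 0L) {
    stop("override(s) on item(s) not in any reported tie set: ",
      paste(bad, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(overrides), table$item)
  if (length(unknown) > 0L) {
    stop("override(s) on unknown item(s): ", paste(unknown, collapse = ", "),
      call. = FALSE)
  }

  new_ranks <- stats::setNames(table$combined_rank, table$item)
  old_ranks <- new_ranks
  new_ranks[names(overrides)] <- as.integer(overrides)
  if (!is_competition_ranking(new_ranks)) {
    stop("overrides produce an invalid competition ranking (rank multiset ",
      paste(sort(new_ranks), collapse = ","), ")", call. = FALSE)
  }

  out <- table
  out$combined_rank <- as.integer(new_ranks[out$item])
  touched <- out$item %in% names(overrides)
  out$override <- out$override | touched
  out$note[touched] <- sprintf(
    "manual tie-break: rank %d -> %d",
    old_ranks[out$item[touched]], out$combined_rank[touched]
  )
  out <- out[order(out$combined_rank, out$item), , drop = FALSE]
  rownames(out) <- NULL
  # recompute surviving tie sets after the override
  still_tied <- split(out$item, out$combined_rank)
  attr(out, "tie_sets") <- unname(Filter(function(v) length(v) > 1L, still_tied))
  tie_group <- stats::setNames(rep("", nrow(out)), out$item)
  for (i in seq_along(attr(out, "tie_sets"))) {
    tie_group[attr(out, "tie_sets")[[i]]] <- sprintf("T%d", i)
  }
  out$tie_group <- tie_group[out$item]
  out
}
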