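#' The admissible pairwise-judgment scale
#'
#' Pairwise importance judgments are elicited on the classic 1-9 ratio scale
#' (1 = equal importance, 9 = extreme importance), with exact reciprocals
#' 1/2...1/9 expressing that the second criterion of the pair dominates the
#' first. Intermediate values (e.g. 9.5, 2.5) are rejected at intake.
#'
#' @return Sorted numeric vector of the 17 admissible values.
#' @export
judgment_scale <- function() {
  sort(c(1 / (9:2), 1:9))
}

is_admissible_judgment <- function(v, tol = 1e-9) {
  !is.na(v) & vapply(v, function(x) any(abs(x - judgment_scale()) <= tol), logical(1))
}

#' Expand elicited judgments into a full pairwise-comparison matrix
#'
#' Only the upper triangle is elicited (3 judgments for the 3 risk criteria, 6
#' for the 4 disease criteria); the full matrix — 9 or 16 cells — is completed
#' with a unit diagonal and exact reciprocals in the lower triangle, so
#' reciprocity can never be violated by transcription.
#'
#' @param judgments Data frame with columns `criterion_i`, `criterion_j`,
#'   `value`, one row per unordered criterion pair with `criterion_i` before
#'   `criterion_j` in catalogue order. `value` may be numeric or text
#'   (`"4"`, `"1/4"`).
#' @param criterion_ids Character vector of the weighted criterion ids in
#'   catalogue order; defines the matrix dimension and row/column order.
#' @return An `n x n` positive reciprocal matrix with dimnames
#'   `criterion_ids`.
#' @examples
#' j <- data.frame(
#'   criterion_i = c("scope", "scope", "frequency"),
#'   criterion_j = c("frequency", "mitigation", "mitigation"),
#'   value = c("2", "4", "2")
#' )
#' pairwise_matrix(j, c("scope", "frequency", "mitigation"))
#' @export
pairwise_matrix <- function(judgments, criterion_ids) {
  n <- length(criterion_ids)
  if (n < 2L) stop("need at least 2 criteria", call. = FALSE)
  vals <- if (is.numeric(judgments$value)) judgments$value else parse_judgment_value(judgments$value)

  bad <- which(!is_admissible_judgment(vals))
  if (length(bad) > 0L) {
    stop("inadmissible judgment value(s) (must be 1..9 or an exact reciprocal): ",
      paste(sprintf(
        "%s~%s=%s", judgments$criterion_i[bad], judgments$criterion_j[bad],
        as.character(judgments$value[bad])
      ), collapse = ", "),
      call. = FALSE
    )
  }
  unknown <- setdiff(c(judgments$criterion_i, judgments$criterion_j), criterion_ids)
  if (length(unknown) > 0L) {
    stop("judgment(s) reference unknown criterion id(s): ",
      paste(unknown, collapse = ", "), call. = FALSE)
  }

  idx_i <- match(judgments$criterion_i, criterion_ids)
  idx_j <- match(judgments$criterion_j, criterion_ids)
  if (any(idx_i >= idx_j)) {
    off <- which(idx_i >= idx_j)
    stop("judgment pair(s) not in upper-triangle catalogue order: ",
      paste(sprintf("(%s, %s)", judgments$criterion_i[off], judgments$criterion_j[off]),
        collapse = ", "), call. = FALSE)
  }
  pair_key <- paste(idx_i, idx_j)
  if (anyDuplicated(pair_key)) {
    dup <- which(duplicated(pair_key))
    stop("duplicate judgment(s) for pair(s): ",
      paste(sprintf("(%s, %s)", judgments$criterion_i[dup], judgments$criterion_j[dup]),
        collapse = ", "), call. = FALSE)
  }
  need <- utils::combn(n, 2L)
  have <- paste(idx_i, idx_j)
  missing <- setdiff(paste(need[1L, ], need[2L, ]), have)
  if (length(missing) > 0L) {
    miss_idx <- do.call(rbind, strsplit(missing, " "))
    stop(sprintf("missing judgment(s) (%d of %d pairs supplied): ", nrow(judgments), ncol(need)),
      paste(sprintf(
        "(%s, %s)",
        criterion_ids[as.integer(miss_idx[, 1L])],
        criterion_ids[as.integer(miss_idx[, 2L])]
      ), collapse = ", "),
      call. = FALSE
    )
  }

  A <- diag(n)
  for (r in seq_along(vals)) {
    A[idx_i[r], idx_j[r]] <- vals[r]
    A[idx_j[r], idx_i[r]] <- 1 / vals[r]
  }
  dimnames(A) <- list(criterion_ids, criterion_ids)
  A
}

#' Saaty's Random Index table
#'
#' Average consistency indices of random reciprocal matrices, used as the
#' denominator of the consistency ratio. Standard published values
#' (RI(1) = RI(2) = 0; RI(3) = 0.58; RI(4) = 0.90; ...); user-overridable in
#' [ahp_consistency()] and [compute_weights()].
#'
#' @return Named numeric vector indexed by matrix dimension `"1"`..`"10"`.
#' @export
saaty_ri <- function() {
  c(
    "1" = 0, "2" = 0, "3" = 0.58, "4" = 0.90, "5" = 1.12,
    "6" = 1.24, "7" = 1.32, "8" = 1.41, "9" = 1.45, "10" = 1.49
  )
}

#' Derive criterion weights from a pairwise-comparison matrix
#'
#' The default method is the classic principal-eigenvector extraction: power
#' iteration on the positive reciprocal matrix (convergence guaranteed by
#' Perron-Frobenius), normalised to sum 1. The row-geometric-mean method is
#' available as an alternative; the two agree exactly on any fully consistent
#' matrix. Consistency diagnostics (lambda_max, CI, CR) are attached.
#'
#' @param A Positive reciprocal judgment matrix (see [pairwise_matrix()]).
#' @param method `"eigenvector"` (default) or `"geometric-mean"`.
#' @param tol Power-iteration convergence tolerance on the weight vector.
#' @param max_iter Power-iteration cap; non-convergence is an error.
#' @param ri Random Index table, a named vector as from [saaty_ri()].
#' @return An object of class `oh_weights`: a list with elements `weights`
#'   (named, positive, summing to 1), `lambda_max`, `ci`, `cr`, `cr_flag`
#'   (`TRUE` when CR > 0.10), `method`, `n`, `iterations`, `note`.
#' @examples
#' A <- pairwise_matrix(
#'   data.frame(
#'     criterion_i = c("scope", "scope", "frequency"),
#'     criterion_j = c("frequency", "mitigation", "mitigation"),
#'     value = c(2, 4, 2)
#'   ),
#'   c("scope", "frequency", "mitigation")
#' )
#' compute_weights(A)$weights # 4/7, 2/7, 1/7
#' @export
compute_weights <- function(A, method = c("eigenvector", "geometric-mean"),
                            tol = 1e-12, max_iter = 10000L, ri = saaty_ri()) {
  method <- match.arg(method)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  if (any(A <= 0)) stop("judgment matrix must be strictly positive", call. = FALSE)
  if (any(abs(diag(A) - 1) > 1e-12)) stop("judgment matrix diagonal must be 1", call. = FALSE)
  if (any(abs(A * t(A) - 1) > 1e-9)) {
    stop("judgment matrix is not reciprocal (a_ij * a_ji != 1)", call. = FALSE)
  }

  iterations <- 0L
  if (method == "eigenvector") {
    w <- rep(1 / n, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      v <- as.vector(A %*% w)
      v <- v / sum(v)
      if (max(abs(v - w)) < tol) {
        w <- v
        iterations <- it
        converged <- TRUE
        break
      }
      w <- v
    }
    if (!converged) {
      stop("power iteration did not converge in ", max_iter, " iterations", call. = FALSE)
    }
  } else {
    gm <- exp(rowMeans(log(A)))
    w <- gm / sum(gm)
  }
  names(w) <- rownames(A)

  cons <- ahp_consistency(A, w, ri = ri)
  structure(
    c(list(weights = w, method = method, n = n, iterations = iterations), cons),
    class = "oh_weights"
  )
}

#' Consistency diagnostics for a judgment matrix
#'
#' Estimates the principal eigenvalue as the mean of `(A w)_i / w_i`, then
#' the consistency index `CI = (lambda_max - n) / (n - 1)` and ratio
#' `CR = CI / RI(n)`. `CR > 0.10` conventionally flags unreliable judgments;
#' the flag is a warning for the moderator, not a hard failure, since group
#' disagreement is resolved by consensus during the workshop.
#'
#' @param A Positive reciprocal judgment matrix.
#' @param w Weight vector computed from `A` (see [compute_weights()]).
#' @param ri Random Index table (named vector; see [saaty_ri()]).
#' @return List with `lambda_max`, `ci`, `cr`, `cr_flag` and `note` (non-`NA`
#'   when `n < 3`, where random inconsistency is impossible and CR is
#'   reported as 0).
#' @export
ahp_consistency <- function(A, w, ri = saaty_ri()) {
  if (inherits(w, "oh_weights")) w <- w$weights
  n <- nrow(A)
  lambda_max <- mean(as.vector(A %*% w) / w)
  if (n < 3L) {
    return(list(
      lambda_max = lambda_max, ci = 0, cr = 0, cr_flag = FALSE,
      note = "CR reported as 0: matrices with n < 3 are always consistent (RI = 0)"
    ))
  }
  ci <- (lambda_max - n) / (n - 1)
  ri_n <- ri[[as.character(n)]]
  if (is.null(ri_n) || is.na(ri_n)) {
    stop("no Random Index entry for n = ", n, call. = FALSE)
  }
  cr <- ci / ri_n
  list(lambda_max = lambda_max, ci = ci, cr = cr, cr_flag = cr > 0.10, note = NA_character_)
}

#' @export
print.oh_weights <- function(x, digits = 4, ...) {
  cat(sprintf("AHP weights (%s method, n = %d)\n", x$method, x$n))
  print(round(x$weights, digits))
  cat(sprintf(
    "lambda_max = %.6f, CI = %.6f, CR = %.6f%s\n",
    x$lambda_max, x$ci, x$cr,
    if (isTRUE(x$cr_flag)) "  ** CR > 0.10: judgments inconsistent, review with the group **" else ""
  ))
  if (!is.na(x$note %||% NA_character_)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Compute per-group criterion weights for every group and stream
#'
#' Applies [pairwise_matrix()] and [compute_weights()] to each (group, stream)
#' judgment set and returns the flat weights table used by the rest of the
#' pipeline. Weights are kept per group through ranking; no consensus matrix
#' is formed.
#'
#' @param judgments Data frame with columns `group`, `stream`, `criterion_i`,
#'   `criterion_j`, `value`.
#' @param criteria Criterion catalogue data frame.
#' @param method,ri Passed to [compute_weights()].
#' @param strict When `TRUE`, a CR above 0.10 is an error instead of a
#'   flagged warning.
#' @return Data frame with columns `group`, `stream`, `criterion`, `weight`,
#'   `lambda_max`, `ci`, `cr`, `cr_flag`.
#' @export
ahp_weights <- function(judgments, criteria,
                        method = c("eigenvector", "geometric-mean"),
                        ri = saaty_ri(), strict = FALSE) {
  method <- match.arg(method)
  out <- list()
  for (s in unique(judgments$stream)) {
    ids <- weighted_criteria(criteria, s)
    if (length(ids) == 0L) {
      stop("no weighted criteria defined for stream '", s, "'", call. = FALSE)
    }
    for (g in unique(judgments$group[judgments$stream == s])) {
      js <- judgments[judgments$stream == s & judgments$group == g, , drop = FALSE]
      A <- pairwise_matrix(js, ids)
      wv <- compute_weights(A, method = method, ri = ri)
      if (strict && isTRUE(wv$cr_flag)) {
        stop(sprintf(
          "group %s, stream %s: consistency ratio %.3f exceeds 0.10 (strict mode)",
          g, s, wv$cr
        ), call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, stream = s, criterion = ids,
        weight = as.numeric(wv$weights),
        lambda_max = wv$lambda_max, ci = wv$ci, cr = wv$cr,
        cr_flag = wv$cr_flag, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "method") <- method
  res
}
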