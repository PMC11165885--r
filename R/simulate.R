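#' Specify a synthetic workshop
#'
#' Defines the conditions of a simulated prioritisation workshop: panel and
#' group sizes, candidate-list lengths, the "true" criterion weights each
#' group's pairwise judgments are generated from, the log-scale judgment
#' noise, and the ordinal score distribution. Defaults emulate a realistic
#' mid-size workshop: 30 candidate risk factors and 30 candidate diseases,
#' 24 participants in 4 groups of 6, shortlists of 10, scale-representable
#' true weights (risk 4/7, 2/7, 1/7; disease 8/15, 4/15, 2/15, 1/15), and a
#' modest judgment noise of 0.1 on the log scale.
#'
#' @param seed Integer seed; the single source of randomness for the whole
#'   bundle.
#' @param n_risk_candidates,n_disease_candidates Candidate-list lengths
#'   (<= 50 each).
#' @param n_participants Total panel size (the workshop format accommodates
#'   20-30).
#' @param n_groups Number of scoring groups (<= 5).
#' @param shortlist_size Requested shortlist size `k`, both streams.
#' @param true_weights Named list with elements `risk` (length 3) and
#'   `disease` (length 4): positive vectors summing to 1 from which pairwise
#'   judgments are generated as `(w_i / w_j) * exp(eps)`.
#' @param judgment_noise Standard deviation of the multiplicative log-scale
#'   judgment error `eps` (>= 0; 0 gives perfectly consistent groups).
#' @param score_distribution Probability vector over ordinal scores {1,2,3},
#'   or a named list of such vectors per criterion id.
#' @param vote_enthusiasm Per-item inclusion probability: a scalar, a vector
#'   recycled over each stream's catalogue, or `NULL` to draw each item's
#'   enthusiasm from Beta(2, 2).
#' @param score_correlation In \[0, 1\]: probability that a score cell is
#'   driven by the item's shared latent severity rather than an independent
#'   draw, so all groups agree more as it approaches 1.
#' @return An object of class `oh_simspec` (a named list, validated).
#' @export
simulation_spec <- function(seed = 1L,
                            n_risk_candidates = 30L,
                            n_disease_candidates = 30L,
                            n_participants = 24L,
                            n_groups = 4L,
                            shortlist_size = 10L,
                            true_weights = list(
                              risk = c(scope = 4 / 7, frequency = 2 / 7, mitigation = 1 / 7),
                              disease = c(
                                severity = 8 / 15, prevalence = 4 / 15,
                                transmissibility = 2 / 15, strategy = 1 / 15
                              )
                            ),
                            judgment_noise = 0.1,
                            score_distribution = c(1, 1, 1) / 3,
                            vote_enthusiasm = NULL,
                            score_correlation = 0) {
  stopifnot(
    n_risk_candidates >= 1L, n_risk_candidates <= 50L,
    n_disease_candidates >= 1L, n_disease_candidates <= 50L,
    n_groups >= 1L, n_groups <= 5L,
    judgment_noise >= 0,
    score_correlation >= 0, score_correlation <= 1,
    length(true_weights$risk) == 3L, length(true_weights$disease) == 4L
  )
  for (s in c("risk", "disease")) {
    w <- true_weights[[s]]
    if (any(w <= 0) || abs(sum(w) - 1) > 1e-9) {
      stop("true_weights$", s, " must be positive and sum to 1", call. = FALSE)
    }
  }
  check_probs <- function(p) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("score_distribution entries must be length-3 probability vectors",
        call. = FALSE)
    }
  }
  if (is.list(score_distribution)) lapply(score_distribution, check_probs) else check_probs(score_distribution)
  if (n_participants < 20L || n_participants > 30L) {
    warning("n_participants = ", n_participants,
      ": the workshop format targets 20-30 participants", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_risk_candidates = as.integer(n_risk_candidates),
      n_disease_candidates = as.integer(n_disease_candidates),
      n_participants = as.integer(n_participants),
      n_groups = as.integer(n_groups),
      shortlist_size = as.integer(shortlist_size),
      true_weights = true_weights,
      judgment_noise = judgment_noise,
      score_distribution = score_distribution,
      vote_enthusiasm = vote_enthusiasm,
      score_correlation = score_correlation
    ),
    class = "oh_simspec"
  )
}

# Snap a positive ratio to the nearest admissible judgment value in log
# space (the scale is multiplicative, so log distance is the natural
# metric); exact midpoint ties go to the value nearer 1 (the more
# conservative judgment).
snap_judgment <- function(r) {
  grid <- judgment_scale()
  lg <- log(grid)
  vapply(r, function(x) {
    d <- abs(log(x) - lg)
    cand <- which(d <= min(d) + 1e-12)
    grid[cand[which.min(abs(lg[cand]))]]
  }, numeric(1))
}

# Inverse-CDF draw of an ordinal score from a length-3 probability vector.
qcat3 <- function(u, probs) {
  findInterval(u, cumsum(probs)[1:2]) + 1L
}

score_probs_for <- function(spec, criterion) {
  sd <- spec$score_distribution
  if (is.list(sd)) sd[[criterion]] %||% c(1, 1, 1) / 3 else sd
}

#' Generate a complete synthetic workshop bundle
#'
#' Produces the *input* artefacts of a workshop — candidate catalogues,
#' per-participant inclusion votes, per-group pairwise judgments, and ordinal
#' score sheets for the shortlisted items — entirely from a seeded generator,
#' so every fixture is reproducible from the spec alone. Draws happen in a
#' fixed documented order (risk votes, disease votes, per-group judgments
#' risk then disease, latent item severities, risk scores, disease scores);
#' judgment ratios `(w_i / w_j) * exp(eps)` are snapped to the nearest
#' admissible scale value in log space, so generated matrices always satisfy
#' the reciprocal-matrix invariants.
#'
#' @param spec A [simulation_spec()].
#' @param dir Optional directory: when given, the bundle is also written in
#'   the canonical file formats.
#' @return An `oh_bundle` containing inputs only (no computed stages).
#' @examples
#' b <- simulate_workshop(simulation_spec(seed = 7, n_groups = 2))
#' b
#' @export
simulate_workshop <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "oh_simspec"))
  set.seed(spec$seed)

  groups <- sprintf("G%d", seq_len(spec$n_groups))
  participants <- sprintf("P%02d", seq_len(spec$n_participants))
  config <- workshop_config(
    groups = groups,
    participants_per_group = max(1L, round(spec$n_participants / spec$n_groups)),
    shortlist_size_risk = spec$shortlist_size,
    shortlist_size_disease = spec$shortlist_size
  )
  criteria <- default_criteria()

  catalogue <- rbind(
    data.frame(
      stream = "risk", id = sprintf("rf%02d", seq_len(spec$n_risk_candidates)),
      label = sprintf("Risk factor %02d", seq_len(spec$n_risk_candidates)),
      source = "catalogue", stringsAsFactors = FALSE
    ),
    data.frame(
      stream = "disease", id = sprintf("ds%02d", seq_len(spec$n_disease_candidates)),
      label = sprintf("Disease %02d", seq_len(spec$n_disease_candidates)),
      source = "catalogue", stringsAsFactors = FALSE
    )
  )

  # 1-2) per-item enthusiasm, then Bernoulli inclusion votes, per stream
  votes <- list()
  for (s in c("risk", "disease")) {
    ids <- catalogue$id[catalogue$stream == s]
    n_it <- length(ids)
    enth <- if (is.null(spec$vote_enthusiasm)) {
      stats::rbeta(n_it, 2, 2)
    } else {
      rep_len(spec$vote_enthusiasm, n_it)
    }
    u <- matrix(stats::runif(spec$n_participants * n_it), spec$n_participants, n_it)
    inc <- sweep(u, 2L, enth, `<`)
    votes[[s]] <- data.frame(
      participant = rep(participants, times = n_it),
      stream = s,
      item = rep(ids, each = spec$n_participants),
      include = as.vector(inc),
      stringsAsFactors = FALSE
    )
  }
  votes <- do.call(rbind, votes)
  rownames(votes) <- NULL
  votes$include <- as.logical(votes$include)

  # 3) pairwise judgments per group, risk then disease
  judgments <- list()
  for (g in groups) {
    for (s in c("risk", "disease")) {
      w <- spec$true_weights[[s]]
      ids <- names(w)
      pairs <- utils::combn(length(w), 2L)
      eps <- stats::rnorm(ncol(pairs), 0, spec$judgment_noise)
      ratio <- w[pairs[1L, ]] / w[pairs[2L, ]] * exp(eps)
      judgments[[length(judgments) + 1L]] <- data.frame(
        group = g, stream = s,
        criterion_i = ids[pairs[1L, ]], criterion_j = ids[pairs[2L, ]],
        value = snap_judgment(ratio), stringsAsFactors = FALSE
      )
    }
  }
  judgments <- do.call(rbind, judgments)
  rownames(judgments) <- NULL

  # shortlists are needed to know which items get scored
  counts <- tally_votes(votes, catalogue)
  shortlists <- lapply(
    stats::setNames(c("risk", "disease"), c("risk", "disease")),
    function(s) select_top(counts[counts$stream == s, , drop = FALSE], spec$shortlist_size)
  )

  # 4) latent item severities, then ordinal scores per (group, item, criterion)
  scores <- list()
  for (s in c("risk", "disease")) {
    items <- shortlists[[s]]$item
    crits <- criteria$id[criteria$stream == s]
    latent <- stats::setNames(stats::runif(length(items)), items)
    for (g in groups) {
      for (it in items) {
        for (cr in crits) {
          probs <- score_probs_for(spec, cr)
          u_mix <- stats::runif(1)
          u_cell <- stats::runif(1)
          u <- if (u_mix < spec$score_correlation) latent[[it]] else u_cell
          scores[[length(scores) + 1L]] <- data.frame(
            group = g, stream = s, item = it, criterion = cr,
            value = qcat3(u, probs), stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL

  bundle <- structure(
    list(
      dir = dir, config = config, criteria = criteria, catalogue = catalogue,
      votes = votes, judgments = judgments, scores = scores,
      shortlists = list(), weights = NULL, composites = NULL,
      rankings = list(),
      report = validate_workshop(config, criteria, catalogue),
      log = list()
    ),
    class = "oh_bundle"
  )
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' Weight-recovery experiment for the AHP stage
#'
#' Repeatedly generates noisy pairwise judgments from known true weights,
#' re-estimates the weights, and summarises how well they are recovered: the
#' per-criterion and overall mean absolute error, the consistency-ratio
#' distribution, and the fraction of replicates flagged CR > 0.10. With zero
#' noise and scale-representable true weights, recovery is exact.
#'
#' @param spec A [simulation_spec()]; supplies the true weights and base
#'   seed.
#' @param replicates Number of replicate judgment sets (>= 1).
#' @param noise Log-scale judgment noise (defaults to the spec's).
#' @param stream `"risk"` or `"disease"`.
#' @param method Weight-extraction method, passed to [compute_weights()].
#' @return List with `mae` (overall mean absolute error), `mae_per_criterion`
#'   (named vector), `cr` (vector of consistency ratios), `frac_flagged`,
#'   `replicates`, `noise`.
#' @export
recover_weights_experiment <- function(spec, replicates, noise = spec$judgment_noise,
                                       stream = c("risk", "disease"),
                                       method = "eigenvector") {
  stream <- match.arg(stream)
  stopifnot(replicates >= 1L)
  w_true <- spec$true_weights[[stream]]
  ids <- names(w_true)
  pairs <- utils::combn(length(w_true), 2L)

  abs_err <- matrix(NA_real_, replicates, length(w_true), dimnames = list(NULL, ids))
  cr <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed((spec$seed + 1000003 * r) %% 2147483647L)
    eps <- stats::rnorm(ncol(pairs), 0, noise)
    ratio <- w_true[pairs[1L, ]] / w_true[pairs[2L, ]] * exp(eps)
    jd <- data.frame(
      criterion_i = ids[pairs[1L, ]], criterion_j = ids[pairs[2L, ]],
      value = snap_judgment(ratio), stringsAsFactors = FALSE
    )
    wv <- compute_weights(pairwise_matrix(jd, ids), method = method)
    abs_err[r, ] <- abs(wv$weights[ids] - w_true)
    cr[r] <- wv$cr
  }
  list(
    mae = mean(abs_err),
    mae_per_criterion = colMeans(abs_err),
    cr = cr,
    frac_flagged = mean(cr > 0.10),
    replicates = replicates,
    noise = noise
  )
}
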