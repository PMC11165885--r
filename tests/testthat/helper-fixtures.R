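# Small fixtures built in code; no data files.

make_catalogue <- function(n_risk = 5, n_disease = 5) {
  one <- function(stream, prefix, what, n) {
    if (n == 0) return(NULL)
    data.frame(
      stream = stream, id = sprintf("%s%02d", prefix, seq_len(n)),
      label = sprintf("%s %02d", what, seq_len(n)),
      source = "catalogue", stringsAsFactors = FALSE
    )
  }
  rbind(
    one("risk", "rf", "Risk factor", n_risk),
    one("disease", "ds", "Disease", n_disease)
  )
}

# Deterministic fully-scored tiny workshop: 2 groups, consistent judgments
# from known weights, every shortlisted item scored on every criterion.
make_tiny_bundle <- function(dir = NULL) {
  spec <- simulation_spec(
    seed = 101, n_risk_candidates = 6, n_disease_candidates = 6,
    n_groups = 2, n_participants = 24, shortlist_size = 3,
    judgment_noise = 0
  )
  suppressWarnings(simulate_workshop(spec, dir = dir))
}

consistent_matrix_3 <- function() {
  pairwise_matrix(
    data.frame(
      criterion_i = c("scope", "scope", "frequency"),
      criterion_j = c("frequency", "mitigation", "mitigation"),
      value = c(2, 4, 2)
    ),
    c("scope", "frequency", "mitigation")
  )
}

cyclic_matrix_3 <- function() {
  matrix(c(1, 1 / 3, 3, 3, 1, 1 / 3, 1 / 3, 3, 1), 3, 3,
    dimnames = rep(list(c("a", "b", "c")), 2)
  )
}

# Independent oracle: a consistent matrix built directly from a weight vector.
consistent_matrix_from <- function(w) {
  outer(w, w, `/`)
}
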