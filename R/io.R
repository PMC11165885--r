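# Canonical on-disk layout of a workshop directory. All artefacts are plain
# UTF-8 delimited text ("." decimal, header row) or YAML; the engine never
# reads spreadsheets.
BUNDLE_FILES <- list(
  config = "config.yml",
  criteria = "criteria.yml",
  catalogue = "catalogue.csv",
  votes = "votes.csv",
  judgments = "judgments.csv",
  scores = "scores.csv",
  shortlist_risk = "shortlist_risk.csv",
  shortlist_disease = "shortlist_disease.csv",
  weights = "weights.csv",
  composites = "composites.csv",
  ranking_risk = "ranking_risk.csv",
  ranking_disease = "ranking_disease.csv",
  report_txt = "report.txt",
  report_html = "report.html",
  runlog = "runlog.json"
)

#' Load a workshop bundle from a directory
#'
#' Reads every stage file present in a workshop directory into a single
#' bundle object. `config.yml`, `criteria.yml` and `catalogue.csv` are
#' mandatory; vote, judgment and score files are optional (a partial bundle
#' is valid — stages simply have not run yet). All intake validation findings
#' are collected in the bundle's report with file and line locations;
#' structural problems (missing mandatory file, missing columns) raise
#' immediately.
#'
#' @param dir Path to the workshop directory.
#' @return An object of class `oh_bundle`: a list with elements `dir`,
#'   `config`, `criteria`, `catalogue`, `votes`, `judgments`, `scores`,
#'   `shortlists`, `weights`, `composites`, `rankings`, `report` (validation
#'   report data frame) and `log`.
#' @seealso [run_pipeline()], [write_bundle()], [simulate_workshop()]
#' @export
load_bundle <- function(dir) {
  path <- function(key) file.path(dir, BUNDLE_FILES[[key]])
  for (key in c("config", "criteria", "catalogue")) {
    if (!file.exists(path(key))) {
      stop("missing mandatory workshop file: ", BUNDLE_FILES[[key]],
        " in ", dir, call. = FALSE)
    }
  }

  raw_cfg <- yaml::read_yaml(path("config"))
  config <- workshop_config(
    groups = raw_cfg$groups %||% "G1",
    participants_per_group = raw_cfg$participants_per_group %||% 6L,
    shortlist_size_risk = raw_cfg$shortlist_size_risk %||% 10L,
    shortlist_size_disease = raw_cfg$shortlist_size_disease %||% 10L,
    catalogue_limit = raw_cfg$catalogue_limit %||% 50L,
    tie_policy = raw_cfg$tie_policy %||% "report",
    combined_rank_method = raw_cfg$combined_rank_method %||% "mean-normalised"
  )
  criteria <- read_criteria(path("criteria"))
  catalogue <- read_workshop_table(path("catalogue"), c("stream", "id", "label"))
  if (is.null(catalogue$source)) catalogue$source <- "catalogue"

  report <- validate_workshop(config, criteria, catalogue)

  bundle <- structure(
    list(
      dir = dir, config = config, criteria = criteria, catalogue = catalogue,
      votes = NULL, judgments = NULL, scores = NULL,
      shortlists = list(), weights = NULL, composites = NULL,
      rankings = list(), report = report, log = list()
    ),
    class = "oh_bundle"
  )

  if (file.exists(path("votes"))) {
    votes <- read_workshop_table(
      path("votes"), c("participant", "stream", "item", "include")
    )
    votes$include <- as.logical(as.integer(votes$include))
    bad <- which(is.na(votes$include))
    for (i in bad) {
      bundle$report <- report_add(bundle$report, "error", "votes", votes$item[i],
        sprintf("%s line %d: include must be 0 or 1", BUNDLE_FILES$votes, i + 1L))
    }
    unknown <- which(!(votes$item %in% catalogue$id))
    for (i in unknown) {
      bundle$report <- report_add(bundle$report, "error", "votes", votes$item[i],
        sprintf(
          "%s line %d: unknown item id '%s'",
          BUNDLE_FILES$votes, i + 1L, votes$item[i]
        ))
    }
    bundle$votes <- votes
  }

  if (file.exists(path("judgments"))) {
    judgments <- read_workshop_table(
      path("judgments"), c("group", "stream", "criterion_i", "criterion_j", "value")
    )
    parsed <- parse_judgment_value(judgments$value)
    bad <- which(!is_admissible_judgment(parsed))
    for (i in bad) {
      bundle$report <- report_add(bundle$report, "error", "judgments",
        paste0(judgments$criterion_i[i], "~", judgments$criterion_j[i]),
        sprintf(
          "%s line %d: value '%s' is not on the 1-9 scale or its reciprocals",
          BUNDLE_FILES$judgments, i + 1L, as.character(judgments$value[i])
        ))
    }
    unknown_g <- which(!(judgments$group %in% config$groups))
    for (i in unknown_g) {
      bundle$report <- report_add(bundle$report, "error", "judgments", judgments$group[i],
        sprintf(
          "%s line %d: unknown group id '%s'",
          BUNDLE_FILES$judgments, i + 1L, judgments$group[i]
        ))
    }
    judgments$value <- parsed
    bundle$judgments <- judgments
  }

  if (file.exists(path("scores"))) {
    scores <- read_workshop_table(
      path("scores"), c("group", "stream", "item", "criterion", "value")
    )
    scores$value <- suppressWarnings(as.numeric(scores$value))
    bad <- which(is.na(scores$value))
    for (i in bad) {
      bundle$report <- report_add(bundle$report, "error", "scores", scores$item[i],
        sprintf("%s line %d: non-numeric score", BUNDLE_FILES$scores, i + 1L))
    }
    bundle$scores <- scores
  }

  # previously computed artefacts, if the pipeline already ran here
  for (s in c("risk", "disease")) {
    slp <- path(paste0("shortlist_", s))
    if (file.exists(slp)) {
      sl <- read_workshop_table(slp, c("item", "votes"))
      bundle$shortlists[[s]] <- sl
    }
  }
  if (file.exists(path("weights"))) {
    bundle$weights <- read_workshop_table(
      path("weights"),
      c("group", "stream", "criterion", "weight", "lambda_max", "ci", "cr", "cr_flag")
    )
  }
  if (file.exists(path("composites"))) {
    bundle$composites <- read_workshop_table(
      path("composites"),
      c("group", "stream", "item", "weighted_sum", "multiplier", "value")
    )
  }
  for (s in c("risk", "disease")) {
    rp <- path(paste0("ranking_", s))
    if (file.exists(rp)) {
      bundle$rankings[[s]] <- read_workshop_table(rp, c("stream", "item", "combined_score", "combined_rank"))
    }
  }
  bundle
}

#' Write a workshop bundle to a directory
#'
#' Writes every artefact present in the bundle in the canonical plain-text
#' formats. Numeric columns are written at full double precision (17
#' significant digits), so write/read round-trips are lossless and repeated
#' runs on identical inputs are byte-identical.
#'
#' @param bundle An `oh_bundle`.
#' @param dir Target directory (created if needed); defaults to the bundle's
#'   own directory.
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir = bundle$dir) {
  if (is.null(dir)) stop("no target directory for the bundle", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(key) file.path(dir, BUNDLE_FILES[[key]])

  yaml::write_yaml(unclass(bundle$config), path("config"))
  write_criteria_yaml(bundle$criteria, path("criteria"))
  write_workshop_table(bundle$catalogue, path("catalogue"))
  if (!is.null(bundle$votes)) {
    v <- bundle$votes
    v$include <- as.integer(v$include)
    write_workshop_table(v, path("votes"))
  }
  if (!is.null(bundle$judgments)) {
    j <- bundle$judgments
    j$value <- format_judgment_value(j$value)
    write_workshop_table(j, path("judgments"))
  }
  if (!is.null(bundle$scores)) write_workshop_table(bundle$scores, path("scores"))
  for (s in names(bundle$shortlists)) {
    sl <- bundle$shortlists[[s]]
    out <- data.frame(
      stream = s, item = sl$item, votes = sl$votes,
      tie_at_cutoff = isTRUE(attr(sl, "tie_at_cutoff")),
      stringsAsFactors = FALSE
    )
    write_workshop_table(out, file.path(dir, paste0("shortlist_", s, ".csv")))
  }
  if (!is.null(bundle$weights)) write_workshop_table(bundle$weights, path("weights"))
  if (!is.null(bundle$composites)) write_workshop_table(bundle$composites, path("composites"))
  for (s in names(bundle$rankings)) {
    write_workshop_table(
      as.data.frame(bundle$rankings[[s]]),
      file.path(dir, paste0("ranking_", s, ".csv"))
    )
  }
  if (length(bundle$log) > 0L) {
    jsonlite::write_json(bundle$log, path("runlog"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(dir)
}

write_criteria_yaml <- function(criteria, path) {
  out <- lapply(split(criteria, criteria$stream), function(cs) {
    lapply(seq_len(nrow(cs)), function(i) {
      list(
        id = cs$id[i], label = cs$label[i], role = cs$role[i],
        question = cs$question[i],
        rubric = as.character(cs[i, c("level_1", "level_2", "level_3")])
      )
    })
  })
  # keep risk before disease for stable output
  out <- out[intersect(c("risk", "disease"), names(out))]
  yaml::write_yaml(out, path)
}

#' @export
print.oh_bundle <- function(x, ...) {
  cat("Workshop bundle", if (!is.null(x$dir)) paste0("(", x$dir, ")"), "\n")
  cat("  groups:    ", paste(x$config$groups, collapse = ", "), "\n")
  for (s in c("risk", "disease")) {
    n_cat <- sum(x$catalogue$stream == s)
    n_sl <- if (!is.null(x$shortlists[[s]])) nrow(x$shortlists[[s]]) else NA_integer_
    cat(sprintf("  %-8s %d candidate(s), shortlist: %s\n", paste0(s, ":"),
      n_cat, if (is.na(n_sl)) "not computed" else paste(n_sl, "item(s)")))
  }
  stages <- c(
    votes = !is.null(x$votes), judgments = !is.null(x$judgments),
    scores = !is.null(x$scores), weights = !is.null(x$weights),
    composites = !is.null(x$composites),
    rankings = length(x$rankings) > 0L
  )
  cat("  stages present:", paste(names(stages)[stages], collapse = ", "), "\n")
  errs <- report_errors(x$report)
  cat("  validation:", if (nrow(errs) == 0L) "no errors" else paste(nrow(errs), "error(s)"),
    sprintf("(%d warning(s))", sum(x$report$severity == "warning")), "\n")
  invisible(x)
}
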