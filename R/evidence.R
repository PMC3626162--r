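#' Construct a single study record
#'
#' A study is one article from the evidence base: its citation, its type
#' (literature `review` or primary `evaluation`), the countries it
#' studied (ISO 3166-1 alpha-3 codes) and its qualitative assessments.
#' Assessments are given as one `(mechanism, goal, score)` triple per
#' assessed combination; for every mechanism the study addresses, goals
#' without a stated score are normalised to an explicit
#' `not_considered` entry, so each addressed mechanism always carries
#' all five goal scores.
#'
#' @param study_id Unique study identifier (non-empty string).
#' @param citation List with elements `authors`, `title`, `year`,
#'   `journal`.
#' @param study_type `"review"` or `"evaluation"`.
#' @param countries Character vector of alpha-3 country codes (may be
#'   empty; validity for evaluations is checked by
#'   [validate_evidence()]).
#' @param assessments Data frame with columns `mechanism`, `goal`,
#'   `score`, at least one row.
#' @param abstract Optional abstract text.
#' @return An object of class `scattar_study`.
#' @export
new_study <- function(study_id, citation, study_type, countries,
                      assessments, abstract = "") {
  if (!is.character(study_id) || length(study_id) != 1 || !nzchar(study_id)) {
    stop_format("study_id must be a single non-empty string")
  }
  needed <- c("authors", "title", "year", "journal")
  if (!is.list(citation) || !all(needed %in% names(citation))) {
    stop_format(sprintf("study %s: citation must have fields %s",
                        study_id, paste(needed, collapse = ", ")))
  }
  assert_vocab(study_type, study_type_levels(), "study_type")
  countries <- as.character(countries %||% character())
  if (!is.data.frame(assessments) ||
      !all(c("mechanism", "goal", "score") %in% names(assessments)) ||
      nrow(assessments) == 0) {
    stop_format(sprintf(
      "study %s: assessments must be a non-empty data frame with columns mechanism, goal, score",
      study_id))
  }
  assert_mechanism(assessments$mechanism)
  assert_goal(assessments$goal)
  assert_score(assessments$score)
  dup <- duplicated(assessments[c("mechanism", "goal")])
  if (any(dup)) {
    stop_integrity(sprintf("study %s: duplicate (mechanism, goal) assessment",
                           study_id))
  }

  # Normalise: every addressed mechanism gets all 5 goals, absent ones
  # stored explicitly as not_considered; rows in canonical order.
  mechs <- intersect(mechanism_levels(), unique(assessments$mechanism))
  full <- expand.grid(goal = goal_levels(), mechanism = mechs,
                      stringsAsFactors = FALSE)[, c("mechanism", "goal")]
  key <- paste(assessments$mechanism, assessments$goal)
  idx <- match(paste(full$mechanism, full$goal), key)
  full$score <- ifelse(is.na(idx), "not_considered",
                       assessments$score[idx])
  rownames(full) <- NULL

  structure(list(
    study_id = study_id,
    citation = list(authors = as.character(citation$authors),
                    title = as.character(citation$title),
                    year = as.integer(citation$year),
                    journal = as.character(citation$journal)),
    abstract = as.character(abstract %||% ""),
    study_type = study_type,
    countries = countries,
    assessments = full
  ), class = "scattar_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

study_mechanisms <- function(study) unique(study$assessments$mechanism)

#' Construct an evidence database
#'
#' @param studies List of [new_study()] objects.
#' @param provenance Free-text description of where the records came
#'   from (source file, generator settings, version).
#' @return An object of class `evidence_db`.
#' @export
new_evidence_db <- function(studies, provenance = "") {
  ids <- vapply(studies, function(s) s$study_id, character(1))
  if (anyDuplicated(ids)) {
    stop_integrity(sprintf("duplicate study_id(s): %s",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(list(studies = studies, provenance = as.character(provenance)),
            class = "evidence_db")
}

#' @export
length.evidence_db <- function(x) length(x$studies)

#' @export
print.evidence_db <- function(x, ...) {
  cat(sprintf("<evidence_db> %d studies (%s reviews, %s evaluations)\n",
              length(x$studies),
              sum(vapply(x$studies, function(s) s$study_type == "review", logical(1))),
              sum(vapply(x$studies, function(s) s$study_type == "evaluation", logical(1)))))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

# --- loading ---------------------------------------------------------------

#' Read an evidence database from JSON or CSV
#'
#' JSON is the canonical nested form; CSV is a flat dialect with one
#' row per `(study, mechanism)` and the five goal scores as columns.
#' Unknown mechanism, goal or score labels are rejected, never coerced.
#'
#' @param path Path to the file.
#' @param format `"json"` or `"csv"`; by default guessed from the file
#'   extension.
#' @return An [new_evidence_db()] object.
#' @seealso [write_evidence()], [validate_evidence()]
#' @export
load_evidence <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (format == "json") load_evidence_json(path) else load_evidence_csv(path)
}

load_evidence_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_format(sprintf("cannot parse JSON %s: %s", path,
                                        conditionMessage(e)))
                  })
  if (is.null(doc$studies)) stop_format(sprintf("%s: missing 'studies' array", path))
  studies <- lapply(seq_along(doc$studies), function(i) {
    rec <- doc$studies[[i]]
    a <- rec$assessments
    if (is.null(a) || length(a) == 0) {
      stop_format(sprintf("%s: record %d has no assessments", path, i))
    }
    assessments <- data.frame(
      mechanism = vapply(a, function(x) as.character(x$mechanism), character(1)),
      goal = vapply(a, function(x) as.character(x$goal), character(1)),
      score = vapply(a, function(x) as.character(x$score), character(1)),
      stringsAsFactors = FALSE)
    new_study(
      study_id = as.character(rec$study_id %||% stop_format(
        sprintf("%s: record %d missing study_id", path, i))),
      citation = rec$citation %||% list(),
      abstract = rec$abstract %||% "",
      study_type = as.character(rec$study_type),
      countries = unlist(rec$countries) %||% character(),
      assessments = assessments)
  })
  new_evidence_db(studies, provenance = as.character(doc$provenance %||% path))
}

evidence_csv_columns <- function() {
  c("study_id", "authors", "title", "year", "journal", "study_type",
    "countries", "mechanism", goal_levels())
}

load_evidence_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = "character"),
                 error = function(e) {
                   stop_format(sprintf("cannot parse CSV %s: %s", path,
                                       conditionMessage(e)))
                 })
  missing <- setdiff(evidence_csv_columns(), names(df))
  if (length(missing) > 0) {
    stop_format(sprintf("%s: missing column(s): %s", path,
                        paste(missing, collapse = ", ")))
  }
  studies <- lapply(split(seq_len(nrow(df)), factor(df$study_id, levels = unique(df$study_id))),
                    function(rows) {
    sub <- df[rows, , drop = FALSE]
    long <- do.call(rbind, lapply(seq_len(nrow(sub)), function(r) {
      data.frame(mechanism = sub$mechanism[r], goal = goal_levels(),
                 score = unlist(sub[r, goal_levels()], use.names = FALSE),
                 stringsAsFactors = FALSE)
    }))
    countries <- sub$countries[1]
    countries <- if (nzchar(countries)) strsplit(countries, ";", fixed = TRUE)[[1]] else character()
    new_study(
      study_id = sub$study_id[1],
      citation = list(authors = sub$authors[1], title = sub$title[1],
                      year = sub$year[1], journal = sub$journal[1]),
      study_type = sub$study_type[1],
      countries = countries,
      assessments = long)
  })
  new_evidence_db(unname(studies), provenance = path)
}

#' Write an evidence database to JSON or CSV
#'
#' @inheritParams load_evidence
#' @param db An [new_evidence_db()] object.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(db, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    doc <- list(
      provenance = db$provenance,
      studies = lapply(db$studies, function(s) {
        list(study_id = s$study_id, citation = s$citation,
             abstract = s$abstract, study_type = s$study_type,
             countries = as.list(s$countries),
             assessments = lapply(seq_len(nrow(s$assessments)), function(r) {
               as.list(s$assessments[r, c("mechanism", "goal", "score")])
             }))
      }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    rows <- do.call(rbind, lapply(db$studies, function(s) {
      do.call(rbind, lapply(study_mechanisms(s), function(m) {
        sub <- s$assessments[s$assessments$mechanism == m, ]
        scores <- stats::setNames(sub$score, sub$goal)[goal_levels()]
        cbind(data.frame(study_id = s$study_id,
                         authors = s$citation$authors,
                         title = s$citation$title,
                         year = s$citation$year,
                         journal = s$citation$journal,
                         study_type = s$study_type,
                         countries = paste(s$countries, collapse = ";"),
                         mechanism = m, stringsAsFactors = FALSE),
              as.data.frame(as.list(scores), stringsAsFactors = FALSE))
      }))
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

# --- validation ------------------------------------------------------------

#' Validate an evidence database
#'
#' Checks the record-level invariants that are not enforced at
#' construction time and returns a report rather than throwing:
#' an evaluation study with no countries is an error (its context match
#' is undefined), a review with no countries is only a warning (reviews
#' sit on the inner ring regardless), and malformed country codes are
#' errors.
#'
#' @param db An [new_evidence_db()] object.
#' @return A tibble of class `validation_report` with columns `level`
#'   (`"error"`/`"warning"`), `study_id`, `message`; zero rows when all
#'   invariants hold.
#' @export
validate_evidence <- function(db) {
  findings <- list()
  add <- function(level, id, msg) {
    findings[[length(findings) + 1]] <<-
      data.frame(level = level, study_id = id, message = msg,
                 stringsAsFactors = FALSE)
  }
  for (s in db$studies) {
    if (length(s$countries) == 0) {
      if (s$study_type == "evaluation") {
        add("error", s$study_id, "evaluation study has no countries")
      } else {
        add("warning", s$study_id, "review study has no countries")
      }
    }
    bad <- s$countries[!is_alpha3(s$countries)]
    if (length(bad) > 0) {
      add("error", s$study_id,
          sprintf("malformed country code(s): %s", paste(bad, collapse = ", ")))
    }
    if (nrow(s$assessments) == 0) {
      add("error", s$study_id, "study has no assessments")
    }
  }
  rep <- if (length(findings) == 0) {
    data.frame(level = character(), study_id = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
  rep <- tibble::as_tibble(rep)
  class(rep) <- c("validation_report", class(rep))
  rep
}

validation_errors <- function(report) report[report$level == "error", ]

# --- querying and summaries ------------------------------------------------

study_summary_rows <- function(db) {
  rows <- lapply(db$studies, function(s) {
    do.call(rbind, lapply(study_mechanisms(s), function(m) {
      sub <- s$assessments[s$assessments$mechanism == m, ]
      scores <- stats::setNames(sub$score, sub$goal)[goal_levels()]
      cbind(data.frame(study_id = s$study_id,
                       authors = s$citation$authors,
                       title = s$citation$title,
                       year = s$citation$year,
                       journal = s$citation$journal,
                       study_type = s$study_type,
                       countries = paste(s$countries, collapse = ";"),
                       mechanism = m, stringsAsFactors = FALSE),
            as.data.frame(as.list(scores), stringsAsFactors = FALSE))
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- stats::setNames(
      as.data.frame(matrix(character(), ncol = length(evidence_csv_columns())),
                    stringsAsFactors = FALSE),
      evidence_csv_columns())
    out$year <- integer()
  }
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Search and sort the study list
#'
#' The tabular engine behind the searchable, sortable study list: one
#' row per `(study, mechanism)` pair, carrying the five goal scores for
#' that mechanism. Free-text search matches case-insensitively against
#' authors, title, journal, abstract and country codes. The sort is
#' stable, so ties keep their input order.
#'
#' @param db An [new_evidence_db()] object.
#' @param text Optional free-text filter.
#' @param mechanism,goal,country Optional vocabulary filters. A `goal`
#'   filter keeps rows whose score for that goal is not
#'   `not_considered`, i.e. studies that actually assessed it.
#' @param sort_key Column to sort by (default `"study_id"`).
#' @param descending Sort direction.
#' @return A tibble of matching summary rows.
#' @export
query_studies <- function(db, text = NULL, mechanism = NULL, goal = NULL,
                          country = NULL, sort_key = "study_id",
                          descending = FALSE) {
  rows <- study_summary_rows(db)
  if (!sort_key %in% names(rows)) {
    stop_usage(sprintf("unknown sort_key %s (valid: %s)", sQuote(sort_key),
                       paste(names(rows), collapse = ", ")))
  }
  if (!is.null(mechanism)) {
    assert_mechanism(mechanism)
    rows <- rows[rows$mechanism %in% mechanism, , drop = FALSE]
  }
  if (!is.null(goal)) {
    assert_goal(goal)
    rows <- rows[rows[[goal]] != "not_considered", , drop = FALSE]
  }
  if (!is.null(country)) {
    hit <- vapply(strsplit(rows$countries, ";", fixed = TRUE),
                  function(cs) any(country %in% cs), logical(1))
    rows <- rows[hit, , drop = FALSE]
  }
  if (!is.null(text) && nzchar(text)) {
    hay <- paste(rows$authors, rows$title, rows$journal, rows$countries,
                 vapply(rows$study_id, function(id) {
                   idx <- match(id, vapply(db$studies, `[[`, character(1), "study_id"))
                   db$studies[[idx]]$abstract
                 }, character(1)))
    rows <- rows[grepl(text, hay, ignore.case = TRUE, fixed = FALSE), ,
                 drop = FALSE]
  }
  ord <- order(xtfrm(rows[[sort_key]]), decreasing = descending,
               method = "radix")
  rows[ord, , drop = FALSE]
}

#' Tally impact scores for one (mechanism, goal) cell
#'
#' Counts, over all studies addressing `mechanism`, how many report
#' each impact score for `goal`. Studies that do not address the
#' mechanism at all are excluded entirely (they are not counted as
#' `not_considered`), so the counts always sum to the number of studies
#' addressing the mechanism.
#'
#' @inheritParams query_studies
#' @param mechanism,goal Single vocabulary members.
#' @return A named integer vector of class `impact_tally`, one entry
#'   per impact score.
#' @export
impact_summary <- function(db, mechanism, goal) {
  assert_mechanism(mechanism)
  assert_goal(goal)
  tally <- stats::setNames(integer(length(impact_levels())), impact_levels())
  for (s in db$studies) {
    hit <- s$assessments$mechanism == mechanism & s$assessments$goal == goal
    if (any(hit)) {
      sc <- s$assessments$score[hit]
      tally[sc] <- tally[sc] + 1L
    }
  }
  structure(tally, class = "impact_tally")
}

#' @export
print.impact_tally <- function(x, ...) {
  df <- data.frame(score = impact_labels[names(unclass(x))],
                   n = as.integer(x))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Retrieve one study with its full score table
#'
#' @inheritParams query_studies
#' @param study_id Identifier of the study to show.
#' @return A list of class `study_detail` with the `scattar_study`
#'   record and `scores`, a tibble with one row per (mechanism, goal)
#'   pair the study addresses — always five goals per addressed
#'   mechanism, `not_considered` shown explicitly.
#' @export
study_detail <- function(db, study_id) {
  ids <- vapply(db$studies, `[[`, character(1), "study_id")
  idx <- match(study_id, ids)
  if (is.na(idx)) stop_not_found(sprintf("no study with id %s", sQuote(study_id)))
  s <- db$studies[[idx]]
  structure(list(study = s, scores = tibble::as_tibble(s$assessments)),
            class = "study_detail")
}

#' @export
print.study_detail <- function(x, ...) {
  s <- x$study
  cat(sprintf("%s (%s, %d) %s. %s\n", s$study_id, s$citation$authors,
              s$citation$year, s$citation$title, s$citation$journal))
  cat(sprintf("type: %s  countries: %s\n", s$study_type,
              if (length(s$countries)) paste(s$countries, collapse = ", ") else "(none)"))
  print(as.data.frame(x$scores), row.names = FALSE)
  invisible(x)
}
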