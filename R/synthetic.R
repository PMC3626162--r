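#' Settings for the synthetic fixture generators
#'
#' The generators produce indicator tables and evidence databases with
#' the same shape as the real tool's inputs, so every part of the
#' pipeline can be exercised without any download. Defaults mirror the
#' published evidence base: the per-mechanism study counts sum to 88
#' assessment pairs and, with the default 10 multi-mechanism merges,
#' to 78 distinct studies.
#'
#' @param n_countries Number of synthetic countries (>= 2).
#' @param studies_per_mechanism Named integer vector: how many studies
#'   address each financing mechanism.
#' @param review_fraction Probability a study is a literature review
#'   (reviews get an empty country list, consistent with their
#'   inner-ring placement).
#' @param countries_per_study Integer range `c(lo, hi)` for the number
#'   of countries an evaluation study covers.
#' @param goal_coverage_prob Probability each (mechanism, goal) pair is
#'   actually assessed; uncovered pairs are recorded explicitly as
#'   `not_considered`.
#' @param score_weights Sampling weights over the five ordered impact
#'   scores, most negative first.
#' @param missing_fraction Fraction of indicator cells blanked to
#'   exercise the partial-coverage distance path.
#' @param n_multi_mechanism Number of study pairs merged across two
#'   mechanisms, yielding multi-mechanism studies while keeping the
#'   per-mechanism counts intact.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_countries = 30,
                             studies_per_mechanism = c(
                               equity_funds_discount_cards = 2,
                               tax_funded = 2,
                               private_health_insurance = 4,
                               user_fees_implementation = 21,
                               user_fees_removal = 10,
                               community_based_health_insurance = 24,
                               national_health_insurance = 25),
                             review_fraction = 0.15,
                             countries_per_study = c(1, 3),
                             goal_coverage_prob = 0.5,
                             score_weights = c(0.10, 0.15, 0.15, 0.30, 0.30),
                             missing_fraction = 0,
                             n_multi_mechanism = 0,
                             seed = 1) {
  if (n_countries < 2) stop_value("n_countries must be >= 2")
  assert_mechanism(names(studies_per_mechanism))
  if (any(studies_per_mechanism < 0)) stop_value("study counts must be non-negative")
  probs <- c(review_fraction, goal_coverage_prob, missing_fraction)
  if (any(probs < 0 | probs > 1)) stop_value("probabilities must be in [0, 1]")
  if (length(score_weights) != 5 || any(score_weights < 0)) {
    stop_value("score_weights must be 5 non-negative weights")
  }
  if (n_multi_mechanism < 0) stop_value("n_multi_mechanism must be non-negative")
  structure(list(n_countries = as.integer(n_countries),
                 studies_per_mechanism = studies_per_mechanism,
                 review_fraction = review_fraction,
                 countries_per_study = as.integer(countries_per_study),
                 goal_coverage_prob = goal_coverage_prob,
                 score_weights = score_weights,
                 missing_fraction = missing_fraction,
                 n_multi_mechanism = as.integer(n_multi_mechanism),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Plausible per-indicator ranges for synthetic countries. Ordinally
# sensible values are enough: no statistical claim depends on them.
indicator_ranges <- function() {
  data.frame(
    indicator = indicator_names(),
    min = c(5, 10, 5, 0.1, 0, 0.2, 5e8, 40, 10, 1, 1e5),
    max = c(500, 1500, 200, 25, 400, 0.9, 5e12, 80, 90, 80, 1e9),
    log_uniform = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                    FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

# Deterministic alpha-3 codes: AAA, AAB, AAC, ...
make_country_codes <- function(n) {
  stopifnot(n <= 26^3)
  i <- seq_len(n) - 1L
  paste0(LETTERS[i %/% 676 + 1], LETTERS[(i %/% 26) %% 26 + 1],
         LETTERS[i %% 26 + 1])
}

#' Generate a synthetic country indicator table
#'
#' Draws `n_countries` rows with values uniform within plausible
#' per-indicator ranges (GDP and population log-uniformly); population
#' is drawn as a raw headcount and logged by the table constructor,
#' exactly as a real CSV would be loaded. Optionally blanks a fraction
#' of cells to exercise partial-coverage distances.
#'
#' @param config A [synthetic_config()].
#' @return An [new_indicator_table()] object, identical for identical
#'   seeds.
#' @export
generate_indicator_table <- function(config = synthetic_config()) {
  with_seed(config$seed, {
    n <- config$n_countries
    rng <- indicator_ranges()
    values <- data.frame(country_code = make_country_codes(n),
                         stringsAsFactors = FALSE)
    for (r in seq_len(nrow(rng))) {
      v <- if (rng$log_uniform[r]) {
        10^stats::runif(n, log10(rng$min[r]), log10(rng$max[r]))
      } else {
        stats::runif(n, rng$min[r], rng$max[r])
      }
      values[[rng$indicator[r]]] <- v
    }
    if (config$missing_fraction > 0) {
      cells <- expand.grid(row = seq_len(n), col = indicator_names(),
                           stringsAsFactors = FALSE)
      k <- floor(nrow(cells) * config$missing_fraction)
      if (k > 0) {
        drop <- cells[sample(nrow(cells), k), ]
        for (j in seq_len(nrow(drop))) {
          values[drop$row[j], drop$col[j]] <- NA_real_
        }
      }
    }
    new_indicator_table(values)
  })
}

surname_pool <- c("Okello", "Mwangi", "Nguyen", "Diallo", "Perez", "Singh",
                  "Osei", "Banda", "Silva", "Haidara", "Rahman", "Castro")
topic_pool <- c("enrolment", "utilisation", "catastrophic spending",
                "provider payment", "risk pooling", "access", "coverage",
                "out-of-pocket payments", "service quality", "revenue")
journal_pool <- c("Health Policy Plan", "Soc Sci Med", "Bull World Health Organ",
                  "Health Econ", "Int J Equity Health", "BMC Health Serv Res")

# Deterministic schedule of multi-mechanism merges: repeatedly pair the
# two mechanisms with the most unmerged single-mechanism studies left.
merge_schedule <- function(counts, n_multi) {
  remaining <- counts
  sets <- list()
  for (j in seq_len(n_multi)) {
    ord <- order(-remaining, match(names(remaining), mechanism_levels()))
    top <- names(remaining)[ord[1:2]]
    if (any(remaining[top] < 1)) {
      stop_value("n_multi_mechanism too large for the configured study counts")
    }
    remaining[top] <- remaining[top] - 1
    sets[[j]] <- top
  }
  list(multi = sets, single = remaining)
}

#' Generate a synthetic evidence database
#'
#' Produces exactly the configured number of studies per mechanism;
#' study countries are sampled from the supplied indicator table so
#' every evaluation dot is placeable. Scores are drawn from
#' `score_weights` for pairs passing the `goal_coverage_prob` gate and
#' recorded as explicit `not_considered` otherwise. Output always
#' passes [validate_evidence()] with no errors, and is identical for
#' identical seeds.
#'
#' @param config A [synthetic_config()].
#' @param table The [new_indicator_table()] to draw study countries
#'   from.
#' @return An [new_evidence_db()] object.
#' @export
generate_evidence_db <- function(config = synthetic_config(),
                                 table = generate_indicator_table(config)) {
  if (nrow(table$values) == 0) stop_value("indicator table is empty")
  sched <- merge_schedule(config$studies_per_mechanism,
                          config$n_multi_mechanism)
  mech_sets <- c(sched$multi,
                 unlist(lapply(mechanism_levels(), function(m) {
                   k <- sched$single[m]
                   if (is.na(k) || k == 0) return(list())
                   rep(list(m), k)
                 }), recursive = FALSE))
  codes <- table$values$country_code
  with_seed(config$seed + 1L, {
    studies <- lapply(seq_along(mech_sets), function(i) {
      mechs <- mech_sets[[i]]
      is_review <- stats::runif(1) < config$review_fraction
      countries <- if (is_review) {
        character()
      } else {
        kk <- seq(config$countries_per_study[1],
                  min(config$countries_per_study[2], length(codes)))
        k <- kk[sample.int(length(kk), 1)]
        sort(sample(codes, k))
      }
      assessments <- do.call(rbind, lapply(mechs, function(m) {
        covered <- stats::runif(5) < config$goal_coverage_prob
        score <- ifelse(covered,
                        sample(ordered_impact_levels(), 5, replace = TRUE,
                               prob = config$score_weights),
                        "not_considered")
        data.frame(mechanism = m, goal = goal_levels(), score = score,
                   stringsAsFactors = FALSE)
      }))
      new_study(
        study_id = sprintf("S%03d", i),
        citation = list(
          authors = paste(sample(surname_pool, 2), collapse = ", "),
          title = sprintf("%s and %s under %s",
                          sample(topic_pool, 1), sample(topic_pool, 1),
                          tolower(mechanism_labels[[mechs[[1]]]])),
          year = sample(1995:2010, 1),
          journal = sample(journal_pool, 1)),
        study_type = if (is_review) "review" else "evaluation",
        countries = countries,
        assessments = assessments)
    })
    new_evidence_db(studies,
                    provenance = sprintf("synthetic evidence database (seed %d)",
                                         config$seed))
  })
}

#' The paper-shaped reference fixture
#'
#' Convenience wrapper producing a synthetic evidence base with the
#' published shape: 30 countries, per-mechanism study counts of 2
#' (equity funds), 2 (tax-funded), 4 (private insurance), 21 (user-fee
#' implementation), 10 (user-fee removal), 24 (CBHI) and 25 (NHI) — 88
#' assessment pairs — carried by 78 distinct studies, ten of which
#' address two mechanisms. Used by integration tests and the worked
#' examples.
#'
#' @param seed Integer seed.
#' @return A list with elements `table` ([new_indicator_table()]),
#'   `db` ([new_evidence_db()]) and `config`.
#' @export
paper_shaped_fixture <- function(seed = 1) {
  config <- synthetic_config(n_multi_mechanism = 10, seed = seed)
  table <- generate_indicator_table(config)
  list(table = table, db = generate_evidence_db(config, table),
       config = config)
}

#' Write a paired set of fixture files
#'
#' Writes `indicators.csv`, `evidence.json` and `evidence.csv` for a
#' generated table/database pair — the `simulate` CLI subcommand's
#' backend.
#'
#' @param dir Output directory (created if needed).
#' @param table An [new_indicator_table()].
#' @param db An [new_evidence_db()].
#' @return The three paths, invisibly.
#' @export
write_fixtures <- function(dir, table, db) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(indicators = file.path(dir, "indicators.csv"),
             evidence_json = file.path(dir, "evidence.json"),
             evidence_csv = file.path(dir, "evidence.csv"))
  write_indicators(table, paths[["indicators"]])
  write_evidence(db, paths[["evidence_json"]], format = "json")
  write_evidence(db, paths[["evidence_csv"]], format = "csv")
  invisible(paths)
}
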