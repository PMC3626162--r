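# In-code fixtures shared across the test files. Everything is built
# programmatically; nothing is read from disk except what a test writes
# itself.

# An indicator table from an explicit matrix of raw values (population
# as a raw headcount; the constructor logs it).
manual_table <- function(raw_rows) {
  df <- data.frame(country_code = names(raw_rows), stringsAsFactors = FALSE)
  mat <- do.call(rbind, raw_rows)
  colnames(mat) <- indicator_names()
  new_indicator_table(cbind(df, as.data.frame(mat)))
}

# Three countries: AAA holds every minimum, BBB every maximum, CCC the
# midpoint of each range — so profiles are 0, 1 and 0.5 exactly.
tiny_indicator_values <- function() {
  lo <- c(10, 100, 20, 1, 10, 0.3, 1e9, 45, 20, 10, 1e5)
  hi <- c(200, 900, 180, 15, 300, 0.8, 1e12, 75, 80, 70, 1e9)
  # midpoint on the *transformed* scale: population midpoint in log10
  mid <- (lo + hi) / 2
  mid[11] <- 10^((log10(lo[11]) + log10(hi[11])) / 2)
  list(AAA = lo, BBB = hi, CCC = mid)
}

tiny_table <- function() manual_table(tiny_indicator_values())

make_assessments <- function(mechanism, scores) {
  data.frame(mechanism = mechanism, goal = names(scores),
             score = unname(scores), stringsAsFactors = FALSE)
}

# 1 review + 2 evaluations, one mechanism, hand-checkable scores.
tiny_db <- function() {
  cit <- function(i) list(authors = paste0("Author", i), title = paste("Study", i),
                          year = 2000 + i, journal = "J Test")
  s1 <- new_study("R1", cit(1), "review", character(),
                  make_assessments("community_based_health_insurance",
                                   c(promote_equity = "evidence_for")))
  s2 <- new_study("E1", cit(2), "evaluation", "AAA",
                  make_assessments("community_based_health_insurance",
                                   c(promote_equity = "some_evidence_against",
                                     increase_use = "evidence_for")))
  s3 <- new_study("E2", cit(3), "evaluation", "BBB",
                  make_assessments("community_based_health_insurance",
                                   c(promote_equity = "no_evidence_of_impact")))
  new_evidence_db(list(s1, s2, s3), provenance = "tiny fixture")
}

# A context vector built directly, bypassing any table.
make_cv <- function(values, country = "ZZZ") {
  structure(list(country = country,
                 values = stats::setNames(values, indicator_names()),
                 present = !is.na(values)),
            class = "context_vector")
}

# Independent loop-based distance oracle: Euclidean over shared
# dimensions, rescaled to the 11-dimension scale.
brute_distance <- function(a, b) {
  s <- 0
  k <- 0
  for (j in 1:11) {
    if (a$present[j] && b$present[j]) {
      k <- k + 1
      s <- s + (a$values[[j]] - b$values[[j]])^2
    }
  }
  sqrt(s * 11 / k)
}

# Field-by-field database comparison (ignores provenance, which records
# the source path on CSV load).
expect_db_equal <- function(a, b) {
  expect_equal(length(a$studies), length(b$studies))
  for (i in seq_along(a$studies)) {
    x <- a$studies[[i]]
    y <- b$studies[[i]]
    expect_identical(x$study_id, y$study_id)
    expect_identical(x$citation, y$citation)
    expect_identical(x$abstract, y$abstract)
    expect_identical(x$study_type, y$study_type)
    expect_identical(x$countries, y$countries)
    expect_identical(x$assessments, y$assessments)
  }
}

write_cli_fixtures <- function(dir = tempfile("cli-fixtures-")) {
  fx <- paper_shaped_fixture(7)
  write_fixtures(dir, fx$table, fx$db)
}
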