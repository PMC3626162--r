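#' The eleven context-matching indicators
#'
#' Country context is summarised by eleven indicators chosen to be
#' independently informative for health financing policy and easily
#' available for most low- and middle-income countries: health
#' expenditure per capita, maternal mortality ratio, under-5 mortality
#' rate, HIV prevalence, malaria incidence, education index, GDP, life
#' expectancy at birth, urban population share, the share living on
#' under $1.25/day, and population (stored as its base-10 logarithm).
#'
#' @return Character vector of the 11 indicator column names, in
#'   canonical order.
#' @export
indicator_names <- function() {
  c("health_expenditure_per_capita_usd", "maternal_mortality_ratio",
    "under5_mortality_rate", "hiv_prevalence", "malaria_incidence",
    "education_index", "gdp_usd", "life_expectancy_at_birth",
    "urban_population_pct", "poverty_125_usd_pct", "population")
}

N_INDICATORS <- 11L

#' Build an indicator table from a country-by-indicator data frame
#'
#' @param values Data frame with a `country_code` column and the 11
#'   indicator columns of [indicator_names()]. `NA` cells are allowed
#'   and flagged as missing.
#' @param population_logged Set to `TRUE` if the `population` column is
#'   already log10-transformed; raw headcounts are logged here so that
#'   min-max bounds are computed on the log scale.
#' @return An object of class `indicator_table` with per-indicator
#'   `(min, max)` bounds computed over the table's countries.
#' @export
new_indicator_table <- function(values, population_logged = FALSE) {
  if (!"country_code" %in% names(values)) {
    stop_format("indicator table needs a country_code column")
  }
  missing <- setdiff(indicator_names(), names(values))
  if (length(missing) > 0) {
    stop_format(sprintf("missing indicator column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(values$country_code)) {
    stop_integrity("duplicate country_code in indicator table")
  }
  values <- values[, c("country_code", indicator_names())]
  for (ind in indicator_names()) {
    if (!is.numeric(values[[ind]])) {
      stop_format(sprintf("column %s is not numeric", ind))
    }
  }
  if (!population_logged) {
    pop <- values$population
    if (any(!is.na(pop) & pop <= 0)) {
      stop_value("population must be positive to take its base-10 log")
    }
    values$population <- log10(pop)
  }
  bounds <- data.frame(
    indicator = indicator_names(),
    min = vapply(indicator_names(), function(i) {
      v <- values[[i]]
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    }, numeric(1)),
    max = vapply(indicator_names(), function(i) {
      v <- values[[i]]
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(bounds) <- NULL
  structure(list(values = tibble::as_tibble(values),
                 indicators = indicator_names(),
                 bounds = bounds),
            class = "indicator_table")
}

#' Read a country indicator table from CSV
#'
#' Expects one row per country with a `country_code` column plus the 11
#' indicator columns; the `population` column holds raw headcounts and
#' is replaced by its base-10 logarithm before the per-indicator
#' min/max bounds are computed. Empty cells are treated as missing;
#' non-numeric text in a numeric cell is a format error naming the
#' offending row and column.
#'
#' @param path Path to the CSV file.
#' @return An [new_indicator_table()] object.
#' @export
load_indicators <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                  colClasses = "character"),
                  error = function(e) {
                    stop_format(sprintf("cannot parse CSV %s: %s", path,
                                        conditionMessage(e)))
                  })
  missing <- setdiff(c("country_code", indicator_names()), names(raw))
  if (length(missing) > 0) {
    stop_format(sprintf("%s: missing column(s): %s", path,
                        paste(missing, collapse = ", ")))
  }
  for (ind in indicator_names()) {
    cell <- trimws(raw[[ind]])
    cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0) {
      stop_format(sprintf("%s: non-numeric value %s in row %d, column %s",
                          path, sQuote(cell[bad[1]]), bad[1], ind))
    }
    raw[[ind]] <- num
  }
  new_indicator_table(raw[, c("country_code", indicator_names())])
}

#' Write an indicator table to CSV
#'
#' The `population` column is written back as raw headcounts
#' (`10^population`) so a written table re-loads identically.
#'
#' @param table An [new_indicator_table()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indicators <- function(table, path) {
  out <- as.data.frame(table$values)
  out$population <- 10^out$population
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Min-max transform of one indicator value
#'
#' Linearly rescales `value` from `[min, max]` to `[0, 1]`:
#' `(value - min) / (max - min)`. Out-of-range inputs clamp to the
#' nearest endpoint, keeping the codomain contract when a user's value
#' falls outside the bounds of the reference country set. A degenerate
#' indicator with `min == max` maps every value to 0.5, so an
#' uninformative dimension contributes nothing to any distance.
#'
#' @param value Numeric vector of raw indicator values.
#' @param min,max Per-indicator bounds over the reference countries.
#' @return Numeric vector in `[0, 1]` (`NA` for `NA` input).
#' @export
transform_indicator <- function(value, min, max) {
  if (any(!is.na(min) & !is.na(max) & min > max)) {
    stop_value("indicator bounds must satisfy min <= max")
  }
  out <- ifelse(min == max, 0.5, (value - min) / (max - min))
  pmin(pmax(out, 0), 1)
}

#' A country's normalised context profile
#'
#' Transforms a country's 11 raw indicator values into the unit
#' hypercube via [transform_indicator()] with the table's bounds. The
#' result is the country's coordinates on the 11-dimensional graph used
#' for context matching; missing raw values stay absent and are flagged
#' in the `present` mask.
#'
#' @param table An [new_indicator_table()] object.
#' @param country Alpha-3 country code present in the table.
#' @return An object of class `context_vector` with fields `country`,
#'   `values` (11 numbers in `[0, 1]`, `NA` where missing) and
#'   `present` (11 logicals).
#' @export
country_profile <- function(table, country) {
  idx <- match(country, table$values$country_code)
  if (is.na(idx)) stop_not_found(sprintf("country %s not in indicator table",
                                         sQuote(country)))
  raw <- as.numeric(unlist(table$values[idx, table$indicators]))
  vals <- transform_indicator(raw, table$bounds$min, table$bounds$max)
  structure(list(country = country,
                 values = stats::setNames(vals, table$indicators),
                 present = !is.na(vals)),
            class = "context_vector")
}

#' Context-match distance between two countries
#'
#' The Euclidean distance between two normalised 11-dimensional context
#' profiles. When some indicators are missing, the distance is computed
#' over the `k` dimensions present in both profiles and rescaled by
#' `sqrt(11 / k)`, so partial-coverage distances stay on the same
#' `[0, sqrt(11)]` scale as full-coverage ones.
#'
#' @param a,b `context_vector` objects sharing the indicator ordering.
#' @return An object of class `match_distance` with fields `value` and
#'   `k_present`.
#' @export
context_distance <- function(a, b) {
  shared <- a$present & b$present
  k <- sum(shared)
  if (k == 0) {
    stop_distance(sprintf(
      "no shared indicator dimensions between %s and %s; distance undefined",
      a$country, b$country))
  }
  diff <- a$values[shared] - b$values[shared]
  structure(list(value = sqrt(sum(diff^2) * N_INDICATORS / k),
                 k_present = as.integer(k)),
            class = "match_distance")
}

#' @export
print.match_distance <- function(x, ...) {
  cat(sprintf("<match_distance> %.4f over %d/11 dimensions\n",
              x$value, x$k_present))
  invisible(x)
}

#' Rank all countries by context match to one country
#'
#' @param table An [new_indicator_table()] object.
#' @param country The reference country code.
#' @param include_self Include the reference country itself (at
#'   distance 0, ranked first)? Default drops it.
#' @return A tibble with columns `country_code`, `distance`,
#'   `k_present`, sorted ascending by distance with ties broken by
#'   country code.
#' @export
rank_matches <- function(table, country, include_self = FALSE) {
  ref <- country_profile(table, country)
  others <- table$values$country_code
  if (!include_self) others <- setdiff(others, country)
  ds <- lapply(others, function(cc) {
    context_distance(ref, country_profile(table, cc))
  })
  out <- tibble::tibble(
    country_code = others,
    distance = vapply(ds, `[[`, numeric(1), "value"),
    k_present = vapply(ds, `[[`, integer(1), "k_present"))
  out[order(out$distance, out$country_code, method = "radix"), ]
}

#' Context distance from a study to a country
#'
#' A study's match to the user's country is the *minimum*
#' [context_distance()] over the countries the study analysed — the
#' best-matching study country determines the dot's radius. Review
#' studies sit on the inner ring by convention and return distance 0
#' without consulting their country lists. Study countries absent from
#' the indicator table are skipped with a warning.
#'
#' @param study A `scattar_study` object.
#' @param country The user's country code.
#' @param table An [new_indicator_table()] object.
#' @return A `match_distance` object.
#' @export
study_distance <- function(study, country, table) {
  if (study$study_type == "review") {
    return(structure(list(value = 0, k_present = N_INDICATORS),
                     class = "match_distance"))
  }
  known <- intersect(study$countries, table$values$country_code)
  skipped <- setdiff(study$countries, known)
  if (length(skipped) > 0) {
    warning(sprintf("study %s: skipping countries absent from indicator table: %s",
                    study$study_id, paste(skipped, collapse = ", ")),
            call. = FALSE)
  }
  if (length(known) == 0) {
    stop_distance(sprintf(
      "evaluation study %s has no country resolvable in the indicator table",
      study$study_id))
  }
  ref <- country_profile(table, country)
  ds <- lapply(known, function(cc) context_distance(ref, country_profile(table, cc)))
  ds[[which.min(vapply(ds, `[[`, numeric(1), "value"))]]
}
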