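#' Controlled vocabularies
#'
#' The evidence model is built on three closed vocabularies: the five
#' goals a health financing policy may pursue, the seven financing
#' mechanisms covered by the tool (user fees split into implementation
#' and removal), and the qualitative impact scale of five ordered scores
#' plus an explicit "not considered" state recording that a study
#' addressed a mechanism but not a given goal.
#'
#' @return A character vector of the vocabulary members, in canonical
#'   order. For `impact_levels()` the first five entries form the
#'   ordered scale from most negative to most positive;
#'   `not_considered` sits outside the scale.
#' @examples
#' goal_levels()
#' mechanism_levels()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
goal_levels <- function() {
  c("promote_equity", "reduce_poverty", "improve_quality",
    "generate_revenue", "increase_use")
}

#' @rdname vocabularies
#' @export
mechanism_levels <- function() {
  c("equity_funds_discount_cards", "tax_funded", "private_health_insurance",
    "user_fees_implementation", "user_fees_removal",
    "community_based_health_insurance", "national_health_insurance")
}

#' @rdname vocabularies
#' @export
impact_levels <- function() {
  c("evidence_against", "some_evidence_against", "no_evidence_of_impact",
    "some_evidence_for", "evidence_for", "not_considered")
}

#' @rdname vocabularies
#' @export
ordered_impact_levels <- function() impact_levels()[1:5]

study_type_levels <- function() c("review", "evaluation")

# Human-readable labels used on plots and in CLI tables.
mechanism_labels <- c(
  equity_funds_discount_cards      = "Equity funds / discount cards",
  tax_funded                       = "Tax-funded",
  private_health_insurance         = "Private health insurance",
  user_fees_implementation         = "User fees (implementation)",
  user_fees_removal                = "User fees (removal)",
  community_based_health_insurance = "Community-based health insurance",
  national_health_insurance        = "National health insurance"
)

goal_labels <- c(
  promote_equity   = "Promote equity",
  reduce_poverty   = "Reduce poverty",
  improve_quality  = "Improve quality",
  generate_revenue = "Generate revenue",
  increase_use     = "Increase use"
)

impact_labels <- c(
  evidence_against      = "Evidence against",
  some_evidence_against = "Some evidence against",
  no_evidence_of_impact = "No evidence of impact",
  some_evidence_for     = "Some evidence for",
  evidence_for          = "Evidence for",
  not_considered        = "Not considered"
)

# --- structured conditions -------------------------------------------------

stop_scattar <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "scattar_error"),
                      call = call))
}

stop_format <- function(message) stop_scattar(message, "scattar_format_error")
stop_vocab <- function(message) stop_scattar(message, "scattar_vocabulary_error")
stop_integrity <- function(message) stop_scattar(message, "scattar_integrity_error")
stop_not_found <- function(message) stop_scattar(message, "scattar_not_found_error")
stop_usage <- function(message) stop_scattar(message, "scattar_usage_error")
stop_value <- function(message) stop_scattar(message, "scattar_value_error")
stop_range <- function(message) stop_scattar(message, "scattar_range_error")
stop_distance <- function(message) stop_scattar(message, "scattar_distance_error")
stop_layout <- function(message) stop_scattar(message, "scattar_layout_error")

assert_vocab <- function(x, levels, what) {
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    stop_vocab(sprintf("unknown %s label(s): %s (valid: %s)", what,
                       paste(sQuote(bad), collapse = ", "),
                       paste(levels, collapse = ", ")))
  }
  invisible(x)
}

assert_goal <- function(x) assert_vocab(x, goal_levels(), "goal")
assert_mechanism <- function(x) assert_vocab(x, mechanism_levels(), "mechanism")
assert_score <- function(x) assert_vocab(x, impact_levels(), "impact score")

is_alpha3 <- function(x) grepl("^[A-Z]{3}$", x)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
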