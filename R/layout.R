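#' Map an impact score to a dot colour category
#'
#' Colours range from green for positive impact to red for negative
#' impact, with orange marking definite evidence of *no* impact and
#' grey marking studies that addressed the mechanism but not the goal
#' under consideration (an evidence gap).
#'
#' @param score Impact score label(s).
#' @return Colour category label(s): one of `green`, `light_green`,
#'   `orange`, `light_red`, `red`, `grey`.
#' @export
dot_color <- function(score) {
  assert_score(score)
  map <- c(evidence_for = "green", some_evidence_for = "light_green",
           no_evidence_of_impact = "orange",
           some_evidence_against = "light_red",
           evidence_against = "red", not_considered = "grey")
  unname(map[score])
}

#' Map a study type to a dot shape
#'
#' Literature reviews are differentiated from evaluation-style studies
#' to reduce the risk of double-counting evidence: reviews are square
#' dots on the inner ring, all other studies round dots.
#'
#' @param study_type `"review"` or `"evaluation"`.
#' @return `"square"` or `"circle"`.
#' @export
dot_shape <- function(study_type) {
  assert_vocab(study_type, study_type_levels(), "study_type")
  unname(c(review = "square", evaluation = "circle")[study_type])
}

#' Geometry settings for a scattar layout
#'
#' @param inner_radius,outer_radius Ring radii in drawing units
#'   (pixels once rendered); dots sit between them.
#' @param sector_gap Angular gap between adjacent mechanism sectors,
#'   radians; must leave room in each of the 7 sectors.
#' @param dot_diameter Marker diameter in drawing units.
#' @param max_distance Context distance mapped to the outer ring; the
#'   theoretical maximum `sqrt(11)` by default so layouts stay
#'   comparable across databases.
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(inner_radius = 60, outer_radius = 230,
                            sector_gap = 0.08, dot_diameter = 9,
                            max_distance = sqrt(11)) {
  if (!(inner_radius > 0 && inner_radius < outer_radius)) {
    stop_value("need 0 < inner_radius < outer_radius")
  }
  if (!(sector_gap >= 0 && sector_gap < 2 * pi / 7)) {
    stop_value("sector_gap must be in [0, 2*pi/7)")
  }
  if (dot_diameter <= 0) stop_value("dot_diameter must be positive")
  if (max_distance <= 0) stop_value("max_distance must be positive")
  structure(list(inner_radius = inner_radius, outer_radius = outer_radius,
                 sector_gap = sector_gap, dot_diameter = dot_diameter,
                 max_distance = max_distance),
            class = "geometry_config")
}

#' Normalised radial position of a dot
#'
#' Maps a context-match distance linearly onto `[0, 1]`, where 0 is the
#' inner ring (an exact country match, or a review) and 1 the outer
#' ring (the theoretical maximum mismatch `sqrt(11)`).
#'
#' @param d A `match_distance` object (or bare non-negative number).
#' @param geometry A [geometry_config()].
#' @return A number in `[0, 1]`, strictly increasing in the distance.
#' @export
dot_radius <- function(d, geometry = geometry_config()) {
  v <- if (inherits(d, "match_distance")) d$value else as.numeric(d)
  if (v < 0) stop_range("distance must be non-negative")
  if (v > geometry$max_distance + 1e-9) {
    stop_range(sprintf("distance %.4f exceeds max_distance %.4f",
                       v, geometry$max_distance))
  }
  min(v / geometry$max_distance, 1)
}

# Angular intervals of the 7 mechanism sectors, clockwise from 12
# o'clock, in the fixed legend order of mechanism_levels().
sector_table <- function() {
  width <- 2 * pi / 7
  data.frame(mechanism = mechanism_levels(),
             start = (seq_len(7) - 1) * width,
             end = seq_len(7) * width,
             stringsAsFactors = FALSE)
}

#' Compute the scattar dot layout for one country and goal
#'
#' The scattar plot is a hybrid scatter/radar display: concentric rings
#' divided into 7 mechanism sectors, with one dot per
#' `(study, mechanism)` assessment pair. Radius encodes the study's
#' context mismatch to `country` ([study_distance()] via
#' [dot_radius()]; reviews at 0), colour encodes the study's impact
#' score for `goal`, shape encodes review vs evaluation. Every plot of
#' the same database has the same dot set: positions depend only on the
#' country, colours only on the goal.
#'
#' Within each sector, dots are sorted by `(radius_norm, study_id)` and
#' assigned deterministic, evenly spread angles inside the sector minus
#' its gap — no random jitter, so identical inputs give byte-identical
#' layouts and co-located dots get successive angular slots instead of
#' overplotting.
#'
#' @param db A validated [new_evidence_db()].
#' @param table An [new_indicator_table()] containing `country` and the
#'   countries of every evaluation study.
#' @param country The user's alpha-3 country code.
#' @param goal The goal whose impact scores colour the dots.
#' @param geometry A [geometry_config()].
#' @return An object of class `scattar_layout` with fields `country`,
#'   `goal`, `sectors`, `geometry` and `dots` (a tibble with columns
#'   `study_id`, `mechanism`, `shape`, `radius_norm`, `angle`, `color`,
#'   `distance`).
#' @export
layout_scattar <- function(db, table, country, goal,
                           geometry = geometry_config()) {
  assert_goal(goal)
  if (!country %in% table$values$country_code) {
    stop_not_found(sprintf("country %s not in indicator table", sQuote(country)))
  }
  errs <- validation_errors(validate_evidence(db))
  if (nrow(errs) > 0) {
    stop_layout(sprintf("evidence database fails validation: %s",
                        paste(sprintf("%s (%s)", errs$message, errs$study_id),
                              collapse = "; ")))
  }

  # one context distance per study, reused across its mechanisms
  dist_of <- lapply(db$studies, function(s) {
    tryCatch(study_distance(s, country, table),
             scattar_distance_error = function(e) {
               stop_layout(sprintf("cannot place study %s: %s", s$study_id,
                                   conditionMessage(e)))
             })
  })

  rows <- do.call(rbind, lapply(seq_along(db$studies), function(i) {
    s <- db$studies[[i]]
    d <- dist_of[[i]]
    r <- if (s$study_type == "review") 0 else dot_radius(d, geometry)
    do.call(rbind, lapply(study_mechanisms(s), function(m) {
      sc <- s$assessments$score[s$assessments$mechanism == m &
                                  s$assessments$goal == goal]
      data.frame(study_id = s$study_id, mechanism = m,
                 shape = dot_shape(s$study_type),
                 radius_norm = r, color = dot_color(sc),
                 distance = if (s$study_type == "review") 0 else d$value,
                 stringsAsFactors = FALSE)
    }))
  }))

  sectors <- sector_table()
  if (is.null(rows)) {
    rows <- data.frame(study_id = character(), mechanism = character(),
                       shape = character(), radius_norm = numeric(),
                       color = character(), distance = numeric(),
                       stringsAsFactors = FALSE)
  }
  rows$angle <- rep(NA_real_, nrow(rows))
  placed <- lapply(seq_len(nrow(sectors)), function(k) {
    sub <- rows[rows$mechanism == sectors$mechanism[k], , drop = FALSE]
    if (nrow(sub) == 0) return(sub)
    sub <- sub[order(sub$radius_norm, sub$study_id, method = "radix"), ,
               drop = FALSE]
    usable <- (sectors$end[k] - sectors$start[k]) - geometry$sector_gap
    n <- nrow(sub)
    sub$angle <- sectors$start[k] + geometry$sector_gap / 2 +
      usable * (seq_len(n) - 0.5) / n
    sub
  })
  dots <- do.call(rbind, placed)
  rownames(dots) <- NULL
  structure(list(country = country, goal = goal, sectors = sectors,
                 geometry = geometry,
                 dots = tibble::as_tibble(dots[, c("study_id", "mechanism",
                                                   "shape", "radius_norm",
                                                   "angle", "color",
                                                   "distance")])),
            class = "scattar_layout")
}

#' @export
print.scattar_layout <- function(x, ...) {
  cat(sprintf("<scattar_layout> %s / %s: %d dots in 7 sectors\n",
              x$country, goal_labels[[x$goal]], nrow(x$dots)))
  print(table(factor(x$dots$mechanism, levels = mechanism_levels())))
  invisible(x)
}

#' One layout per goal, sharing positions
#'
#' Computes the five per-goal layouts used as thumbnails under the main
#' plot. Because positions depend only on the country and colours only
#' on the goal, the five layouts have pairwise identical
#' `(study_id, mechanism, radius, angle)` sets and differ only in
#' colour.
#'
#' @inheritParams layout_scattar
#' @return A named list of five `scattar_layout` objects, in
#'   [goal_levels()] order.
#' @export
layout_thumbnails <- function(db, table, country,
                              geometry = geometry_config()) {
  stats::setNames(lapply(goal_levels(), function(g) {
    layout_scattar(db, table, country, g, geometry)
  }), goal_levels())
}

#' Serialise a layout for external renderers
#'
#' Writes the dot set with both polar coordinates (`radius_norm`,
#' `angle` clockwise from 12 o'clock) and pre-computed Cartesian
#' coordinates in drawing units with the origin at the plot centre.
#'
#' @param layout A [layout_scattar()] result.
#' @param path Optional path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
layout_to_json <- function(layout, path = NULL) {
  g <- layout$geometry
  r <- g$inner_radius + layout$dots$radius_norm * (g$outer_radius - g$inner_radius)
  dots <- as.data.frame(layout$dots)
  dots$x <- round(r * sin(dots$angle), 6)
  dots$y <- round(-r * cos(dots$angle), 6)
  doc <- list(country = layout$country, goal = layout$goal,
              geometry = unclass(g), sectors = layout$sectors, dots = dots)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
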