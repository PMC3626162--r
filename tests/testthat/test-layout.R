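test_that("score-to-colour and type-to-shape maps follow the display rules", {
  expect_identical(dot_color("evidence_for"), "green")
  expect_identical(dot_color("some_evidence_for"), "light_green")
  expect_identical(dot_color("no_evidence_of_impact"), "orange")
  expect_identical(dot_color("some_evidence_against"), "light_red")
  expect_identical(dot_color("evidence_against"), "red")
  expect_identical(dot_color("not_considered"), "grey")
  # bijective over the vocabulary
  expect_equal(anyDuplicated(dot_color(impact_levels())), 0)

  expect_identical(dot_shape("review"), "square")
  expect_identical(dot_shape("evaluation"), "circle")
  expect_error(dot_shape("meta_analysis"), class = "scattar_vocabulary_error")
})

test_that("radius normalisation is linear in distance with range errors", {
  g <- geometry_config()
  expect_equal(dot_radius(0, g), 0)
  expect_equal(dot_radius(sqrt(11), g), 1)
  expect_equal(dot_radius(sqrt(11) / 2, g), 0.5)
  d <- structure(list(value = 1.2, k_present = 11L), class = "match_distance")
  expect_equal(dot_radius(d, g), 1.2 / sqrt(11))
  expect_error(dot_radius(4, g), class = "scattar_range_error")
  expect_error(dot_radius(-1, g), class = "scattar_range_error")
  expect_error(geometry_config(inner_radius = 0), class = "scattar_value_error")
  expect_error(geometry_config(sector_gap = 1), class = "scattar_value_error")
})

test_that("hand-built fixture lands where the display rules dictate", {
  lay <- layout_scattar(tiny_db(), tiny_table(), "AAA", "promote_equity")
  dots <- lay$dots
  expect_equal(nrow(dots), 3)
  expect_true(all(dots$mechanism == "community_based_health_insurance"))

  sq <- dots[dots$study_id == "R1", ]      # review square on inner ring
  expect_equal(sq$shape, "square")
  expect_equal(sq$radius_norm, 0)
  exact <- dots[dots$study_id == "E1", ]   # exact country match
  expect_equal(exact$shape, "circle")
  expect_equal(exact$radius_norm, 0)
  far <- dots[dots$study_id == "E2", ]     # BBB is at distance sqrt(11)
  expect_equal(far$radius_norm, 1)

  expect_equal(sq$color, "green")
  expect_equal(exact$color, "light_red")
  expect_equal(far$color, "orange")

  # angles sit inside the CBHI sector minus the gap
  sec <- lay$sectors[lay$sectors$mechanism == "community_based_health_insurance", ]
  gap <- lay$geometry$sector_gap
  expect_true(all(dots$angle >= sec$start + gap / 2 - 1e-12))
  expect_true(all(dots$angle <= sec$end - gap / 2 + 1e-12))
})

test_that("positions follow the country, colours follow the goal", {
  fx <- paper_shaped_fixture(2)
  cc <- fx$table$values$country_code
  base <- layout_scattar(fx$db, fx$table, cc[1], "promote_equity")

  other_goal <- layout_scattar(fx$db, fx$table, cc[1], "generate_revenue")
  pos_cols <- c("study_id", "mechanism", "shape", "radius_norm", "angle")
  expect_identical(base$dots[pos_cols], other_goal$dots[pos_cols])

  # row order follows radius, so compare colours keyed by (study, mechanism)
  other_country <- layout_scattar(fx$db, fx$table, cc[9], "promote_equity")
  key <- function(d) d[order(d$study_id, d$mechanism),
                       c("study_id", "mechanism", "color")]
  expect_identical(key(base$dots), key(other_country$dots))
  expect_equal(nrow(other_country$dots), nrow(base$dots))
})

test_that("radius-zero dots are exactly reviews and exact country matches", {
  fx <- paper_shaped_fixture(4)
  cc <- fx$table$values$country_code[3]
  lay <- layout_scattar(fx$db, fx$table, cc, "improve_quality")
  ids <- vapply(fx$db$studies, `[[`, character(1), "study_id")
  for (i in seq_len(nrow(lay$dots))) {
    s <- fx$db$studies[[match(lay$dots$study_id[i], ids)]]
    at_zero <- lay$dots$radius_norm[i] == 0
    expect_equal(at_zero, s$study_type == "review" || cc %in% s$countries,
                 info = lay$dots$study_id[i])
    if (lay$dots$shape[i] == "square") expect_true(at_zero)
  }
})

test_that("layouts are deterministic and sector containment always holds", {
  fx <- paper_shaped_fixture(8)
  cc <- fx$table$values$country_code[2]
  a <- layout_scattar(fx$db, fx$table, cc, "reduce_poverty")
  b <- layout_scattar(fx$db, fx$table, cc, "reduce_poverty")
  expect_identical(a, b)

  gap <- a$geometry$sector_gap
  for (k in seq_len(7)) {
    sec <- a$sectors[k, ]
    sub <- a$dots[a$dots$mechanism == sec$mechanism, ]
    expect_true(all(sub$angle >= sec$start + gap / 2 - 1e-12))
    expect_true(all(sub$angle <= sec$end - gap / 2 + 1e-12))
  }
})

test_that("layout rejects bad inputs with the right condition classes", {
  fx <- paper_shaped_fixture(5)
  expect_error(layout_scattar(fx$db, fx$table, "QQQ", "promote_equity"),
               class = "scattar_not_found_error")
  expect_error(layout_scattar(fx$db, fx$table,
                              fx$table$values$country_code[1], "win_votes"),
               class = "scattar_vocabulary_error")

  cit <- list(authors = "A", title = "T", year = 2001, journal = "J")
  broken <- new_evidence_db(list(
    new_study("B1", cit, "evaluation", character(),
              make_assessments("tax_funded", c(promote_equity = "evidence_for")))))
  expect_error(layout_scattar(broken, fx$table,
                              fx$table$values$country_code[1], "promote_equity"),
               class = "scattar_layout_error")
})

test_that("thumbnails share positions and count grey dots per goal", {
  fx <- paper_shaped_fixture(6)
  cc <- fx$table$values$country_code[1]
  thumbs <- layout_thumbnails(fx$db, fx$table, cc)
  expect_named(thumbs, goal_levels())
  pos_cols <- c("study_id", "mechanism", "radius_norm", "angle")
  for (g in goal_levels()[-1]) {
    expect_identical(thumbs[[g]]$dots[pos_cols],
                     thumbs[[1]]$dots[pos_cols])
    expect_equal(nrow(thumbs[[g]]$dots), nrow(thumbs[[1]]$dots))
  }
  # grey dots per goal equal the brute-force not_considered count
  for (g in goal_levels()) {
    planted <- sum(vapply(fx$db$studies, function(s) {
      sum(s$assessments$goal == g & s$assessments$score == "not_considered")
    }, numeric(1)))
    expect_equal(sum(thumbs[[g]]$dots$color == "grey"), planted)
  }
})

test_that("layout serialises with consistent polar and Cartesian coordinates", {
  lay <- layout_scattar(tiny_db(), tiny_table(), "AAA", "promote_equity")
  doc <- jsonlite::fromJSON(layout_to_json(lay))
  expect_equal(nrow(doc$dots), 3)
  g <- lay$geometry
  r <- g$inner_radius + doc$dots$radius_norm * (g$outer_radius - g$inner_radius)
  expect_equal(doc$dots$x, round(r * sin(doc$dots$angle), 6))
  expect_equal(doc$dots$y, round(-r * cos(doc$dots$angle), 6))
})
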