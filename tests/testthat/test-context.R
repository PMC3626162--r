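test_that("min-max transform hits its boundaries, midpoint and clamps", {
  expect_identical(transform_indicator(2, 2, 10), 0)
  expect_identical(transform_indicator(10, 2, 10), 1)
  expect_identical(transform_indicator(6, 2, 10), 0.5)
  expect_identical(transform_indicator(-5, 2, 10), 0)   # clamp below
  expect_identical(transform_indicator(99, 2, 10), 1)   # clamp above
  expect_identical(transform_indicator(7, 7, 7), 0.5)   # degenerate bounds
  expect_error(transform_indicator(1, 10, 2), class = "scattar_value_error")
})

test_that("indicator loading logs population and recomputes bounds", {
  tab <- tiny_table()
  expect_equal(nrow(tab$bounds), 11)
  # population bounds are on the log10 scale
  pop <- tab$bounds[tab$bounds$indicator == "population", ]
  expect_equal(pop$min, 5)
  expect_equal(pop$max, 9)

  p <- tempfile(fileext = ".csv")
  write_indicators(tab, p)
  reloaded <- load_indicators(p)
  expect_equal(as.data.frame(reloaded$values), as.data.frame(tab$values))
  expect_equal(reloaded$bounds, tab$bounds)

  # format errors name the offending cell or column
  df <- utils::read.csv(p, stringsAsFactors = FALSE)
  df$hiv_prevalence[2] <- "high"
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(load_indicators(p), "row 2, column hiv_prevalence",
               class = "scattar_format_error")
  df$hiv_prevalence <- NULL
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(load_indicators(p), class = "scattar_format_error")

  bad <- tiny_indicator_values()
  bad$AAA[11] <- -5
  expect_error(manual_table(bad), class = "scattar_value_error")
})

test_that("missing cells are masked and bounds use the remaining rows", {
  vals <- tiny_indicator_values()
  vals$BBB[4] <- NA  # drop the HIV maximum
  tab <- manual_table(vals)
  prof <- country_profile(tab, "BBB")
  expect_false(prof$present[4])
  # brute-force bound recomputation over non-missing rows
  expect_equal(tab$bounds$max[4], max(vals$AAA[4], vals$CCC[4]))
  expect_equal(tab$bounds$min[4], min(vals$AAA[4], vals$CCC[4]))
})

test_that("country profiles match a per-dimension scalar oracle", {
  tab <- tiny_table()
  expect_equal(unname(country_profile(tab, "AAA")$values), rep(0, 11))
  expect_equal(unname(country_profile(tab, "BBB")$values), rep(1, 11))
  expect_equal(unname(country_profile(tab, "CCC")$values), rep(0.5, 11))

  gen <- generate_indicator_table(synthetic_config(n_countries = 12, seed = 5))
  cc <- gen$values$country_code[7]
  prof <- country_profile(gen, cc)
  for (j in seq_len(11)) {
    raw <- gen$values[[gen$indicators[j]]][7]
    expected <- (raw - gen$bounds$min[j]) / (gen$bounds$max[j] - gen$bounds$min[j])
    expect_equal(unname(prof$values[j]), expected)
  }
  expect_error(country_profile(tab, "ZZZ"), class = "scattar_not_found_error")
})

test_that("context distance obeys metric axioms and the brute-force oracle", {
  set.seed(42)
  for (i in 1:200) {
    a <- make_cv(runif(11))
    b <- make_cv(runif(11))
    c <- make_cv(runif(11))
    dab <- context_distance(a, b)
    expect_gte(dab$value, 0)
    expect_lte(dab$value, sqrt(11) + 1e-12)
    expect_equal(dab$value, context_distance(b, a)$value)
    expect_equal(context_distance(a, a)$value, 0)
    expect_lte(dab$value,
               context_distance(a, c)$value + context_distance(c, b)$value + 1e-12)
    expect_equal(dab$value, brute_distance(a, b), tolerance = 1e-14)
  }
  # analytically forced values
  expect_equal(context_distance(make_cv(rep(0, 11)), make_cv(rep(1, 11)))$value,
               sqrt(11))
  one_axis <- make_cv(c(0.5, rep(0, 10)))
  expect_equal(context_distance(one_axis, make_cv(rep(0, 11)))$value, 0.5)
})

test_that("partial profiles rescale by sqrt(11/k) and empty overlap errors", {
  a <- make_cv(c(rep(0.2, 6), rep(NA, 5)))
  b <- make_cv(c(rep(0.9, 6), rep(NA, 5)))
  d <- context_distance(a, b)
  expect_equal(d$k_present, 6L)
  expect_equal(d$value, sqrt(6 * 0.7^2 * 11 / 6))
  expect_equal(d$value, brute_distance(a, b))

  left <- make_cv(c(rep(0.1, 5), rep(NA, 6)))
  right <- make_cv(c(rep(NA, 5), rep(0.1, 6)))
  expect_error(context_distance(left, right),
               class = "scattar_distance_error")
})

test_that("adding an interior country changes no existing distance", {
  vals <- tiny_indicator_values()
  tab1 <- manual_table(vals)
  d_before <- context_distance(country_profile(tab1, "AAA"),
                               country_profile(tab1, "CCC"))$value
  inner <- (vals$AAA + 3 * vals$BBB) / 4  # strictly inside every bound
  inner[11] <- 10^((log10(vals$AAA[11]) + 3 * log10(vals$BBB[11])) / 4)
  vals$DDD <- inner
  tab2 <- manual_table(vals)
  d_after <- context_distance(country_profile(tab2, "AAA"),
                              country_profile(tab2, "CCC"))$value
  expect_equal(d_after, d_before)
})

test_that("rank_matches orders by distance with stable code tie-breaks", {
  tab <- tiny_table()
  rk <- rank_matches(tab, "AAA")
  expect_setequal(rk$country_code, c("BBB", "CCC"))
  # brute-force check of the order
  dB <- brute_distance(country_profile(tab, "AAA"), country_profile(tab, "BBB"))
  dC <- brute_distance(country_profile(tab, "AAA"), country_profile(tab, "CCC"))
  expect_equal(rk$country_code, c("BBB", "CCC")[order(c(dB, dC))])
  expect_equal(rk$distance, sort(c(dB, dC)))

  with_self <- rank_matches(tab, "AAA", include_self = TRUE)
  expect_equal(with_self$country_code[1], "AAA")
  expect_equal(with_self$distance[1], 0)
  expect_error(rank_matches(tab, "ZZZ"), class = "scattar_not_found_error")
})

test_that("study distance is the minimum over study countries", {
  tab <- tiny_table()
  cit <- list(authors = "A", title = "T", year = 2002, journal = "J")
  scores <- make_assessments("tax_funded", c(promote_equity = "evidence_for"))

  exact <- new_study("X1", cit, "evaluation", "AAA", scores)
  expect_equal(study_distance(exact, "AAA", tab)$value, 0)

  multi <- new_study("X2", cit, "evaluation", c("AAA", "BBB"), scores)
  expect_equal(study_distance(multi, "AAA", tab)$value, 0)

  pair <- new_study("X3", cit, "evaluation", c("BBB", "CCC"), scores)
  dB <- brute_distance(country_profile(tab, "AAA"), country_profile(tab, "BBB"))
  dC <- brute_distance(country_profile(tab, "AAA"), country_profile(tab, "CCC"))
  expect_equal(study_distance(pair, "AAA", tab)$value, min(dB, dC))
  # monotone: adding a country never increases the distance
  expect_lte(study_distance(multi, "AAA", tab)$value,
             study_distance(new_study("X4", cit, "evaluation", "BBB", scores),
                            "AAA", tab)$value)

  review <- new_study("X5", cit, "review", c("BBB"), scores)
  expect_equal(study_distance(review, "AAA", tab)$value, 0)

  off_table <- new_study("X6", cit, "evaluation", c("QQQ", "BBB"), scores)
  expect_warning(d <- study_distance(off_table, "AAA", tab), "QQQ")
  expect_equal(d$value, dB)
  lost <- new_study("X7", cit, "evaluation", "QQQ", scores)
  expect_error(suppressWarnings(study_distance(lost, "AAA", tab)),
               class = "scattar_distance_error")
})
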