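test_that("management action classification follows the timing/outcome rules", {
  cfg <- threshold_config()
  yrs <- 2011:2018
  density <- c(0.02, 0.05, 0.15, 0.30, 0.20, 0.08, 0.05, 0.05)
  timeline <- tibble::tibble(year = yrs, density = density)
  cover_flat <- tibble::tibble(year = yrs, cover = 0.30)

  # culling two years before the first crossing: proactive
  pro <- classify_action(timeline,
                         tibble::tibble(year = 2011, hours = 50), cfg,
                         cover = cover_flat, sector_id = "S")
  expect_equal(as.character(pro$action), "Proactive")
  expect_equal(pro$cull_start_year, 2011L)

  # no hours at all: NoAction
  no <- classify_action(timeline, tibble::tibble(year = integer(), hours = numeric()),
                        cfg, cover = cover_flat)
  expect_equal(as.character(no$action), "NoAction")

  # culling at the crossing, density then suppressed with cover held: timely
  tim <- classify_action(timeline, tibble::tibble(year = 2013, hours = 120),
                         cfg, cover = cover_flat, sector_id = "S")
  expect_equal(as.character(tim$action), "Timely")
  expect_true(tim$suppression_achieved)

  # same timing but cover collapsed: prey depletion, not suppression
  cover_crash <- tibble::tibble(year = yrs,
                                cover = seq(0.30, 0.06, length.out = length(yrs)))
  dep <- classify_action(timeline, tibble::tibble(year = 2013, hours = 120),
                         cfg, cover = cover_crash, sector_id = "S")
  expect_false(dep$suppression_achieved)
  expect_equal(as.character(dep$action), "Reactive")

  # density never suppressed, culling before severe: reactive
  hot <- tibble::tibble(year = yrs,
                        density = c(0.02, 0.05, 0.15, 0.5, 0.9, 1.4, 1.5, 1.2))
  rea <- classify_action(hot, tibble::tibble(year = 2014, hours = 60),
                         cfg, cover = cover_flat)
  expect_equal(as.character(rea$action), "Reactive")

  # culling only at/after severe: limited
  lim <- classify_action(hot, tibble::tibble(year = 2016, hours = 60),
                         cfg, cover = cover_flat)
  expect_equal(as.character(lim$action), "Limited")

  # suppression test without a cover series is a hard error
  expect_error(classify_action(hot, tibble::tibble(year = 2014, hours = 60), cfg),
               "cover series required")
})

test_that("effort ratio and threshold-hour arithmetic are exact", {
  expect_equal(effort_ratio(242.62, 2.0), 121.31)
  expect_equal(effort_ratio(0, 0.5), 0)
  expect_equal(effort_ratio(121.31, 1.0), 121.31)
  expect_error(effort_ratio(10, 0), "positive")
  expect_equal(effort_threshold_hours(121.31, 0.1), 12.131)
  expect_equal(effort_threshold_hours(121.31, 1.0), 121.31)
  expect_equal(effort_threshold_hours(55, 0), 0)
})

test_that("effort stratification splits at the effort-ratio median", {
  reefs <- tibble::tibble(
    reef_id = sprintf("R%d", 1:6),
    total_hours = c(50, 100, 200, 400, 0, 500),
    max_density = c(1, 1, 1, 1, 0.5, 0.05)
  )
  s <- stratify_effort(reefs)
  expect_equal(s$median_ratio_used[1], 150)  # median of {50,100,200,400}
  expect_equal(as.character(s$category),
               c("BelowMedian", "BelowMedian", "AboveMedian", "AboveMedian",
                 "NoEffort", "NoOutbreak"))
  # partition: counts sum to the reef total
  expect_equal(sum(table(s$category)), nrow(reefs))

  # ties at the median go above
  tied <- tibble::tibble(reef_id = c("A", "B", "C"),
                         total_hours = c(100, 100, 100),
                         max_density = c(1, 1, 1))
  st <- stratify_effort(tied)
  expect_true(all(st$category == "AboveMedian"))

  # invariant to reef ordering
  shuf <- stratify_effort(reefs[sample(nrow(reefs)), ])
  expect_equal(dplyr::arrange(shuf, reef_id)$category,
               dplyr::arrange(s, reef_id)$category)

  # degenerate: outbreak reefs but nobody culled
  none <- tibble::tibble(reef_id = c("A", "B"), total_hours = c(0, 0),
                         max_density = c(0.5, 0.05))
  expect_warning(sn <- stratify_effort(none), "degenerates")
  expect_equal(as.character(sn$category), c("NoEffort", "NoOutbreak"))
})

test_that("stratification matches the brute-force oracle on random reefs", {
  set.seed(31)
  reefs <- tibble::tibble(
    reef_id = sprintf("R%02d", 1:40),
    total_hours = round(runif(40, 0, 300)) * rbinom(40, 1, 0.8),
    max_density = round(runif(40, 0, 2), 2)
  )
  got <- stratify_effort(reefs)
  want <- oracle_stratify(reefs)
  expect_equal(as.character(got$category), unname(want))
})

test_that("sector effort shares reproduce the published arithmetic and sum to 100", {
  hours <- c(3558, 15352, 11082, 23534, 221, 1599, 6619)
  shares <- effort_share(hours, hours)
  expect_equal(shares, c(5.7, 24.8, 17.9, 38.0, 0.4, 2.6, 10.7))
  expect_lte(abs(sum(shares) - 100), 0.3)
  expect_equal(effort_share(42, 42), 100.0)
  expect_error(effort_share(1, 0), "positive")
})

test_that("synthetic presets are recovered by the downstream classifier", {
  for (p in c("limited", "reactive", "timely", "proactive")) {
    sc <- cached_scenario(p, 4)
    expect_equal(tolower(recovered_label(sc)), p,
                 label = paste("preset", p))
  }
})
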