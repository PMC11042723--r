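series_of <- function(density, start_year = 2011L) {
  tibble::tibble(year = seq(start_year, by = 1L, length.out = length(density)),
                 density = density)
}

test_that("outbreak detection handles the canonical rule traces", {
  cfg <- threshold_config()
  # never crosses: no window
  expect_equal(nrow(detect_outbreak_period(series_of(rep(0.05, 6)), cfg)), 0)

  # single-year exceedance fails the persistence criterion
  expect_equal(nrow(detect_outbreak_period(
    series_of(c(0.05, 0.15, 0.09, 0.05, 0.05)), cfg)), 0)

  # full trace: inception year2, escalation year3, start year1,
  # decline year5, end year6 (closing sub-threshold years included)
  w <- detect_outbreak_period(
    series_of(c(0.05, 0.15, 0.25, 0.30, 0.08, 0.06), 2011L), cfg)
  expect_equal(w$inception_year, 2012L)
  expect_equal(w$escalation_year, 2013L)
  expect_equal(w$start_year, 2011L)
  expect_equal(w$decline_year, 2015L)
  expect_equal(w$end_year, 2016L)
  expect_false(w$ongoing)

  # end-year convention is switchable
  w2 <- detect_outbreak_period(
    series_of(c(0.05, 0.15, 0.25, 0.30, 0.08, 0.06), 2011L),
    threshold_config(include_decline_years = FALSE))
  expect_equal(w2$end_year, 2014L)

  # no decline observed: flagged ongoing through the last year
  w3 <- detect_outbreak_period(series_of(c(0.05, 0.15, 0.25, 0.5, 0.9)), cfg)
  expect_true(w3$ongoing)
  expect_equal(w3$end_year, 2015L)
  expect_true(is.na(w3$decline_year))

  expect_error(detect_outbreak_period(series_of(c(0.1, 0.2)), cfg), "shorter")
})

test_that("established-threshold inception raises the bar for flagged sectors", {
  d <- c(0.05, 0.15, 0.15, 0.15, 0.05, 0.05)
  # potential-based inception finds a window only if established is exceeded
  expect_equal(nrow(detect_outbreak_period(series_of(d))), 0)  # never > 0.22
  d2 <- c(0.05, 0.15, 0.15, 0.30, 0.05, 0.05)
  w <- detect_outbreak_period(series_of(d2))
  expect_equal(w$inception_year, 2012L)
  # same series under the established-inception override: 0.15 persistence
  # years no longer count, and a single 0.30 year fails persistence
  expect_equal(nrow(detect_outbreak_period(
    series_of(d2), uses_established_inception = TRUE)), 0)
  d3 <- c(0.05, 0.25, 0.30, 0.30, 0.05, 0.05)
  w3 <- detect_outbreak_period(series_of(d3), uses_established_inception = TRUE)
  expect_equal(w3$inception_year, 2012L)
})

test_that("detection agrees with the enumeration oracle on random series", {
  cfg <- threshold_config()
  set.seed(2024)
  n_cases <- 2000
  for (i in seq_len(n_cases)) {
    len <- sample(4:12, 1)
    d <- random_density_series(len)
    flag <- sample(c(TRUE, FALSE), 1)
    got <- detect_outbreak_period(series_of(d), cfg, flag)
    want <- oracle_outbreak_window(seq(2011L, by = 1L, length.out = len), d,
                                   uses_established = flag)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), 1)
      for (f in names(want)) {
        expect_equal(got[[f]], want[[f]],
                     label = paste0(f, " for series ", paste(d, collapse = ",")))
      }
    }
  }
})

test_that("raising all densities never delays inception", {
  cfg <- threshold_config()
  set.seed(77)
  for (i in 1:200) {
    d <- random_density_series(8)
    w0 <- detect_outbreak_period(series_of(d), cfg)
    w1 <- detect_outbreak_period(series_of(d + 0.05), cfg)
    if (nrow(w0) == 1) {
      expect_equal(nrow(w1), 1)
      expect_lte(w1$inception_year, w0$inception_year)
    }
  }
})

test_that("detected windows track the generating truth on synthetic scenarios", {
  cfg <- threshold_config()
  hits <- 0L
  seeds <- 1:10
  for (s in seeds) {
    sc <- cached_scenario("limited", s)
    rd <- reef_year_density(sc$tows)
    ss <- sector_density_series(rd, sc$registry, cfg)
    ob <- detect_outbreaks(ss, sc$registry, cfg)
    truth_series <- sc$truth |>
      dplyr::group_by(sector_id, year) |>
      dplyr::summarise(density = mean(true_density), .groups = "drop")
    truth_ob <- detect_outbreaks(truth_series, sc$registry, cfg)
    jac <- vapply(truth_ob$sector_id, function(sec) {
      wt <- truth_ob[truth_ob$sector_id == sec, ]
      wo <- ob[ob$sector_id == sec, ]
      if (nrow(wo) == 0) return(0)
      a <- seq(wt$start_year, wt$end_year)
      b <- seq(wo$start_year, wo$end_year)
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1))
    if (all(jac >= 0.6)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
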