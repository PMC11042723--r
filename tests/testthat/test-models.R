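test_that("posterior_summary matches closed-form quantiles on analytic samples", {
  set.seed(123)
  z <- rnorm(20000)
  s <- posterior_summary(z, "z")
  expect_lt(abs(s$median), 0.03)
  expect_lt(abs(s$ci90_lo - qnorm(0.05)), 0.05)
  expect_lt(abs(s$ci90_hi - qnorm(0.95)), 0.05)
  expect_lt(abs(s$ci66_lo - qnorm(0.17)), 0.05)
  expect_lt(abs(s$prob_direction - 50), 2)
  # nesting invariant
  expect_lte(s$ci90_lo, s$ci66_lo)
  expect_gte(s$ci90_hi, s$ci66_hi)

  const <- posterior_summary(rep(5, 600))
  expect_equal(const$median, 5)
  expect_equal(const$ci90_lo, 5)
  expect_equal(const$ci90_hi, 5)
  expect_equal(const$prob_direction, 100)

  # a sample with 68% of its mass above zero
  mix <- c(rep(1, 680), rep(-1, 320))
  expect_equal(posterior_summary(mix)$prob_direction, 68)

  expect_error(posterior_summary(rnorm(100)), "500")
})

test_that("fold change is the exact ratio of medians", {
  expect_equal(round(fold_change(1.50, 0.21)), 7)
  expect_equal(fold_change(3, 3), 1)
  expect_equal(fold_change(3.6, 1.6), 2.25)
  expect_error(fold_change(1, 0), "positive")
})

test_that("sector cover model recovers degenerate data and ignores row order", {
  tows <- tidyr::expand_grid(year = 2015:2016, tow_index = 1:30) |>
    dplyr::mutate(reef_id = "R1", sector_id = "A", program = "LTMP",
                  cover_category = 3L, cots_count = 0L, tow_area_m2 = 2000)
  fit <- fit_sector_cover_model(tows, seed = 42)
  expect_equal(nrow(fit$summaries), 2)
  expect_true(all(abs(fit$summaries$median - 0.405) < 0.02))
  expect_equal(fit$diagnostics$A$n_draws, 1800)

  # permuting tow order leaves summaries unchanged (canonical internal sort)
  fit2 <- fit_sector_cover_model(tows[sample(nrow(tows)), ], seed = 42)
  expect_identical(fit$summaries, fit2$summaries)

  # repeated runs with the same seed are identical
  fit3 <- fit_sector_cover_model(tows, seed = 42)
  expect_identical(fit$summaries, fit3$summaries)

  g <- glance(fit)
  expect_equal(g$sector_id, "A")
  expect_equal(g$n_iter, 4000L)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("wave model reports near-zero contrasts for identical responses", {
  data <- tidyr::expand_grid(reef_id = sprintf("R%d", 1:10),
                             wave = c("3rd", "4th")) |>
    dplyr::mutate(sector_id = "A", value = 25)
  fit <- fit_wave_comparison_model(data, "cover_change", seed = 9)
  con <- fit$summaries[fit$summaries$type == "contrast", ]
  expect_equal(nrow(con), 1)
  expect_lt(abs(con$median), 0.5)
  expect_lt(con$ci90_hi - con$ci90_lo, 2)
  cells <- fit$summaries[fit$summaries$type == "cell", ]
  expect_true(all(abs(cells$median - 25) < 0.5))
})

test_that("wave model recovers a simulated density fold change", {
  set.seed(17)
  n <- 12
  base <- exp(rnorm(n, log(1.4), 0.35))
  data <- tibble::tibble(
    reef_id = rep(sprintf("R%d", 1:n), 2),
    sector_id = "A",
    wave = rep(c("3rd", "4th"), each = n),
    value = c(base * exp(rnorm(n, 0, 0.15)),
              base / 7 * exp(rnorm(n, 0, 0.15)))
  )
  fit <- fit_wave_comparison_model(data, "density", seed = 18)
  con <- fit$summaries[fit$summaries$type == "contrast", ]
  expect_gt(con$fold, 4)
  expect_lt(con$fold, 10)
  expect_gt(con$prob_direction, 95)
})

test_that("single-wave sectors get a cell but no contrast", {
  data <- tibble::tibble(
    reef_id = c(sprintf("A%d", 1:6), sprintf("B%d", 1:6), sprintf("A%d", 1:6)),
    sector_id = c(rep("A", 6), rep("B", 6), rep("A", 6)),
    wave = c(rep("3rd", 12), rep("4th", 6)),
    value = exp(rnorm(18, log(0.5), 0.2))
  )
  fit <- fit_wave_comparison_model(data, "density", seed = 3)
  expect_equal(sum(fit$summaries$type == "cell"), 3)
  expect_equal(sum(fit$summaries$type == "contrast"), 1)
  expect_match(fit$notes, "^B: observed in one wave")
})

test_that("effort model covers a common mean when categories do not differ", {
  set.seed(21)
  data <- tidyr::expand_grid(
    category = c("NoOutbreak", "AboveMedian", "BelowMedian", "NoEffort"),
    rep = 1:10
  ) |>
    dplyr::mutate(reef_id = paste0(category, rep),
                  sector_id = sample(c("S1", "S2", "S3"), dplyr::n(), TRUE),
                  annual_change_pp = rnorm(dplyr::n(), 0, 1))
  fit <- fit_effort_model(data, seed = 22)
  expect_equal(nrow(fit$summaries), 4)
  expect_true(all(fit$summaries$ci90_lo < 0.5 & fit$summaries$ci90_hi > -0.5))
  expect_true(glance(fit)$converged)

  small <- dplyr::bind_rows(data,
    tibble::tibble(reef_id = "X", sector_id = "S1", category = "Extra",
                   annual_change_pp = 0))
  expect_warning(fit_effort_model(small, seed = 22), "< 2 reefs")
})

test_that("trajectory smoother recovers a straight line and a flat zero", {
  set.seed(4)
  traj <- tibble::tibble(
    years_since_onset = rep(0:6, each = 10),
    relative_change_pct = 3 * rep(0:6, each = 10) + rnorm(70, 0, 2),
    few_surveys = FALSE
  )
  fit <- fit_trajectory_smoother(traj)
  expect_equal(fit$curves$years_since_onset, 0:6)
  expect_true(all(abs(fit$curves$fit - 3 * (0:6)) < 2))

  flat <- tibble::tibble(years_since_onset = rep(0:4, 3),
                         relative_change_pct = 0)
  ffit <- fit_trajectory_smoother(flat)
  expect_true(all(abs(ffit$curves$fit) < 1e-6))

  tiny <- tibble::tibble(years_since_onset = 0:2, relative_change_pct = 1:3)
  expect_warning(skip <- fit_trajectory_smoother(tiny), "< 5 points")
  expect_equal(nrow(skip$curves), 0)
})

test_that("tidiers and autoplot produce the expected shapes", {
  traj <- tibble::tibble(years_since_onset = rep(0:5, 4),
                         relative_change_pct = rnorm(24),
                         group = rep(c("a", "b"), each = 12))
  fit <- fit_trajectory_smoother(traj, by = "group")
  expect_setequal(unique(tidy(fit)$group), c("a", "b"))
  expect_equal(nrow(glance(fit)), 2)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
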