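test_that("coral grows logistically when predation and disturbance are absent", {
  cfg <- sim_config(n_sectors = 1, reefs_per_sector = 4, predation_coeff = 0,
                    cots_seed_density = 0, seed = 7)
  truth <- simulate_truth(cfg)
  gains <- truth |>
    dplyr::group_by(reef_id) |>
    dplyr::summarise(mono = all(diff(true_cover) > 0),
                     mean_gain_pp = 100 * mean(diff(true_cover)))
  expect_true(all(gains$mono))
  # calibration anchor: about +1 pp/yr at moderate cover
  expect_true(all(gains$mean_gain_pp > 0.5 & gains$mean_gain_pp < 2))
})

test_that("cover declines under sustained predation with no growth", {
  cfg <- sim_config(n_sectors = 1, reefs_per_sector = 2, r_coral = 0,
                    cots_growth = 1, cots_seed_density = 0.5,
                    cots_collapse_cover = 0, wave_onset_year = 2010, seed = 7)
  truth <- simulate_truth(cfg)
  decl <- truth |>
    dplyr::group_by(reef_id) |>
    dplyr::summarise(mono = all(diff(true_cover) < 0))
  expect_true(all(decl$mono))
})

test_that("culling removes density linearly and monotonically", {
  cfg <- sim_config(cull_efficiency = 0.5)
  expect_equal(apply_culling(0.7, 0, cfg), 0.7)
  expect_equal(apply_culling(0.5, 100, cfg), 0.0)
  expect_error(apply_culling(-1, 0, cfg), "non-negative")
  # monotone non-increasing in hours over a grid
  for (d in c(0, 0.1, 0.5, 2)) {
    hrs <- seq(0, 300, by = 25)
    out <- apply_culling(rep(d, length(hrs)), hrs, cfg)
    expect_true(all(diff(out) <= 0))
    expect_true(all(out >= 0))
  }
})

test_that("tow observation model matches its Poisson and binning contracts", {
  cfg <- sim_config(n_sectors = 1, reefs_per_sector = 1, tows_per_reef = 10,
                    cots_seed_density = 0, seed = 11)
  truth <- simulate_truth(cfg)
  tows <- observe_tows(truth, cfg)
  expect_true(all(tows$cots_count == 0))

  # Monte-Carlo check of the Poisson mean at fixed density
  cfg2 <- sim_config(n_sectors = 1, reefs_per_sector = 1, tows_per_reef = 10000,
                     detection_scale = 1, obs_cover_sd = 0, seed = 12,
                     years = 2010:2012)
  truth2 <- simulate_truth(cfg2)
  truth2$true_density <- 0.5
  tows2 <- observe_tows(truth2, cfg2)
  one_year <- tows2[tows2$year == 2010, ]
  se <- sqrt(0.5 / nrow(one_year))
  expect_lt(abs(mean(one_year$cots_count) - 0.5), 3 * se)

  # noiseless cover at a bin midpoint reports that bin
  truth2$true_cover <- 0.405
  tows3 <- observe_tows(truth2, cfg2)
  expect_true(all(tows3$cover_category == 3L))
})

test_that("simulation and scenario outputs are byte-identical for a fixed seed", {
  sc1 <- generate_scenario("reactive", seed = 5)
  sc2 <- generate_scenario("reactive", seed = 5)
  expect_identical(sc1$truth, sc2$truth)
  expect_identical(sc1$tows, sc2$tows)
  expect_identical(sc1$culls, sc2$culls)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_scenario("reactive", seed = 5, dir = d1)
  generate_scenario("reactive", seed = 5, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("scenario presets encode their management signatures by construction", {
  pro <- cached_scenario("proactive", 2)
  tim <- cached_scenario("timely", 2)
  lim <- cached_scenario("limited", 2)

  # proactive: culling starts before the sector's potential crossing in truth
  truth_sectors <- pro$truth |>
    dplyr::group_by(sector_id, year) |>
    dplyr::summarise(density = mean(true_density), .groups = "drop")
  for (sec in unique(pro$culls$sector_id)) {
    first_cull <- min(pro$culls$year[pro$culls$sector_id == sec])
    ts <- truth_sectors[truth_sectors$sector_id == sec, ]
    crossing <- suppressWarnings(min(ts$year[ts$density > 0.11]))
    expect_lt(first_cull, crossing)
  }

  # limited allocates under 10% of the timely effort at the same seed
  expect_lt(sum(lim$culls$hours), 0.1 * sum(tim$culls$hours))

  # limited preset reaches severe densities and major coral loss
  sector_truth <- lim$truth |>
    dplyr::group_by(sector_id, year) |>
    dplyr::summarise(density = mean(true_density), cover = mean(true_cover),
                     .groups = "drop")
  expect_true(any(sector_truth$density > 1.0))
  loss6 <- sector_truth |>
    dplyr::group_by(sector_id) |>
    dplyr::summarise(rel_loss = {
      onset <- min(year[density > 0])
      span <- cover[year >= onset & year <= onset + 6]
      (span[1] - min(span)) / span[1]
    })
  expect_true(any(loss6$rel_loss >= 0.4))

  expect_error(generate_scenario("bogus", 1), "unknown preset")
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(K = 1.5), "K must be")
  expect_error(sim_config(r_coral = -1), "rates")
  expect_error(sim_config(years = c(2010, 2012)), "consecutive")
})
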