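# shared scenario fixtures, generated once per test run
.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(preset, seed, config = sim_config()) {
  key <- paste(preset, seed, rlang::hash(unclass(config)), sep = "_")
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- generate_scenario(preset, seed = seed, config = config)
  }
  .scenario_cache[[key]]
}

# classify every sector of a scenario and return the labels
classify_scenario_sectors <- function(sc, config = threshold_config()) {
  rd <- reef_year_density(sc$tows)
  ss <- sector_density_series(rd, sc$registry, config)
  ob <- detect_outbreaks(ss, sc$registry, config)
  rc <- reef_year_cover(sc$tows)
  scov <- rc |>
    dplyr::group_by(sector_id, year) |>
    dplyr::summarise(cover = mean(cover), .groups = "drop")
  vapply(sort(unique(ss$sector_id)), function(sec) {
    culls <- sc$culls[sc$culls$sector_id == sec, ] |>
      dplyr::group_by(year) |>
      dplyr::summarise(hours = sum(hours), .groups = "drop")
    as.character(classify_action(
      ss[ss$sector_id == sec, ], culls, config,
      cover = scov[scov$sector_id == sec, ],
      window = ob[ob$sector_id == sec, ],
      sector_id = sec
    )$action)
  }, character(1))
}

# modal sector label = the scenario-level recovered action
recovered_label <- function(sc, config = threshold_config()) {
  labs <- classify_scenario_sectors(sc, config)
  names(sort(table(labs), decreasing = TRUE))[1]
}

# small registry + tow fixture used across io/density tests
make_registry_fixture <- function() {
  as_registry(tibble::tibble(
    reef_id = c("R01", "R02", "R03"),
    sector_id = c("A", "A", "B"),
    sector_order = c(1L, 1L, 2L),
    uses_established_inception = c(FALSE, FALSE, TRUE)
  ))
}

write_tow_fixture <- function(path, rows) {
  writeLines(c("reef_id,year,program,tow_index,cover_category,cots_count", rows), path)
}
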