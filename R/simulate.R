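#' Simulation settings for the synthetic reefscape
#'
#' Configures a coupled predator-coral simulator that emulates the
#' statistical structure of sector-scale COTS surveillance data: an outbreak
#' wave seeded in the first sector that propagates to later sectors with a
#' fixed lag, logistic coral growth (about +1 percentage point per year at
#' moderate cover under the defaults), density-proportional COTS predation,
#' optional episodic disturbance mortality, culling that removes density in
#' proportion to diver hours, and a tow-level observation model (Poisson COTS
#' counts, ordinal cover categories with additive observer noise).
#'
#' All rate constants are calibration knobs for generating test data with
#' realistic magnitudes; they are not estimates of Great Barrier Reef
#' parameters.
#'
#' @param n_sectors,reefs_per_sector Reefscape size.
#' @param years Integer vector of consecutive survey years.
#' @param wave_onset_year Year the outbreak wave is seeded in sector 1.
#' @param wave_lag_years Onset delay per sector position along the wave path.
#' @param r_coral Logistic growth rate of coral cover per year.
#' @param K Carrying-capacity cover proportion.
#' @param predation_coeff Proportional cover loss per (COTS/tow) per year.
#' @param cots_growth Multiplicative annual growth of outbreak density.
#' @param cots_seed_density Density at which the wave is seeded in a sector.
#' @param cots_cap Ceiling on true density (prey handling saturates).
#' @param cots_collapse_cover Cover floor below which the outbreak collapses
#'   through prey depletion.
#' @param collapse_factor Multiplier applied to density each year cover sits
#'   below `cots_collapse_cover`.
#' @param cull_efficiency Density removed per 100 diver-hours at a reef.
#' @param disturbance_schedule Optional tibble (`year`, `sector_id`,
#'   `mortality`) of episodic mortality fractions (cyclones, bleaching).
#' @param tows_per_reef Manta tows surveyed per reef per year.
#' @param detection_scale Expected COTS count per tow per unit true density.
#' @param obs_cover_sd SD of additive observer noise on the cover proportion.
#' @param reef_density_sd SD (log scale) of fixed per-reef density multipliers.
#' @param init_cover_range Range of initial cover proportions across reefs.
#' @param seed RNG seed; all outputs are byte-identical given the seed.
#' @return A list of class `cots_sim_config`.
#' @export
sim_config <- function(n_sectors = 4L,
                       reefs_per_sector = 10L,
                       years = 2010:2024,
                       wave_onset_year = 2013L,
                       wave_lag_years = 2L,
                       r_coral = 0.067,
                       K = 0.8,
                       predation_coeff = 0.12,
                       cots_growth = 2.8,
                       cots_seed_density = 0.08,
                       cots_cap = 3,
                       cots_collapse_cover = 0.08,
                       collapse_factor = 0.1,
                       cull_efficiency = 0.5,
                       disturbance_schedule = NULL,
                       tows_per_reef = 10L,
                       detection_scale = 1,
                       obs_cover_sd = 0.03,
                       reef_density_sd = 0.2,
                       init_cover_range = c(0.15, 0.35),
                       seed = 1L) {
  cfg <- list(
    n_sectors = as.integer(n_sectors),
    reefs_per_sector = as.integer(reefs_per_sector),
    years = as.integer(years),
    wave_onset_year = as.integer(wave_onset_year),
    wave_lag_years = as.integer(wave_lag_years),
    r_coral = r_coral, K = K,
    predation_coeff = predation_coeff,
    cots_growth = cots_growth,
    cots_seed_density = cots_seed_density,
    cots_cap = cots_cap,
    cots_collapse_cover = cots_collapse_cover,
    collapse_factor = collapse_factor,
    cull_efficiency = cull_efficiency,
    disturbance_schedule = disturbance_schedule,
    tows_per_reef = as.integer(tows_per_reef),
    detection_scale = detection_scale,
    obs_cover_sd = obs_cover_sd,
    reef_density_sd = reef_density_sd,
    init_cover_range = init_cover_range,
    seed = as.integer(seed)
  )
  if (cfg$K <= 0 || cfg$K > 1) rlang::abort("K must be in (0, 1]")
  rates <- c(cfg$r_coral, cfg$predation_coeff, cfg$cots_growth, cfg$cull_efficiency,
             cfg$cots_seed_density, cfg$detection_scale, cfg$obs_cover_sd)
  if (any(rates < 0)) rlang::abort("all rates must be >= 0")
  if (any(diff(cfg$years) != 1L)) rlang::abort("years must be consecutive")
  structure(cfg, class = "cots_sim_config")
}

# evaluate code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Registry for a simulated reefscape
#'
#' @param config A [sim_config()].
#' @return A registry tibble (see [read_registry()]); sectors are ordered
#'   along the wave path and no sector uses the established-inception
#'   override by default.
#' @export
sim_registry <- function(config) {
  sec <- sprintf("SEC%02d", seq_len(config$n_sectors))
  reg <- tidyr::expand_grid(
    sector_order = seq_len(config$n_sectors),
    reef = seq_len(config$reefs_per_sector)
  )
  as_registry(tibble::tibble(
    reef_id = sprintf("S%02dR%02d", reg$sector_order, reg$reef),
    sector_id = sec[reg$sector_order],
    sector_order = reg$sector_order,
    uses_established_inception = FALSE
  ))
}

#' Remove COTS density through culling
#'
#' Culling removes density linearly in diver bottom-hours:
#' `density' = max(0, density - cull_efficiency * hours / 100)`, so the
#' result is monotone non-increasing in hours.
#'
#' @param density Non-negative COTS density (COTS/tow), vectorized.
#' @param hours Non-negative diver bottom-hours, vectorized.
#' @param config A [sim_config()] supplying `cull_efficiency`.
#' @return Reduced density, same length as the inputs.
#' @export
#' @examples
#' apply_culling(0.5, 100, sim_config(cull_efficiency = 0.5))
apply_culling <- function(density, hours, config = sim_config()) {
  if (any(density < 0) || any(hours < 0)) {
    rlang::abort("density and hours must be non-negative")
  }
  pmax(0, density - config$cull_efficiency * hours / 100)
}

#' Simulate true reef dynamics
#'
#' Runs the annual-step predator-coral model per reef:
#' `cover' = cover + r_coral * cover * (1 - cover/K) -
#' predation_coeff * density * cover - disturbance mortality`, with the COTS
#' wave seeded in each sector at its onset year, growing multiplicatively,
#' culled before it preys (pre-cull density is what surveys observe, since
#' surveys precede cull operations), and collapsing once cover falls below
#' the prey-depletion floor. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param cull_schedule Optional tibble (`reef_id`, `year`, `hours`) of
#'   diver hours applied.
#' @return Tibble with one row per reef-year: `reef_id`, `sector_id`,
#'   `year`, `true_cover`, `true_density` (pre-cull), `applied_hours`.
#' @export
simulate_truth <- function(config, cull_schedule = NULL) {
  reg <- sim_registry(config)
  reefs <- reg$reef_id
  R <- length(reefs)
  yrs <- config$years
  T <- length(yrs)
  onset <- config$wave_onset_year +
    config$wave_lag_years * (reg$sector_order - 1L)

  draws <- with_seed(config$seed, {
    list(
      mult = exp(stats::rnorm(R, 0, config$reef_density_sd)),
      cover0 = stats::runif(R, config$init_cover_range[1], config$init_cover_range[2])
    )
  })

  hours <- matrix(0, R, T, dimnames = list(reefs, yrs))
  if (!is.null(cull_schedule) && nrow(cull_schedule) > 0) {
    sched <- dplyr::group_by(cull_schedule, .data$reef_id, .data$year) |>
      dplyr::summarise(hours = sum(.data$hours), .groups = "drop")
    keep <- sched$reef_id %in% reefs & sched$year %in% yrs
    sched <- sched[keep, , drop = FALSE]
    hours[cbind(match(sched$reef_id, reefs), match(sched$year, yrs))] <- sched$hours
  }

  mort <- matrix(0, R, T)
  ds <- config$disturbance_schedule
  if (!is.null(ds) && nrow(ds) > 0) {
    for (i in seq_len(nrow(ds))) {
      rows <- reg$sector_id == ds$sector_id[i]
      col <- match(ds$year[i], yrs)
      if (!is.na(col)) mort[rows, col] <- mort[rows, col] + ds$mortality[i]
    }
  }

  cover <- matrix(NA_real_, R, T)
  dens <- matrix(NA_real_, R, T)
  cover[, 1] <- draws$cover0
  dens[, 1] <- ifelse(yrs[1] == onset, config$cots_seed_density * draws$mult, 0)

  for (t in seq_len(T)) {
    d_post <- apply_culling(dens[, t], hours[, t], config)
    if (t < T) {
      grow <- config$r_coral * cover[, t] * (1 - cover[, t] / config$K)
      loss <- config$predation_coeff * d_post * cover[, t] + mort[, t] * cover[, t]
      cover[, t + 1] <- pmin(pmax(cover[, t] + grow - loss, 0), config$K)
      d_next <- pmin(config$cots_cap, d_post * config$cots_growth)
      d_next <- ifelse(yrs[t + 1] == onset,
                       pmax(d_next, config$cots_seed_density * draws$mult), d_next)
      d_next <- ifelse(cover[, t + 1] < config$cots_collapse_cover,
                       d_next * config$collapse_factor, d_next)
      dens[, t + 1] <- d_next
    }
  }
  if (any(!is.finite(cover)) || any(!is.finite(dens))) {
    bad <- which(!is.finite(cover) | !is.finite(dens), arr.ind = TRUE)[1, ]
    rlang::abort(paste0("non-finite state at reef ", reefs[bad[1]], ", year ", yrs[bad[2]]))
  }

  tibble::tibble(
    reef_id = rep(reefs, T),
    sector_id = rep(reg$sector_id, T),
    year = rep(yrs, each = R),
    true_cover = as.vector(cover),
    true_density = as.vector(dens),
    applied_hours = as.vector(hours)
  ) |>
    dplyr::arrange(.data$reef_id, .data$year)
}

#' Observe manta tows over a simulated truth
#'
#' Generates `tows_per_reef` records per reef-year. COTS counts are Poisson
#' with mean `detection_scale * true_density`; the recorded cover category
#' bins the true cover plus additive observer noise (truncated to `[0, 1]`).
#'
#' @param truth Output of [simulate_truth()].
#' @param config The [sim_config()] used to generate `truth`.
#' @return A tow-record tibble in the schema of [read_tow_records()].
#' @export
observe_tows <- function(truth, config) {
  k <- config$tows_per_reef
  n <- nrow(truth) * k
  scheme <- category_scheme()
  with_seed(config$seed + 1L, {
    cover_obs <- rep(truth$true_cover, each = k) +
      stats::rnorm(n, 0, config$obs_cover_sd)
    cover_obs <- pmin(pmax(cover_obs, 0), 1)
    tibble::tibble(
      reef_id = rep(truth$reef_id, each = k),
      sector_id = rep(truth$sector_id, each = k),
      year = rep(truth$year, each = k),
      program = "LTMP",
      tow_index = rep(seq_len(k), nrow(truth)),
      cover_category = cover_to_category(cover_obs, scheme),
      cots_count = stats::rpois(n, config$detection_scale *
                                  rep(truth$true_density, each = k)),
      tow_area_m2 = 2000
    )
  })
}

#' Generate a complete management scenario
#'
#' Builds a synthetic dataset in which culling timing and effort encode one
#' of the four management actions, relative to each sector's simulated
#' threshold crossings (computed from an uncontrolled run of the same seed):
#'
#' * `proactive` - culling starts at wave onset, before the potential
#'   threshold (0.11 COTS/tow) is crossed, with enough effort to stop the
#'   wave;
#' * `timely` - culling starts the year the sector crosses the potential
#'   threshold, with enough effort to suppress the outbreak;
#' * `reactive` - culling starts a year later, before severe densities, but
#'   with too little effort to suppress;
#' * `limited` - culling starts only once densities are severe, with under
#'   10% of the timely scenario's total hours.
#'
#' @param preset One of `"limited"`, `"reactive"`, `"timely"`, `"proactive"`.
#' @param seed Integer seed; overrides `config$seed`.
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, `tows.csv`, `culls.csv`,
#'   `registry.csv` and `truth.csv` are written there.
#' @return A list with elements `tows`, `culls`, `registry`, `truth`,
#'   `config`, `preset` and `cull_schedule`.
#' @export
generate_scenario <- function(preset, seed = 1L,
                              config = sim_config(), dir = NULL) {
  presets <- c("limited", "reactive", "timely", "proactive")
  if (!is.character(preset) || length(preset) != 1 || !preset %in% presets) {
    rlang::abort(paste0("unknown preset; must be one of: ", paste(presets, collapse = ", ")))
  }
  config$seed <- as.integer(seed)
  reg <- sim_registry(config)
  base <- simulate_truth(config, NULL)

  sector_truth <- base |>
    dplyr::group_by(.data$sector_id, .data$year) |>
    dplyr::summarise(density = mean(.data$true_density), .groups = "drop")
  crossings <- sector_truth |>
    dplyr::group_by(.data$sector_id) |>
    dplyr::summarise(
      y_onset = first_year_above(.data$year, .data$density, 0),
      y_pot = first_year_above(.data$year, .data$density, 0.11),
      y_sev = first_year_at_or_above(.data$year, .data$density, 1.0),
      .groups = "drop"
    )

  last_year <- max(config$years)
  plan <- switch(preset,
    proactive = list(start = crossings$y_onset, hours = 40, span = 3L),
    timely    = list(start = crossings$y_pot, hours = 100, span = 4L),
    reactive  = list(start = crossings$y_pot + 1L, hours = 15, span = NA),
    limited   = list(start = crossings$y_sev, hours = 5, span = NA)
  )
  sched <- purrr::pmap_dfr(
    list(crossings$sector_id, plan$start),
    function(sec, start) {
      if (is.na(start)) return(tibble::tibble())
      end <- if (is.na(plan$span)) last_year else min(last_year, start + plan$span - 1L)
      if (end < start) return(tibble::tibble())
      tidyr::expand_grid(
        reef_id = reg$reef_id[reg$sector_id == sec],
        year = seq(start, end)
      ) |>
        dplyr::mutate(hours = plan$hours)
    }
  )

  truth <- simulate_truth(config, sched)
  tows <- observe_tows(truth, config)
  culls <- if (nrow(sched) > 0) {
    sched |>
      dplyr::mutate(sector_id = reg$sector_id[match(.data$reef_id, reg$reef_id)]) |>
      dplyr::select("reef_id", "sector_id", "year", "hours") |>
      dplyr::arrange(.data$reef_id, .data$year)
  } else {
    tibble::tibble(reef_id = character(), sector_id = character(),
                   year = integer(), hours = numeric())
  }

  out <- list(tows = tows, culls = culls, registry = reg, truth = truth,
              config = config, preset = preset, cull_schedule = sched)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_table(tows, file.path(dir, "tows.csv"), digits = 4)
    write_table(dplyr::select(culls, "reef_id", "year", "hours"),
                file.path(dir, "culls.csv"), digits = 4)
    write_table(reg, file.path(dir, "registry.csv"), digits = 4)
    write_table(dplyr::select(truth, "reef_id", "year", "true_cover", "true_density"),
                file.path(dir, "truth.csv"), digits = 6)
  }
  out
}

first_year_above <- function(year, density, threshold) {
  hit <- which(density > threshold)
  if (length(hit) == 0) NA_integer_ else as.integer(year[min(hit)])
}

first_year_at_or_above <- function(year, density, threshold) {
  hit <- which(density >= threshold)
  if (length(hit) == 0) NA_integer_ else as.integer(year[min(hit)])
}
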