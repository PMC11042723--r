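#' Reef-year COTS densities with the max-across-programs rule
#'
#' Computes, for each reef, year and survey program, the mean COTS count per
#' tow, then keeps the maximum of the per-program means as the
#' representative density for the reef-year (supplementary program surveys
#' are run before culling starts, so the largest per-program mean is the
#' least biased by removals).
#'
#' @param tows Tow-record tibble, see [read_tow_records()].
#' @return Tibble with one row per reef-year: `reef_id`, `sector_id`,
#'   `year`, `mean_cots_per_tow`, `n_tows` (tows of the winning program),
#'   `source_program` and `programs_seen`.
#' @export
#' @examples
#' tows <- tibble::tibble(
#'   reef_id = "R1", sector_id = "S1", year = 2015,
#'   program = c("LTMP", "LTMP", "LTMP", "CONTROL", "CONTROL"),
#'   tow_index = c(1, 2, 3, 1, 2),
#'   cover_category = 3, cots_count = c(0, 1, 2, 1, 3), tow_area_m2 = 2000
#' )
#' reef_year_density(tows) # CONTROL mean 2.0 beats LTMP mean 1.0
reef_year_density <- function(tows) {
  if (nrow(tows) == 0) {
    return(tibble::tibble(
      reef_id = character(), sector_id = character(), year = integer(),
      mean_cots_per_tow = numeric(), n_tows = integer(),
      source_program = character(), programs_seen = character()
    ))
  }
  per_program <- tows |>
    dplyr::group_by(.data$reef_id, .data$sector_id, .data$year, .data$program) |>
    dplyr::summarise(
      mean_cots_per_tow = mean(.data$cots_count),
      n_tows = dplyr::n(),
      .groups = "drop"
    )
  per_program |>
    dplyr::group_by(.data$reef_id, .data$sector_id, .data$year) |>
    dplyr::arrange(dplyr::desc(.data$mean_cots_per_tow), .data$program,
                   .by_group = TRUE) |>
    dplyr::summarise(
      programs_seen = paste(sort(unique(.data$program)), collapse = ","),
      source_program = dplyr::first(.data$program),
      n_tows = dplyr::first(.data$n_tows),
      mean_cots_per_tow = dplyr::first(.data$mean_cots_per_tow),
      .groups = "drop"
    ) |>
    dplyr::select("reef_id", "sector_id", "year", "mean_cots_per_tow",
                  "n_tows", "source_program", "programs_seen") |>
    dplyr::arrange(.data$reef_id, .data$year)
}

#' Grade reef outbreak status from density
#'
#' The operational threshold ladder: `below` up to and including 0.11
#' COTS/tow, `potential` above 0.11, `established` above 0.22, and `severe`
#' from 1 COTS/tow upwards. The lower boundaries are strict (a density of
#' exactly 0.11 is still `below`); the severe boundary is inclusive.
#'
#' @param density Non-negative COTS densities (COTS/tow).
#' @param config A [threshold_config()].
#' @return Ordered factor with levels below < potential < established <
#'   severe.
#' @export
#' @examples
#' classify_reef_status(c(0.05, 0.15, 0.5, 1.2))
classify_reef_status <- function(density, config = threshold_config()) {
  if (any(is.na(density)) || any(density < 0)) {
    rlang::abort("density must be non-negative")
  }
  lv <- c("below", "potential", "established", "severe")
  out <- dplyr::case_when(
    density >= config$severe ~ "severe",
    density > config$established ~ "established",
    density > config$potential ~ "potential",
    TRUE ~ "below"
  )
  factor(out, levels = lv, ordered = TRUE)
}

#' Sector-wide annual density series
#'
#' The sector density for a year is the unweighted mean of the reef-level
#' densities surveyed that year (optionally tow-weighted). Interior years
#' with no surveyed reef are filled by linear interpolation and flagged;
#' leading or trailing gaps are not extrapolated.
#'
#' @param densities Reef-year densities from [reef_year_density()].
#' @param registry Registry tibble; used to resolve sectors when
#'   `densities` lacks a `sector_id` column.
#' @param config A [threshold_config()]; `weight_by_tows` selects the
#'   tow-weighted mean.
#' @return Tibble with one row per sector-year: `sector_id`, `year`,
#'   `density`, `imputed`, `n_reefs`.
#' @export
sector_density_series <- function(densities, registry = NULL,
                                  config = threshold_config()) {
  if (!"sector_id" %in% names(densities)) {
    if (is.null(registry)) rlang::abort("registry needed to resolve sectors")
    densities$sector_id <- registry$sector_id[
      match(densities$reef_id, registry$reef_id)]
  }
  if (nrow(densities) == 0) {
    return(tibble::tibble(sector_id = character(), year = integer(),
                          density = numeric(), imputed = logical(),
                          n_reefs = integer()))
  }
  observed <- densities |>
    dplyr::group_by(.data$sector_id, .data$year) |>
    dplyr::summarise(
      density = if (config$weight_by_tows) {
        stats::weighted.mean(.data$mean_cots_per_tow, .data$n_tows)
      } else {
        mean(.data$mean_cots_per_tow)
      },
      n_reefs = dplyr::n(),
      .groups = "drop"
    )
  observed |>
    dplyr::group_by(.data$sector_id) |>
    dplyr::group_modify(~ interpolate_series(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sector_id, .data$year)
}

interpolate_series <- function(x) {
  yrs <- seq(min(x$year), max(x$year))
  full <- tibble::tibble(year = as.integer(yrs))
  out <- dplyr::left_join(full, x, by = "year")
  out$imputed <- is.na(out$density)
  if (any(out$imputed)) {
    out$density <- stats::approx(x$year, x$density, xout = out$year)$y
    out$n_reefs[out$imputed] <- 0L
  }
  out
}
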