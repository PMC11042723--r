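#' Reef-year coral cover from tow categories
#'
#' Converts each tow's ordinal cover category to its bin midpoint and
#' averages over the tows of a reef-year, giving the raw point estimate used
#' for reef-level change metrics (the model-based sector estimate is
#' [fit_sector_cover_model()]).
#'
#' @param tows Tow-record tibble, see [read_tow_records()].
#' @param scheme A [category_scheme()].
#' @return Tibble with one row per reef-year: `reef_id`, `sector_id`,
#'   `year`, `cover` (proportion), `n_tows`.
#' @export
reef_year_cover <- function(tows, scheme = category_scheme()) {
  tows |>
    dplyr::mutate(midpoint = category_to_midpoint(.data$cover_category, scheme)) |>
    dplyr::group_by(.data$reef_id, .data$sector_id, .data$year) |>
    dplyr::summarise(cover = mean(.data$midpoint), n_tows = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$reef_id, .data$year)
}

#' Relative change in coral cover
#'
#' Percent change of the end cover relative to the start cover:
#' `100 * (end - start) / start`.
#'
#' @param cover_start,cover_end Cover proportions; `cover_start` must be
#'   positive (a reef starting at zero cover has no defined relative change
#'   and is excluded upstream).
#' @return Percent change, vectorized.
#' @export
#' @examples
#' relative_change(0.20, 0.28) # +40
relative_change <- function(cover_start, cover_end) {
  if (any(is.na(cover_start)) || any(cover_start <= 0)) {
    rlang::abort("cover_start must be positive; exclude zero-cover reefs")
  }
  100 * (cover_end - cover_start) / cover_start
}

#' Annual absolute change in coral cover
#'
#' Percentage points of cover gained or lost per year:
#' `100 * (end - start) / duration`.
#'
#' @inheritParams relative_change
#' @param duration_years Window length in years; must be at least 1.
#' @return Percentage points per year, vectorized.
#' @export
#' @examples
#' annual_absolute_change(0.30, 0.12, 5) # -3.6 pp/yr
annual_absolute_change <- function(cover_start, cover_end, duration_years) {
  if (any(is.na(duration_years)) || any(duration_years < 1)) {
    rlang::abort("duration_years must be >= 1")
  }
  100 * (cover_end - cover_start) / duration_years
}

#' Align reef cover trajectories to outbreak onset
#'
#' For each reef, computes the relative cover change at 0-6 years since the
#' sector outbreak window opened, against a baseline taken at the window
#' start year (or the nearest earlier survey; failing that, the first survey
#' inside the window, with the baseline year recorded). Reefs surveyed fewer
#' than three times over the span are flagged and excluded by the trajectory
#' smoother.
#'
#' @param covers Reef-year cover tibble, see [reef_year_cover()].
#' @param window One-row outbreak window (needs `start_year`; see
#'   [detect_outbreak_period()]).
#' @param max_years Longest offset retained (default 6).
#' @return Tibble: `reef_id`, `years_since_onset`, `relative_change_pct`,
#'   `baseline_year`, `few_surveys`. Reefs with no usable baseline are
#'   dropped and listed in `attr(x, "excluded")`.
#' @export
align_to_onset <- function(covers, window, max_years = 6L) {
  if (is.null(window) || nrow(window) != 1) {
    rlang::abort("align_to_onset needs a single outbreak window")
  }
  start <- window$start_year
  horizon <- start + max_years
  excluded <- character()
  out <- covers |>
    dplyr::group_by(.data$reef_id) |>
    dplyr::group_map(function(x, key) {
      prior <- x[x$year <= start, , drop = FALSE]
      base_year <- if (nrow(prior) > 0) {
        max(prior$year)
      } else {
        inside <- x$year[x$year > start & x$year <= horizon]
        if (length(inside) == 0) return(NULL)
        min(inside)
      }
      base <- x$cover[x$year == base_year]
      if (base <= 0) return(NULL)
      span <- x[x$year >= start & x$year <= horizon, , drop = FALSE]
      if (nrow(span) == 0) return(NULL)
      tibble::tibble(
        reef_id = key$reef_id,
        years_since_onset = span$year - start,
        relative_change_pct = relative_change(base, span$cover),
        baseline_year = base_year,
        few_surveys = nrow(span) < 3
      )
    }) |>
    purrr::compact()
  kept <- if (length(out) > 0) dplyr::bind_rows(out) else {
    tibble::tibble(reef_id = character(), years_since_onset = integer(),
                   relative_change_pct = numeric(), baseline_year = integer(),
                   few_surveys = logical())
  }
  excluded <- setdiff(unique(covers$reef_id), unique(kept$reef_id))
  if (length(excluded) > 0) {
    rlang::inform(paste0(length(excluded),
                         " reef(s) excluded from onset alignment (no usable baseline)"))
  }
  attr(kept, "excluded") <- excluded
  kept
}

#' Per-reef change in cover over an outbreak window
#'
#' For each reef with surveys inside a sector's outbreak window, takes the
#' survey nearest the window start and the survey nearest the window end and
#' computes the relative change and the annual absolute change between them.
#'
#' @param covers Reef-year cover tibble, see [reef_year_cover()].
#' @param outbreaks Outbreak windows per sector, see [detect_outbreaks()].
#' @param registry Registry tibble resolving reefs to sectors.
#' @return Tibble: `reef_id`, `sector_id`, `start_year`, `end_year`,
#'   `cover_start`, `cover_end`, `relative_change_pct`,
#'   `annual_pp_per_year`. Reefs whose start cover is zero or that have
#'   fewer than two distinct surveys in the window are dropped.
#' @export
reef_wave_changes <- function(covers, outbreaks, registry) {
  if (!"sector_id" %in% names(covers)) {
    covers$sector_id <- registry$sector_id[match(covers$reef_id, registry$reef_id)]
  }
  purrr::pmap_dfr(
    list(outbreaks$sector_id, outbreaks$start_year, outbreaks$end_year),
    function(sec, ws, we) {
      covers |>
        dplyr::filter(.data$sector_id == sec,
                      .data$year >= ws, .data$year <= we) |>
        dplyr::group_by(.data$reef_id, .data$sector_id) |>
        dplyr::group_modify(function(x, key) {
          if (nrow(x) < 2) return(tibble::tibble())
          y0 <- x$year[which.min(abs(x$year - ws))]
          y1 <- x$year[which.max(x$year)]
          if (y1 <= y0) return(tibble::tibble())
          c0 <- x$cover[x$year == y0]
          c1 <- x$cover[x$year == y1]
          if (c0 <= 0) return(tibble::tibble())
          tibble::tibble(
            start_year = y0, end_year = y1,
            cover_start = c0, cover_end = c1,
            relative_change_pct = relative_change(c0, c1),
            annual_pp_per_year = annual_absolute_change(c0, c1, y1 - y0)
          )
        }) |>
        dplyr::ungroup()
    }
  )
}

#' Per-reef density statistics over an outbreak window
#'
#' Mean and maximum reef density during the sector's outbreak years, the
#' inputs to the wave-comparison model and the effort stratification. Reefs
#' in sectors without a detected window use their full series.
#'
#' @param densities Reef-year densities, see [reef_year_density()].
#' @param outbreaks Outbreak windows per sector, see [detect_outbreaks()].
#' @param registry Registry tibble.
#' @return Tibble: `reef_id`, `sector_id`, `mean_density`, `max_density`,
#'   `in_window` (whether a sector window bounded the statistics).
#' @export
reef_window_density <- function(densities, outbreaks, registry) {
  if (!"sector_id" %in% names(densities)) {
    densities$sector_id <- registry$sector_id[match(densities$reef_id, registry$reef_id)]
  }
  densities |>
    dplyr::left_join(
      dplyr::select(outbreaks, "sector_id", "start_year", "end_year"),
      by = "sector_id"
    ) |>
    dplyr::mutate(
      in_window = !is.na(.data$start_year) &
        .data$year >= .data$start_year & .data$year <= .data$end_year
    ) |>
    dplyr::group_by(.data$reef_id, .data$sector_id) |>
    dplyr::group_modify(function(x, key) {
      use <- if (any(x$in_window)) x[x$in_window, ] else x
      tibble::tibble(
        mean_density = mean(use$mean_cots_per_tow),
        max_density = max(use$mean_cots_per_tow),
        in_window = any(x$in_window)
      )
    }) |>
    dplyr::ungroup()
}
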