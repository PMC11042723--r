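#' Classify the sector-level management action
#'
#' Categorises the culling campaign in a sector by when it started relative
#' to the sector's outbreak-threshold crossings and whether it achieved
#' suppression:
#'
#' * `NoAction` - no culling hours at all;
#' * `Proactive` - culling started before the sector ever exceeded the
#'   potential threshold (0.11 COTS/tow);
#' * `Timely` - culling started at or after the potential crossing and
#'   suppression was achieved;
#' * `Reactive` - culling started before severe densities (1 COTS/tow) but
#'   suppression failed;
#' * `Limited` - everything else (culling started at or after severe
#'   densities, or failed with marginal effort).
#'
#' Suppression is a two-part test: after culling starts, the sector density
#' must fall below the potential threshold for at least
#' `persistence_years` consecutive years, *and* sector coral cover at the
#' end of the assessment window must be at least
#' `(1 - depletion_fraction)` of its start value - a density crash that
#' rides on coral collapse is prey depletion, not management suppression.
#'
#' @param timeline Tibble with columns `year`, `density` (sector series).
#' @param culls Tibble with columns `year`, `hours` (sector totals).
#' @param config A [threshold_config()].
#' @param cover Optional tibble (`year`, `cover`) of sector mean cover;
#'   required whenever the suppression test is reached.
#' @param window Optional one-row outbreak window (see
#'   [detect_outbreak_period()]) defining the cover assessment span;
#'   defaults to culling start through the last observed year.
#' @param sector_id Optional label carried into the result.
#' @return One-row tibble: `sector_id`, `action`, `cull_start_year`,
#'   `suppression_achieved`, `rationale`.
#' @export
classify_action <- function(timeline, culls, config = threshold_config(),
                            cover = NULL, window = NULL, sector_id = NA_character_) {
  timeline <- dplyr::arrange(timeline, .data$year)
  d <- timeline$density
  yrs <- timeline$year

  total_hours <- if (is.null(culls) || nrow(culls) == 0) 0 else sum(culls$hours)
  if (total_hours == 0) {
    return(action_row(sector_id, "NoAction", NA_integer_, NA,
                      "no culling hours recorded"))
  }
  y_cull <- min(culls$year[culls$hours > 0])
  y_pot <- first_year_above(yrs, d, config$potential)
  y_sev <- first_year_at_or_above(yrs, d, config$severe)
  y_pot_cmp <- ifelse(is.na(y_pot), Inf, y_pot)
  y_sev_cmp <- ifelse(is.na(y_sev), Inf, y_sev)

  if (y_cull < y_pot_cmp) {
    return(action_row(
      sector_id, "Proactive", y_cull, NA,
      sprintf("culling started %d, before any potential-threshold crossing (%s)",
              y_cull, ifelse(is.na(y_pot), "never crossed", y_pot))
    ))
  }

  if (is.null(cover) || nrow(cover) == 0) {
    rlang::abort("sector cover series required for the suppression test")
  }
  after <- yrs > y_cull
  low_run <- first_run_start(d < config$potential & after, config$persistence_years)
  density_suppressed <- !is.na(low_run) && all(after[low_run:(low_run + config$persistence_years - 1L)])

  span <- if (!is.null(window) && nrow(window) == 1) {
    c(window$start_year, window$end_year)
  } else {
    c(y_cull, max(yrs))
  }
  c_start <- cover_at(cover, span[1])
  c_end <- cover_at(cover, span[2])
  cover_kept <- c_end >= (1 - config$depletion_fraction) * c_start
  suppressed <- density_suppressed && cover_kept

  trace <- sprintf(
    paste0("culling started %d; potential crossed %s; severe crossed %s; ",
           "density below potential for %d consecutive years after start: %s; ",
           "cover %s -> %s over %d-%d (kept >= %d%%: %s)"),
    y_cull, ifelse(is.na(y_pot), "never", y_pot),
    ifelse(is.na(y_sev), "never", y_sev),
    config$persistence_years, density_suppressed,
    signif(c_start, 3), signif(c_end, 3), span[1], span[2],
    round(100 * (1 - config$depletion_fraction)), cover_kept
  )

  action <- if (suppressed) {
    "Timely"
  } else if (y_cull < y_sev_cmp) {
    "Reactive"
  } else {
    "Limited"
  }
  action_row(sector_id, action, y_cull, suppressed, trace)
}

action_row <- function(sector_id, action, y_cull, suppressed, rationale) {
  tibble::tibble(
    sector_id = sector_id,
    action = factor(action, levels = c("Proactive", "Timely", "Reactive",
                                       "Limited", "NoAction")),
    cull_start_year = as.integer(y_cull),
    suppression_achieved = suppressed,
    rationale = rationale
  )
}

cover_at <- function(cover, year) {
  i <- which.min(abs(cover$year - year))
  cover$cover[i]
}

#' Culling-effort ratio
#'
#' Effort standardized by outbreak severity: culling hours divided by the
#' maximum COTS density recorded at the reef, in hours per (COTS/tow).
#'
#' @param total_hours Total diver bottom-hours at the reef.
#' @param max_density Maximum COTS density at the reef over the assessment
#'   window; must be positive (zero-density reefs belong in the NoOutbreak
#'   stratum, not here).
#' @return Hours per (COTS/tow).
#' @export
#' @examples
#' effort_ratio(242.62, 2.0)
effort_ratio <- function(total_hours, max_density) {
  if (any(is.na(max_density)) || any(max_density <= 0)) {
    rlang::abort("max_density must be positive; route zero-density reefs to NoOutbreak")
  }
  total_hours / max_density
}

#' Hours needed to reach above-median culling effort
#'
#' Inverts the effort ratio: at a given density, the hour level that sits at
#' the median effort ratio.
#'
#' @param median_ratio Median effort ratio, hours per (COTS/tow).
#' @param density COTS density (COTS/tow).
#' @return Hours (`median_ratio * density`).
#' @export
#' @examples
#' effort_threshold_hours(121.31, 0.1) # 12.131 hours at a potential-outbreak reef
effort_threshold_hours <- function(median_ratio, density) {
  if (any(median_ratio < 0) || any(density < 0)) {
    rlang::abort("median_ratio and density must be non-negative")
  }
  median_ratio * density
}

#' Stratify reefs by culling effort
#'
#' Assigns each reef to one of four strata: `NoOutbreak` (maximum density
#' below the reef outbreak threshold - the control group), `NoEffort`
#' (outbreak but zero hours), and `AboveMedian` / `BelowMedian` split at the
#' median effort ratio computed over outbreak reefs that received effort
#' (including zero-effort reefs in the median would drag it to zero and
#' merge the strata). Ties at the median go to `AboveMedian`.
#'
#' @param reefs Tibble with columns `reef_id`, `total_hours`, `max_density`
#'   (and any others, which are carried through).
#' @param config A [threshold_config()]; `reef_outbreak_threshold` sets the
#'   control-group cut.
#' @return `reefs` with added columns `effort_ratio`, `category` (factor)
#'   and `median_ratio_used`.
#' @export
stratify_effort <- function(reefs, config = threshold_config()) {
  lv <- c("NoOutbreak", "AboveMedian", "BelowMedian", "NoEffort")
  out <- reefs |>
    dplyr::mutate(
      outbreak = .data$max_density >= config$reef_outbreak_threshold,
      effort_ratio = dplyr::if_else(.data$outbreak & .data$max_density > 0,
                                    .data$total_hours / .data$max_density,
                                    NA_real_)
    )
  eligible <- out$outbreak & out$total_hours > 0
  if (!any(eligible)) {
    if (any(out$outbreak)) {
      rlang::warn("no outbreak reef received culling effort; median stratification degenerates")
    }
    med <- NA_real_
  } else {
    med <- stats::median(out$effort_ratio[eligible])
  }
  out |>
    dplyr::mutate(
      category = factor(dplyr::case_when(
        !.data$outbreak ~ "NoOutbreak",
        .data$total_hours == 0 ~ "NoEffort",
        .data$effort_ratio >= med ~ "AboveMedian",
        TRUE ~ "BelowMedian"
      ), levels = lv),
      median_ratio_used = med
    ) |>
    dplyr::select(-"outbreak")
}

#' Sector shares of total culling effort
#'
#' @param sector_hours Hours for the sector(s) of interest, vectorized.
#' @param all_sector_hours Hours of every sector (the denominator).
#' @return Percentages of the total, rounded half-up to one decimal.
#' @export
#' @examples
#' hours <- c(3558, 15352, 11082, 23534, 221, 1599, 6619)
#' effort_share(hours, hours)
effort_share <- function(sector_hours, all_sector_hours) {
  total <- sum(all_sector_hours)
  if (is.na(total) || total <= 0) rlang::abort("total culling hours must be positive")
  round_half_up(100 * sector_hours / total, 1)
}
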