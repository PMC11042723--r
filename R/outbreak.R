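#' Delimit the sector-wide outbreak period in a density series
#'
#' Applies the operational outbreak-period criteria to an annual sector
#' density series:
#'
#' * **Inception** - the density exceeds the inception threshold (the
#'   potential threshold 0.11 COTS/tow, or the established threshold 0.22
#'   for sectors whose outbreaks historically run several-fold denser) for
#'   at least `persistence_years` consecutive years; the inception year is
#'   the first year of that run.
#' * **Escalation** - at or after inception, the density exceeds the
#'   established threshold.
#' * A sector-wide outbreak exists only if both criteria are met. The
#'   window additionally includes the year before the density crossed the
#'   potential threshold on its way into the outbreak, to capture the
#'   beginning of rapid population growth.
#' * **Decline** - the outbreak ends with `decline_years` consecutive years
#'   below the potential threshold; by default those closing years are
#'   counted inside the window (`include_decline_years`). If no decline is
#'   observed the outbreak is flagged `ongoing` and the window runs to the
#'   last observed year.
#'
#' @param series Tibble with columns `year` (consecutive) and `density`.
#' @param config A [threshold_config()].
#' @param uses_established_inception Use the established threshold for the
#'   inception criterion (per-sector registry flag).
#' @return A one-row tibble (`start_year`, `end_year`, `ongoing`,
#'   `inception_year`, `escalation_year`, `decline_year`) or a zero-row
#'   tibble when no outbreak window exists.
#' @export
#' @examples
#' s <- tibble::tibble(year = 2011:2016,
#'                     density = c(0.05, 0.15, 0.25, 0.30, 0.08, 0.06))
#' detect_outbreak_period(s)
detect_outbreak_period <- function(series, config = threshold_config(),
                                   uses_established_inception = FALSE) {
  series <- dplyr::arrange(series, .data$year)
  yrs <- series$year
  d <- series$density
  n <- length(d)
  p <- config$persistence_years
  q <- config$decline_years
  if (n < 3 || n < p) {
    rlang::abort("density series shorter than the persistence window")
  }
  if (any(diff(yrs) != 1)) rlang::abort("series years must be consecutive")

  empty <- tibble::tibble(
    start_year = integer(), end_year = integer(), ongoing = logical(),
    inception_year = integer(), escalation_year = integer(),
    decline_year = integer()
  )

  t_inc <- if (uses_established_inception) config$established else config$potential
  above_inc <- d > t_inc
  inception <- first_run_start(above_inc, p)
  if (is.na(inception)) return(empty)
  escalation <- inception - 1 + match(TRUE, d[inception:n] > config$established)
  if (is.na(escalation)) return(empty)

  # walk back through the run of years above the potential threshold that
  # leads into the outbreak, then include one year prior
  above_pot <- d > config$potential
  run_start <- inception
  while (run_start > 1 && above_pot[run_start - 1]) run_start <- run_start - 1
  start <- max(1L, run_start - 1L)

  below_pot <- d < config$potential
  decline <- if (escalation < n) {
    idx <- first_run_start(below_pot, q, from = escalation + 1L)
    idx
  } else NA_integer_

  if (is.na(decline)) {
    end <- n
    ongoing <- TRUE
  } else {
    end <- if (config$include_decline_years) decline + q - 1L else decline - 1L
    ongoing <- FALSE
  }

  tibble::tibble(
    start_year = yrs[start],
    end_year = yrs[end],
    ongoing = ongoing,
    inception_year = yrs[inception],
    escalation_year = yrs[escalation],
    decline_year = if (is.na(decline)) NA_integer_ else yrs[decline]
  )
}

# index of the first position i >= from such that x[i..i+len-1] are all TRUE
first_run_start <- function(x, len, from = 1L) {
  n <- length(x)
  if (from > n - len + 1L) return(NA_integer_)
  for (i in seq(from, n - len + 1L)) {
    if (all(x[i:(i + len - 1L)])) return(i)
  }
  NA_integer_
}

#' Detect outbreak windows for every sector
#'
#' @param sector_series Output of [sector_density_series()].
#' @param registry Registry tibble carrying the per-sector
#'   `uses_established_inception` flag.
#' @param config A [threshold_config()].
#' @return Tibble with one row per sector that has an outbreak window,
#'   columns as in [detect_outbreak_period()] plus `sector_id`.
#' @export
detect_outbreaks <- function(sector_series, registry,
                             config = threshold_config()) {
  flags <- registry |>
    dplyr::distinct(.data$sector_id, .data$uses_established_inception)
  sector_series |>
    dplyr::group_by(.data$sector_id) |>
    dplyr::group_modify(function(x, key) {
      flag <- flags$uses_established_inception[flags$sector_id == key$sector_id]
      flag <- isTRUE(flag[1])
      detect_outbreak_period(x, config, uses_established_inception = flag)
    }) |>
    dplyr::ungroup()
}
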