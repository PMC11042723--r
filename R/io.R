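#' Read the reef/sector registry
#'
#' The registry maps every surveyed reef to exactly one latitudinal sector,
#' orders sectors along the outbreak wave path, and records which sectors use
#' the established-outbreak threshold for outbreak inception (on the GBR,
#' Townsville and Swain, whose outbreaks run 3-5x denser than other sectors).
#'
#' @param path CSV with columns `reef_id`, `sector_id`, `sector_order`,
#'   `uses_established_inception`.
#' @return A tibble of class `cots_registry`.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("registry file not found: ", path))
  reg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_registry(reg)
}

#' Validate a registry data frame
#'
#' @param reg Data frame with registry columns (see [read_registry()]).
#' @return The validated registry tibble.
#' @export
as_registry <- function(reg) {
  need <- c("reef_id", "sector_id", "sector_order", "uses_established_inception")
  missing <- setdiff(need, names(reg))
  if (length(missing) > 0) {
    rlang::abort(paste0("registry is missing columns: ", paste(missing, collapse = ", ")))
  }
  reg <- tibble::as_tibble(reg)
  reg$reef_id <- as.character(reg$reef_id)
  reg$sector_id <- as.character(reg$sector_id)
  reg$uses_established_inception <- as.logical(reg$uses_established_inception)
  dup <- reg$reef_id[duplicated(reg$reef_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("reefs mapped to more than one sector: ",
                        paste(unique(dup), collapse = ", ")))
  }
  sectors <- dplyr::distinct(reg, .data$sector_id, .data$sector_order)
  if (anyDuplicated(sectors$sector_id) > 0) {
    rlang::abort("a sector has more than one sector_order")
  }
  if (!setequal(sectors$sector_order, seq_len(nrow(sectors)))) {
    rlang::abort("sector_order values must be a permutation of 1..S")
  }
  class(reg) <- c("cots_registry", class(reg))
  reg
}

#' Read and validate manta-tow survey records
#'
#' Each row is one two-minute manta tow (~2000 m2 swept): an ordinal
#' hard-coral cover category (0-5) and a count of COTS seen. Rows with an
#' invalid cover category or missing numeric fields are rejected (with the
#' reasons attached as the `rejects` attribute and a warning); an unknown
#' reef or a duplicated (reef, year, program, tow) key is a hard error,
#' since either indicates a corrupted extract rather than a bad record.
#'
#' @param path CSV with columns `reef_id`, `sector_id` (optional), `year`,
#'   `program` (LTMP, RJFMP or CONTROL), `tow_index`, `cover_category`,
#'   `cots_count`, and optionally `tow_area_m2`.
#' @param registry Registry used to resolve reefs to sectors, see
#'   [read_registry()].
#' @param years Optional integer range; rows outside it are rejected.
#' @return Tibble of validated tow records with reefs resolved to sectors.
#'   Rejected rows (if any) are attached as `attr(x, "rejects")`.
#' @export
read_tow_records <- function(path, registry, years = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("tow file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("reef_id", "year", "program", "tow_index", "cover_category", "cots_count")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("tow file is missing columns: ", paste(missing, collapse = ", ")))
  }
  raw$reef_id <- as.character(raw$reef_id)
  unknown <- setdiff(unique(raw$reef_id), registry$reef_id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("tow records reference reefs absent from the registry: ",
                        paste(unknown, collapse = ", ")))
  }

  reason <- rep(NA_character_, nrow(raw))
  bad_cat <- is.na(raw$cover_category) | !(raw$cover_category %in% 0:5)
  reason[bad_cat] <- "cover_category outside 0-5"
  bad_count <- is.na(reason) & (is.na(raw$cots_count) | raw$cots_count < 0)
  reason[bad_count] <- "missing or negative cots_count"
  bad_prog <- is.na(reason) & !(raw$program %in% c("LTMP", "RJFMP", "CONTROL"))
  reason[bad_prog] <- "unknown program"
  bad_year <- is.na(reason) & is.na(raw$year)
  if (!is.null(years)) {
    bad_year <- bad_year | (is.na(reason) & !(raw$year %in% years))
  }
  reason[bad_year] <- "year missing or outside configured range"

  rejects <- raw[!is.na(reason), , drop = FALSE]
  if (nrow(rejects) > 0) {
    rejects$reject_reason <- reason[!is.na(reason)]
    rlang::warn(paste0("rejected ", nrow(rejects), " tow record(s); see attr(x, 'rejects')"))
  }
  tows <- raw[is.na(reason), , drop = FALSE]

  key <- paste(tows$reef_id, tows$year, tows$program, tows$tow_index, sep = "|")
  if (anyDuplicated(key) > 0) {
    rlang::abort(paste0("duplicate tow keys (reef_id, year, program, tow_index): ",
                        paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; ")))
  }

  tows$sector_id <- registry$sector_id[match(tows$reef_id, registry$reef_id)]
  if (!"tow_area_m2" %in% names(tows)) tows$tow_area_m2 <- 2000
  tows <- dplyr::select(
    tows, "reef_id", "sector_id", "year", "program", "tow_index",
    "cover_category", "cots_count", "tow_area_m2"
  )
  tows$year <- as.integer(tows$year)
  tows$tow_index <- as.integer(tows$tow_index)
  tows$cover_category <- as.integer(tows$cover_category)
  tows$cots_count <- as.integer(tows$cots_count)
  out <- tibble::as_tibble(tows)
  attr(out, "rejects") <- if (nrow(rejects) > 0) tibble::as_tibble(rejects) else NULL
  out
}

#' Read a culling log and aggregate to reef-year totals
#'
#' Hours are diver bottom-time spent injecting COTS. Multiple entries for the
#' same reef and year are summed; totals are conserved.
#'
#' @param path CSV with columns `reef_id`, `year`, `hours`.
#' @param registry Registry used to resolve reefs to sectors.
#' @return Tibble with one row per (reef, year): `reef_id`, `sector_id`,
#'   `year`, `hours`.
#' @export
read_cull_log <- function(path, registry) {
  if (!file.exists(path)) rlang::abort(paste0("cull log not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    rlang::warn("cull log is empty; returning zero cull records")
    return(tibble::tibble(reef_id = character(), sector_id = character(),
                          year = integer(), hours = numeric()))
  }
  need <- c("reef_id", "year", "hours")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("cull log is missing columns: ", paste(missing, collapse = ", ")))
  }
  raw$reef_id <- as.character(raw$reef_id)
  if (any(is.na(raw$hours)) || any(raw$hours < 0)) {
    rlang::abort("cull log contains missing or negative hours")
  }
  unknown <- setdiff(unique(raw$reef_id), registry$reef_id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("cull log references reefs absent from the registry: ",
                        paste(unknown, collapse = ", ")))
  }
  raw |>
    dplyr::group_by(reef_id = .data$reef_id, year = as.integer(.data$year)) |>
    dplyr::summarise(hours = sum(.data$hours), .groups = "drop") |>
    dplyr::mutate(sector_id = registry$sector_id[match(.data$reef_id, registry$reef_id)]) |>
    dplyr::select("reef_id", "sector_id", "year", "hours") |>
    dplyr::arrange(.data$reef_id, .data$year)
}

#' Write a result table deterministically
#'
#' Rows are sorted by every column left to right, numeric columns are rounded
#' half-up to the configured number of decimals, and the file is written as
#' UTF-8 CSV, so that identical inputs always produce byte-identical files
#' and read -> write -> read is an identity at the declared precision.
#'
#' @param records A data frame; an empty one yields a header-only file.
#' @param path Output CSV path.
#' @param digits Decimal places for numeric columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, digits = 4) {
  if (is.null(records)) rlang::abort("records must be non-null")
  records <- tibble::as_tibble(records)
  num <- vapply(records, is.double, logical(1))
  records[num] <- lapply(records[num], round_half_up, digits = digits)
  if (nrow(records) > 0) {
    records <- dplyr::arrange(records, dplyr::across(dplyr::everything()))
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) rlang::abort(paste0("output directory does not exist: ", dir))
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
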