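# Independent brute-force oracles, written as literal year-by-year scans so
# they stay independent of the vectorised implementations they check.

oracle_outbreak_window <- function(years, density,
                                   potential = 0.11, established = 0.22,
                                   persistence = 2L, decline = 2L,
                                   uses_established = FALSE,
                                   include_decline = TRUE) {
  n <- length(density)
  t_inc <- if (uses_established) established else potential

  inception <- NA_integer_
  for (i in seq_len(n)) {
    if (i + persistence - 1L > n) break
    ok <- TRUE
    for (j in i:(i + persistence - 1L)) if (!(density[j] > t_inc)) ok <- FALSE
    if (ok) { inception <- i; break }
  }
  if (is.na(inception)) return(NULL)

  escalation <- NA_integer_
  for (i in inception:n) {
    if (density[i] > established) { escalation <- i; break }
  }
  if (is.na(escalation)) return(NULL)

  run_start <- inception
  while (run_start > 1L && density[run_start - 1L] > potential) {
    run_start <- run_start - 1L
  }
  start <- max(1L, run_start - 1L)

  dec <- NA_integer_
  if (escalation < n) {
    for (i in (escalation + 1L):n) {
      if (i + decline - 1L > n) break
      ok <- TRUE
      for (j in i:(i + decline - 1L)) if (!(density[j] < potential)) ok <- FALSE
      if (ok) { dec <- i; break }
    }
  }
  if (is.na(dec)) {
    list(start_year = years[start], end_year = years[n], ongoing = TRUE,
         inception_year = years[inception], escalation_year = years[escalation],
         decline_year = NA_integer_)
  } else {
    end <- if (include_decline) dec + decline - 1L else dec - 1L
    list(start_year = years[start], end_year = years[end], ongoing = FALSE,
         inception_year = years[inception], escalation_year = years[escalation],
         decline_year = years[dec])
  }
}

# group-by recomputation of reef-year densities using base loops only
oracle_reef_density <- function(tows) {
  out <- list()
  for (rf in unique(tows$reef_id)) {
    for (yr in unique(tows$year[tows$reef_id == rf])) {
      sub <- tows[tows$reef_id == rf & tows$year == yr, ]
      best <- -Inf; best_prog <- NA
      for (pg in sort(unique(sub$program))) {
        m <- mean(sub$cots_count[sub$program == pg])
        if (m > best) { best <- m; best_prog <- pg }
      }
      out[[length(out) + 1]] <- data.frame(
        reef_id = rf, year = yr, density = best, program = best_prog
      )
    }
  }
  do.call(rbind, out)
}

oracle_stratify <- function(reefs, threshold = 0.11) {
  ratios <- c()
  for (i in seq_len(nrow(reefs))) {
    if (reefs$max_density[i] >= threshold && reefs$total_hours[i] > 0) {
      ratios <- c(ratios, reefs$total_hours[i] / reefs$max_density[i])
    }
  }
  med <- if (length(ratios) > 0) stats::median(ratios) else NA
  cat_of <- function(h, d) {
    if (d < threshold) return("NoOutbreak")
    if (h == 0) return("NoEffort")
    if (h / d >= med) "AboveMedian" else "BelowMedian"
  }
  mapply(cat_of, reefs$total_hours, reefs$max_density)
}

random_density_series <- function(len) {
  grid <- c(0, 0.05, 0.08, 0.11, 0.12, 0.15, 0.2, 0.22, 0.25, 0.5, 1.0, 1.5)
  sample(grid, len, replace = TRUE)
}
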