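#' Configure an end-to-end pipeline run
#'
#' @param tows,culls,registry Paths to the input CSVs (see
#'   [read_tow_records()], [read_cull_log()], [read_registry()]).
#' @param out_dir Output directory; created if absent.
#' @param thresholds A [threshold_config()].
#' @param scheme A [category_scheme()].
#' @param mcmc A [model_spec()].
#' @param seed Integer seed used by every stochastic stage.
#' @param strict_convergence Abort when a model's reported estimands fail
#'   the rhat < 1.01 check.
#' @param run_models Fit the Bayesian models and smoothers (the slow
#'   stage); classification-only runs set this to `FALSE`.
#' @return A list of class `cots_pipeline_config`.
#' @export
pipeline_config <- function(tows, culls, registry, out_dir,
                            thresholds = threshold_config(),
                            scheme = category_scheme(),
                            mcmc = model_spec(),
                            seed = 1L,
                            strict_convergence = FALSE,
                            run_models = TRUE) {
  structure(
    list(tows = tows, culls = culls, registry = registry, out_dir = out_dir,
         thresholds = thresholds, scheme = scheme, mcmc = mcmc,
         seed = as.integer(seed),
         strict_convergence = isTRUE(strict_convergence),
         run_models = isTRUE(run_models)),
    class = "cots_pipeline_config"
  )
}

stage <- function(name, log_env, code) {
  t0 <- Sys.time()
  out <- tryCatch(force(code), error = function(e) {
    rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                        conditionMessage(e)))
  })
  elapsed <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  log_env$log <- c(log_env$log, paste0("stage ", name, " done"))
  rlang::inform(paste0("[", name, "] ", elapsed, "s"))
  out
}

#' Run the surveillance pipeline end to end
#'
#' Executes the stages in dependency order: input validation, reef and
#' sector densities, outbreak-window detection, management-action and
#' culling-effort classification, cover-change metrics, and (optionally)
#' the hierarchical models and trajectory smoothers. All tables are written
#' to `out_dir` deterministically; rerunning with the same inputs and seed
#' reproduces the bundle byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `cots_bundle` holding every intermediate and
#'   final table, the fitted models (when run), the run log, and the
#'   config hash.
#' @export
run_pipeline <- function(config) {
  le <- new.env(); le$log <- character()
  th <- config$thresholds
  cfg_hash <- rlang::hash(list(th, config$scheme, config$mcmc, config$seed))

  io <- stage("io", le, {
    for (p in c(config$tows, config$culls, config$registry)) {
      if (!file.exists(p)) rlang::abort(paste0("input file not found: ", p))
    }
    registry <- read_registry(config$registry)
    list(
      registry = registry,
      tows = read_tow_records(config$tows, registry),
      culls = read_cull_log(config$culls, registry)
    )
  })

  dens <- stage("densities", le, {
    rd <- reef_year_density(io$tows)
    list(reef = rd, sector = sector_density_series(rd, io$registry, th))
  })

  cover <- stage("cover", le, {
    rc <- reef_year_cover(io$tows, config$scheme)
    sc <- rc |>
      dplyr::group_by(.data$sector_id, .data$year) |>
      dplyr::summarise(cover = mean(.data$cover), .groups = "drop")
    list(reef = rc, sector = sc)
  })

  outbreaks <- stage("outbreaks", le, {
    detect_outbreaks(dens$sector, io$registry, th)
  })

  actions <- stage("actions", le, {
    sectors <- sort(unique(dens$sector$sector_id))
    purrr::map_dfr(sectors, function(sec) {
      classify_action(
        timeline = dens$sector[dens$sector$sector_id == sec, ],
        culls = io$culls[io$culls$sector_id == sec, ] |>
          dplyr::group_by(.data$year) |>
          dplyr::summarise(hours = sum(.data$hours), .groups = "drop"),
        config = th,
        cover = cover$sector[cover$sector$sector_id == sec, ],
        window = outbreaks[outbreaks$sector_id == sec, ],
        sector_id = sec
      )
    })
  })

  effort <- stage("effort", le, {
    wd <- reef_window_density(dens$reef, outbreaks, io$registry)
    hours <- io$culls |>
      dplyr::group_by(.data$reef_id) |>
      dplyr::summarise(total_hours = sum(.data$hours), .groups = "drop")
    wd |>
      dplyr::left_join(hours, by = "reef_id") |>
      dplyr::mutate(total_hours = tidyr::replace_na(.data$total_hours, 0)) |>
      stratify_effort(th)
  })

  changes <- stage("changes", le, {
    ch <- reef_wave_changes(cover$reef, outbreaks, io$registry)
    if (nrow(ch) == 0) ch else {
      dplyr::left_join(ch, dplyr::select(effort, "reef_id", "category"),
                       by = "reef_id")
    }
  })

  trajectories <- stage("trajectories", le, {
    purrr::map_dfr(seq_len(nrow(outbreaks)), function(i) {
      w <- outbreaks[i, ]
      cc <- cover$reef[cover$reef$sector_id == w$sector_id, ]
      if (nrow(cc) == 0) return(tibble::tibble())
      tr <- align_to_onset(cc, w)
      if (nrow(tr) == 0) return(tibble::tibble())
      tr$sector_id <- w$sector_id
      tr
    })
  })

  models <- NULL
  if (config$run_models) {
    models <- stage("models", le, {
      out <- list()
      out$sector_cover <- fit_sector_cover_model(
        io$tows, config$mcmc, config$scheme, seed = config$seed,
        strict = config$strict_convergence
      )
      if (nrow(changes) > 0 && length(unique(effort$category)) >= 2) {
        eff_data <- changes |>
          dplyr::transmute(.data$reef_id, .data$sector_id,
                          category = .data$category,
                          annual_change_pp = .data$annual_pp_per_year)
        out$effort <- fit_effort_model(eff_data, config$mcmc,
                                       seed = config$seed + 1L,
                                       strict = config$strict_convergence)
      }
      if (nrow(trajectories) > 0) {
        out$trajectory <- fit_trajectory_smoother(trajectories, by = "sector_id")
      }
      # density comparison across sectors for the (single) detected wave:
      # only reefs that ever exceeded the potential outbreak threshold
      wd <- reef_window_density(dens$reef, outbreaks, io$registry)
      wave_data <- dens$reef |>
        dplyr::group_by(.data$reef_id, .data$sector_id) |>
        dplyr::summarise(ever = max(.data$mean_cots_per_tow), .groups = "drop") |>
        dplyr::filter(.data$ever > th$potential) |>
        dplyr::inner_join(dplyr::select(wd, "reef_id", "mean_density"),
                          by = "reef_id") |>
        dplyr::transmute(.data$reef_id, .data$sector_id, wave = "W1",
                         value = .data$mean_density)
      if (nrow(wave_data) >= 4) {
        out$wave_density <- fit_wave_comparison_model(
          wave_data, "density", config$mcmc, seed = config$seed + 2L,
          strict = config$strict_convergence
        )
      }
      out
    })
  }

  bundle <- structure(
    list(
      registry = io$registry, tows = io$tows, culls = io$culls,
      reef_density = dens$reef, sector_series = dens$sector,
      reef_cover = cover$reef, sector_cover = cover$sector,
      outbreaks = outbreaks, actions = actions, effort = effort,
      changes = changes, trajectories = trajectories, models = models,
      seed = config$seed, config_hash = cfg_hash, log = le$log
    ),
    class = "cots_bundle"
  )

  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  d <- th$rounding
  out <- config$out_dir
  write_table(dens$sector, file.path(out, "sector_series.csv"), d)
  write_table(outbreaks, file.path(out, "outbreaks.csv"), d)
  write_table(dplyr::select(actions, -"rationale"),
              file.path(out, "actions.csv"), d)
  write_table(effort, file.path(out, "effort.csv"), d)
  write_table(cover$reef, file.path(out, "cover.csv"), d)
  write_table(changes, file.path(out, "changes.csv"), d)
  write_table(trajectories, file.path(out, "trajectories.csv"), d)
  if (!is.null(models)) {
    summaries <- purrr::imap_dfr(models, function(m, name) {
      if (inherits(m, "cots_gam_fit")) return(tibble::tibble())
      s <- tidy(m)
      s$model <- name
      s$rhat_max <- if (inherits(m, "cots_cover_fit")) {
        max(purrr::map_dbl(m$diagnostics, "rhat_max_estimands"))
      } else m$diagnostics$rhat_max_estimands
      s
    })
    write_table(summaries, file.path(out, "summaries.csv"), d)
    if (!is.null(models$trajectory)) {
      write_table(models$trajectory$curves, file.path(out, "curves.csv"), d)
    }
  }
  writeLines(c(paste0("seed: ", config$seed),
               paste0("config_hash: ", cfg_hash), le$log),
             file.path(out, "run_log.txt"))
  bundle
}

#' Render summary report tables from a pipeline bundle
#'
#' Builds the headline tables: a sector table (culling hours, effort
#' shares, outbreak windows, management action), a posterior contrast
#' table, and a culling-effort table. Sections whose inputs are missing
#' from the bundle are skipped and listed under `missing`.
#'
#' @param bundle A `cots_bundle` from [run_pipeline()].
#' @return A list with elements `sector_table`, `contrast_table`,
#'   `effort_table` (tibbles or `NULL`) and `missing` (character vector).
#' @export
render_report <- function(bundle) {
  missing <- character()

  hours <- bundle$culls |>
    dplyr::group_by(.data$sector_id) |>
    dplyr::summarise(hours = sum(.data$hours), .groups = "drop")
  sectors <- bundle$registry |>
    dplyr::distinct(.data$sector_id, .data$sector_order) |>
    dplyr::arrange(.data$sector_order)
  all_hours <- sectors |>
    dplyr::left_join(hours, by = "sector_id") |>
    dplyr::mutate(hours = tidyr::replace_na(.data$hours, 0))
  sector_table <- all_hours |>
    dplyr::mutate(effort_share_pct = effort_share(.data$hours, .data$hours)) |>
    dplyr::left_join(dplyr::select(bundle$actions, "sector_id", "action",
                                   "cull_start_year"),
                     by = "sector_id") |>
    dplyr::left_join(dplyr::select(bundle$outbreaks, "sector_id", "start_year",
                                   "end_year", "ongoing"),
                     by = "sector_id")

  contrast_table <- NULL
  if (!is.null(bundle$models$wave_density)) {
    contrast_table <- tidy(bundle$models$wave_density)
  } else {
    missing <- c(missing, "contrast_table")
  }

  effort_table <- NULL
  if (!is.null(bundle$models$effort)) {
    effort_table <- tidy(bundle$models$effort)
  } else if (!is.null(bundle$effort) && nrow(bundle$effort) > 0) {
    effort_table <- bundle$effort |>
      dplyr::count(.data$category, name = "n_reefs") |>
      dplyr::mutate(median_ratio_used = bundle$effort$median_ratio_used[1])
  } else {
    missing <- c(missing, "effort_table")
  }

  list(sector_table = sector_table, contrast_table = contrast_table,
       effort_table = effort_table, missing = missing)
}
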