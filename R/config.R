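#' Outbreak threshold configuration
#'
#' Density thresholds (COTS per manta tow) and window rules used to grade
#' reef outbreak status and delimit sector-wide outbreak periods. The default
#' ladder is the one used operationally on the Great Barrier Reef: a reef is a
#' *Potential* outbreak above 0.11 COTS/tow, *Established* above 0.22, and
#' *Severe* at 1 COTS/tow and beyond.
#'
#' @param potential Potential-outbreak density threshold (COTS/tow).
#' @param established Established-outbreak density threshold (COTS/tow).
#' @param severe Severe-outbreak density threshold (COTS/tow).
#' @param persistence_years Consecutive years the sector density must exceed
#'   the inception threshold before an outbreak is declared.
#' @param decline_years Consecutive years below `potential` that end an
#'   outbreak.
#' @param reef_outbreak_threshold Per-reef density below which a reef is
#'   treated as having had no outbreak in the culling-effort stratification.
#' @param depletion_fraction Maximum tolerated proportional coral-cover loss
#'   for a density decline to count as management suppression rather than
#'   prey depletion.
#' @param rounding Decimal places used when writing report tables.
#' @param include_decline_years Should the two closing sub-threshold years be
#'   counted inside the outbreak window? Defaults to `TRUE`.
#' @param weight_by_tows Weight sector means by tow counts instead of the
#'   unweighted mean of reef means. Defaults to `FALSE`.
#'
#' @return A list of class `cots_thresholds`.
#' @export
#' @examples
#' cfg <- threshold_config()
#' cfg$established
threshold_config <- function(potential = 0.11,
                             established = 0.22,
                             severe = 1.0,
                             persistence_years = 2L,
                             decline_years = 2L,
                             reef_outbreak_threshold = 0.11,
                             depletion_fraction = 0.25,
                             rounding = 4L,
                             include_decline_years = TRUE,
                             weight_by_tows = FALSE) {
  cfg <- list(
    potential = potential,
    established = established,
    severe = severe,
    persistence_years = as.integer(persistence_years),
    decline_years = as.integer(decline_years),
    reef_outbreak_threshold = reef_outbreak_threshold,
    depletion_fraction = depletion_fraction,
    rounding = as.integer(rounding),
    include_decline_years = isTRUE(include_decline_years),
    weight_by_tows = isTRUE(weight_by_tows)
  )
  validate_threshold_config(cfg)
  structure(cfg, class = "cots_thresholds")
}

validate_threshold_config <- function(cfg) {
  if (!(cfg$potential > 0 && cfg$potential < cfg$established &&
        cfg$established < cfg$severe)) {
    rlang::abort("thresholds must satisfy 0 < potential < established < severe")
  }
  if (cfg$persistence_years < 1L) rlang::abort("persistence_years must be >= 1")
  if (cfg$decline_years < 1L) rlang::abort("decline_years must be >= 1")
  if (cfg$depletion_fraction < 0 || cfg$depletion_fraction > 1) {
    rlang::abort("depletion_fraction must be in [0, 1]")
  }
  invisible(cfg)
}

#' Read / write a threshold configuration as YAML
#'
#' @param path File path of a YAML key-value file whose keys mirror the
#'   arguments of [threshold_config()]. Unknown keys are an error.
#' @return [read_threshold_config()] returns a `cots_thresholds` object;
#'   [write_threshold_config()] returns `path` invisibly.
#' @export
read_threshold_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(threshold_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown threshold config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(threshold_config, vals)
}

#' @rdname read_threshold_config
#' @param config A `cots_thresholds` object.
#' @export
write_threshold_config <- function(config, path) {
  stopifnot(inherits(config, "cots_thresholds"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Manta-tow coral cover category scheme
#'
#' The standard manta-tow protocol records hard-coral cover as one of six
#' ordinal categories. Analyses replace each category with the midpoint of its
#' percent-cover bin, expressed as a proportion.
#'
#' @return A tibble with columns `category` (0-5), `lower` and `upper`
#'   (percent-cover bin edges; bins are `(lower, upper]` except category 0
#'   which is exactly zero) and `midpoint` (proportion).
#' @export
#' @examples
#' category_scheme()
category_scheme <- function() {
  tibble::tibble(
    category = 0:5,
    lower = c(0, 0, 10, 30, 50, 75),
    upper = c(0, 10, 30, 50, 75, 100),
    midpoint = c(0, 0.055, 0.205, 0.405, 0.63, 0.88)
  )
}

#' Convert cover categories to bin midpoints
#'
#' @param category Integer vector of ordinal cover codes, 0-5.
#' @param scheme A category scheme, see [category_scheme()].
#' @return Numeric vector of cover proportions.
#' @export
#' @examples
#' category_to_midpoint(c(0, 3, 5))
category_to_midpoint <- function(category, scheme = category_scheme()) {
  if (any(is.na(category)) || any(!category %in% scheme$category)) {
    rlang::abort("cover category outside the scheme (must be one of 0-5)")
  }
  scheme$midpoint[match(category, scheme$category)]
}

#' Bin a cover proportion into its ordinal category
#'
#' Inverse of [category_to_midpoint()] for noiseless data: a proportion equal
#' to a bin midpoint maps back to that bin.
#'
#' @param cover Numeric vector of cover proportions in `[0, 1]`.
#' @inheritParams category_to_midpoint
#' @return Integer vector of categories 0-5.
#' @export
cover_to_category <- function(cover, scheme = category_scheme()) {
  if (any(is.na(cover)) || any(cover < 0 | cover > 1)) {
    rlang::abort("cover must be a proportion in [0, 1]")
  }
  pct <- cover * 100
  # bins are (lower, upper]; exactly-zero cover is its own category
  out <- findInterval(pct, c(scheme$upper[-nrow(scheme)]), left.open = TRUE)
  out[pct == 0] <- 0L
  as.integer(out)
}

#' MCMC sampler settings for the hierarchical models
#'
#' Defaults follow the study protocol for the comparative models: three
#' chains of 4000 iterations each, the first 25% (1000 iterations) discarded
#' as burn-in, and the remainder thinned at five-step intervals, giving 1800
#' retained draws.
#'
#' @param chains Number of chains.
#' @param iterations Total iterations per chain, including burn-in.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param thin Thinning interval applied after burn-in.
#' @param prior_sd_fixed Prior SD for standardized fixed effects
#'   (normal, mean 0).
#' @param prior_sd_sd Scale of the half-normal priors on random-effect and
#'   residual SDs.
#' @return A list of class `cots_model_spec`.
#' @export
model_spec <- function(chains = 3L,
                       iterations = 4000L,
                       burn_in = 1000L,
                       thin = 5L,
                       prior_sd_fixed = 2.5,
                       prior_sd_sd = 1) {
  spec <- list(
    chains = as.integer(chains),
    iterations = as.integer(iterations),
    burn_in = as.integer(burn_in),
    thin = as.integer(thin),
    prior_sd_fixed = prior_sd_fixed,
    prior_sd_sd = prior_sd_sd
  )
  if (spec$chains < 1L || spec$iterations <= spec$burn_in || spec$thin < 1L) {
    rlang::abort("invalid MCMC settings: need chains >= 1, iterations > burn_in, thin >= 1")
  }
  structure(spec, class = "cots_model_spec")
}

# round half away from zero, the convention used in the report tables
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
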