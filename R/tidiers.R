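#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted model
#'
#' @param x A `cots_cover_fit`, `cots_wave_fit`, `cots_effort_fit` or
#'   `cots_gam_fit` object.
#' @param ... Unused.
#' @return A tibble of posterior summaries (or fitted curves for the
#'   smoother), one row per reported estimand.
#' @export
tidy.cots_cover_fit <- function(x, ...) x$summaries

#' @rdname tidy.cots_cover_fit
#' @export
tidy.cots_wave_fit <- function(x, ...) x$summaries

#' @rdname tidy.cots_cover_fit
#' @export
tidy.cots_effort_fit <- function(x, ...) x$summaries

#' @rdname tidy.cots_cover_fit
#' @export
tidy.cots_gam_fit <- function(x, ...) x$curves

#' One-row model-level diagnostics
#'
#' @param x A fitted model object from this package.
#' @param ... Unused.
#' @return A tibble with convergence diagnostics (per sector for the cover
#'   model): maximum rhat over reported estimands, convergence flag, and the
#'   MCMC settings used.
#' @export
glance.cots_cover_fit <- function(x, ...) {
  purrr::imap_dfr(x$diagnostics, function(d, sec) {
    tibble::tibble(sector_id = sec, rhat_max = d$rhat_max_estimands,
                   converged = d$converged, n_chains = d$n_chains,
                   n_iter = d$n_iter, burn_in = d$burn_in, thin = d$thin,
                   n_draws = d$n_draws)
  })
}

#' @rdname glance.cots_cover_fit
#' @export
glance.cots_wave_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(response = x$response, rhat_max = d$rhat_max_estimands,
                 converged = d$converged, n_chains = d$n_chains,
                 n_iter = d$n_iter, burn_in = d$burn_in, thin = d$thin,
                 n_draws = d$n_draws)
}

#' @rdname glance.cots_cover_fit
#' @export
glance.cots_effort_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(rhat_max = d$rhat_max_estimands, converged = d$converged,
                 n_chains = d$n_chains, n_iter = d$n_iter,
                 burn_in = d$burn_in, thin = d$thin, n_draws = d$n_draws)
}

#' @rdname glance.cots_cover_fit
#' @export
glance.cots_gam_fit <- function(x, ...) {
  purrr::imap_dfr(x$models, function(m, name) {
    tibble::tibble(group = name, edf = sum(m$edf), n = stats::nobs(m),
                   deviance = stats::deviance(m))
  })
}
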