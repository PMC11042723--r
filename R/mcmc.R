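# Internal JAGS plumbing shared by the hierarchical models.
# Chains are seeded deterministically from the user seed so that repeated
# runs with the same seed produce identical summaries.

run_jags <- function(model_string, data, monitor, spec, seed) {
  # block updaters for linear sub-graphs; markedly better mixing than
  # single-site Gibbs on the cell-mean + random-intercept models
  rjags::load.module("glm", quiet = TRUE)
  inits <- lapply(seq_len(spec$chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (abs(as.integer(seed)) %% 1000000L) * 100L + k)
  })
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  model <- rjags::jags.model(con, data = data, inits = inits,
                             n.chains = spec$chains, quiet = TRUE)
  stats::update(model, n.iter = spec$burn_in, progress.bar = "none")
  rjags::coda.samples(model, variable.names = monitor,
                      n.iter = spec$iterations - spec$burn_in,
                      thin = spec$thin, progress.bar = "none")
}

rhat_table <- function(samples) {
  params <- colnames(samples[[1]])
  rhat <- rep(NA_real_, length(params))
  gd <- try(coda::gelman.diag(samples, multivariate = FALSE,
                              autoburnin = FALSE), silent = TRUE)
  if (!inherits(gd, "try-error")) {
    rhat <- gd$psrf[match(params, rownames(gd$psrf)), 1]
  }
  tibble::tibble(parameter = params, rhat = unname(rhat))
}

# stack chains into one draw matrix (rows = retained draws)
draw_matrix <- function(samples) {
  do.call(rbind, lapply(samples, as.matrix))
}

make_diagnostics <- function(samples, spec, estimands, note = NULL) {
  rt <- rhat_table(samples)
  est <- rt[rt$parameter %in% estimands, ]
  list(
    rhat = rt,
    rhat_max_estimands = if (nrow(est) > 0) max(est$rhat, na.rm = TRUE) else NA_real_,
    converged = nrow(est) > 0 && all(!is.na(est$rhat)) && all(est$rhat < 1.01),
    n_chains = spec$chains,
    n_iter = spec$iterations,
    burn_in = spec$burn_in,
    thin = spec$thin,
    n_draws = spec$chains * nrow(samples[[1]]),
    note = note
  )
}

check_strict <- function(diagnostics, strict, what) {
  if (strict && !diagnostics$converged) {
    rlang::abort(paste0(what, ": rhat >= 1.01 on reported estimands (strict mode)"))
  }
  if (!diagnostics$converged) {
    rlang::warn(paste0(what, ": rhat >= 1.01 on reported estimands; result flagged"))
  }
  invisible(diagnostics)
}

#' Summarise a posterior sample
#'
#' Median, central 66% and 90% credible intervals, and the probability of
#' direction (the percentage of posterior mass on the dominant side of
#' zero).
#'
#' @param draws Numeric vector of at least 500 post-burn-in draws.
#' @param label Name attached to the summary row.
#' @return One-row tibble: `label`, `median`, `ci66_lo`, `ci66_hi`,
#'   `ci90_lo`, `ci90_hi`, `prob_direction`.
#' @export
#' @examples
#' posterior_summary(rnorm(2000), "z")
posterior_summary <- function(draws, label = "effect") {
  draws <- as.numeric(draws)
  if (length(draws) < 500) {
    rlang::abort("posterior_summary needs at least 500 draws")
  }
  q <- stats::quantile(draws, c(0.05, 0.17, 0.5, 0.83, 0.95), names = FALSE)
  tibble::tibble(
    label = label,
    median = q[3],
    ci66_lo = q[2], ci66_hi = q[4],
    ci90_lo = q[1], ci90_hi = q[5],
    prob_direction = 100 * max(mean(draws >= 0), mean(draws <= 0))
  )
}

summarise_draw_matrix <- function(mat, labels) {
  purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    posterior_summary(mat[, j], labels[j])
  })
}

#' Fold change between two medians
#'
#' @param median_a Numerator (e.g. the earlier outbreak wave's median
#'   density).
#' @param median_b Denominator; must be positive.
#' @return `median_a / median_b`.
#' @export
#' @examples
#' fold_change(1.50, 0.21) # ~7-fold
fold_change <- function(median_a, median_b) {
  if (any(is.na(median_b)) || any(median_b <= 0)) {
    rlang::abort("median_b must be positive")
  }
  median_a / median_b
}
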