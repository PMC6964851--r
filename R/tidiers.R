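#' Tidy a richness-model fit
#'
#' One row per parameter with posterior mean, standard deviation,
#' equal-tailed 95% credible interval and the Gelman-Rubin PSRF. Protocol
#' detection rates (`lambda_*` terms, `exp(eta)`) are appended after the
#' sampled parameters.
#'
#' @param x A `richness_fit`.
#' @param ... Unused.
#' @return A tibble `term, estimate, std.error, conf.low, conf.high, psrf`.
#' @method tidy richness_fit
#' @export
tidy.richness_fit <- function(x, ...) {
  pars <- x$psrf$parameter
  draw_cols <- x$draws[pars]
  summarise_one <- function(v, term, psrf) {
    ci <- unname(stats::quantile(v, c(0.025, 0.975)))
    tibble::tibble(term = term, estimate = mean(v), std.error = stats::sd(v),
                   conf.low = ci[1], conf.high = ci[2], psrf = psrf)
  }
  base <- purrr::map2_dfr(draw_cols, pars, function(v, p) {
    summarise_one(v, p, x$psrf$psrf[x$psrf$parameter == p])
  })
  rates <- purrr::map_dfr(x$protocols, function(p) {
    summarise_one(rate_draws(x, p), paste0("lambda_", p), NA_real_)
  })
  dplyr::bind_rows(base, rates)
}

#' Glance at a richness-model fit
#'
#' @param x A `richness_fit`.
#' @param ... Unused.
#' @return A one-row tibble: chain/iteration counts, pooled retained draws,
#'   maximum PSRF, minimum effective sample size, convergence flag.
#' @method glance richness_fit
#' @export
glance.richness_fit <- function(x, ...) {
  tibble::tibble(
    n_chains = x$config$n_chains,
    n_iter = x$config$n_iter,
    n_retained = x$n_retained,
    max_psrf = max(x$psrf$psrf),
    min_ess = min(x$psrf$ess),
    converged = x$converged
  )
}
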