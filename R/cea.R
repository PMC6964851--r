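#' Cost per species detected
#'
#' Combines a protocol's average marginal cost with the posterior uncertainty
#' in how many species it detects per transect: each posterior rate draw
#' `lambda` yields one cost-per-species draw `cost / lambda`. The summary is
#' the draw mean and the equal-tailed 95% credible interval (2.5% and 97.5%
#' quantiles). Because `1/lambda` is convex, the mean cost per species
#' exceeds cost divided by the mean rate (Jensen's inequality).
#'
#' @param mean_marginal_cost A single non-negative cost (AUD), typically a
#'   grid mean from [scenario_summary()].
#' @param rate_draws Posterior draws of the protocol detection rate
#'   ([rate_draws()]); at least 1000, all strictly positive.
#' @return A list of class `cea_result`: `draws`, `mean`, `ci_lower`,
#'   `ci_upper`.
#' @export
#' @examples
#' cost_per_species(3449, rgamma(5000, 53, 10))
cost_per_species <- function(mean_marginal_cost, rate_draws) {
  if (length(mean_marginal_cost) != 1 || mean_marginal_cost < 0) {
    stop("mean_marginal_cost must be a single non-negative number",
         call. = FALSE)
  }
  if (length(rate_draws) < 1000) {
    stop("at least 1000 rate draws are required (got ", length(rate_draws),
         ")", call. = FALSE)
  }
  if (any(rate_draws <= 0)) {
    stop("rate draws must be strictly positive", call. = FALSE)
  }
  draws <- mean_marginal_cost / rate_draws
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  structure(
    list(draws = draws, mean = mean(draws),
         ci_lower = ci[1], ci_upper = ci[2]),
    class = "cea_result"
  )
}

#' Cost-effectiveness of every protocol on a scenario grid
#'
#' For each requested protocol: the mean marginal cost over the grid divided,
#' draw by draw, by the protocol's posterior detection-rate draws. With
#' `propagate_cost = TRUE` the spread of marginal cost over the grid is also
#' propagated (every grid scenario crossed with every rate draw) — a
#' sensitivity mode; the default reproduces the study's scalar-cost
#' treatment, where only detection uncertainty enters the interval.
#'
#' @param fit A [run_mcmc()] fit of the richness model.
#' @param profiles Cost profiles tibble ([load_cost_profiles()]).
#' @param grid A [scenario_grid()].
#' @param protocols Protocol labels to include (default: all fitted).
#' @param n_draws Number of pooled posterior draws to use (default 10000).
#' @param propagate_cost Also propagate grid spread in marginal cost.
#' @return A tibble of class `cea_tbl`:
#'   `protocol, grid, mean_marginal_cost, mean, ci_lower, ci_upper`
#'   (AUD per species detected), protocols in canonical order.
#' @export
cost_effectiveness <- function(fit, profiles, grid, protocols = NULL,
                               n_draws = 10000, propagate_cost = FALSE) {
  if (is.null(protocols)) protocols <- fit$protocols
  protocols <- vapply(protocols, check_protocol, character(1))
  summaries <- scenario_summary(profiles, grid)
  grid_costs <- marginal_cost_grid(profiles, grid)
  label <- attr(grid, "label") %||% "custom"
  out <- purrr::map_dfr(protocols, function(p) {
    cost <- summaries$mean[summaries$protocol == p]
    if (length(cost) != 1) {
      stop("no cost profile for protocol '", p, "'", call. = FALSE)
    }
    lam <- rate_draws(fit, p, n_draws)
    if (propagate_cost) {
      costs <- grid_costs$marginal_cost[grid_costs$protocol == p]
      draws <- as.vector(outer(costs, lam, `/`))
      ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
      res <- list(mean = mean(draws), ci_lower = ci[1], ci_upper = ci[2])
    } else {
      res <- cost_per_species(cost, lam)
    }
    tibble::tibble(protocol = p, grid = label, mean_marginal_cost = cost,
                   mean = res$mean, ci_lower = res$ci_lower,
                   ci_upper = res$ci_upper)
  }) |>
    dplyr::mutate(protocol = as_protocol(.data$protocol)) |>
    dplyr::arrange(.data$protocol)
  class(out) <- c("cea_tbl", class(out))
  out
}

#' Combine cost-effectiveness results into one report table
#'
#' @param results A list of `cea_tbl` tibbles (e.g. one per grid) or a
#'   single `cea_tbl`.
#' @return One `cea_tbl`, protocols in canonical order within grid; duplicate
#'   protocol/grid pairs or empty input are errors.
#' @export
cea_table <- function(results) {
  if (inherits(results, "cea_tbl")) results <- list(results)
  if (length(results) == 0) stop("no cost-effectiveness results supplied",
                                 call. = FALSE)
  out <- dplyr::bind_rows(results) |>
    dplyr::arrange(.data$grid, .data$protocol)
  if (nrow(out) == 0) stop("no cost-effectiveness results supplied",
                           call. = FALSE)
  if (anyDuplicated(out[, c("protocol", "grid")])) {
    stop("duplicate protocol/grid pairs in cost-effectiveness results",
         call. = FALSE)
  }
  class(out) <- c("cea_tbl", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
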