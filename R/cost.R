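#' Total cost of repeated surveys
#'
#' Evaluates `T(m) = E (1 + r (m - 1)) + m (V + C + h L) + h l + v` per
#' protocol: the equipment outlay `E` is paid once up front and a fraction
#' `r` (the equipment replacement rate) of it again for each repeat survey;
#' vehicle `V`, consumables `C` and wages `h L` recur every survey; the
#' one-off deployment costs `h l + v` (artificial refuges and pitfall traps
#' dug in once) are paid regardless of `m`.
#'
#' @param profiles Cost profiles tibble from [load_cost_profiles()]
#'   (optionally filtered to some protocols).
#' @param r Equipment replacement rate, a fraction in `[0, 1]`.
#' @param h Hourly labour rate, AUD/hour (>= 0).
#' @param m Number of surveys (integer >= 1).
#' @return A tibble `protocol, r, h, m, total_cost` with one row per
#'   profile x scenario; `r`, `h`, `m` are recycled against each other to
#'   form the scenarios.
#' @export
#' @examples
#' total_cost(load_cost_profiles(), r = 0, h = c(0, 55), m = 1)
total_cost <- function(profiles, r = 0, h = 0, m = 1) {
  scen <- scenario_frame(r, h, m)
  tidyr::crossing(profiles, scen) |>
    dplyr::mutate(total_cost = .data$equipment * (1 + .data$r * (.data$m - 1)) +
                    .data$m * (.data$vehicle + .data$consumables +
                                 .data$h * .data$labour_h) +
                    .data$h * .data$deploy_labour_h + .data$deploy_vehicle) |>
    dplyr::select(dplyr::all_of(c("protocol", "r", "h", "m", "total_cost")))
}

#' Marginal cost of one additional survey
#'
#' The derivative of total cost in the number of surveys:
#' `M = r E + V + C + h L`. Independent of `m`, so it governs long-run cost
#' projections.
#'
#' @inheritParams total_cost
#' @return A tibble `protocol, r, h, marginal_cost`.
#' @export
#' @examples
#' marginal_cost(load_cost_profiles(), r = 0.05, h = 30)
marginal_cost <- function(profiles, r = 0, h = 0) {
  scen <- scenario_frame(r, h)
  tidyr::crossing(profiles, scen) |>
    dplyr::mutate(marginal_cost = .data$r * .data$equipment + .data$vehicle +
                    .data$consumables + .data$h * .data$labour_h) |>
    dplyr::select(dplyr::all_of(c("protocol", "r", "h", "marginal_cost")))
}

scenario_frame <- function(r, h, m = NULL) {
  if (any(r < 0 | r > 1)) stop("replacement rate r must be in [0, 1]",
                               call. = FALSE)
  if (any(h < 0)) stop("hourly rate h must be >= 0", call. = FALSE)
  if (!is.null(m) && any(m < 1 | m != round(m))) {
    stop("number of surveys m must be a positive integer", call. = FALSE)
  }
  if (is.null(m)) tibble::tibble(r = r, h = h)
  else tibble::tibble(r = r, h = h, m = m)
}

#' Build a replacement-rate by wage scenario grid
#'
#' The case study sweeps the equipment replacement rate (RoR) in 1%
#' increments from 0% (no losses) to 30% (considerable losses), crossed with
#' hourly wages in $1 increments from $0 (volunteers) to $55 (roughly a
#' senior casual research assistant). Its "realistic" focal region is
#' RoR < 10% and wage > $10, read on the discrete grid as `r <= 0.09` and
#' `h >= 11`.
#'
#' @param kind `"full"` (31 x 56 = 1736 scenarios), `"realistic"`
#'   (10 x 45 = 450 scenarios) or `"custom"` (supply `r_values`/`h_values`).
#' @param r_values,h_values Grid values for a custom grid.
#' @return A tibble `r, h` with one row per scenario; the grid label is kept
#'   in attribute `"label"`.
#' @export
#' @examples
#' nrow(scenario_grid("full"))
scenario_grid <- function(kind = c("full", "realistic", "custom"),
                          r_values = NULL, h_values = NULL) {
  kind <- match.arg(kind)
  if (kind == "full") {
    r_values <- seq(0, 0.30, by = 0.01); h_values <- 0:55
  } else if (kind == "realistic") {
    r_values <- seq(0, 0.09, by = 0.01); h_values <- 11:55
  } else {
    if (is.null(r_values) || is.null(h_values) ||
        length(r_values) == 0 || length(h_values) == 0 ||
        any(!is.finite(r_values)) || any(!is.finite(h_values))) {
      stop("custom grid needs non-empty finite r_values and h_values",
           call. = FALSE)
    }
    if (anyDuplicated(r_values) || anyDuplicated(h_values)) {
      stop("custom grid values must be distinct (is a step size zero?)",
           call. = FALSE)
    }
  }
  if (any(r_values < 0 | r_values > 1) || any(h_values < 0)) {
    stop("grid values outside scenario bounds (0 <= r <= 1, h >= 0)",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(r = r_values, h = h_values)
  attr(grid, "label") <- kind
  grid
}

#' Marginal cost at every grid scenario
#'
#' @param profiles Cost profiles tibble.
#' @param grid A [scenario_grid()].
#' @return A tidy tibble `protocol, r, h, marginal_cost` over the whole grid.
#' @export
marginal_cost_grid <- function(profiles, grid) {
  if (nrow(grid) == 0) stop("empty scenario grid", call. = FALSE)
  marginal_cost(profiles, r = grid$r, h = grid$h)
}

#' Summarise marginal cost over a scenario grid
#'
#' Mean and population (divide-by-N) standard deviation of the marginal cost
#' across every scenario in the grid, per protocol. The grid is treated as
#' the full population of scenarios under consideration, hence the
#' population SD.
#'
#' @inheritParams marginal_cost_grid
#' @return A tibble `protocol, grid, n_scenarios, mean, sd`.
#' @export
#' @examples
#' scenario_summary(load_cost_profiles(), scenario_grid("full"))
scenario_summary <- function(profiles, grid) {
  label <- attr(grid, "label")
  if (is.null(label)) label <- "custom"
  marginal_cost_grid(profiles, grid) |>
    dplyr::group_by(.data$protocol) |>
    dplyr::summarise(
      grid = label,
      n_scenarios = dplyr::n(),
      mean = mean(.data$marginal_cost),
      sd = sqrt(mean((.data$marginal_cost - mean(.data$marginal_cost))^2)),
      .groups = "drop"
    )
}
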