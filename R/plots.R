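#' Plot pairwise protocol superiority probabilities
#'
#' Heatmap of the posterior probability that the row protocol detects at
#' least as many species per transect as the column protocol.
#'
#' @param object A `superiority_tbl` from [pairwise_superiority()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot superiority_tbl
#' @export
autoplot.superiority_tbl <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    protocol_x = as_protocol(.data$protocol_x),
    protocol_y = as_protocol(.data$protocol_y)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protocol_y,
                                   y = .data$protocol_x,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), name = "P(X ≥ Y)") +
    ggplot2::scale_y_discrete(limits = rev(protocol_levels())) +
    ggplot2::labs(x = "protocol Y", y = "protocol X",
                  title = "P(row detects ≥ species than column)")
}

#' Plot cost per species detected
#'
#' Point-and-interval plot of the posterior mean cost per species with 95%
#' credible intervals, grouped by scenario grid.
#'
#' @param object A `cea_tbl` from [cost_effectiveness()] or [cea_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cea_tbl
#' @export
autoplot.cea_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protocol, y = .data$mean / 1000,
                                   colour = .data$grid)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lower / 1000,
                   ymax = .data$ci_upper / 1000),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::labs(x = "survey protocol",
                  y = "cost ($'000) per species detected",
                  colour = "scenario grid")
}

#' Plot total cost against number of surveys
#'
#' Total-cost trajectories for chosen protocols at chosen
#' replacement-rate/wage scenarios.
#'
#' @param profiles Cost profiles tibble.
#' @param protocols Protocol labels to draw.
#' @param scenarios A tibble with columns `r` and `h` (one line per
#'   protocol x scenario).
#' @param m_max Largest survey count on the x axis.
#' @return A ggplot object.
#' @export
plot_total_cost <- function(profiles,
                            protocols = c("CT-74", "AR"),
                            scenarios = tibble::tibble(r = c(0, 0.30),
                                                       h = c(0, 55)),
                            m_max = 10) {
  keep <- dplyr::filter(profiles, .data$protocol %in% protocols)
  df <- purrr::pmap_dfr(scenarios, function(r, h) {
    total_cost(keep, r = r, h = h, m = seq_len(m_max)) |>
      dplyr::mutate(scenario = sprintf("RoR %.0f%%, $%g/h", 100 * r, h))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$total_cost / 1000,
                                   colour = .data$protocol,
                                   linetype = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of surveys (m)", y = "total cost ($'000)",
                  colour = "protocol", linetype = "scenario")
}
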