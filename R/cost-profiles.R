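#' Load per-protocol survey cost profiles
#'
#' Reads the cost components of running each survey protocol once: equipment
#' outlay `E` (AUD, a sunk cost subject to a replacement rate in repeat
#' surveys), per-survey vehicle cost `V` (AUD), consumables `C` (AUD), labour
#' hours `L`, and the one-off deployment costs for artificial refuges and
#' pitfall traps — labour hours `l` and vehicle cost `v`. Camera-only
#' protocols have no such deployment line: blank cells are read as zero.
#'
#' The expected CSV is wide, header `item,All-74,CT-74,All-16,CT-16,LI,AR,PF`
#' with rows `equipment`, `vehicle`, `consumables`, `labour_h`,
#' `deploy_labour_h`, `deploy_vehicle`. With `source = NULL` the packaged
#' case-study profile table is loaded.
#'
#' @param source Path to a CSV file, or `NULL` for the packaged fixture.
#' @return A tibble with one row per protocol (canonical order) and columns
#'   `protocol`, `equipment`, `vehicle`, `consumables`, `labour_h`,
#'   `deploy_labour_h`, `deploy_vehicle`.
#' @export
#' @examples
#' load_cost_profiles()
load_cost_profiles <- function(source = NULL) {
  if (is.null(source)) source <- trapcost_example("cost_profiles.csv")
  wide <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  items <- c("equipment", "vehicle", "consumables", "labour_h",
             "deploy_labour_h", "deploy_vehicle")
  if (!"item" %in% names(wide)) {
    stop("cost profile table must have an 'item' column", call. = FALSE)
  }
  missing_items <- setdiff(items, wide$item)
  if (length(missing_items) > 0) {
    stop("cost profile table is missing row(s): ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  missing_proto <- setdiff(protocol_levels(), names(wide))
  if (length(missing_proto) > 0) {
    stop("cost profile table is missing protocol column(s): ",
         paste(missing_proto, collapse = ", "), call. = FALSE)
  }
  profiles <- wide |>
    tidyr::pivot_longer(dplyr::all_of(protocol_levels()),
                        names_to = "protocol", values_to = "value") |>
    dplyr::mutate(value = dplyr::coalesce(.data$value, 0)) |>
    tidyr::pivot_wider(names_from = "item", values_from = "value") |>
    dplyr::mutate(protocol = as_protocol(.data$protocol)) |>
    dplyr::arrange(.data$protocol) |>
    dplyr::select(dplyr::all_of(c("protocol", items)))
  bad <- vapply(items, function(i) any(profiles[[i]] < 0), logical(1))
  if (any(bad)) {
    stop("negative cost component(s): ", paste(items[bad], collapse = ", "),
         call. = FALSE)
  }
  profiles
}
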