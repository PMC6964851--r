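#' Reconstruct a species-by-transect detection incidence cube
#'
#' The case study publishes, per species, only the *number* of transects with
#' a detection under each protocol — not which transects. This operation
#' builds one canonical boolean incidence array (species x transect x base
#' method, methods `CT-16`, `CT-74`, `AR`, `PF`) whose protocol marginals
#' (after the unions `LI = AR | PF`, `All-16 = CT-16 | LI`,
#' `All-74 = CT-74 | LI`, with `CT-16` a subset of `CT-74`) match every
#' printed count exactly.
#'
#' The reconstruction is deterministic: species are processed in table order
#' and, at each choice, transects are preferred in ascending order of the
#' running total of detections already assigned (ties broken by ascending
#' transect index), which spreads detections evenly across transects. The
#' required overlap between each camera layer and the labour-intensive
#' transect set follows from inclusion-exclusion on the printed counts
#' (`|CT-x & LI| = CT-x + LI - All-x`), so any valid reconstruction shares
#' those overlap sizes; only the transect identities are a convention.
#'
#' @param table A validated detection table ([load_detection_table()]).
#' @param n_transects Number of transects (default 10).
#' @return An incidence cube: a long tibble with columns `species`,
#'   `transect`, `method`, `present` (one row per species x transect x base
#'   method) and class `incidence_cube`.
#' @export
#' @examples
#' cube <- reconstruct_incidence(load_detection_table())
#' species_detected_count(cube, "AR")
reconstruct_incidence <- function(table, n_transects = 10) {
  validate_detection_table(table, n_transects = n_transects)
  n <- n_transects
  methods <- base_methods()
  species <- table$species
  layers <- lapply(methods, function(m) {
    matrix(FALSE, nrow = length(species), ncol = n,
           dimnames = list(species, NULL))
  })
  names(layers) <- methods
  load <- numeric(n) # running detections per transect, across species/methods

  for (k in seq_along(species)) {
    row <- table[k, ]
    ct74 <- row[["CT-74"]]; ct16 <- row[["CT-16"]]
    ar <- row[["AR"]]; pf <- row[["PF"]]; li <- row[["LI"]]
    a16 <- row[["All-16"]]; a74 <- row[["All-74"]]
    k_both <- ar + pf - li          # |AR & PF|
    o74 <- ct74 + li - a74          # |CT-74 & LI|
    o16 <- ct16 + li - a16          # |CT-16 & LI|
    if (k_both < 0 || o74 < 0 || o16 < 0 || o16 > o74) {
      stop("infeasible marginals for species '", species[k], "'",
           call. = FALSE)
    }
    pick <- function(size, from) {
      if (size > length(from)) {
        stop("infeasible marginals for species '", species[k], "'",
             call. = FALSE)
      }
      from[order(load[from], from)][seq_len(size)]
    }
    assign_cells <- function(method, transects) {
      layers[[method]][k, transects] <<- TRUE
      load[transects] <<- load[transects] + 1
    }
    li_set <- pick(li, seq_len(n))
    both <- pick(k_both, li_set)
    assign_cells("AR", both); assign_cells("PF", both)
    ar_only <- pick(ar - k_both, setdiff(li_set, both))
    assign_cells("AR", ar_only)
    pf_only <- setdiff(li_set, c(both, ar_only))
    assign_cells("PF", pf_only)

    ct74_in <- pick(o74, li_set)
    ct74_out <- pick(ct74 - o74, setdiff(seq_len(n), li_set))
    assign_cells("CT-74", c(ct74_in, ct74_out))
    ct16_in <- pick(o16, ct74_in)
    ct16_out <- pick(ct16 - o16, ct74_out)
    assign_cells("CT-16", c(ct16_in, ct16_out))
  }

  cube <- layers_to_cube(layers, species, n)
  new_incidence_cube(cube, n_transects = n, species = species)
}

# stack base-method layer matrices into the long cube tibble
layers_to_cube <- function(layers, species, n_transects) {
  cube <- tidyr::expand_grid(species = species,
                             transect = seq_len(n_transects),
                             method = names(layers))
  idx <- cbind(match(cube$species, species), cube$transect)
  present <- logical(nrow(cube))
  for (m in names(layers)) {
    sel <- cube$method == m
    present[sel] <- layers[[m]][idx[sel, , drop = FALSE]]
  }
  cube$present <- present
  cube
}

new_incidence_cube <- function(cube, n_transects, species) {
  cube <- tibble::as_tibble(cube)
  attr(cube, "n_transects") <- n_transects
  attr(cube, "species") <- species
  class(cube) <- c("incidence_cube", class(cube))
  cube
}

# species x transect logical matrix for one base method
method_layer <- function(cube, method) {
  species <- attr(cube, "species")
  n <- attr(cube, "n_transects")
  sub <- cube[cube$method == method, ]
  m <- matrix(FALSE, nrow = length(species), ncol = n,
              dimnames = list(species, NULL))
  m[cbind(match(sub$species, species), sub$transect)] <- sub$present
  m
}

#' Species-by-transect presence under one protocol
#'
#' Applies the protocol unions to an incidence cube's four base-method
#' layers and returns a logical species x transect matrix.
#'
#' @param cube An [reconstruct_incidence()] cube.
#' @param protocol One of [protocol_levels()].
#' @return Logical matrix, species in rows, transects in columns.
#' @export
protocol_layer <- function(cube, protocol) {
  check_protocol(protocol)
  switch(protocol,
    "CT-16" = method_layer(cube, "CT-16"),
    "CT-74" = method_layer(cube, "CT-74"),
    "AR" = method_layer(cube, "AR"),
    "PF" = method_layer(cube, "PF"),
    "LI" = method_layer(cube, "AR") | method_layer(cube, "PF"),
    "All-16" = method_layer(cube, "CT-16") | method_layer(cube, "AR") |
      method_layer(cube, "PF"),
    "All-74" = method_layer(cube, "CT-74") | method_layer(cube, "AR") |
      method_layer(cube, "PF")
  )
}

#' Species richness per protocol and transect
#'
#' Builds the response of the detection-effectiveness model: `s_ij`, the
#' number of species detected by protocol `i` at transect `j`, from an
#' incidence cube (unions applied for the derived protocols).
#'
#' @param cube An incidence cube.
#' @return A tibble with columns `protocol` (factor, canonical order),
#'   `transect` and `species_detected`, 7 x n_transects rows.
#' @export
#' @examples
#' richness_matrix(reconstruct_incidence(load_detection_table()))
richness_matrix <- function(cube) {
  purrr::map_dfr(protocol_levels(), function(p) {
    tibble::tibble(
      protocol = p,
      transect = seq_len(attr(cube, "n_transects")),
      species_detected = as.integer(colSums(protocol_layer(cube, p)))
    )
  }) |>
    dplyr::mutate(protocol = as_protocol(.data$protocol))
}

# richness tibble (or matrix) -> protocols x transects integer matrix
as_richness_wide <- function(s) {
  if (is.matrix(s)) return(s)
  stopifnot(all(c("protocol", "transect", "species_detected") %in% names(s)))
  wide <- tidyr::pivot_wider(s, names_from = "transect",
                             values_from = "species_detected")
  m <- as.matrix(wide[, -1])
  rownames(m) <- as.character(wide$protocol)
  storage.mode(m) <- "double"
  m
}

#' Number of species detected anywhere by a protocol
#'
#' @param cube An incidence cube.
#' @param protocol One of [protocol_levels()].
#' @return Integer: species with presence on at least one transect.
#' @export
#' @examples
#' cube <- reconstruct_incidence(load_detection_table())
#' species_detected_count(cube, "CT-74")
species_detected_count <- function(cube, protocol) {
  sum(rowSums(protocol_layer(cube, protocol)) > 0)
}

#' Write / read an incidence cube as long-format CSV
#'
#' Columns `species,transect,method,present` with method one of the four
#' base methods; `present` written as 0/1.
#'
#' @param cube An incidence cube.
#' @param path File path.
#' @return `write_incidence()` returns `path` invisibly; `read_incidence()`
#'   returns an incidence cube.
#' @export
write_incidence <- function(cube, path) {
  out <- dplyr::mutate(tibble::as_tibble(cube),
                       present = as.integer(.data$present))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_incidence
#' @param n_transects Number of transects (defaults to the maximum transect
#'   index present).
#' @export
read_incidence <- function(path, n_transects = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("species", "transect", "method", "present") %in% names(raw)))
  if (!all(raw$method %in% base_methods())) {
    stop("incidence methods must be one of: ",
         paste(base_methods(), collapse = ", "), call. = FALSE)
  }
  raw$present <- as.logical(raw$present)
  if (is.null(n_transects)) n_transects <- max(raw$transect)
  new_incidence_cube(raw, n_transects = n_transects,
                     species = unique(raw$species))
}

#' Describe a survey design
#'
#' Captures the field-effort quantities of the case-study design: ten ~100 m
#' transects, each with four pitfall traps, two artificial-refuge arrays and
#' four camera traps; sixteen labour-intensive survey days inspected twice
#' daily; 69 effective camera days (74 deployed minus 5 maintenance days).
#'
#' @param n_transects,pitfalls_per_transect,ar_arrays_per_transect
#'   Transect count and devices per transect.
#' @param cameras_per_transect Camera traps per transect.
#' @param li_days Days of labour-intensive surveying.
#' @param ct_days Effective camera-trap days of deployment.
#' @param inspections_per_day Labour-intensive inspections per day.
#' @return A list of class `survey_design`.
#' @export
survey_design <- function(n_transects = 10, pitfalls_per_transect = 4,
                          ar_arrays_per_transect = 2,
                          cameras_per_transect = 4, li_days = 16,
                          ct_days = 69, inspections_per_day = 2) {
  design <- list(
    n_transects = n_transects,
    pitfalls_per_transect = pitfalls_per_transect,
    ar_arrays_per_transect = ar_arrays_per_transect,
    cameras_per_transect = cameras_per_transect,
    li_days = li_days,
    ct_days = ct_days,
    inspections_per_day = inspections_per_day
  )
  bad <- vapply(design, function(x) {
    !is.numeric(x) || length(x) != 1 || x < 0 || x != round(x)
  }, logical(1))
  if (any(bad)) {
    stop("survey design fields must be non-negative integers: ",
         paste(names(design)[bad], collapse = ", "), call. = FALSE)
  }
  structure(design, class = "survey_design")
}

#' Summarise survey effort
#'
#' Trap-days and inspection counts implied by a survey design. Camera-trap
#' days accept an explicit outage adjustment (e.g. failed units), since
#' realized outages are survey-specific and not derivable from the design.
#'
#' @param design A [survey_design()].
#' @param camera_outage_days Total camera-days lost to failures/outages.
#' @return A tibble with columns `quantity` and `value`: pitfall trap-days,
#'   artificial-refuge trap-days, total labour-intensive trap-days,
#'   inspections, and camera-trap-days.
#' @export
#' @examples
#' survey_effort(survey_design())
survey_effort <- function(design, camera_outage_days = 0) {
  stopifnot(inherits(design, "survey_design"))
  pf_days <- design$n_transects * design$pitfalls_per_transect * design$li_days
  ar_days <- design$n_transects * design$ar_arrays_per_transect * design$li_days
  li_days <- pf_days + ar_days
  tibble::tibble(
    quantity = c("pitfall_trap_days", "ar_trap_days", "li_trap_days",
                 "inspections", "camera_trap_days"),
    value = c(
      pf_days, ar_days, li_days,
      li_days * design$inspections_per_day,
      design$cameras_per_transect * design$n_transects * design$ct_days -
        camera_outage_days
    )
  )
}
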