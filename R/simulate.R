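#' Protocol log-rates matching the case-study data
#'
#' The per-transect detection rates implied by the packaged detection table:
#' each protocol's column sum divided by the 10 transects, on the log scale.
#' These are the default generating values for [simulate_richness()], so
#' simulations reproduce the study's conditions.
#'
#' @return Named numeric vector of length 7 (log rates).
#' @export
#' @examples
#' exp(study_log_rates())
study_log_rates <- function() {
  tbl <- load_detection_table()
  counts <- vapply(protocol_levels(), function(p) sum(tbl[[p]]), numeric(1))
  log(counts / 10)
}

#' Simulate a richness matrix from the hierarchical Poisson model
#'
#' Forward-simulates the detection-effectiveness model: transect effects
#' `gamma_j ~ Normal(0, theta^2)`, then
#' `s_ij ~ Poisson(exp(eta_i + gamma_j))`. Defaults reproduce the study
#' conditions: 7 protocols at the case-study rates ([study_log_rates()]),
#' 10 transects, and moderate transect heterogeneity `theta = 0.3`.
#'
#' @param eta Named vector of true protocol log-rates.
#' @param theta True transect-effect standard deviation (>= 0).
#' @param n_transects Number of transects.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list: `richness` (tibble `protocol, transect,
#'   species_detected`), and the generating `eta`, `gamma`, `theta`.
#' @export
#' @examples
#' sim <- simulate_richness(seed = 42)
#' head(sim$richness)
simulate_richness <- function(eta = study_log_rates(), theta = 0.3,
                              n_transects = 10, seed = 1) {
  stopifnot(theta >= 0, n_transects >= 1)
  if (is.null(names(eta))) names(eta) <- paste0("p", seq_along(eta))
  set.seed(seed)
  gamma <- stats::rnorm(n_transects, 0, theta)
  lambda <- exp(outer(eta, gamma, `+`))
  s <- matrix(stats::rpois(length(lambda), lambda), nrow = length(eta),
              dimnames = list(names(eta), NULL))
  richness <- tidyr::expand_grid(protocol = names(eta),
                                 transect = seq_len(n_transects)) |>
    dplyr::mutate(species_detected = s[cbind(match(.data$protocol, names(eta)),
                                             .data$transect)])
  list(richness = richness, eta = eta, gamma = gamma, theta = theta)
}

#' Simulate species-by-transect detection incidence
#'
#' Generates raw detection incidence with the structure the pipeline
#' assumes: each species is present at a transect with probability
#' `occupancy`; where present, each base method detects it independently
#' (`CT-74` with probability `p_ct74`; `CT-16` by thinning `CT-74`
#' detections with probability `p_thin`, which enforces the camera nesting
#' by construction; `AR` and `PF` with their own probabilities). The
#' detection table is derived from the simulated cube by the protocol
#' unions, so it is always feasible for [reconstruct_incidence()]. Default
#' probabilities are matched to the case-study fixture's per-cell detection
#' prevalences.
#'
#' @param n_species,n_transects Dimensions.
#' @param occupancy Probability a species is present at a transect.
#' @param p_ct74,p_thin,p_ar,p_pf Detection probabilities (see above).
#' @param seed Integer seed.
#' @return A list: `table` (a valid detection-table tibble) and `cube`
#'   (the generating incidence cube).
#' @export
#' @examples
#' sim <- simulate_incidence(seed = 7)
#' validate_detection_table(sim$table)
simulate_incidence <- function(n_species = 10, n_transects = 10,
                               occupancy = 0.8, p_ct74 = 0.65,
                               p_thin = 0.65, p_ar = 0.30, p_pf = 0.25,
                               seed = 1) {
  probs <- c(occupancy, p_ct74, p_thin, p_ar, p_pf)
  stopifnot(all(probs >= 0 & probs <= 1), n_species >= 1, n_transects >= 1)
  set.seed(seed)
  species <- sprintf("sim_species_%02d", seq_len(n_species))
  draw <- function(p, mask) {
    matrix(stats::runif(n_species * n_transects) < p, n_species,
           dimnames = list(species, NULL)) & mask
  }
  occupied <- draw(occupancy, TRUE)
  ct74 <- draw(p_ct74, occupied)
  ct16 <- draw(p_thin, ct74)
  ar <- draw(p_ar, occupied)
  pf <- draw(p_pf, occupied)
  layers <- list("CT-16" = ct16, "CT-74" = ct74, "AR" = ar, "PF" = pf)

  cube <- new_incidence_cube(layers_to_cube(layers, species, n_transects),
                             n_transects = n_transects, species = species)

  li <- ar | pf
  counts <- list(
    "All-74" = ct74 | li, "CT-74" = ct74, "All-16" = ct16 | li,
    "CT-16" = ct16, "LI" = li, "AR" = ar, "PF" = pf
  )
  table <- tibble::tibble(
    species = species,
    common_name = paste("Simulated species", seq_len(n_species)),
    size_class = rep(c("small_lizard", "medium_large_lizard", "snake"),
                     length.out = n_species)
  )
  for (p in protocol_levels()) table[[p]] <- as.integer(rowSums(counts[[p]]))
  validate_detection_table(table, n_transects = n_transects)
  list(table = table, cube = cube)
}
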