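# shared fixtures, computed once per test run

.trapcost_cache <- new.env(parent = emptyenv())

fixture_table <- function() {
  if (is.null(.trapcost_cache$table)) {
    .trapcost_cache$table <- load_detection_table()
  }
  .trapcost_cache$table
}

fixture_cube <- function() {
  if (is.null(.trapcost_cache$cube)) {
    .trapcost_cache$cube <- reconstruct_incidence(fixture_table())
  }
  .trapcost_cache$cube
}

fixture_richness <- function() {
  if (is.null(.trapcost_cache$richness)) {
    .trapcost_cache$richness <- richness_matrix(fixture_cube())
  }
  .trapcost_cache$richness
}

fixture_profiles <- function() {
  if (is.null(.trapcost_cache$profiles)) {
    .trapcost_cache$profiles <- load_cost_profiles()
  }
  .trapcost_cache$profiles
}

# full-length study fit (2 chains, 12000 pooled retained draws), shared by the
# model tests and the acceptance checks
fixture_fit <- function() {
  if (is.null(.trapcost_cache$fit)) {
    .trapcost_cache$fit <- run_mcmc(fixture_richness(),
                                    config = mcmc_config(seed = 42))
  }
  .trapcost_cache$fit
}

# independently coded term-by-term log joint density (oracle for
# log_posterior): plain loops, no shared code with the implementation
oracle_log_posterior <- function(eta, gamma, theta, s_mat, spec) {
  if (theta <= 0 || theta >= spec$scale_prior_upper) return(-Inf)
  total <- 0
  for (i in seq_along(eta)) {
    for (j in seq_along(gamma)) {
      lam <- exp(eta[i] + gamma[j])
      total <- total + s_mat[i, j] * log(lam) - lam - lfactorial(s_mat[i, j])
    }
  }
  for (i in seq_along(eta)) {
    total <- total + dnorm(eta[i], spec$prior_intercept_mean,
                           sqrt(spec$prior_intercept_var), log = TRUE)
  }
  for (j in seq_along(gamma)) {
    total <- total + dnorm(gamma[j], 0, theta, log = TRUE)
  }
  total + dunif(theta, 0, spec$scale_prior_upper, log = TRUE)
}
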